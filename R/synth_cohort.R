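#' @title Synthetic cohort generation
#' @name synth_cohort
#' @description
#' Generates synthetic patient cohorts whose genotype mix, covariates,
#' ln-scale metabolic ratios, solanidine concentration, chromatographic peak
#' areas and non-detection pattern follow the reference cohort model (see
#' [sola_ref_params()]). Outcomes are drawn from the published linear model
#' (genotype group, sex, centered age) with homoscedastic normal residuals on
#' the ln scale, the residual SD being calibrated so that an OLS refit
#' attains the published model R-squared.
NULL

# mean and variance of a normal(mean, sd) truncated to [lo, hi]
.truncnorm_moments <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / Z
  v <- sd^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  list(mean = m, var = v)
}

# Variance of the linear predictor X*beta under independent covariates:
# categorical genotype, Bernoulli sex, truncated-normal centered age.
.linpred_variance <- function(beta_genotype, genotype_probs, beta_male,
                              female_prob, beta_age, age_var) {
  p <- genotype_probs / sum(genotype_probs)
  b <- beta_genotype[names(p)]
  vg <- sum(p * b^2) - sum(p * b)^2
  pm <- 1 - female_prob
  vg + beta_male^2 * pm * (1 - pm) + beta_age^2 * age_var
}

#' Calibrate the residual standard deviation to a target model R-squared
#'
#' For a linear model with known coefficients and a known covariate mixture,
#' the population R-squared is Var(Xb) / (Var(Xb) + sigma^2). Inverting gives
#' sigma = sqrt(Var(Xb) * (1 - R2) / R2), where Var(Xb) is the variance of
#' the linear predictor under the genotype / sex / age mixture.
#'
#' @param params List with `beta_genotype` (named vector of genotype
#'   contrasts, reference group coded 0), `beta_male`, `beta_age` and
#'   `r_squared_target` in (0, 1).
#' @param genotype_probs Named probabilities of the genotype groups entering
#'   the model (normalized internally).
#' @param covariate_moments List with `female_prob` and `age_var` (variance
#'   of the centered age covariate).
#' @return The residual standard deviation (ln scale).
#' @export
#' @examples
#' # equal explained and unexplained variance
#' calibrate_residual_sd(
#'   list(beta_genotype = c(a = 0, b = 2), beta_male = 0, beta_age = 0,
#'        r_squared_target = 0.5),
#'   genotype_probs = c(a = 0.5, b = 0.5),
#'   covariate_moments = list(female_prob = 0.5, age_var = 0))
calibrate_residual_sd <- function(params, genotype_probs, covariate_moments) {
  r2 <- params$r_squared_target
  if (!is.numeric(r2) || length(r2) != 1L || r2 <= 0 || r2 >= 1) {
    stop("r_squared_target must lie strictly between 0 and 1")
  }
  v <- .linpred_variance(params$beta_genotype, genotype_probs,
                         params$beta_male, covariate_moments$female_prob,
                         params$beta_age, covariate_moments$age_var)
  sqrt(v * (1 - r2) / r2)
}

#' Build a cohort generator configuration
#'
#' All distributional defaults come from the reference cohort
#' ([sola_ref_params()]): genotype-group frequencies, 341/839 female, age
#' normal(41.3, 11.0) truncated to 18--65 years, and for each of the eight
#' outcomes the published coefficients with residual SD calibrated to the
#' published R-squared. Residual-SD calibration uses the conclusive genotype
#' groups only (the population the models were fitted on); the three
#' inconclusive duplication groups are generated with proxy contrasts but do
#' not enter the calibration.
#'
#' @param n_patients Number of patients to simulate.
#' @param genotype_probs Named probabilities over [genotype_groups()]
#'   (must sum to 1).
#' @param female_prob,age_mean,age_sd,age_range Covariate distribution.
#' @param model_params Named list (one element per outcome in
#'   [sola_outcomes()]) of lists with `intercept`, `beta_male`, `beta_age`,
#'   `beta_genotype` (contrasts for all ten groups), `residual_sd`. Defaults
#'   to the calibrated reference model.
#' @param area_per_nM Chromatographic response factor: peak-area units per
#'   nmol/L of solanidine (default 1000, placing default detection limits in
#'   the same magnitude range as the reference truncation constants).
#' @param lod Named per-analyte limit of detection in area units, or the
#'   string `"calibrated"` (default) to solve for limits reproducing the
#'   reference detection fractions, or `"none"` for fully detected data.
#' @param inhibitor_frac Fraction of patients flagged as CYP2D6-inhibitor
#'   users (default 0).
#' @param inhibitor_effects Named additive ln-scale shifts applied to the
#'   outcomes of inhibitor users. No default is supplied beyond 0: the
#'   reference study reports significance but not effect sizes, so any
#'   non-null effect must be user-specified.
#' @param seed Integer seed recorded in the configuration; `generate_cohort()`
#'   seeds from it.
#' @return A list of class `"sola_cohort_config"`.
#' @export
cohort_config <- function(n_patients,
                          genotype_probs = NULL,
                          female_prob = NULL,
                          age_mean = NULL, age_sd = NULL, age_range = NULL,
                          model_params = NULL,
                          area_per_nM = 1000,
                          lod = "calibrated",
                          inhibitor_frac = 0,
                          inhibitor_effects = NULL,
                          seed = 1L) {
  ref <- sola_ref_params()
  if (is.null(genotype_probs)) genotype_probs <- ref$genotype_probs
  if (is.null(female_prob)) female_prob <- ref$female_prob
  if (is.null(age_mean)) age_mean <- ref$age_mean
  if (is.null(age_sd)) age_sd <- ref$age_sd
  if (is.null(age_range)) age_range <- ref$age_range

  stopifnot(n_patients >= 1,
            abs(sum(genotype_probs) - 1) < 1e-9,
            all(genotype_probs >= 0), all(genotype_probs <= 1),
            female_prob >= 0, female_prob <= 1,
            setequal(names(genotype_probs), genotype_groups()))
  genotype_probs <- genotype_probs[genotype_groups()]

  age_mom <- .truncnorm_moments(age_mean, age_sd, age_range[1], age_range[2])

  if (is.null(model_params)) {
    model_params <- default_model_params(genotype_probs, female_prob,
                                         age_var = age_mom$var)
  }
  for (nm in sola_outcomes()) {
    mp <- model_params[[nm]]
    if (is.null(mp)) stop("model_params missing outcome ", nm)
    if (is.null(mp$residual_sd) || mp$residual_sd < 0) {
      stop("model_params for ", nm, " needs a non-negative residual_sd")
    }
  }

  cfg <- structure(list(
    n_patients = as.integer(n_patients),
    genotype_probs = genotype_probs,
    female_prob = female_prob,
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    age_var = age_mom$var, age_mean_trunc = age_mom$mean,
    model_params = model_params,
    area_per_nM = area_per_nM,
    inhibitor_frac = inhibitor_frac,
    inhibitor_effects = inhibitor_effects,
    seed = as.integer(seed)
  ), class = "sola_cohort_config")

  cfg$lod <- if (identical(lod, "calibrated")) {
    calibrate_lod(cfg, sola_ref_params()$detection_frac)
  } else if (identical(lod, "none")) {
    stats::setNames(rep(0, length(sola_analytes())), sola_analytes())
  } else {
    stopifnot(is.numeric(lod), setequal(names(lod), sola_analytes()))
    lod[sola_analytes()]
  }
  cfg
}

#' Default (calibrated) model parameters for the cohort generator
#'
#' @param genotype_probs,female_prob Covariate mixture used for residual-SD
#'   calibration; only the conclusive genotype groups are used (renormalized).
#' @param age_var Variance of the centered age covariate.
#' @return Named list over [sola_outcomes()] of parameter lists with a
#'   calibrated `residual_sd`.
#' @export
default_model_params <- function(genotype_probs = NULL, female_prob = NULL,
                                 age_var = NULL) {
  ref <- sola_ref_params()
  if (is.null(genotype_probs)) genotype_probs <- ref$genotype_probs
  if (is.null(female_prob)) female_prob <- ref$female_prob
  if (is.null(age_var)) {
    age_var <- .truncnorm_moments(ref$age_mean, ref$age_sd,
                                  ref$age_range[1], ref$age_range[2])$var
  }
  concl <- conclusive_groups()
  p_concl <- genotype_probs[concl] / sum(genotype_probs[concl])
  out <- lapply(sola_outcomes(), function(nm) {
    cf <- ref$coefficients[nm, ]
    bg <- c("*1/*1" = 0,
            cf[c("*1/*1xN", "*1/red", "*1/def", "Red/red", "Def/red", "Def/def")])
    names(bg) <- c("*1/*1", "*1/*1xN", "*1/red", "*1/def",
                   "Red/red", "Def/red", "Def/def")
    # inconclusive duplication groups borrow their non-duplicated proxy
    bg[names(.inconclusive_proxy)] <- bg[.inconclusive_proxy]
    p <- list(intercept = unname(cf["intercept"]),
              beta_male = unname(cf["male"]),
              beta_age = unname(cf["age_c"]),
              beta_genotype = bg[genotype_groups()],
              r_squared_target = unname(ref$r_squared[nm]))
    p$residual_sd <- calibrate_residual_sd(
      list(beta_genotype = p$beta_genotype[concl], beta_male = p$beta_male,
           beta_age = p$beta_age, r_squared_target = p$r_squared_target),
      genotype_probs = p_concl,
      covariate_moments = list(female_prob = female_prob, age_var = age_var))
    p
  })
  stats::setNames(out, sola_outcomes())
}

# ln peak area of analyte `a` is, per genotype x sex cell, normal with
# mean ln(area_per_nM) + mu_lnC [+ mu_lnMR] and variance
# beta_age^2 * age_var + sigma^2 summed over the independent outcome draws.
.ln_area_mixture <- function(cfg, analyte) {
  grid <- expand.grid(group = genotype_groups(), male = c(0, 1),
                      stringsAsFactors = FALSE)
  grid$w <- cfg$genotype_probs[grid$group] *
    ifelse(grid$male == 1, 1 - cfg$female_prob, cfg$female_prob)
  comp_mu_var <- function(mp) {
    mu <- mp$intercept + mp$beta_male * grid$male +
      mp$beta_age * (cfg$age_mean_trunc - cfg$age_mean) +
      mp$beta_genotype[grid$group]
    v <- mp$beta_age^2 * cfg$age_var + mp$residual_sd^2
    list(mu = mu, var = rep(v, length(mu)))
  }
  sol <- comp_mu_var(cfg$model_params$ln_sola_conc)
  mu <- log(cfg$area_per_nM) + sol$mu
  v <- sol$var
  if (analyte != "solanidine") {
    mr <- comp_mu_var(cfg$model_params[[paste0("lnMR_", analyte)]])
    mu <- mu + mr$mu
    v <- v + mr$var
  }
  list(w = grid$w, mu = mu, sd = sqrt(v))
}

#' Solve per-analyte detection limits for target detection fractions
#'
#' Under the generator model, the ln peak area of each analyte is a finite
#' mixture of normals over genotype x sex cells; the detection limit
#' reproducing a target detection fraction is the corresponding quantile of
#' that mixture, found by root-finding on the mixture CDF. Deterministic: no
#' simulation involved.
#'
#' @param config A `"sola_cohort_config"` (its `lod` element is ignored).
#' @param detection_frac Named target detected fractions per analyte.
#' @return Named vector of detection limits (area units).
#' @export
calibrate_lod <- function(config, detection_frac = sola_ref_params()$detection_frac) {
  stopifnot(all(sola_analytes() %in% names(detection_frac)))
  out <- vapply(sola_analytes(), function(a) {
    mix <- .ln_area_mixture(config, a)
    target <- 1 - detection_frac[[a]]
    if (target <= 0) return(0)
    cdf <- function(q) sum(mix$w * stats::pnorm(q, mix$mu, mix$sd)) - target
    lo <- min(mix$mu - 10 * mix$sd)
    hi <- max(mix$mu + 10 * mix$sd)
    exp(stats::uniroot(cdf, c(lo, hi), tol = 1e-10)$root)
  }, numeric(1))
  stats::setNames(out, sola_analytes())
}

#' Generate a synthetic patient cohort
#'
#' Draws genotype groups, sex and truncated-normal age; evaluates the eight
#' ln-scale outcome models with independent normal residuals; converts the ln
#' solanidine concentration to a peak area through the `area_per_nM` response
#' factor and each metabolite area as `area_solanidine * exp(lnMR)`; then
#' applies the configured detection limits. Runs with the same configuration
#' (including seed) are bit-reproducible.
#'
#' @param config A `"sola_cohort_config"` from [cohort_config()].
#' @return A data.frame with one row per patient: `id`, `cyp2d6_diplotype`,
#'   `genotype_group`, `phenotype`, `sex`, `age`, `inhibitor_user`,
#'   `solanidine_conc` (nmol/L), `area_<analyte>` and `detected_<analyte>`
#'   columns. The configuration (with seed) is attached as attribute
#'   `"config"`.
#' @export
#' @examples
#' cfg <- cohort_config(50, lod = "none", seed = 42)
#' cohort <- generate_cohort(cfg)
#' table(cohort$phenotype)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sola_cohort_config"))
  n <- config$n_patients
  set.seed(config$seed)

  grp <- sample(genotype_groups(), n, replace = TRUE, prob = config$genotype_probs)
  male <- stats::rbinom(n, 1L, 1 - config$female_prob)
  # inverse-CDF sampling of the truncated normal age
  plo <- stats::pnorm(config$age_range[1], config$age_mean, config$age_sd)
  phi <- stats::pnorm(config$age_range[2], config$age_mean, config$age_sd)
  age <- stats::qnorm(stats::runif(n, plo, phi), config$age_mean, config$age_sd)
  inhibitor <- stats::runif(n) < config$inhibitor_frac

  records <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    cyp2d6_diplotype = unname(.group_diplotype[grp]),
    sex = ifelse(male == 1, "male", "female"),
    age = age,
    inhibitor_user = inhibitor,
    stringsAsFactors = FALSE
  )
  records <- call_phenotypes(records)

  outcomes <- matrix(NA_real_, n, length(sola_outcomes()),
                     dimnames = list(NULL, sola_outcomes()))
  for (nm in sola_outcomes()) {
    mp <- config$model_params[[nm]]
    mu <- mp$intercept + mp$beta_male * male +
      mp$beta_age * (age - config$age_mean) + mp$beta_genotype[grp]
    if (any(inhibitor) && !is.null(config$inhibitor_effects[[nm]])) {
      mu <- mu + config$inhibitor_effects[[nm]] * inhibitor
    }
    outcomes[, nm] <- mu + stats::rnorm(n, 0, mp$residual_sd)
  }

  records$solanidine_conc <- exp(outcomes[, "ln_sola_conc"])
  records$area_solanidine <- records$solanidine_conc * config$area_per_nM
  for (m in sola_analytes()[-1]) {
    records[[paste0("area_", m)]] <-
      records$area_solanidine * exp(outcomes[, paste0("lnMR_", m)])
  }
  records <- apply_lod(records, config$lod)
  attr(records, "config") <- config
  records
}

#' Apply per-analyte detection limits to a patient table
#'
#' Sets `detected_<analyte>` to `areas >= lod`; areas themselves are kept
#' (downstream truncation replaces undetected values).
#'
#' @param records Patient table with `area_<analyte>` columns.
#' @param lod Named per-analyte detection limits (area units, >= 0).
#' @return `records` with refreshed `detected_<analyte>` columns.
#' @export
apply_lod <- function(records, lod) {
  stopifnot(all(sola_analytes() %in% names(lod)))
  for (a in sola_analytes()) {
    records[[paste0("detected_", a)]] <- records[[paste0("area_", a)]] >= lod[[a]]
  }
  records
}

#' Write / read a patient table as tab-separated text
#'
#' The generator seed and detection limits travel in `# key: value` header
#' comments so a written cohort is self-describing.
#'
#' @param records Patient table (from [generate_cohort()] or compatible).
#' @param path File path.
#' @return `read_cohort()` returns the patient table; `write_cohort()` its
#'   `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  cfg <- attr(records, "config")
  if (!is.null(cfg)) {
    writeLines(sprintf("# seed: %d", cfg$seed), con)
    writeLines(sprintf("# lod: %s",
                       paste(sprintf("%s=%.6g", names(cfg$lod), cfg$lod),
                             collapse = " ")), con)
  }
  utils::write.table(records, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  records <- utils::read.table(path, sep = "\t", header = TRUE,
                               comment.char = "#", stringsAsFactors = FALSE)
  call_phenotypes(records)
}
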