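#' @title Genotype/age/sex linear models and group comparisons
#' @name regression
#' @description
#' Ordinary-least-squares models of each ln metabolic ratio (and ln
#' solanidine concentration) on CYP2D6 genotype group, sex and centered age,
#' with Bonferroni-adjusted genotype contrasts against the *1/*1 reference;
#' one-way ANOVA with Dunnett-type many-to-one comparisons; and the
#' inhibitor-use t-tests restricted to *1/*1 carriers.
NULL

.model_rows <- function(ratio_table, outcome) {
  keep <- as.character(ratio_table$genotype_group) %in% conclusive_groups()
  if ("inhibitor_user" %in% names(ratio_table)) {
    keep <- keep & !ratio_table$inhibitor_user
  }
  inc <- sub("^lnMR_", "included_", outcome)
  if (inc != outcome && inc %in% names(ratio_table)) {
    keep <- keep & ratio_table[[inc]]
  }
  ratio_table[keep, , drop = FALSE]
}

#' Fit the genotype/sex/age model for one outcome
#'
#' OLS with terms male sex, age centered on the analysis-sample mean, and the
#' six conclusive genotype-group contrasts against *1/*1 (reference: female,
#' mean age, *1/*1). Inconclusive genotypes, inhibitor users and rows whose
#' per-metabolite inclusion flag is off are dropped first. Genotype-contrast
#' p-values are Bonferroni-multiplied by the number of genotype contrasts;
#' sex and age p-values are unadjusted. Genotype groups absent from the data
#' are dropped with a warning.
#'
#' @param ratio_table Ratio table from [compute_ratios()].
#' @param outcome One of [sola_outcomes()].
#' @return A list of class `"genotype_model_fit"`: `outcome`, `n`,
#'   `coefficients` (data.frame term/B/SE/p/p_adjusted), `r_squared`,
#'   `adj_r_squared`, `sigma`, and the underlying `lm` fit.
#' @export
fit_genotype_model <- function(ratio_table, outcome) {
  stopifnot(outcome %in% sola_outcomes(), outcome %in% names(ratio_table))
  d <- .model_rows(ratio_table, outcome)
  d$genotype_group <- factor(as.character(d$genotype_group),
                             levels = conclusive_groups())
  present <- levels(droplevels(d$genotype_group))
  if (!"*1/*1" %in% present) stop("reference group *1/*1 absent from the data")
  if (length(present) < length(conclusive_groups())) {
    warning("genotype group(s) with no data dropped: ",
            paste(setdiff(conclusive_groups(), present), collapse = ", "))
  }
  d$genotype_group <- factor(as.character(d$genotype_group),
                             levels = intersect(conclusive_groups(), present))
  d$genotype_group <- stats::relevel(d$genotype_group, ref = "*1/*1")
  d$male <- as.integer(d$sex == "male")
  d$age_c <- d$age - mean(d$age)
  d$.y <- d[[outcome]]

  fit <- stats::lm(.y ~ male + age_c + genotype_group, data = d)
  sm <- summary(fit)
  cf <- sm$coefficients
  term <- rownames(cf)
  term[term == "(Intercept)"] <- "intercept"
  term <- sub("^genotype_group", "", term)
  is_geno <- !(term %in% c("intercept", "male", "age_c"))
  k <- sum(is_geno)
  p_adj <- cf[, 4]
  p_adj[is_geno] <- pmin(1, k * p_adj[is_geno])

  structure(list(
    outcome = outcome,
    n = nrow(d),
    coefficients = data.frame(term = term, B = cf[, 1], SE = cf[, 2],
                              p = cf[, 4], p_adjusted = p_adj,
                              row.names = NULL),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    sigma = sm$sigma,
    fit = fit
  ), class = "genotype_model_fit")
}

#' Fit the genotype model for every outcome
#'
#' @param ratio_table Ratio table from [compute_ratios()].
#' @param outcomes Outcomes to fit (default all of [sola_outcomes()]).
#' @return Named list of `"genotype_model_fit"` objects.
#' @export
fit_all_models <- function(ratio_table, outcomes = sola_outcomes()) {
  stats::setNames(lapply(outcomes, fit_genotype_model,
                         ratio_table = ratio_table), outcomes)
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Classical one-way ANOVA across the conclusive genotype groups followed by
#' Dunnett-type comparisons of every group against the control. Adjusted
#' p-values are computed by Monte-Carlo evaluation of the null distribution
#' of the maximum absolute Dunnett t-statistic (pooled variance, group means
#' simulated under the null with the observed group sizes), which avoids
#' multivariate-t quadrature and is easy to verify against a permutation
#' oracle.
#'
#' @param ratio_table Ratio table.
#' @param outcome One of [sola_outcomes()].
#' @param control Control group (default `"*1/*1"`).
#' @param nsim Monte-Carlo draws (default 1e5).
#' @param seed Seed for the Monte-Carlo draws.
#' @return List with `f_statistic`, `p_overall`, and `comparisons`
#'   (data.frame group/n/mean/diff/t/p_adjusted).
#' @export
anova_dunnett <- function(ratio_table, outcome, control = "*1/*1",
                          nsim = 1e5, seed = 1L) {
  d <- .model_rows(ratio_table, outcome)
  g <- droplevels(factor(as.character(d$genotype_group),
                         levels = conclusive_groups()))
  y <- d[[outcome]]
  sizes <- table(g)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("group(s) with fewer than 2 members excluded: ",
            paste(small, collapse = ", "))
    keep <- !(as.character(g) %in% small)
    y <- y[keep]; g <- droplevels(g[keep])
  }
  stopifnot(control %in% levels(g), nlevels(g) >= 2)

  av <- stats::aov(y ~ g)
  ft <- summary(av)[[1]]
  df_err <- ft["Residuals", "Df"]
  s2 <- ft["Residuals", "Mean Sq"]

  others <- setdiff(levels(g), control)
  n0 <- sum(g == control)
  m0 <- mean(y[g == control])
  comp <- data.frame(group = others,
                     n = as.integer(table(g)[others]),
                     mean = vapply(others, function(k) mean(y[g == k]), 0.0))
  comp$diff <- comp$mean - m0
  comp$t <- comp$diff / sqrt(s2 * (1 / comp$n + 1 / n0))

  # null distribution of max |t| over the many-to-one family
  set.seed(seed)
  z0 <- stats::rnorm(nsim, 0, 1 / sqrt(n0))
  s2sim <- stats::rchisq(nsim, df_err) / df_err # shared pooled-variance draw
  maxt <- rep(0, nsim)
  for (i in seq_along(others)) {
    zi <- stats::rnorm(nsim, 0, 1 / sqrt(comp$n[i]))
    ti <- (zi - z0) / sqrt((1 / comp$n[i] + 1 / n0) * s2sim)
    maxt <- pmax(maxt, abs(ti))
  }
  comp$p_adjusted <- vapply(comp$t, function(t) mean(maxt >= abs(t)), 0.0)

  list(f_statistic = ft["g", "F value"],
       p_overall = ft["g", "Pr(>F)"],
       df = c(ft["g", "Df"], df_err),
       comparisons = comp)
}

#' Effect of CYP2D6-inhibitor use in *1/*1 carriers
#'
#' Two-sided Student's t-tests (equal variances) comparing each outcome
#' between *1/*1 inhibitor users and *1/*1 non-users of the reference
#' (test) cohort.
#'
#' @param ratio_table Ratio table containing both inhibitor users and
#'   non-users (genotype group *1/*1 rows are selected internally).
#' @param outcomes Outcomes to compare (default all).
#' @return Data.frame with per-outcome group sizes, means, difference and
#'   p-value (`NA` with a note when a group has fewer than 2 members).
#' @export
inhibitor_comparison <- function(ratio_table, outcomes = sola_outcomes()) {
  d <- ratio_table[as.character(ratio_table$genotype_group) == "*1/*1", ,
                   drop = FALSE]
  stopifnot("inhibitor_user" %in% names(d))
  rows <- lapply(outcomes, function(nm) {
    inc <- sub("^lnMR_", "included_", nm)
    dd <- if (inc != nm && inc %in% names(d)) d[d[[inc]], , drop = FALSE] else d
    yu <- dd[[nm]][dd$inhibitor_user]
    yn <- dd[[nm]][!dd$inhibitor_user]
    out <- data.frame(outcome = nm, n_user = length(yu), n_nonuser = length(yn),
                      mean_user = mean(yu), mean_nonuser = mean(yn),
                      difference = mean(yu) - mean(yn),
                      p_value = NA_real_, stringsAsFactors = FALSE)
    if (length(yu) >= 2 && length(yn) >= 2) {
      out$p_value <- stats::t.test(yu, yn, var.equal = TRUE)$p.value
    }
    out
  })
  do.call(rbind, rows)
}
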