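test_that("residual-sd calibration inverts the R-squared identity", {
  # sigma = sqrt(Var(Xb) (1 - R2) / R2) with Var(Xb) fixed by construction:
  # a two-group contrast of size b at p = 1/2 has Var = b^2/4
  pars <- function(b, r2) list(beta_genotype = c(a = 0, b = b), beta_male = 0,
                               beta_age = 0, r_squared_target = r2)
  mom <- list(female_prob = 0.5, age_var = 0)
  probs <- c(a = 0.5, b = 0.5)
  # equal explained/unexplained variance
  expect_equal(calibrate_residual_sd(pars(2, 0.5), probs, mom), 1.0)
  # arithmetic case: Var(Xb) = 7.76, R2 = 0.688 -> sigma^2 = 7.76 * 0.312/0.688
  b <- 2 * sqrt(7.76)
  expect_equal(calibrate_residual_sd(pars(b, 0.688), probs, mom),
               sqrt(7.76 * 0.312 / 0.688), tolerance = 1e-12)
  # R2 -> 1 limit drives the residual to 0
  expect_lt(calibrate_residual_sd(pars(2, 1 - 1e-9), probs, mom), 1e-3)
  expect_error(calibrate_residual_sd(pars(2, 1), probs, mom), "between 0 and 1")
  expect_error(calibrate_residual_sd(pars(2, 0), probs, mom), "between 0 and 1")
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- cohort_config(10, seed = 123)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("genotype mix and group means follow the configured model", {
  cfg <- cohort_config(100000, lod = "none", seed = 11)
  co <- generate_cohort(cfg)
  # PM fraction ~ 58/839
  expect_equal(mean(co$phenotype == "PM"), 58 / 839, tolerance = 0.06)
  # mean ln M414 ratio in the PM group ~ intercept + Def/def contrast
  rt <- compute_ratios(co)
  pm_mean <- mean(rt$lnMR_M414[rt$phenotype == "PM"])
  expect_equal(pm_mean, 2.90 - 11.2, tolerance = 0.05 * abs(2.90 - 11.2))
})

test_that("an OLS refit recovers coefficients and R-squared (parameter recovery)", {
  cfg <- cohort_config(60000, lod = "none", seed = 21)
  co <- generate_cohort(cfg)
  rt <- compute_ratios(co)
  for (outcome in c("lnMR_M440", "ln_sola_conc")) {
    mp <- cfg$model_params[[outcome]]
    f <- fit_genotype_model(rt, outcome)
    cf <- f$coefficients
    for (g in c("*1/def", "Def/red", "Def/def")) {
      est <- cf$B[cf$term == g]
      se <- cf$SE[cf$term == g]
      expect_lt(abs(est - mp$beta_genotype[[g]]), 3.5 * se)
    }
    expect_equal(f$r_squared, mp$r_squared_target, tolerance = 0.02)
  }
})

test_that("lognormal construction gives the closed-form concentration mean", {
  # single-group configuration: lnC ~ N(mu, sigma^2) exactly
  mp <- default_model_params()
  for (nm in names(mp)) {
    mp[[nm]]$beta_male <- 0
    mp[[nm]]$beta_age <- 0
    mp[[nm]]$beta_genotype[] <- 0
  }
  mu <- mp$ln_sola_conc$intercept
  sigma <- 0.8
  mp$ln_sola_conc$residual_sd <- sigma
  cfg <- cohort_config(200000, model_params = mp, lod = "none", seed = 31)
  co <- generate_cohort(cfg)
  expect_equal(mean(co$solanidine_conc), exp(mu + sigma^2 / 2),
               tolerance = 0.02)
})

test_that("detection limits behave at the extremes and at calibration", {
  cfg <- cohort_config(20000, lod = "none", seed = 41)
  co <- generate_cohort(cfg)
  zero <- setNames(rep(0, 8), sola_analytes())
  inf <- setNames(rep(Inf, 8), sola_analytes())
  expect_true(all(apply_lod(co, zero)$detected_solanidine))
  expect_false(any(apply_lod(co, inf)$detected_M414))
  # calibrated limits reproduce the target detection fractions
  cfg2 <- cohort_config(100000, seed = 42) # lod = "calibrated" default
  co2 <- generate_cohort(cfg2)
  target <- sola_ref_params()$detection_frac
  for (a in c("solanidine", "M412", "M432")) {
    expect_equal(mean(co2[[paste0("detected_", a)]]), target[[a]],
                 tolerance = 0.02)
  }
})

test_that("inhibitor users receive the configured ln-scale shift", {
  cfg <- cohort_config(20000, lod = "none", inhibitor_frac = 0.5,
                       inhibitor_effects = list(lnMR_M414 = -2), seed = 51)
  co <- generate_cohort(cfg)
  rt <- compute_ratios(co)
  d <- rt[rt$genotype_group == "*1/*1", ]
  diff <- mean(d$lnMR_M414[d$inhibitor_user]) -
    mean(d$lnMR_M414[!d$inhibitor_user])
  expect_equal(diff, -2, tolerance = 0.15)
})

test_that("a written cohort reads back with phenotypes intact", {
  cfg <- cohort_config(25, seed = 61)
  co <- generate_cohort(cfg)
  f <- tempfile(fileext = ".tsv")
  write_cohort(co, f)
  back <- read_cohort(f)
  expect_equal(nrow(back), 25)
  expect_equal(as.character(back$phenotype), as.character(co$phenotype))
  expect_equal(back$area_M414, co$area_M414, tolerance = 1e-6)
})
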