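#' Analyte names of the solanidine biomarker panel
#'
#' Solanidine plus its seven serum metabolites, labelled by nominal mass of
#' the protonated molecule. M444 is 3,4-seco-solanidine-3,4-dioic acid; the
#' others are oxidative metabolites not yet structurally assigned.
#'
#' @return Character vector of the eight analyte names, solanidine first.
#' @export
sola_analytes <- function() {
  c("solanidine", "M402", "M412", "M414", "M416", "M432", "M440", "M444")
}

#' Metabolic-ratio outcome names
#'
#' @return Names of the eight ln-scale model outcomes: one
#'   metabolite-to-solanidine ratio per metabolite (`lnMR_M402` ...) plus the
#'   ln solanidine concentration (`ln_sola_conc`).
#' @export
sola_outcomes <- function() {
  c(paste0("lnMR_", sola_analytes()[-1]), "ln_sola_conc")
}

#' Reference parameter set for the solanidine CYP2D6 biomarker model
#'
#' The package's reference parameterization, taken from a large clinical
#' cohort of CYP2D6-genotyped adult TDM patients (n = 839 after exclusion of
#' CYP2D6-inhibitor users): genotype-group counts, covariate summaries, the
#' multiple-linear-regression coefficient matrix for the seven ln
#' metabolite-to-solanidine ratios and the ln solanidine concentration
#' (reference level: female, mean age, *1/*1), the model R-squared values,
#' per-analyte truncation constants (half the minimum detected peak area),
#' per-analyte detection fractions, and the validated ln-scale decision
#' thresholds for predicting the PM phenotype.
#'
#' Coefficients are on the natural-log scale. Genotype effects are contrasts
#' against the *1/*1 group; `male` is the male-vs-female contrast and
#' `age_c` the slope per year of age centered on the cohort mean.
#'
#' @return A list with elements `genotype_counts`, `genotype_probs`,
#'   `female_prob`, `age_mean`, `age_sd`, `age_range`, `coefficients`
#'   (outcomes x terms matrix), `r_squared` (named vector),
#'   `truncation_area`, `detection_frac`, `thresholds` (named vector,
#'   ln scale) and `marker_directions` (`"low"`: values at or below the
#'   threshold predict PM; `"high"`: values at or above it do).
#' @export
sola_ref_params <- function() {
  groups <- genotype_groups()

  # test + validation cohort genotype-group counts (sums to 839)
  counts <- c(
    "*1/*1xN" = 26, "*1/*1" = 348, "*1/red" = 101, "*1/def" = 231,
    "Red/red" = 17, "Def/red" = 36, "Def/def" = 58,
    "*1/red xN" = 8, "*1/def xN" = 8, "Red/def xN" = 6
  )[groups]

  terms <- c("intercept", "male", "age_c",
             "*1/*1xN", "*1/red", "*1/def", "Red/red", "Def/red", "Def/def")
  coef <- rbind(
    lnMR_M402    = c( 0.51, -0.005, 0.005,  0.93,  -0.56, -1.88, -3.87, -3.44,  -8.75),
    lnMR_M412    = c(-3.06,  0.073, 0.008,  0.13,  -0.20, -0.71, -1.37, -1.04,  -5.54),
    lnMR_M414    = c( 2.90,  0.039, 0.001,  0.31,  -0.27, -0.88, -1.06, -1.87, -11.2),
    lnMR_M416    = c( 2.61, -0.006, 0.011,  0.8,   -0.38, -1.58, -2.50, -2.92, -10.4),
    lnMR_M432    = c( 1.58,  0.22,  0.007,  0.69,  -0.27, -1.16, -0.83, -2.04,  -4.16),
    lnMR_M440    = c(-0.49, -0.058, 0.003, -0.050, -0.23, -1.50, -1.70, -2.53,  -7.71),
    lnMR_M444    = c( 0.80, -0.05,  0.013,  0.94,  -0.95, -2.32, -3.85, -4.76,  -9.38),
    ln_sola_conc = c(-1.01, -0.033, 0.0001, -0.31,  0.16,  0.39,  0.57,  0.93,   2.78)
  )
  colnames(coef) <- terms

  r2 <- c(lnMR_M402 = 0.371, lnMR_M412 = 0.325, lnMR_M414 = 0.688,
          lnMR_M416 = 0.475, lnMR_M432 = 0.117, lnMR_M440 = 0.442,
          lnMR_M444 = 0.377, ln_sola_conc = 0.227)

  trunc <- c(solanidine = 1278, M402 = 970, M412 = 798, M414 = 782,
             M416 = 1117, M432 = 844, M440 = 963, M444 = 629)

  det <- c(solanidine = 0.76, M402 = 0.71, M412 = 0.42, M414 = 0.91,
           M416 = 0.87, M432 = 0.98, M440 = 0.61, M444 = 0.71)

  thr <- c(lnMR_M414 = -4.28, lnMR_M416 = -5.71, lnMR_M440 = -7.01,
           lnMR_M402 = -6.18, lnMR_M412 = -6.59, lnMR_M444 = -6.83,
           lnMR_M432 = -1.24, ln_sola_conc = 0.31)
  dir <- c(lnMR_M414 = "low", lnMR_M416 = "low", lnMR_M440 = "low",
           lnMR_M402 = "low", lnMR_M412 = "low", lnMR_M444 = "low",
           lnMR_M432 = "low", ln_sola_conc = "high")

  list(
    genotype_counts = counts,
    genotype_probs = counts / sum(counts),
    female_prob = 341 / 839,
    age_mean = 41.3,
    age_sd = 11.0,
    age_range = c(18, 65),
    coefficients = coef,
    r_squared = r2,
    truncation_area = trunc,
    detection_frac = det,
    thresholds = thr,
    marker_directions = dir
  )
}

# Representative diplotype string for each genotype group, used when
# synthesizing patient tables (the genotype module re-derives group and
# phenotype from these, closing the loop between the two modules).
.group_diplotype <- c(
  "*1/*1xN"    = "*1xN/*1",
  "*1/*1"      = "*1/*1",
  "*1/red"     = "*1/*41",
  "*1/def"     = "*1/*4",
  "Red/red"    = "*41/*41",
  "Def/red"    = "*4/*41",
  "Def/def"    = "*4/*5",
  "*1/red xN"  = "*1xN/*41",
  "*1/def xN"  = "*1xN/*4",
  "Red/def xN" = "*41xN/*4"
)

# The inconclusive duplication groups have no published model contrasts (they
# are excluded from the regression); for simulation they borrow the contrast
# of their non-duplicated counterpart.
.inconclusive_proxy <- c(
  "*1/red xN"  = "*1/red",
  "*1/def xN"  = "*1/def",
  "Red/def xN" = "Def/red"
)
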