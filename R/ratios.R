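#' @title Truncation and metabolic-ratio computation
#' @name ratios
#' @description
#' Undetectable peak areas are truncated to half the minimum detected area of
#' the corresponding analyte so metabolic ratios stay defined; ratios are
#' ln-transformed for all downstream statistics. A patient is excluded from a
#' metabolite's analyses only when both solanidine and that metabolite are
#' undetected; exclusion is therefore per metabolite, not global, so the
#' included n differs across metabolites.
NULL

#' Half-minimum truncation value for one analyte
#'
#' @param areas Numeric peak areas across patients for one analyte.
#' @param detected Logical vector of the same length.
#' @return Half of the minimum detected area.
#' @export
#' @examples
#' derive_truncation(c(2556, 4000, 900), c(TRUE, TRUE, FALSE)) # 1278
derive_truncation <- function(areas, detected) {
  stopifnot(length(areas) == length(detected))
  if (!any(detected)) {
    stop("no detected measurements: analyte unusable, cannot derive a truncation value")
  }
  0.5 * min(areas[detected])
}

#' Truncation constants for every analyte of a patient table
#'
#' @param records Patient table with `area_` / `detected_` columns.
#' @return Named vector over [sola_analytes()].
#' @export
truncation_from_cohort <- function(records) {
  vapply(sola_analytes(), function(a) {
    derive_truncation(records[[paste0("area_", a)]],
                      records[[paste0("detected_", a)]])
  }, numeric(1))
}

#' Compute ln metabolic ratios and ln solanidine concentration
#'
#' Replaces undetected areas by the truncation constant, computes
#' `lnMR_<m> = ln(area_m / area_solanidine)` for each metabolite, and an
#' `included_<m>` flag that is `FALSE` only when solanidine and metabolite m
#' are both undetected. `ln_sola_conc` is the ln of the quantified solanidine
#' concentration; when solanidine is undetected the truncation area is pushed
#' through the same area-to-concentration mapping so the concentration
#' analysis stays defined for every patient.
#'
#' @param records Patient table with area/detected columns and (optionally)
#'   `solanidine_conc`.
#' @param truncation Named truncation constants per analyte; default derived
#'   from `records` via [truncation_from_cohort()]. Pin to fixed values to
#'   reproduce a previous analysis.
#' @param conc_from_area Function mapping a solanidine peak area to nmol/L,
#'   used (a) when `solanidine_conc` is absent and (b) for the truncated
#'   concentration of solanidine non-detects. Defaults to the generator's
#'   linear response `area / area_per_nM` with `area_per_nM = 1000`; supply
#'   the inverse calibration line from [quantify_solanidine()] for measured
#'   data.
#' @return A data.frame (the "ratio table") carrying `id`, covariates,
#'   `genotype_group`, `phenotype`, `inhibitor_user`, one `lnMR_<m>` and
#'   `included_<m>` pair per metabolite, and `ln_sola_conc`. The truncation
#'   constants used are attached as attribute `"truncation"`.
#' @export
compute_ratios <- function(records, truncation = NULL,
                           conc_from_area = function(area) area / 1000) {
  if (is.null(truncation)) truncation <- truncation_from_cohort(records)
  stopifnot(all(sola_analytes() %in% names(truncation)),
            all(truncation > 0))

  trunc_area <- function(a) {
    area <- records[[paste0("area_", a)]]
    det <- records[[paste0("detected_", a)]]
    ifelse(det, area, truncation[[a]])
  }
  area_sol <- trunc_area("solanidine")
  if (any(area_sol <= 0)) stop("non-positive solanidine area after truncation")

  keep <- intersect(c("id", "cyp2d6_diplotype", "genotype_group", "phenotype",
                      "sex", "age", "inhibitor_user"), names(records))
  out <- records[, keep, drop = FALSE]

  for (m in sola_analytes()[-1]) {
    area_m <- trunc_area(m)
    if (any(area_m <= 0)) stop("non-positive ", m, " area after truncation")
    out[[paste0("lnMR_", m)]] <- log(area_m / area_sol)
    out[[paste0("included_", m)]] <-
      records[[paste0("detected_", "solanidine")]] |
      records[[paste0("detected_", m)]]
  }

  det_sol <- records[["detected_solanidine"]]
  conc <- if ("solanidine_conc" %in% names(records)) {
    records$solanidine_conc
  } else {
    conc_from_area(records$area_solanidine)
  }
  conc_trunc <- conc_from_area(truncation[["solanidine"]])
  out$ln_sola_conc <- log(ifelse(det_sol, conc, conc_trunc))

  attr(out, "truncation") <- truncation
  out
}
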