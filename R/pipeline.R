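#' @title End-to-end pipeline
#' @name pipeline
#' @description
#' Orchestrates the full analysis: cohort input (patient table or synthetic
#' generator), eligibility exclusions (age 18--65, CYP2D6-inhibitor users,
#' inconclusive genotypes flagged), truncation and ratio computation,
#' stratified 4:1 split, ROC threshold derivation on the test cohort,
#' threshold evaluation on the validation cohort, the per-outcome genotype
#' regression models, and (when inhibitor users are present) the
#' inhibitor-use comparisons. Every exclusion is counted by reason and all
#' outputs are pure functions of the input plus the seed.
NULL

#' Build a pipeline run configuration
#'
#' @param records A patient table (e.g. from [generate_cohort()] or
#'   [read_cohort()]); mutually exclusive with `generator`.
#' @param generator A `"sola_cohort_config"`; the pipeline will generate the
#'   cohort itself.
#' @param seed Seed for the stratified split (and the Dunnett Monte-Carlo).
#' @param split_ratio Test:validation ratio (default 4).
#' @param age_range Eligible age range in years (default 18--65, inclusive).
#' @param markers Named directions (`"low"`/`"high"`) of the markers to
#'   analyse; defaults to the full reference panel.
#' @param thresholds `"derive"` (ROC on the test cohort) or a named numeric
#'   vector of pinned ln-scale thresholds evaluated on both cohorts.
#' @param truncation `"derive"` (half-minimum rule on the eligible
#'   population) or a named per-analyte vector of pinned constants.
#' @return A list of class `"sola_run_config"`.
#' @export
run_config <- function(records = NULL, generator = NULL, seed = 1L,
                       split_ratio = 4, age_range = c(18, 65),
                       markers = sola_ref_params()$marker_directions,
                       thresholds = "derive",
                       truncation = "derive") {
  if (is.null(records) == is.null(generator)) {
    stop("exactly one of `records` or `generator` must be supplied")
  }
  structure(list(records = records, generator = generator,
                 seed = as.integer(seed), split_ratio = split_ratio,
                 age_range = age_range, markers = markers,
                 thresholds = thresholds, truncation = truncation),
            class = "sola_run_config")
}

.marker_scores <- function(ratio_table, marker) {
  stopifnot(marker %in% names(ratio_table))
  inc <- sub("^lnMR_", "included_", marker)
  keep <- if (inc != marker && inc %in% names(ratio_table)) {
    ratio_table[[inc]]
  } else rep(TRUE, nrow(ratio_table))
  list(scores = ratio_table[[marker]][keep],
       labels = as.character(ratio_table$phenotype)[keep] == "PM")
}

#' Run the full analysis
#'
#' @param config A `"sola_run_config"` from [run_config()].
#' @return A list of class `"sola_run_result"` with elements `exclusions`
#'   (counts by reason), `truncation`, `split`, `balance` (cohort-balance
#'   table), `roc` (per-marker list: `roc_result`, CI, optimum),
#'   `test_evaluation` and `validation_evaluation` (per-marker
#'   `threshold_evaluation` at the derived or pinned thresholds), `models`
#'   (per-outcome fits), `inhibitor` (comparison table or `NULL`), and the
#'   `seed`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "sola_run_config"))
  records <- if (!is.null(config$generator)) {
    generate_cohort(config$generator)
  } else {
    config$records
  }
  if (!"phenotype" %in% names(records)) records <- call_phenotypes(records)
  n0 <- nrow(records)

  age_ok <- records$age >= config$age_range[1] &
    records$age <= config$age_range[2]
  excl_age <- sum(!age_ok)
  records <- records[age_ok, , drop = FALSE]

  inhib <- if ("inhibitor_user" %in% names(records)) {
    records$inhibitor_user
  } else rep(FALSE, nrow(records))
  inhibitor_records <- records[inhib, , drop = FALSE]
  records <- records[!inhib, , drop = FALSE]

  inconclusive <- as.character(records$phenotype) == "inconclusive"
  exclusions <- data.frame(
    reason = c("age outside range", "CYP2D6 inhibitor use",
               "inconclusive genotype (flagged, not removed)"),
    n = c(excl_age, nrow(inhibitor_records), sum(inconclusive)))

  truncation <- if (identical(config$truncation, "derive")) {
    truncation_from_cohort(records)
  } else config$truncation
  ratio_table <- compute_ratios(records, truncation = truncation)

  split <- stratified_split(records, ratio = config$split_ratio,
                            seed = config$seed)
  records <- assign_cohort(records, split)
  ratio_table$cohort <- records$cohort

  test_rt <- ratio_table[ratio_table$cohort == "test", , drop = FALSE]
  val_rt <- ratio_table[ratio_table$cohort == "validation", , drop = FALSE]
  balance <- compare_cohorts(records[records$cohort == "test", ],
                             records[records$cohort == "validation", ])

  concl_test <- test_rt[as.character(test_rt$phenotype) != "inconclusive", ]
  concl_val <- val_rt[as.character(val_rt$phenotype) != "inconclusive", ]

  derive <- identical(config$thresholds, "derive")
  roc_out <- list(); test_eval <- list(); val_eval <- list()
  for (m in names(config$markers)) {
    dirn <- config$markers[[m]]
    tr <- .marker_scores(concl_test, m)
    vl <- .marker_scores(concl_val, m)
    thr <- NA_real_
    if (derive) {
      roc <- roc_curve(tr$scores, tr$labels, dirn, marker = m)
      ci <- auc_ci(tr$scores, tr$labels, dirn)
      opt <- optimal_threshold(roc)
      thr <- opt$threshold
      roc_out[[m]] <- list(roc = roc, auc = roc$auc, auc_ci = ci$ci,
                           p_vs_chance = ci$p_value, optimum = opt)
    } else {
      if (!m %in% names(config$thresholds)) {
        stop("no pinned threshold supplied for marker ", m)
      }
      thr <- config$thresholds[[m]]
    }
    if (is.finite(thr)) {
      test_eval[[m]] <- evaluate_threshold(tr$scores, tr$labels, thr, dirn)
      val_eval[[m]] <- evaluate_threshold(vl$scores, vl$labels, thr, dirn)
    }
  }

  models <- fit_all_models(concl_test)

  inhibitor <- NULL
  if (nrow(inhibitor_records) > 0) {
    inhib_rt <- compute_ratios(inhibitor_records, truncation = truncation)
    both <- rbind(inhib_rt[names(test_rt)[names(test_rt) %in% names(inhib_rt)]],
                  test_rt[names(test_rt) %in% names(inhib_rt)])
    inhibitor <- inhibitor_comparison(both)
  }

  structure(list(
    n_input = n0, exclusions = exclusions, truncation = truncation,
    split = split, balance = balance, roc = roc_out,
    test_evaluation = test_eval, validation_evaluation = val_eval,
    models = models, inhibitor = inhibitor,
    ratio_table = ratio_table, seed = config$seed
  ), class = "sola_run_result")
}

#' Evaluate pinned thresholds on a ratio table
#'
#' Skips ROC derivation entirely: applies externally supplied ln-scale
#' thresholds (e.g. previously validated ones) to a cohort and reports the
#' confusion metrics.
#'
#' @param ratio_table Ratio table (inconclusive genotypes are removed
#'   internally).
#' @param thresholds Named numeric vector of thresholds per marker.
#' @param directions Named `"low"`/`"high"` per marker; defaults to the
#'   reference panel directions.
#' @return Named list of `"threshold_evaluation"` objects.
#' @export
pin_thresholds <- function(ratio_table, thresholds,
                           directions = sola_ref_params()$marker_directions) {
  concl <- ratio_table[as.character(ratio_table$phenotype) != "inconclusive", ]
  out <- list()
  for (m in names(thresholds)) {
    if (!m %in% names(directions)) {
      stop("marker ", m, " has no direction; supply one via `directions`")
    }
    sc <- .marker_scores(concl, m)
    thr <- thresholds[[m]]
    out[[m]] <- if (is.finite(thr)) {
      evaluate_threshold(sc$scores, sc$labels, thr, directions[[m]])
    } else {
      # -Inf (direction "low") / +Inf ("high"): nothing is ever called PM
      evaluate_threshold(sc$scores, sc$labels,
                         if (directions[[m]] == "low") min(sc$scores) - 1
                         else max(sc$scores) + 1,
                         directions[[m]])
    }
  }
  out
}

#' Summarize a pipeline run as table-shaped data frames
#'
#' @param result A `"sola_run_result"`.
#' @return List with `thresholds` (per-marker AUC, CI, threshold, and
#'   validation specificity/sensitivity/PPV/NPV/MCC) and `models`
#'   (per-outcome coefficient long table plus n and R-squared).
#' @export
summarize_run <- function(result) {
  stopifnot(inherits(result, "sola_run_result"))
  thr_rows <- lapply(names(result$validation_evaluation), function(m) {
    ev <- result$validation_evaluation[[m]]
    r <- result$roc[[m]]
    data.frame(
      marker = m,
      auc = if (!is.null(r)) r$auc else NA_real_,
      auc_lo = if (!is.null(r)) r$auc_ci[1] else NA_real_,
      auc_hi = if (!is.null(r)) r$auc_ci[2] else NA_real_,
      p_vs_chance = if (!is.null(r)) r$p_vs_chance else NA_real_,
      threshold = ev$threshold, direction = ev$direction,
      specificity = ev$specificity, sensitivity = ev$sensitivity,
      ppv_pct = 100 * ev$ppv, npv_pct = 100 * ev$npv, mcc = ev$mcc,
      stringsAsFactors = FALSE)
  })
  mod_rows <- lapply(result$models, function(f) {
    cbind(outcome = f$outcome, f$coefficients,
          n = f$n, r_squared = f$r_squared,
          adj_r_squared = f$adj_r_squared, stringsAsFactors = FALSE)
  })
  list(thresholds = do.call(rbind, thr_rows),
       models = do.call(rbind, c(mod_rows, make.row.names = FALSE)))
}

#' Write a pipeline report bundle
#'
#' Writes the threshold table, the model table, the balance table, per-marker
#' ROC points as tab-separated text, and a machine-readable JSON summary
#' (including the seed and truncation constants for provenance).
#'
#' @param result A `"sola_run_result"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sm <- summarize_run(result)
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(sm$thresholds, "thresholds.tsv")
  tsv(sm$models, "models.tsv")
  tsv(result$balance, "cohort_balance.tsv")
  tsv(result$exclusions, "exclusions.tsv")
  for (m in names(result$roc)) {
    tsv(result$roc[[m]]$roc$points,
        paste0("roc_points_", gsub("[^A-Za-z0-9]", "_", m), ".tsv"))
  }
  summary <- list(
    seed = result$seed,
    n_input = result$n_input,
    exclusions = result$exclusions,
    truncation = as.list(result$truncation),
    strata = result$split$strata,
    thresholds = sm$thresholds,
    r_squared = lapply(result$models, `[[`, "r_squared")
  )
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
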