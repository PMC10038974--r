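#' @title Stratified cohort splitting and balance checks
#' @name split
#' @description
#' 4:1 test/validation randomization stratified on the PM and UM phenotypes
#' (everyone else pooled in a third stratum), with per-stratum validation
#' share `round(n/5)` (half rounded up; 58 PMs therefore always yield 12
#' validation PMs), plus the usual demographics balance table (Student's
#' t-tests for continuous variables, Fisher's exact tests for proportions).
NULL

.round_half_up <- function(x) floor(x + 0.5)

#' Stratified 4:1 test/validation split
#'
#' @param records Patient table with a `phenotype` column. Patients with an
#'   inconclusive phenotype are split like everyone else but are flagged
#'   analysis-ineligible downstream; CYP2D6-inhibitor users should be removed
#'   before splitting.
#' @param ratio Test:validation ratio (default 4, i.e. 4:1).
#' @param seed Integer seed; the assignment is uniformly random given the
#'   seed and reproducible.
#' @return A list of class `"cohort_split"` with `test_ids`,
#'   `validation_ids`, a `strata` data.frame (stratum, n, n_test,
#'   n_validation) and the `seed`.
#' @export
stratified_split <- function(records, ratio = 4, seed = 1L) {
  stopifnot(is.data.frame(records), "phenotype" %in% names(records),
            "id" %in% names(records), ratio > 0)
  set.seed(seed)
  stratum <- as.character(records$phenotype)
  stratum[!stratum %in% c("PM", "UM")] <- "other"

  test_ids <- character(0)
  val_ids <- character(0)
  tab <- list()
  for (s in c("PM", "UM", "other")) {
    ids <- records$id[stratum == s]
    n <- length(ids)
    n_val <- .round_half_up(n / (ratio + 1))
    chosen <- if (n_val > 0) sample(ids, n_val) else character(0)
    val_ids <- c(val_ids, chosen)
    test_ids <- c(test_ids, setdiff(ids, chosen))
    tab[[s]] <- data.frame(stratum = s, n = n, n_test = n - n_val,
                           n_validation = n_val, stringsAsFactors = FALSE)
  }
  structure(list(test_ids = test_ids, validation_ids = val_ids,
                 strata = do.call(rbind, tab), seed = as.integer(seed)),
            class = "cohort_split")
}

#' Append the cohort assignment to a patient table
#'
#' @param records Patient table with an `id` column.
#' @param split A `"cohort_split"`.
#' @return `records` with a `cohort` column (`"test"` / `"validation"`).
#' @export
assign_cohort <- function(records, split) {
  stopifnot(inherits(split, "cohort_split"))
  records$cohort <- ifelse(records$id %in% split$validation_ids,
                           "validation",
                           ifelse(records$id %in% split$test_ids, "test",
                                  NA_character_))
  records
}

#' Test/validation balance report
#'
#' Compares the two cohorts on age and solanidine concentration (two-sided
#' Student's t-test, equal variances) and on sex and each genotype group
#' (two-sided Fisher's exact test on the 2 x 2 table of group membership vs
#' cohort). A zero-variance continuous variable yields `NA` with a note.
#'
#' @param test,validation Patient tables.
#' @return A data.frame with columns `variable`, `test`, `validation`
#'   (formatted summaries), `p_value` and `method`.
#' @export
compare_cohorts <- function(test, validation) {
  stopifnot(nrow(test) > 0, nrow(validation) > 0)
  rows <- list()
  add <- function(variable, t_sum, v_sum, p, method) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, test = t_sum, validation = v_sum,
      p_value = p, method = method, stringsAsFactors = FALSE)
  }

  cont <- function(variable, x, y) {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      add(variable, sprintf("%.1f (0)", mean(x)), sprintf("%.1f (0)", mean(y)),
          NA_real_, "t-test (undefined: zero variance)")
    } else {
      p <- stats::t.test(x, y, var.equal = TRUE)$p.value
      add(variable, sprintf("%.1f (%.1f)", mean(x), stats::sd(x)),
          sprintf("%.1f (%.1f)", mean(y), stats::sd(y)), p, "Student's t-test")
    }
  }
  cont("age", test$age, validation$age)
  if ("solanidine_conc" %in% names(test)) {
    cont("solanidine_conc", test$solanidine_conc, validation$solanidine_conc)
  }

  fisher2x2 <- function(variable, t_in, v_in) {
    tab <- matrix(c(sum(t_in), sum(!t_in), sum(v_in), sum(!v_in)), 2)
    p <- stats::fisher.test(tab)$p.value
    add(variable, sprintf("%d/%d", sum(t_in), sum(!t_in)),
        sprintf("%d/%d", sum(v_in), sum(!v_in)), p, "Fisher's exact test")
  }
  if ("sex" %in% names(test)) {
    fisher2x2("female/male", test$sex == "female", validation$sex == "female")
  }
  if ("genotype_group" %in% names(test)) {
    for (g in genotype_groups()) {
      fisher2x2(paste0("genotype ", g),
                as.character(test$genotype_group) == g,
                as.character(validation$genotype_group) == g)
    }
  }
  for (a in sola_analytes()) {
    col <- paste0("detected_", a)
    if (col %in% names(test)) {
      fisher2x2(paste0("undetected ", a), !test[[col]], !validation[[col]])
    }
  }
  do.call(rbind, rows)
}
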