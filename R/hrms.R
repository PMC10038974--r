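#' @title Targeted reprocessing of full-scan HRMS runs
#' @name hrms
#' @description
#' Targeted re-extraction of configured analytes from centroided full-scan
#' LC-HRMS runs: extracted ion chromatograms (XICs) at a +/-5 ppm mass
#' tolerance on the protonated molecular ion, automatic peak integration
#' with a robust median baseline, identity confirmation via the diagnostic
#' MS2 fragment at m/z 98.0967 (the iminium fragment shared by solanidine
#' and its metabolites), and absolute solanidine quantification from a
#' three-point calibration line. This module is an optional front end: the
#' statistical pipeline consumes peak-area tables directly.
NULL

.monoisotopic <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
                   O = 15.9949146221, S = 31.97207069, P = 30.97376151)
.proton_mass <- 1.00727646677

#' Theoretical m/z of the protonated molecule from a molecular formula
#'
#' @param formula Molecular formula such as `"C27H43NO"` (elements C, H, N,
#'   O, S, P).
#' @return Monoisotopic \[M+H\]+ m/z.
#' @export
#' @examples
#' formula_mz("C27H43NO") # solanidine, ~398.3418
formula_mz <- function(formula) {
  vapply(as.character(formula), function(f) {
    m <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (!length(m) || paste(m, collapse = "") != f) {
      stop("cannot parse molecular formula: ", sQuote(f))
    }
    el <- sub("[0-9]*$", "", m)
    cnt <- as.numeric(ifelse(sub("^[A-Z][a-z]?", "", m) == "", "1",
                             sub("^[A-Z][a-z]?", "", m)))
    if (any(!el %in% names(.monoisotopic))) {
      stop("unsupported element(s): ",
           paste(setdiff(el, names(.monoisotopic)), collapse = ", "))
    }
    sum(.monoisotopic[el] * cnt) + .proton_mass
  }, numeric(1), USE.NAMES = FALSE)
}

#' Define a targeted analyte
#'
#' @param name Analyte name.
#' @param formula Molecular formula; used to compute `mz` when absent.
#' @param mz Theoretical m/z of the protonated molecule (overrides
#'   `formula`).
#' @param rt_expected Expected retention time (minutes).
#' @param rt_window Half-width of the retention-time search window (minutes,
#'   default 0.3).
#' @param fragment_mz Diagnostic MS2 fragment m/z (default 98.0967).
#' @param truncation_area Optional pinned truncation constant (area units).
#' @return A list of class `"analyte_definition"`.
#' @export
analyte_definition <- function(name, formula = NULL, mz = NULL,
                               rt_expected, rt_window = 0.3,
                               fragment_mz = 98.0967,
                               truncation_area = NULL) {
  if (is.null(mz)) {
    if (is.null(formula)) stop("either formula or mz must be given")
    mz <- formula_mz(formula)
  }
  stopifnot(mz > 0, rt_window > 0)
  structure(list(name = name, formula = formula, mz = mz,
                 rt_expected = rt_expected, rt_window = rt_window,
                 fragment_mz = fragment_mz,
                 truncation_area = truncation_area),
            class = "analyte_definition")
}

#' Relative mass difference in parts per million
#'
#' @param observed_mz,theoretical_mz Positive m/z values.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @export
ppm_difference <- function(observed_mz, theoretical_mz) {
  stopifnot(all(observed_mz > 0), all(theoretical_mz > 0))
  1e6 * (observed_mz - theoretical_mz) / theoretical_mz
}

#' Construct an in-memory spectrum run
#'
#' @param scans List of scans; each scan a list with `rt` (minutes),
#'   `ms_level` (1 or 2), `precursor_mz` (MS2 only, else `NA`), and numeric
#'   vectors `mz` and `intensity` of equal length.
#' @return A list of class `"spectrum_run"`.
#' @export
spectrum_run <- function(scans) {
  rt <- vapply(scans, `[[`, 0.0, "rt")
  if (is.unsorted(rt)) stop("scan retention times must be non-decreasing")
  for (s in scans) {
    if (length(s$mz) != length(s$intensity)) {
      stop("mz and intensity arrays must have equal length")
    }
  }
  structure(list(scans = scans), class = "spectrum_run")
}

#' Simulate a centroided full-scan run with Gaussian chromatographic peaks
#'
#' Builds a synthetic `"spectrum_run"`: a regular MS1 scan grid on which each
#' configured peak contributes one centroid at its m/z (optionally offset in
#' ppm) whose intensity follows a Gaussian elution profile
#' `height * exp(-(rt - rt_apex)^2 / (2 * rt_sd^2))`, plus optional MS2
#' scans carrying the diagnostic fragment.
#'
#' @param peaks Data.frame with columns `mz`, `rt_apex` (minutes), `height`,
#'   `rt_sd` (minutes) and optionally `ppm_offset`.
#' @param rt_grid Retention times of the MS1 scans (minutes).
#' @param ms2 Optional data.frame with columns `rt`, `precursor_mz`,
#'   `fragment_mz`, `intensity` describing MS2 scans to interleave.
#' @param intensity_floor Centroids below this intensity are dropped,
#'   emulating the instrument threshold (default 1e-6).
#' @return A `"spectrum_run"`.
#' @export
synthetic_run <- function(peaks, rt_grid, ms2 = NULL, intensity_floor = 1e-6) {
  if (is.null(peaks$ppm_offset)) peaks$ppm_offset <- 0
  scans <- lapply(rt_grid, function(rt) {
    inten <- peaks$height * exp(-(rt - peaks$rt_apex)^2 / (2 * peaks$rt_sd^2))
    keep <- inten > intensity_floor
    mz <- peaks$mz[keep] * (1 + peaks$ppm_offset[keep] / 1e6)
    ord <- order(mz)
    list(rt = rt, ms_level = 1L, precursor_mz = NA_real_,
         mz = mz[ord], intensity = inten[keep][ord])
  })
  if (!is.null(ms2)) {
    for (i in seq_len(nrow(ms2))) {
      scans[[length(scans) + 1L]] <- list(
        rt = ms2$rt[i], ms_level = 2L, precursor_mz = ms2$precursor_mz[i],
        mz = ms2$fragment_mz[i], intensity = ms2$intensity[i])
    }
    scans <- scans[order(vapply(scans, `[[`, 0.0, "rt"))]
  }
  spectrum_run(scans)
}

#' Extracted ion chromatogram at a ppm tolerance
#'
#' One intensity per MS1 scan: the sum of centroid intensities whose m/z lies
#' within `tol_ppm` (inclusive on both sides) of the analyte's theoretical
#' m/z; centroids outside the window contribute nothing.
#'
#' @param run A `"spectrum_run"`.
#' @param analyte An `"analyte_definition"`.
#' @param tol_ppm Mass tolerance (default 5 ppm).
#' @return Data.frame with columns `rt` and `intensity`.
#' @export
build_xic <- function(run, analyte, tol_ppm = 5) {
  stopifnot(inherits(run, "spectrum_run"), length(run$scans) > 0)
  ms1 <- Filter(function(s) s$ms_level == 1L, run$scans)
  rt <- vapply(ms1, `[[`, 0.0, "rt")
  # inclusive window expressed as m/z bounds so that a centroid generated at
  # exactly +/- tol ppm (same floating-point product) is included bit-exactly
  lo <- analyte$mz * (1 - tol_ppm / 1e6)
  hi <- analyte$mz * (1 + tol_ppm / 1e6)
  inten <- vapply(ms1, function(s) {
    if (!length(s$mz)) return(0)
    sum(s$intensity[s$mz >= lo & s$mz <= hi])
  }, numeric(1))
  data.frame(rt = rt, intensity = inten)
}

#' Integrate the analyte peak of an XIC
#'
#' The baseline is the median intensity of scans outside the retention-time
#' window; the peak is the maximal contiguous run of above-baseline scans
#' inside the window (the one with the largest area when several exist);
#' the area is the trapezoidal integral over that run. The analyte counts as
#' detected only when some scan in the window exceeds
#' `baseline + 3 * MAD` of the outside-window intensities.
#'
#' @param xic Data.frame from [build_xic()].
#' @param analyte An `"analyte_definition"` (provides `rt_expected`,
#'   `rt_window`).
#' @return A list of class `"integration_result"`: `analyte`, `peak_area`,
#'   `apex_rt`, `detected`, `baseline`.
#' @export
integrate_peak <- function(xic, analyte) {
  inside <- abs(xic$rt - analyte$rt_expected) <= analyte$rt_window
  if (!any(inside)) {
    return(structure(list(analyte = analyte$name, peak_area = 0,
                          apex_rt = NA_real_, detected = FALSE,
                          baseline = NA_real_),
                     class = "integration_result"))
  }
  out_int <- xic$intensity[!inside]
  baseline <- if (length(out_int)) stats::median(out_int) else 0
  noise <- if (length(out_int)) stats::mad(out_int) else 0

  rt <- xic$rt[inside]
  y <- pmax(xic$intensity[inside] - baseline, 0)
  above <- xic$intensity[inside] > baseline
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  best_area <- 0; best <- NULL
  for (k in which(runs$values)) {
    idx <- starts[k]:ends[k]
    a <- if (length(idx) > 1) {
      sum(diff(rt[idx]) * (y[idx][-1] + y[idx][-length(idx)]) / 2)
    } else 0
    if (a > best_area) { best_area <- a; best <- idx }
  }
  apex <- if (!is.null(best)) rt[best][which.max(y[best])] else NA_real_
  detected <- any(xic$intensity[inside] > baseline + 3 * noise) && best_area > 0
  structure(list(analyte = analyte$name, peak_area = best_area,
                 apex_rt = apex, detected = detected, baseline = baseline),
            class = "integration_result")
}

#' Confirm analyte identity by the diagnostic MS2 fragment
#'
#' @param run A `"spectrum_run"`.
#' @param analyte An `"analyte_definition"`.
#' @param precursor_tol_ppm Precursor match tolerance (default 10 ppm).
#' @param fragment_tol_mz Fragment match tolerance in Da (default 0.005;
#'   absolute rather than ppm because at m/z 98 a ppm window would be
#'   sub-millidalton).
#' @return Logical: `TRUE` iff some MS2 scan whose precursor matches the
#'   analyte contains a centroid within `fragment_tol_mz` of the expected
#'   fragment. When the run holds no MS2 scans the result is `FALSE` with
#'   attribute `acquired = FALSE`.
#' @export
confirm_fragment <- function(run, analyte, precursor_tol_ppm = 10,
                             fragment_tol_mz = 0.005) {
  ms2 <- Filter(function(s) s$ms_level == 2L, run$scans)
  if (!length(ms2)) return(structure(FALSE, acquired = FALSE))
  hit <- any(vapply(ms2, function(s) {
    abs(ppm_difference(s$precursor_mz, analyte$mz)) <= precursor_tol_ppm &&
      any(abs(s$mz - analyte$fragment_mz) <= fragment_tol_mz)
  }, logical(1)))
  structure(hit, acquired = TRUE)
}

#' Absolute solanidine quantification from a calibration line
#'
#' Fits an ordinary least-squares line (free intercept) through the
#' calibration points and maps the sample area through its inverse. Negative
#' predicted concentrations are clipped to 0 with a warning.
#'
#' @param area Sample peak area(s).
#' @param calibration Data.frame with columns `conc` (nmol/L) and `area`,
#'   at least two distinct concentrations (three calibrators spanning
#'   2--60 nmol/L in the reference method).
#' @return Concentration(s) in nmol/L.
#' @export
#' @examples
#' cal <- data.frame(conc = c(2, 20, 60), area = c(2000, 20000, 60000))
#' quantify_solanidine(10000, cal) # 10
quantify_solanidine <- function(area, calibration) {
  stopifnot(all(c("conc", "area") %in% names(calibration)),
            nrow(calibration) >= 2)
  if (length(unique(calibration$conc)) < 2) {
    stop("degenerate calibration: at least two distinct concentrations required")
  }
  fit <- stats::lm(area ~ conc, data = calibration)
  b <- stats::coef(fit)
  conc <- (area - b[[1]]) / b[[2]]
  if (any(conc < 0)) {
    warning("negative predicted concentration(s) clipped to 0 nmol/L")
    conc <- pmax(conc, 0)
  }
  unname(conc)
}

#' Extract and integrate a set of analytes from one run
#'
#' @param run A `"spectrum_run"`.
#' @param analytes List of `"analyte_definition"` objects.
#' @param tol_ppm XIC mass tolerance (default 5 ppm).
#' @return Data.frame with one row per analyte: `analyte`, `peak_area`,
#'   `apex_rt`, `detected`, `fragment_confirmed`, `ms2_acquired`.
#' @export
extract_analytes <- function(run, analytes, tol_ppm = 5) {
  rows <- lapply(analytes, function(a) {
    res <- integrate_peak(build_xic(run, a, tol_ppm), a)
    frag <- confirm_fragment(run, a)
    data.frame(analyte = a$name, peak_area = res$peak_area,
               apex_rt = res$apex_rt, detected = res$detected,
               fragment_confirmed = as.logical(frag),
               ms2_acquired = isTRUE(attr(frag, "acquired")),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Read / write a spectrum run as mzML
#'
#' Thin adapters around the Bioconductor `mzR` backend (listed in Suggests).
#' `read_mzml_run()` loads a centroided mzML file into a
#' `"spectrum_run"`; `write_mzml_run()` serializes one (e.g. from
#' [synthetic_run()]) so external tools can read it.
#'
#' @param path mzML file path.
#' @param run A `"spectrum_run"`.
#' @return `read_mzml_run()`: a `"spectrum_run"`; `write_mzml_run()`: `path`,
#'   invisibly.
#' @export
read_mzml_run <- function(path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the 'mzR' package")
  }
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  scans <- lapply(seq_len(nrow(h)), function(i) {
    list(rt = h$retentionTime[i] / 60, # mzR reports seconds
         ms_level = as.integer(h$msLevel[i]),
         precursor_mz = if (h$msLevel[i] > 1) h$precursorMZ[i] else NA_real_,
         mz = pk[[i]][, 1], intensity = pk[[i]][, 2])
  })
  spectrum_run(scans)
}

#' @rdname read_mzml_run
#' @export
write_mzml_run <- function(run, path) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("writing mzML requires the 'mzR' package")
  }
  stopifnot(inherits(run, "spectrum_run"))
  n <- length(run$scans)
  lv <- vapply(run$scans, function(s) as.integer(s$ms_level), 0L)
  npk <- vapply(run$scans, function(s) length(s$mz), 0L)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lv,
    polarity = rep(1L, n), peaksCount = npk,
    totIonCurrent = vapply(run$scans, function(s) sum(s$intensity), 0.0),
    retentionTime = vapply(run$scans, `[[`, 0.0, "rt") * 60,
    basePeakMZ = vapply(run$scans, function(s)
      if (length(s$mz)) s$mz[which.max(s$intensity)] else 0, 0.0),
    basePeakIntensity = vapply(run$scans, function(s)
      if (length(s$intensity)) max(s$intensity) else 0, 0.0),
    collisionEnergy = rep(0, n), ionisationEnergy = rep(0, n),
    lowMZ = rep(100, n), highMZ = rep(1500, n),
    precursorScanNum = rep(0L, n),
    precursorMZ = vapply(run$scans, function(s)
      if (s$ms_level > 1) s$precursor_mz else 0, 0.0),
    precursorCharge = ifelse(lv > 1L, 1L, 0L),
    precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(0, n), filterString = rep(NA_character_, n),
    spectrumId = sprintf("scan=%d", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = rep(NA_real_, n),
    isolationWindowLowerOffset = rep(NA_real_, n),
    isolationWindowUpperOffset = rep(NA_real_, n),
    scanWindowLowerLimit = rep(100, n), scanWindowUpperLimit = rep(1500, n),
    stringsAsFactors = FALSE)
  pks <- lapply(run$scans, function(s) cbind(mz = s$mz, intensity = s$intensity))
  mzR::writeMSData(pks, path, header = hdr)
  invisible(path)
}
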