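sola_def <- function(rt_expected = 5, rt_window = 0.3) {
  analyte_definition("solanidine", formula = "C27H43NO",
                     rt_expected = rt_expected, rt_window = rt_window)
}

test_that("ppm difference is exact arithmetic with a mass-table oracle", {
  expect_equal(ppm_difference(100.0005, 100.0000), 5.0)
  expect_equal(ppm_difference(398.3417, 398.3417), 0)
  # independent oracle: monoisotopic element masses summed by hand
  m_hand <- 27 * 12 + 43 * 1.0078250319 + 14.0030740052 + 15.9949146221 +
    1.00727646677
  mz <- formula_mz("C27H43NO")
  expect_equal(mz, m_hand, tolerance = 1e-9)
  expect_equal(ppm_difference(mz + 1e-3, mz), 1e6 * 1e-3 / mz,
               tolerance = 1e-9)
  expect_error(ppm_difference(-1, 100))
  expect_error(formula_mz("C27H43NoX"))
})

test_that("the 5-ppm XIC window is inclusive at +/-5.00 and excludes +/-5.01", {
  mz <- formula_mz("C27H43NO")
  for (off in c(-5, 5)) {
    run <- default_gaussian_run(mz, ppm_offset = off)
    xic <- build_xic(run, sola_def())
    expect_gt(max(xic$intensity), 0)
  }
  for (off in c(-5.01, 5.01, 6)) {
    run <- default_gaussian_run(mz, ppm_offset = off)
    xic <- build_xic(run, sola_def())
    expect_identical(max(xic$intensity), 0)
  }
})

test_that("a single on-mass centroid passes through the XIC unchanged", {
  mz <- formula_mz("C27H43NO")
  run <- spectrum_run(list(list(rt = 5, ms_level = 1L, precursor_mz = NA,
                                mz = mz, intensity = 123)))
  xic <- build_xic(run, sola_def())
  expect_equal(xic$intensity, 123)
})

test_that("integration recovers Gaussian areas within 1% and is linear", {
  mz <- formula_mz("C27H43NO")
  run <- default_gaussian_run(mz, height = 1e6, rt_sd = 0.05)
  res <- integrate_peak(build_xic(run, sola_def()), sola_def())
  analytic <- 1e6 * 0.05 * sqrt(2 * pi)
  expect_lt(abs(res$peak_area - analytic) / analytic, 0.01)
  expect_true(res$detected)
  expect_equal(res$apex_rt, 5, tolerance = 0.011)
  # linearity: a 2:1 amplitude ratio is preserved in the areas
  run2 <- default_gaussian_run(mz, height = 5e5, rt_sd = 0.05)
  res2 <- integrate_peak(build_xic(run2, sola_def()), sola_def())
  expect_equal(res$peak_area / res2$peak_area, 2, tolerance = 0.01)
  # flat-zero chromatogram: nothing detected
  xic0 <- data.frame(rt = seq(3, 7, 0.01), intensity = 0)
  res0 <- integrate_peak(xic0, sola_def())
  expect_equal(res0$peak_area, 0)
  expect_false(res0$detected)
  # empty retention-time window
  res_empty <- integrate_peak(xic0[xic0$rt < 4, ], sola_def())
  expect_false(res_empty$detected)
})

test_that("fragment confirmation honours tolerances and flags missing MS2", {
  mz <- formula_mz("C27H43NO")
  mk <- function(frag, prec = mz) synthetic_run(
    peaks = data.frame(mz = mz, rt_apex = 5, height = 1e5, rt_sd = 0.05),
    rt_grid = seq(4, 6, 0.05),
    ms2 = data.frame(rt = 5, precursor_mz = prec, fragment_mz = frag,
                     intensity = 1e3))
  expect_true(confirm_fragment(mk(98.0967), sola_def()))
  expect_false(confirm_fragment(mk(98.9000), sola_def()))
  # wrong precursor: fragment present but not attributable to the analyte
  expect_false(confirm_fragment(mk(98.0967, prec = mz + 1), sola_def()))
  no_ms2 <- default_gaussian_run(mz)
  got <- confirm_fragment(no_ms2, sola_def())
  expect_false(as.logical(got))
  expect_false(attr(got, "acquired"))
})

test_that("calibration-line quantification inverts correctly", {
  cal <- data.frame(conc = c(2, 20, 60), area = c(2000, 20000, 60000))
  expect_equal(quantify_solanidine(10000, cal), 10)
  cal2 <- data.frame(conc = c(2, 20, 60), area = c(2500, 20500, 60500))
  expect_equal(quantify_solanidine(10500, cal2), 10)
  expect_warning(got <- quantify_solanidine(0, cal2), "clipped")
  expect_equal(got, 0)
  expect_error(quantify_solanidine(1, data.frame(conc = c(5, 5),
                                                 area = c(10, 20))),
               "degenerate")
  # invariance under uniform scaling of all areas
  expect_equal(quantify_solanidine(10500 * 7,
                                   transform(cal2, area = area * 7)), 10)
})

test_that("synthetic runs survive an mzML round-trip", {
  skip_if_not_installed("mzR")
  mz <- formula_mz("C27H43NO")
  run <- synthetic_run(
    peaks = data.frame(mz = mz, rt_apex = 5, height = 1e6, rt_sd = 0.05),
    rt_grid = seq(4, 6, 0.02),
    ms2 = data.frame(rt = 5.01, precursor_mz = mz, fragment_mz = 98.0967,
                     intensity = 1e4))
  f <- tempfile(fileext = ".mzML")
  write_mzml_run(run, f)
  back <- read_mzml_run(f)
  expect_equal(length(back$scans), length(run$scans))
  expect_true(as.logical(confirm_fragment(back, sola_def())))
  a1 <- integrate_peak(build_xic(run, sola_def()), sola_def())$peak_area
  a2 <- integrate_peak(build_xic(back, sola_def()), sola_def())$peak_area
  expect_equal(a2, a1, tolerance = 1e-6)
})

test_that("extract_analytes summarises a multi-analyte run", {
  sola <- sola_def()
  m444 <- analyte_definition("M444", mz = 444.3108, rt_expected = 4,
                             rt_window = 0.3)
  run <- synthetic_run(
    peaks = data.frame(mz = c(sola$mz, 444.3108), rt_apex = c(5, 4),
                       height = c(1e6, 2e5), rt_sd = 0.05),
    rt_grid = seq(3, 7, 0.01))
  tab <- extract_analytes(run, list(sola, m444))
  expect_equal(tab$analyte, c("solanidine", "M444"))
  expect_true(all(tab$detected))
  expect_false(any(tab$ms2_acquired))
  expect_equal(tab$peak_area[1] / tab$peak_area[2], 5, tolerance = 0.01)
})
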