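test_that("AUC equals the Mann-Whitney pair-count on worked examples", {
  # perfect separation
  r <- roc_curve(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE), "low")
  expect_equal(r$auc, 1.0)
  # interleaved: 3 of 4 pairs concordant
  r <- roc_curve(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE), "low")
  expect_equal(r$auc, 0.75)
  # an uninformative marker traces the diagonal: AUC exactly 0.5
  r <- roc_curve(rep(1, 10), rep(c(TRUE, FALSE), 5), "low")
  expect_identical(r$auc, 0.5)
})

test_that("trapezoidal AUC equals brute-force pair counting on random instances", {
  set.seed(9)
  for (i in 1:200) {
    n1 <- sample(2:8, 1); n0 <- sample(2:8, 1)
    scores <- sample(1:6, n1 + n0, replace = TRUE) # many ties on purpose
    labels <- c(rep(TRUE, n1), rep(FALSE, n0))
    for (dirn in c("low", "high")) {
      auc <- roc_curve(scores, labels, dirn)$auc
      s <- if (dirn == "low") -scores else scores
      expect_equal(auc, auc_paircount(s[labels], s[!labels]),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(10)
  scores <- rnorm(60)
  labels <- rep(c(TRUE, FALSE), 30)
  a1 <- roc_curve(scores, labels, "low")$auc
  a2 <- roc_curve(exp(scores), labels, "low")$auc
  expect_identical(a1, a2)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  scores <- rnorm(80); labels <- rep(c(TRUE, FALSE), 40)
  ours <- roc_curve(scores, labels, "low")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, direction = ">",
                                        levels = c(FALSE, TRUE), quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("Youden-optimal threshold maximizes J with the documented tie-breaks", {
  r <- roc_curve(c(-8, -6, -3, -1, 0), c(TRUE, TRUE, FALSE, FALSE, FALSE), "low")
  opt <- optimal_threshold(r)
  expect_equal(opt$threshold, -4.5)
  expect_equal(opt$sensitivity, 1.0)
  expect_equal(opt$specificity, 1.0)
  # brute force over every candidate midpoint confirms the optimum
  cand <- r$points$threshold[is.finite(r$points$threshold)]
  js <- vapply(cand, function(t) {
    ev <- evaluate_threshold(c(-8, -6, -3, -1, 0),
                             c(TRUE, TRUE, FALSE, FALSE, FALSE), t, "low")
    ev$sensitivity + ev$specificity - 1
  }, 0.0)
  expect_equal(opt$youden, max(js))
  # fully overlapping scores carry no signal
  r0 <- roc_curve(rep(2, 6), rep(c(TRUE, FALSE), 3), "low")
  expect_true(optimal_threshold(r0)$degenerate)
})

test_that("evaluating the optimum on the same data reproduces its sens/spec", {
  set.seed(13)
  scores <- c(rnorm(15, -6), rnorm(50, 0))
  labels <- c(rep(TRUE, 15), rep(FALSE, 50))
  r <- roc_curve(scores, labels, "low")
  opt <- optimal_threshold(r)
  ev <- evaluate_threshold(scores, labels, opt$threshold, "low")
  expect_identical(ev$sensitivity, opt$sensitivity)
  expect_identical(ev$specificity, opt$specificity)
})

test_that("DeLong interval is clipped, centered and matches a bootstrap", {
  # perfect separation: upper limit clipped to 1
  ci <- auc_ci(c(rnorm(50, -10), rnorm(200, 0)),
               c(rep(TRUE, 50), rep(FALSE, 200)), "low")
  expect_equal(ci$auc, 1.0)
  expect_equal(ci$ci[2], 1.0)
  # symmetric scores, equal n (PM at 1 and 4, non-PM at 2 and 3): AUC 0.5
  # with a class-symmetric placement pattern, so the interval centers on 0.5
  x <- c(1, 4, 2, 3)
  lab <- c(TRUE, TRUE, FALSE, FALSE)
  ci2 <- auc_ci(x, lab, "low")
  expect_equal(mean(ci2$ci), 0.5, tolerance = 1e-9)
  # bootstrap oracle on an informative simulated marker
  set.seed(14)
  scores <- c(rnorm(40, -2), rnorm(160, 0))
  labels <- c(rep(TRUE, 40), rep(FALSE, 160))
  ci3 <- auc_ci(scores, labels, "low")
  boots <- replicate(2000, {
    i <- c(sample(which(labels), replace = TRUE),
           sample(which(!labels), replace = TRUE))
    roc_curve(scores[i], labels[i], "low")$auc
  })
  expect_equal(unname(ci3$ci),
               unname(quantile(boots, c(0.025, 0.975))), tolerance = 0.02)
})

test_that("confusion metrics match worked examples and conventions", {
  # flawless validation outcome
  ev <- evaluate_threshold(c(rep(-9, 12), rep(0, 157)),
                           c(rep(TRUE, 12), rep(FALSE, 157)), -4.28, "low")
  expect_equal(c(ev$tp, ev$fp, ev$fn, ev$tn), c(12, 0, 0, 157))
  expect_equal(ev$ppv, 1.0)
  expect_equal(ev$npv, 1.0)
  expect_equal(ev$mcc, 1.0)
  # direct formula evaluation for a mixed confusion matrix
  scores <- c(rep(-9, 11), -1, rep(-9, 4), rep(0, 153))
  labels <- c(rep(TRUE, 12), rep(FALSE, 157))
  ev2 <- evaluate_threshold(scores, labels, -4.28, "low")
  expect_equal(c(ev2$tp, ev2$fp, ev2$fn, ev2$tn), c(11, 4, 1, 153))
  expect_equal(ev2$mcc, (11 * 153 - 4 * 1) /
                 sqrt(15) / sqrt(12) / sqrt(157) / sqrt(154))
  expect_equal(ev2$mcc, 0.805, tolerance = 0.001)
  # degenerate denominator: MCC 0 by convention, flagged
  ev3 <- evaluate_threshold(c(1, 2), c(FALSE, FALSE), 0, "low")
  expect_equal(ev3$mcc, 0)
  expect_true(ev3$mcc_degenerate)
})

test_that("high-direction markers predict PM at or above the threshold", {
  ev <- evaluate_threshold(c(0.31, 0.30, 1.0), c(TRUE, FALSE, TRUE),
                           0.31, "high")
  expect_equal(c(ev$tp, ev$fp, ev$fn, ev$tn), c(2, 0, 0, 1))
})

test_that("MCC is symmetric under joint class/prediction swap", {
  set.seed(16)
  scores <- rnorm(40); labels <- runif(40) < 0.3
  ev_a <- evaluate_threshold(scores, labels, 0.2, "low")
  ev_b <- evaluate_threshold(scores, !labels, 0.2, "high")
  # swapping labels and flipping the prediction rule swaps TP<->TN, FP<->FN
  expect_equal(ev_b$mcc, ev_a$mcc, tolerance = 1e-12)
})
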