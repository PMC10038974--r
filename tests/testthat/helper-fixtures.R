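# Shared fixtures, built in code at test time.

# a minimal hand-written patient table exercising detection patterns
tiny_records <- function() {
  r <- data.frame(
    id = c("A", "B", "C", "D"),
    cyp2d6_diplotype = c("*1/*1", "*4/*5", "*1/*4", "*1/*41"),
    sex = c("female", "male", "female", "male"),
    age = c(30, 45, 50, 28),
    inhibitor_user = FALSE,
    solanidine_conc = c(5, 1.278, 2, 3),
    stringsAsFactors = FALSE
  )
  r <- solapheno::call_phenotypes(r)
  areas <- rbind( # solanidine, M402..M444
    c(5000, 7820, 5000, 5000, 5000, 5000, 5000, 5000),
    c(1278, 7820,  900,  900,  900,  900,  900,  900), # sol undetected
    c(2000,  970,  798,  782, 1117,  844,  963,  629), # metabolites undetected
    c(3000, 3000, 3000, 3000, 3000, 3000, 3000, 3000)
  )
  det <- rbind(
    rep(TRUE, 8),
    c(FALSE, rep(TRUE, 7)),
    c(TRUE, rep(FALSE, 7)),
    rep(TRUE, 8)
  )
  for (j in seq_along(solapheno::sola_analytes())) {
    a <- solapheno::sola_analytes()[j]
    r[[paste0("area_", a)]] <- areas[, j]
    r[[paste0("detected_", a)]] <- det[, j]
  }
  r
}

ref_truncation <- function() solapheno::sola_ref_params()$truncation_area

# brute-force two-sided Fisher p: sum of probabilities of all tables with the
# observed margins whose hypergeometric probability is <= the observed one
fisher_bruteforce <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  a_range <- max(0, c1 - r2):min(r1, c1)
  prob <- function(a) {
    choose(r1, a) * choose(r2, c1 - a) / choose(n, c1)
  }
  p_obs <- prob(tab[1, 1])
  ps <- vapply(a_range, prob, numeric(1))
  sum(ps[ps <= p_obs * (1 + 1e-7)])
}

# brute-force Mann-Whitney AUC by pair counting (ties count 1/2);
# oriented so that larger `x` (PM) scores mean a better marker
auc_paircount <- function(pm, nonpm) {
  tot <- 0
  for (a in pm) for (b in nonpm) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pm) * length(nonpm))
}

default_gaussian_run <- function(mz, rt_apex = 5, height = 1e6, rt_sd = 0.05,
                                 ppm_offset = 0, rt_grid = seq(3, 7, 0.01)) {
  solapheno::synthetic_run(
    peaks = data.frame(mz = mz, rt_apex = rt_apex, height = height,
                       rt_sd = rt_sd, ppm_offset = ppm_offset),
    rt_grid = rt_grid)
}
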