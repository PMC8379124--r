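fake_meas <- function(measured, true, diam = NULL, converged = TRUE) {
  n <- length(measured)
  data.frame(hole_id = seq_len(n),
             diameter_mm = if (is.null(diam)) rep(3, n) else diam,
             true_area_mm2 = true, measured_area_mm2 = measured,
             converged = rep_len(converged, n))
}

test_that("accuracy and precision behave on degenerate inputs", {
  true <- rep(pi * 1.5^2, 10)
  perfect <- accuracy_precision(fake_meas(true, true))
  expect_equal(perfect$accuracy_mm2, 0)
  expect_equal(perfect$precision_mm2, 0)
  biased <- accuracy_precision(fake_meas(true + 0.5, true))
  expect_equal(biased$accuracy_mm2, 0.5)
  expect_equal(biased$precision_mm2, 0)
  expect_equal(biased$error_dispersion_mm2, 0)
})

test_that("accuracy_precision equals its brute-force recomputation", {
  set.seed(42)
  diam <- rep(seq(3.00, 3.42, by = 0.02), each = 5)
  true <- pi * (diam / 2)^2
  for (rep_i in 1:5) {
    meas <- fake_meas(true + rnorm(length(true), 0.2, 0.3), true, diam)
    # drop a few holes to exercise the non-convergence path
    meas$converged[sample(length(true), 4)] <- FALSE
    ap <- accuracy_precision(meas)
    bf <- bf_accuracy_precision(meas)
    expect_equal(ap$accuracy_mm2, bf$accuracy, tolerance = 1e-12)
    expect_equal(ap$precision_mm2, bf$precision, tolerance = 1e-12)
    expect_equal(ap$error_dispersion_mm2, bf$dispersion, tolerance = 1e-12)
    expect_identical(ap$n_holes_used, sum(meas$converged))
  }
  # per-diameter repeat SD recovers the generating noise scale; the sample
  # SD at n = 5 underestimates sigma by the c4 factor, and the mean of 22
  # such SDs has SE sigma * sqrt(1 - c4^2) / sqrt(22)
  set.seed(7)
  meas <- fake_meas(true + rnorm(length(true), 0, 0.3), true, diam)
  ap <- accuracy_precision(meas)
  c4 <- sqrt(2 / 4) * gamma(5 / 2) / gamma(4 / 2)
  se <- 0.3 * sqrt(1 - c4^2) / sqrt(22)
  expect_lt(abs(ap$precision_mm2 - c4 * 0.3), 3 * se)
})

test_that("accuracy_precision rejects unusable input", {
  true <- rep(7, 5)
  expect_error(accuracy_precision(fake_meas(true, true, converged = FALSE)),
               "at least 2 converged")
  m <- fake_meas(true, true)
  m$energy <- c("40keV", "40keV", "55keV", "55keV", "55keV")
  expect_error(accuracy_precision(m), "mix")
})

test_that("the mean-absolute accuracy variant is available", {
  true <- rep(7, 6)
  meas <- fake_meas(true + c(-1, 1, -1, 1, -1, 1), true)
  expect_equal(accuracy_precision(meas)$accuracy_mm2, 0)
  expect_equal(accuracy_precision(meas, method = "mean_abs")$accuracy_mm2, 1)
})

test_that("cnr implements the pooled-SD contrast ratio", {
  expect_equal(cnr(roi_sample(100, 1), roi_sample(0, 1)), 100)
  expect_equal(cnr(roi_sample(50, 3), roi_sample(50, 7)), 0)
  # hand evaluation: 488 / sqrt((400 + 625)/2)
  expect_equal(cnr(roi_sample(400, 20), roi_sample(-88, 25)),
               488 / sqrt(0.5 * (400 + 625)), tolerance = 1e-12)
  expect_equal(round(cnr(roi_sample(400, 20), roi_sample(-88, 25)), 2), 21.56)
  # symmetry and shift invariance
  set.seed(1)
  for (i in 1:10) {
    m1 <- rnorm(1, 0, 200); m2 <- rnorm(1, 0, 200)
    s1 <- runif(1, 1, 50); s2 <- runif(1, 1, 50); b <- rnorm(1, 0, 100)
    expect_equal(cnr(roi_sample(m1, s1), roi_sample(m2, s2)),
                 cnr(roi_sample(m2, s2), roi_sample(m1, s1)))
    expect_equal(cnr(roi_sample(m1 + b, s1), roi_sample(m2 + b, s2)),
                 cnr(roi_sample(m1, s1), roi_sample(m2, s2)))
  }
  expect_error(cnr(roi_sample(10, 0), roi_sample(5, 0)), "degenerate")
})

test_that("summarize_by_energy sorts and locates the best energy", {
  mk <- function(e, acc, prec) {
    m <- fake_meas(rep(7, 4) + acc, rep(7, 4))
    m$energy <- e; m$iodine_conc <- 10.5; m$patient_size <- "kg70"
    ap <- accuracy_precision(m)
    ap$precision_mm2 <- prec  # inject a known precision for ranking
    ap
  }
  tab <- summarize_by_energy(list(mk("115keV", 1.2, 0.9),
                                  mk("40keV", 0.3, 0.2),
                                  mk("conventional", 0.8, 0.5)))
  expect_identical(tab$energy, c("conventional", "40keV", "115keV"))
  expect_identical(unname(attr(tab, "best")["accuracy"]), "40keV")
  expect_identical(unname(attr(tab, "best")["precision"]), "40keV")
  expect_error(summarize_by_energy(list(mk("40keV", 1, 1))), "at least 2")
})

test_that("low VMI energies outperform high energies in the simulator", {
  tr <- trend10()
  expect_identical(nrow(tr), 100L)  # 5 energies x 2 sizes x 10 seeds
  low <- c("40keV", "55keV"); high <- c("100keV", "115keV", "130keV")
  for (sz in c("kg70", "kg120")) {
    expect_lt(trend_group_mean(tr, low, sz, "accuracy_mm2"),
              trend_group_mean(tr, high, sz, "accuracy_mm2"))
    expect_lt(trend_group_mean(tr, low, sz, "precision_mm2"),
              trend_group_mean(tr, high, sz, "precision_mm2"))
  }
  # low-energy conditions always segment all 110 holes
  expect_true(all(tr$n_holes_used[tr$energy %in% low] == 110L))
})
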