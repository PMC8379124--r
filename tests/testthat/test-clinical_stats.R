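test_that("the Wald interval reproduces hand evaluation and symmetry", {
  # hand evaluation of the formula for 90/100 vs 80/100
  r <- diff_ci_wald(90, 100, 80, 100)
  se <- sqrt(0.9 * 0.1 / 100 + 0.8 * 0.2 / 100)
  z <- qnorm(0.975)
  expect_equal(r$diff, 0.1)
  expect_equal(r$ci_low, 0.1 - z * se, tolerance = 1e-12)
  expect_equal(r$ci_high, 0.1 + z * se, tolerance = 1e-12)
  # equal inputs give a zero difference and a symmetric interval
  for (x in c(10, 50, 77)) {
    r <- diff_ci_wald(x, 100, x, 100)
    expect_equal(r$diff, 0)
    expect_equal(r$ci_low, -r$ci_high)
  }
  expect_error(diff_ci_wald(5, 0, 1, 10))
  expect_warning(diff_ci_wald(100, 100, 90, 100), "degenerate")
})

test_that("sample size scales with margin and power as designed", {
  expect_identical(sample_size_noninferiority(0.92, 0.20)$n_per_group, 23L)
  # monotonicity over a grid: nonincreasing in margin, nondecreasing in power
  for (p in c(0.85, 0.92)) {
    ns <- vapply(c(0.05, 0.10, 0.15, 0.20), function(m)
      sample_size_noninferiority(p, m)$n_per_group, 1L)
    expect_true(all(diff(ns) <= 0))
    np <- vapply(c(0.55, 0.70, 0.80, 0.90), function(pw)
      sample_size_noninferiority(p, 0.10, power = pw)$n_per_group, 1L)
    expect_true(all(diff(np) >= 0))
    expect_lt(sample_size_noninferiority(p, 0.1, power = 0.51)$n_per_group,
              sample_size_noninferiority(p, 0.1, power = 0.80)$n_per_group)
  }
  expect_error(sample_size_noninferiority(0.92, 0), "margin")
})

test_that("chisq_2x2 is Pearson without continuity correction", {
  r <- chisq_2x2(10, 10, 10, 10)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # against the reference implementation on an arbitrary table
  ref <- stats::chisq.test(matrix(c(44, 47, 11, 16), 2), correct = FALSE)
  r2 <- chisq_2x2(44, 11, 47, 16)
  expect_equal(r2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r2$p, ref$p.value, tolerance = 1e-12)
  refy <- stats::chisq.test(matrix(c(44, 47, 11, 16), 2), correct = TRUE)
  expect_equal(chisq_2x2(44, 11, 47, 16, correct = TRUE)$p, refy$p.value,
               tolerance = 1e-12)
  expect_error(chisq_2x2(0, 0, 5, 5), "margin")
})

test_that("weighted kappa handles agreement extremes and bands", {
  ratings <- c(4, 3, 2, 1, 4, 4, 3, 2)
  k <- weighted_kappa(ratings, ratings, categories = 1:4)
  expect_equal(k$kappa, 1)
  expect_identical(k$band, "excellent")
  expect_identical(kappa_band(0.70), "substantial")
  expect_identical(kappa_band(-0.2), "poor")
  expect_identical(kappa_band(0.15), "slight")
  expect_identical(kappa_band(0.35), "fair")
  expect_identical(kappa_band(0.55), "moderate")
  expect_identical(kappa_band(0.95), "excellent")
  # independent uniform ratings: kappa near 0
  set.seed(31)
  r1 <- sample(1:4, 1e4, replace = TRUE)
  r2 <- sample(1:4, 1e4, replace = TRUE)
  expect_lt(abs(weighted_kappa(r1, r2)$kappa), 0.05)
  # quadratic weights forgive near-misses more than linear
  a <- c(1, 2, 3, 4, 1, 2, 3, 4, 1, 2)
  b <- c(2, 3, 4, 3, 2, 1, 2, 3, 1, 2)
  expect_gt(weighted_kappa(a, b, weights = "quadratic")$kappa,
            weighted_kappa(a, b, weights = "linear")$kappa)
  expect_warning(kc <- weighted_kappa(rep(3, 5), rep(3, 5)), "constant")
  expect_true(kc$undefined)
  expect_true(is.na(kc$kappa))
})

test_that("kruskal_holm combines the omnibus test with Holm post hocs", {
  same <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4))
  r <- kruskal_holm(same)
  expect_equal(r$H, 0, tolerance = 1e-12)
  expect_equal(r$p_raw, 1, tolerance = 1e-12)
  # identical values in every group: degenerate, p = 1
  r0 <- kruskal_holm(list(a = rep(2, 5), b = rep(2, 5)))
  expect_true(r0$degenerate)
  expect_equal(r0$p_raw, 1)
  # strictly separated supports drive the smallest adjusted p below 0.001
  sep <- list(lo = 1:20, mid = 101:120, hi = 201:220)
  rs <- kruskal_holm(sep)
  expect_lt(min(rs$pairwise$p_holm), 0.001)
  expect_lt(rs$p_raw, 1e-6)
  # adjusted p dominates raw p and is dominated by Bonferroni
  expect_true(all(rs$pairwise$p_holm >= rs$pairwise$p_raw))
  expect_true(all(rs$pairwise$p_holm <=
                    pmin(1, rs$pairwise$p_raw * nrow(rs$pairwise))))
})

test_that("Holm adjustment agrees with the hand-stepped oracle", {
  p <- c(0.01, 0.04, 0.03)
  expect_equal(hand_holm(p), c(0.03, 0.06, 0.06))
  expect_equal(stats::p.adjust(p, "holm"), hand_holm(p))
  set.seed(13)
  for (i in 1:20) {
    pr <- runif(sample(2:8, 1))
    expect_equal(stats::p.adjust(pr, "holm"), hand_holm(pr))
    expect_true(all(hand_holm(pr) >= pr))
    expect_true(all(hand_holm(pr) <= pmin(1, pr * length(pr))))
  }
})

test_that("analyze_cohort assembles the full report", {
  co <- simulate_cohort(cohort_params(n_a = 40L, n_b = 40L), seed = 21)
  rep <- analyze_cohort(co)
  expect_s3_class(rep, "cohort_report")
  expect_identical(rep$rates$n, c(40L, 40L))
  expect_equal(rep$rates$diagnostic,
               c(sum(co$patients$diagnostic[co$patients$group == "A"]),
                 sum(co$patients$diagnostic[co$patients$group == "B"])))
  expect_identical(nrow(rep$segment_scores), 14L)
  expect_true(all(rep$segment_scores$p_holm >= rep$segment_scores$p_raw))
  # 7 VMI energies enter the attenuation omnibus test
  expect_identical(rep$attenuation_by_energy$df, 6L)
  expect_lt(rep$attenuation_by_energy$p_raw, 0.001)
  # CNR rows: group A conventional x3 scenarios + group B 7 energies x3
  expect_identical(nrow(rep$cnr), 24L)
  expect_true(all(rep$cnr$cnr > 0))
  expect_identical(rep$kappa$A$weights, "linear")
  # dropping a rater column downgrades kappa to a warning
  co2 <- co
  co2$scores$rater2 <- NULL
  expect_warning(rep2 <- analyze_cohort(co2), "kappa skipped")
  expect_null(rep2$kappa)
})

test_that("noninferiority declarations track the design power", {
  # analytic normal-approximation prediction for the two-sided-within-margin
  # rule at the default group sizes and true rates
  p <- cohort_params()
  d <- p$p_diag_a - p$p_diag_b
  se <- sqrt(p$p_diag_a * (1 - p$p_diag_a) / p$n_a +
               p$p_diag_b * (1 - p$p_diag_b) / p$n_b)
  z <- qnorm(0.975)
  pred <- pnorm((0.10 - z * se - d) / se) - pnorm((-0.10 + z * se - d) / se)
  hits <- vapply(1:100, function(s)
    analyze_cohort(simulate_cohort(p, seed = 1000 + s))$noninferiority$noninferior,
    TRUE)
  expect_lt(abs(mean(hits) - pred), 0.15)
})
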