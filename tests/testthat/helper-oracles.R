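# Independent oracles and shared (memoised) expensive fixtures.

# Radial profile of a uniform disk of radius R convolved with an isotropic
# 2-D Gaussian of sd sigma: the squared distance of N(re, sigma^2 I) from
# the origin is sigma^2 * noncentral-chi^2(df = 2, ncp = (r/sigma)^2), so
# the blurred indicator equals a noncentral chi-squared CDF.
blurred_disk_profile <- function(r, R, sigma) {
  stats::pchisq((R / sigma)^2, df = 2, ncp = (r / sigma)^2)
}

# Brute-force FWHM area: evaluate the analytic blurred-disk profile on a
# grid `fine` times finer than the pixel spacing and count samples at or
# above half the central (peak) value.
oracle_fwhm_area <- function(R, sigma, spacing, fine = 10) {
  h <- spacing / fine
  g <- seq(-R - 4 * sigma, R + 4 * sigma, by = h)
  prof <- blurred_disk_profile(sqrt(outer(g^2, g^2, "+")), R, sigma)
  peak <- blurred_disk_profile(0, R, sigma)
  sum(prof >= peak / 2) * h^2
}

# Literal re-statement of the accuracy/precision definitions, written
# independently of accuracy_precision().
bf_accuracy_precision <- function(meas) {
  ok <- meas[meas$converged, ]
  d <- ok$measured_area_mm2 - ok$true_area_mm2
  sds <- numeric(0)
  for (dd in unique(ok$diameter_mm)) {
    v <- ok$measured_area_mm2[ok$diameter_mm == dd]
    if (length(v) >= 2)
      sds <- c(sds, sqrt(sum((v - mean(v))^2) / (length(v) - 1)))
  }
  list(accuracy = abs(sum(d) / length(d)), precision = mean(sds),
       dispersion = stats::sd(d))
}

# Hand-stepped Holm adjustment (step-down, running maximum, capped at 1).
hand_holm <- function(p) {
  o <- order(p)
  m <- length(p)
  adj <- pmin(1, (m - seq_len(m) + 1) * p[o])
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

.fixture_cache <- new.env(parent = emptyenv())
memo_fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Noiseless default-geometry phantom at 55 keV / 10.5 mg I/mL, segmented.
noiseless_meas55 <- function() memo_fixture("nl55", {
  sp <- phantom_spec(noise_sigma_conventional = c(kg70 = 0, kg120 = 0))
  segment_phantom(render_phantom(sp, energy_spec("vmi", 55), 10.5, "kg70"))
})

# The 10-seed accuracy/precision-versus-energy experiment with defaults.
trend10 <- function() memo_fixture("trend10", {
  run_energy_trend(energies = list(40, 55, 100, 115, 130), concs = 10.5,
                   sizes = c("kg70", "kg120"), seeds = 1:10)
})

# 200 reduced-n cohorts, simulated and analyzed with defaults.  At n = 60
# and p ~ 0.89 an occasional cohort is 60/60 diagnostic; the degenerate-
# interval warning that diff_ci_wald correctly raises there is expected.
recovery200 <- function() memo_fixture("recovery200", {
  p <- cohort_params(n_a = 60L, n_b = 60L)
  lapply(1:200, function(s)
    suppressWarnings(analyze_cohort(simulate_cohort(p, seed = s))))
})

trend_group_mean <- function(tr, energies, size, metric) {
  mean(tr[[metric]][tr$energy %in% energies & tr$patient_size == size],
       na.rm = TRUE)
}
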