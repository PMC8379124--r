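#' Wald confidence interval for a difference of two proportions, with a
#' noninferiority decision
#'
#' `diff = x_a/n_a - x_b/n_b` with the large-sample Wald interval (no
#' continuity correction).  The protocol under test is declared noninferior
#' when the two-sided interval lies entirely within `(-margin, margin)`.
#'
#' @param x_a,n_a successes and size in group A.
#' @param x_b,n_b successes and size in group B.
#' @param conf two-sided confidence level (default 0.95).
#' @param margin noninferiority margin on the proportion scale (default 0.10).
#' @return An object of class `noninferiority_result` with fields `rate_a`,
#'   `rate_b`, `diff`, `ci_low`, `ci_high`, `margin`, `conf`, `noninferior`,
#'   `degenerate` (TRUE when either rate is 0 or 1, collapsing the interval).
#' @examples
#' diff_ci_wald(91, 103, 89, 100)
#' @export
diff_ci_wald <- function(x_a, n_a, x_b, n_b, conf = 0.95, margin = 0.10) {
  stopifnot(n_a > 0, n_b > 0, x_a >= 0, x_b >= 0, x_a <= n_a, x_b <= n_b,
            conf > 0, conf < 1, margin > 0)
  p_a <- x_a / n_a
  p_b <- x_b / n_b
  diff <- p_a - p_b
  se <- sqrt(p_a * (1 - p_a) / n_a + p_b * (1 - p_b) / n_b)
  z <- stats::qnorm((1 + conf) / 2)
  ci <- diff + c(-1, 1) * z * se
  degenerate <- p_a %in% c(0, 1) || p_b %in% c(0, 1)
  if (degenerate)
    warning("a rate of 0 or 1 degenerates the Wald interval")
  structure(list(rate_a = p_a, rate_b = p_b, diff = diff,
                 ci_low = ci[1], ci_high = ci[2], margin = margin,
                 conf = conf,
                 noninferior = ci[1] > -margin && ci[2] < margin,
                 degenerate = degenerate),
            class = "noninferiority_result")
}

#' @export
print.noninferiority_result <- function(x, ...) {
  cat(sprintf("<noninferiority> diff %.4f (%.0f%% CI %.4f to %.4f), margin %.2f: %s\n",
              x$diff, 100 * x$conf, x$ci_low, x$ci_high, x$margin,
              if (x$noninferior) "noninferior" else "not noninferior"))
  invisible(x)
}

#' Sample size for a noninferiority comparison of two proportions
#'
#' Normal-approximation design for two groups with a common expected rate
#' `p`: `n per group = (z_{1-alpha} + z_{power})^2 * 2 p (1-p) / margin^2`,
#' rounded up.  The raw value is rounded to 0.1 before the ceiling: design
#' z-quantiles are conventionally quoted to 2-3 decimals, so figures beyond
#' the first decimal of n carry no design information (91.007 is a design of
#' 91 per group, not 92).
#'
#' @param expected_rate anticipated success rate in both groups, in (0,1).
#' @param margin noninferiority margin, in (0,1).
#' @param alpha_one_sided one-sided type-I error (default 0.05).
#' @param power target power (default 0.80).
#' @return Object of class `sample_size_result` with `n_per_group`, `total`
#'   and the design inputs.
#' @examples
#' sample_size_noninferiority(0.92, 0.10)  # 91 per group, 182 total
#' @export
sample_size_noninferiority <- function(expected_rate, margin,
                                       alpha_one_sided = 0.05, power = 0.80) {
  stopifnot(expected_rate > 0, expected_rate < 1,
            alpha_one_sided > 0, alpha_one_sided < 1,
            power > 0, power < 1)
  if (margin <= 0) stop("margin must be positive")
  z_a <- stats::qnorm(1 - alpha_one_sided)
  z_b <- stats::qnorm(power)
  raw <- (z_a + z_b)^2 * 2 * expected_rate * (1 - expected_rate) / margin^2
  n <- as.integer(ceiling(round(raw, 1)))
  structure(list(n_per_group = n, total = 2L * n, raw = raw,
                 expected_rate = expected_rate, margin = margin,
                 alpha_one_sided = alpha_one_sided, power = power),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("<sample_size> %d per group (%d total) for rate %.2f, margin %.2f, one-sided alpha %.2f, power %.2f\n",
              x$n_per_group, x$total, x$expected_rate, x$margin,
              x$alpha_one_sided, x$power))
  invisible(x)
}

#' Pearson chi-squared test on a 2x2 table
#'
#' Counts are laid out as rows `(a, b)` and `(c, d)`.  No continuity
#' correction by default (set `correct = TRUE` for Yates).
#'
#' @param a,b,c,d non-negative cell counts.
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return List with `statistic`, `df` (1) and `p`.
#' @examples
#' chisq_2x2(91, 12, 89, 11)  # p = 0.884
#' @export
chisq_2x2 <- function(a, b, c, d, correct = FALSE) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), all(is.finite(counts)))
  n <- sum(counts)
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (any(c(r1, r2, c1, c2) == 0)) stop("zero row or column margin")
  num <- abs(a * d - b * c)
  if (correct) num <- max(0, num - n / 2)
  stat <- n * num^2 / (r1 * r2 * c1 * c2)
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Interpretation band for a kappa coefficient
#'
#' Maps kappa to the conventional agreement scale: <= 0 poor; 0.01-0.20
#' slight; 0.21-0.40 fair; 0.41-0.60 moderate; 0.61-0.80 substantial;
#' >= 0.81 excellent.
#'
#' @param kappa agreement coefficient in [-1, 1].
#' @return Character band label.
#' @export
kappa_band <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa <= 0) "poor"
  else if (kappa <= 0.20) "slight"
  else if (kappa <= 0.40) "fair"
  else if (kappa <= 0.60) "moderate"
  else if (kappa <= 0.80) "substantial"
  else "excellent"
}

#' Weighted kappa for paired ordinal ratings
#'
#' Chance-corrected agreement with distance-dependent disagreement weights:
#' `kappa = 1 - sum(W * O) / sum(W * E)` where `O` is the observed joint
#' proportion table, `E` the product of the marginals, and
#' `W[s,t] = |s-t| / (K-1)` (linear, default) or its square (quadratic).
#'
#' @param ratings_r1,ratings_r2 paired ordinal ratings (equal length >= 2).
#' @param weights `"linear"` (default) or `"quadratic"`.
#' @param categories full ordered scale; defaults to the sorted union of the
#'   observed ratings.  Supply explicitly (e.g. `1:4`) when not all scale
#'   points are observed.
#' @return An object of class `kappa_result` with `kappa`, `weights`,
#'   `band`, `n`, and `undefined` (TRUE when both raters are constant, in
#'   which case `kappa` is `NA`).
#' @examples
#' weighted_kappa(c(4, 3, 4, 2), c(4, 3, 3, 2), categories = 1:4)
#' @export
weighted_kappa <- function(ratings_r1, ratings_r2,
                           weights = c("linear", "quadratic"),
                           categories = NULL) {
  weights <- match.arg(weights)
  stopifnot(length(ratings_r1) == length(ratings_r2),
            length(ratings_r1) >= 2L)
  if (anyNA(ratings_r1) || anyNA(ratings_r2)) stop("ratings contain NA")
  if (is.null(categories))
    categories <- sort(unique(c(ratings_r1, ratings_r2)))
  if (!all(c(ratings_r1, ratings_r2) %in% categories))
    stop("ratings outside the declared categories")
  K <- length(categories)
  if (K == 1L) {
    warning("both raters constant: expected agreement undefined")
    return(structure(list(kappa = NA_real_, weights = weights,
                          band = NA_character_, n = length(ratings_r1),
                          undefined = TRUE), class = "kappa_result"))
  }
  f1 <- factor(ratings_r1, levels = categories)
  f2 <- factor(ratings_r2, levels = categories)
  O <- table(f1, f2) / length(ratings_r1)
  p <- rowSums(O); q <- colSums(O)
  W <- abs(outer(seq_len(K), seq_len(K), "-")) / (K - 1)
  if (weights == "quadratic") W <- W^2
  exp_dis <- sum(W * outer(p, q))
  if (exp_dis == 0) {
    warning("both raters constant: expected agreement undefined")
    return(structure(list(kappa = NA_real_, weights = weights,
                          band = NA_character_, n = length(ratings_r1),
                          undefined = TRUE), class = "kappa_result"))
  }
  kappa <- 1 - sum(W * O) / exp_dis
  structure(list(kappa = kappa, weights = weights, band = kappa_band(kappa),
                 n = length(ratings_r1), undefined = FALSE),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("<kappa> %.3f (%s weights, n = %d): %s\n",
              x$kappa, x$weights, x$n,
              if (is.na(x$band)) "undefined" else x$band))
  invisible(x)
}

#' Kruskal-Wallis test with Holm-adjusted pairwise post hoc comparisons
#'
#' Rank-based H statistic with tie correction, followed by pairwise
#' Wilcoxon rank-sum tests whose p-values are adjusted by the Holm
#' step-down method.
#'
#' @param groups named list mapping group label to a numeric vector.
#' @return List with `H`, `df`, `p_raw`, `pairwise` (data.frame `group1`,
#'   `group2`, `p_raw`, `p_holm`) and `degenerate` (TRUE when every value in
#'   every group is identical, forcing `p = 1`).
#' @export
kruskal_holm <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L,
            all(vapply(groups, length, 1L) >= 1L))
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), vapply(groups, length, 1L)),
                   levels = names(groups))
  if (length(unique(values)) == 1L) {
    pairs <- t(utils::combn(names(groups), 2))
    return(list(H = 0, df = length(groups) - 1L, p_raw = 1,
                pairwise = data.frame(group1 = pairs[, 1],
                                      group2 = pairs[, 2],
                                      p_raw = 1, p_holm = 1),
                degenerate = TRUE))
  }
  kw <- stats::kruskal.test(values, labels)
  pairs <- t(utils::combn(names(groups), 2))
  p_raw <- apply(pairs, 1L, function(pr)
    stats::wilcox.test(groups[[pr[1]]], groups[[pr[2]]],
                       exact = FALSE)$p.value)
  list(H = unname(kw$statistic), df = unname(kw$parameter),
       p_raw = kw$p.value,
       pairwise = data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                             p_raw = p_raw,
                             p_holm = stats::p.adjust(p_raw, "holm")),
       degenerate = FALSE)
}

#' Full statistical report on a (synthetic) cohort
#'
#' Reproduces the clinical analysis stack on a [simulate_cohort()] table:
#' per-group diagnostic rates with the Wald noninferiority decision,
#' per-segment mean quality scores with Holm-adjusted pairwise group
#' comparisons, attenuation-by-energy Kruskal-Wallis (group B pooled lumen),
#' cohort-level CNR per scenario (lumen vs fat / muscle / trabecular bone,
#' using across-patient dispersion as the noise term), and weighted kappa
#' per group.
#'
#' @param cohort a `cohort_table`.
#' @param margin noninferiority margin (default 0.10).
#' @param conf confidence level (default 0.95).
#' @param kappa_weights passed to [weighted_kappa()].
#' @return An object of class `cohort_report`: list with `rates`,
#'   `noninferiority`, `segment_scores`, `attenuation_by_energy`, `cnr`,
#'   `kappa`.
#' @export
analyze_cohort <- function(cohort, margin = 0.10, conf = 0.95,
                           kappa_weights = "linear") {
  stopifnot(inherits(cohort, "cohort_table"))
  pat <- cohort$patients
  if (length(unique(pat$group)) < 2L)
    stop("cohort must contain both groups")
  x_a <- sum(pat$diagnostic[pat$group == "A"])
  n_a <- sum(pat$group == "A")
  x_b <- sum(pat$diagnostic[pat$group == "B"])
  n_b <- sum(pat$group == "B")
  rates <- data.frame(group = c("A", "B"), n = c(n_a, n_b),
                      diagnostic = c(x_a, x_b),
                      rate = c(x_a / n_a, x_b / n_b))
  noninf <- diff_ci_wald(x_a, n_a, x_b, n_b, conf = conf, margin = margin)

  sc <- cohort$scores
  seg_rows <- lapply(split(sc, sc$segment), function(d) {
    pr <- stats::wilcox.test(d$rater1[d$group == "A"],
                             d$rater1[d$group == "B"],
                             exact = FALSE)$p.value
    data.frame(segment = d$segment[1],
               mean_score_a = mean(d$rater1[d$group == "A"]),
               mean_score_b = mean(d$rater1[d$group == "B"]),
               p_raw = pr)
  })
  segment_scores <- do.call(rbind, seg_rows)
  segment_scores$p_holm <- stats::p.adjust(segment_scores$p_raw, "holm")
  rownames(segment_scores) <- NULL

  att <- cohort$attenuation
  lum_b <- att[att$group == "B" & att$kind == "lumen", ]
  attenuation_by_energy <- if (nrow(lum_b) > 0 &&
                               length(unique(lum_b$energy)) >= 2L)
    kruskal_holm(split(lum_b$hu, lum_b$energy)) else NULL

  cnr_rows <- list()
  for (g in c("A", "B")) {
    energies <- unique(att$energy[att$group == g])
    for (e in energies) {
      sel <- att$group == g & att$energy == e
      lum <- att$hu[sel & att$roi == "ascending_aorta"]
      for (tis in c("fat", "muscle", "trabecular_bone")) {
        tv <- att$hu[sel & att$roi == tis]
        if (length(lum) < 2L || length(tv) < 2L) next
        cnr_rows[[length(cnr_rows) + 1L]] <- data.frame(
          group = g, energy = e, scenario = paste0("lumen_vs_", tis),
          cnr = cnr(roi_sample(mean(lum), stats::sd(lum)),
                    roi_sample(mean(tv), stats::sd(tv))))
      }
    }
  }
  cnr_tab <- if (length(cnr_rows)) do.call(rbind, cnr_rows) else NULL

  kap <- NULL
  if (all(c("rater1", "rater2") %in% names(sc))) {
    kap <- lapply(split(sc, sc$group), function(d)
      weighted_kappa(d$rater1, d$rater2, weights = kappa_weights,
                     categories = 1:4))
  } else {
    warning("rater columns missing: kappa skipped")
  }

  structure(list(rates = rates, noninferiority = noninf,
                 segment_scores = segment_scores,
                 attenuation_by_energy = attenuation_by_energy,
                 cnr = cnr_tab, kappa = kap),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf("  diagnostic rate: A %.1f%% (%d/%d), B %.1f%% (%d/%d)\n",
              100 * x$rates$rate[1], x$rates$diagnostic[1], x$rates$n[1],
              100 * x$rates$rate[2], x$rates$diagnostic[2], x$rates$n[2]))
  print(x$noninferiority)
  if (!is.null(x$kappa))
    for (g in names(x$kappa))
      cat(sprintf("  kappa group %s: %.3f (%s)\n", g, x$kappa[[g]]$kappa,
                  x$kappa[[g]]$band))
  invisible(x)
}
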