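# The 14 coronary segments scored in the per-segment quality analysis.
COHORT_SEGMENTS <- c("RCA1", "RCA2", "RCA3", "PDA", "PLB", "LM", "LAD1",
                     "LAD2", "LAD3", "D1", "D2", "Cx1", "Cx2", "OM")

# Segment-quality score counts per group (4 = excellent ... 1 = poor),
# normalised to probabilities.
default_likert_probs <- function() {
  list(A = c(`4` = 1220, `3` = 74, `2` = 35, `1` = 55) / 1384,
       B = c(`4` = 949, `3` = 267, `2` = 31, `1` = 63) / 1310)
}

#' Parameters of the synthetic patient cohort
#'
#' Defaults reproduce the statistical structure of the clinical comparison
#' being emulated: 103 regular-dose (group A, conventional images) and 100
#' reduced-dose patients (group B, VMI reconstructions), diagnostic-study
#' rates of 88.4\% and 89\%, segment-quality score distributions and
#' catheter-site frequencies taken from the printed group tables, and
#' lumen/tissue attenuations anchored to the median/IQR attenuation table.
#'
#' @param n_a,n_b group sizes (defaults 103, 100).
#' @param p_diag_a,p_diag_b probability that a patient's study is diagnostic
#'   (defaults 0.884, 0.89).
#' @param likert_probs per-group probabilities over scores 4..1 for rater 1.
#' @param rater_agreement probability that rater 2 repeats rater 1's score;
#'   otherwise an adjacent score is drawn (default 0.8).
#' @param catheter_probs per-group probabilities over catheter sites
#'   (antecubital, forearm, hand/wrist).
#' @param motion_fraction_nondx per-group probability that a non-diagnostic
#'   study is motion-related (defaults 0.833, 0.909).
#' @param anchors attenuation anchor table ([attenuation_anchors()])
#'   providing per-ROI (median, IQR) at each energy.
#' @param patient_effect_share fraction of the log-scale attenuation variance
#'   attributed to a patient-level random effect shared across ROIs
#'   (default 0.3); the marginal median/IQR anchors are preserved.
#' @param seed default RNG seed for [simulate_cohort()].
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_a = 103L, n_b = 100L,
                          p_diag_a = 0.884, p_diag_b = 0.89,
                          likert_probs = default_likert_probs(),
                          rater_agreement = 0.8,
                          catheter_probs = list(
                            A = c(antecubital = 89, forearm = 12,
                                  hand_wrist = 2) / 103,
                            B = c(antecubital = 64, forearm = 19,
                                  hand_wrist = 17) / 100),
                          motion_fraction_nondx = c(A = 0.833, B = 0.909),
                          anchors = attenuation_anchors(),
                          patient_effect_share = 0.3,
                          seed = 1L) {
  stopifnot(n_a > 0, n_b > 0,
            p_diag_a >= 0, p_diag_a <= 1, p_diag_b >= 0, p_diag_b <= 1,
            rater_agreement >= 0, rater_agreement <= 1,
            patient_effect_share >= 0, patient_effect_share <= 1)
  for (g in c("A", "B")) {
    lp <- likert_probs[[g]]
    if (is.null(lp) || length(lp) != 4L || any(lp < 0) ||
        abs(sum(lp) - 1) > 1e-8)
      stop("likert_probs$", g, " must be 4 non-negative probabilities summing to 1")
    cp <- catheter_probs[[g]]
    if (is.null(cp) || any(cp < 0) || abs(sum(cp) - 1) > 1e-8)
      stop("catheter_probs$", g, " must sum to 1")
  }
  if (any(motion_fraction_nondx < 0) || any(motion_fraction_nondx > 1))
    stop("motion_fraction_nondx must be probabilities")
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 p_diag_a = p_diag_a, p_diag_b = p_diag_b,
                 likert_probs = likert_probs,
                 rater_agreement = rater_agreement,
                 catheter_probs = catheter_probs,
                 motion_fraction_nondx = motion_fraction_nondx,
                 anchors = anchors,
                 patient_effect_share = patient_effect_share,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

# Log-normal parameters matching a target median and IQR.  For LN(mu, sigma),
# median = exp(mu) and IQR = 2 * median * sinh(z75 * sigma), hence
# sigma = asinh(IQR / (2 * median)) / z75.  Negative medians (fat) are
# handled by simulating the magnitude and restoring the sign.
lognormal_from_median_iqr <- function(median_hu, iqr_hu) {
  stopifnot(median_hu != 0, iqr_hu >= 0)
  z75 <- stats::qnorm(0.75)
  list(mu = log(abs(median_hu)),
       sigma = asinh(iqr_hu / (2 * abs(median_hu))) / z75,
       sign = sign(median_hu))
}

# Rater 2 given rater 1: repeat with probability `agree`, otherwise move to
# an adjacent score (uniformly over the 1 or 2 valid neighbours).
draw_rater2 <- function(r1, agree) {
  n <- length(r1)
  keep <- stats::runif(n) < agree
  step <- ifelse(r1 == 4L, -1L, ifelse(r1 == 1L, 1L,
                                       sample(c(-1L, 1L), n, replace = TRUE)))
  ifelse(keep, r1, r1 + step)
}

#' Simulate a synthetic patient cohort
#'
#' Generates per-patient diagnostic flags, catheter sites, two raters'
#' 4-point segment-quality scores, and per-ROI attenuations.  Group A
#' patients carry conventional-reconstruction attenuations only; group B
#' patients carry all seven VMI levels.  Attenuations are log-normal with
#' median/IQR matching the configured anchors, with a patient-level random
#' effect shared across ROIs.
#'
#' @param params a [cohort_params()].
#' @param seed RNG seed (default `params$seed`).
#' @return An object of class `cohort_table`: a list with data.frames
#'   `patients` (patient_id, group, diagnostic, nondx_cause, catheter_site),
#'   `scores` (patient_id, group, segment, rater1, rater2) and
#'   `attenuation` (patient_id, group, energy, roi, kind, hu), plus `params`.
#' @export
simulate_cohort <- function(params = cohort_params(), seed = params$seed) {
  stopifnot(inherits(params, "cohort_params"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)

  n <- params$n_a + params$n_b
  group <- rep(c("A", "B"), c(params$n_a, params$n_b))
  p_diag <- ifelse(group == "A", params$p_diag_a, params$p_diag_b)
  diagnostic <- stats::runif(n) < p_diag
  p_motion <- params$motion_fraction_nondx[group]
  nondx_cause <- ifelse(diagnostic, "none",
                        ifelse(stats::runif(n) < p_motion, "motion",
                               "enhancement"))
  catheter <- character(n)
  for (g in c("A", "B")) {
    idx <- which(group == g)
    catheter[idx] <- sample(names(params$catheter_probs[[g]]), length(idx),
                            replace = TRUE, prob = params$catheter_probs[[g]])
  }
  patients <- data.frame(patient_id = seq_len(n), group = group,
                         diagnostic = diagnostic, nondx_cause = nondx_cause,
                         catheter_site = catheter,
                         stringsAsFactors = FALSE)

  nseg <- length(COHORT_SEGMENTS)
  scores <- do.call(rbind, lapply(seq_len(n), function(i) {
    lp <- params$likert_probs[[group[i]]]
    r1 <- sample(c(4L, 3L, 2L, 1L), nseg, replace = TRUE, prob = lp)
    data.frame(patient_id = i, group = group[i], segment = COHORT_SEGMENTS,
               rater1 = r1, rater2 = draw_rater2(r1, params$rater_agreement),
               stringsAsFactors = FALSE)
  }))

  anch <- params$anchors
  anch <- anch[anch$kind %in% c("lumen", "tissue"), ]
  share <- params$patient_effect_share
  z_pat <- stats::rnorm(n)
  att <- list()
  for (g in c("A", "B")) {
    idx <- which(group == g)
    energies <- if (g == "A") "conventional" else as.character(VMI_LEVELS)
    sub <- anch[anch$energy %in% energies, ]
    for (r in seq_len(nrow(sub))) {
      par <- lognormal_from_median_iqr(sub$median_hu[r], sub$iqr_hu[r])
      eps <- stats::rnorm(length(idx))
      logv <- par$mu + par$sigma * (sqrt(share) * z_pat[idx] +
                                      sqrt(1 - share) * eps)
      att[[length(att) + 1L]] <- data.frame(
        patient_id = idx, group = g, energy = sub$energy[r],
        roi = sub$roi[r], kind = sub$kind[r], hu = par$sign * exp(logv),
        stringsAsFactors = FALSE)
    }
  }
  attenuation <- do.call(rbind, att)
  rownames(attenuation) <- NULL

  structure(list(patients = patients, scores = scores,
                 attenuation = attenuation, params = params, seed = seed),
            class = "cohort_table")
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table>", nrow(x$patients), "patients (",
      sum(x$patients$group == "A"), "A /", sum(x$patients$group == "B"),
      "B );", nrow(x$scores), "segment scores\n")
  invisible(x)
}

#' Write a cohort as tidy CSV files
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(cohort$patients, file.path(dir, "patients.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$scores, file.path(dir, "scores.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$attenuation, file.path(dir, "attenuation.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Weighted kappa implied by the rater-2 generative model
#'
#' Closed-form expectation of the weighted kappa between rater 1 (scores
#' drawn from `likert_probs`) and rater 2 (repeat-or-adjacent with the given
#' agreement probability), i.e. the population value the simulator targets.
#'
#' @param likert_probs probabilities over scores 4..1 (named "4".."1").
#' @param agreement repeat probability.
#' @param weights `"linear"` or `"quadratic"` disagreement weights.
#' @return The implied kappa (scalar).
#' @export
implied_weighted_kappa <- function(likert_probs, agreement,
                                   weights = c("linear", "quadratic")) {
  weights <- match.arg(weights)
  scores <- 1:4
  p <- rev(unname(likert_probs))   # index s = score value 1..4
  T <- matrix(0, 4, 4)
  for (s in scores) {
    T[s, s] <- agreement
    nb <- intersect(c(s - 1L, s + 1L), scores)
    T[s, nb] <- (1 - agreement) / length(nb)
  }
  J <- p * T                        # joint P(r1 = s, r2 = t)
  q <- colSums(J)
  W <- abs(outer(scores, scores, "-")) / 3
  if (weights == "quadratic") W <- W^2
  1 - sum(W * J) / sum(W * outer(p, q))
}
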