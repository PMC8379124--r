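#' Segmentation accuracy and precision for one imaging condition
#'
#' Accuracy is the mean deviation of the measured lumen area from the drilled
#' ground-truth area; precision is the spread of repeated measurements.
#' With per-hole differences `d_i = measured_i - true_i` over converged
#' holes: accuracy is `|mean(d_i)|` (or `mean(|d_i|)` with
#' `method = "mean_abs"`); precision is the mean over diameters of the
#' sample SD of the measured areas across that diameter's repeats (the five
#' repeats are the natural replicates).  The pooled SD of `d_i` over all
#' converged holes is exposed as `error_dispersion` for error bars.
#'
#' @param measurements data.frame from [segment_phantom()] (or the same
#'   columns); must belong to a single imaging condition.
#' @param method `"abs_mean"` (default) or `"mean_abs"`.
#' @return An object of class `accuracy_precision`: a list with
#'   `accuracy_mm2`, `precision_mm2`, `error_dispersion_mm2`,
#'   `n_holes_used`, `n_holes_total`, `method` and, when present in the
#'   input, the condition fields.
#' @export
accuracy_precision <- function(measurements,
                               method = c("abs_mean", "mean_abs")) {
  method <- match.arg(method)
  need <- c("measured_area_mm2", "true_area_mm2", "diameter_mm", "converged")
  stopifnot(all(need %in% names(measurements)))
  for (f in c("energy", "iodine_conc", "patient_size"))
    if (f %in% names(measurements) &&
        length(unique(measurements[[f]])) > 1L)
      stop("measurements mix more than one imaging condition (", f, ")")
  ok <- measurements[measurements$converged %in% TRUE, ]
  if (nrow(ok) < 2L)
    stop("need at least 2 converged measurements, got ", nrow(ok))
  d <- ok$measured_area_mm2 - ok$true_area_mm2
  accuracy <- if (method == "abs_mean") abs(mean(d)) else mean(abs(d))
  sds <- tapply(ok$measured_area_mm2, ok$diameter_mm, function(v)
    if (length(v) >= 2L) stats::sd(v) else NA_real_)
  sds <- sds[!is.na(sds)]
  if (length(sds) == 0L)
    stop("precision undefined: no diameter has >= 2 converged repeats")
  cond <- list()
  for (f in c("energy", "iodine_conc", "patient_size"))
    if (f %in% names(measurements)) cond[[f]] <- measurements[[f]][1]
  structure(c(cond,
              list(accuracy_mm2 = accuracy,
                   precision_mm2 = mean(sds),
                   error_dispersion_mm2 = stats::sd(d),
                   n_holes_used = nrow(ok),
                   n_holes_total = nrow(measurements),
                   method = method)),
            class = "accuracy_precision")
}

#' @export
print.accuracy_precision <- function(x, ...) {
  cat(sprintf("<accuracy_precision> accuracy %.4g mm^2, precision %.4g mm^2 (%d/%d holes)\n",
              x$accuracy_mm2, x$precision_mm2, x$n_holes_used,
              x$n_holes_total))
  invisible(x)
}

#' Region-of-interest sample
#'
#' @param mean_hu mean CT number (HU) within the ROI.
#' @param sd_hu standard deviation of CT numbers within the ROI (>= 0).
#' @param area_mm2 ROI area (optional).
#' @param label tissue / lumen tag.
#' @return An object of class `roi_sample`.
#' @export
roi_sample <- function(mean_hu, sd_hu, area_mm2 = NA_real_, label = "") {
  stopifnot(is.finite(mean_hu), is.finite(sd_hu), sd_hu >= 0)
  structure(list(mean_hu = mean_hu, sd_hu = sd_hu, area_mm2 = area_mm2,
                 label = label), class = "roi_sample")
}

#' Contrast-to-noise ratio between two regions of interest
#'
#' `CNR = |mean_lumen - mean_tissue| / sqrt((SD_lumen^2 + SD_tissue^2) / 2)`.
#' Symmetric in its arguments and invariant to adding a constant to both
#' means.
#'
#' @param lumen,tissue [roi_sample()] objects (or lists with `mean_hu`,
#'   `sd_hu`).
#' @return Dimensionless CNR.
#' @examples
#' cnr(roi_sample(400, 20), roi_sample(-88, 25))
#' @export
cnr <- function(lumen, tissue) {
  pooled <- sqrt((lumen$sd_hu^2 + tissue$sd_hu^2) / 2)
  if (pooled == 0)
    stop("degenerate ROIs: both standard deviations are zero")
  abs(lumen$mean_hu - tissue$mean_hu) / pooled
}

#' Summarise accuracy/precision across imaging conditions
#'
#' @param all_conditions list of [accuracy_precision()] results (each carrying
#'   its condition fields).
#' @return Long-format data.frame sorted by energy (conventional first, then
#'   increasing keV) with columns `energy`, `iodine_conc`, `patient_size`,
#'   `accuracy_mm2`, `precision_mm2`, `error_dispersion_mm2`,
#'   `n_holes_used`; the attribute `"best"` names the arg-min energy for
#'   each metric.
#' @export
summarize_by_energy <- function(all_conditions) {
  stopifnot(length(all_conditions) >= 1L)
  rows <- lapply(all_conditions, function(ap) {
    stopifnot(inherits(ap, "accuracy_precision"))
    data.frame(energy = if (is.null(ap$energy)) NA_character_ else ap$energy,
               iodine_conc = if (is.null(ap$iodine_conc)) NA_real_ else ap$iodine_conc,
               patient_size = if (is.null(ap$patient_size)) NA_character_ else ap$patient_size,
               accuracy_mm2 = ap$accuracy_mm2,
               precision_mm2 = ap$precision_mm2,
               error_dispersion_mm2 = ap$error_dispersion_mm2,
               n_holes_used = ap$n_holes_used)
  })
  tab <- do.call(rbind, rows)
  if (length(unique(tab$energy)) < 2L)
    stop("summary requires at least 2 energies")
  ord <- order(energy_rank(tab$energy), tab$iodine_conc, tab$patient_size)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "best") <- c(
    accuracy = tab$energy[which.min(tab$accuracy_mm2)],
    precision = tab$energy[which.min(tab$precision_mm2)])
  tab
}

energy_rank <- function(e) ifelse(e == "conventional", -1,
                                  suppressWarnings(as.numeric(sub("keV$", "", e))))

#' Run the phantom experiment over a grid of conditions and seeds
#'
#' Convenience driver reproducing the accuracy/precision-versus-energy
#' experiment: renders the phantom, segments all holes and computes
#' [accuracy_precision()] for every (energy, size, seed) combination.
#' Conditions where fewer than two holes converge (as happens near the
#' iodine/PMMA contrast crossover at mid-to-high VMI energies) are reported
#' with `NA` metrics rather than an error; a completely failed segmentation
#' is, for ranking purposes, worse than any numeric result.
#'
#' @param energies vector of energies ([as_energy()]-coercible), each paired
#'   with the matching entry of `concs`.
#' @param concs iodine concentrations (mg I/mL), recycled to `energies`.
#' @param sizes simulated patient sizes to run (default both).
#' @param seeds integer vector of noise seeds.
#' @param spec base [phantom_spec()] (its `seed` field is overridden).
#' @param cfg a [segmentation_config()].
#' @param model a [spectral_model()].
#' @return data.frame with one row per condition x seed: condition fields,
#'   `seed`, `accuracy_mm2`, `precision_mm2`, `error_dispersion_mm2`,
#'   `n_holes_used`.
#' @export
run_energy_trend <- function(energies, concs,
                             sizes = c("kg70", "kg120"),
                             seeds = 1:10,
                             spec = phantom_spec(),
                             cfg = segmentation_config(),
                             model = spectral_model()) {
  energies <- lapply(energies, as_energy)
  concs <- rep_len(concs, length(energies))
  out <- list()
  for (s in seeds) {
    sp <- spec; sp$seed <- as.integer(s)
    for (size in sizes) {
      for (i in seq_along(energies)) {
        img <- render_phantom(sp, energies[[i]], concs[i], size, model)
        meas <- segment_phantom(img, cfg)
        row <- data.frame(energy = format(energies[[i]]),
                          iodine_conc = concs[i], patient_size = size,
                          seed = s, accuracy_mm2 = NA_real_,
                          precision_mm2 = NA_real_,
                          error_dispersion_mm2 = NA_real_,
                          n_holes_used = sum(meas$converged))
        ap <- tryCatch(accuracy_precision(meas), error = function(e) NULL)
        if (!is.null(ap)) {
          row$accuracy_mm2 <- ap$accuracy_mm2
          row$precision_mm2 <- ap$precision_mm2
          row$error_dispersion_mm2 <- ap$error_dispersion_mm2
          row$n_holes_used <- ap$n_holes_used
        }
        out[[length(out) + 1L]] <- row
      }
    }
  }
  do.call(rbind, out)
}
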