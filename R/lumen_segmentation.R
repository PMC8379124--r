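#' Configure the FWHM lumen segmentation
#'
#' The lumen interface is delineated at full width at half maximum (FWHM):
#' half of the peak-to-background CT-number difference, referenced to the
#' local background (the PMMA slab is far from 0 HU, so an absolute-HU
#' half-maximum would be meaningless).  Sub-pixel machinery is mandatory
#' because the 0.02 mm diameter granularity of the phantom is far below the
#' pixel spacing.
#'
#' @param patch_halfwidth analysis patch half-width as a multiple of the
#'   nominal hole diameter (default 1.5).
#' @param annulus_inner,annulus_outer background annulus radii as multiples
#'   of the nominal hole radius (defaults 1.8 and 2.4); the annulus must lie
#'   inside the patch.
#' @param upsample_factor integer bicubic upsampling factor applied to the
#'   patch before isocontour extraction (default 8).
#' @param peak_estimator `"central_mean"` (mean HU over pixels within
#'   `central_frac` of the nominal radius from the center; robust to noise)
#'   or `"smoothed_max"` (extremum of a lightly smoothed patch, for small
#'   lumens).
#' @param central_frac radius fraction used by `central_mean` (default 0.25).
#' @param min_contrast minimum |peak - background| in HU below which the
#'   measurement is reported as non-converged (default 30).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(patch_halfwidth = 1.5,
                                annulus_inner = 1.8,
                                annulus_outer = 2.4,
                                upsample_factor = 8L,
                                peak_estimator = c("central_mean",
                                                   "smoothed_max"),
                                central_frac = 0.25,
                                min_contrast = 30) {
  peak_estimator <- match.arg(peak_estimator)
  upsample_factor <- as.integer(upsample_factor)
  stopifnot(patch_halfwidth > 0, annulus_inner > 0,
            annulus_outer > annulus_inner, upsample_factor >= 1L,
            central_frac > 0, min_contrast >= 0)
  # annulus_outer is in units of radius, patch_halfwidth in units of diameter
  if (annulus_outer / 2 > patch_halfwidth)
    stop("background annulus must lie inside the analysis patch")
  structure(list(patch_halfwidth = patch_halfwidth,
                 annulus_inner = annulus_inner,
                 annulus_outer = annulus_outer,
                 upsample_factor = upsample_factor,
                 peak_estimator = peak_estimator,
                 central_frac = central_frac,
                 min_contrast = min_contrast),
            class = "segmentation_config")
}

# Catmull-Rom (Keys a = -0.5) cubic convolution weights for the 4-point
# neighbourhood; t in [0,1) is the fractional offset from the second point.
cubic_weights <- function(t) {
  cbind(((-0.5 * t + 1) * t - 0.5) * t,
        (1.5 * t - 2.5) * t * t + 1,
        ((-1.5 * t + 2) * t + 0.5) * t,
        (0.5 * t - 0.5) * t * t)
}

# Dense interpolation matrix mapping n samples to ((n-1)*U + 1) fine samples
# along one axis, with edge replication.
bicubic_matrix <- function(n, U) {
  s <- seq(1, n, by = 1 / U)
  i0 <- pmin(floor(s), n - 1L)
  t <- s - i0
  w <- cubic_weights(t)
  W <- matrix(0, nrow = length(s), ncol = n)
  for (k in 1:4) {
    idx <- pmin(pmax(i0 + k - 2L, 1L), n)
    W[cbind(seq_along(s), idx)] <- W[cbind(seq_along(s), idx)] + w[, k]
  }
  W
}

# Shoelace polygon area (absolute value), coordinates in mm.
shoelace_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Even-odd ray-casting point-in-polygon test.
point_in_polygon <- function(px, py, x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  crosses <- ((y > py) != (y[j] > py)) &
    (px < (x[j] - x) * (py - y) / (y[j] - y) + x)
  sum(crosses) %% 2L == 1L
}

not_converged <- function(hole, peak, bg, thr) {
  data.frame(hole_id = hole$hole_id, diameter_mm = hole$diameter_mm,
             true_area_mm2 = hole$true_area_mm2,
             measured_area_mm2 = NA_real_, peak_hu = peak,
             background_hu = bg, threshold_hu = thr, converged = FALSE)
}

#' Segment one hole by the FWHM criterion
#'
#' Extracts a patch around the known hole center, estimates local background
#' (median over an annulus) and lumen peak, upsamples the patch bicubically,
#' extracts the closed sub-pixel isocontour at the half-maximum threshold
#' that encloses the center (marching squares with linear interpolation),
#' and returns the shoelace area of that contour.  Works for both bright
#' (lumen above background) and dark (lumen below background, as occurs at
#' high VMI energies where iodine attenuates less than PMMA) lumens.
#'
#' @param img a [render_phantom()] image (or compatible `phantom_image`).
#' @param hole one row of `img$truth` (list/data.frame with `hole_id`,
#'   `diameter_mm`, `center_x_mm`, `center_y_mm`, `true_area_mm2`).
#' @param cfg a [segmentation_config()].
#' @return One-row data.frame: `hole_id`, `diameter_mm`, `true_area_mm2`,
#'   `measured_area_mm2`, `peak_hu`, `background_hu`, `threshold_hu`,
#'   `converged`.  Degenerate patches yield a non-converged row, not an
#'   error.
#' @export
segment_hole <- function(img, hole, cfg = segmentation_config()) {
  stopifnot(inherits(img, "phantom_image"), inherits(cfg, "segmentation_config"))
  sp <- img$pixel_spacing
  nx <- ncol(img$pixels); ny <- nrow(img$pixels)
  xs_all <- (seq_len(nx) - 0.5) * sp
  ys_all <- (seq_len(ny) - 0.5) * sp
  cx <- hole$center_x_mm; cy <- hole$center_y_mm
  if (cx < 0 || cx > nx * sp || cy < 0 || cy > ny * sp)
    stop("hole center outside image")
  half <- cfg$patch_halfwidth * hole$diameter_mm
  jx <- which(abs(xs_all - cx) <= half)
  jy <- which(abs(ys_all - cy) <= half)
  if (length(jx) < 4L || length(jy) < 4L)
    stop("analysis patch out of bounds or too small")
  P <- img$pixels[jy, jx, drop = FALSE]
  xs <- xs_all[jx]; ys <- ys_all[jy]
  r_nom <- hole$diameter_mm / 2
  dist <- sqrt(outer((ys - cy)^2, (xs - cx)^2, "+"))

  in_annulus <- dist >= cfg$annulus_inner * r_nom &
    dist <= cfg$annulus_outer * r_nom
  if (!any(in_annulus)) stop("background annulus contains no pixels")
  bg <- stats::median(P[in_annulus])

  peak <- if (cfg$peak_estimator == "central_mean") {
    inner <- dist <= cfg$central_frac * r_nom
    if (any(inner)) mean(P[inner]) else P[which.min(dist)]
  } else {
    k <- gaussian_kernel(1)
    S <- t(conv_cols(t(conv_cols(P, k, bg)), k, bg))
    cand <- S[dist <= r_nom]
    cand[which.max(abs(cand - bg))]
  }

  contrast <- peak - bg
  thr <- bg + 0.5 * contrast
  if (abs(contrast) < cfg$min_contrast || !is.finite(thr))
    return(not_converged(hole, peak, bg, thr))

  U <- cfg$upsample_factor
  if (U > 1L) {
    Wy <- bicubic_matrix(nrow(P), U)
    Wx <- bicubic_matrix(ncol(P), U)
    Pf <- Wy %*% P %*% t(Wx)
    xf <- seq(xs[1], xs[length(xs)], length.out = ncol(Pf))
    yf <- seq(ys[1], ys[length(ys)], length.out = nrow(Pf))
  } else {
    Pf <- P; xf <- xs; yf <- ys
  }

  # contourLines expects z[i, j] at (x[i], y[j]); Pf is [y, x]
  cl <- grDevices::contourLines(x = xf, y = yf, z = t(Pf), levels = thr)
  best <- NA_real_
  for (cc in cl) {
    closed <- abs(cc$x[1] - cc$x[length(cc$x)]) < 1e-9 &&
      abs(cc$y[1] - cc$y[length(cc$y)]) < 1e-9
    if (!closed) next
    if (!point_in_polygon(cx, cy, cc$x, cc$y)) next
    a <- shoelace_area(cc$x, cc$y)
    # innermost enclosing contour = boundary of the connected region
    # containing the center
    if (is.na(best) || a < best) best <- a
  }
  if (is.na(best)) return(not_converged(hole, peak, bg, thr))
  data.frame(hole_id = hole$hole_id, diameter_mm = hole$diameter_mm,
             true_area_mm2 = hole$true_area_mm2, measured_area_mm2 = best,
             peak_hu = peak, background_hu = bg, threshold_hu = thr,
             converged = TRUE)
}

#' Segment every hole of a phantom image
#'
#' @param img a `phantom_image` with truth records.
#' @param cfg a [segmentation_config()].
#' @return data.frame with one row per ground-truth hole (order preserved),
#'   the columns of [segment_hole()] plus the imaging condition (`energy`,
#'   `iodine_conc`, `patient_size`).
#' @export
segment_phantom <- function(img, cfg = segmentation_config()) {
  stopifnot(inherits(img, "phantom_image"), nrow(img$truth) >= 1L)
  rows <- lapply(seq_len(nrow(img$truth)), function(i)
    segment_hole(img, img$truth[i, ], cfg))
  out <- do.call(rbind, rows)
  out$energy <- format(img$condition$energy)
  out$iodine_conc <- img$condition$iodine_conc
  out$patient_size <- img$condition$patient_size
  out
}
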