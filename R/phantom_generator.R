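#' Specify the digital resolution phantom
#'
#' The physical module being emulated is a 2-cm PMMA slab drilled with 110
#' lumen-mimicking holes: 22 diameter steps from 3.00 to 3.42 mm in 0.02 mm
#' increments, each repeated five times.  The digital version places the
#' holes on a deterministic grid ordered by (diameter, repeat) and records
#' exact pre-blur geometry as ground truth.
#'
#' @param diameters hole diameters in mm (default the 22-step ladder).
#' @param repeats number of repeats per diameter (default 5).
#' @param pixel_spacing in-plane pixel size in mm/px (default 0.4,
#'   approximately clinical coronary CT).
#' @param pitch center-to-center hole spacing in mm; must be at least twice
#'   the largest diameter (default 8).
#' @param margin distance from image border to the outermost hole centers,
#'   in mm (default `pitch`).
#' @param psf_sigma isotropic Gaussian point-spread-function sigma in mm
#'   (default 0.45).
#' @param noise_sigma_conventional named HU noise sigmas for the two
#'   simulated patient sizes at the conventional reconstruction
#'   (default `c(kg70 = 20, kg120 = 40)`).
#' @param vmi_noise_factor named multiplier per VMI level applied to the
#'   conventional sigma (default 0.8 at every level, reflecting the noise
#'   reduction of monochromatic reconstructions).
#' @param seed integer seed controlling the noise realisation.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(diameters = seq(3.00, 3.42, by = 0.02),
                         repeats = 5L,
                         pixel_spacing = 0.4,
                         pitch = 8,
                         margin = pitch,
                         psf_sigma = 0.45,
                         noise_sigma_conventional = c(kg70 = 20, kg120 = 40),
                         vmi_noise_factor = stats::setNames(
                           rep(0.8, length(VMI_LEVELS)), VMI_LEVELS),
                         seed = 1L) {
  stopifnot(length(diameters) >= 1L, all(is.finite(diameters)),
            all(diff(diameters) > 0), repeats >= 1L,
            pixel_spacing > 0, pitch > 0, margin > 0)
  if (psf_sigma < 0) stop("psf_sigma must be non-negative")
  if (!all(c("kg70", "kg120") %in% names(noise_sigma_conventional)))
    stop("noise_sigma_conventional must name kg70 and kg120")
  if (any(noise_sigma_conventional < 0) || any(vmi_noise_factor < 0))
    stop("noise parameters must be non-negative")
  if (!all(as.character(VMI_LEVELS) %in% names(vmi_noise_factor)))
    stop("vmi_noise_factor must name every VMI level")
  if (pitch < 2 * max(diameters))
    stop("hole pitch ", pitch, " mm violates the minimum clearance of twice ",
         "the largest diameter (", 2 * max(diameters), " mm)")
  structure(list(diameters = diameters, repeats = as.integer(repeats),
                 pixel_spacing = pixel_spacing, pitch = pitch,
                 margin = margin, psf_sigma = psf_sigma,
                 noise_sigma_conventional = noise_sigma_conventional,
                 vmi_noise_factor = vmi_noise_factor,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>", length(x$diameters), "diameters x", x$repeats,
      "repeats =", length(x$diameters) * x$repeats, "holes;",
      x$pixel_spacing, "mm/px; PSF sigma", x$psf_sigma, "mm\n")
  invisible(x)
}

# Deterministic grid layout ordered by (diameter, repeat), row-major with
# ceil(sqrt(n_holes)) columns.  Returns the ground-truth table.
layout_holes <- function(spec) {
  d <- rep(spec$diameters, each = spec$repeats)
  rep_id <- rep(seq_len(spec$repeats), times = length(spec$diameters))
  n <- length(d)
  ncol_grid <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  col <- idx %% ncol_grid
  row <- idx %/% ncol_grid
  data.frame(hole_id = seq_len(n),
             diameter_mm = d,
             repeat_id = rep_id,
             center_x_mm = spec$margin + col * spec$pitch,
             center_y_mm = spec$margin + row * spec$pitch,
             true_area_mm2 = pi * (d / 2)^2)
}

# Fractional disk coverage of each pixel in a bounding box, by regular
# nsub x nsub subsampling of the pixel footprint (deterministic).
disk_coverage <- function(xs, ys, cx, cy, radius, spacing, nsub = 16L) {
  off <- (seq_len(nsub) - 0.5) / nsub - 0.5
  cov <- matrix(0, nrow = length(ys), ncol = length(xs))
  for (ox in off) {
    dx2 <- (xs + ox * spacing - cx)^2
    for (oy in off) {
      dy2 <- (ys + oy * spacing - cy)^2
      cov <- cov + (outer(dy2, dx2, "+") <= radius^2)
    }
  }
  cov / nsub^2
}

# Same-size 1-D convolution of each matrix column with symmetric kernel k,
# padding with the scalar `pad`.
conv_cols <- function(M, k, pad) {
  m <- (length(k) - 1L) %/% 2L
  if (m == 0L) return(M * k)
  P <- rbind(matrix(pad, m, ncol(M)), M, matrix(pad, m, ncol(M)))
  out <- stats::filter(P, k, method = "convolution", sides = 2)
  matrix(out[(m + 1L):(m + nrow(M)), ], nrow = nrow(M))
}

gaussian_kernel <- function(sigma_px) {
  m <- max(1L, ceiling(4 * sigma_px))
  k <- stats::dnorm(seq(-m, m), sd = sigma_px)
  k / sum(k)
}

# Mix condition identifiers into the spec seed so different conditions get
# different (but reproducible) noise realisations.  Kept below 2^31.
condition_seed <- function(seed, energy_key, iodine_conc, patient_size) {
  code <- utf8ToInt(paste(energy_key, format(iodine_conc), patient_size,
                          sep = "|"))
  h <- sum(code * seq_along(code))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

#' Render the digital phantom under one imaging condition
#'
#' Renders PMMA background with iodine-filled disks at the hole centers
#' (area-weighted antialiasing at edges), convolves with an isotropic
#' Gaussian point-spread function, and adds i.i.d. Gaussian HU noise whose
#' sigma depends on simulated patient size and reconstruction energy.
#' Ground-truth records describe the exact pre-blur geometry.
#'
#' @param spec a [phantom_spec()].
#' @param energy reconstruction energy ([energy_spec()] or coercible).
#' @param iodine_conc iodine concentration of the hole filling, mg I/mL.
#' @param patient_size `"kg70"` or `"kg120"` (noise level selector).
#' @param model a [spectral_model()] supplying HU values.
#' @return An object of class `phantom_image` with fields `pixels` (HU
#'   matrix, rows = y), `pixel_spacing`, `condition`, `truth`, and the
#'   rendered `lumen_hu` / `background_hu`.
#' @examples
#' sp <- phantom_spec(diameters = c(3, 3.2), repeats = 2)
#' img <- render_phantom(sp, energy_spec("vmi", 55), 10.5, "kg70")
#' @export
render_phantom <- function(spec, energy, iodine_conc,
                           patient_size = c("kg70", "kg120"),
                           model = spectral_model()) {
  stopifnot(inherits(spec, "phantom_spec"))
  patient_size <- match.arg(patient_size)
  energy <- as_energy(energy)
  key <- energy_key(energy)
  truth <- layout_holes(spec)

  # pairwise clearance check (layout is a grid, but diameters/pitch are
  # user-configurable)
  if (nrow(truth) > 1L) {
    dmax <- max(truth$diameter_mm)
    if (spec$pitch < dmax * 2)
      stop("holes overlap or violate clearance after layout")
  }

  lumen_hu <- attenuation("iodine_mixture", iodine_conc, energy, model)
  bg_hu <- attenuation("pmma", 0, energy, model)

  sp <- spec$pixel_spacing
  width <- max(truth$center_x_mm) + spec$margin
  height <- max(truth$center_y_mm) + spec$margin
  nx <- ceiling(width / sp)
  ny <- ceiling(height / sp)
  xs <- (seq_len(nx) - 0.5) * sp
  ys <- (seq_len(ny) - 0.5) * sp
  if (any(truth$center_x_mm - truth$diameter_mm / 2 < 0) ||
      any(truth$center_x_mm + truth$diameter_mm / 2 > width) ||
      any(truth$center_y_mm + truth$diameter_mm / 2 > height))
    stop("hole extends outside the image")

  pixels <- matrix(bg_hu, nrow = ny, ncol = nx)
  amp <- lumen_hu - bg_hu
  for (i in seq_len(nrow(truth))) {
    r <- truth$diameter_mm[i] / 2
    jx <- which(abs(xs - truth$center_x_mm[i]) <= r + sp)
    jy <- which(abs(ys - truth$center_y_mm[i]) <= r + sp)
    cov <- disk_coverage(xs[jx], ys[jy], truth$center_x_mm[i],
                         truth$center_y_mm[i], r, sp)
    pixels[jy, jx] <- pixels[jy, jx] + amp * cov
  }

  if (spec$psf_sigma > 0) {
    k <- gaussian_kernel(spec$psf_sigma / sp)
    pixels <- conv_cols(pixels, k, bg_hu)
    pixels <- t(conv_cols(t(pixels), k, bg_hu))
  }

  sigma <- unname(spec$noise_sigma_conventional[[patient_size]])
  if (energy$mode == "vmi")
    sigma <- sigma * unname(spec$vmi_noise_factor[[as.character(energy$level_keV)]])
  if (sigma > 0) {
    rs <- condition_seed(spec$seed, key, iodine_conc, patient_size)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(rs)
    pixels <- pixels + matrix(stats::rnorm(length(pixels), 0, sigma),
                              nrow = ny, ncol = nx)
  }

  structure(list(pixels = pixels, pixel_spacing = sp,
                 condition = list(energy = energy, iodine_conc = iodine_conc,
                                  patient_size = patient_size),
                 truth = truth, lumen_hu = lumen_hu, background_hu = bg_hu,
                 psf_sigma = spec$psf_sigma, noise_sigma = sigma,
                 seed = spec$seed),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat("<phantom_image>", nrow(x$pixels), "x", ncol(x$pixels), "px @",
      x$pixel_spacing, "mm;", nrow(x$truth), "holes;",
      format(x$condition$energy), "/", x$condition$iodine_conc, "mg I/mL /",
      x$condition$patient_size, "\n")
  invisible(x)
}

fmt17 <- function(x) sprintf("%.17g", x)

#' Write / read a phantom image as a plain-text container
#'
#' A lossless self-describing text format: a header of `key value` lines, a
#' ground-truth CSV block, and the pixel matrix with 17 significant digits
#' (bit-exact round trip for IEEE doubles).
#'
#' @param img a `phantom_image`.
#' @param path file path.
#' @return `write_phantom_image` returns `path` invisibly;
#'   `read_phantom_image` returns the `phantom_image`.
#' @export
write_phantom_image <- function(img, path) {
  stopifnot(inherits(img, "phantom_image"))
  con <- file(path, "w")
  on.exit(close(con))
  e <- img$condition$energy
  writeLines(c("vmilumen-phantom-v1",
               paste("energy", format(e)),
               paste("iodine_conc", fmt17(img$condition$iodine_conc)),
               paste("patient_size", img$condition$patient_size),
               paste("pixel_spacing", fmt17(img$pixel_spacing)),
               paste("psf_sigma", fmt17(img$psf_sigma)),
               paste("noise_sigma", fmt17(img$noise_sigma)),
               paste("lumen_hu", fmt17(img$lumen_hu)),
               paste("background_hu", fmt17(img$background_hu)),
               paste("seed", img$seed),
               paste("truth_rows", nrow(img$truth))), con)
  writeLines(paste(colnames(img$truth), collapse = ","), con)
  tr <- img$truth
  writeLines(paste(tr$hole_id, fmt17(tr$diameter_mm), tr$repeat_id,
                   fmt17(tr$center_x_mm), fmt17(tr$center_y_mm),
                   fmt17(tr$true_area_mm2), sep = ","), con)
  writeLines(paste("pixels", nrow(img$pixels), ncol(img$pixels)), con)
  writeLines(apply(img$pixels, 1L, function(r) paste(fmt17(r), collapse = "\t")),
             con)
  invisible(path)
}

#' @rdname write_phantom_image
#' @export
read_phantom_image <- function(path) {
  lines <- readLines(path)
  fail <- function(ln, what) stop("malformed phantom file at line ", ln, ": ",
                                  what)
  if (length(lines) < 13L || lines[1] != "vmilumen-phantom-v1")
    fail(1, "missing vmilumen-phantom-v1 magic")
  kv <- strsplit(lines[2:11], " ", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  expect_keys <- c("energy", "iodine_conc", "patient_size", "pixel_spacing",
                   "psf_sigma", "noise_sigma", "lumen_hu", "background_hu",
                   "seed", "truth_rows")
  if (!identical(keys, expect_keys)) fail(2, "bad header keys")
  meta <- stats::setNames(as.list(vals), keys)
  ntr <- as.integer(meta$truth_rows)
  hdr <- strsplit(lines[12], ",", fixed = TRUE)[[1]]
  if (!identical(hdr, c("hole_id", "diameter_mm", "repeat_id", "center_x_mm",
                        "center_y_mm", "true_area_mm2")))
    fail(12, "bad truth header")
  tr_lines <- lines[13:(12 + ntr)]
  tm <- do.call(rbind, strsplit(tr_lines, ",", fixed = TRUE))
  if (ncol(tm) != 6L) fail(13, "truth rows must have 6 fields")
  truth <- data.frame(hole_id = as.integer(tm[, 1]),
                      diameter_mm = as.numeric(tm[, 2]),
                      repeat_id = as.integer(tm[, 3]),
                      center_x_mm = as.numeric(tm[, 4]),
                      center_y_mm = as.numeric(tm[, 5]),
                      true_area_mm2 = as.numeric(tm[, 6]))
  pl <- 13L + ntr
  ph <- strsplit(lines[pl], " ", fixed = TRUE)[[1]]
  if (length(ph) != 3L || ph[1] != "pixels") fail(pl, "missing pixels header")
  npr <- as.integer(ph[2]); npc <- as.integer(ph[3])
  if (length(lines) < pl + npr) fail(pl, "truncated pixel block")
  px <- lines[(pl + 1L):(pl + npr)]
  pixels <- matrix(scan(text = px, what = double(), sep = "\t",
                        quiet = TRUE), nrow = npr, ncol = npc, byrow = TRUE)
  structure(list(pixels = pixels,
                 pixel_spacing = as.numeric(meta$pixel_spacing),
                 condition = list(energy = as_energy(sub("keV$", "", meta$energy)),
                                  iodine_conc = as.numeric(meta$iodine_conc),
                                  patient_size = meta$patient_size),
                 truth = truth,
                 lumen_hu = as.numeric(meta$lumen_hu),
                 background_hu = as.numeric(meta$background_hu),
                 psf_sigma = as.numeric(meta$psf_sigma),
                 noise_sigma = as.numeric(meta$noise_sigma),
                 seed = as.integer(meta$seed)),
            class = "phantom_image")
}
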