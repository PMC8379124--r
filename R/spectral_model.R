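# Reconstruction energies available on the simulated dual-layer system:
# polychromatic 120 kVp ("conventional") plus seven virtual monochromatic
# levels from 40 to 130 keV in 15 keV increments.
VMI_LEVELS <- c(40L, 55L, 70L, 85L, 100L, 115L, 130L)

#' Specify a reconstruction energy
#'
#' An energy is either the conventional polychromatic 120 kVp reconstruction
#' or a virtual monochromatic image (VMI) at one of the seven supported
#' levels (40--130 keV in 15 keV steps).  No interpolation between levels is
#' performed.
#'
#' @param mode `"conventional"` or `"vmi"`.
#' @param level_keV VMI energy in keV; required iff `mode = "vmi"`.
#' @return An object of class `energy_spec`.
#' @examples
#' energy_spec("vmi", 55)
#' energy_spec("conventional")
#' @export
energy_spec <- function(mode = c("conventional", "vmi"), level_keV = NULL) {
  mode <- match.arg(mode)
  if (mode == "conventional") {
    if (!is.null(level_keV))
      stop("level_keV must be absent for conventional reconstructions")
  } else {
    if (is.null(level_keV) || length(level_keV) != 1L || is.na(level_keV))
      stop("level_keV is required for VMI reconstructions")
    level_keV <- as.integer(level_keV)
    if (!level_keV %in% VMI_LEVELS)
      stop("VMI level must be one of ", paste(VMI_LEVELS, collapse = ", "),
           " keV (no interpolation between reconstructed levels)")
  }
  structure(list(mode = mode, level_keV = level_keV), class = "energy_spec")
}

#' Coerce to an energy specification
#'
#' Accepts an existing `energy_spec`, a number (interpreted as a VMI level in
#' keV) or the strings `"conventional"` / `"conv"`.
#'
#' @param x object to coerce.
#' @return An `energy_spec`.
#' @export
as_energy <- function(x) {
  if (inherits(x, "energy_spec")) return(x)
  if (is.numeric(x)) return(energy_spec("vmi", x))
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("conventional", "conv"))
      return(energy_spec("conventional"))
    if (grepl("^[0-9]+$", x))
      return(energy_spec("vmi", as.integer(x)))
  }
  stop("cannot interpret ", deparse(substitute(x)), " as an energy")
}

#' @export
format.energy_spec <- function(x, ...) {
  if (x$mode == "conventional") "conventional" else paste0(x$level_keV, "keV")
}

#' @export
print.energy_spec <- function(x, ...) {
  cat("<energy_spec>", format(x), "\n")
  invisible(x)
}

# Column key used to index calibration tables ("conventional", "40", ...).
energy_key <- function(energy) {
  energy <- as_energy(energy)
  if (energy$mode == "conventional") "conventional" else as.character(energy$level_keV)
}

#' Read the attenuation anchor table
#'
#' The package ships a plain-text calibration table of median CT numbers (HU)
#' and interquartile ranges for coronary lumen segments, pooled lumen, fat,
#' muscle and trabecular bone at the conventional reconstruction and at each
#' VMI level.  Users may supply their own file with the same columns
#' (`roi`, `kind`, `energy`, `median_hu`, `iqr_hu`).
#'
#' @param path optional path to an alternative CSV calibration file.
#' @return A data.frame with one row per ROI x energy.
#' @export
attenuation_anchors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "attenuation_anchors.csv",
                        package = "vmilumen", mustWork = TRUE)
  anchors <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("roi", "kind", "energy", "median_hu", "iqr_hu")
  if (!all(needed %in% names(anchors)))
    stop("anchor table must have columns: ", paste(needed, collapse = ", "))
  anchors$energy <- as.character(anchors$energy)
  anchors
}

# Default PMMA slab CT numbers.  PMMA is not represented in the anchor
# table; ~120 HU at 120 kVp with a mild rise toward low keV is a config
# default of the simulator, not a measured value.
default_pmma_hu <- function() {
  c(conventional = 120, "40" = 134, "55" = 127, "70" = 123,
    "85" = 121, "100" = 120, "115" = 119.5, "130" = 119)
}

#' Build the energy-dependent attenuation model
#'
#' Maps (material, iodine concentration, energy) to a mean CT number.  For
#' iodine/saline mixtures the model is affine in concentration at fixed
#' energy, `HU(c, E) = base + c * k(E)`.  The energy scaling `k(E)` follows
#' the pooled lumen anchor row: the configured blood/saline baseline is
#' subtracted from the pooled lumen median at each energy and the result is
#' normalised so that the calibration concentration reproduces the
#' calibration HU at the conventional reconstruction (default: 18.5 mg I/mL
#' gives 400 HU at 120 kVp).  Fat, muscle and trabecular bone are direct
#' anchor-table lookups; water is 0 HU at every energy.
#'
#' @param anchors anchor table from [attenuation_anchors()].
#' @param blood_baseline_hu HU of the zero-iodine mixture baseline
#'   (default 40; a config default, not a measured value).
#' @param pmma_hu named vector of PMMA HU per energy key; default
#'   `default_pmma_hu()`.
#' @param cal_conc,cal_hu calibration pair tying concentration to HU at the
#'   conventional energy (defaults 18.5 mg I/mL, 400 HU).
#' @return An object of class `spectral_model`.
#' @examples
#' m <- spectral_model()
#' attenuation("iodine_mixture", 18.5, "conventional", m)  # 400
#' attenuation("fat", 0, energy_spec("vmi", 55), m)        # -124
#' @export
spectral_model <- function(anchors = attenuation_anchors(),
                           blood_baseline_hu = 40,
                           pmma_hu = default_pmma_hu(),
                           cal_conc = 18.5, cal_hu = 400) {
  stopifnot(is.finite(blood_baseline_hu), cal_conc > 0,
            cal_hu > blood_baseline_hu)
  keys <- c("conventional", as.character(VMI_LEVELS))
  if (!all(keys %in% names(pmma_hu)))
    stop("pmma_hu must name every energy key: ", paste(keys, collapse = ", "))
  pooled <- anchors[anchors$kind == "lumen_pooled", ]
  if (nrow(pooled) != length(keys))
    stop("anchor table must contain a pooled lumen row per energy")
  s <- stats::setNames(pooled$median_hu, pooled$energy)[keys] - blood_baseline_hu
  if (any(s <= 0))
    stop("pooled lumen anchors must exceed the blood baseline at all energies")
  # k(conventional) = (cal_hu - base)/cal_conc; other energies scale with the
  # baseline-subtracted pooled lumen curve.
  k <- (cal_hu - blood_baseline_hu) / cal_conc * s / s[["conventional"]]
  tissue <- anchors[anchors$kind == "tissue", ]
  tissue_hu <- lapply(split(tissue, tissue$roi), function(d)
    stats::setNames(d$median_hu, d$energy)[keys])
  structure(list(anchors = anchors, base_hu = blood_baseline_hu,
                 k = k, pmma_hu = pmma_hu[keys], tissue_hu = tissue_hu,
                 cal_conc = cal_conc, cal_hu = cal_hu),
            class = "spectral_model")
}

#' @export
print.spectral_model <- function(x, ...) {
  cat("<spectral_model> iodine HU(c,E) =", x$base_hu, "+ c * k(E)\n")
  cat("  k:", paste(names(x$k), signif(x$k, 4), sep = "=", collapse = " "), "\n")
  invisible(x)
}

SPECTRAL_MATERIALS <- c("iodine_mixture", "pmma", "fat", "muscle",
                        "trabecular_bone", "water")

#' Mean CT number of a material at a reconstruction energy
#'
#' @param material one of `"iodine_mixture"`, `"pmma"`, `"fat"`, `"muscle"`,
#'   `"trabecular_bone"`, `"water"`.
#' @param iodine_conc iodine concentration in mg I/mL; must be 0 unless
#'   `material = "iodine_mixture"`.
#' @param energy an [energy_spec()] (or anything [as_energy()] accepts).
#' @param model a [spectral_model()]; defaults to the shipped calibration.
#' @return Mean CT number in HU (finite scalar).
#' @export
attenuation <- function(material, iodine_conc = 0, energy,
                        model = spectral_model()) {
  if (length(material) != 1L || !material %in% SPECTRAL_MATERIALS)
    stop("unknown material: ", paste(material, collapse = ", "))
  if (!is.numeric(iodine_conc) || length(iodine_conc) != 1L ||
      !is.finite(iodine_conc) || iodine_conc < 0)
    stop("iodine_conc must be a finite non-negative scalar (mg I/mL)")
  if (material != "iodine_mixture" && iodine_conc != 0)
    stop("iodine_conc must be 0 for material ", material)
  key <- energy_key(energy)
  hu <- switch(material,
    iodine_mixture = model$base_hu + iodine_conc * model$k[[key]],
    pmma = model$pmma_hu[[key]],
    water = 0,
    model$tissue_hu[[switch(material, fat = "fat", muscle = "muscle",
                            trabecular_bone = "trabecular_bone")]][[key]])
  stopifnot(is.finite(hu))
  unname(hu)
}
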