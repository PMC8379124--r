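test_that("segmentation config validates its geometry", {
  expect_s3_class(segmentation_config(), "segmentation_config")
  expect_error(segmentation_config(annulus_outer = 1.5), "annulus_outer")
  expect_error(segmentation_config(patch_halfwidth = 1.0),
               "annulus must lie inside")
  expect_error(segmentation_config(upsample_factor = 0), "upsample_factor")
})

test_that("FWHM of a sharp top-hat disk recovers its true area", {
  sp <- phantom_spec(diameters = 3.20, repeats = 1L, pixel_spacing = 0.05,
                     psf_sigma = 0,
                     noise_sigma_conventional = c(kg70 = 0, kg120 = 0))
  img <- render_phantom(sp, "conv", 18.5, "kg70")
  m <- segment_hole(img, img$truth[1, ])
  expect_true(m$converged)
  expect_lt(abs(m$measured_area_mm2 / (pi * 1.6^2) - 1), 0.01)
  # threshold sits halfway between background and peak
  expect_equal(m$threshold_hu,
               m$background_hu + 0.5 * (m$peak_hu - m$background_hu))
})

test_that("blurred-disk measurement matches the analytic oracle", {
  # single-diameter check at default geometry; the full 22-diameter sweep is
  # exercised by the acceptance suite
  sp <- phantom_spec(diameters = 3.00, repeats = 1L,
                     noise_sigma_conventional = c(kg70 = 0, kg120 = 0))
  img <- render_phantom(sp, 55, 10.5, "kg70")
  m <- segment_hole(img, img$truth[1, ])
  oracle <- oracle_fwhm_area(1.5, sp$psf_sigma, sp$pixel_spacing)
  expect_lt(abs(m$measured_area_mm2 / oracle - 1), 0.02)
})

test_that("contrast below the floor yields a non-converged result", {
  sp <- phantom_spec(diameters = 3.2, repeats = 1L,
                     noise_sigma_conventional = c(kg70 = 0, kg120 = 0))
  # near the iodine/PMMA crossover the contrast collapses
  img <- render_phantom(sp, 85, 10.5, "kg70")
  m <- segment_hole(img, img$truth[1, ])
  expect_false(m$converged)
  expect_true(is.na(m$measured_area_mm2))
})

test_that("a degenerate constant patch is non-converged, not an error", {
  img <- structure(list(
    pixels = matrix(120, 60, 60), pixel_spacing = 0.4,
    condition = list(energy = energy_spec("conventional"),
                     iodine_conc = 0, patient_size = "kg70"),
    truth = data.frame(hole_id = 1L, diameter_mm = 3, repeat_id = 1L,
                       center_x_mm = 12, center_y_mm = 12,
                       true_area_mm2 = pi * 1.5^2)),
    class = "phantom_image")
  m <- segment_hole(img, img$truth[1, ])
  expect_false(m$converged)
})

test_that("dark lumens (negative contrast) are segmented like bright ones", {
  sp <- phantom_spec(diameters = 3.2, repeats = 1L,
                     noise_sigma_conventional = c(kg70 = 0, kg120 = 0))
  img <- render_phantom(sp, 130, 10.5, "kg70")  # iodine below PMMA here
  expect_lt(img$lumen_hu, img$background_hu)
  m <- segment_hole(img, img$truth[1, ])
  expect_true(m$converged)
  expect_gt(m$measured_area_mm2, 0)
})

test_that("measurement is invariant under affine HU rescaling", {
  sp <- phantom_spec(diameters = c(3.0, 3.42), repeats = 1L,
                     noise_sigma_conventional = c(kg70 = 0, kg120 = 0))
  img <- render_phantom(sp, 55, 10.5, "kg70")
  img2 <- img
  img2$pixels <- 1.7 * img$pixels - 300
  for (i in seq_len(nrow(img$truth))) {
    a <- segment_hole(img, img$truth[i, ])
    b <- segment_hole(img2, img$truth[i, ])
    expect_lt(abs(b$measured_area_mm2 / a$measured_area_mm2 - 1), 0.001)
  }
})

test_that("the imaging chain is scale equivariant", {
  base <- phantom_spec(diameters = 3.1, repeats = 1L,
                       noise_sigma_conventional = c(kg70 = 0, kg120 = 0))
  twice <- phantom_spec(diameters = 6.2, repeats = 1L, pixel_spacing = 0.8,
                        pitch = 16, margin = 16, psf_sigma = 0.9,
                        noise_sigma_conventional = c(kg70 = 0, kg120 = 0))
  a <- segment_hole(render_phantom(base, 55, 10.5, "kg70"),
                    vmilumen:::layout_holes(base)[1, ])
  b <- segment_hole(render_phantom(twice, 55, 10.5, "kg70"),
                    vmilumen:::layout_holes(twice)[1, ])
  expect_lt(abs(b$measured_area_mm2 / (4 * a$measured_area_mm2) - 1), 0.01)
})

test_that("noiseless measured area increases monotonically with diameter", {
  meas <- noiseless_meas55()
  expect_true(all(meas$converged))
  per_d <- tapply(meas$measured_area_mm2, meas$diameter_mm, mean)
  expect_true(all(diff(per_d) > 0))
})

test_that("segment_phantom preserves order and is deterministic", {
  sp <- phantom_spec(diameters = c(3, 3.2), repeats = 2L, seed = 5L)
  img <- render_phantom(sp, 55, 10.5, "kg120")
  m1 <- segment_phantom(img)
  m2 <- segment_phantom(img)
  expect_identical(m1, m2)
  expect_identical(m1$hole_id, img$truth$hole_id)
  expect_identical(unique(m1$energy), "55keV")
})
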