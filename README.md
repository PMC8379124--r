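# vmilumen

Quantitative machinery for evaluating reduced-iodine-dose coronary CT
angiography (CCTA) with virtual monochromatic images (VMI), built around a
fully synthetic test bench.

## The problem

Dual-energy CT can reconstruct virtual monochromatic images at a chosen
photon energy (40–130 keV). Low-keV VMI boost iodine contrast, which in
principle allows a CCTA protocol with ~40% less iodine to match the vessel
depiction of a conventional 120 kVp scan at full dose. Two questions follow:

1. **In vitro** — how do reconstruction energy, iodine concentration and
   patient size (image noise) affect the *accuracy* and *precision* of
   coronary lumen cross-sectional area segmentation? This is answered with a
   high-precision resolution phantom: a PMMA slab drilled with 110 holes
   (22 diameters from 3.00 to 3.42 mm in 0.02 mm steps, 5 repeats each)
   filled with iodine/saline mixtures (18.5 mg I/mL ≈ 400 HU and
   10.5 mg I/mL ≈ 242 HU at 120 kVp).
2. **In vivo** — is the reduced-dose protocol (group B, 55 keV VMI)
   *noninferior* to the regular protocol (group A, conventional images) in
   the rate of diagnostic studies, with a 10-percentage-point margin?

No scanner or patient data are public, so this package re-creates the whole
pipeline digitally: an energy-dependent attenuation model calibrated to
printed anchors, a phantom renderer with exact ground truth, the
full-width-at-half-maximum (FWHM) segmentation algorithm, the
accuracy/precision and contrast-to-noise (CNR) statistics, a synthetic
patient-cohort generator, and the clinical statistics stack.

## Core statistics

* **FWHM lumen area** — the lumen boundary is the closed sub-pixel
  isocontour at `background + ½·(peak − background)`; the area is the
  shoelace area of that contour (bicubic 8× upsampling, marching squares).
* **Accuracy / precision** — with per-hole differences
  `dᵢ = measuredᵢ − trueᵢ`: accuracy = `|mean(dᵢ)|`; precision = mean over
  the 22 diameters of the SD across each diameter's 5 repeats.
* **CNR** = `|μ_lumen − μ_tissue| / √(½(σ²_lumen + σ²_tissue))`.
* **Noninferiority** — Wald interval for `p_A − p_B` (no continuity
  correction); noninferior iff the two-sided 95% CI lies within ±0.10.
  Design: `n/group = (z₀.₉₅ + z₀.₈₀)²·2p(1−p)/δ²`.
* **Agreement** — weighted kappa (linear or quadratic weights) with the
  standard poor→excellent interpretation bands; group comparisons via
  Pearson χ², Wilcoxon, Kruskal–Wallis with Holm-adjusted post hocs.

## Worked example

```r
library(vmilumen)

## clinical arithmetic: 91/103 diagnostic vs 89/100
diff_ci_wald(91, 103, 89, 100)
#> <noninferiority> diff -0.0065 (95% CI -0.0937 to 0.0807), margin 0.10: noninferior

sample_size_noninferiority(0.92, 0.10)
#> <sample_size> 91 per group (182 total) for rate 0.92, margin 0.10, one-sided alpha 0.05, power 0.80

## digital phantom, noiseless, 55 keV VMI at the reduced concentration
sp  <- phantom_spec(noise_sigma_conventional = c(kg70 = 0, kg120 = 0))
img <- render_phantom(sp, energy_spec("vmi", 55), 10.5, "kg70")
img
#> <phantom_image> 220 x 240 px @ 0.4 mm; 110 holes; 55keV / 10.5 mg I/mL / kg70

accuracy_precision(segment_phantom(img))
#> <accuracy_precision> accuracy 0.6407 mm^2, precision 1.272e-12 mm^2 (110/110 holes)

round(cnr(roi_sample(400, 20), roi_sample(-88, 25)), 2)
#> [1] 21.56
```

The noiseless accuracy of 0.64 mm² is the *intrinsic* FWHM bias of a ~3 mm
disk blurred by a 0.45 mm PSF (the method undercalls convex boundaries);
precision is numerically zero because repeats are identical without noise.
With the default noise levels both metrics degrade with energy above
55 keV, reproducing the qualitative in vitro finding that 40–55 keV VMI
give the best segmentation.

```r
## synthetic cohort and the full clinical report
analyze_cohort(simulate_cohort(cohort_params(seed = 42)))
#> <cohort_report>
#>   diagnostic rate: A 83.5% (86/103), B 90.0% (90/100)
#> <noninferiority> diff -0.0650 (95% CI -0.1578 to 0.0277), margin 0.10: not noninferior
#>   kappa group A: 0.612 (substantial)
#>   kappa group B: 0.691 (substantial)
```

(A single simulated cohort at these group sizes declares noninferiority
only when the observed rate difference is very small — the decision rule is
strict; see the methods vignette.)

## Command line

```sh
Rscript inst/cli/vmilumen-cli.R phantom-render  --energies conv,40,55 --conc 10.5 --size kg120 --seed 1 --out imgs/
Rscript inst/cli/vmilumen-cli.R phantom-segment --images imgs/ --out measurements.csv
Rscript inst/cli/vmilumen-cli.R phantom-metrics --measurements measurements.csv --out summary.csv
Rscript inst/cli/vmilumen-cli.R cohort-simulate --seed 1 --out cohort/
Rscript inst/cli/vmilumen-cli.R cohort-analyze  --in cohort/ --margin 0.10 --out report/
```

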