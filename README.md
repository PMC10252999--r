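# vesselIQ

Objective and subjective image-quality assessment for coronary CT
angiography (CCTA) reconstruction grids.

Modern photon-counting CT scanners reconstruct each CCTA acquisition with
several convolution kernels (body regular *Br*, body vascular *Bv*, quantum
regular *Qr*) at several sharpness levels (36–48), and radiologists and
physicists need quantitative tools to compare the resulting images. vesselIQ
implements the standard objective readouts on Hounsfield-unit (HU) images
with physical voxel spacing:

- **ROI metrics** — mean attenuation and image noise (sample SD) inside
  circular regions of interest placed on the coronary lumen and
  pericoronary fat, and the contrast-to-noise ratio

  CNR = (HU_coronary − HU_fat) / SD_coronary

- **Vessel sharpness** — attenuation profiles are extracted perpendicular to
  the vessel border (bilinear interpolation in mm coordinates) and fitted
  with a double-sigmoid edge model

  S(x) = b + A · [ 1/(1 + e^(−s(x−x₁))) − 1/(1 + e^(−s(x−x₂))) ]

  by bounded Levenberg–Marquardt least squares; the shared slope *s* (1/mm)
  is the vessel sharpness. Higher *s* means a crisper vessel wall.

- **Statistics** — one-way ANOVA with Tukey HSD post hoc comparisons across
  kernels/levels, tie-corrected Kruskal–Wallis tests and median (IQR)
  summaries for 5-point Likert reader ratings, and inter-reader agreement by
  ICC(2,1) (two-way random effects, absolute agreement) with qualitative
  bins (poor < 0.2 … excellent > 0.8).

Because clinical DICOM data are rarely shareable, the package ships a
first-class synthetic generator: a circular contrast-enhanced lumen
(~800 HU) in pericoronary fat (~−80 HU), blurred by a kernel-specific
Gaussian point-spread function, corrupted by kernel-specific white noise,
for all 12 (family × level) reconstructions, plus a latent-quality generator
for two-rater ordinal rating tables. Every generator is seeded and
bit-reproducible.

## Worked example

```r
library(vesselIQ)

kern <- KernelSpec("Bv", 44)
kern
#> KernelSpec Bv44: psf sigma 0.208 mm, noise 71.3 HU, bias +15 HU

img <- generateVesselImage(PhantomSpec(vesselDiameter = 3.5,
                                       kernel = kern, seed = 11))
img
#> ImageVolume: 67 x 67 voxels, spacing (0.3, 0.3) mm, HU range [-355.3, 941.1]

site <- ProfileSite("RCA_prox", c(10, 10), c(cos(pi/6), sin(pi/6)),
                    halfLength = 4, step = 0.1)
fit <- fitDoubleSigmoid(extractProfile(img, site))
fit
#> DoubleSigmoidFit 'RCA_prox': s = 5.48 /mm, b = -95.0 HU, A = 906.0 HU, edges 2.40..5.77 mm
#>   rmse 50.37 HU, converged (11 iterations)

lumen <- roiMeanSD(img, CircularROI("RCA_prox", c(10, 10), 0.9))
fat   <- roiMeanSD(img, CircularROI("fat", c(5, 5), 2))
cnr(lumen, fat)
#>   coronary_label     cnr
#> 1       RCA_prox 15.2816

iccAbsoluteAgreement(cbind(c(4, 5, 3, 4, 5, 2), c(4, 4, 3, 5, 5, 3)))
#> ICC(2,1) two-way random, absolute agreement, single measures: ICC = 0.7619 (substantial agreement)
```

The fitted slope 5.48 /mm sits in the expected range for a sharp vascular
kernel at this noise level (the noiseless Bv44 phantom is calibrated to
6.5 /mm; noise at 71 HU adds scatter to a single-profile fit). The CNR of
15.3 reflects the ~910 HU lumen-fat contrast divided by the lumen SD.

The full pipeline — simulate the 12-reconstruction grid for a cohort,
measure every ROI and profile, run the comparison statistics, and write
tidy CSVs plus a text report and an md5 manifest — is one call:

```r
runSimulate("out/run1", seed = 42)
```

or, from a shell, `Rscript inst/scripts/vesseliq.R simulate --out out/run1
--seed 42`. `runMeasure()` applies a stored ROI/profile-site layout
unchanged to every reconstruction of each subject, as is standard practice
when comparing reconstructions of the same scan.

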