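---
title: "Methods: quantifying image quality across CCTA reconstruction kernels"
author: "vesselIQ"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying image quality across CCTA reconstruction kernels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vesselIQ)
```

# The measurement problem

A coronary CT angiography acquisition can be reconstructed with different
convolution kernels and sharpness levels, trading spatial resolution against
noise. vesselIQ quantifies that trade-off on reconstructed images with three
objective readouts — ROI attenuation, ROI noise, contrast-to-noise ratio —
and one model-based readout, vessel border sharpness, plus the statistical
layer used to compare reconstructions and readers.

All geometry is expressed in physical millimetres, never pixels: one ROI and
profile-site layout, defined once, is applied unchanged to every
reconstruction of a subject, regardless of each reconstruction's pixel
spacing. This mirrors how such measurements are made in practice (a stored
ROI set replayed over all reconstructions of the same scan) and makes the
comparison across kernels paired by construction.

# ROI metrics and CNR

`roiMeanSD()` selects the pixels whose *centres* fall inside the circle —
the default semantics of the common image-analysis tools — and reports the
mean and the sample standard deviation (denominator \(n-1\)). We
deliberately do not area-weight boundary pixels: the binary rule is simple,
matches the tooling the field uses, and its discretization error is
negligible for ROIs that are large relative to the pixel.

`cnr()` implements

\[
\mathrm{CNR} = \frac{\overline{HU}_\text{coronary} - \overline{HU}_\text{fat}}
                    {SD_\text{coronary}},
\]

with the denominator taken from the *coronary* ROI, exactly as the defining
formula states. Image noise reported per reconstruction, by contrast, is
conventionally measured in the fat ROI; both quantities are computed and
kept separate in the output tables. A zero coronary SD (possible only on
degenerate synthetic input) raises an error rather than returning infinity.

Two invariances follow from the formula and are enforced by tests: CNR is
unchanged by a global HU offset, and scales as \(1/c\) when the image noise
is scaled by \(c\) at fixed means.

# The double-sigmoid sharpness model

An attenuation profile sampled across a vessel rises from the fat baseline
to the contrast-filled lumen and falls again. We model it as

\[
S(x) = b + A\left(\frac{1}{1+e^{-s(x-x_1)}} -
                   \frac{1}{1+e^{-s(x-x_2)}}\right),
\]

with baseline \(b\) (HU), amplitude \(A\) (HU), edge centres
\(x_1 < x_2\) (mm) and one shared slope \(s\) (1/mm). The single \(s\) for
both edges is intentional — the model has one sharpness readout per profile
— and units of 1/mm are used throughout. Typical coronary values run from
roughly 3 /mm (soft kernels) to 10 /mm (sharp vascular kernels).

**Profile extraction.** `extractProfile()` samples the image by bilinear
interpolation along the segment, default step 0.1 mm and half-length 4 mm.
The step guarantees at least ten samples across the sharpest expected edge
(\(s \approx 10\)/mm has a 10–90% rise of about 0.44 mm); bilinear
interpolation is exact for affine intensity fields, which the tests verify.

**Initialization.** The fit starts from a profile-shape heuristic: baseline
= mean of the outer 10% of samples on each side; amplitude = maximum −
baseline; edge centres = first and last half-maximum crossings (linearly
interpolated); slope = 4·max|finite-difference slope|/A, which is exact for
a logistic edge since its maximal derivative is \(As/4\). Profiles without a
pulse shape (maximum not above both endpoints) are rejected with an error
naming the site, because the model is then unidentifiable.

**Optimization.** Bounded Levenberg–Marquardt least squares
(`minpack.lm::nls.lm`) with an analytic Jacobian; \(s\) is constrained to
\((0, 100]\)/mm and the edge ordering is enforced by optimizing
\(w = \log(x_2 - x_1)\). Convergence tolerances are \(10^{-10}\) on
gradient, step and objective; sigmoid exponents are clamped at ±700 so the
asymptotes stay exact in double precision instead of overflowing.
Non-convergence is reported through a flag — never an exception — and
downstream summaries exclude and count flagged fits, since a handful of
failed profiles should not abort a cohort analysis.

On noiseless synthetic profiles the fitter recovers all five generating
parameters to well below 0.1% relative error across the admissible range
(\(s\) from 1 to 10 /mm, pulse widths 1–4 mm), and under heavy noise
(40 HU) the median of 200 replicate fits stays within 10% of the true
slope; an exhaustive grid search over \((s, x_1, x_2)\) at 0.01 resolution,
with the linear parameters solved in closed form, serves as the independent
check that the optimizer finds the global minimum.

# The vessel phantom

Because the underlying patient images cannot be redistributed, the package
generates its own imaging substrate with known ground truth.

**Scene.** A circular lumen of diameter ≥ 2 mm (proximal sites default to
3.5 mm, distal to 2 mm — the calibre range at which coronaries are
evaluated) at 800 HU, embedded in −80 HU fat, centred in a 20 mm field of
view at 0.3 mm pixel spacing. Fat HU and pixel spacing are configurable
assumptions, not measured constants.

**Blur.** Each reconstruction kernel is reduced to a single isotropic
Gaussian PSF width. This is the simplest blur model with one interpretable
parameter; real reconstruction kernels have structured MTFs, which is out
of scope. The disk–Gaussian convolution is evaluated in closed form — for
a disk of radius \(R\), the blurred value at radius \(r\) is the noncentral
\(\chi^2_2\) probability \(P(\chi^2_2(r^2/\sigma^2) \le R^2/\sigma^2)\) —
then area-averaged over an 8×8 supersample per pixel, so the noiseless
image is free of grid artifacts that would bias edge fits. For very narrow
PSFs (\(R/\sigma > 500\)) the locally-flat Gaussian edge-spread form is
used; for large images the radial profile is tabulated at \(\sigma/50\)
resolution and spline-interpolated (interpolation error below
\(10^{-9}\) of the contrast).

**Noise.** White Gaussian, added after blurring. Real CT noise is spatially
correlated with a kernel-dependent noise power spectrum; white noise is
sufficient for exercising the metric layer and keeps the noise level
interpretable as a single SD in HU. Consequently, ROI noise here estimates
the generator's SD directly, which real-data noise would not.

**Calibration of the 12-cell grid.** The default grid fixes, per
(family, level): the noise SD at the reported per-kernel image-noise means
(e.g. 37.9 → 79.3 HU across Br levels); the PSF width by numerically
inverting the noiseless pipeline (blurred 3.5 mm disk → profile → fit) so
the fitted sharpness lands on targets in the observed 3–7 /mm range,
increasing with level within each family and highest for Bv at every level
(Br 3.2/3.8/4.0/4.4, Bv 5.1/5.8/6.5/6.9, Qr 3.3/3.7/4.0/4.4 /mm — two
reported Br cells tie at 3.9, which we split slightly to honour the strict
monotonicity of the PSF in level); and an additive lumen offset
(Br +40, Bv +15, Qr 0 HU) reproducing the observed family ordering of mean
attenuation without modelling spectral physics. Pixel \((i,j)\) centres map
to \(((i-0.5)h, (j-0.5)h)\) in mm (1-based indices), making sub-pixel
geometry unambiguous.

**Ratings.** The two-reader Likert generator is plumbing, not a model of
readers: each reconstruction has a latent quality (an additive family +
level structure favouring Bv and the softer levels), each rater adds a bias
and Gaussian noise (default SD 0.5), and four ascending thresholds cut the
latent value into scores 1–5 (score = 1 + number of thresholds exceeded, so
clamping is automatic). Zero rater noise and bias collapse to perfect
agreement, which pins ICC at exactly 1 — a useful end-to-end check.

# Statistical layer

- **ANOVA**: `stats::aov` with Tukey HSD post hoc comparisons. The post hoc
  method is our choice (the conventional companion of one-way ANOVA).
  All-identical observations make F a 0/0; this is reported as a degenerate
  result, not NaN. Note the design caveat: applied to repeated
  reconstructions of the same subjects, the one-way layout ignores the
  pairing; it is implemented as specified and the caveat is documented.
- **Kruskal–Wallis**: `stats::kruskal.test`, whose H carries the tie
  correction — essential for Likert data, which are heavily tied. All-tied
  input returns H = 0, p = 1 by convention. On tiny samples the asymptotic
  chi-square p is checked in the tests against full permutation enumeration.
- **ICC(2,1)**: two-way random effects, absolute agreement, single
  measures, computed from the mean-squares decomposition. This form is our
  choice for two fixed readers scoring the same targets where systematic
  rater shifts should count as disagreement. The qualitative bins are
  poor ≤ 0.2 < fair ≤ 0.4 < moderate ≤ 0.6 < substantial ≤ 0.8 < excellent;
  boundary values deterministically fall in the lower bin.
- **Likert summaries**: median and IQR with type-7 (linear interpolation)
  quantiles, formatted "m (q1–q3)". The quantile rule is stated so the
  formatted strings are reproducible.

# Problem sizes and what the tests show

The suite exercises the full pipeline at sizes chosen to estimate each
quantity with adequate precision: the grid-trend check averages noise and
CNR over 30 phantom subjects per cell (matching a typical cohort) and
sharpness over 72 profile fits per cell (6 images × 12 profile angles),
repeated over 20 seeds with at least 19 required to reproduce every ordinal
pattern (noise up and CNR down with level in every family; sharpness up
with level and highest for Bv). The type-I-error check simulates 2000 null
datasets of 3×10 observations. Passing these tests shows the machinery is
correct and calibrated *on the phantom's assumptions* — isotropic Gaussian
blur, white noise, circular cross-sections; it does not certify behaviour
on real vessels with plaque, motion, or correlated noise.

# Known limitations

- No CT physics: no projection/reconstruction, iterative-reconstruction
  behaviour, beam hardening, or spectral synthesis.
- No automatic vessel segmentation or ROI placement; layouts are inputs.
- The sharpness model has a single shared slope; asymmetric or multi-edge
  profiles (calcified plaque) are out of scope.
- 2D analysis plane: 3D volumes are sliced before measurement, matching the
  on-plane measurement protocol.
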