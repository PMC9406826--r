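---
title: "Synthetic renal ASL data and the processing pipeline: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic renal ASL data and the processing pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(renasl)
```

# Why a synthetic benchmark

Renal perfusion measured with arterial spin labeling (ASL) MRI depends not
only on the acquisition but also on every step of the processing pipeline:
motion correction, quantification and segmentation. Pipelines differ
between centres, and with in-vivo data there is no ground truth to decide
which differences matter. `renasl` generates fully synthetic renal ASL
time series with known voxelwise perfusion, applies a complete processing
pipeline to them, and scores the pipeline against the known truth. Every
stage is exercised: a 3-D abdominal phantom, spin-echo signal formation,
kinetic-model perfusion weighting, background suppression, respiratory
motion, noise, groupwise non-rigid registration, consensus quantification,
k-means cortex/medulla segmentation, and the evaluation statistics (MSSIM,
Dice, line profiles).

# The forward model

## Phantom

`build_phantom()` constructs a voxelized abdomen: a soft-tissue torso,
bean-shaped kidneys (ellipsoid minus a medial notch ellipsoid) with a
cortical shell of at least two voxels around the medullary interior and a
fluid-like renal pelvis in the hilar notch, a liver adjacent to the right
kidney and a spleen adjacent to the left — the two adjacencies that make
renal segmentation and cropping hard in practice. The anatomy seed jitters
kidney size (±15 %), position (±10 mm) and long-axis tilt, so seeds 1–5
play the role of five body models with different organ geometry.

Tissue properties live in an editable table (`default_tissue_table()`),
not in code: relative proton density, T1 and T2 at 3 T (literature
values: cortex 1142/76 ms, medulla 1545/81 ms, liver 809/34 ms, spleen
1328/61 ms), perfusion (healthy: cortex 250, medulla 50 mL/100 g/min — the
5:1 ratio of healthy kidneys; the abnormal-right scenario reduces the
right kidney to 100/20) and arterial transit times (cortex 1141 ms,
medulla 1123 ms). Simulating a different disease state is a one-line
table edit.

A smooth multiplicative *texture* field (default 25 % standard deviation,
about one voxel correlation length) modulates the equilibrium signal
within each tissue. Real parenchyma is not uniform, and this matters more
than it may seem: with perfectly piecewise-constant organs, image
similarity metrics barely react to motion (almost all voxels see an
identical neighbour after a shift), so motion correction could never show
the benefit it has on real data, and the registration itself would have
almost no structure to lock onto. The texture field is static anatomy: it
travels with the phantom under motion, and because quantification divides
the difference signal by the same textured M0, all round-trip identities
are untouched. Set `texture_amp = 0` for the uniform-tissue idealisation.

## Signal formation

Labels are converted to spin-echo magnitudes `S = rho (1 - e^{-TR/T1})
e^{-TE/T2}` with TR 5000 ms and TE 23 ms. Control images are the M0
reduced to 20 % by background suppression; labeled images additionally
subtract the kinetic-model difference signal dM. The single-compartment
model with the apparent tissue T1 set equal to the blood T1 (1650 ms)
gives, for perfusion `f` (converted to mL/g/s), transit time `dt` and
bolus duration `tau` (PCASL, measured at `tau + PLD`):

dM = 2 M0/lambda · f · alpha · 0.93² · T1b (e^{-(t-min(t,dt+tau))/T1b} - e^{-(t-dt)/T1b})

and for PASL measured at TI with bolus TI1:

dM = 2 M0/lambda · f · alpha · 0.93² · e^{-TI/T1b} (min(TI, dt+TI1) - dt).

Two sign/notation conventions deserve note. First, the quantification
equations are implemented with a *positive* decay-correction exponent
(`e^{+PLD/T1}`, `e^{+TI/T1}`): only this sign inverts the kinetic model,
and the forward/inverse pair is verified to round-trip to machine
precision. Second, the background-suppression correction is `0.93²`
(two suppression pulses of 0.93 each, = 0.8649); it attenuates dM in the
forward direction and is divided out in quantification, so the pair is
consistent.

With the literature transit times, PCASL (PLD 1200 ms ≥ ATT) is in the
fully delivered regime and quantification is exact. PASL with TI 1800 ms,
TI1 1200 ms and ATT 1141 ms is in the *inflow* regime (TI < ATT + TI1):
the consensus PASL equation then underestimates truth by the delivered
fraction (TI − ATT)/TI1 ≈ 0.55. The simulator implements this physics
faithfully and exposes `att_mode = "zero"` to place PASL in the exactly
invertible regime. The package's full-pipeline benchmark uses that mode
for PASL: published renal PASL studies with this timing report
near-nominal cortical perfusion, which implies an effectively delivered
bolus in practice.

## Motion, sampling and noise

Respiratory motion is a craniocaudal translation of the whole phantom
with the classic breathing waveform `d(phi) = A sin^4(pi phi)` over one
cycle centred on the exhalation plateau, discretised into 100 phases; 51
phases are drawn without replacement as the acquisition time points (one
M0 + 25 control–label pairs), with the least-displaced phase reserved for
the M0 frame. The coronal-oblique slice (12° about the left-right axis)
is extracted *after* displacing the phantom, so through-plane motion
changes the in-plane organ shape, as it does for oblique slices of a
breathing abdomen. Noise is additive white Gaussian on the magnitude
images with sigma = (mean kidney M0)/SNR, applied independently per frame
after background suppression.

Defaults: amplitude 16 mm (free-breathing kidney excursions of 10–20 mm
are typical), period 4 s, SNR 40. The SNR default is anchored to the
per-voxel spread it produces in the quantified perfusion maps — roughly
40–50 mL/100 g/min, the level renal ASL maps of this protocol show — since
map noise is what the downstream clustering actually sees; the texture
amplitude and motion amplitude jointly set the uncorrected image
similarity at a level where motion correction has realistic headroom.
All three are configuration, not physics, and are exposed
(`amplitude_mm`, `snr`, `texture_amp`).

# The processing pipeline

## Cropping

Registration runs separately per kidney on a rectangular crop
(`crop_kidney()`). The automatic box thresholds the *temporal mean
control-minus-label* image at 40 % of its in-half maximum, takes the
largest connected component on the requested side and pads by 5 voxels.
The perfusion-weighted image is used rather than the raw mean image
because the kidneys are the only perfused structures: with realistic
intra-tissue texture, raw intensity no longer separates kidney (≈0.66)
from body (≈0.55) reliably, while the difference image lights up only the
kidneys regardless of texture and noise. A manual box is accepted
unchanged, and a zero-perfusion series produces an explicit error asking
for one.

## Groupwise registration

All 51 frames are corrected jointly (`register_groupwise()`): one cubic
B-spline free-form deformation per frame, optimised against the
rank-weighted eigenvalue sum of the inter-frame correlation matrix
(`pca_groupwise_metric()`: eigenvalues sorted descending, metric
`sum_j j·lambda_j`, lower = variance concentrated in leading components =
better aligned), under the constraint that the mean displacement over
frames is zero at every voxel — the stack converges to an implicit mean
image, not to a privileged frame, and the M0 frame participates like any
other (the correlation-based metric is invariant to its different
intensity scale). A groupwise translation stage (per-frame rigid shifts against the same
metric, bounded to ±8 voxels) runs first and absorbs the bulk of the
respiratory displacement — including the control-vs-label group offset
that the random phase sampling produces — because a pure translation
converges far faster than the equivalent B-spline mode.
Multi-resolution then uses six levels of Gaussian
pre-smoothing with sigmas (10, 8, 2, 4, 2, 1) voxels; control-point
spacing is 8 voxels at the finest level, doubled per coarser level; the
optimiser is an adaptive stochastic gradient descent (800 iterations per
level, 50 % voxel subsampling, seeded, with the step-size time advancing
quickly when successive gradients anti-correlate so steps shrink once
aligned). Intensities are interpolated with prefiltered cubic B-splines;
the analytic metric gradient is chained through the interpolation and the
B-spline basis.

Two regularisers are essential and deserve an honest explanation. The
PCA metric's global optimum on ASL data is *not* at true alignment: the
perfusion signal itself is a systematic intensity difference between
control and label frames, and the metric can be improved by deforming the
two groups apart until the cortical difference-signal ring cancels. Left
unchecked this inverts the quantified cortex/medulla contrast — the
classic hazard of registering perfusion-weighted series. Both failure
modes are orthogonal to real breathing motion, which is translation-like
and independent of frame type, so two penalties suppress them without
touching the motion: a bending-energy penalty on each frame's control
lattice (curvature-free translations pass freely; local ring-squeezing is
expensive), and a soft penalty on the difference between the mean
displacement of the control group and that of the label group (real
motion has no systematic control/label split; the contrast-erasure mode
is exactly such a split). Weights (`bend_weight = 0.005`,
`split_weight = 1`) were chosen so that a noise-free, motion-free series
is left essentially untouched (max displacement ≈ 0.1 voxel) while known
rigid shifts are still recovered to better than half a voxel; both are
settings.

Divergence (metric rising by more than 10 % over a level) aborts with the
metric trace attached. Deformations are returned as dense per-frame
displacement fields; on the benchmark simulations their Jacobian
determinants stay positive essentially everywhere.

## Quantification and segmentation

`mean_difference()` averages the 25 control and 25 label frames and
subtracts (identical to averaging per-pair differences); `quantify()`
applies the consensus single-compartment equations (above) with
lambda = 0.9 mL/g, alpha = 0.95 (PASL) / 0.85 (PCASL). Voxels with
negligible M0 are flagged invalid (NA), never silently zeroed.

Segmentation (`segment_kidney()`) follows the semi-automatic recipe: the
whole-kidney outline is an input (a provided mask, or an emulated manual
drawing that dilates the ground-truth outline's boundary voxels with
probability 0.5 — human contours over-include), then 1-D k-means with
k = 2 on the perfusion values inside the mask separates cortex from
medulla. Voxels with physiologically implausible quantified values
(outside −100 to 600 mL/100 g/min by default) are excluded from the
clustering first: residual-motion artifacts at strong intensity edges can
produce extreme outliers, and k-means is notoriously sensitive to them —
without the plausibility filter a single artifact blob can capture one of
the two clusters. Such clamping of implausible perfusion values is
standard practice in ASL analysis. Initialisation is deterministic at the 10th/90th percentiles
(the reference for this step leaves initialisation unstated; percentile
seeding is reproducible, and with 5:1 contrast Lloyd iterations converge
to the same fixed point as random restarts). The higher-mean cluster is
the cortex. Finally the medulla mask is multiplied by the whole-kidney
mask eroded with side-specific 4×5 diagonal structuring elements (origin
at row 2, column 3 — the element definition leaves the origin implicit),
removing spurious medulla on the outer rim; removed voxels are dropped
(the medulla mask is simply multiplied by the eroded whole-kidney mask;
`reassign = "cortex"` instead adds them to the cortex so the two masks
partition the clustered voxels).

# Evaluation

`mssim()` is the standard structural similarity index (11×11 Gaussian
window, sigma 1.5, k1 = 0.01, k2 = 0.03) averaged over the valid
interior; the dynamic range is fixed to the maximum over the whole
51-frame data set rather than per pair, so comparisons against the bright
M0 frame are penalised consistently — these M0 pairs are the lowest
values of the distribution, as expected under background suppression.
`all_pairs_mssim()` enumerates unordered pairs *including* self-pairs
(51 frames → 1326 values, with the 51 self-pairs contributing exactly 1).
MSSIM is computed on the per-kidney crops. Dice overlap compares pipeline
masks with ground-truth masks transformed through the M0 frame's
deformation and rebinarized at 0.5, so both live in the registered space.
Line profiles (`line_profile()`) extract a fixed row/column across all
frames; their total variation along the frame axis is the smoothness
statistic that registration should reduce.

# Problem sizes and numerical choices

The default phantom grid is 96×96×32 voxels at 3×3×5 mm; the extracted
slice is 53×96 at 3×3 mm; per-kidney crops are roughly 40×25. The
benchmark suite processes 5 anatomy seeds × 2 labeling schemes × 2
kidneys. These sizes keep a full benchmark run in the minutes range on a
single core while leaving every organ several voxels thick.
Interpolation: nearest-neighbour for label images and masks, trilinear
for continuous maps, prefiltered cubic B-splines for registration
resampling. K-means runs Lloyd iterations to a fixed point (cap 300).
Degenerate inputs take defined paths with warnings: constant perfusion
inside a kidney mask returns the whole mask as cortex; constant frame
stacks return the uniform-eigenvalue fallback metric `G(G+1)/2`; two
empty masks have Dice 1.

# What passing tests do and do not show

The generator emulates the features the pipeline actually exercises —
two-compartment kidneys with 5:1 perfusion contrast, confounding adjacent
organs, through-plane shape change from oblique slicing, suppressed-frame
noise statistics, intra-tissue heterogeneity — but it is not anatomically
realistic: no vasculature, no pelvis/calyces detail, no cardiac
pulsation, no bulk motion, no dispersion or two-compartment exchange, and
its motion is a pure craniocaudal translation. Results on this benchmark
bound what the pipeline can do under idealised conditions; they do not
certify performance on patient data, where transit-time heterogeneity,
imperfect suppression and non-rigid organ deformation add failure modes
the phantom does not contain.
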