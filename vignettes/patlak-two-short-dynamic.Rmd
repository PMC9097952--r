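---
title: "Whole-body Patlak parametric imaging from two short dynamic acquisitions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body Patlak parametric imaging from two short dynamic acquisitions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynpatlak)
```

## The problem

Whole-body Patlak parametric FDG-PET produces voxel-wise maps of the
metabolic rate of FDG (MR~FDG~ = K~i~ × blood glucose) and of the Patlak
intercept (DV, the apparent distribution volume of free tracer). The
standard protocol keeps the patient on the bed for the full 0–75 min after
injection. A two-short-dynamic protocol instead acquires only the 0–6 min
bolus passage (a single bed over the heart and descending aorta) and the
60–75 min equilibrium phase, merging the aorta time–activity curves from
both windows into one image-derived input function (IDIF). The question the
pipeline addresses: do the parametric values from the shortened protocol
agree with the standard ones?

Patient scans for this comparison are not publicly available, so the
package treats the question end-to-end on synthetic data whose construction
is itself first-class, tested code: a kinetic forward model with known
Patlak ground truth, a framed and noisy acquisition simulator for both
protocols, the IDIF/merging/bridging workflow, voxel-wise map generation,
VOI quantification, and the method-comparison statistics.

## Forward model

The arterial input is by default a Feng-type bolus,

$$C_p(u) = (A_1 u - A_2 - A_3)e^{-\lambda_1 u} + A_2 e^{-\lambda_2 u} + A_3 e^{-\lambda_3 u},
\qquad u = t - t_{\text{peak offset}},$$

zero before tracer arrival (default delay 0.4 min), with amplitudes in
kBq/ml and rates in 1/min. This family was chosen because it reproduces the
sharp early peak and slow late washout of a real arterial curve *and*
admits closed-form integrals and convolutions. A pure tri-exponential model
and tabulated curves are also supported.

Tissue follows the irreversible two-tissue-compartment model (k~4~ = 0, the
Patlak assumption) with transport K~1~, efflux k~2~, trapping k~3~ and
fractional blood volume v~b~. The measured voxel activity is

$$C(t) = \frac{K_1 k_3}{k_2+k_3}\int_0^t C_p
       + \frac{K_1 k_2}{k_2+k_3}\,\big(e^{-(k_2+k_3)t} \ast C_p\big)
       + v_b C_p(t),$$

so the Patlak asymptote has slope $K_i = K_1 k_3/(k_2+k_3)$ and intercept
$V = v_b + K_1 k_2/(k_2+k_3)^2$ exactly. All activities are decay-corrected
to injection time; time is minutes and activity kBq/ml throughout.

Internally, every curve is a finite sum of terms $a\,t^p e^{-\lambda t}$.
This family is closed under running integration and under convolution with
an exponential, so tissue curves, their integrals and per-frame averages
are evaluated in closed form rather than numerically; the test suite checks
them against stiff-ODE integration (0.1% tolerance; observed agreement is
at the 1e-7 level) and adaptive quadrature.

## Acquisition simulation

The standard schedule is: a 6-min single-bed cardiac acquisition sub-framed
as 12×5 s + 8×15 s + 6×30 s, a 4-min dead time, then 16 whole-body passes
(5×2 min, 11×5 min), ending at exactly 75 min with the last three frames at
60–65, 65–70 and 70–75 min. The published pass durations alone total 71
min, so the dead time after the cardiac bed is a reconciliation to honour
both the pass list and the 60–75 min placement of the last three frames;
both the sub-framing and the dead time are configurable. The two-short
schedule is the subset covering 0–6 and 60–75 min.

Each voxel of a phantom region carries the *exact* frame average of its
region's tissue curve; the aorta region carries the frame-averaged plasma
curve. Noise is zero-mean Gaussian in image space with per-voxel, per-frame
standard deviation $\sigma_0\sqrt{\bar A/\Delta t}$ — the count-statistics
scaling (variance ∝ activity, ∝ 1/frame duration) without simulating the
reconstruction chain, which is out of scope. The default
$\sigma_0 = 0.4$ kBq/ml gives late-frame voxel noise of roughly 5–10% on
avid organs, a plausible magnitude for dynamic whole-body frames. Noise is
drawn per frame from a seed derived from the image seed and the frame start
time, which makes an important study property hold bit-exactly: restricting
a simulated standard acquisition to the two-short frames is identical to
simulating the two-short protocol directly — both study arms really are
subsets of one session.

The default grid is 48×48×48 voxels of 4 mm with seven normal organs
(brain, lung, liver, spleen, heart wall, bone, muscle), a descending-aorta
blood column and optional spherical lesions. Organ kinetics are solved
backwards from target MR~FDG~ and DV values chosen inside clinically
reported whole-body bands, with overall turnover $k_2+k_3 = 0.35$/min and
$v_b$ set to a quarter of the intercept; given the targets, the
micro-parameters follow in closed form.

What the generator does *not* emulate: reconstruction point-spread and
partial-volume effects, attenuation/scatter residuals, patient motion and
peristalsis, plasma-to-whole-blood differences, and spatially correlated
noise. Passing tests therefore demonstrate the internal consistency and
statistical behaviour of the workflow, not clinical performance on real
scanners.

## The input-function gap

The two-short IDIF samples 0–6 and 60–75 min; the Patlak abscissa needs
$\int_0^t C_p$ with $t$ in the last three frames, so the 6–60 min interval
must be modelled. The default family is a sum of three positive decaying
exponentials — the standard description of FDG plasma clearance, and
identifiable from the two windows alone — fitted by Levenberg–Marquardt
least squares on the log scale to the exact frame-averaged model (so
noiseless recovery is exact). Samples within 1 min of the peak are
excluded from this fit: they are dominated by bolus transit, which a
decaying-exponential family cannot represent, and including them was found
to drag the washout components and inflate the bridged integral by about
2% for bolus-shaped inputs; with the exclusion the bridging error drops
below 0.1% while recovery of a genuinely tri-exponential curve remains
exact. Two alternative families are available: a refit of the full Feng
bolus shape, and a crude mono-exponential bridge between the windows.

The running integral combines trapezoids over sampled segments (midpoint
timestamps; the first frame's mean held from the frame start, which is a
zero-anchored rise for a real IDIF whose first 5-s frame precedes tracer
arrival) with the fitted model's closed-form integral across any sampling
hole wider than 6 min. The 4-min dead time inside the standard schedule is
therefore bridged by trapezoid, the 54-min gap of the two-short protocol by
the model. Negative model values are clamped at zero with a warning.

## Maps, VOIs and statistics

Both protocols run through the identical voxel-wise code path: Patlak
coordinates from the last three frames, ordinary least squares for slope
and intercept, MR~FDG~ = K~i~ × glucose (µmol/min/ml with glucose in
mmol/L) and DV reported in percent; no lumped constant is applied. Voxels
with non-positive plasma activity become NaN rather than zero. SUV images
come from the mean of the last three frames scaled by configured
dose/weight.

Lesion VOIs use the 41% of-maximum isocontour: the 26-connected component
containing the seed, thresholded at 41% of the component's own maximum and
iterated to a fixed point (capped at 20 rounds, re-anchoring on the hottest
voxel). On a Gaussian blob this recovers the analytic isocontour radius
$\sigma\sqrt{2\ln(1/0.41)}$ to well within a voxel. Organ VOIs are fixed
spheres (default 10 mm, liver 25 mm). "Peak" is the PERCIST-style highest
mean of a 1-cm³ spherical neighborhood centered on any VOI voxel. VOIs are
defined on the standard maps and copied unchanged to the two-short maps, so
the paired samples have equal voxel counts by construction.

The agreement battery is implemented from scratch: Passing–Bablok
regression (shifted median of pairwise slopes, slopes of −1 excluded,
rank-based confidence bounds), a residual-sign cusum linearity test, and
Bland–Altman analysis with Spearman correlation. Numerical choices worth
stating: the cusum excursion statistic carries a +0.3 continuity
correction before the Kolmogorov–Smirnov reference — the discrete walk's
maximum undershoots the Brownian-bridge supremum, and without the
correction the nominal 5% level is unattainable at cohort-sized n (the
calibration is verified by simulation in the test suite, with the observed
type-I rate near 0.045). Bland–Altman "95% CI" values in the clinical
literature are often numerically limits of agreement; this package
computes and labels limits of agreement (bias ± 1.96 sd) and separately a
true confidence interval of the bias. The Spearman CI uses the Fisher
transform with Fieller's standard error; all p-values are two-sided and no
multiplicity correction is applied.

## The synthetic study

`run_study()` emulates the study design: 21 subjects by default, organ
targets drawn from truncated normals (CV 25%) around the default bands,
1–3 lesions per subject with MR~FDG~ targets of 0.05–0.25 µmol/min/ml,
blood glucose from a truncated normal below the 11 mmol/L exclusion bound,
per-subject input-function amplitude and arrival-time variation. Per
subject, the standard acquisition is simulated once and the two-short arm
is its frame subset; the merged two-short IDIF round-trips through the CSV
exchange dialect (`frame_start_s,frame_end_s,activity_kBq_ml`, UTF-8, LF,
17 significant digits — bit-exact) before gap fitting; maps, copied VOIs
and max/mean/peak extraction follow; the pooled pairs per metric
(MR/DV × max/mean/peak) feed the battery, reported for normal organs,
lesions and pooled. Every random draw descends from the configuration
seed, and a rerun with the same configuration is bit-identical. A failed
subject is skipped with a warning rather than aborting the run.

Problem sizes were chosen so a full study is a desk-scale computation: the
48³ grid, 31 standard frames and 21 subjects run in well under a minute,
and the complete test suite in about one. With the default noise the
pooled comparison lands where the study design predicts: Passing–Bablok
slopes within a fraction of a percent of 1, Bland–Altman biases below 0.2%
of the metric means, Spearman rho above 0.999, and the cusum test retains
linearity — the idealized analogue of near-unity clinical agreement
tables.

## Known limitations

The simulation shares one session between the arms; a clinical two-visit
protocol would add repositioning, two CT scans and two independently
placed aorta VOIs, none of which are modelled. The intercept (DV) estimated
from three late frames is strongly noise-amplified (its per-voxel error is
roughly the Ki error scaled by the mean normalized time, ~100), so DV VOI
statistics are intrinsically noisy at realistic noise — visible in the
wide DV spreads the study reports. The 41% threshold is taken of the
component maximum and iterated; other conventions (global maximum, single
pass) exist and would give slightly different lesion volumes. Tabulated
input functions are supported for evaluation and integration but not for
closed-form tissue generation.
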