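---
title: "Resting-state EEG features and motor-imagery BCI performance: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG features and motor-imagery BCI performance: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(restalpha)
```

## The scientific question

A sizeable fraction of people cannot control a motor-imagery (MI)
brain–computer interface above chance, and screening candidates before
lengthy training is a practical problem.  This package implements a
resting-state screening pipeline: it computes three features of eyes-open
and eyes-closed resting EEG — relative power level (RPL), power spectral
entropy (PSE) and Lempel–Ziv complexity (LZC), per frequency band and
channel — scores each subject's MI ability with a multiclass CSP + linear
SVM classifier under repeated cross-validation, and relates the two with
channel-wise Pearson correlation maps, repeated-measures band contrasts,
group comparisons, and screening classifiers that separate high (H) from
low (L) performers.

## The performance score

MI trials (left hand, right hand, both hands, both feet) are band-pass
filtered to 8–30 Hz with a 4th-order Butterworth filter applied zero-phase.
For each class a one-vs-rest common-spatial-patterns problem is solved: with
$\Sigma_c$ the mean trace-normalized trial covariance of class $c$ and
$\Sigma_{\bar c}$ the pooled covariance of the remaining classes, the
filters $w$ solve $\Sigma_c w = \lambda (\Sigma_c + \Sigma_{\bar c}) w$, and
the two eigenvectors with the largest $\lambda$ are kept (eight filters for
four classes).  Under this normalization $\lambda = 0.5$ marks an
uninformative direction.  Features are the log of each filter's trial
variance normalized by the total variance over all filters, which makes them
invariant to trial amplitude scaling.  A linear SVM with $C = 1$ is trained
on these features and evaluated with ten repetitions of stratified ten-fold
cross-validation; the mean accuracy is the subject's MI performance, and the
subject is assigned to group H (≥ 60%), M ([40, 60)) or L (< 40%).

Two deliberate protocol choices, both configurable:

* **CSP is refit inside every training fold.**  Fitting spatial filters once
  on all trials and then cross-validating only the classifier leaks test
  information into the filters; the refitting protocol is the defensible
  default, and a `fit_once = TRUE` mode exists for replication of the
  laxer reading.
* **Welch/trace normalization and shrinkage.**  Trial covariances are
  normalized by their trace before averaging; if the composite covariance is
  not safely positive definite, both matrices are shrunk 5% towards a scaled
  identity with a warning.

## The resting-state features

Resting runs are common-average referenced, filtered per band (theta 4–8,
alpha 8–13, beta 13–30, gamma 30–50 Hz; 4th-order zero-phase Butterworth),
and only then cut into consecutive non-overlapping 1500-sample epochs (six
per one-minute run at 160 Hz), so epochs carry no filter transients.  Each
feature is computed per epoch and channel and averaged over epochs.

* **RPL** is the band's mean-square power divided by the total 4–50 Hz
  power.  The total is defined as the *sum of the four band powers* — the
  bands partition 4–50 Hz — so the four RPLs of an epoch sum to exactly 1.
  A broadband-filter total is available as `p_all = "broadband"`; it agrees
  within a few percent but loses the exact simplex property.
* **PSE** is the Shannon entropy (nats) of the plain rectangular-window
  periodogram of the band-filtered epoch, restricted to the in-band bins and
  normalized to sum to one.  It is bounded by $\ln n_\text{bins}$ and
  reaches the bound only for a flat in-band spectrum.  Note that a *noise*
  signal with a flat expected spectrum does not reach the bound: single-epoch
  periodogram bins of Gaussian noise are exponentially distributed, which
  costs about $1 - \gamma \approx 0.42$ nats.  Flatness checks in the tests
  therefore use a deterministic equal-amplitude multi-sine on the in-band
  periodogram grid.
* **LZC** binarizes the band-filtered epoch at its median (ties map to 1, so
  a constant epoch is a well-defined all-ones sequence), counts LZ76
  patterns $C(n)$ with the counter initialized at 1, and normalizes by the
  random-sequence asymptote: $\text{LZC} = C(n)\log_2(n)/n$.  Under this
  convention iid binary sequences approach 1 and a constant 1500-sample
  epoch gives $2\log_2(1500)/1500 \approx 0.0141$.  The median threshold
  (rather than the mean, offered as an option) is the dominant convention
  and gives exact amplitude-scale invariance.

All three features are invariant to positive amplitude scaling, so the
microvolt calibration of a recording never matters downstream.

## The association and screening analyses

Every feature cell (state × band × channel) is Pearson-correlated with the
per-subject performance measure; p-values come from the usual t
transformation, are floored at `1e-300`, and zero-variance cells are
reported as `NA` rather than 0.  No multiplicity correction is applied by
default, matching the uncorrected significance stars typical of channel-map
figures; Benjamini–Hochberg can be applied downstream from the tidy output.

To compare bands, the absolute correlations are treated as repeated
measures with *channels as units* and band as the within-unit factor:
Mauchly's sphericity test, the Greenhouse–Geisser-corrected F-test (epsilon
computed as $\mathrm{tr}(E)^2 / ((k-1)\,\mathrm{tr}(E^2))$ on an orthonormal
contrast basis), and all pairwise paired t-tests.  Channels are spatially
correlated, so this ANOVA describes the band profile of the map rather than
an inference over independent units — the same caveat applies to the
analysis convention it reproduces.

Per-subject scalar features average two channels per feature (C3/C4 for
RPL, C4/Cp4 for PSE, C3/Cp4 for LZC; eyes-open alpha).  Group contrasts are
Welch t-tests (the unequal-variance form is the safer reading of an
"independent sample t-test" between groups of different sizes).  The
screening classifiers are linear SVMs ($C = 1$) on these scalars — each
feature alone (a 1-D SVM is effectively a learned threshold) and the 3-D
combination — under stratified 10-fold cross-validation with z-scoring
fitted inside each training fold.  Class imbalance between H and L is left
unweighted by default.  Accuracy is the pooled confusion-matrix diagonal,
so the reported accuracy and the confusion matrix are consistent by
construction.

## The synthetic cohort generator

The generator exists so that every stage is testable end-to-end without any
data download, and its defaults encode the study conditions the analysis
assumes: 64-channel 10-10 montage at 160 Hz, one-minute eyes-open and
eyes-closed resting runs (9600 samples → six 1500-sample epochs), and 75
four-second trials per MI class (25 per run, three runs).

**Resting signals** are a sum of a $1/f$ background (default 25% of the
4–50 Hz power, spectral slope 1) and four independent band-limited Gaussian
components produced by filtering white noise with the *same* Butterworth
filters the analysis uses downstream — this choice trades nominal
exactness of band fractions for consistency with the measuring filters, so
the planted power profile is recovered within Monte-Carlo tolerance.  Each
component is variance-normalized before scaling, so planted fractions do
not depend on a component's bandwidth.

**Planted structure.**  Each subject has a latent pair (alpha fraction,
MI separability) drawn from a Gaussian copula with correlation
`planted_rho`.  Separability maps uniformly onto `separability_range`;
the alpha fraction maps through a cubic power of its quantile onto
`alpha_range` (0.15–0.55).  The convex link makes only clearly
high-separability subjects show distinctly elevated alpha, reproducing the
observed group geometry in which H is separable while M and L overlap.  The
same latent also narrows the alpha component's bandwidth around 10.5 Hz for
high-alpha subjects, so their in-band spectrum is more peaked: PSE and LZC
of the alpha band then correlate *negatively* with separability, as the
analysis expects, without planting them separately.  Non-alpha band shares
receive per-subject log-normal jitter (sd 0.3); without it, the simplex
constraint would force every other band's RPL to mirror alpha exactly and
all bands would correlate equally strongly in magnitude.

**Eyes-closed state.**  A widespread, posterior-dominant extra alpha
component is added (power weight 1.2 on occipital channels, 0.6 elsewhere),
with a per-subject magnitude drawn independently of separability and scaled
to the cohort's typical alpha level rather than the subject's own.  This
models the classic eyes-closed occipital alpha increase as a masking
signal: it leaves the eyes-open maps untouched and attenuates the
eyes-closed correlations, which is why the pipeline finds eyes-open
features more predictive.

**MI trials** are unit-variance broadband noise plus a dominant alpha-band
(mu-rhythm) component whose variance on the class-specific sensorimotor
channel group is reduced by `erd_depth × separability` — an
event-related-desynchronization-like covariance contrast.  The groups
follow contralateral ERD topography: right hand → C3/C5/Cp3/Cp5, left hand
→ C4/C6/Cp4/Cp6, both hands → both groups, feet → Cz/Cpz/Fz.  The
constants `erd_depth = 0.6` and `mu_power = 0.6` were fixed once by
Monte-Carlo calibration of the accuracy curve: chance (≈25%) at
separability 0, ≈40% at 0.5, >80% at 1, monotone throughout, so a uniform
separability marginal populates all three groups with L the largest — the
group-size ordering seen in practice.

**Reproducibility.**  Every subject, state and run draws from its own
stream derived from the master seed (high-volume noise comes from a
dedicated 64-bit Mersenne stream seeded from R's RNG), so a subject's data
are bit-identical regardless of cohort size and the whole pipeline is
byte-for-byte reproducible from the seed.

**What the generator does not emulate.**  No volume conduction or forward
model (channels are independent up to CAR), no ocular/muscle artifacts, no
non-stationarity within runs, no 1/f knee, and trial ERD is stationary
within the trial window.  Passing recovery tests on this cohort
demonstrates that the pipeline measures what it claims under its own
assumptions; it does not certify performance on real recordings.

## Numerical choices and degenerate inputs

* Zero-phase filtering uses steady-state initial conditions and
  odd-reflection padding (three filter lengths), the standard
  forward–backward treatment; the magnitude response is the squared
  Butterworth response, so band edges sit at 1/4 power.
* Adjacent analysis bands share their edge frequency; their filtered
  outputs are therefore not exactly orthogonal (normalized cross-power
  ≈ 0.08 at the shared edge), a property of any band partition with
  finite-order filters.
* CSP filters are unit-norm with the largest-magnitude coefficient made
  positive, so fits are deterministic and comparable across refits.
* All-zero epochs make RPL and PSE undefined and raise errors; constant
  epochs are a *defined* LZC case (all-ones sequence, $C(n) = 2$).
* Group boundaries: 40.0 → M and 60.0 → H (intervals $[40,60)$ and
  $[60,100]$), resolving the overlapping printed range labels
  deterministically.
* Annotations are stored in samples, not seconds, to avoid floating-point
  drift at 160 Hz; EDF round-trips are exact up to the 16-bit quantization
  step of the declared physical range.

## Problem sizes used by the tests

The test suite exercises the full pipeline at sizes chosen to make the
Monte-Carlo checks decisive while keeping a laptop-scale run: a 100-subject
cohort (planted rho 0.5, full 64-channel montage, 10×10 cross-validation)
for correlation recovery, a 63-subject cohort (planted rho 0.9) for the
screening checks, and reduced montages (24 channels) for unit tests and the
demonstration pipeline.  The acceptance script reports the same quantities
at 60 and 50 subjects.

## Known limitations

* The repeated-measures band ANOVA treats channels as units (see above).
* The EDF reader implements the 16-bit continuous (EDF+C) dialect with one
  annotation track — what the motor-imagery database uses — not the full
  EDF+ zoo (no discontinuous files, no sub-second record offsets).
* The screening SVM is linear by design; no hyperparameter search is
  performed anywhere, matching the fixed-$C$ protocol.
* With strong class imbalance the unweighted SVM favours the majority
  class; a class-weighted variant can be obtained by passing priors through
  `e1071::svm`'s interface if needed, but is deliberately not the default.
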