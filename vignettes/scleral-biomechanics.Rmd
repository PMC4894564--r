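---
title: "Models and calibration in scleramech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and calibration in scleramech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scleramech)
```

# The measurement problem

Inherited open-angle glaucoma in *ADAMTS10*-mutant dogs produces a slow,
life-long rise in intraocular pressure (IOP) beginning around 9–12 months of
age. The mechanical state of the corneoscleral shell — how stiff the posterior
sclera is, how much damping it provides, how the whole globe resists volume
changes — is both a suspected modifier of glaucomatous damage and a secondary
casualty of chronic pressure elevation. `scleramech` implements the full
analysis chain used to characterise this system *ex vivo*, across four
measurement modalities on the same eye, together with a calibrated synthetic
cohort generator so that every analyzer can be validated by parameter
recovery:

1. **A-mode biometry** — globe diameters from ultrasound time of flight, and
   an ellipsoidal estimate of ocular volume.
2. **Whole-globe infusion** — Friedenwald ocular rigidity from a bolus
   pressure trace.
3. **Scleral-shell inflation** — tangential and radial strain maps from
   high-frequency ultrasound radiofrequency (RF) speckle tracking.
4. **Uniaxial strip testing** — dynamic mechanical analysis (DMA) and a
   tensile ramp with an exponential constitutive fit.
5. **Cohort statistics** — age × genotype linear models, Pearson
   correlations, paired comparisons and group summaries.

# Per-modality models

## Biometry

Echo round-trip times convert to one-way distances with the pulse-echo
convention $d = c\,t/2$, using sound speeds of 1605 m/s (cornea/sclera),
1540 m/s (aqueous/vitreous) and 1645 m/s (lens). At the 500 MHz RF sampling
rate this gives a per-sample distance resolution of about 1.5 µm. The factor
of two is a deliberate design decision: the ~1.5 µm/sample figure is only
consistent with half the round-trip path at 500 MHz. Ocular volume treats the
three measured lengths as full ellipsoid diameters,
$V_0 = \tfrac{\pi}{6}\,d_{ax} d_{nt} d_{si}$ (mm³ ≡ µL).

## Infusion and ocular rigidity

Friedenwald's pressure–volume relation defines ocular rigidity
$$K = \frac{\ln(\mathrm{IOP}/\mathrm{IOP}_0)}{V - V_0},$$
so a constant-flow bolus produces $\mathrm{IOP}(t) =
\mathrm{IOP}_0\,e^{K q t}$. The simulator uses the study protocol (15 mmHg
baseline, 15 µL/s for 1 s) and the estimator takes the baseline and plateau
as window means (defaults: 5 s before onset; 1–3 s after the bolus). Because
larger eyes are intrinsically less rigid, the volume-normalized rigidity
$k = V_0 K$ is also reported; it is treated as dimensionless (µL·µL⁻¹).
**Units caveat:** the absolute scale of $K$ is per-µL throughout; every
printed rigidity value in this package is on that scale. Outflow during the
1 s bolus is neglected (posterior-chamber infusion minimises washout), and
the two protocol replicate infusions are combined as the mean of the two $K$
estimates (`pool_rigidity()`).

## DMA

A small sinusoidal strain $\varepsilon_0 \sin(2\pi f t)$ superimposed on a
static preload produces, in the linear range, a sinusoidal stress with
amplitude ratio $E^*$ (complex modulus) and phase lead $\delta$:
$E' = E^*\cos\delta$, $E'' = E^*\sin\delta$, $\tan\delta = E''/E'$.
Amplitude and phase are estimated by **harmonic least squares** at the known
drive frequency — a linear fit of $a + b\sin + c\cos$ (optionally plus a
linear drift regressor absorbing preload relaxation) over the last 8 of 12
cycles. This was chosen over FFT peak-picking because it is exact for
non-integer numbers of cycles and robust in short windows; the estimator is
exercised against its own closed form and under noise in the test suite.
Preloads of 0.04 N and 0.1 N reproduce Laplace-law hoop stress
$\sigma = P r/(2t)$ at ~15 and ~35 mmHg with generic globe geometry
($r$ = 12 mm, $t$ = 0.5 mm). The 0.25% linearity bound on strain amplitude is
enforced as a warning flag; the default amplitude is 0.15%. Preconditioning
and rest periods are protocol metadata only — no constitutive evolution is
modelled.

## Tensile ramp

Engineering stress (force over undeformed thickness × width) and strain
(grip displacement over post-preload gauge length) from a 0.1%/s ramp to
3.5% strain are fit to the exponential model
$$\sigma = A\,(e^{B\varepsilon} - 1),$$
whose initial tangent modulus is $A\cdot B$ and whose $B$ measures how fast
stiffness grows with stress. The fit uses Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with starting values from the log-linearised tangent
modulus: $\log(d\sigma/d\varepsilon)$ is linear in $\varepsilon$ with slope
$B$. The curve is binned (15 strain bins) before differencing so per-sample
noise cannot swamp the finite differences, and up to five jittered restarts
guard against non-convergence. Goodness of fit is reported as both R² and
RMSE. The simulator's default sampling rate is 50 Hz, typical of a
servo-controlled test frame. The small preload stress is *not* subtracted
from the reported engineering stress; strain is zeroed at the preloaded
state.

## Inflation: speckle tracking and strain estimation

RF frames of the posterior sclera are modelled as a point-scatterer phantom
convolved with a separable point-spread function: a Gaussian-enveloped cosine
at the 55 MHz center frequency along the beam (sampled at 500 MHz) and a
Gaussian lateral beam profile. Envelope widths correspond to ~30 µm axial and
~62 µm lateral resolution. The default phantom is a 0.7 × 1.0 mm field with
3500 scatterers/mm² (≈ 6.7 per resolution cell, comfortably developed
speckle); these sizes are the package's own choices, set so a frame
synthesises in a fraction of a second.

Displacements are estimated by **normalized cross-correlation block
matching**; the study protocol references a previously described
cross-correlation tracker without algorithmic detail, so standard NCC
matching with the same contract stands in for it here. Three numerical
choices matter:

* the integer-lag peak is refined **parabolically** along the beam axis,
  where the RF carrier makes the correlation peak sharp;
* lateral refinement instead **maximizes the NCC against a laterally
  interpolated post kernel**, because three-point interpolation of the broad
  lateral correlation profile systematically underestimates sub-pitch
  shifts;
* after a first pass, the post frame is axially resampled by the estimated
  global axial strain and tracking is repeated (**temporal stretching /
  companding**). Removing the bulk stretch restores kernel correlation to
  ≈ 0.999 and removes the noise that axial deformation otherwise injects
  into the lateral estimates.

Nodes whose peak correlation falls below 0.6 or sits on the search border
are flagged invalid. Strain is the **least-squares slope** of displacement
versus position in a sliding kernel of nodes (default 7), per axis — exact
for affine fields, and excluding invalid nodes from each local regression
(fewer than 3 valid nodes gives a missing value).

Beam-aligned strains rotate to tissue-aligned ones by plane strain-tensor
rotation through the local surface-tangent angle θ; with zero shear and the
beam normal to the surface the mapping is the identity (radial = axial,
tangential = lateral), and the trace is always preserved. Whether the original
analysis used local surface fitting or a global spherical assumption is not
stated, so orientation is an explicit input here.

An inflation series follows the protocol schedule (5→20 mmHg in 0.5 mmHg
steps, then 2.5 mmHg steps to 30, then 35/40/45), tracks **incrementally**
between consecutive steps — small steps keep the speckle correlated — and
accumulates stretches multiplicatively, referencing all strains to the
5 mmHg baseline. An eye with more than 20% invalid nodes at any step is
flagged `tracking_failed` and excluded from strain outputs; the 20%
threshold is the package's own (the original protocol only reports that
tracking failed in some eyes). Radial strain is negative (compression) by
the extension-positive sign convention, stated in every output header.

## Cohort statistics

All models are ordinary least squares: the age × genotype model (with the
interaction giving per-group lines that equal separate per-group fits
exactly), the two-covariate model of normalized rigidity on age and last
IOP, Pearson correlations with two-sided t-based p-values, and paired
t-tests for anterior/posterior comparisons. p-values are two-sided with no
multiple-testing correction, matching the study convention. A site covariate
is supported but off by default. Mean and interval-weighted IOP summaries
(arithmetic mean of all readings; trapezoid-weighted mean over the last 24
months) are provided as utilities. Mixed-effects modelling of the
frequency × preload sweep is deliberately out of scope: its specification
would have to be guessed.

# The synthetic cohort: what it encodes and how it is calibrated

The generator's defaults *are* the study conditions; they are not tuning
knobs. One eye per animal, two groups (carriers pooled with wild-type as
"normal"), default sizes 15 affected / 10 normal.

**Ages** come from a two-component truncated-normal mixture per group — a
young pre-glaucomatous subset and an older subset, split at 45 months — with
component means/weights matching the published cohort structure (affected:
7/15 young at 15 ± 12 months, 8/15 old at 95 ± 25; normal: 5/10 at 8 ± 9 and
5/10 at 86 ± 17). This reproduces the published group age summaries
(≈ 57.5 ± 45 and ≈ 48.5 ± 42 months) that a uniform age draw cannot, and it
is what reconciles the published group SDs with the published age
correlations.

**Mechanical properties** sit on group-specific age lines: the published
lines for complex modulus, loss tangent and initial tangent modulus; for $B$
and posterior thickness (no printed lines) the slope is derived from the
published correlation × SD ratio, anchored at the group mean age. Residual
SDs are then calibrated in closed form so the *pooled* property–age Pearson
correlations equal the published values (0.857, −0.716, 0.668, −0.44,
−0.827): with $Y = L_g(a) + \sigma_\varepsilon Z$,
$$r = \frac{\mathrm{cov}(L, a)}{\mathrm{sd}(a)\sqrt{\mathrm{var}(L) +
\sigma_\varepsilon^2}},$$
solved for $\sigma_\varepsilon$ on a deterministic internal calibration
sample. Residuals are Gaussian, truncated only at physical bounds — except
$A\cdot B$, which is strictly positive with a published SD comparable to its
young-age line values; a Gaussian would be clipped heavily and its group
mean inflated. $A\cdot B$ therefore uses a **mean-preserving lognormal
residual**, $AB = L(a)\,e^{\sigma Z - \sigma^2/2}$, with σ calibrated by the
analogous moment identity. $A$ is derived as $AB/B$, preserving the
$A\cdot B \equiv A \times B$ identity exactly.

**IOP trajectories**: normal eyes stay in an 8–16 mmHg normotensive band;
affected eyes hold a ≈ 16 mmHg baseline until onset at 10.5 months, then
rise at 0.55 mmHg/month with an 8 mmHg residual SD — numbers chosen once to
match the published cohort table (young affected eyes at 14–17 mmHg, the
60–95-month eyes at ~30–80 mmHg) and the published positive age–IOP
correlation in the affected group.

**Rigidity**: affected eyes sit on the published plane
$k = 181.1 + 0.995\,\mathrm{age} - 2.940\,\mathrm{IOP}$ with a Gaussian
residual of 14 (≈ 10% of the group mean). No plane is printed for normals;
the package's own choice is a line $k = 150 + 1.2\,\mathrm{age}$ with
residual SD 20, giving a within-group age correlation near the published
0.91 and a higher group mean than the affected eyes, as reported. $K$
follows as $k/V_0$ with $V_0$ from group-specific globe-dimension
distributions.

**Inflation strains** are linked to stiffness through softened reciprocal
links with lognormal noise: $T_{c,15} = s/(E^* + c)\,e^{\sigma\eta}$ (and
similarly $T_{m,15}$), and $R_{c,15} = -s'/(k + c')\,e^{\sigma'\eta}$, which
keeps radial strain strictly compressive. The offsets (3 MPa, 100) act as a
background compliance and are needed because a pure reciprocal of a
truncated-normal stiffness has heavy tails that cap the attainable
correlation magnitude below the published values. Each σ is solved in
closed form from the moment identity so the population correlations equal
the published −0.744 (Tc–E*), −0.544 (Tm–E*) and 0.78 (Rc–k). Correlations
among properties are thus induced through the shared stiffness variables
($E^*$, $k$) rather than a full covariance matrix — parsimonious and
sufficient for the printed pairwise targets.

**What the generator does not emulate:** within-dog correlation between
eyes (one eye per animal), the two slow-progressor outliers as a distinct
class, disease-stage grading, drug effects, measurement-site effects,
strain-rate dependence, and any nonlinear viscoelasticity (QLV/Prony) or
hydration/temperature physics. Passing recovery tests therefore validates
the estimators against the *stated statistical structure*, not against
every feature of real tissue data.

# Determinism and degenerate inputs

Every stochastic function takes a seed; the same (seed, config) reproduces a
cohort bit-for-bit, and seeds are restored after use so callers' RNG streams
are unaffected. Degenerate inputs fail loudly: non-positive counts or
dimensions, plateau below baseline in a pressure trace, zero strain
amplitude, rank-deficient designs, zero-variance correlations, too few
samples for a fit. Truncated-normal draws with zero SD degenerate exactly to
the line value, which is what makes the zero-noise closure tests exact.

# Problem sizes used in validation

The test suite and acceptance script use: noise-free closure on single eyes
(machine precision to 1e-4 relative); Monte-Carlo unbiasedness at 500
replicates per estimator; Table-style group-mean recovery over 200 replicate
study-sized cohorts (5% tolerance); slope and plane-coefficient recovery on
cohorts of 2000–7000 eyes; correlation recovery at n = 5000 (±0.02); and
speckle-pipeline verification on single frame pairs plus a short coarse
pressure series. These sizes were chosen so each check is statistically
decisive at its stated tolerance while any single test still runs in seconds
to a couple of minutes.

# Known limitations

* The absolute scale of $K$ depends on the per-µL unit convention; compare
  normalized rigidity $k$ across studies, not raw $K$, unless units are
  stated.
* The speckle tracker is 2-D; out-of-plane motion — the dominant failure
  mode in real shells — only enters as the invalid-node/decorrelation
  pathway.
* The exponential constitutive fit is phenomenological; $A$ and $B$
  covary strongly and only $A\cdot B$ is robustly identified near the toe
  region.
* Group summary means are reported raw (not age-adjusted); group p-values
  are age-adjusted, mirroring the study reporting convention, where the same ambiguity
  exists.
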