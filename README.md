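# scleramech

Simulation and analysis of ocular biomechanics in an inherited canine
open-angle glaucoma model (*ADAMTS10*-mutant dogs versus pooled
carrier/wild-type "normal" animals).

Dogs carrying the mutation develop slowly rising intraocular pressure (IOP)
from about a year of age. Characterising how their corneoscleral shell
stiffens with age — and whether the mutant sclera is mechanically different —
requires combining four *ex vivo* measurements on the same eye, each with its
own estimator:

* **A-mode biometry** — globe diameters from ultrasound time of flight
  (pulse-echo, `d = c·t/2`) and ocular volume from the ellipsoid formula
  `V0 = (π/6)·d_ax·d_nt·d_si`.
* **Whole-globe infusion** — Friedenwald ocular rigidity
  `K = ln(IOP/IOP0)/(V − V0)` from a 15 µL/s, 1 s bolus at a 15 mmHg
  baseline, and its volume-normalized form `k = V0·K`.
* **Scleral-shell inflation** — tangential and radial strains at 15 mmHg
  (5 mmHg baseline) from high-frequency ultrasound RF speckle tracking
  (normalized cross-correlation block matching with companding), a
  least-squares strain estimator, and a strain-tensor rotation into tissue
  axes.
* **Uniaxial strip testing** — dynamic mechanical analysis (complex modulus
  `E*`, loss tangent `tan δ` via harmonic least squares at 1 Hz / 0.04 N
  reference conditions) and a tensile-ramp fit of the exponential model
  `σ = A(e^{Bε} − 1)` by Levenberg–Marquardt, reporting the initial tangent
  modulus `A·B`.
* **Cohort statistics** — age × genotype OLS models, the two-covariate model
  of normalized rigidity on age and last IOP, Pearson correlations and
  paired t-tests.

Because the study's raw records are not public, the package ships a
first-class synthetic cohort generator whose defaults encode the published
cohort structure: the group-specific age-regression lines, group means/SDs,
the affected-group rigidity plane
`k = 181.1 + 0.995·age − 2.940·lastIOP`, the affected IOP trajectory, and
noise calibrated so the population pairwise correlations match the printed
ones (for example E*–age 0.857, thickness–age −0.827, Tc–E* −0.744). Every
analyzer is validated by recovering these quantities from simulated raw
signals. The methods vignette (`vignettes/scleral-biomechanics.Rmd`)
documents the models and every calibration decision.

## Worked example

```r
library(scleramech)

co <- generate_cohort(n_affected = 15, n_normal = 10, seed = 1)
truth <- co[1, ]

# simulate raw records for one eye, with realistic noise, and analyze them
b <- render_raw_records(truth, seed = 2,
                        noise = list(iop_sd = 0.2, stress_frac = 0.02,
                                     ramp_sd = 0.005))
a <- analyze_bundle(b, v0 = truth$v0)
cat(sprintf("recovered E* = %.2f MPa (truth %.2f)\n", a$E_star, truth$E_star))
cat(sprintf("recovered tan(delta) = %.3f (truth %.3f)\n", a$tan_delta, truth$tan_delta))
cat(sprintf("recovered A*B = %.2f MPa (truth %.2f)\n", a$AB, truth$AB))
cat(sprintf("recovered K = %.5f per uL, k = %.1f (truth %.1f)\n",
            a$K, a$k_norm, truth$k_norm))

group_summary(co, "E_star")
fit_age_genotype(co$E_star, co$age, co$group)
```

This prints (abridged):

```
recovered E* = 3.56 MPa (truth 3.55)
recovered tan(delta) = 0.111 (truth 0.111)
recovered A*B = 0.56 MPa (truth 0.56)
recovered K = 0.02745 per uL, k = 149.4 (truth 149.4)

     group  n     mean       sd
1 affected 15 6.827872 2.391399
2   normal 10 6.385634 2.024804

Per-group lines:
     group intercept   slope
1 affected     3.872 0.05082
2   normal     4.753 0.04314
```

The first block is the closure property that anchors the package: raw
signals rendered from a known tissue truth, pushed through the analyzers,
come back as the truth (exactly when noise-free; unbiased under noise). The
group summary and per-group regression lines are the study-style outputs —
at n = 15/10 the fitted affected-group slope (0.051 MPa/month here) scatters
around the generating line (0.0568 MPa/month), and converges to it on large
cohorts, which is what the acceptance checks verify.

The slow piece, the RF speckle pipeline, runs as:

```r
pair <- simulate_speckle_pair(tangential_strain = 0.01, radial_strain = -0.005,
                              seed = 3)
field <- track_displacement(pair)   # NCC block matching + companding
strain <- ls_strain(field)          # least-squares strain estimator
median(strain$lateral_strain, na.rm = TRUE)  # ~0.010 (tangential truth)
```

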