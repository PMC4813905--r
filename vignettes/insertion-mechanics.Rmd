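---
title: "Insertion mechanics of coated flexible neural probes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insertion mechanics of coated flexible neural probes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probeflex)
```

## The problem

Flexible intracortical microprobes (Parylene C shanks a few micrometres
thick) cannot be driven into brain tissue on their own: the axial force
needed to penetrate the pia/cortex exceeds their Euler buckling load by
orders of magnitude. A sacrificial stiff polymer coating (here a
tyrosine-derived polycarbonate, E = 1.9 GPa) temporarily rigidifies the
shank; it dissolves within hours of implantation. The design question is
how much coating is enough — and how much is too much, since every extra
micrometre of coating enlarges the insertion wound.

`probeflex` frames that trade-off through a single metric, the **safety
factor**

$$ \mathrm{SF} = \frac{F_{\text{buckle}}}{F_{\text{insert}}}, $$

the ratio of the predicted critical buckling load of the coated shank to
the predicted peak force required to penetrate the tissue. A design with
SF = 1 is on the knife edge; empirically the probability of a successful
insertion follows a logistic curve in SF, which the package fits to 22
cohorts of bench insertions (uncoated and coated SU-8 and Parylene C probes
in embryonic chick and adult rat brain).

## Buckling side

The coating and probe are perfectly bonded, so the coated shank is a
composite column: the flexural rigidity is $\sum_i E_i I_i$ about the weak
bending axis, with the coating contributing its enclosing rectangle minus
the probe footprint. Two solvers are provided:

* `euler_critical_force()` — the closed form $F = \pi^2 \sum EI/(KL)^2$
  with effective-length factor $K$ (default boundary condition is
  fixed–pinned, $K = 0.6992$: the top of the shank is clamped to the
  actuator, the tip bears on the tissue; the effective-length assumption is
  configurable because the physical end restraint is uncertain).
* `fe_buckling()` — Hermite-cubic beam elements and the generalized
  eigenproblem between elastic and geometric stiffness. It exists for
  stepped columns (partially coated shanks, coating defects) and is
  verified against the closed form to 0.1% and against a shooting-method
  integration of the fourth-order buckling ODE for stepped sections.
  Rotation degrees of freedom are scaled by the element length so the
  eigenproblem stays well conditioned at fine discretizations.

Flexural moduli for the polymers were identified from self-weight
cantilever sag, $E = qL^4/(8 I \delta_{\max})$ (`flexural_modulus()`), with
$g = 9.81\,$m/s² and $I = w t^3/12$ about the thin axis.

## Insertion side

### What the data demand

The cohort outcomes, combined with buckling loads that are fixed by the
printed moduli and geometry, pin down the scale and shape of the insertion
force quite tightly: a 50 × 50 µm coated tip that inserts only half the
time must see ≈ 0.9 mN (≈ 370 kPa of tip pressure), while a 320 × 5 µm
uncoated SU-8 blade that inserts every time must see < 0.01 mN. No
scale-free continuum model reproduces both; penetration pressure rises
steeply with the minor tip dimension and saturates for blunt tips. The
package encodes this as an empirical penetration-strength law

$$ \sigma(m) = \sigma_\infty \, \frac{m^2}{m^2 + m_0^2}, $$

with $m$ the minor tip dimension, $m_0 = 65\,\mu$m a cortical process-zone
length, and $\sigma_\infty$ the saturated strength of the tissue preset
(1.0 MPa for dura-intact cortex; 291 kPa for the 0.6% agarose phantom,
identified once from the single published reference measurement of
1.19 mN for a 75 × 100 µm coated tip — the same single-point experimental
calibration role that the deletion threshold played in the original
element-deletion study). These constants are versioned in
`pf_calibration()` and are deliberately *not* refit per analysis.

### The analytic surrogate

`surrogate_insertion_force()` evaluates

$$ F = A_{\text{tip}}\; \sigma_{\text{crit}}(m, \gamma_c)\; g(\theta)\;
      \bigl(1 + c_f\,\mu/0.5\bigr), $$

where $\sigma_{\text{crit}}$ combines the strength law with the
confined-compression Ogden stress ratio at the deletion threshold
$\gamma_c$, $g(\theta) = 1 - 0.5(\theta/75)^3$ is the bevel factor (shallow
bevels barely help; an appreciable reduction needs ≥ 60°), and
$c_f = 0.12$ reproduces the weak observed dependence of total insertion
force on the Coulomb coefficient. The surrogate costs microseconds per
design and backs the cohort pipeline, the design-space sweeps and the
defect study.

### The reduced penetration solver

`simulate_insertion()` is a 2-D plane-strain, displacement-driven,
quasi-static finite-element model: the minor tip dimension lies in the
plane, forces are scaled by the major dimension, and the rigid beveled
punch (the coating is ~6 orders of magnitude stiffer than tissue) advances
in increments of half an element. Its ingredients:

* **Tissue**: one-term compressible Ogden ($G_0 = \mu$, exponent
  $\alpha = -4.7$, the standard softening exponent for brain-like tissue);
  bilinear quadrilaterals with stabilized selective reduced integration
  (volumetric term at the centroid, 20% retained at the Gauss points to
  restrain hourglass modes — with $\mu/\kappa \sim 10^{-5}$ a pure
  one-point volumetric rule is numerically singular).
* **Failure**: after each converged increment the maximum shear strain
  $(\varepsilon_1-\varepsilon_3)/2$ of the logarithmic strain is evaluated
  per element (the measure is recorded in the run metadata; the original
  study says only "shear strain"). Elements soften linearly from the
  threshold (default 0.05) to 3× the threshold and are then deleted;
  deleted elements never return and transmit no force. Removal proceeds a
  few elements at a time with re-equilibration between passes — the
  quasi-static analogue of "deleted prior to the next increment" — which
  suppresses the cascade bifurcations that all-at-once removal produces at
  desk-scale meshes.
* **Contact**: node-to-rigid-surface penalty, softplus-smoothed in the gap
  (C¹, so the Newton active set cannot chatter), with Coulomb friction on
  the sliding faces. The normal force saturates smoothly at the tissue's
  penetration strength at the tip scale, $\sigma_\infty s(m)$: the
  interface cannot transmit more pressure than the tissue can bear before
  failing, which is the cavity-expansion/limit-pressure idiom. Side walls
  saturate at the tissue's own confined failure stress instead, so the
  carved channel relaxes to physical wall pressures and the side
  frictional force stays an order of magnitude below the insertion force.
* **Domain**: fixed bottom, fixed far side edges, width 20× the tip
  (standing in for far-field elements), graded mesh with 4/5/8 elements
  per tip width at the coarse/default/fine levels; insertion speed
  0.1 mm/s is recorded but inertial terms are negligible and the solve is
  quasi-static (full Newton with a consistent finite-difference element
  tangent and a backtracking line search).

The solver's equilibrium path is deterministic — no random state anywhere.

### What the reduction does and does not capture

The reference case (75 × 100 µm coated SU-8 tip, agarose preset, default
mesh) yields a force profile that rises to a peak of ≈ 1.5 mN as the tip
first penetrates and then settles ~25% lower with a small sawtooth as
rows of elements fail — the characteristic experimental shape. The peak is
within a factor of 1.3 of the published 1.19 mN measurement (the stated
reduction tolerance for this quantity is a factor of 2). Deletion-based
penetration force is resolution sensitive: across the coarse/default/fine
meshes the peak spans 1.34–2.00 mN, and the calibration is therefore bound
to the default discretization exactly as the original study's threshold
was bound to its mesh. The threshold sensitivity emerges with the right
signs (−1.5% at 0.01, +7.3% at 0.25); the friction share of the total
force is larger than in 3-D (the 2-D wedge faces carry all of the drag
that a pyramidal tip distributes), so friction-change percentages
overshoot the published ones. The bevel response of a limit-pressure
interface is projection-invariant — faces lengthen exactly as their
vertical traction component shrinks — so the bevel factor $g(\theta)$ is
anchored to the reference experiments rather than calibrated against the
solver (`calibrate_surrogate()` fits and reports the backend agreement on
a size/threshold grid at the default bevel; residuals there are ≈ 8%).

## From forces to probability

`cohort_safety_factors()` runs the mechanics over the 22 packaged cohorts
(uncoated Parylene C probes land at SF ≈ 0.003; 100 × 100 µm coatings at
SF ≈ 3). One tissue preset is used for all cohorts, as the source
experiments pooled chick and rat outcomes into a single curve. Three
printed coating triplets (SU-8 probes wider than their nominal coating)
are interpreted as per-side layer thicknesses — the fabrication process
coats each side — since an overall reading cannot enclose the probe.

`fit_logistic()` maximizes the binomial likelihood of the pass counts
under the two-parameter symmetric logistic
$p(\mathrm{SF}) = 1/(1+e^{-k(\mathrm{SF}-\mathrm{SF}_{50})})$.
Count weighting matters because cohorts have unequal sizes (8–12); the
symmetric two-parameter form was chosen over a four-parameter sigmoid for
parsimony with 22 points and is recorded in `fit_meta`. Complete
separation raises an error advising the ridge option rather than silently
diverging. "100% success" is operationalized as $p \ge 0.99$
(`sf_at_probability()`), since a logistic never reaches 1.

```{r cohorts}
tbl <- cohort_safety_factors()
fit <- fit_logistic(tbl)
fit
sf_at_probability(fit, 0.99)
```

The fitted midpoint lands near 1.24 (published: ~1.35) and every all-fail
cohort sits below it, every all-pass cohort above it. The fitted curve
saturates earlier than the published one (p ≥ 0.99 by SF ≈ 2.2 rather
than 3.5): the package mechanics place the three all-success 100 × 100 µm
cohorts at SF ≈ 3.0, so nothing in the likelihood opposes a steep upper
tail. Parameter recovery on synthetic cohorts (true k = 3, SF₅₀ = 1.4,
200 replicates) is unbiased to within two standard errors.

## Design-space exploration

`design_space()` carries the eight modeled parameter ranges (per-side
coating thickness 0–200 µm, probe length 0.01–10 mm, coating stiffness
0.001–100 GPa, coating aspect ratio 0.1–10, probe width 5–350 µm, bevel
0–75°, probe stiffness 1–5000 MPa, brain stiffness 0.5–5 kPa).
`sweep_design()` evaluates factorial grids over chosen pairs (8–12 points
per axis with the surrogate backend is the default desk-scale grid) or a
deterministic Latin-hypercube sample of all eight parameters for the
regression. `probability_map()` turns a sweep into a 2-D probability map
through the fitted logistic, bilinearly interpolating and flagging gaps.

`map_statistics()` summarises a map by the variance, skewness and kurtosis
of each fixed-ρ₂ row, averaged over rows. The default row convention takes
unweighted sample moments of the probability *values* along the row: a row
that succeeds almost everywhere with a few failures is then strongly
left-skewed and leptokurtic, which matches how the published statistics
behave (their aspect-ratio map, success everywhere past a thin-coating
sliver, carries kurtosis ≈ 8.7 and skewness ≈ −2.7 — exactly the moments
of a heavily unbalanced binary row). The alternative `"density"`
convention — normalize the profile to unit mass and take positional
moments, a discretized Gaussian row then giving kurtosis 3 — is also
available; it is the natural reading of "treat the profile as a
distribution" but cannot reproduce the published numbers, which is why it
is not the default. On the package's own sweeps the probe-length ×
coating-thickness map has the largest variance (matching the published
ranking) while the highest-kurtosis pair comes out as coating stiffness ×
thickness rather than aspect ratio × thickness; only rankings, not
magnitudes, are comparable at desk scale and this residual disagreement is
reported as-is.

`regress_safety_factor()` is ordinary least squares of SF on the eight
parameters in their design units (so coefficients are comparable to the
published table), with 95% CIs, p-values sorted ascending (ties by |t|)
and standardized coefficients attached. On a 500-point hypercube sample
probe length (negative) and coating thickness (positive) are reliably the
two most significant effects.

## Coating defects

`apply_defect()` models a cylindrical void of radius
`radius_fraction` × coating thickness. On the buckling path the coating
section is reduced over an axial window equal to the void diameter (exact
circle subtraction when the void fits inside the section, grid integration
when it is clipped), and the stepped column is re-solved with
`fe_buckling()`. On the insertion path a *tip* void blunts the beveled
apex — the divot destroys the bevel over the void diameter, so the
effective bevel factor relaxes toward 1 and the insertion force rises;
a mid-shank side void leaves the tip untouched. This is the package's
design choice for how a tip defect can *lower* the safety factor, as
observed: a bearing-area reading (tip void removes bearing surface) would
lower the insertion force faster than the buckling force and raise SF
instead, contradicting the reported behaviour. With a fixed 50 µm void
diameter the worst safety-factor loss across the four study coating
thicknesses (50/75/100/200 µm) is ≈ 11%, at the thinnest coating, and the
loss grows monotonically with void size.

## Numerical choices and limitations

* Internal units are SI; interfaces speak µm and mN. Config files require
  explicit unit suffixes (`length: 3500 um`) because this domain invites
  µm/m mistakes.
* Newton tolerance is 10⁻⁴ of the current force scale with an absolute
  floor tied to the running historical contact force (a punch momentarily
  between contacts would otherwise face a noise-level reference).
* Contact penalty is 20× the confined modulus (floored at 100× the limit
  pressure); the smoothing length is 7% of the tip width, read as the
  crushed-debris layer through which the face loads the intact tissue.
* Problem sizes: the default penetration mesh is a few hundred elements
  and a run takes seconds; the full acceptance pipeline (22 cohorts, six
  solver runs, a 500-point regression sweep) completes in well under a
  minute.
* Not modeled: 3-D effects (pyramidal tips, out-of-plane flow),
  viscoelastic rate dependence, dura (reported negligible for the bench
  tests), post-insertion chronic response, CAD geometries.
* The synthetic design sweeps emulate the *mechanics* pipeline, not
  biological variability: passing the cohort tests shows the mechanics and
  the fitting machinery are consistent with the bench outcomes, not that
  the logistic would transfer to other tissues or insertion protocols.
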