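# probeflex

Insertion mechanics of flexible neural microprobes stiffened by a
sacrificial polymer coating.

Flexible intracortical probes (e.g. Parylene C shanks a few micrometres
thick) buckle long before they penetrate brain tissue; a stiff,
fast-degrading polymer coating carries them through insertion. `probeflex`
is a desk-scale simulator and design explorer for that problem. For a
coated probe design it predicts

* the critical buckling force `F_b` of the composite column
  (transformed-section Euler theory, `F = π² ΣEᵢIᵢ/(KL)²`, plus a
  finite-element beam eigensolver for stepped sections),
* the tissue insertion force `F_i` (a reduced 2-D plane-strain
  quasi-static FEM with one-term Ogden hyperelasticity, shear-strain
  element deletion, penalty contact and Coulomb friction — or a calibrated
  analytic surrogate for large sweeps),
* the **safety factor** `SF = F_b / F_i`, and
* the probability of successful insertion, via a binomial-likelihood
  logistic `p(SF) = 1/(1+exp(−k(SF−SF₅₀)))` fitted to 22 packaged cohorts
  of bench insertions into chick and rat brain.

It also builds design-space probability maps over eight probe/coating/
tissue parameters with bivariate kurtosis/variance/skewness summaries, a
multi-variable regression of safety factor on the design parameters, and a
coating-defect (cylindrical void) sensitivity analysis.

## Worked example

```r
library(probeflex)

probe <- probe_spec(20, 5, 3500, "parylene_c")            # w x t x L in um
asm   <- coated_assembly(probe, coating_spec(75, 100, 4000))

fit  <- fit_logistic(cohort_safety_factors())             # 22-cohort logistic
pred <- predict_insertion(asm, tissue_preset("brain"), logistic = fit)
pred
#> F_buckle = 8.428 mN, F_insert = 4.096 mN, safety factor = 2.06, p(insert) = 0.977
fit
#> <logistic> SF50 = 1.238, slope = 4.573 (n = 22, converged = TRUE)
sf_at_probability(fit, 0.99)
#> [1] 2.24
```

A 75 × 100 µm coating on a 20 × 5 µm Parylene C shank buckles at 8.4 mN
and needs 4.1 mN to penetrate cortex: safety factor 2.06, which the fitted
cohort logistic maps to a 97.7% insertion probability. The fitted midpoint
(SF₅₀ ≈ 1.24) is the design at which insertion and buckling are a coin
flip; operational certainty (p ≥ 0.99) is reached near SF ≈ 2.2.

Running the penetration solver itself on the same design in the agarose
phantom preset:

```r
simulate_insertion(asm, tissue_preset("agarose"))
#> insertion force = 1.523 mN (peak), side friction = 0.02772 mN, 22 elements deleted
```

A command-line wrapper ships in `exec/probeflex`
(`probeflex buckle|insert|fit-logistic|sweep|map|regress|defect`), reading
YAML/JSON configs with mandatory unit suffixes and writing JSON/CSV/PNG.

The methods — model reductions, tissue presets, the penetration-strength
calibration, and known limitations — are documented in
`vignettes/insertion-mechanics.Rmd`.

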