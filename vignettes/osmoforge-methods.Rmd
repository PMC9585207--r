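---
title: "Methods and design notes for osmoforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for osmoforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

osmoforge models the computational workflow behind developing an osmotic
controlled-release tablet: scoring the powder blend for direct
compression, screening formulation factors with a two-level factorial
design, characterising the dissolution kinetics of the resulting tablets,
and translating in vitro release into a predicted plasma profile. This
vignette records the models, their assumptions, and the design choices
made where the underlying conventions are genuinely open.

## SeDeM powder scoring

The SeDeM expert system maps twelve micromeritic measurements onto a
common 0–10 "radius" scale and displays them as a 12-axis radar diagram.
The derived parameters follow the standard formulas: bulk density
`Da = P/Va`, tapped density `Dc = P/Vc` (after 2500 taps), inter-particle
porosity `Ie = (Dc − Da)/(Dc·Da)`, Carr's index `IC = 100(Dc − Da)/Dc`,
Hausner ratio `IH = Dc/Da`, and the angle of repose from
`tan α = 2h/d`. The cohesion index `Icd` is the mean crushing force of
three compacts in newtons; flow time, loss on drying, hygroscopicity and
the sub-50 µm fines fraction are direct measurements. The homogeneity
index weights the mass in each sieve fraction by its diameter distance
(µm) from the modal fraction.

Linearization uses the standard conversion-factor table (e.g. `10v` for
the densities, `v/20` for the cohesion index, `5(3 − v)` for the Hausner
ratio) with every radius clamped to `[0, 10]`. Radii of at least 5 are
considered acceptable.

Design choices:

* **Reliability factor.** The field quotes `f = 0.952` for a 12-parameter
  diagram even though the exact regular-12-gon/circle area ratio is
  `12·sin(30°)/(2π) = 0.9549`. `reliability_factor(12)` returns the
  published 0.952 so that IGC values match the literature; any other `n`
  uses the geometric formula. `compute_indices()` refuses profiles with
  `n ≠ 12` unless `generalized = TRUE` is given explicitly.
* **IPP.** The profile index is the arithmetic mean of **all** twelve
  radii; the "≥ 5" attached to it in most write-ups is read as the
  acceptance limit on the result, not as a filter on which radii enter
  the mean. The alternative reading would make `IGC = IPP·f`
  inconsistent with published index values.
* **Hardness units.** Hardness testers often report kg-force;
  `kgf_to_newton()` converts (1 kgf = 9.807 N) at data ingestion. No
  formula converts units internally.
* **Homogeneity index.** Bin mean diameters are taken as midpoints of
  adjacent sieve sizes of the 355/212/100/50 µm series by default;
  arbitrary series are accepted.
* Radii are reported to 2 decimal places in outputs; full precision is
  retained internally.

The corrective-excipient formula
`CP = 100 − (RE − R)/(RE − RP)·100` gives the minimum percentage of a
well-performing excipient (radius `RE`) needed to lift a deficient powder
radius `RP` to the target `R` (by default 5). It is defined only when
`RE > RP` and `RE ≥ R`; both violations raise distinct errors.

## Factorial design and desirability optimization

`build_design(k, seed)` constructs the full `2^k` design in standard
order with a seed-determined randomized run order (the seed is a required
input and is logged, because the run order is part of the experiment's
provenance). The default model is **main effects only** in coded units,
matching the model form usually reported for osmotic-tablet screening
studies; on the orthogonal design every coefficient equals half the
high/low contrast, which the tests verify against an independent oracle.
Interactions can be examined by passing an augmented coded matrix, but
they are not part of the default model.

ANOVA partitions term-wise sums of squares against the residual mean
square (for a `2^4` main-effects model, 11 residual df). A saturated
model reports `NA` p-values rather than a misleading zero.

Desirability uses Derringer–Suich linear ramps with weight 1: two-sided
"range" goals ramp from 0 at the lower bound to 1 at the target
(defaulting to the midpoint) and back to 0 at the upper bound;
"maximize"/"minimize" are one-sided ramps. The overall desirability is
the weighted geometric mean, maximized by exhaustive grid search over
`[−1, 1]^k` (default resolution 0.1). Ties are broken by the
lexicographically smallest coded point, and all tied optima are
returned. An empty feasible region returns the best point with
`feasible = FALSE` and a warning instead of failing.

## Dissolution kinetics

Seven classical models are implemented: zero order, first order, Higuchi,
Korsmeyer–Peppas, Hixson–Crowell, Baker–Lonsdale and Weibull. All fits
minimise squared error on the **untransformed** cumulative-release scale
(the convention of the widely used DD-Solver add-in), never by
log-linearization, so the reported `r²` refers to the release scale.
Starting values come from closed-form transforms (log–log slope for the
Korsmeyer–Peppas exponent, probit-style transforms for Weibull), refined
by derivative-free optimization on log-scaled parameters with seeded
jittered restarts; one-parameter models use Brent's method. The
Baker–Lonsdale forward curve solves its implicit equation by bracketed
root-finding to 1e-12; the Hixson–Crowell cube-root law is capped at
100% past its domain (`kHC·t > 1`). The Weibull model is parameterised as
`F = 100(1 − exp(−t^β/α))` with lag time fixed at zero, which is why
fitted `α` values can be numerically large for steep sigmoidal profiles.

The release-mechanism classification is a pure function of the
Korsmeyer–Peppas exponent: `n ≤ 0.5` Fickian diffusion,
`0.5 < n ≤ 0.85` anomalous transport, `0.85 < n ≤ 1` case II
(near-zero-order), `n > 1` super case II.

The f2 similarity factor is
`f2 = 50·log10(100/sqrt(1 + mean((R_t − T_t)²)))`. Identical profiles
give 100, and a uniform 10-percentage-point difference gives 49.89 — the
classical similarity boundary. Note that a uniform 2-point difference
gives `50·log10(100/√5) = 82.53`; a value near 65 sometimes quoted for
this case corresponds to omitting the square root and is arithmetically
wrong. Following regulatory practice, at most one sampling point beyond
85% release of the reference profile is included; `truncate_85 = FALSE`
evaluates the plain formula.

Two-stage dissolution runs (2 h at pH 1.2, then pH 6.8) are fitted as a
single pooled time-course; the stage annotation is metadata only.

## Pharmacokinetic simulation

Disposition is a classical two-compartment model parameterised by
`Vc` (L/kg), `k12`, `k21` (1/h) and `CL` (L/h/kg), scaled by a
configurable body weight (default 70 kg). Oral dosing with first-order
absorption has the closed-form tri-exponential solution; an independent
fixed-step RK4 integration of the same ODEs serves as the test oracle.
Near-coincident rate constants are nudged apart by a relative 1e-8 and
flagged rather than failing.

The absorption model for release-rate-limited products is a classical
compartmental-absorption-and-transit (CAT) chain — by default one
gastric compartment (emptying rate 4 h⁻¹), seven serial small-intestine
compartments traversed in 3.32 h, and a terminal colon compartment —
rather than any proprietary physiology (pH-dependent regional solubility,
gut-wall metabolism and regional pH tables are out of scope). Absorption
from each intestinal compartment is first order at `ka = 2·Peff/r`
(`r` = 1.75 cm), scaled by 0.1 in the colon for its reduced surface
area. The in vitro cumulative release curve is interpolated
piecewise-linearly and differentiated to give the gastric input rate
(negative rates are clamped to zero); the fraction `1 − F` of the
absorbed flux is lost pre-systemically. Integration is fixed-step RK4 on
the full linear system with steps aligned to the release knots, which
preserves total mass to machine precision — the conservation invariant
checked on every simulation. A consequence of the simplification is that
simulated Cmax/Tmax/AUC values for controlled-release inputs are
qualitative shape anchors (delayed Tmax, depressed Cmax, matched
dose-normalized AUC), not reproductions of any proprietary simulator's
output.

Because the oral tri-exponential is invariant under exchanging `ka` with
the fast hybrid constant λ1 ("flip-flop"), the fitter reports the
conventional branch with `ka ≥ λ1`, reaching the mirror solution through
an analytic remapping when the optimizer lands on the other branch.
Fitting supports unweighted or proportional (1/pred²) weighting; the
latter is the statistically matched choice for proportional assay error.
Mono-exponential data are detected by refitting with the distribution
pathway pinned shut and comparing fits; such data yield `k12` pinned
near zero with a warning.

One supplied parameter set deserves a caution: a clearance of
0.00572 L/h/kg with `k21 = 0.0569 h⁻¹` implies a terminal half-life of
roughly 1400 h, far below literature tramadol clearance and inconsistent
with plasma AUCs in the low thousands of ng/ml·h unless the bioavailable
fraction is implausibly small. The package takes such parameters
verbatim and surfaces the tension in the pipeline's PK validation note
instead of silently correcting units. For the same reason the
parameter-recovery simulation study samples its synthetic profiles far
into the terminal phase (out to 6000 h) — with any shorter window the
clearance is simply not identifiable.

NCA uses the maximum observed sample for Cmax/Tmax, the linear
trapezoidal rule for AUCt (not log-linear; documented, and the
refinement property is tested), log-linear regression over the last 3
positive concentrations (configurable) for λz, and
`AUCinf = AUCt + Clast/λz`. Multiple-dose profiles come from time-shifted
superposition under linear kinetics, extrapolating by λz (with a flag)
when the single-dose horizon is too short. Relative bioavailability is
the dose-normalized AUC ratio in percent, printed to two decimals.

The absorption rate constant of an immediate-release reference is rarely
published alongside disposition parameters, so `calibrate_ka()` tunes
`ka` by monotone bisection until the simulated single-dose Tmax matches a
target (e.g. 1.12 h).

## Synthetic data

Every pipeline input can be generated with known ground truth, and every
generator writes a truth sidecar (generating parameters, noise model,
seed). The guiding property, enforced by tests, is that zero-noise output
pushed back through its analysis stage returns the generating truth.

* **Powder**: target radii are inverted through the linearization table
  into bench measurements (a 10 g density sample, an 8 cm repose cone, a
  three-fraction sieve table solved for the homogeneity target). The
  density-derived parameters (Ie, IC, IH) follow from the generated
  Da/Dc rather than being independently targetable — they are not
  independent in reality either. The default target set emulates a
  freely flowing but poorly compactable crystalline drug substance:
  cohesion index and inter-particle porosity deficient, ten of twelve
  radii compliant. Measurement noise is multiplicative Gaussian with a
  chosen CV.
* **Dissolution**: model curve plus additive Gaussian noise, default
  σ = 2% of label claim (typical paddle-apparatus variability), on an
  hourly schedule with the two-stage pH annotation. Values are clipped
  to the physical `[0, 110]` band; parameter-recovery studies therefore
  use schedules on which the generating curve stays below that bound,
  since a clipped curve no longer carries the generating parameters.
* **Plasma**: closed-form simulation with proportional log-normal error
  (default CV 10%, typical combined bioanalytical/biological
  variability), mean-unbiased by construction.
* **Factorial responses**: `y = Xβ + N(0, σ²)` over the coded design.

What a green test does *not* establish: the generators produce idealised
data — no sampling-time errors, no inter-tablet variability, no
heteroscedastic dissolution error, no below-quantification censoring in
plasma profiles, and a release curve that exactly follows one kinetic
model. Conclusions about robustness to those realities require real
data.

All generators draw from private, seed-derived RNG streams and restore
the global RNG state, so adding a generator call never perturbs other
randomized output.

## Numerical conventions

* Optimizations run on log-scaled parameters (positivity by
  construction); derivative-free simplex/Brent searches with seeded
  jittered multi-starts, then gradient polish where the surface is
  smooth.
* The desirability grid includes both endpoints of `[−1, 1]` even when
  the resolution does not divide 2 exactly.
* Tie-breaks (desirability optima, model ranking) are deterministic and
  documented: lexicographic coded point; higher r², then fewer
  parameters, then lower AIC.
* Pipeline reports contain no timestamps, so reruns with identical
  configuration and seeds are byte-identical.

## Known limitations

* No fractional-factorial, response-surface or mixture designs; no
  automatic stepwise term selection.
* No mixing rule predicting a blend's SeDeM profile from component
  profiles.
* The CAT model omits regional pH, solubility/precipitation dynamics and
  gut-wall metabolism; colonic absorption is a single scale factor.
* f2 is computed on shared nominal time grids only; no interpolation
  between mismatched schedules.
* The configuration format is JSON (not YAML), with strict key checking.
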