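---
title: "Quantifying VMAT beam complexity with vmatcx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying VMAT beam complexity with vmatcx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vmatcx)
```

## The problem

Volumetric modulated arc therapy (VMAT) delivers radiation while the gantry
rotates, the multileaf collimator (MLC) reshapes the aperture and the dose
rate varies. A plan that meets its dose objectives may still be *heavily
modulated*: built from many small, irregular, spatially scattered apertures.
Such plans use more monitor units (MU), take longer to deliver, and are more
sensitive to leaf-position errors — which is why complexity metrics are part
of patient-specific QA programs. `vmatcx` computes the standard
aperture-based complexity scores from arc-therapy RT Plans, estimates
delivery kinematics, and compares paired plan cohorts produced for two
different delivery systems.

## The scores

An arc plan is a sequence of control points (CPs); the span between two
consecutive CPs is a *segment* (the two terms are often used
interchangeably; all per-"segment" scores below are evaluated at CPs and
combined over consecutive CP pairs). For one CP, with `pos` the leaf
coordinate along the travel axis and $n$ indexing the $N$ in-field leaf
pairs:

* **Segment width** $SW = \max_{n}\,(pos_{n,\mathrm{left}} -
  pos_{n,\mathrm{right}})$, cm — the widest opening.
* **Segment area** $SA = \sum_{n} (pos_{n,\mathrm{left}} -
  pos_{n,\mathrm{right}})\,\times\,\mathrm{LeafWidth}_n$, cm² — the aperture
  area. Leaf widths enter per pair, so mixed-width MLCs are handled without
  a uniform-width assumption.
* **Leaf sequence variability**
  $LSV = \prod_{\mathrm{bank}} \frac{\sum_{n=1}^{N-1}
  \big(pos_{\max} - |pos_n - pos_{n+1}|\big)}{(N-1)\,pos_{\max}}$, where
  $pos_{\max}$ is that bank's position range over the in-field pairs — how
  smoothly each bank's leaf front varies.
* **Aperture area variability** $AAV$ = the CP's $SA$ divided by the
  maximal aperture of the arc: per pair, the largest left-bank position
  minus the smallest right-bank position over all CPs, times the leaf
  width, summed over pairs that open at least once.
* **Modulation complexity score**
  $MCS = \sum_{i=1}^{I-1} \frac{LSV_i + LSV_{i+1}}{2}\cdot
  \frac{AAV_i + AAV_{i+1}}{2}\cdot w_i$, with $w_i$ the fraction of the
  arc's MU delivered in segment $i$ (differences of the cumulative meterset
  weight). $MCS = 1$ means no modulation; more modulation pushes it toward
  0. MCS is invariant to rescaling the beam MU and to a rigid translation
  of the whole leaf pattern.

### Conventions the formulas leave open

* **In-field rule.** A pair is in-field when its gap strictly exceeds the
  closed-gap threshold *and* its leaf strip overlaps the open y-jaw
  interval by a positive amount. Leaves that stay closed are excluded from
  every score.
* **Closed-gap threshold.** Defaults to 0.05 cm (`closedGap` argument
  everywhere): leaf tips parked or abutted are "closed". The threshold is a
  convention, not physics; it is configurable because vendors park leaves
  differently.
* **Degenerate LSV.** When a bank has fewer than two in-field pairs or zero
  position range, its factor is defined as 1 (no shape variability). This
  is what makes the no-modulation limit exact: a constant rectangular
  aperture yields $LSV = AAV = 1$ at every CP and $MCS = 1$.
* **Empty apertures.** SW and SA of an all-closed CP are 0, and its AAV
  is 0; only an arc closed at *every* CP is an error, since the AAV
  denominator then vanishes.
* **Jaws.** The y-jaws select in-field pairs; the x-jaws never clip the
  gaps entering SW/SA, because the scores are defined on leaf positions.
  Plans that rely on heavy x-jaw collimation will therefore score slightly
  larger apertures than the fluence they deliver.
* **Non-contiguous in-field sets.** The bank sums run over the in-field
  pairs in physical order, differencing consecutive members even across a
  hole; `scorePlan()` flags such CPs in the `contiguous` column.

`scorePlan()` reports per-segment values, per-arc aggregates and a plan
summary. Site-style means are reported both unweighted (pooled CPs) and
MU-weighted, since either convention is defensible and published tables
rarely say which was used; the plan-level MCS is the MU-weighted mean of
the arc MCS values.

## Machine templates

Two delivery-system geometries are built in:

* `millennium120()` — 60 leaf pairs; the outer 10 per side project 10 mm at
  isocenter and the central 40 project 5 mm; 15.0 cm overtravel.
* `elektaMLCi()` — 40 pairs of 10 mm; 12.5 cm overtravel.

Their kinematic limits differ in *dose-rate control*:
`defaultConstraints("continuous-type")` models continuously variable dose
rate (4.8 deg/s gantry, 600 MU/min, 2.5 cm/s leaves) and
`defaultConstraints("binned-type")` a binned system whose rate ladder is
600/300/150/75/37.5 MU/min (6.0 deg/s gantry, 2.0 cm/s leaves). The leaf
geometry follows the two modeled MLC designs; the numeric limits are
editable assumptions — typical configuration values for these system
classes — shipped in `inst/extdata/machines.yaml`, because no authoritative
values are bundled with plan data. Users can register further machines via
the same YAML file without code changes.

## Delivery kinematics

`estimateKinematics()` is a forward model, not a log reconstruction. For
each segment the duration is the largest of three limit times: gantry
travel at maximum speed, MU delivery at maximum dose rate, and the largest
single-leaf travel at maximum leaf speed. Gantry angle differences are
taken on the circle along the arc's rotation direction. For binned systems
the continuous dose-rate solution is reduced to the largest bin not
exceeding it and the duration recomputed — binning can only lengthen a
delivery, never shorten it. When the continuous solution falls below the
smallest bin, the machine would pulse the beam: the reported rate is the
smallest bin (the instantaneous rate) and the duration keeps its
continuous-limit value. Acceleration limits are ignored (piecewise-constant
speed per segment): no acceleration data exist in plan files, and the
approximation only matters for very short segments. A segment with no
gantry motion, no MU and no leaf travel has an undefined duration and is
reported as an explicit error naming the segment.

## The synthetic generator

Real paired two-machine cohorts are patient data and cannot ship with a
package, so `generatePlan()` builds arc plans with controlled modulation:

* **Arc layouts.** `"full_dual"` — two full arcs (CW 181° to 179° through
  0°, then CCW back) at 2° CP spacing, the common head-and-neck
  configuration; `"partial_dual"` — two 40° arcs (296°–336° and 104°–144°),
  the tangential breast configuration.
* **Aperture.** Leaves conform to a projected ellipse: each pair opens to
  the chord at its strip's y-midpoint; strips missing the ellipse stay
  closed. Default semi-axes are 4 × 5 cm for full arcs and 5.5 × 6 cm for
  partial arcs, chosen so the conformal aperture areas (≈ 63 and 104 cm²)
  sit in the range reported for head-and-neck and breast arcs. Default MU
  (800 full / 420 partial) follows the same logic.
* **Modulation.** Independent zero-mean Gaussian perturbations of SD
  `modulationAmplitude` (default 0.5 cm) are added to every leaf at every
  CP, clipped to overtravel; pairs whose leaves would cross collapse to
  their midpoint so the gap invariant holds. Amplitude 0 gives a perfectly
  conformal plan; increasing amplitude monotonically depresses the mean
  MCS.
* **MU profile.** `"uniform"` or `"random-dirichlet"` cumulative weights.
* **Determinism.** One seed drives all draws; the caller's RNG state is
  saved and restored, and the same config reproduces the identical plan.

What the generator does *not* emulate: optimizer-style correlated leaf
sequences, dose-driven aperture shapes, jaw tracking, or site anatomy.
Passing tests on synthetic plans therefore demonstrates the correctness of
the score arithmetic and the I/O under the stated conventions — not that
any clinical cohort will reproduce a particular published mean.
`pairedCohortFixture()` emulates the paired study design: one set of target
shapes, each realized on both leaf grids, so machine contrasts (e.g. finer
central leaves giving smaller discretized areas) can be studied with the
pairing intact.

## Cohort statistics

`compareCohorts()` mirrors the usual evaluation layer: mean ± SD per cohort
(sample SD, $n-1$) and a two-sided Wilcoxon matched-pair signed-rank test
per metric (MU, SW, SA, LSV, AAV, MCS) at α = 0.05, with no
multiple-testing correction (each metric is reported at its own α, the
usual convention in planning-study tables; correct downstream if needed).
Zero differences are dropped before ranking and ties are mid-ranked. For
≤ 25 non-zero differences the p-value comes from the exact permutation
distribution, computed by convolution over sign patterns — this remains
exact with mid-ranks, which `stats::wilcox.test` refuses to handle exactly;
above 25 a normal approximation with continuity and tie corrections is
used. Pairs are matched by plan identity; unpaired ids are an error that
lists them. Comparison can run per plan (default) or per pooled segment —
published tables are often ambiguous about this unit, so the choice is
explicit and recorded in the returned table's `unit` attribute.

## RT Plan I/O

`readRTPlan()`/`writeRTPlan()` speak explicit-VR little-endian DICOM RT
Plan (beam, control-point and leaf/jaw device sequences, fraction-group
metersets). Positions are mm in the file and cm in memory; conversion
happens only at this boundary. Two file dialects are normalized on read:
jaw and MLC positions defined only at the first CP are carried forward, and
the two MLC banks are mapped to "right"/"left" by choosing the assignment
that makes the per-pair gap non-negative on the majority of pairs (vendor
bank order differs; the choice is recorded in the parse log). Cumulative
weights are normalized by the final cumulative meterset weight, clamped
into [0, 1] when within 1e-6, and rejected as non-monotone beyond that.
Beams with a single control point or zero meterset (setup/imaging fields)
are dropped. The leaf-boundary table is matched against the machine
registry; an unmatched table is a distinct error rather than a silent
guess. When a file carries no fraction-group meterset, per-beam MU can be
supplied as a sidecar argument.

## Numerical choices and problem sizes

* Validity tolerances: 1e-9 cm for geometry identities, 1e-6 for
  cumulative-weight endpoints, 1e-4 cm for file round-trips (DICOM decimal
  strings carry 10 significant digits).
* The test suite checks the vectorized scores against a deliberately naive
  double-loop reference at 1e-12 relative tolerance on 100 random arcs per
  machine, and checks score ranges on 200 random arcs per machine; random
  arcs use coarsened CP spacings (4°–12°) to keep the suite quick, while
  ladder and acceptance computations use the full 2° spacing.
* Exact Wilcoxon enumeration is validated against brute-force enumeration
  of all $2^n$ sign patterns for $n \le 10$.

## Known limitations

* Tongue-and-groove geometry, rounded leaf ends, transmission and
  interdigitation constraints are outside the aperture model.
* The kinematic model knows no acceleration limits and no beam-hold logic;
  its outputs are plan-side estimates for comparing delivery regimes, not
  predictions of measured delivery traces.
* Gamma pass-rate analysis requires measurements and is out of scope.
* Only explicit-VR little-endian DICOM is read or written.

## A worked example

```{r example}
plan <- generatePlan(generatorConfig(machine = millennium120(),
  arcLayout = "partial_dual", modulationAmplitude = 0.3, seed = 42))
report <- scorePlan(plan)
report
round(report@plan, 3)

arc <- arcs(plan)[[1]]
constraints(arc) <- defaultConstraints("continuous-type")
beamOnTime(arc)
```
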