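# vmatcx

Beam-complexity analytics for volumetric modulated arc therapy (VMAT)
plans.

VMAT delivers radiation with a rotating gantry while the multileaf
collimator (MLC) continuously reshapes the beam aperture and the dose rate
varies. Plans that meet identical dose objectives can differ widely in how
*modulated* they are — how small, irregular and scattered their apertures
become — and heavily modulated plans cost monitor units (MU), delivery time
and robustness to leaf-position errors. Medical physicists therefore score
plan complexity as part of patient-specific QA and when comparing delivery
platforms. `vmatcx` is for that audience: it parses arc-therapy DICOM RT
Plans, computes the standard aperture-based complexity scores, estimates
delivery kinematics under two dose-rate control schemes, and runs paired
cohort comparisons.

## The scores

For each control point (CP) of an arc, over the N in-field leaf pairs
(open more than a threshold, inside the y-jaws):

- **SW** (cm): the maximum leaf-pair opening,
  `max_n(pos_left − pos_right)`.
- **SA** (cm²): the aperture area,
  `Σ_n (pos_left − pos_right) · LeafWidth_n`.
- **LSV** ∈ [0,1]: leaf sequence variability — per bank,
  `Σ_{n=1}^{N−1}(pos_max − |pos_n − pos_{n+1}|) / ((N−1)·pos_max)` with
  `pos_max` the bank's position range; the LSV is the product of the two
  bank factors.
- **AAV** ∈ [0,1]: aperture area variability — the CP's SA divided by the
  arc's maximal aperture (per pair, max left position minus min right
  position over all CPs, times leaf width).
- **MCS** ∈ [0,1]: the modulation complexity score of an arc,

  ```
  MCS = Σ_{i=1}^{I−1} (LSV_i + LSV_{i+1})/2 · (AAV_i + AAV_{i+1})/2 · w_i
  ```

  where `w_i` is the MU fraction delivered between CPs i and i+1.
  MCS = 1 means no modulation; more modulation drives it toward 0.

Two MLC geometries ship built in: a 60-pair mixed-width model (10/5/10 mm
pattern, 15 cm overtravel) and a 40-pair 10 mm model (12.5 cm overtravel),
plus constraint sets for continuously-variable and binned dose-rate
control. Further machines can be added through a YAML config.

## Worked example

```r
library(vmatcx)

# a synthetic dual partial-arc plan (tangential breast-style layout) on the
# mixed-width MLC, lightly modulated
plan <- generatePlan(generatorConfig(machine = millennium120(),
  arcLayout = "partial_dual", modulationAmplitude = 0.3, seed = 42))
report <- scorePlan(plan)
report
#> ComplexityReport for plan 'synth-millennium120-partial_dual-seed42'
#>   arcs: 2, segments scored: 42
#>   plan MCS (MU-weighted): 0.6957
round(report@plan, 3)
#>    mu   mcs meanSW  meanSA meanLSV meanAAV wMeanSW wMeanSA wMeanLSV wMeanAAV
#> 1 420 0.696 11.429 104.001   0.792   0.879  11.431 103.997    0.792    0.879
```

The plan delivers 420 MU over two 40° arcs; its mean aperture is about
104 cm², the leaf fronts are fairly smooth (LSV 0.79), apertures stay near
the arc maximum (AAV 0.88), and the combined MCS of 0.70 marks a lightly
modulated plan. Kinematics under continuous dose-rate control:

```r
arc <- arcs(plan)[[1]]
constraints(arc) <- defaultConstraints("continuous-type")
beamOnTime(arc)
#> [1] 21.00093  # seconds for the 40° arc
```

Paired cohort comparison on synthetic plans (same targets realized on both
leaf grids):

```r
cohort <- pairedCohortFixture(8, seed = 3)
compareCohorts(cohort$a, cohort$b)[, c("metric", "meanA", "meanB", "pValue")]
#>   metric       meanA       meanB    pValue
#> 1     MU 792.8492281 792.8492281 1.0000000
#> 2     SW   8.6640445   8.3827112 0.0078125
#> 3     SA  60.8826682  60.8932674 0.9453125
#> 4    LSV   0.6729132   0.5546447 0.0078125
#> 5    AAV   0.6980728   0.6947315 0.7421875
#> 6    MCS   0.4705353   0.3851715 0.0078125
```

MU is identical by construction (the fixture pairs share MU), so that row
degenerates to p = 1; the finer-leaf machine realizes the same targets
with a significantly higher MCS in this fixture.

A thin command-line front end is installed with the package
(`<library>/vmatcx/exec/vmatcx`) with subcommands `score`, `kinematics`,
`synth` and `compare`; results go to stdout or files as JSON/CSV, logs to
stderr.

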