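# a control point on a toy 1 cm-width geometry; unused pairs closed at 0
toyCP <- function(machine, a, b, jawY = c(-20, 20), w = 0) {
  n <- nPairs(machine)
  A <- rep(0, n); B <- rep(0, n)
  A[seq_along(a)] <- a; B[seq_along(b)] <- b
  controlPoint(0L, 0, A, B, jawX = c(-15, 15), jawY = jawY, cumWeight = w)
}

test_that("in-field pairs require an open gap strictly inside the y-jaws", {
  m <- elektaMLCi()
  # all pairs closed
  cp <- toyCP(m, numeric(0), numeric(0))
  expect_length(infieldPairs(cp, m), 0)

  # 3 open pairs inside the jaws, 2 open pairs fully above the top jaw;
  # boundaries of pair k are [k-21, k-20] cm
  a <- rep(0, 40); b <- rep(0, 40)
  a[10:12] <- -2; b[10:12] <- 2          # strips [-11,-8], inside jaws
  a[35:36] <- -2; b[35:36] <- 2          # strips [14,16], above jawY hi = 12
  cp <- controlPoint(0L, 0, a, b, jawX = c(-15, 15), jawY = c(-12, 12),
    cumWeight = 0)
  expect_identical(infieldPairs(cp, m), 10:12)

  # a gap exactly at the threshold is excluded (strict inequality)
  cpEq <- toyCP(m, c(-0.025), c(0.025))
  expect_length(infieldPairs(cpEq, m, closedGap = 0.05), 0)
  cpAbove <- toyCP(m, c(-0.026), c(0.026))
  expect_identical(infieldPairs(cpAbove, m, closedGap = 0.05), 1L)
})

test_that("segment width is the maximum in-field opening", {
  m <- elektaMLCi()
  cp <- toyCP(m, c(-1, -1.5, -2), c(1, 1.5, 2)) # gaps 2, 3, 4
  expect_equal(segmentWidth(cp, m), 4)

  rect <- toyCP(m, rep(-5, 10), rep(5, 10))
  expect_equal(segmentWidth(rect, m), 10)

  closed <- toyCP(m, numeric(0), numeric(0))
  expect_equal(segmentWidth(closed, m), 0)
})

test_that("segment area sums gap times leaf width over in-field pairs", {
  m <- elektaMLCi() # unit leaf widths
  cp <- toyCP(m, c(-1, -1.5, -2), c(1, 1.5, 2))
  expect_equal(segmentArea(cp, m), 9.0)

  rect <- toyCP(m, rep(-5, 10), rep(5, 10))
  expect_equal(segmentArea(rect, m), 100.0)

  expect_equal(segmentArea(toyCP(m, numeric(0), numeric(0)), m), 0.0)

  # non-uniform widths weight each gap by its own leaf width
  mm <- millennium120()
  n <- nPairs(mm)
  a <- rep(0, n); b <- rep(0, n)
  a[c(5, 30)] <- -1; b[c(5, 30)] <- 1 # a 1.0 cm and a 0.5 cm pair, gap 2
  cp2 <- controlPoint(0L, 0, a, b, jawX = c(-15, 15), jawY = c(-20, 20),
    cumWeight = 0)
  expect_equal(segmentArea(cp2, mm), 2 * 1.0 + 2 * 0.5)
})

test_that("per-bank position range behaves as a range", {
  m <- elektaMLCi()
  cp <- toyCP(m, c(0, 1, 2), c(3, 4, 5))
  expect_equal(posMax(cp, m, "A"), 2)
  expect_equal(posMax(cp, m, "B"), 2)

  flat <- toyCP(m, rep(-2, 5), rep(2, 5))
  expect_equal(posMax(flat, m, "A"), 0)

  single <- toyCP(m, -1, 1)
  expect_equal(posMax(single, m, "A"), 0)
})

test_that("LSV matches the hand-derived example and its degenerate limits", {
  m <- elektaMLCi()
  # both banks with in-field positions {0, 1, 2}: per bank (1+1)/(2*2) = 0.5
  cp <- toyCP(m, c(0, 1, 2), c(2.1, 3.1, 4.1))
  # bank B positions {2.1, 3.1, 4.1}: same spacing, factor 0.5 -> product 0.25
  expect_equal(leafSequenceVariability(cp, m), 0.25)

  rect <- toyCP(m, rep(-5, 10), rep(5, 10))
  expect_equal(leafSequenceVariability(rect, m), 1)

  single <- toyCP(m, -1, 1)
  expect_equal(leafSequenceVariability(single, m), 1)
})

test_that("AAV relates each aperture to the arc's maximal aperture", {
  m <- elektaMLCi()
  # constant aperture: AAV = 1 at every control point
  p <- unmodulatedFixture(m, nCP = 7)
  expect_equal(apertureAreaVariability(arcs(p)[[1]]), rep(1, 7))

  # 2-CP arc, one pair, gaps 2 and 4 with a shared bank-A position
  cps <- list(
    toyCP(m, -1, 1, w = 0),
    toyCP(m, -1, 3, w = 1)
  )
  arc <- arcBeam(m, cps, beamMU = 100)
  expect_equal(apertureAreaVariability(arc), c(0.5, 1.0))

  # a closed control point inside an open arc scores 0
  cps3 <- list(
    toyCP(m, -1, 1, w = 0),
    toyCP(m, 0, 0, w = 0.5),
    toyCP(m, -1, 1, w = 1)
  )
  arc3 <- arcBeam(m, cps3, beamMU = 100)
  expect_equal(apertureAreaVariability(arc3)[2], 0)

  # a fully closed arc has no defined AAV
  closedArc <- arcBeam(m, list(toyCP(m, 0, 0, w = 0), toyCP(m, 0, 0, w = 1)),
    beamMU = 10)
  expect_error(apertureAreaVariability(closedArc), "closed")
})

test_that("segment weights are cumulative-weight differences summing to 1", {
  m <- elektaMLCi()
  w5 <- seq(0, 1, length.out = 5)
  arc <- arcBeam(m, lapply(seq_along(w5), function(i)
    toyCP(m, -1, 1, w = w5[i])), beamMU = 100)
  expect_equal(segmentWeights(arc), rep(0.25, 4))

  arc2 <- arcBeam(m, list(toyCP(m, -1, 1, w = 0), toyCP(m, -1, 1, w = 0.4),
    toyCP(m, -1, 1, w = 1)), beamMU = 100)
  expect_equal(segmentWeights(arc2), c(0.4, 0.6))
  expect_equal(sum(segmentWeights(arc2)), 1, tolerance = 1e-6)
})

test_that("MCS combines consecutive-CP scores with MU weights", {
  expect_equal(mcsFromScores(c(1, 0.5, 1), c(1, 0.5, 1), c(0.5, 0.5)), 0.5625)

  # constant rectangular aperture scores exactly 1, any weights
  m <- millennium120()
  for (nCP in c(2, 9, 37)) {
    p <- unmodulatedFixture(m, nCP = nCP)
    expect_equal(mcsArc(arcs(p)[[1]]), 1)
  }

  # MU rescaling leaves the MCS unchanged
  arc <- randomSyntheticArc(elektaMLCi(), seed = 42)
  scaled <- arc
  scaled@beamMU <- arc@beamMU * 10
  expect_identical(mcsArc(scaled), mcsArc(arc))
})

test_that("plan scoring aggregates arcs by MU weight", {
  m <- elektaMLCi()
  p1 <- unmodulatedFixture(m, nCP = 5)
  expect_equal(scorePlan(p1)@plan$mcs, mcsArc(arcs(p1)[[1]]))

  # two identical arcs: plan MCS equals either arc's
  p2 <- rtPlan("two", list(arcs(p1)[[1]], arcs(p1)[[1]]))
  expect_equal(scorePlan(p2)@plan$mcs, mcsArc(arcs(p1)[[1]]))

  # weighted mean by hand: MUs 100/300, arc MCS m1/m2
  a1 <- randomSyntheticArc(m, seed = 7, amplitude = 0.8)
  a2 <- randomSyntheticArc(m, seed = 8, amplitude = 0.2)
  a1@beamMU <- 100; a2@beamMU <- 300
  rep2 <- scorePlan(rtPlan("w", list(a1, a2)))
  expect_equal(rep2@plan$mcs, 0.25 * mcsArc(a1) + 0.75 * mcsArc(a2))
})

test_that("scores stay in range and weights telescope on random arcs", {
  k <- 0
  for (m in machineRegistry()) {
    for (seed in 1:25) {
      arc <- randomSyntheticArc(m, seed = 1000 + seed)
      lsv <- vapply(controlPoints(arc), leafSequenceVariability, numeric(1),
        machine = machine(arc))
      aav <- apertureAreaVariability(arc)
      expect_true(all(lsv >= 0 & lsv <= 1))
      expect_true(all(aav >= 0 & aav <= 1 + 1e-12))
      expect_equal(sum(segmentWeights(arc)), 1, tolerance = 1e-6)
      mcs <- mcsArc(arc)
      expect_gte(mcs, 0)
      expect_lte(mcs, 1)
      k <- k + 1
    }
  }
  expect_equal(k, 50)
})

test_that("scores are invariant to a global leaf translation", {
  for (seed in c(3, 4)) {
    arc <- randomSyntheticArc(millennium120(), seed = 300 + seed)
    shift <- 2.5
    shifted <- arc
    shifted@cps <- lapply(controlPoints(arc), function(cp) {
      cp@leafA <- cp@leafA + shift
      cp@leafB <- cp@leafB + shift
      cp@jawX <- cp@jawX + shift
      cp
    })
    m <- machine(arc)
    for (i in seq_along(controlPoints(arc))) {
      c0 <- controlPoints(arc)[[i]]
      c1 <- controlPoints(shifted)[[i]]
      expect_equal(segmentArea(c1, m), segmentArea(c0, m))
      expect_equal(segmentWidth(c1, m), segmentWidth(c0, m))
      expect_equal(leafSequenceVariability(c1, m),
        leafSequenceVariability(c0, m))
    }
    expect_equal(apertureAreaVariability(shifted),
      apertureAreaVariability(arc))
    expect_equal(mcsArc(shifted), mcsArc(arc))
  }
})

test_that("widening one in-field gap strictly increases SA, never lowers SW", {
  m <- elektaMLCi()
  for (seed in c(21, 22, 23)) {
    arc <- randomSyntheticArc(m, seed = seed)
    cp <- controlPoints(arc)[[3]]
    idx <- infieldPairs(cp, m)
    expect_gt(length(idx), 0)
    pick <- idx[1 + (seed %% length(idx))]
    wider <- cp
    wider@leafB[pick] <- wider@leafB[pick] + 0.7
    expect_gt(segmentArea(wider, m), segmentArea(cp, m))
    expect_gte(segmentWidth(wider, m), segmentWidth(cp, m))
  }
})

test_that("vectorized scores agree with the naive double-loop reference", {
  for (m in machineRegistry()) {
    for (seed in 1:10) {
      arc <- randomSyntheticArc(m, seed = 5000 + seed)
      ref <- oracleArcScores(arc)
      mm <- machine(arc)
      sw <- vapply(controlPoints(arc), segmentWidth, numeric(1), machine = mm)
      sa <- vapply(controlPoints(arc), segmentArea, numeric(1), machine = mm)
      lsv <- vapply(controlPoints(arc), leafSequenceVariability, numeric(1),
        machine = mm)
      relDiff <- function(x, y) max(abs(x - y) / pmax(abs(y), 1e-300))
      expect_lt(max(abs(sw - ref$sw)), 1e-12 * max(1, max(abs(ref$sw))))
      expect_lt(max(abs(sa - ref$sa)), 1e-12 * max(1, max(abs(ref$sa))))
      expect_lt(max(abs(lsv - ref$lsv)), 1e-12)
      expect_lt(max(abs(apertureAreaVariability(arc) - ref$aav)), 1e-12)
      expect_lt(abs(mcsArc(arc) - ref$mcs), 1e-12 * max(1, abs(ref$mcs)))
    }
  }
})
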