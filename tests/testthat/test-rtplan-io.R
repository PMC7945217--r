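# small hand-built arcs for I/O tests
twoCPArc <- function(machine = elektaMLCi(), mu = 200,
                     weights = c(0, 1)) {
  n <- nPairs(machine)
  open <- function(gap) {
    a <- rep(0, n); b <- rep(0, n)
    a[15:25] <- -gap / 2; b[15:25] <- gap / 2
    list(a = a, b = b)
  }
  cps <- lapply(seq_along(weights), function(i) {
    o <- open(2 + i)
    controlPoint(i - 1L, 180 + 2 * i, o$a, o$b,
      jawX = c(-6, 6), jawY = c(-6, 6), cumWeight = weights[i])
  })
  arcBeam(machine, cps, beamMU = mu)
}

test_that("write then read is the identity on a minimal 2-CP plan", {
  plan <- rtPlan("mini", twoCPArc())
  path <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(plan, path)
  got <- readRTPlan(path)
  expect_length(arcs(got), 1)
  arc <- arcs(got)[[1]]
  expect_length(controlPoints(arc), 2)
  expect_equal(beamMU(arc), 200)
  expect_identical(machine(arc)@name, "elektaMLCi")
})

test_that("round-trip preserves all numeric content for both machines", {
  for (m in machineRegistry()) {
    for (seed in c(11, 12)) {
      plan <- generatePlan(generatorConfig(machine = m, seed = seed,
        gantrySpacing = 8, muProfile = "random-dirichlet",
        modulationAmplitude = 0.6))
      path <- withr::local_tempfile(fileext = ".dcm")
      writeRTPlan(plan, path)
      got <- readRTPlan(path)
      expect_length(arcs(got), length(arcs(plan)))
      for (ai in seq_along(arcs(plan))) {
        a0 <- arcs(plan)[[ai]]
        a1 <- arcs(got)[[ai]]
        expect_identical(a1@rotation, a0@rotation)
        expect_equal(beamMU(a1), beamMU(a0), tolerance = 1e-8)
        for (ci in seq_along(controlPoints(a0))) {
          c0 <- controlPoints(a0)[[ci]]
          c1 <- controlPoints(a1)[[ci]]
          expect_lt(max(abs(c1@leafA - c0@leafA),
            abs(c1@leafB - c0@leafB),
            abs(c1@jawX - c0@jawX), abs(c1@jawY - c0@jawY)), 1e-4)
          expect_lt(abs(c1@cumWeight - c0@cumWeight), 1e-6)
          expect_lt(abs(c1@gantryAngle - c0@gantryAngle), 1e-6)
          # bank-gap invariant holds after reading
          expect_true(all(c1@leafB - c1@leafA >= -1e-9))
        }
      }
    }
  }
})

test_that("a written 40-pair plan carries a 41-entry boundary table", {
  path <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(rtPlan("b", twoCPArc(elektaMLCi())), path)
  ds <- vmatcx:::.dcmRead(path)
  beam <- ds[["300A00B0"]][[1]]
  mlcx <- Filter(function(d) identical(d[["300A00B8"]], "MLCX"),
    beam[["300A00B6"]])[[1]]
  expect_length(mlcx[["300A00BE"]], 41)
})

test_that("segment MU follows the cumulative-weight differences", {
  arc <- twoCPArc(weights = c(0, 0.4, 1), mu = 200)
  expect_equal(segmentMU(arc), c(80, 120))

  uniform <- twoCPArc(weights = seq(0, 1, length.out = 5), mu = 100)
  expect_equal(segmentMU(uniform), rep(25, 4))

  random <- twoCPArc(weights = c(0, 0.13, 0.55, 0.71, 1), mu = 317)
  expect_equal(sum(segmentMU(random)), 317, tolerance = 1e-6)
})

test_that("decreasing cumulative weights are a distinct read error", {
  # bypass the writer's validity gate by patching the weights in the raw file
  plan <- rtPlan("bad", twoCPArc(weights = c(0, 0.5, 1)))
  path <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(plan, path)
  raw <- readBin(path, "raw", file.info(path)$size)
  # cumulative weight 0.5 is encoded as the DS string "0.5 " (padded)
  pat <- charToRaw("0.5 ")
  hit <- NULL
  for (i in seq_len(length(raw) - 3)) {
    if (all(raw[i:(i + 3)] == pat)) { hit <- i; break }
  }
  expect_false(is.null(hit))
  raw[hit:(hit + 3)] <- charToRaw("-0.5")
  # keep the plan parsable: -0.5 after 0 violates monotonicity
  writeBin(raw, path)
  expect_error(readRTPlan(path), "non-monotone|decrease")
})

test_that("plans without MLC or arcs fail with explicit errors", {
  expect_error(new("RTPlan", planID = "empty", arcs = list()) |>
    validObject(), "at least one arc")
  # a plan whose boundaries match no registered machine
  plan <- rtPlan("odd", twoCPArc(elektaMLCi()))
  path <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(plan, path)
  expect_error(readRTPlan(path, registry = list(m = millennium120())),
    "unmatchable")
})

test_that("the MU sidecar supplies beam meterset by beam number", {
  plan <- rtPlan("side", twoCPArc(mu = 123))
  path <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(plan, path)
  got <- readRTPlan(path, beamMU = c("1" = 999))
  expect_equal(beamMU(arcs(got)[[1]]), 999)
})

test_that("pydicom parses the files the writer emits", {
  plan <- unmodulatedFixture(millennium120(), nCP = 5)
  path <- withr::local_tempfile(fileext = ".dcm")
  writeRTPlan(plan, path)
  script <- paste(
    "import pydicom, json, sys",
    "ds = pydicom.dcmread(sys.argv[1])",
    "b = ds.BeamSequence[0]",
    "mlc = [d for d in b.BeamLimitingDeviceSequence",
    "       if d.RTBeamLimitingDeviceType == 'MLCX'][0]",
    "cp = b.ControlPointSequence[2]",
    "pos = [d for d in cp.BeamLimitingDevicePositionSequence",
    "       if d.RTBeamLimitingDeviceType == 'MLCX'][0].LeafJawPositions",
    "print(json.dumps({'n': int(b.NumberOfControlPoints),",
    " 'pairs': int(mlc.NumberOfLeafJawPairs),",
    " 'mu': float(ds.FractionGroupSequence[0]",
    "   .ReferencedBeamSequence[0].BeamMeterset),",
    " 'w': float(cp.CumulativeMetersetWeight),",
    " 'minpos': min(map(float, pos)), 'maxpos': max(map(float, pos))}))",
    sep = "\n")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script),
    shQuote(path)), stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  expect_true(is.null(status) || status == 0)
  parsed <- jsonlite::fromJSON(paste(out, collapse = ""))
  expect_equal(parsed$n, 5)
  expect_equal(parsed$pairs, 60)
  expect_equal(parsed$mu, 400)
  expect_equal(parsed$w, 0.5)
  expect_equal(parsed$minpos, -50) # mm
  expect_equal(parsed$maxpos, 50)
})
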