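#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Multileaf collimator geometry
#'
#' Static geometry of one MLC: the number of opposed leaf pairs, the projected
#' width of each pair at the isocenter plane, the y-coordinates of the pair
#' edges, and the maximum distance a leaf tip may travel across the beam
#' central axis (overtravel). All lengths are cm at isocenter; DICOM millimetre
#' values are converted at the I/O boundary.
#'
#' @slot name label of the machine template.
#' @slot nPairs integer, number of opposed leaf pairs.
#' @slot leafWidths numeric, per-pair widths (cm), ordered from the most
#'   negative y boundary upward.
#' @slot leafBoundaries numeric of length \code{nPairs + 1}, strictly
#'   increasing pair-edge y-coordinates (cm), symmetric about 0 for the
#'   built-in templates.
#' @slot overtravel numeric, maximum leaf travel past the central axis (cm).
#' @slot minGap numeric, minimum allowed leaf-pair opening (cm).
#'
#' @seealso [millennium120()], [elektaMLCi()]
#' @export
setClass("MLCModel",
  representation(
    name = "character",
    nPairs = "integer",
    leafWidths = "numeric",
    leafBoundaries = "numeric",
    overtravel = "numeric",
    minGap = "numeric"
  )
)

setValidity("MLCModel", function(object) {
  msg <- character()
  n <- object@nPairs
  if (length(n) != 1L || is.na(n) || n < 1L)
    msg <- c(msg, "nPairs must be a single positive integer")
  if (length(object@leafWidths) != n)
    msg <- c(msg, "leafWidths must have one entry per leaf pair")
  if (any(object@leafWidths <= 0))
    msg <- c(msg, "all leafWidths must be > 0")
  b <- object@leafBoundaries
  if (length(b) != n + 1L)
    msg <- c(msg, "leafBoundaries must have nPairs + 1 entries")
  else {
    if (any(diff(b) <= 0))
      msg <- c(msg, "leafBoundaries must be strictly increasing")
    if (length(object@leafWidths) == n &&
        any(abs(diff(b) - object@leafWidths) > 1e-9))
      msg <- c(msg, "boundary differences must equal leafWidths (tol 1e-9 cm)")
  }
  if (length(object@overtravel) != 1L || object@overtravel < 0)
    msg <- c(msg, "overtravel must be a single non-negative number")
  if (length(object@minGap) != 1L || object@minGap < 0)
    msg <- c(msg, "minGap must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Delivery-system constraint set
#'
#' Kinematic and output limits of a delivery system: maximum gantry speed,
#' maximum dose rate and its control mode (continuously variable, or a ladder
#' of discrete bins), and maximum leaf speed. The built-in defaults are
#' configuration assumptions, not vendor specifications.
#'
#' @slot maxGantrySpeed numeric, deg/s.
#' @slot maxDoseRate numeric, MU/min.
#' @slot doseRateMode \code{"continuous"} or \code{"binned"}.
#' @slot doseRateBins numeric or NULL; descending MU/min values, required when
#'   mode is binned.
#' @slot maxLeafSpeed numeric, cm/s.
#'
#' @seealso [defaultConstraints()]
#' @export
setClass("MachineConstraints",
  representation(
    maxGantrySpeed = "numeric",
    maxDoseRate = "numeric",
    doseRateMode = "character",
    doseRateBins = "numericOrNULL",
    maxLeafSpeed = "numeric"
  )
)

setValidity("MachineConstraints", function(object) {
  msg <- character()
  if (!object@doseRateMode %in% c("continuous", "binned"))
    msg <- c(msg, "doseRateMode must be 'continuous' or 'binned'")
  if (object@maxGantrySpeed <= 0) msg <- c(msg, "maxGantrySpeed must be > 0")
  if (object@maxDoseRate <= 0) msg <- c(msg, "maxDoseRate must be > 0")
  if (object@maxLeafSpeed <= 0) msg <- c(msg, "maxLeafSpeed must be > 0")
  if (identical(object@doseRateMode, "binned")) {
    if (is.null(object@doseRateBins) || length(object@doseRateBins) == 0L)
      msg <- c(msg, "binned mode requires a non-empty doseRateBins list")
    else if (any(object@doseRateBins > object@maxDoseRate + 1e-9))
      msg <- c(msg, "all doseRateBins must be <= maxDoseRate")
  }
  if (length(msg)) msg else TRUE
})

#' One control point of an arc beam
#'
#' An instantaneous machine state: gantry angle, per-pair signed leaf
#' positions for the two MLC banks, jaw positions and the cumulative meterset
#' weight reached at this point. Positions are signed coordinates on the
#' leaf-travel axis in cm; bank B (the "left" bank) sits at equal or larger
#' coordinates than bank A on open pairs, so \code{leafB - leafA} is the
#' per-pair gap and is never negative.
#'
#' @slot index integer control-point index (0-based, as in RT Plan files).
#' @slot gantryAngle numeric, deg in [0, 360).
#' @slot leafA,leafB numeric, per-pair leaf positions (cm).
#' @slot jawX,jawY numeric length 2, (low, high) jaw edges (cm).
#' @slot cumWeight numeric, cumulative meterset weight in [0, 1].
#'
#' @export
setClass("ControlPoint",
  representation(
    index = "integer",
    gantryAngle = "numeric",
    leafA = "numeric",
    leafB = "numeric",
    jawX = "numeric",
    jawY = "numeric",
    cumWeight = "numeric"
  )
)

setValidity("ControlPoint", function(object) {
  msg <- character()
  if (length(object@leafA) != length(object@leafB))
    msg <- c(msg, "leafA and leafB must have equal length")
  if (any(object@leafB - object@leafA < -1e-9))
    msg <- c(msg, "per-pair gap leafB - leafA must be non-negative")
  if (length(object@jawX) != 2L || object@jawX[1] >= object@jawX[2])
    msg <- c(msg, "jawX must be (low, high) with low < high")
  if (length(object@jawY) != 2L || object@jawY[1] >= object@jawY[2])
    msg <- c(msg, "jawY must be (low, high) with low < high")
  if (object@cumWeight < -1e-9 || object@cumWeight > 1 + 1e-9)
    msg <- c(msg, "cumWeight must lie in [0, 1]")
  if (object@gantryAngle < 0 || object@gantryAngle >= 360)
    msg <- c(msg, "gantryAngle must lie in [0, 360)")
  if (length(msg)) msg else TRUE
})

#' An arc beam
#'
#' An ordered sequence of control points delivered during one gantry arc,
#' together with the machine geometry, an optional constraint set, the total
#' beam monitor units and the rotation direction. This is the unit over which
#' the modulation complexity score is defined.
#'
#' @slot machine [MLCModel-class] geometry the leaf positions refer to.
#' @slot constraints [MachineConstraints-class] or NULL.
#' @slot cps list of [ControlPoint-class], ordered by cumulative weight.
#' @slot beamMU numeric, total monitor units of the beam.
#' @slot rotation \code{"CW"} or \code{"CCW"}.
#' @slot collimatorAngle numeric, deg.
#'
#' @export
setClass("ArcBeam",
  representation(
    machine = "MLCModel",
    constraints = "ANY",
    cps = "list",
    beamMU = "numeric",
    rotation = "character",
    collimatorAngle = "numeric"
  ),
  prototype(constraints = NULL, rotation = "CW", collimatorAngle = 0)
)

setValidity("ArcBeam", function(object) {
  msg <- character()
  if (!is.null(object@constraints) &&
      !is(object@constraints, "MachineConstraints"))
    msg <- c(msg, "constraints must be NULL or a MachineConstraints")
  if (length(object@cps) < 2L)
    msg <- c(msg, "an arc needs at least 2 control points")
  if (!all(vapply(object@cps, is, logical(1), "ControlPoint")))
    return("cps must be a list of ControlPoint objects")
  n <- object@machine@nPairs
  bad <- vapply(object@cps, function(cp) length(cp@leafA) != n, logical(1))
  if (any(bad))
    msg <- c(msg, "every control point must carry nPairs leaf positions")
  w <- vapply(object@cps, slot, numeric(1), "cumWeight")
  if (any(diff(w) < -1e-9))
    msg <- c(msg, "cumulative meterset weights must be non-decreasing")
  if (abs(w[1]) > 1e-6 || abs(w[length(w)] - 1) > 1e-6)
    msg <- c(msg, "cumulative weights must start at 0 and end at 1 (tol 1e-6)")
  if (length(object@beamMU) != 1L || object@beamMU <= 0)
    msg <- c(msg, "beamMU must be a single positive number")
  if (!object@rotation %in% c("CW", "CCW"))
    msg <- c(msg, "rotation must be 'CW' or 'CCW'")
  if (length(msg)) msg else TRUE
})

#' An arc-therapy plan
#'
#' One treatment plan: a plan identifier plus one or more arc beams.
#'
#' @slot planID character label.
#' @slot arcs list of [ArcBeam-class].
#'
#' @export
setClass("RTPlan",
  representation(planID = "character", arcs = "list")
)

setValidity("RTPlan", function(object) {
  if (length(object@arcs) < 1L)
    return("a plan needs at least one arc")
  if (!all(vapply(object@arcs, is, logical(1), "ArcBeam")))
    return("arcs must be a list of ArcBeam objects")
  TRUE
})

#' Plan-level complexity report
#'
#' Aggregated complexity scores of a plan: one row per segment, one per arc,
#' and a single plan-level summary with both unweighted and MU-weighted means
#' of SW, SA, LSV and AAV, plus the MU-weighted plan MCS.
#'
#' @slot planID character.
#' @slot plan one-row data.frame of plan-level aggregates.
#' @slot arcs data.frame, one row per arc.
#' @slot segments data.frame, one row per control point per arc.
#'
#' @seealso [scorePlan()]
#' @export
setClass("ComplexityReport",
  representation(
    planID = "character",
    plan = "data.frame",
    arcs = "data.frame",
    segments = "data.frame"
  )
)
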