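#' Build an MLC geometry model
#'
#' Boundaries are derived from the widths and centered so the field is
#' symmetric about the beam central axis, the convention both built-in
#' templates use.
#'
#' @param name label for the model.
#' @param leafWidths per-pair projected widths at isocenter, cm.
#' @param overtravel maximum leaf travel past the central axis, cm.
#' @param minGap minimum allowed leaf-pair opening, cm (default 0).
#' @param leafBoundaries optional explicit boundaries; computed from
#'   \code{leafWidths} (symmetric about 0) when omitted.
#' @return An [MLCModel-class].
#' @examples
#' m <- mlcModel("uniform10", rep(1, 40), overtravel = 12.5)
#' nPairs(m)
#' @export
mlcModel <- function(name, leafWidths, overtravel, minGap = 0,
                     leafBoundaries = NULL) {
  if (is.null(leafBoundaries)) {
    total <- sum(leafWidths)
    leafBoundaries <- cumsum(c(-total / 2, leafWidths))
  }
  new("MLCModel",
    name = as.character(name),
    nPairs = length(leafWidths),
    leafWidths = as.numeric(leafWidths),
    leafBoundaries = as.numeric(leafBoundaries),
    overtravel = as.numeric(overtravel),
    minGap = as.numeric(minGap)
  )
}

#' Build a delivery constraint set
#'
#' @param maxGantrySpeed deg/s.
#' @param maxDoseRate MU/min.
#' @param doseRateMode "continuous" or "binned".
#' @param doseRateBins descending MU/min bins (binned mode only).
#' @param maxLeafSpeed cm/s.
#' @return A [MachineConstraints-class].
#' @export
machineConstraints <- function(maxGantrySpeed, maxDoseRate,
                               doseRateMode = c("continuous", "binned"),
                               doseRateBins = NULL, maxLeafSpeed = 2.5) {
  doseRateMode <- match.arg(doseRateMode)
  if (!is.null(doseRateBins))
    doseRateBins <- sort(as.numeric(doseRateBins), decreasing = TRUE)
  new("MachineConstraints",
    maxGantrySpeed = as.numeric(maxGantrySpeed),
    maxDoseRate = as.numeric(maxDoseRate),
    doseRateMode = doseRateMode,
    doseRateBins = doseRateBins,
    maxLeafSpeed = as.numeric(maxLeafSpeed)
  )
}

#' Build a control point
#'
#' @param index 0-based control-point index.
#' @param gantryAngle deg in [0, 360).
#' @param leafA,leafB per-pair leaf positions, cm; \code{leafB - leafA} is the
#'   pair gap and must be non-negative.
#' @param jawX,jawY length-2 (low, high) jaw edges, cm.
#' @param cumWeight cumulative meterset weight in [0, 1].
#' @return A [ControlPoint-class].
#' @export
controlPoint <- function(index, gantryAngle, leafA, leafB,
                         jawX = c(-20, 20), jawY = c(-20, 20), cumWeight) {
  new("ControlPoint",
    index = as.integer(index),
    gantryAngle = as.numeric(gantryAngle) %% 360,
    leafA = as.numeric(leafA),
    leafB = as.numeric(leafB),
    jawX = as.numeric(jawX),
    jawY = as.numeric(jawY),
    cumWeight = as.numeric(cumWeight)
  )
}

#' Build an arc beam
#'
#' @param machine [MLCModel-class].
#' @param cps list of [ControlPoint-class], ordered.
#' @param beamMU total monitor units.
#' @param rotation "CW" or "CCW".
#' @param collimatorAngle deg.
#' @param constraints optional [MachineConstraints-class].
#' @return An [ArcBeam-class].
#' @export
arcBeam <- function(machine, cps, beamMU, rotation = "CW",
                    collimatorAngle = 0, constraints = NULL) {
  new("ArcBeam",
    machine = machine, constraints = constraints, cps = cps,
    beamMU = as.numeric(beamMU), rotation = rotation,
    collimatorAngle = as.numeric(collimatorAngle)
  )
}

#' Build a plan
#'
#' @param planID character label.
#' @param arcs list of [ArcBeam-class].
#' @return An [RTPlan-class].
#' @export
rtPlan <- function(planID, arcs) {
  if (is(arcs, "ArcBeam")) arcs <- list(arcs)
  new("RTPlan", planID = as.character(planID), arcs = arcs)
}

#' Accessors for MLC geometry
#'
#' @param x an [MLCModel-class].
#' @return \code{nPairs}: integer; \code{leafWidths}, \code{leafBoundaries},
#'   \code{overtravel}: numeric, cm.
#' @name MLCModel-accessors
NULL

#' @rdname MLCModel-accessors
#' @export
setMethod("nPairs", "MLCModel", function(x) x@nPairs)
#' @rdname MLCModel-accessors
#' @export
setMethod("leafWidths", "MLCModel", function(x) x@leafWidths)
#' @rdname MLCModel-accessors
#' @export
setMethod("leafBoundaries", "MLCModel", function(x) x@leafBoundaries)
#' @rdname MLCModel-accessors
#' @export
setMethod("overtravel", "MLCModel", function(x) x@overtravel)

#' Accessors for arc beams
#'
#' @param x an [ArcBeam-class].
#' @param value replacement value.
#' @name ArcBeam-accessors
NULL

#' @rdname ArcBeam-accessors
#' @export
setMethod("controlPoints", "ArcBeam", function(x) x@cps)
#' @rdname ArcBeam-accessors
#' @export
setMethod("beamMU", "ArcBeam", function(x) x@beamMU)
#' @rdname ArcBeam-accessors
#' @export
setMethod("machine", "ArcBeam", function(x) x@machine)
#' @rdname ArcBeam-accessors
#' @export
setMethod("constraints", "ArcBeam", function(x) x@constraints)
#' @rdname ArcBeam-accessors
#' @export
setReplaceMethod("constraints", "ArcBeam", function(x, value) {
  x@constraints <- value
  validObject(x)
  x
})

#' Accessors for plans
#'
#' @param x an [RTPlan-class].
#' @name RTPlan-accessors
NULL

#' @rdname RTPlan-accessors
#' @export
setMethod("arcs", "RTPlan", function(x) x@arcs)
#' @rdname RTPlan-accessors
#' @export
setMethod("planID", "RTPlan", function(x) x@planID)

setMethod("show", "MLCModel", function(object) {
  cat("MLCModel '", object@name, "': ", object@nPairs, " leaf pairs, ",
    "widths ", paste(unique(object@leafWidths), collapse = "/"),
    " cm, overtravel ", object@overtravel, " cm\n", sep = "")
})

setMethod("show", "MachineConstraints", function(object) {
  cat("MachineConstraints: gantry <= ", object@maxGantrySpeed, " deg/s, ",
    "dose rate <= ", object@maxDoseRate, " MU/min (", object@doseRateMode,
    ")", sep = "")
  if (identical(object@doseRateMode, "binned"))
    cat(", bins ", paste(object@doseRateBins, collapse = "/"), sep = "")
  cat(", leaf <= ", object@maxLeafSpeed, " cm/s\n", sep = "")
})

setMethod("show", "ControlPoint", function(object) {
  cat("ControlPoint #", object@index, ": gantry ",
    round(object@gantryAngle, 2), " deg, cumWeight ",
    round(object@cumWeight, 4), ", ", length(object@leafA),
    " leaf pairs\n", sep = "")
})

setMethod("show", "ArcBeam", function(object) {
  cat("ArcBeam on '", object@machine@name, "': ", length(object@cps),
    " control points, ", object@beamMU, " MU, ", object@rotation,
    "\n", sep = "")
})

setMethod("show", "RTPlan", function(object) {
  cat("RTPlan '", object@planID, "' with ", length(object@arcs),
    " arc(s)\n", sep = "")
  for (a in object@arcs) show(a)
})

setMethod("show", "ComplexityReport", function(object) {
  cat("ComplexityReport for plan '", object@planID, "'\n", sep = "")
  cat("  arcs: ", nrow(object@arcs), ", segments scored: ",
    nrow(object@segments), "\n", sep = "")
  cat("  plan MCS (MU-weighted): ", signif(object@plan$mcs, 4), "\n", sep = "")
})
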