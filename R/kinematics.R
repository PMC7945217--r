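# signed gantry travel from a1 to a2 along the arc's rotation direction, deg
.gantryDelta <- function(a1, a2, rotation) {
  d <- if (rotation == "CW") (a2 - a1) %% 360 else (a1 - a2) %% 360
  d
}

#' Per-segment delivery kinematics of an arc
#'
#' A forward kinematic model of the delivery: for each segment (the span
#' between consecutive control points) the segment time is the largest of the
#' three limit times — gantry travel at maximum gantry speed, MU delivery at
#' maximum dose rate, and the largest single-leaf travel at maximum leaf
#' speed. Gantry speed and dose rate follow from the segment time, and the
#' binding constraint is recorded.
#'
#' For machines with binned dose-rate control the continuous dose-rate
#' solution is reduced to the largest bin not exceeding it and the segment
#' time recomputed; when the continuous solution falls below the smallest
#' bin, the nominal (pulsed) rate is the smallest bin and the segment time is
#' unchanged. Acceleration limits are ignored: speed is piecewise constant
#' per segment. This is a plan-side estimator, not a log reconstruction.
#'
#' @param arc an [ArcBeam-class] with a [MachineConstraints-class] attached.
#' @return data.frame with one row per segment: \code{dt} (s),
#'   \code{gantrySpeed} (deg/s), \code{doseRate} (MU/min),
#'   \code{limitingFactor} (\code{"gantry"}, \code{"dose_rate"} or
#'   \code{"leaf"}).
#' @seealso [beamOnTime()]
#' @export
estimateKinematics <- function(arc) {
  stopifnot(is(arc, "ArcBeam"))
  k <- arc@constraints
  if (is.null(k))
    stop("arc has no machine constraints attached; see defaultConstraints()")
  cps <- arc@cps
  I <- length(cps)
  mus <- segmentMU(arc)
  out <- vector("list", I - 1L)
  for (i in seq_len(I - 1L)) {
    a <- cps[[i]]; b <- cps[[i + 1L]]
    dg <- .gantryDelta(a@gantryAngle, b@gantryAngle, arc@rotation)
    dmu <- mus[i]
    dleaf <- max(abs(b@leafA - a@leafA), abs(b@leafB - a@leafB))
    tG <- dg / k@maxGantrySpeed
    tD <- dmu / k@maxDoseRate * 60
    tL <- dleaf / k@maxLeafSpeed
    dt <- max(tG, tD, tL)
    if (dt <= 0)
      stop("segment ", i, " has no gantry motion, no MU and no leaf travel; ",
        "its duration is undefined")
    dr <- dmu / dt * 60
    if (identical(k@doseRateMode, "binned") && dmu > 0) {
      bins <- sort(k@doseRateBins, decreasing = TRUE)
      fit <- bins[bins <= dr + 1e-9]
      if (length(fit) > 0L) {
        dr <- fit[1]
        dt <- max(tG, tL, dmu / dr * 60)
      } else {
        dr <- bins[length(bins)] # pulsed at the lowest bin; dt unchanged
      }
    }
    lims <- c(gantry = tG, dose_rate = tD, leaf = tL)
    out[[i]] <- data.frame(
      segment = i, dt = dt, gantrySpeed = dg / dt, doseRate = dr,
      limitingFactor = names(lims)[which.max(lims)]
    )
  }
  do.call(rbind, out)
}

#' Beam-on time of an arc
#'
#' The sum of the per-segment times of the forward kinematic model, in
#' seconds.
#'
#' @inheritParams estimateKinematics
#' @return Seconds.
#' @export
beamOnTime <- function(arc) {
  sum(estimateKinematics(arc)$dt)
}

#' Kinematic summary of a plan
#'
#' @param plan an [RTPlan-class] whose arcs carry constraints.
#' @return data.frame with one row per arc: mean gantry speed, mean dose rate
#'   (MU-weighted over segments), and beam-on time; plus a plan total row.
#' @export
planKinematics <- function(plan) {
  stopifnot(is(plan, "RTPlan"))
  rows <- lapply(seq_along(plan@arcs), function(ai) {
    kin <- estimateKinematics(plan@arcs[[ai]])
    data.frame(
      arc = ai,
      meanGantrySpeed = sum(kin$gantrySpeed * kin$dt) / sum(kin$dt),
      meanDoseRate = sum(kin$doseRate * kin$dt) / sum(kin$dt),
      beamOnTime = sum(kin$dt)
    )
  })
  do.call(rbind, rows)
}
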