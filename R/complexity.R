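#' In-field leaf pairs of a control point
#'
#' A pair counts as in-field when (a) its opening exceeds the closed-gap
#' threshold (leaves abutted or parked are excluded from all scores) and (b)
#' its leaf-width strip overlaps the open y-jaw interval by a positive
#' amount. Both conditions use strict inequalities, so a pair whose gap
#' equals the threshold is excluded.
#'
#' @param cp a [ControlPoint-class].
#' @param machine the [MLCModel-class] the positions refer to.
#' @param closedGap gap threshold in cm below or at which a pair is
#'   considered closed; default 0.05 cm.
#' @return Integer indices of the in-field pairs (possibly empty).
#' @export
infieldPairs <- function(cp, machine, closedGap = 0.05) {
  gaps <- cp@leafB - cp@leafA
  b <- machine@leafBoundaries
  lo <- b[-length(b)]
  hi <- b[-1]
  open <- gaps > closedGap
  inJaw <- (pmin(hi, cp@jawY[2]) - pmax(lo, cp@jawY[1])) > 0
  which(open & inJaw)
}

#' Segment width (SW)
#'
#' The maximum leaf-pair opening (bank B minus bank A) over the in-field
#' pairs of one control point, in cm. An all-closed control point has SW 0.
#'
#' @inheritParams infieldPairs
#' @return SW in cm.
#' @examples
#' m <- elektaMLCi()
#' cp <- controlPoint(0, 0, rep(0, 40), c(rep(0, 18), 2, 3, 4, rep(0, 19)),
#'   jawY = c(-3, 3), cumWeight = 0)
#' segmentWidth(cp, m) # 4
#' @export
segmentWidth <- function(cp, machine, closedGap = 0.05) {
  idx <- infieldPairs(cp, machine, closedGap)
  if (length(idx) == 0L) return(0)
  max(cp@leafB[idx] - cp@leafA[idx])
}

#' Segment area (SA)
#'
#' The aperture area of one control point: the sum over in-field pairs of the
#' pair opening times the projected leaf width, in cm². Closed pairs
#' contribute nothing; an all-closed control point has SA 0.
#'
#' @inheritParams infieldPairs
#' @return SA in cm².
#' @export
segmentArea <- function(cp, machine, closedGap = 0.05) {
  idx <- infieldPairs(cp, machine, closedGap)
  if (length(idx) == 0L) return(0)
  sum((cp@leafB[idx] - cp@leafA[idx]) * machine@leafWidths[idx])
}

#' Per-bank position range over the in-field pairs
#'
#' The spread (max minus min) of one bank's leaf positions across the
#' in-field pairs; the normalizer of the leaf sequence variability.
#'
#' @inheritParams infieldPairs
#' @param bank \code{"A"} (right bank) or \code{"B"} (left bank).
#' @return Range in cm; 0 when fewer than two pairs are in-field.
#' @export
posMax <- function(cp, machine, bank = c("A", "B"), closedGap = 0.05) {
  bank <- match.arg(bank)
  idx <- infieldPairs(cp, machine, closedGap)
  if (length(idx) < 2L) return(0)
  pos <- if (bank == "A") cp@leafA[idx] else cp@leafB[idx]
  max(pos) - min(pos)
}

.bankLSV <- function(pos) {
  n <- length(pos)
  if (n < 2L) return(1)
  pm <- max(pos) - min(pos)
  if (pm <= 0) return(1)
  sum(pm - abs(diff(pos))) / ((n - 1) * pm)
}

#' Leaf sequence variability (LSV)
#'
#' Characterizes the variation in segment shape: for each bank, adjacent
#' in-field leaf positions are compared and their similarity normalized by
#' the bank's position range; the LSV is the product of the two bank factors
#' and lies in [0, 1]. Degenerate banks (a single in-field pair, or zero
#' position range as in a rectangular field) contribute a factor of 1, so an
#' unmodulated aperture scores exactly 1.
#'
#' In-field pairs are traversed in physical leaf order; when the in-field set
#' is non-contiguous the consecutive members are still differenced, and the
#' condition is reported by [scorePlan()].
#'
#' @inheritParams infieldPairs
#' @return LSV, dimensionless in [0, 1].
#' @export
leafSequenceVariability <- function(cp, machine, closedGap = 0.05) {
  idx <- infieldPairs(cp, machine, closedGap)
  .bankLSV(cp@leafB[idx]) * .bankLSV(cp@leafA[idx])
}

# per-pair maximal opening over the whole arc (bank B max minus bank A min),
# zeroed for pairs never in-field at any control point
.arcMaxAperture <- function(arc, closedGap = 0.05) {
  m <- arc@machine
  union <- logical(m@nPairs)
  maxB <- rep(-Inf, m@nPairs)
  minA <- rep(Inf, m@nPairs)
  for (cp in arc@cps) {
    union[infieldPairs(cp, m, closedGap)] <- TRUE
    maxB <- pmax(maxB, cp@leafB)
    minA <- pmin(minA, cp@leafA)
  }
  open <- pmax(maxB - minA, 0)
  open[!union] <- 0
  list(open = open, union = union)
}

#' Aperture area variability (AAV)
#'
#' Characterizes each control point's aperture relative to the maximal
#' aperture defined by all control points of the arc: per pair, the largest
#' bank-B position minus the smallest bank-A position over the arc, summed
#' with leaf widths over the pairs that open at least once. The per-control-
#' point value is the segment area divided by this maximal area and lies in
#' [0, 1]; a closed control point inside an open arc scores 0.
#'
#' @param arc an [ArcBeam-class].
#' @param closedGap closed-pair threshold, cm.
#' @return Numeric vector, one AAV per control point.
#' @export
apertureAreaVariability <- function(arc, closedGap = 0.05) {
  m <- arc@machine
  mx <- .arcMaxAperture(arc, closedGap)
  denom <- sum(mx$open * m@leafWidths)
  if (denom <= 0)
    stop("aperture area variability undefined: every control point of the ",
      "arc is closed")
  vapply(arc@cps, function(cp) segmentArea(cp, m, closedGap) / denom,
    numeric(1))
}

#' Per-segment MU weights of an arc
#'
#' The fraction of the arc's monitor units delivered between consecutive
#' control points: differences of the cumulative meterset weights. They sum
#' to 1.
#'
#' @param arc an [ArcBeam-class].
#' @return Numeric vector of length (number of control points − 1).
#' @export
segmentWeights <- function(arc) {
  w <- vapply(arc@cps, slot, numeric(1), "cumWeight")
  diff(w)
}

#' Combine per-control-point scores into an MCS
#'
#' The modulation complexity score of an arc is the MU-weighted sum, over
#' consecutive control-point pairs, of the mean LSV times the mean AAV:
#' \deqn{MCS = \sum_{i=1}^{I-1} \frac{LSV_i + LSV_{i+1}}{2}
#'   \cdot \frac{AAV_i + AAV_{i+1}}{2} \cdot w_i.}
#'
#' @param lsv,aav numeric vectors of per-control-point scores (length I).
#' @param weights per-segment MU fractions (length I − 1, summing to 1).
#' @return MCS, dimensionless in [0, 1].
#' @examples
#' mcsFromScores(c(1, 0.5, 1), c(1, 0.5, 1), c(0.5, 0.5)) # 0.5625
#' @export
mcsFromScores <- function(lsv, aav, weights) {
  stopifnot(length(lsv) == length(aav),
    length(weights) == length(lsv) - 1L)
  i <- seq_len(length(lsv) - 1L)
  sum((lsv[i] + lsv[i + 1L]) / 2 * (aav[i] + aav[i + 1L]) / 2 * weights)
}

#' Modulation complexity score of an arc
#'
#' Evaluates LSV and AAV at every control point, averages them over
#' consecutive pairs and sums with the per-segment MU weights; see
#' [mcsFromScores()]. A constant rectangular aperture scores exactly 1
#' ("no modulation"); increasing modulation drives the score toward 0. The
#' score is invariant to rescaling the beam MU.
#'
#' @inheritParams apertureAreaVariability
#' @return MCS, dimensionless in [0, 1].
#' @export
mcsArc <- function(arc, closedGap = 0.05) {
  m <- arc@machine
  lsv <- vapply(arc@cps, leafSequenceVariability, numeric(1),
    machine = m, closedGap = closedGap)
  aav <- apertureAreaVariability(arc, closedGap)
  mcsFromScores(lsv, aav, segmentWeights(arc))
}

.isContiguous <- function(idx) {
  length(idx) <= 1L || all(diff(idx) == 1L)
}

#' Score a plan
#'
#' Computes all per-control-point metrics (SW, SA, LSV, AAV, in-field count,
#' MU weight) for every arc, the per-arc MCS and metric means, and
#' plan-level aggregates. The plan MCS is the MU-weighted mean of the arc
#' MCS values; SW, SA, LSV and AAV are reported both as unweighted means over
#' pooled control points and as MU-weighted means (consecutive-control-point
#' averages weighted by segment MU fractions).
#'
#' @param plan an [RTPlan-class].
#' @param closedGap closed-pair threshold, cm.
#' @return A [ComplexityReport-class].
#' @export
scorePlan <- function(plan, closedGap = 0.05) {
  stopifnot(is(plan, "RTPlan"))
  validObject(plan)
  segRows <- list()
  arcRows <- list()
  for (ai in seq_along(plan@arcs)) {
    arc <- plan@arcs[[ai]]
    m <- arc@machine
    I <- length(arc@cps)
    sw <- sa <- lsv <- numeric(I)
    nIn <- integer(I)
    contig <- logical(I)
    for (i in seq_len(I)) {
      cp <- arc@cps[[i]]
      idx <- infieldPairs(cp, m, closedGap)
      sw[i] <- segmentWidth(cp, m, closedGap)
      sa[i] <- segmentArea(cp, m, closedGap)
      lsv[i] <- leafSequenceVariability(cp, m, closedGap)
      nIn[i] <- length(idx)
      contig[i] <- .isContiguous(idx)
    }
    aav <- apertureAreaVariability(arc, closedGap)
    w <- segmentWeights(arc)
    mcs <- mcsFromScores(lsv, aav, w)
    segRows[[ai]] <- data.frame(
      arc = ai, cp = seq_len(I) - 1L, sw = sw, sa = sa, lsv = lsv,
      aav = aav, weight = c(w, 0), nInfield = nIn, contiguous = contig
    )
    wMean <- function(x) sum((x[-I] + x[-1]) / 2 * w)
    arcRows[[ai]] <- data.frame(
      arc = ai, machine = m@name, nCP = I, mu = arc@beamMU, mcs = mcs,
      meanSW = mean(sw), meanSA = mean(sa), meanLSV = mean(lsv),
      meanAAV = mean(aav),
      wMeanSW = wMean(sw), wMeanSA = wMean(sa), wMeanLSV = wMean(lsv),
      wMeanAAV = wMean(aav)
    )
  }
  segs <- do.call(rbind, segRows)
  arcsDF <- do.call(rbind, arcRows)
  muW <- arcsDF$mu / sum(arcsDF$mu)
  planDF <- data.frame(
    mu = sum(arcsDF$mu),
    mcs = sum(muW * arcsDF$mcs),
    meanSW = mean(segs$sw), meanSA = mean(segs$sa),
    meanLSV = mean(segs$lsv), meanAAV = mean(segs$aav),
    wMeanSW = sum(muW * arcsDF$wMeanSW), wMeanSA = sum(muW * arcsDF$wMeanSA),
    wMeanLSV = sum(muW * arcsDF$wMeanLSV),
    wMeanAAV = sum(muW * arcsDF$wMeanAAV)
  )
  new("ComplexityReport", planID = plan@planID, plan = planDF,
    arcs = arcsDF, segments = segs)
}

#' Export a complexity report
#'
#' JSON export nests plan, arcs and per-segment metrics; CSV export writes
#' one row per segment followed by arc and plan summary rows.
#'
#' @param report a [ComplexityReport-class].
#' @param json,csv optional output paths; at least one must be given.
#' @return Invisibly, a list of the paths written.
#' @export
writeReport <- function(report, json = NULL, csv = NULL) {
  stopifnot(is(report, "ComplexityReport"))
  if (is.null(json) && is.null(csv))
    stop("provide at least one of 'json' or 'csv'")
  written <- list()
  if (!is.null(json)) {
    payload <- list(
      plan_id = report@planID,
      plan = as.list(report@plan),
      arcs = report@arcs,
      segments = report@segments
    )
    jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA)
    written$json <- json
  }
  if (!is.null(csv)) {
    segs <- report@segments
    segs$level <- "segment"
    a <- report@arcs
    a$level <- "arc"
    p <- report@plan
    p$level <- "plan"
    p$planID <- report@planID
    all <- Reduce(function(x, y) merge(x, y, all = TRUE, sort = FALSE),
      list(segs, a, p))
    utils::write.csv(all, csv, row.names = FALSE)
    written$csv <- csv
  }
  invisible(written)
}
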