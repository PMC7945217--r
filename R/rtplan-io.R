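# DICOM tag keys used by the RT Plan reader/writer
.TAG <- list(
  sopClass = "00080016", sopInstance = "00080018", modality = "00080060",
  planLabel = "300A0002",
  fractionGroupSeq = "300A0070", refBeamSeq = "300C0004",
  beamMeterset = "300A0086", refBeamNumber = "300C0006",
  numberOfBeams = "300A0080",
  beamSeq = "300A00B0", beamNumber = "300A00C0", beamName = "300A00C2",
  beamType = "300A00C4", deliveryType = "300A00CE",
  bldSeq = "300A00B6", bldType = "300A00B8", nLeafJawPairs = "300A00BC",
  leafBoundaries = "300A00BE",
  nControlPoints = "300A0110", cpSeq = "300A0111", cpIndex = "300A0112",
  cumWeight = "300A0134", gantryAngle = "300A011E", gantryRotDir = "300A011F",
  collimatorAngle = "300A0120", bldPosSeq = "300A011A",
  leafJawPositions = "300A011C", finalCumWeight = "300A010E"
)

#' Read an arc-therapy DICOM RT Plan
#'
#' Parses the beam and control-point sequences of an RT Plan, converts all
#' positions from mm to cm, resolves the MLC bank orientation so that the
#' per-pair gap (bank B minus bank A) is non-negative, matches the plan's
#' leaf-boundary table against a machine registry, and drops static
#' (setup/imaging) beams. Beam monitor units are taken from the referenced
#' fraction group when present, else from the \code{beamMU} sidecar.
#'
#' A parse log (machine matched per beam, bank mapping, warnings) is attached
#' as attribute \code{"parseLog"}.
#'
#' @param path DICOM RT Plan file.
#' @param registry named list of candidate [MLCModel-class] geometries;
#'   default [machineRegistry()].
#' @param beamMU optional named numeric: monitor units per beam, named by beam
#'   number, used when the file carries no fraction-group meterset.
#' @param constraints optional [MachineConstraints-class] attached to every
#'   arc.
#' @return An [RTPlan-class].
#' @seealso [writeRTPlan()], [segmentMU()]
#' @export
readRTPlan <- function(path, registry = machineRegistry(), beamMU = NULL,
                       constraints = NULL) {
  ds <- .dcmRead(path)
  beams <- ds[[.TAG$beamSeq]]
  if (is.null(beams) || length(beams) == 0L)
    stop("RT Plan contains no beam sequence: ", path)

  musByNumber <- list()
  for (fg in ds[[.TAG$fractionGroupSeq]]) {
    for (rb in fg[[.TAG$refBeamSeq]]) {
      num <- rb[[.TAG$refBeamNumber]]
      if (!is.null(num) && !is.null(rb[[.TAG$beamMeterset]]))
        musByNumber[[as.character(num)]] <- rb[[.TAG$beamMeterset]]
    }
  }
  if (!is.null(beamMU))
    musByNumber[names(beamMU)] <- as.list(unname(beamMU))

  log <- list()
  arcs <- list()
  for (b in beams) {
    beamNum <- b[[.TAG$beamNumber]]
    nCP <- b[[.TAG$nControlPoints]]
    mu <- musByNumber[[as.character(beamNum)]]
    if (is.null(nCP) || nCP < 2L || is.null(mu) || mu <= 0) next # static beam

    bnd <- NULL
    for (bld in b[[.TAG$bldSeq]]) {
      if (identical(bld[[.TAG$bldType]], "MLCX"))
        bnd <- bld[[.TAG$leafBoundaries]] / 10 # mm -> cm
    }
    if (is.null(bnd))
      stop("beam ", beamNum, " has no MLCX device (missing MLC sequence)")

    mach <- .matchMachine(bnd, registry)
    if (is.null(mach))
      stop("beam ", beamNum, ": leaf-boundary table matches no registered ",
        "machine (unmatchable leaf boundaries)")
    n <- mach@nPairs

    cpsRaw <- b[[.TAG$cpSeq]]
    if (length(cpsRaw) != nCP)
      warning("beam ", beamNum, ": control-point count mismatch")

    # carry-forward state for fields many dialects define only at CP 0
    gantry <- 0; jawX <- NULL; jawY <- NULL; mlc <- NULL
    rotation <- "CW"; collim <- 0
    weights <- numeric(0); states <- list()
    for (cp in cpsRaw) {
      if (!is.null(cp[[.TAG$gantryAngle]])) gantry <- cp[[.TAG$gantryAngle]]
      if (!is.null(cp[[.TAG$gantryRotDir]])) {
        rd <- cp[[.TAG$gantryRotDir]]
        if (rd %in% c("CW", "CC")) rotation <- if (rd == "CW") "CW" else "CCW"
      }
      if (!is.null(cp[[.TAG$collimatorAngle]]))
        collim <- cp[[.TAG$collimatorAngle]]
      for (dev in cp[[.TAG$bldPosSeq]]) {
        typ <- dev[[.TAG$bldType]]
        posn <- dev[[.TAG$leafJawPositions]] / 10 # mm -> cm
        if (typ %in% c("X", "ASYMX")) jawX <- posn
        else if (typ %in% c("Y", "ASYMY")) jawY <- posn
        else if (typ == "MLCX") mlc <- posn
      }
      w <- cp[[.TAG$cumWeight]]
      if (is.null(w)) stop("beam ", beamNum, ": control point without ",
        "cumulative meterset weight")
      weights <- c(weights, w)
      if (is.null(mlc) || length(mlc) != 2L * n)
        stop("beam ", beamNum, ": MLCX position count != 2 x nPairs")
      states[[length(states) + 1L]] <- list(
        gantry = gantry,
        jawX = if (is.null(jawX)) c(-20, 20) else jawX,
        jawY = if (is.null(jawY)) c(-20, 20) else jawY,
        bank1 = mlc[seq_len(n)], bank2 = mlc[n + seq_len(n)]
      )
    }

    final <- b[[.TAG$finalCumWeight]]
    if (is.null(final) || final <= 0) final <- weights[length(weights)]
    if (final <= 0) stop("beam ", beamNum, ": zero final cumulative weight")
    weights <- weights / final
    if (any(diff(weights) < -1e-6))
      stop("beam ", beamNum, ": cumulative meterset weights decrease ",
        "(non-monotone)")
    weights <- pmin(pmax(weights, 0), 1)
    weights[abs(weights) < 1e-6] <- 0
    weights[abs(weights - 1) < 1e-6] <- 1

    # bank orientation: choose the assignment making most gaps non-negative
    gaps12 <- vapply(states, function(s) mean(s$bank2 - s$bank1 >= -1e-9),
      numeric(1))
    swap <- mean(gaps12) < 0.5
    cps <- vector("list", length(states))
    for (i in seq_along(states)) {
      s <- states[[i]]
      a <- if (swap) s$bank2 else s$bank1
      bb <- if (swap) s$bank1 else s$bank2
      cps[[i]] <- controlPoint(i - 1L, s$gantry, a, bb,
        jawX = sort(s$jawX), jawY = sort(s$jawY), cumWeight = weights[i])
    }

    arcs[[length(arcs) + 1L]] <- arcBeam(mach, cps, beamMU = mu,
      rotation = rotation, collimatorAngle = collim,
      constraints = constraints)
    log[[length(log) + 1L]] <- list(beamNumber = beamNum,
      machine = mach@name, bankSwapped = swap, nCP = length(cps), mu = mu)
  }

  if (length(arcs) == 0L)
    stop("no arc beams (>1 control point, non-zero meterset) found in ", path)
  lbl <- ds[[.TAG$planLabel]]
  plan <- rtPlan(if (is.null(lbl)) basename(path) else lbl, arcs)
  attr(plan, "parseLog") <- log
  plan
}

.matchMachine <- function(boundariesCm, registry, tol = 1e-4) {
  for (m in registry) {
    if (length(boundariesCm) == m@nPairs + 1L &&
        max(abs(boundariesCm - m@leafBoundaries)) < tol)
      return(m)
  }
  NULL
}

#' Write a plan as a DICOM RT Plan
#'
#' Emits an explicit-VR little-endian RT Plan readable by [readRTPlan()]:
#' beam sequence with jaw and MLCX devices and leaf boundaries, control-point
#' sequence with gantry angle, jaw/MLC positions and cumulative meterset
#' weights, and a fraction group carrying each beam's meterset. Positions are
#' written in mm (DICOM convention) from the plan's cm values.
#'
#' @param plan a valid [RTPlan-class]; invariant violations abort the write.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRTPlan <- function(plan, path) {
  validObject(plan, complete = TRUE)
  for (a in plan@arcs) {
    validObject(a)
    for (cp in a@cps) validObject(cp)
  }

  beamItems <- list()
  refItems <- list()
  for (bi in seq_along(plan@arcs)) {
    arc <- plan@arcs[[bi]]
    m <- arc@machine
    bldItems <- list(
      c(.dcmStrElem(0x300A, 0x00B8, "CS", "ASYMX"),
        .dcmIS(0x300A, 0x00BC, 1L)),
      c(.dcmStrElem(0x300A, 0x00B8, "CS", "ASYMY"),
        .dcmIS(0x300A, 0x00BC, 1L)),
      c(.dcmStrElem(0x300A, 0x00B8, "CS", "MLCX"),
        .dcmIS(0x300A, 0x00BC, m@nPairs),
        .dcmDS(0x300A, 0x00BE, m@leafBoundaries * 10))
    )
    cpItems <- lapply(arc@cps, function(cp) {
      posItems <- list(
        c(.dcmStrElem(0x300A, 0x00B8, "CS", "ASYMX"),
          .dcmDS(0x300A, 0x011C, cp@jawX * 10)),
        c(.dcmStrElem(0x300A, 0x00B8, "CS", "ASYMY"),
          .dcmDS(0x300A, 0x011C, cp@jawY * 10)),
        c(.dcmStrElem(0x300A, 0x00B8, "CS", "MLCX"),
          .dcmDS(0x300A, 0x011C, c(cp@leafA, cp@leafB) * 10))
      )
      c(
        .dcmIS(0x300A, 0x0112, cp@index),
        .dcmDS(0x300A, 0x011E, cp@gantryAngle),
        .dcmStrElem(0x300A, 0x011F, "CS",
          if (arc@rotation == "CW") "CW" else "CC"),
        .dcmDS(0x300A, 0x0120, arc@collimatorAngle),
        .dcmSeq(0x300A, 0x011A, posItems),
        .dcmDS(0x300A, 0x0134, cp@cumWeight)
      )
    })
    beamItems[[bi]] <- c(
      .dcmIS(0x300A, 0x00C0, bi),
      .dcmStrElem(0x300A, 0x00C2, "LO", sprintf("Arc%d", bi)),
      .dcmStrElem(0x300A, 0x00C4, "CS", "DYNAMIC"),
      .dcmStrElem(0x300A, 0x00CE, "CS", "TREATMENT"),
      .dcmSeq(0x300A, 0x00B6, bldItems),
      .dcmDS(0x300A, 0x010E, 1),
      .dcmIS(0x300A, 0x0110, length(arc@cps)),
      .dcmSeq(0x300A, 0x0111, cpItems)
    )
    refItems[[bi]] <- c(
      .dcmDS(0x300A, 0x0086, arc@beamMU),
      .dcmIS(0x300C, 0x0006, bi)
    )
  }
  fgItem <- c(
    .dcmIS(0x300A, 0x0071, 1L),
    .dcmIS(0x300A, 0x0078, 1L),
    .dcmIS(0x300A, 0x0080, length(plan@arcs)),
    .dcmSeq(0x300C, 0x0004, refItems)
  )

  uid <- .newUID()
  body <- c(
    .dcmStrElem(0x0008, 0x0016, "UI", .SOP_RTPLAN),
    .dcmStrElem(0x0008, 0x0018, "UI", uid),
    .dcmStrElem(0x0008, 0x0060, "CS", "RTPLAN"),
    .dcmStrElem(0x300A, 0x0002, "SH", substr(plan@planID, 1, 16)),
    .dcmSeq(0x300A, 0x0070, list(fgItem)),
    .dcmSeq(0x300A, 0x00B0, beamItems)
  )
  writeBin(c(.dcmFileMeta(uid), body), path)
  invisible(path)
}

#' Per-segment monitor units of an arc
#'
#' Segment \eqn{i} spans control points \eqn{i} and \eqn{i+1}; its MU is the
#' cumulative-weight difference times the beam MU. The values telescope to
#' the beam MU.
#'
#' @param arc an [ArcBeam-class].
#' @return Numeric vector of length (number of control points − 1), MU.
#' @examples
#' p <- unmodulatedFixture(elektaMLCi(), nCP = 5)
#' segmentMU(arcs(p)[[1]]) # four equal segments
#' @export
segmentMU <- function(arc) {
  stopifnot(is(arc, "ArcBeam"))
  w <- vapply(arc@cps, slot, numeric(1), "cumWeight")
  diff(w) * arc@beamMU
}
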