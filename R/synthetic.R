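#' Configuration for the synthetic arc-plan generator
#'
#' Describes one synthetic plan: the machine geometry, the arc layout (two
#' full arcs at 2 degree control-point spacing, or two 40 degree partial
#' arcs), the elliptical target aperture the leaves conform to, the leaf
#' perturbation amplitude that injects modulation, and the MU profile.
#'
#' @param machine an [MLCModel-class].
#' @param arcLayout \code{"full_dual"} (CW 181 to 179 deg and CCW back) or
#'   \code{"partial_dual"} (CW 296-336 and 104-144 deg).
#' @param gantrySpacing control-point spacing, deg; default 2.
#' @param semiAxes length-2 numeric, ellipse semi-axes (x, y) in cm.
#'   Defaults: 4 x 5 cm for full arcs, 5.5 x 6 cm for partial arcs
#'   (aperture areas in the range reported for head-and-neck and breast
#'   arcs respectively).
#' @param center length-2 aperture center offset (x, y), cm.
#' @param modulationAmplitude SD of the zero-mean Gaussian leaf perturbation,
#'   cm; 0 gives an unmodulated (conformal) plan.
#' @param muTotal total plan MU, split equally between the two arcs.
#'   Defaults: 800 MU for full arcs, 420 MU for partial arcs.
#' @param muProfile \code{"uniform"} or \code{"random-dirichlet"} segment MU
#'   weights.
#' @param seed integer seed; generation is deterministic given the config.
#' @return A list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(machine = millennium120(),
                            arcLayout = c("full_dual", "partial_dual"),
                            gantrySpacing = 2,
                            semiAxes = NULL, center = c(0, 0),
                            modulationAmplitude = 0.5,
                            muTotal = NULL,
                            muProfile = c("uniform", "random-dirichlet"),
                            seed = 1L) {
  arcLayout <- match.arg(arcLayout)
  muProfile <- match.arg(muProfile)
  if (is.null(semiAxes))
    semiAxes <- if (arcLayout == "full_dual") c(4, 5) else c(5.5, 6)
  if (is.null(muTotal))
    muTotal <- if (arcLayout == "full_dual") 800 else 420
  stopifnot(modulationAmplitude >= 0, gantrySpacing > 0,
    all(semiAxes > 0), muTotal > 0)
  structure(list(
    machine = machine, arcLayout = arcLayout, gantrySpacing = gantrySpacing,
    semiAxes = semiAxes, center = center,
    modulationAmplitude = modulationAmplitude,
    muTotal = muTotal, muProfile = muProfile, seed = as.integer(seed)
  ), class = "GeneratorConfig")
}

# gantry angle ladders for the two layouts, deg in [0, 360)
.arcAngles <- function(arcLayout, spacing) {
  if (arcLayout == "full_dual") {
    span <- 358 # 181 CW around through 0 to 179
    nSeg <- ceiling(span / spacing)
    cw <- (181 + spacing * seq(0, nSeg)) %% 360
    cw[length(cw)] <- 179
    list(list(angles = cw, rotation = "CW", collimator = 15),
      list(angles = rev(cw), rotation = "CCW", collimator = 345))
  } else {
    n1 <- ceiling(40 / spacing)
    a1 <- pmin(296 + spacing * seq(0, n1), 336)
    a2 <- pmin(104 + spacing * seq(0, n1), 144)
    list(list(angles = a1, rotation = "CW", collimator = 5),
      list(angles = a2, rotation = "CW", collimator = 10))
  }
}

# leaf openings conforming the machine's pair strips to an ellipse: the
# half-chord at each pair's y-midpoint; strips missing the ellipse are closed
.ellipseChords <- function(machine, semiAxes, center) {
  b <- machine@leafBoundaries
  yMid <- (b[-length(b)] + b[-1]) / 2
  u <- (yMid - center[2]) / semiAxes[2]
  half <- ifelse(abs(u) < 1, semiAxes[1] * sqrt(pmax(0, 1 - u^2)), NA_real_)
  list(a = ifelse(is.na(half), center[1], center[1] - half),
    b = ifelse(is.na(half), center[1], center[1] + half),
    open = !is.na(half))
}

.cumWeights <- function(nCP, muProfile) {
  if (muProfile == "uniform") {
    seq(0, 1, length.out = nCP)
  } else {
    g <- stats::rgamma(nCP - 1L, shape = 1)
    cumsum(c(0, g / sum(g)))
  }
}

#' Generate a synthetic arc plan
#'
#' Builds a two-arc plan on the configured machine: at every control point
#' the leaves conform to the projected target ellipse (per-pair opening from
#' the chord at the pair's y-midpoint), then independent zero-mean Gaussian
#' perturbations of SD \code{modulationAmplitude} are added to every leaf,
#' clipped to the machine overtravel; pairs whose perturbed positions cross
#' are collapsed to their midpoint so the gap invariant holds. Jaws enclose
#' the open pairs. Generation is deterministic given the config (one seeded
#' generator, no global state is left disturbed).
#'
#' @param config a [generatorConfig()].
#' @return An [RTPlan-class] with two arcs.
#' @examples
#' p <- generatePlan(generatorConfig(modulationAmplitude = 0, seed = 7))
#' mcsArc(arcs(p)[[1]]) < 1 # conformed ellipse still varies across pairs
#' @export
generatePlan <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  m <- config$machine
  chords <- .ellipseChords(m, config$semiAxes, config$center)
  if (!any(chords$open))
    stop("target ellipse does not intersect any leaf pair")
  if (config$semiAxes[1] + abs(config$center[1]) > m@overtravel +
      sum(m@leafWidths) / 2 || config$semiAxes[2] + abs(config$center[2]) >
      sum(m@leafWidths) / 2)
    stop("target ellipse larger than the machine field")

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(config$seed)

  jawY <- range(m@leafBoundaries[c(which(chords$open),
    max(which(chords$open)) + 1L)])
  arcsOut <- list()
  layouts <- .arcAngles(config$arcLayout, config$gantrySpacing)
  for (li in seq_along(layouts)) {
    lay <- layouts[[li]]
    nCP <- length(lay$angles)
    w <- .cumWeights(nCP, config$muProfile)
    cps <- vector("list", nCP)
    for (i in seq_len(nCP)) {
      a <- chords$a
      bb <- chords$b
      if (config$modulationAmplitude > 0) {
        a <- a + stats::rnorm(m@nPairs, 0, config$modulationAmplitude)
        bb <- bb + stats::rnorm(m@nPairs, 0, config$modulationAmplitude)
        # closed pairs stay closed; open pairs keep a non-negative gap
        a[!chords$open] <- chords$a[!chords$open]
        bb[!chords$open] <- chords$b[!chords$open]
        crossed <- bb < a
        mid <- (a + bb) / 2
        a[crossed] <- mid[crossed]
        bb[crossed] <- mid[crossed]
        fieldHalf <- sum(m@leafWidths) / 2
        a <- pmax(pmin(a, m@overtravel), -fieldHalf)
        bb <- pmin(pmax(bb, -m@overtravel), fieldHalf)
        bb <- pmax(bb, a)
      }
      jawX <- range(c(a, bb)) + c(-0.5, 0.5)
      cps[[i]] <- controlPoint(i - 1L, lay$angles[i], a, bb,
        jawX = jawX, jawY = jawY, cumWeight = w[i])
    }
    arcsOut[[li]] <- arcBeam(m, cps, beamMU = config$muTotal / 2,
      rotation = lay$rotation, collimatorAngle = lay$collimator)
  }
  rtPlan(sprintf("synth-%s-%s-seed%d", m@name, config$arcLayout,
    config$seed), arcsOut)
}

#' Unmodulated rectangular-aperture fixture
#'
#' One full arc with a constant rectangular 10 x 10 cm aperture and uniform
#' cumulative weights: the textbook "no modulation" case whose MCS is
#' exactly 1 on any machine.
#'
#' @param machine an [MLCModel-class].
#' @param nCP number of control points; default 180 (2 deg spacing over a
#'   full arc).
#' @param fieldSize side length of the square aperture, cm.
#' @param beamMU total MU.
#' @return An [RTPlan-class] with one arc.
#' @examples
#' mcsArc(arcs(unmodulatedFixture(millennium120()))[[1]]) # 1
#' @export
unmodulatedFixture <- function(machine, nCP = 180L, fieldSize = 10,
                               beamMU = 400) {
  half <- fieldSize / 2
  b <- machine@leafBoundaries
  lo <- b[-length(b)]
  hi <- b[-1]
  open <- lo < half & hi > -half
  a <- ifelse(open, -half, 0)
  bb <- ifelse(open, half, 0)
  angles <- (181 + seq(0, nCP - 1L) * (358 / (nCP - 1L))) %% 360
  w <- seq(0, 1, length.out = nCP)
  cps <- lapply(seq_len(nCP), function(i) {
    controlPoint(i - 1L, angles[i], a, bb,
      jawX = c(-half - 0.5, half + 0.5), jawY = c(-half, half),
      cumWeight = w[i])
  })
  rtPlan(sprintf("unmod-%s", machine@name),
    list(arcBeam(machine, cps, beamMU = beamMU, rotation = "CW")))
}

#' Paired two-machine cohort fixture
#'
#' Emulates a paired study design: \code{nPlans} target shapes are drawn
#' once (jittered ellipse semi-axes, modulation amplitude, MU), and each is
#' realized on both machine geometries, so plan \code{i} of the two lists
#' shares its target and MU but differs in leaf discretization. Plan ids
#' match across the lists.
#'
#' @param nPlans number of paired plans (>= 2).
#' @param machineA,machineB the two [MLCModel-class] geometries.
#' @param seed integer seed.
#' @param arcLayout forwarded to [generatorConfig()].
#' @param modulationAmplitude baseline perturbation SD, cm; per-plan
#'   amplitudes are jittered around it.
#' @return List with elements \code{a} and \code{b}, each a list of
#'   [RTPlan-class] with matching ids.
#' @export
pairedCohortFixture <- function(nPlans, machineA = millennium120(),
                                machineB = elektaMLCi(), seed = 1L,
                                arcLayout = "full_dual",
                                modulationAmplitude = 0.5) {
  stopifnot(nPlans >= 2L)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  base <- if (arcLayout == "full_dual") c(4, 5) else c(5.5, 6)
  muBase <- if (arcLayout == "full_dual") 800 else 420
  shapes <- lapply(seq_len(nPlans), function(i) {
    list(
      semiAxes = base * stats::runif(2, 0.85, 1.15),
      amplitude = modulationAmplitude * stats::runif(1, 0.7, 1.3),
      mu = muBase * stats::runif(1, 0.9, 1.1),
      seed = sample.int(.Machine$integer.max %/% 2L, 1L)
    )
  })
  build <- function(machine) {
    lapply(seq_len(nPlans), function(i) {
      s <- shapes[[i]]
      p <- generatePlan(generatorConfig(machine = machine,
        arcLayout = arcLayout, semiAxes = s$semiAxes,
        modulationAmplitude = s$amplitude, muTotal = s$mu,
        muProfile = "random-dirichlet", seed = s$seed))
      p@planID <- sprintf("pair%02d", i)
      p
    })
  }
  list(a = build(machineA), b = build(machineB))
}
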