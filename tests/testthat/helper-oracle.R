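# Deliberately naive per-leaf, per-segment reference implementation of the
# complexity scores, written as explicit double loops so it shares no code
# path with the package's vectorized implementation.

oracleInfield <- function(cp, m, closedGap) {
  idx <- integer(0)
  b <- leafBoundaries(m)
  for (n in seq_len(nPairs(m))) {
    gap <- cp@leafB[n] - cp@leafA[n]
    overlap <- min(b[n + 1], cp@jawY[2]) - max(b[n], cp@jawY[1])
    if (gap > closedGap && overlap > 0) idx <- c(idx, n)
  }
  idx
}

oracleBankFactor <- function(pos) {
  if (length(pos) < 2) return(1)
  pm <- max(pos) - min(pos)
  if (pm <= 0) return(1)
  s <- 0
  for (k in seq_len(length(pos) - 1)) {
    s <- s + (pm - abs(pos[k] - pos[k + 1]))
  }
  s / ((length(pos) - 1) * pm)
}

# per-arc scores: list(sw, sa, lsv, aav, weights, mcs)
oracleArcScores <- function(arc, closedGap = 0.05) {
  m <- machine(arc)
  cps <- controlPoints(arc)
  I <- length(cps)
  sw <- sa <- lsv <- aav <- numeric(I)

  # maximal per-pair opening over the arc, zero for never-open pairs
  everOpen <- rep(FALSE, nPairs(m))
  maxOpen <- numeric(nPairs(m))
  for (n in seq_len(nPairs(m))) {
    bmax <- -Inf; amin <- Inf
    for (cp in cps) {
      if (cp@leafB[n] > bmax) bmax <- cp@leafB[n]
      if (cp@leafA[n] < amin) amin <- cp@leafA[n]
    }
    maxOpen[n] <- max(bmax - amin, 0)
  }
  for (cp in cps) everOpen[oracleInfield(cp, m, closedGap)] <- TRUE
  denom <- 0
  for (n in seq_len(nPairs(m)))
    if (everOpen[n]) denom <- denom + maxOpen[n] * leafWidths(m)[n]

  for (i in seq_len(I)) {
    cp <- cps[[i]]
    idx <- oracleInfield(cp, m, closedGap)
    if (length(idx) > 0) {
      g <- -Inf
      area <- 0
      for (n in idx) {
        gap <- cp@leafB[n] - cp@leafA[n]
        if (gap > g) g <- gap
        area <- area + gap * leafWidths(m)[n]
      }
      sw[i] <- g
      sa[i] <- area
    }
    lsv[i] <- oracleBankFactor(cp@leafB[idx]) * oracleBankFactor(cp@leafA[idx])
    aav[i] <- sa[i] / denom
  }
  w <- numeric(I - 1)
  for (i in seq_len(I - 1)) w[i] <- cps[[i + 1]]@cumWeight - cps[[i]]@cumWeight
  mcs <- 0
  for (i in seq_len(I - 1)) {
    mcs <- mcs + (lsv[i] + lsv[i + 1]) / 2 * (aav[i] + aav[i + 1]) / 2 * w[i]
  }
  list(sw = sw, sa = sa, lsv = lsv, aav = aav, weights = w, mcs = mcs)
}

# brute-force exact two-sided signed-rank p-value: enumerate all 2^n sign
# patterns of the mid-ranked absolute differences
bruteForceSignedRankP <- function(d) {
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- signs %*% r
  pLo <- mean(Ws <= W + 1e-9)
  pHi <- mean(Ws >= W - 1e-9)
  min(1, 2 * min(pLo, pHi))
}

# a compact random arc for property tests: coarse control-point spacing so
# suites stay fast, random machine use left to the caller
randomSyntheticArc <- function(machine, seed, amplitude = NULL) {
  set.seed(seed)
  if (is.null(amplitude)) amplitude <- runif(1, 0, 1)
  cfg <- generatorConfig(
    machine = machine,
    arcLayout = sample(c("full_dual", "partial_dual"), 1),
    gantrySpacing = sample(c(4, 8, 12), 1),
    semiAxes = c(runif(1, 2.5, 6), runif(1, 3, 7)),
    modulationAmplitude = amplitude,
    muProfile = sample(c("uniform", "random-dirichlet"), 1),
    seed = seed
  )
  arcs(generatePlan(cfg))[[sample(1:2, 1)]]
}
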