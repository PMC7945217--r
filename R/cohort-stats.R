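#' Mean and sample standard deviation
#'
#' @param values numeric, at least two values.
#' @return Named numeric: \code{mean}, \code{sd} (n − 1 denominator).
#' @examples
#' summarizeMetric(c(1, 2, 3)) # mean 2, sd 1
#' @export
summarizeMetric <- function(values) {
  if (length(values) < 2L)
    stop("at least two values are needed for a mean/SD summary")
  c(mean = mean(values), sd = stats::sd(values))
}

# exact null distribution of the signed-rank statistic for given ranks:
# counts over doubled rank sums (mid-ranks are half-integers)
.signedRankExactP <- function(W, ranks) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  counts <- numeric(total + 1L) # index k+1 holds #patterns with doubled sum k
  counts[1L] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), counts[seq_len(total + 1L - r)])
    counts <- counts + shifted
  }
  probs <- counts / 2^length(ranks)
  w2 <- round(2 * W)
  pLo <- sum(probs[seq_len(min(w2, total) + 1L)])        # P(W <= w)
  pHi <- sum(probs[(max(w2, 0) + 1L):(total + 1L)])       # P(W >= w)
  min(1, 2 * min(pLo, pHi))
}

.signedRankNormalP <- function(W, ranks) {
  n <- length(ranks)
  mu <- n * (n + 1) / 4
  tie <- table(ranks)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  cc <- sign(W - mu) * 0.5 # continuity correction toward the mean
  z <- (W - mu - cc) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Paired two-sided Wilcoxon signed-rank test
#'
#' Compares paired per-plan (or per-segment) metric values from two delivery
#' systems. Zero differences are dropped before ranking and ties are
#' mid-ranked. For 25 or fewer non-zero differences the p-value comes from
#' the exact permutation distribution of the signed-rank statistic (computed
#' by convolution over sign patterns, valid with mid-ranks); above that a
#' normal approximation with continuity and tie corrections is used.
#'
#' @param valuesA,valuesB equal-length numeric vectors, paired by plan.
#' @param metricName label carried into the output row.
#' @param alpha significance threshold; default 0.05.
#' @return One-row data.frame: \code{metric}, \code{n} (pairs),
#'   \code{meanA}, \code{sdA}, \code{meanB}, \code{sdB}, \code{pValue},
#'   \code{significant}, \code{allZero} (TRUE when every difference is zero,
#'   in which case p = 1 with a warning).
#' @examples
#' wilcoxonPaired(1:7 + 0.5, 1:7, "toy") # all-positive differences, p = 2/128
#' @export
wilcoxonPaired <- function(valuesA, valuesB, metricName = "metric",
                           alpha = 0.05) {
  if (length(valuesA) != length(valuesB))
    stop("paired cohorts must have equal lengths")
  if (length(valuesA) < 2L)
    stop("at least two pairs are required")
  d <- valuesA - valuesB
  nz <- d[d != 0]
  allZero <- length(nz) == 0L
  if (allZero) {
    warning("all paired differences are zero; p-value set to 1")
    p <- 1
  } else {
    ranks <- rank(abs(nz))
    W <- sum(ranks[nz > 0])
    p <- if (length(nz) <= 25L) .signedRankExactP(W, ranks)
    else .signedRankNormalP(W, ranks)
  }
  sa <- summarizeMetric(valuesA)
  sb <- summarizeMetric(valuesB)
  data.frame(
    metric = metricName, n = length(valuesA),
    meanA = sa[["mean"]], sdA = sa[["sd"]],
    meanB = sb[["mean"]], sdB = sb[["sd"]],
    pValue = p, significant = p < alpha, allZero = allZero
  )
}

.planMetricTable <- function(plans, unit, closedGap) {
  rows <- lapply(plans, function(p) {
    rep_ <- scorePlan(p, closedGap = closedGap)
    if (unit == "plan") {
      data.frame(planID = p@planID, MU = rep_@plan$mu, SW = rep_@plan$meanSW,
        SA = rep_@plan$meanSA, LSV = rep_@plan$meanLSV,
        AAV = rep_@plan$meanAAV, MCS = rep_@plan$mcs)
    } else {
      s <- rep_@segments
      data.frame(planID = p@planID, segment = seq_len(nrow(s)),
        MU = s$weight * rep_@arcs$mu[s$arc], SW = s$sw, SA = s$sa,
        LSV = s$lsv, AAV = s$aav, MCS = rep_@plan$mcs)
    }
  })
  do.call(rbind, rows)
}

#' Compare two paired plan cohorts
#'
#' Scores every plan in both cohorts, pairs them by plan identity, and emits
#' one [wilcoxonPaired()] row per metric (MU, SW, SA, LSV, AAV, MCS) with
#' mean/SD summaries for each cohort. With \code{unit = "plan"} each pair
#' contributes its plan-level value; with \code{unit = "segment"} the pooled
#' per-segment values are paired segment-by-segment (cohorts must then have
#' identical segment counts per plan).
#'
#' @param plansA,plansB lists of [RTPlan-class], paired by \code{planID}.
#' @param unit \code{"plan"} or \code{"segment"}.
#' @param closedGap closed-pair threshold forwarded to [scorePlan()].
#' @param alpha significance threshold.
#' @return data.frame with six rows, one per metric.
#' @export
compareCohorts <- function(plansA, plansB, unit = c("plan", "segment"),
                           closedGap = 0.05, alpha = 0.05) {
  unit <- match.arg(unit)
  idsA <- vapply(plansA, planID, character(1))
  idsB <- vapply(plansB, planID, character(1))
  unpaired <- c(setdiff(idsA, idsB), setdiff(idsB, idsA))
  if (length(unpaired) > 0L)
    stop("unpaired plan ids: ", paste(unique(unpaired), collapse = ", "))
  if (anyDuplicated(idsA) || anyDuplicated(idsB))
    stop("plan ids must be unique within each cohort")
  plansB <- plansB[match(idsA, idsB)]

  tabA <- .planMetricTable(plansA, unit, closedGap)
  tabB <- .planMetricTable(plansB, unit, closedGap)
  if (nrow(tabA) != nrow(tabB))
    stop("segment-level pairing requires identical segment counts; got ",
      nrow(tabA), " vs ", nrow(tabB))

  metrics <- c("MU", "SW", "SA", "LSV", "AAV", "MCS")
  rows <- lapply(metrics, function(m) {
    wilcoxonPaired(tabA[[m]], tabB[[m]], metricName = m, alpha = alpha)
  })
  out <- do.call(rbind, rows)
  attr(out, "unit") <- unit
  out
}
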