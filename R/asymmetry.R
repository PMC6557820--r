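# N-/C-terminal thread asymmetry and chirality statistics on weighted
# (effectively counted) entangled loops.

#' Weighted N/C thread-side fractions
#'
#' Fractions of N- and C-terminal threads among weighted loops, with a
#' binomial standard error on the effective count (the sum of clustering
#' weights) and the significance of the deviation from 1/2 in standard
#' deviations.
#'
#' @param loops loop table with \code{side} and \code{weight} columns
#'   (typically from \code{\link{clusterEnsemble}}).
#' @return list with \code{fracN}, \code{fracC}, \code{stderr},
#'   \code{nEff} and \code{zHalf} (one-sided z of fracN vs 0.5).
#' @export
sideFractions <- function(loops) {
  ok <- !is.na(loops$side)
  w <- loops$weight[ok]
  nEff <- sum(w)
  if (nEff <= 0)
    return(list(fracN = NA_real_, fracC = NA_real_, stderr = NA_real_,
                nEff = 0, zHalf = NA_real_))
  fracN <- sum(w[loops$side[ok] == "N"]) / nEff
  fracC <- 1 - fracN
  se <- sqrt(fracN * fracC / nEff)
  list(fracN = fracN, fracC = fracC, stderr = se, nEff = nEff,
       zHalf = (fracN - 0.5) / se)
}

# admissible thread-segment counts on each side of a loop: contiguous
# [j1, j2] with j2 - j1 >= m0, separated from the loop by >= smin.
.sideSegmentCounts <- function(i1, i2, n, m0 = 10L, smin = 1L) {
  tri <- function(k) ifelse(k > 0, k * (k + 1) / 2, 0)
  c(N = tri(i1 - smin - m0), C = tri(n - i2 - smin - m0 + 1))
}

#' Random-reference thread side for loops
#'
#' For each loop, draws one putative thread uniformly over all contiguous
#' segments of length >= \code{m0} that do not overlap the loop (on either
#' side, separation >= \code{smin}) and returns its side.  The uniform
#' measure is computed by exact enumeration of admissible segments, not
#' by rejection.  Loops with no admissible segment return NA.
#'
#' @param loops loop table with columns \code{i1,i2,n} (chain length).
#' @param m0 minimum thread length.
#' @param smin minimum loop-thread separation.
#' @param seed integer seed.
#' @return character vector of \code{"N"}/\code{"C"} (NA if infeasible).
#' @export
randomReferenceSide <- function(loops, m0 = 10L, smin = 1L, seed = 1L) {
  rng <- .localRNG(seed)
  vapply(seq_len(nrow(loops)), function(k) {
    cnt <- .sideSegmentCounts(loops$i1[k], loops$i2[k], loops$n[k],
                              m0 = m0, smin = smin)
    tot <- sum(cnt)
    if (tot == 0) return(NA_character_)
    if (rng$runif(1L) * tot < cnt["N"]) "N" else "C"
  }, character(1))
}

#' Exact side probabilities of the random reference
#'
#' @inheritParams randomReferenceSide
#' @return two-column matrix of P(N), P(C) per loop (NaN if infeasible).
#' @export
referenceSideProbs <- function(loops, m0 = 10L, smin = 1L) {
  t(vapply(seq_len(nrow(loops)), function(k) {
    cnt <- .sideSegmentCounts(loops$i1[k], loops$i2[k], loops$n[k],
                              m0 = m0, smin = smin)
    cnt / sum(cnt)
  }, numeric(2)))
}

#' Weighted separation distribution
#'
#' Normalized weighted histogram of the loop-thread sequence separation
#' \code{s} (bin width 1), with per-bin binomial error bars on the
#' effective count.
#'
#' @param loops loop table with \code{s}, \code{weight} and \code{side}.
#' @param side optional side filter (\code{"N"} or \code{"C"}).
#' @return list with \code{s} (bin centers), \code{freq} (sums to 1),
#'   \code{err}, \code{nEff}, and the raw weighted sample
#'   (\code{values}, \code{weights}) for downstream tests.
#' @export
separationDistribution <- function(loops, side = NULL) {
  keep <- !is.na(loops$s)
  if (!is.null(side)) keep <- keep & loops$side %in% side
  v <- loops$s[keep]; w <- loops$weight[keep]
  if (length(v) == 0L)
    return(list(s = integer(0), freq = numeric(0), err = numeric(0),
                nEff = 0, values = integer(0), weights = numeric(0)))
  nEff <- sum(w)
  agg <- tapply(w, factor(v, levels = sort(unique(v))), sum)
  freq <- as.numeric(agg) / nEff
  list(s = as.integer(names(agg)), freq = freq,
       err = sqrt(pmax(freq * (1 - freq), 0) / nEff), nEff = nEff,
       values = v, weights = w)
}

# Kolmogorov asymptotic survival function Q(lambda).
.qKolmogorov <- function(lambda) {
  if (lambda < 1e-8) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

#' Two-sample comparison of weighted distributions
#'
#' Weighted two-sample Kolmogorov-Smirnov test.  The default method
#' evaluates the maximum distance between the weighted empirical CDFs and
#' the asymptotic Kolmogorov p-value at the effective sample sizes
#' (sums of weights); \code{method = "resample"} instead draws
#' \code{round(nEff)} unweighted observations per sample proportionally
#' to the weights and applies \code{stats::ks.test}.
#'
#' @param h1,h2 weighted samples: outputs of
#'   \code{\link{separationDistribution}} or lists with \code{values} and
#'   \code{weights}.
#' @param method \code{"asymptotic"} (deterministic) or \code{"resample"}.
#' @param seed seed for the resampling method.
#' @return list with \code{statistic} (D), \code{p.value}, \code{nEff1},
#'   \code{nEff2}.
#' @export
compareDistributions <- function(h1, h2,
                                 method = c("asymptotic", "resample"),
                                 seed = 1L) {
  method <- match.arg(method)
  v1 <- h1$values; w1 <- h1$weights
  v2 <- h2$values; w2 <- h2$weights
  if (length(v1) == 0L || length(v2) == 0L)
    stop("both samples must be non-empty")
  n1 <- sum(w1); n2 <- sum(w2)
  if (method == "resample") {
    rng <- .localRNG(seed)
    r1 <- v1[rng$sampleInt(length(v1), max(1L, round(n1)), replace = TRUE,
                           prob = w1)]
    r2 <- v2[rng$sampleInt(length(v2), max(1L, round(n2)), replace = TRUE,
                           prob = w2)]
    kt <- suppressWarnings(stats::ks.test(r1, r2))
    return(list(statistic = unname(kt$statistic),
                p.value = kt$p.value, nEff1 = n1, nEff2 = n2))
  }
  grid <- sort(unique(c(v1, v2)))
  # step CDFs on the pooled support, ties merged
  stepCdf <- function(v, w) {
    agg <- tapply(w, factor(v, levels = grid), sum)
    agg[is.na(agg)] <- 0
    cumsum(as.numeric(agg)) / sum(w)
  }
  D <- max(abs(stepCdf(v1, w1) - stepCdf(v2, w2)))
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  list(statistic = D, p.value = .qKolmogorov(lambda), nEff1 = n1,
       nEff2 = n2)
}

#' Weighted chirality bias
#'
#' Weighted fraction of positive-score (right-handed) entangled loops,
#' overall and/or restricted to one thread side.
#'
#' @param loops weighted entangled loop table.
#' @param side optional \code{"N"} or \code{"C"} filter.
#' @return list with \code{fracPositive}, \code{stderr}, \code{nEff}.
#' @export
chiralityBias <- function(loops, side = NULL) {
  keep <- !is.na(loops$g)
  if (!is.null(side)) keep <- keep & loops$side %in% side
  w <- loops$weight[keep]
  nEff <- sum(w)
  if (nEff <= 0)
    return(list(fracPositive = NA_real_, stderr = NA_real_, nEff = 0))
  f <- sum(w[loops$g[keep] > 0]) / nEff
  list(fracPositive = f, stderr = sqrt(pmax(f * (1 - f), 0) / nEff),
       nEff = nEff)
}
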