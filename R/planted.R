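# Sequence-labeled synthetic ensembles with planted contact statistics.
#
# Each structure concatenates helix-wrap units (each contributing exactly
# one entangled contact-closed loop) and hairpin units (each contributing
# exactly one non-entangled loop-closing contact), joined by linkers
# routed through a clearance corridor below the units so no unintended
# contact at sequence separation >= 10 arises.  Labels are drawn so the
# loop-closing contacts of entangled loops follow a planted pair
# distribution whose ratio to the overall contact distribution is the
# enrichment factor: the ground truth for dE_enr is -tau log(factor).

# hairpin unit: two strands splaying from 4 A (closure) to sepTop,
# closed between its first and last residue only.
.hairpinUnit <- function(H = 22, sepTop = 12, gap = 4.0, step = 3.8) {
  pts <- rbind(c(0, 0, 0))
  pts <- rbind(pts, .segPoints(pts[nrow(pts), ], c(0, 0, H), step))
  pts <- rbind(pts, .segPoints(pts[nrow(pts), ], c(sepTop / 2, 0, H + 5),
                               step))
  pts <- rbind(pts, .segPoints(pts[nrow(pts), ], c(sepTop, 0, H), step))
  pts <- rbind(pts, .segPoints(pts[nrow(pts), ], c(gap, 0, 0), step))
  list(points = pts, closure = c(1L, nrow(pts)))
}

# assemble unit point sets into one chain with corridor linkers
.assembleUnits <- function(units, spacing = 40, step = 3.8) {
  zc <- min(vapply(units, function(u) min(u$points[, 3]), 0)) - 8
  pts <- NULL
  unitOf <- integer()
  closures <- list()
  for (k in seq_along(units)) {
    u <- units[[k]]
    up <- u$points
    up[, 1] <- up[, 1] + (k - 1) * spacing
    if (is.null(pts)) {
      beforeEntry <- 0L
      pts <- up
      unitOf <- rep(k, nrow(up))
    } else {
      # linker: sideways exit, drop to the corridor, traverse, rise;
      # the final linker point is the unit entry itself
      last <- pts[nrow(pts), ]
      entry <- up[1L, ]
      exitPt <- last + c(2, 6, 0)
      dropPt <- c(exitPt[1], exitPt[2], zc)
      risePt <- c(entry[1], entry[2], zc)
      link <- rbind(.segPoints(last, exitPt, step),
                    .segPoints(exitPt, dropPt, step),
                    .segPoints(dropPt, risePt, step),
                    .segPoints(risePt, entry, step))
      beforeEntry <- nrow(pts) + nrow(link) - 1L
      pts <- rbind(pts, link, up[-1L, , drop = FALSE])
      unitOf <- c(unitOf, rep(0L, nrow(link) - 1L), rep(k, nrow(up)))
    }
    closures[[k]] <- beforeEntry + u$closure
  }
  list(points = pts, unitOf = unitOf, closures = closures)
}

# planted pair-probability vectors (210-long, canonical order)
.basePairProbs <- function(baseFreq) {
  p <- numeric(.NPAIR)
  for (a in seq_len(.NAA)) for (b in a:.NAA) {
    p[.pairIdx(a, b)] <- if (a == b) baseFreq[a]^2 else
      2 * baseFreq[a] * baseFreq[b]
  }
  p / sum(p)
}

.pairKeyIdx <- function(key) {
  aa <- strsplit(key, "")[[1L]]
  i <- match(aa, aminoAcids())
  if (anyNA(i) || length(i) != 2L)
    stop("enrichment keys must be two one-letter amino acids, got ", key)
  .pairIdx(i[1L], i[2L])
}

# apply planted factors exactly: planted entries are multiplied, the
# remaining entries are scaled by a common factor to renormalize, so the
# planted ratio new/old equals the factor exactly.
.applyFactors <- function(p, factors) {
  if (is.null(factors) || length(factors) == 0L) return(p)
  idx <- vapply(names(factors), .pairKeyIdx, 1L)
  out <- p
  out[idx] <- p[idx] * as.numeric(factors)
  planted <- sum(out[idx])
  if (planted >= 1)
    stop("planted probabilities exceed 1; lower the factors")
  rest <- setdiff(seq_along(p), idx)
  out[rest] <- p[rest] * (1 - planted) / sum(p[rest])
  out
}

#' Ensemble with planted contact-composition enrichment
#'
#' Generates \code{nStructures} labeled chains, each hosting
#' \code{nWraps} entangled loops (compact helix wraps, winding 2) and
#' \code{nHairpins} non-entangled loop-closing contacts (hairpins).  The
#' amino-acid pair closing each contact is drawn from planted
#' distributions such that the overall contact composition follows
#' \code{contactFactors} applied to the base-frequency pair distribution,
#' and the entangled-contact composition follows \code{entangledFactors}
#' applied to the contact distribution.  All remaining residues are
#' labeled iid from \code{baseFreq}.  The exact ground truth is
#' \code{dE_enr(pair) = -tau log(entangledFactors[pair])} and
#' \code{E_norm(pair) ~ -tau log(contactFactors[pair])}.
#'
#' @param nStructures number of chains.
#' @param nWraps entangled (wrap) units per chain.
#' @param nHairpins normal (hairpin) units per chain; the entangled
#'   fraction \code{nWraps/(nWraps+nHairpins)} times the largest
#'   entangled factor must stay below 1 for the mixture to be feasible.
#' @param baseFreq amino-acid frequencies (default uniform).
#' @param contactFactors named numeric vector of planted contact
#'   enrichments, names are two-letter pairs (e.g. \code{c(LL = 60)}).
#' @param entangledFactors named numeric vector of planted
#'   entangled-contact enrichments relative to contacts.
#' @param seed integer seed.
#' @param tau score scale used in the reported ground truth.
#' @return list with \code{traces}, \code{groundTruth} (expected
#'   \code{deltaE} 210-vector, planted factor maps, the three planted
#'   pair-probability vectors) and the generator \code{spec}.
#' @export
makePlantedSequenceEnsemble <- function(nStructures, nWraps = 4L,
                                        nHairpins = 10L,
                                        baseFreq = rep(1 / 20, 20),
                                        contactFactors = NULL,
                                        entangledFactors = NULL,
                                        seed = 1L, tau = 100) {
  stopifnot(nStructures >= 1L, nWraps >= 0L, nHairpins >= 0L,
            nWraps + nHairpins >= 1L)
  if (any(baseFreq <= 0)) stop("baseFreq must be positive")
  baseFreq <- baseFreq / sum(baseFreq)
  if (!is.null(entangledFactors) && any(entangledFactors <= 0))
    stop("entangled enrichment factors must be positive")
  if (!is.null(contactFactors) && any(contactFactors <= 0))
    stop("contact enrichment factors must be positive")
  pBase <- .basePairProbs(baseFreq)
  pC <- .applyFactors(pBase, contactFactors)
  pG <- .applyFactors(pC, entangledFactors)
  rho <- nWraps / (nWraps + nHairpins)
  qH <- (pC - rho * pG) / (1 - rho)
  if (min(qH) < -1e-12)
    stop("infeasible mixture: entangled fraction times factor exceeds 1; ",
         "reduce nWraps/(nWraps+nHairpins) or the factors")
  qH <- pmax(qH, 0); qH <- qH / sum(qH)
  rng <- .localRNG(seed)
  # spread the wraps evenly among the hairpins, deterministically
  nU <- nWraps + nHairpins
  units <- rep("H", nU)
  if (nWraps > 0L)
    units[unique(round(seq(1, nU, length.out = nWraps)))] <- "W"
  nWrapsEff <- sum(units == "W")
  if (nWrapsEff != nWraps) {  # rounding collisions: fill from the left
    units <- rep("H", nU)
    units[seq_len(nWraps)] <- "W"
  }
  pairLetters <- function(idx) {
    # invert canonical pair index
    for (a in seq_len(.NAA)) {
      lo <- .pairIdx(a, a); hi <- .pairIdx(a, .NAA)
      if (idx >= lo && idx <= hi) return(c(a, a + (idx - lo)))
    }
    stop("bad pair index")
  }
  traces <- vector("list", nStructures)
  for (sNo in seq_len(nStructures)) {
    built <- .assembleUnits(lapply(units, function(u)
      if (u == "W") .wrapUnit(2L, Rh = 5.5, pitch = 5, margin = 8,
                              gap = 4.0)
      else .hairpinUnit()))
    pts <- built$points
    n <- nrow(pts)
    pts <- pts + rng$rnorm(3L * n, sd = 0.05)
    labIdx <- rng$sampleInt(.NAA, n, replace = TRUE, prob = baseFreq)
    for (k in seq_along(units)) {
      dist <- if (units[k] == "W") pG else qH
      pair <- pairLetters(rng$sampleInt(.NPAIR, 1L, prob = dist))
      if (rng$runif(1L) < 0.5) pair <- rev(pair)
      cl <- built$closures[[k]]
      labIdx[cl[1L]] <- pair[1L]
      labIdx[cl[2L]] <- pair[2L]
    }
    traces[[sNo]] <- ChainTrace(
      pts, id = sprintf("planted_%05d", sNo),
      residues = aminoAcids()[labIdx],
      meta = list(units = units, closures = built$closures,
                  unitOf = built$unitOf, seed = seed))
  }
  deltaE <- rep(0, .NPAIR)
  ok <- pC > 0 & pG > 0
  deltaE[ok] <- -tau * log(pG[ok] / pC[ok])
  deltaE[!ok] <- NA_real_
  list(traces = traces,
       groundTruth = list(deltaE = deltaE, pBase = pBase, pC = pC,
                          pG = pG, qH = qH,
                          entangledFactors = entangledFactors,
                          contactFactors = contactFactors, tau = tau),
       spec = list(nStructures = nStructures, nWraps = nWraps,
                   nHairpins = nHairpins, seed = seed))
}
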