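# Knowledge-based contact potentials for normal and entangled contacts.
#
# Frequencies are compared within three pair universes sharing the same
# m0 >= 10 sequence-separation filter: all generic residue pairs (N,
# N(a,b)), side-chain contacts (Nc, Nc(a,b)) and the loop-closing
# contacts of entangled loops (NcG, NcG(a,b)).  Scores are
#   E_norm = -tau log(f_c / f),  E_GE = -tau log(f_c^G / f),
#   dE_enr = -tau log(f_c^G / f_c) = E_GE - E_norm,
# with tau = 100.  Counting is over unordered pairs (each counted once,
# homo-pairs once); the convention cancels in every frequency ratio.
# Uncertainties come from bootstrap resampling of whole proteins.

.NAA <- 20L
.NPAIR <- 210L

# canonical index of the unordered amino-acid pair (a, b), 1-based
.pairIdx <- function(a, b) {
  lo <- pmin(a, b); hi <- pmax(a, b)
  as.integer((lo - 1L) * .NAA - (lo - 1L) * lo / 2L + hi)
}

# fold a 210-vector into a symmetric 20x20 matrix
.pairVecToMatrix <- function(v) {
  m <- matrix(NA_real_, .NAA, .NAA, dimnames = list(aminoAcids(),
                                                    aminoAcids()))
  k <- 0L
  for (a in seq_len(.NAA)) for (b in a:.NAA) {
    k <- k + 1L
    m[a, b] <- v[k]; m[b, a] <- v[k]
  }
  m
}

.aaIndex <- function(labels) match(labels, aminoAcids())

#' Generic residue-pair counts of one trace
#'
#' Counts every unordered residue pair with sequence separation
#' \code{>= m0} by amino-acid type.  Residues with unknown labels are
#' excluded from counting.
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @param m0 minimum sequence separation.
#' @return integer vector of length 210 (canonical pair order).
#' @export
countPairs <- function(trace, m0 = 10L) {
  idx <- .aaIndex(residues(trace))
  n <- length(idx)
  out <- numeric(.NPAIR)
  if (n <= m0) return(out)
  ind <- matrix(0, n, .NAA)
  ok <- !is.na(idx)
  ind[cbind(which(ok), idx[ok])] <- 1
  # S[i, b] = number of residues of type b at positions >= i
  S <- apply(ind[n:1, , drop = FALSE], 2L, cumsum)[n:1, , drop = FALSE]
  M <- t(ind[seq_len(n - m0), , drop = FALSE]) %*%
    S[(m0 + 1L):n, , drop = FALSE]
  for (a in seq_len(.NAA)) for (b in seq_len(.NAA)) {
    if (M[a, b] > 0) {
      k <- .pairIdx(a, b)
      out[k] <- out[k] + M[a, b]
    }
  }
  out
}

# fold a list of residue index pairs into 210-vector counts by label
.countLabeledPairs <- function(idx, pairs) {
  out <- numeric(.NPAIR)
  if (is.null(pairs) || nrow(pairs) == 0L) return(out)
  a <- idx[pairs[, 1L]]; b <- idx[pairs[, 2L]]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(out)
  tab <- table(.pairIdx(a[ok], b[ok]))
  out[as.integer(names(tab))] <- as.numeric(tab)
  out
}

#' Side-chain contact counts of one trace
#'
#' Counts unordered side-chain heavy-atom contacts (min atom distance
#' \code{<= cutoff}) at sequence separation \code{>= m0}, by amino-acid
#' pair.  Residues without side-chain atoms fall back to all heavy atoms.
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @param cutoff contact distance (Angstrom).
#' @param m0 minimum sequence separation.
#' @param mode contact definition (see \code{\link{computeContacts}}).
#' @return list with \code{counts} (210-vector) and \code{pairs}
#'   (residue index pairs).
#' @export
countContacts <- function(trace, cutoff = 4.5, m0 = 10L,
                          mode = "sidechain_heavy") {
  pairs <- computeContacts(trace, cutoff = cutoff, mode = mode,
                           minsep = as.integer(m0))
  list(counts = .countLabeledPairs(.aaIndex(residues(trace)), pairs),
       pairs = pairs)
}

#' Entangled-contact counts of one trace
#'
#' Counts the loop-closing contacts of entangled loops (|G'c(i)| >= 1)
#' by amino-acid pair.  When \code{contactPairs} is supplied (the
#' potential-mode contact list), closures absent from it are dropped,
#' mirroring the requirement that an entangled contact must also qualify
#' as a potential-counting contact.
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @param loops loop table of this trace (from \code{\link{scanLoops}}).
#' @param contactPairs optional residue pair matrix to intersect with.
#' @return 210-vector of counts.
#' @export
countEntangledContacts <- function(trace, loops, contactPairs = NULL) {
  ent <- loops[!is.na(loops$g) & abs(loops$g) >= 1, , drop = FALSE]
  if (nrow(ent) == 0L) return(numeric(.NPAIR))
  pairs <- unique(cbind(ent$i1, ent$i2))
  if (!is.null(contactPairs) && nrow(contactPairs) > 0L) {
    key <- paste(pairs[, 1L], pairs[, 2L])
    keyC <- paste(contactPairs[, 1L], contactPairs[, 2L])
    pairs <- pairs[key %in% keyC, , drop = FALSE]
  }
  .countLabeledPairs(.aaIndex(residues(trace)), pairs)
}

# per-protein count triples for an ensemble
.ensembleCounts <- function(traces, loopTables, m0 = 10L, cutoff = 4.5,
                            contactMode = "sidechain_heavy",
                            requireContactMode = TRUE) {
  np <- length(traces)
  gen <- matrix(0, np, .NPAIR)
  con <- matrix(0, np, .NPAIR)
  ent <- matrix(0, np, .NPAIR)
  for (k in seq_len(np)) {
    tr <- traces[[k]]
    gen[k, ] <- countPairs(tr, m0 = m0)
    cc <- countContacts(tr, cutoff = cutoff, m0 = m0, mode = contactMode)
    con[k, ] <- cc$counts
    ent[k, ] <- countEntangledContacts(
      tr, loopTables[[k]],
      contactPairs = if (requireContactMode) cc$pairs else NULL)
  }
  list(gen = gen, con = con, ent = ent)
}

.scoreFromCounts <- function(num, den, tau) {
  fx <- num / sum(num)
  f <- den / sum(den)
  out <- rep(NA_real_, length(num))
  ok <- num > 0 & den > 0
  out[ok] <- -tau * log(fx[ok] / f[ok])
  out
}

#' Potential matrix from two count vectors
#'
#' The log-odds score \code{-tau * log(fx / fref)} comparing pair
#' frequencies within a focal universe (e.g. contacts) against a
#' reference universe (e.g. all generic pairs).  Entries with zero focal
#' or reference counts are undefined (NA).
#'
#' @param focal,reference 210-vectors of pair counts (canonical order,
#'   see \code{\link{countPairs}}), or symmetric 20 x 20 count matrices.
#' @param tau score scale (default 100).
#' @param kind label stored in the result.
#' @return a \linkS4class{PotentialMatrix} (no bootstrap errors).
#' @export
potentialFromCounts <- function(focal, reference, tau = 100,
                                kind = "norm") {
  f <- if (is.matrix(focal)) .matrixToPairVec(focal) else as.numeric(focal)
  r <- if (is.matrix(reference)) .matrixToPairVec(reference) else
    as.numeric(reference)
  if (sum(f) == 0 || sum(r) == 0)
    stop("empty counts: cannot form frequencies")
  v <- .pairVecToMatrix(.scoreFromCounts(f, r, tau))
  na <- matrix(NA_real_, .NAA, .NAA)
  new("PotentialMatrix", values = v, stderr = na,
      mask = !is.na(v), tau = tau, kind = kind)
}

.matrixToPairVec <- function(m) {
  v <- numeric(.NPAIR)
  for (a in seq_len(.NAA)) for (b in a:.NAA) v[.pairIdx(a, b)] <- m[a, b]
  v
}

#' Infer normal and entangled contact potentials
#'
#' Full potential inference over an ensemble: generic-pair, contact and
#' entangled-contact counting, the three scores E_norm, E_GE and the
#' enrichment dE_enr = E_GE - E_norm, and bootstrap standard errors from
#' resampling whole proteins with replacement.
#'
#' @param traces list of \linkS4class{ChainTrace}.
#' @param loopTables list of loop tables aligned with \code{traces}
#'   (computed by \code{\link{scanLoops}} when NULL; loop closure then
#'   uses the \code{loopContactMode} contact definition).
#' @param tau score scale (default 100).
#' @param m0 minimum sequence separation (default 10).
#' @param cutoff contact distance (default 4.5 Angstrom).
#' @param contactMode contact definition for potential counting.
#' @param loopContactMode contact definition for loop closure.
#' @param nBoot bootstrap resamplings (default 101; 0 disables).
#' @param seed bootstrap seed.
#' @return list with \linkS4class{PotentialMatrix} entries \code{norm},
#'   \code{ge}, \code{enrichment}, plus the aggregate \code{counts}
#'   (totals \code{N}, \code{Nc}, \code{NcG} and 210-vectors).
#' @export
inferPotentials <- function(traces, loopTables = NULL, tau = 100,
                            m0 = 10L, cutoff = 4.5,
                            contactMode = "sidechain_heavy",
                            loopContactMode = "any_heavy",
                            nBoot = 101L, seed = 1L) {
  if (is.null(loopTables))
    loopTables <- lapply(traces, scanLoops, cutoff = cutoff, m0 = m0,
                         contactMode = loopContactMode)
  pc <- .ensembleCounts(traces, loopTables, m0 = m0, cutoff = cutoff,
                        contactMode = contactMode)
  tot <- lapply(pc, colSums)
  if (sum(tot$gen) == 0 || sum(tot$con) == 0)
    stop("empty ensemble: no generic pairs or no contacts")
  eNorm <- .scoreFromCounts(tot$con, tot$gen, tau)
  eGE <- .scoreFromCounts(tot$ent, tot$gen, tau)
  eEnr <- .scoreFromCounts(tot$ent, tot$con, tau)
  np <- length(traces)
  seNorm <- seGE <- seEnr <- rep(NA_real_, .NPAIR)
  if (nBoot > 0L && np > 1L) {
    rng <- .localRNG(seed)
    bNorm <- bGE <- bEnr <- matrix(NA_real_, nBoot, .NPAIR)
    for (b in seq_len(nBoot)) {
      take <- rng$sampleInt(np, np, replace = TRUE)
      g <- colSums(pc$gen[take, , drop = FALSE])
      cn <- colSums(pc$con[take, , drop = FALSE])
      en <- colSums(pc$ent[take, , drop = FALSE])
      bNorm[b, ] <- .scoreFromCounts(cn, g, tau)
      bGE[b, ] <- .scoreFromCounts(en, g, tau)
      bEnr[b, ] <- .scoreFromCounts(en, cn, tau)
    }
    sdDefined <- function(m) apply(m, 2L, function(x)
      if (sum(!is.na(x)) >= 2L) stats::sd(x, na.rm = TRUE) else NA_real_)
    seNorm <- sdDefined(bNorm); seGE <- sdDefined(bGE)
    seEnr <- sdDefined(bEnr)
  }
  mk <- function(v, se, kind) {
    vm <- .pairVecToMatrix(v); sm <- .pairVecToMatrix(se)
    new("PotentialMatrix", values = vm, stderr = sm,
        mask = !is.na(vm) & !is.na(sm) & abs(vm) > sm,
        tau = tau, kind = kind)
  }
  list(norm = mk(eNorm, seNorm, "norm"), ge = mk(eGE, seGE, "ge"),
       enrichment = mk(eEnr, seEnr, "enrichment"),
       counts = list(N = sum(tot$gen), Nc = sum(tot$con),
                     NcG = sum(tot$ent), N_ab = tot$gen,
                     Nc_ab = tot$con, NcG_ab = tot$ent))
}

#' Correlation between enrichment score and normal potential
#'
#' Pearson and Spearman correlations (with p-values) and the linear-fit
#' slope of dE_enr(a,b) against E_norm(a,b) over the unordered pairs
#' where both scores are defined.
#'
#' @param enr,norm \linkS4class{PotentialMatrix} objects (enrichment and
#'   normal potential).
#' @return list with \code{pearson}, \code{pearson.p}, \code{spearman},
#'   \code{spearman.p}, \code{slope}, \code{nPairs}.
#' @export
correlationAnalysis <- function(enr, norm) {
  up <- upper.tri(matrix(0, .NAA, .NAA), diag = TRUE)
  x <- potentialValues(norm)[up]
  y <- potentialValues(enr)[up]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 10L)
    stop("fewer than 10 jointly defined pairs")
  pe <- stats::cor.test(x[ok], y[ok], method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x[ok], y[ok],
                                         method = "spearman"))
  fit <- stats::lm(y[ok] ~ x[ok])
  list(pearson = unname(pe$estimate), pearson.p = pe$p.value,
       spearman = unname(sp$estimate), spearman.p = sp$p.value,
       slope = unname(stats::coef(fit)[2L]), nPairs = sum(ok))
}
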