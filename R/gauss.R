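#' Discretized Gauss double sum between two subchains
#'
#' Computes the mutual winding of two non-overlapping residue ranges of a
#' Calpha trace by the discretized Gauss double integral.  With bond
#' midpoints \eqn{R_i = (r_i + r_{i+1})/2} and bond vectors
#' \eqn{\Delta R_i = r_{i+1} - r_i}, the score is
#' \deqn{G = \frac{1}{4\pi} \sum_{i=i_1}^{i_2-1} \sum_{j=j_1}^{j_2-1}
#'   \frac{R_i - R_j}{|R_i - R_j|^3} \cdot
#'   (\Delta R_i \times \Delta R_j).}
#' For two closed curves this is the (integer) linking number; on open
#' subchains it is a real-valued entanglement measure.  The score is
#' symmetric under exchanging the two ranges, invariant under rigid
#' motions, antisymmetric under reversing one subchain's orientation, and
#' flips sign under mirror reflection.
#'
#' This is the direct double-sum evaluation; use \code{\link{buildKernel}}
#' plus \code{\link{rangeScore}} when many range pairs are scored on one
#' trace.
#'
#' @param trace a \linkS4class{ChainTrace} (or an n x 3 coordinate matrix).
#' @param loop integer pair \code{c(i1, i2)}: first residue range.
#' @param other integer pair \code{c(j1, j2)}: second residue range.
#' @return signed numeric scalar.
#' @export
gaussPairScore <- function(trace, loop, other) {
  xyz <- if (is(trace, "ChainTrace")) trace@calpha else as.matrix(trace)
  n <- nrow(xyz)
  .checkRange(loop, n); .checkRange(other, n)
  if (max(loop[1], other[1]) <= min(loop[2], other[2]))
    stop("subchain ranges overlap: [", loop[1], ",", loop[2], "] vs [",
         other[1], ",", other[2], "]")
  mid <- (xyz[-n, , drop = FALSE] + xyz[-1, , drop = FALSE]) / 2
  dR <- diff(xyz)
  ia <- loop[1]:(loop[2] - 1L)
  ib <- other[1]:(other[2] - 1L)
  tot <- 0
  for (i in ia) {
    rx <- mid[i, 1] - mid[ib, 1]
    ry <- mid[i, 2] - mid[ib, 2]
    rz <- mid[i, 3] - mid[ib, 3]
    cx <- dR[i, 2] * dR[ib, 3] - dR[i, 3] * dR[ib, 2]
    cy <- dR[i, 3] * dR[ib, 1] - dR[i, 1] * dR[ib, 3]
    cz <- dR[i, 1] * dR[ib, 2] - dR[i, 2] * dR[ib, 1]
    d2 <- rx * rx + ry * ry + rz * rz
    tot <- tot + sum((rx * cx + ry * cy + rz * cz) / (d2 * sqrt(d2)))
  }
  tot / (4 * pi)
}

.checkRange <- function(r, n) {
  if (length(r) != 2L || any(!is.finite(r)) || r[1] < 1L || r[2] > n ||
      r[2] - r[1] < 1L)
    stop("invalid residue range: must satisfy 1 <= a1 < a2 <= n")
  invisible(TRUE)
}

#' Precompute the Gauss kernel of a trace
#'
#' Builds the (n-1) x (n-1) matrix of bond-pair contributions to the
#' discretized Gauss integral together with its 2D prefix-sum table, so
#' that the score of any subchain pair is a constant-time rectangle sum
#' (\code{\link{rangeScore}}).  Cost is O(n^2) once per trace.
#'
#' @param trace a \linkS4class{ChainTrace} or an n x 3 coordinate matrix.
#' @return a \linkS4class{GaussKernel}.
#' @export
buildKernel <- function(trace) {
  xyz <- if (is(trace, "ChainTrace")) trace@calpha else as.matrix(trace)
  K <- cpp_gauss_kernel(xyz)
  new("GaussKernel", pair = K, prefix = cpp_prefix(K),
      n = nrow(xyz))
}

#' Subchain-pair score from a precomputed kernel
#'
#' @param kernel a \linkS4class{GaussKernel}.
#' @param loop,other residue index pairs as in \code{\link{gaussPairScore}}.
#' @return signed numeric scalar, equal to the direct double sum.
#' @export
rangeScore <- function(kernel, loop, other) {
  n <- kernel@n
  .checkRange(loop, n); .checkRange(other, n)
  if (max(loop[1], other[1]) <= min(loop[2], other[2]))
    stop("subchain ranges overlap")
  cpp_range_score(kernel@prefix, loop[1], loop[2], other[1], other[2])
}

#' Gauss linking sum of two closed polygonal curves
#'
#' Treats each input as a closed polygon (an implicit bond joins the last
#' vertex back to the first) and returns the discretized Gauss double sum
#' over all bond pairs.  For well-separated discretizations this converges
#' to the integer linking number.
#'
#' @param curve1,curve2 k x 3 vertex matrices of two closed curves.
#' @return signed numeric scalar.
#' @export
gaussLinkingNumber <- function(curve1, curve2) {
  close1 <- rbind(as.matrix(curve1), as.matrix(curve1)[1, ])
  close2 <- rbind(as.matrix(curve2), as.matrix(curve2)[1, ])
  .gaussBlocks(close1, close2)
}

.gaussBlocks <- function(a, b) {
  midA <- (a[-nrow(a), , drop = FALSE] + a[-1, , drop = FALSE]) / 2
  dA <- diff(a)
  midB <- (b[-nrow(b), , drop = FALSE] + b[-1, , drop = FALSE]) / 2
  dB <- diff(b)
  tot <- 0
  for (i in seq_len(nrow(midA))) {
    rx <- midA[i, 1] - midB[, 1]
    ry <- midA[i, 2] - midB[, 2]
    rz <- midA[i, 3] - midB[, 3]
    cx <- dA[i, 2] * dB[, 3] - dA[i, 3] * dB[, 2]
    cy <- dA[i, 3] * dB[, 1] - dA[i, 1] * dB[, 3]
    cz <- dA[i, 1] * dB[, 2] - dA[i, 2] * dB[, 1]
    d2 <- rx * rx + ry * ry + rz * rz
    tot <- tot + sum((rx * cx + ry * cy + rz * cz) / (d2 * sqrt(d2)))
  }
  tot / (4 * pi)
}

#' Residue-residue contact map
#'
#' Two residues are in contact when the minimum distance between their
#' atom sets is at most \code{cutoff} (default 4.5 Angstrom).  Mode
#' \code{"any_heavy"} uses all non-hydrogen atoms (the loop-closure
#' definition); \code{"sidechain_heavy"} uses side-chain heavy atoms only
#' (the potential-counting definition), falling back to all heavy atoms
#' for residues without side-chain atoms (glycine).
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @param cutoff contact distance threshold in Angstrom.
#' @param mode \code{"any_heavy"} or \code{"sidechain_heavy"}.
#' @param minsep minimum sequence separation of reported pairs.
#' @return integer matrix with columns \code{i1}, \code{i2} (i1 < i2),
#'   with attributes \code{mode} and \code{cutoff}.
#' @export
computeContacts <- function(trace, cutoff = 4.5,
                            mode = c("any_heavy", "sidechain_heavy"),
                            minsep = 1L) {
  mode <- match.arg(mode)
  n <- length(trace)
  sets <- if (mode == "any_heavy") trace@heavyAtoms else
    lapply(seq_len(n), function(i) {
      sc <- trace@sidechainAtoms[[i]]
      if (is.null(sc) || nrow(sc) == 0L) trace@heavyAtoms[[i]] else sc
    })
  counts <- vapply(sets, nrow, 1L)
  if (all(counts == 1L)) {
    xyz <- do.call(rbind, sets)
    out <- cpp_point_contacts(xyz, cutoff, as.integer(minsep))
  } else {
    xyz <- do.call(rbind, sets)
    resid <- rep.int(seq_len(n), counts)
    out <- cpp_atom_contacts(xyz, resid, n, cutoff, as.integer(minsep))
  }
  colnames(out) <- c("i1", "i2")
  attr(out, "mode") <- mode
  attr(out, "cutoff") <- cutoff
  out
}

#' Enumerate contact-closed loops
#'
#' A loop is a subchain whose end residues are in contact and whose length
#' \eqn{m = i_2 - i_1} is at least \code{m0} (default 10).
#'
#' @param contacts contact matrix from \code{\link{computeContacts}}.
#' @param m0 minimum loop length in residues.
#' @return integer matrix of loop ranges sorted by \code{(i1, i2)}.
#' @export
enumerateLoops <- function(contacts, m0 = 10L) {
  keep <- contacts[, 2L] - contacts[, 1L] >= m0
  out <- contacts[keep, , drop = FALSE]
  out <- out[order(out[, 1L], out[, 2L]), , drop = FALSE]
  attr(out, "mode") <- attr(contacts, "mode")
  attr(out, "cutoff") <- attr(contacts, "cutoff")
  out
}

#' Best thread of a loop
#'
#' Scans every contiguous subchain \code{[j1, j2]} with
#' \code{j2 - j1 >= m0}, lying entirely on one side of the loop and
#' separated from it by at least \code{smin} residues, and returns the
#' thread maximizing the absolute Gauss score.  Ties are broken
#' deterministically in scan order: N-side ranges before C-side, then
#' lexicographically by \code{(j1, j2)}.
#'
#' @param kernel a \linkS4class{GaussKernel}.
#' @param loop integer pair \code{c(i1, i2)}.
#' @param m0 minimum thread length (residues).
#' @param smin minimum loop-thread sequence separation.
#' @param fullArm when TRUE, only the two full arms (loop edge to the
#'   respective terminus) are considered as threads instead of every
#'   contiguous subchain; a sensitivity-check mode.
#' @return one-row data.frame with columns \code{i1,i2,m,j1,j2,side,s,g,
#'   entangled}; thread columns are NA (and \code{side} is \code{NA}) when
#'   no admissible thread exists.
#' @export
bestThread <- function(kernel, loop, m0 = 10L, smin = 1L,
                       fullArm = FALSE) {
  n <- kernel@n
  .checkRange(loop, n)
  r <- if (fullArm) .bestFullArm(kernel, loop, n, m0, smin) else
    cpp_best_thread(kernel@prefix, loop[1], loop[2], n,
                    as.integer(m0), as.integer(smin))
  if (!r$found)
    return(data.frame(i1 = loop[1], i2 = loop[2], m = loop[2] - loop[1],
                      j1 = NA_integer_, j2 = NA_integer_,
                      side = NA_character_, s = NA_integer_, g = NA_real_,
                      entangled = NA, stringsAsFactors = FALSE))
  s <- if (r$side == "N") loop[1] - r$j2 else r$j1 - loop[2]
  data.frame(i1 = loop[1], i2 = loop[2], m = loop[2] - loop[1],
             j1 = r$j1, j2 = r$j2, side = r$side, s = s, g = r$g,
             entangled = abs(r$g) >= 1, stringsAsFactors = FALSE)
}

# full-arm candidates only: [1, i1-smin] and [i2+smin, n]
.bestFullArm <- function(kernel, loop, n, m0, smin) {
  cand <- list()
  if (loop[1] - smin - 1L >= m0)
    cand <- c(cand, list(list(j1 = 1L, j2 = loop[1] - smin,
                              side = "N")))
  if (n - (loop[2] + smin) >= m0)
    cand <- c(cand, list(list(j1 = loop[2] + smin, j2 = n,
                              side = "C")))
  if (length(cand) == 0L)
    return(list(found = FALSE, g = NA_real_, j1 = NA_integer_,
                j2 = NA_integer_, side = NA_character_))
  gs <- vapply(cand, function(cd)
    cpp_range_score(kernel@prefix, loop[1], loop[2], cd$j1, cd$j2),
    numeric(1))
  k <- which.max(abs(gs))
  list(found = TRUE, g = gs[k], j1 = cand[[k]]$j1, j2 = cand[[k]]$j2,
       side = cand[[k]]$side)
}

#' Score all contact-closed loops of a trace
#'
#' Full per-trace loop scan: contacts, loop enumeration, and the
#' best-thread score G'c(i) of every loop.  Loops with no admissible
#' thread are kept with NA thread columns.
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @param cutoff contact cutoff (Angstrom).
#' @param m0 minimum loop and thread length (residues).
#' @param smin minimum loop-thread separation (residues).
#' @param contactMode contact definition for loop closure.
#' @param kernel optional precomputed \linkS4class{GaussKernel}.
#' @return data.frame with one row per loop (columns as in
#'   \code{\link{bestThread}}, plus \code{id} and \code{weight = 1}).
#' @export
scanLoops <- function(trace, cutoff = 4.5, m0 = 10L, smin = 1L,
                      contactMode = c("any_heavy", "sidechain_heavy"),
                      kernel = NULL) {
  contactMode <- match.arg(contactMode)
  cmap <- computeContacts(trace, cutoff = cutoff, mode = contactMode)
  loops <- enumerateLoops(cmap, m0 = m0)
  empty <- data.frame(id = character(), i1 = integer(), i2 = integer(),
                      m = integer(), j1 = integer(), j2 = integer(),
                      side = character(), s = integer(), g = numeric(),
                      entangled = logical(), weight = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(loops) == 0L) return(empty)
  if (is.null(kernel)) kernel <- buildKernel(trace)
  rows <- lapply(seq_len(nrow(loops)), function(k)
    bestThread(kernel, loops[k, ], m0 = m0, smin = smin))
  out <- do.call(rbind, rows)
  out <- cbind(id = trace@id, out, stringsAsFactors = FALSE)
  out$weight <- 1
  out
}

#' Per-protein entanglement: G'c and L'
#'
#' The protein-level Gaussian entanglement G'c is the extreme (largest
#' modulus, sign retained) of the per-loop scores G'c(i).  The linking
#' entanglement L' is the extreme Gauss score over pairs of disjoint
#' contact-closed loops; since loop pairs are a subset of loop-thread
#' pairs, |L'| <= |G'c| always holds.
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @inheritParams scanLoops
#' @return an \linkS4class{EntanglementResult}.
#' @export
proteinEntanglement <- function(trace, cutoff = 4.5, m0 = 10L, smin = 1L,
                                contactMode = c("any_heavy",
                                                "sidechain_heavy")) {
  contactMode <- match.arg(contactMode)
  kernel <- buildKernel(trace)
  loops <- scanLoops(trace, cutoff = cutoff, m0 = m0, smin = smin,
                     contactMode = contactMode, kernel = kernel)
  ge <- NA_real_; le <- NA_real_
  geLoop <- c(NA_integer_, NA_integer_)
  geThread <- c(NA_integer_, NA_integer_)
  leLoops <- rep(NA_integer_, 4L)
  scored <- loops[!is.na(loops$g), , drop = FALSE]
  if (nrow(scored) > 0L) {
    k <- which.max(abs(scored$g))
    ge <- scored$g[k]
    geLoop <- c(scored$i1[k], scored$i2[k])
    geThread <- c(scored$j1[k], scored$j2[k])
  }
  if (nrow(loops) >= 2L) {
    lp <- cpp_best_loop_pair(kernel@prefix,
                             as.matrix(loops[, c("i1", "i2")]),
                             as.integer(smin))
    if (lp$found) {
      le <- lp$g
      leLoops <- c(loops$i1[lp$a], loops$i2[lp$a],
                   loops$i1[lp$b], loops$i2[lp$b])
    }
  }
  new("EntanglementResult", id = trace@id, ge = ge, le = le,
      geLoop = as.integer(geLoop), geThread = as.integer(geThread),
      leLoops = as.integer(leLoops), loops = loops)
}

#' Mirror-reflect a trace
#'
#' Reflects all coordinates through the xy-plane.  Every Gauss score is a
#' pseudoscalar, so reflection flips the sign of every entanglement score
#' while preserving magnitudes, sides and separations.
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @return the reflected \linkS4class{ChainTrace}.
#' @export
mirrorTrace <- function(trace) {
  flip <- function(m) { m[, 3] <- -m[, 3]; m }
  new("ChainTrace", id = trace@id, calpha = flip(trace@calpha),
      residues = trace@residues,
      heavyAtoms = lapply(trace@heavyAtoms, flip),
      sidechainAtoms = lapply(trace@sidechainAtoms, flip),
      meta = trace@meta)
}
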