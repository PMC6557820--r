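# Effective counting of entangled loops.  Within one protein, nearly
# identical loop-thread configurations (e.g. the same arm threading the
# loop (i1, i2) and the loop (i1+1, i2)) must not be counted twice.

#' Distance between two loop records
#'
#' Euclidean distance over the four defining indices plus a weighted
#' squared difference of the entanglement scores:
#' \deqn{d_{AB} = \sqrt{(i_1^A-i_1^B)^2 + (i_2^A-i_2^B)^2 +
#'   (j_1^A-j_1^B)^2 + (j_2^A-j_2^B)^2 + w_g (g^A - g^B)^2}.}
#'
#' @param a,b one-row loop records (any object with \code{i1,i2,j1,j2,g}).
#' @param wg weight of the squared score difference (default 1e4).
#' @return non-negative numeric scalar.
#' @export
loopDistance <- function(a, b, wg = 1e4) {
  sqrt((a$i1 - b$i1)^2 + (a$i2 - b$i2)^2 + (a$j1 - b$j1)^2 +
         (a$j2 - b$j2)^2 + wg * (a$g - b$g)^2)
}

#' Greedy clustering of loops within one protein
#'
#' Iteratively selects the loop with the largest number of neighbors
#' (loops at distance below \code{dStar}), assigns it and its neighbors
#' to one cluster, removes them, and repeats until no loop remains.  Each
#' member of a cluster of size \eqn{N_C} receives counting weight
#' \eqn{1/N_C}, so weights sum to the number of clusters.  Ties on the
#' neighbor count are broken by the lexicographically smallest
#' \code{(i1, i2, j1, j2)}.
#'
#' @param loops loop record data.frame for a single protein
#'   (columns \code{i1,i2,j1,j2,g}; rows with NA scores are not allowed).
#' @param dStar distance threshold (default 20).
#' @param wg score-difference weight (default 1e4).
#' @return the input with columns \code{cluster} (integer id) and
#'   \code{weight} (1/cluster size) set.
#' @export
clusterLoops <- function(loops, dStar = 20, wg = 1e4) {
  m <- nrow(loops)
  if (is.null(m) || m == 0L) {
    loops$cluster <- integer(0)
    loops$weight <- numeric(0)
    return(loops)
  }
  emb <- cbind(loops$i1, loops$i2, loops$j1, loops$j2, sqrt(wg) * loops$g)
  if (anyNA(emb)) stop("clusterLoops needs complete i1,i2,j1,j2,g")
  D <- as.matrix(stats::dist(emb))
  near <- D < dStar
  alive <- rep(TRUE, m)
  cluster <- integer(m)
  ord <- order(loops$i1, loops$i2, loops$j1, loops$j2)
  rank <- integer(m); rank[ord] <- seq_len(m)
  cid <- 0L
  while (any(alive)) {
    counts <- colSums(near[alive, , drop = FALSE])
    counts[!alive] <- -1L
    top <- which(counts == max(counts))
    pick <- top[which.min(rank[top])]
    members <- which(alive & near[, pick])
    cid <- cid + 1L
    cluster[members] <- cid
    alive[members] <- FALSE
  }
  loops$cluster <- cluster
  size <- table(cluster)
  loops$weight <- 1 / as.numeric(size[as.character(cluster)])
  loops
}

#' Cluster entangled loops protein by protein
#'
#' Applies \code{\link{clusterLoops}} within each protein id of a pooled
#' loop table.  Only entangled loops (|g| >= 1) are clustered; rows that
#' are not entangled are dropped (effective counting applies to
#' entangled loops only; use raw tables for unweighted statistics).
#'
#' @param loops pooled loop table with an \code{id} column (e.g. rows
#'   bound from \code{\link{scanLoops}}).
#' @param dStar,wg see \code{\link{clusterLoops}}.
#' @return the entangled subset with per-protein \code{cluster} and
#'   \code{weight} columns.
#' @export
clusterEnsemble <- function(loops, dStar = 20, wg = 1e4) {
  ent <- loops[!is.na(loops$g) & abs(loops$g) >= 1, , drop = FALSE]
  if (nrow(ent) == 0L) return(ent)
  parts <- split(ent, ent$id)
  out <- do.call(rbind, lapply(parts, clusterLoops, dStar = dStar, wg = wg))
  rownames(out) <- NULL
  out
}
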