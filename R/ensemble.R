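# Length-stratified comparison of loop-entanglement distributions
# between ensembles (natural domains vs compact decoy backbones).

#' Filter an ensemble by chain length
#'
#' @param traces list of \linkS4class{ChainTrace}.
#' @param nMin,nMax inclusive residue-count window (defaults 55 and 64,
#'   the window matching a 60-residue decoy ensemble).
#' @return the retained sublist.
#' @export
filterByLength <- function(traces, nMin = 55L, nMax = 64L) {
  keep <- vapply(traces, function(tr) {
    n <- length(tr); n >= nMin && n <= nMax
  }, logical(1))
  traces[keep]
}

#' Ensemble-level loop and entanglement summary
#'
#' @param loopTables list of per-trace loop tables (from
#'   \code{\link{scanLoops}}), or one pooled table with an \code{id}
#'   column.
#' @return list with \code{nStructures}, \code{nLoops},
#'   \code{nEntangled}, \code{fracEntangled},
#'   \code{nStructuresWithEntangled}, \code{fracStructuresWithEntangled}
#'   and the pooled per-loop \code{table} (raw counts, no cluster
#'   weighting).
#' @export
ensembleSummary <- function(loopTables) {
  if (is.data.frame(loopTables)) {
    pooled <- loopTables
    nStruct <- length(unique(pooled$id))
    perStruct <- split(pooled, pooled$id)
  } else {
    pooled <- do.call(rbind, loopTables)
    nStruct <- length(loopTables)
    perStruct <- loopTables
  }
  if (is.null(pooled)) pooled <- data.frame()
  ent <- !is.na(pooled$g) & abs(pooled$g) >= 1
  hosts <- sum(vapply(perStruct, function(t)
    any(!is.na(t$g) & abs(t$g) >= 1), logical(1)))
  nLoops <- nrow(pooled)
  list(nStructures = nStruct, nLoops = nLoops, nEntangled = sum(ent),
       fracEntangled = if (nLoops > 0) sum(ent) / nLoops else NA_real_,
       nStructuresWithEntangled = hosts,
       fracStructuresWithEntangled =
         if (nStruct > 0) hosts / nStruct else NA_real_,
       table = pooled)
}

#' Loop-length-stratified entanglement profiles
#'
#' For each loop-length class, the normalized histogram of the loop
#' scores G'c(i) (bin width \code{gBin}), plus the root-mean-square
#' score as a function of the exact loop length m.  Raw loop counts are
#' used (no cluster weighting), matching ensemble-fraction bookkeeping.
#'
#' @param summary output of \code{\link{ensembleSummary}} (or a pooled
#'   loop table).
#' @param mClasses list of inclusive length intervals, e.g.
#'   \code{list(c(20, 24), c(30, 34), c(40, 44))}.
#' @param gBin histogram bin width for g.
#' @return list with \code{histograms} (one per class: \code{breaks},
#'   \code{mids}, \code{freq} summing to 1, \code{n}) and \code{rms}
#'   (data.frame of m, rms g, loop count).
#' @export
loopLengthProfiles <- function(summary,
                               mClasses = list(c(20L, 24L), c(30L, 34L),
                                               c(40L, 44L)),
                               gBin = 0.1) {
  tab <- if (is.data.frame(summary)) summary else summary$table
  tab <- tab[!is.na(tab$g), , drop = FALSE]
  hists <- lapply(mClasses, function(cl) {
    g <- tab$g[tab$m >= cl[1] & tab$m <= cl[2]]
    if (length(g) == 0L)
      return(list(class = cl, breaks = numeric(0), mids = numeric(0),
                  freq = numeric(0), n = 0L))
    lo <- floor(min(g) / gBin) * gBin
    hi <- ceiling(max(g) / gBin) * gBin
    breaks <- seq(lo - gBin / 2, hi + gBin / 2, by = gBin)
    h <- hist(g, breaks = breaks, plot = FALSE)
    list(class = cl, breaks = h$breaks, mids = h$mids,
         freq = h$counts / sum(h$counts), n = length(g))
  })
  rms <- do.call(rbind, lapply(split(tab$g, tab$m), function(g)
    data.frame(rms = sqrt(mean(g^2)), n = length(g))))
  rms <- data.frame(m = as.integer(rownames(rms)), rms = rms$rms,
                    n = rms$n)
  rms <- rms[order(rms$m), ]
  rownames(rms) <- NULL
  list(histograms = hists, rms = rms)
}
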