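# Synthetic structure generators with known topological and statistical
# ground truth.  All synthetic traces are Calpha-only: the heavy-atom set
# of each residue is its Calpha, so the 4.5 A contact criterion acts on
# Calpha distances, and loop closures are engineered at ~4.0 A.

#' Two closed curves with an exact linking number
#'
#' Builds a planar core ring of radius \code{R} and a second closed curve
#' winding \code{turns} times around its tube (a (1, turns)-style torus
#' winding of tube radius \code{r}), so the topological linking number is
#' exactly \code{turns}; negative values reverse the handedness.  With
#' \code{turns = 0} the second ring is a displaced, unlinked circle.
#'
#' @param turns signed integer winding number.
#' @param nPoints vertices per curve (>= 16).
#' @param R core ring radius (Angstrom).
#' @param r tube radius (Angstrom); must satisfy 0 < r < R.
#' @return list with k x 3 vertex matrices \code{curve1}, \code{curve2}
#'   and the ground truth \code{linking}.
#' @export
makeLinkedRings <- function(turns, nPoints = 128L, R = 10, r = 4) {
  if (nPoints < 16L) stop("nPoints must be at least 16")
  if (r <= 0 || r >= R) stop("degenerate radii: need 0 < r < R")
  phi <- seq(0, 2 * pi, length.out = nPoints + 1L)[-(nPoints + 1L)]
  curve1 <- cbind(R * cos(phi), R * sin(phi), 0)
  if (turns == 0L) {
    curve2 <- cbind(R * cos(phi) + 3 * R, R * sin(phi), 0)
  } else {
    w <- abs(turns) * phi
    sgn <- -sign(turns)
    curve2 <- cbind((R + r * cos(w)) * cos(phi),
                    (R + r * cos(w)) * sin(phi),
                    sgn * r * sin(w))
  }
  list(curve1 = curve1, curve2 = curve2, linking = as.numeric(turns))
}

# Evenly spaced points along the straight segment from `from` to `to`,
# excluding `from`, ending exactly at `to`, spacing as close to `step` as
# an integer subdivision allows.
.segPoints <- function(from, to, step = 3.8) {
  d <- sqrt(sum((to - from)^2))
  k <- max(1L, round(d / step))
  t <- seq_len(k) / k
  cbind(from[1] + t * (to[1] - from[1]),
        from[2] + t * (to[2] - from[2]),
        from[3] + t * (to[3] - from[3]))
}

# Helix arc of `turns` turns (theta from 0 to 2*pi*turns), radius Rh,
# descending `pitch` per turn from z1, sampled at ~step arc spacing with
# exact endpoints.  Returns points excluding the theta = 0 start.
.helixPoints <- function(turns, Rh, pitch, z1, step = 3.8) {
  thetaEnd <- 2 * pi * turns
  arcPerTurn <- sqrt((2 * pi * Rh)^2 + pitch^2)
  k <- max(2L, round(arcPerTurn * turns / step))
  theta <- seq(0, thetaEnd, length.out = k + 1L)[-1L]
  cbind(Rh * cos(theta), Rh * sin(theta), z1 - pitch * theta / (2 * pi))
}

# One helix-wrap unit in local coordinates: a straight thread along z, a
# connector, a helical loop of `turns` turns wound around the thread, and
# a return path closing the loop at `gap` Angstrom from the helix start.
# Returns the point matrix and the local indices of the closure pair.
# Positive turns give right-handed winding (positive Gauss score).
.wrapUnit <- function(turns, Rh = 8, pitch = 7, margin = 40, gap = 4.0,
                      step = 3.8) {
  stopifnot(turns != 0)
  t <- abs(turns)
  z1 <- 0
  z2 <- z1 - t * pitch
  R2 <- Rh + 12
  pts <- rbind(c(0, 0, z2 - margin))                      # thread bottom
  pts <- rbind(pts, .segPoints(pts[nrow(pts), ], c(0, 0, z1 + margin), step))
  thrTop <- nrow(pts)
  # connector: out of the axis, down to the helix start
  pts <- rbind(pts, .segPoints(pts[nrow(pts), ],
                               c(0.6 * Rh, 0, z1 + 0.6 * margin), step))
  pts <- rbind(pts, .segPoints(pts[nrow(pts), ], c(Rh, 0, z1 + 6), step))
  pts <- rbind(pts, .segPoints(pts[nrow(pts), ], c(Rh, 0, z1), step))
  helixStart <- nrow(pts)
  pts <- rbind(pts, .helixPoints(t, Rh, pitch, z1, step))
  # return: radially out, up outside the helix, back in to the closure
  pts <- rbind(pts, .segPoints(pts[nrow(pts), ], c(R2, 0, z2), step))
  pts <- rbind(pts, .segPoints(pts[nrow(pts), ], c(R2, 0, z1), step))
  pts <- rbind(pts, .segPoints(pts[nrow(pts), ], c(Rh + gap, 0, z1), step))
  if (turns < 0) pts[, 2] <- -pts[, 2]
  list(points = pts, closure = c(helixStart, nrow(pts)), thrTop = thrTop)
}

#' Open chain with a loop wound around a thread
#'
#' Generates a single open Calpha chain consisting of a straight thread
#' segment and a helical loop of \code{|turns|} turns wound around it,
#' with the loop endpoints brought within contact distance so that the
#' loop scan detects one contact-closed loop whose entanglement score is
#' approximately \code{turns} (handedness sets the sign).  With
#' \code{side = "N"} the thread precedes the loop in sequence; with
#' \code{side = "C"} the chain is reversed so the thread follows it.
#'
#' @param turns signed non-zero integer winding.
#' @param side \code{"N"} or \code{"C"}: thread placement in sequence.
#' @param seed integer seed for the coordinate jitter and residue labels.
#' @param jitter Gaussian coordinate noise, Angstrom.
#' @param Rh helix (loop) radius, Angstrom.
#' @param pitch helix advance per turn, Angstrom.
#' @param margin thread extension beyond the helix span on each side,
#'   Angstrom; larger margins bring the score closer to \code{turns}.
#' @param id trace identifier.
#' @return a \linkS4class{ChainTrace} with attribute-free ground truth in
#'   \code{meta}: \code{turns}, \code{side}, \code{closure} (residue pair
#'   closing the loop).
#' @export
makeHelixWrap <- function(turns, side = c("N", "C"), seed = 1L,
                          jitter = 0.05, Rh = 8, pitch = 7, margin = 40,
                          id = NULL) {
  side <- match.arg(side)
  if (turns == 0) stop("turns must be non-zero")
  unit <- .wrapUnit(turns, Rh = Rh, pitch = pitch, margin = margin)
  pts <- unit$points
  n <- nrow(pts)
  closure <- unit$closure
  if (side == "C") {
    pts <- pts[n:1, , drop = FALSE]
    closure <- sort(n + 1L - closure)
  }
  rng <- .localRNG(seed)
  pts <- pts + rng$rnorm(3L * n, sd = jitter)
  if (is.null(id))
    id <- sprintf("wrap_t%+d_%s_s%d", turns, side, seed)
  ChainTrace(pts, id = id,
             residues = rng$sampleChar(aminoAcids(), n, replace = TRUE),
             meta = list(turns = turns, side = side, closure = closure,
                         seed = seed))
}

#' Self-avoiding compact random backbone
#'
#' Grows a fixed-bond random walk (bond 3.8 Angstrom) inside a sphere of
#' radius \code{confinement}, rejecting any step closer than 4 Angstrom
#' to a non-adjacent previous residue.  Dead ends restart the chain; the
#' generator errors (reporting the seed) when \code{maxRestarts} is
#' exhausted.  Tighter confinement yields more compact, more entangled
#' decoys.
#'
#' @param n residue count (>= 12).
#' @param bond bond length in Angstrom.
#' @param confinement sphere radius in Angstrom.
#' @param seed integer seed.
#' @param excluded minimum non-neighbor residue distance, Angstrom.
#' @param maxTries candidate directions per step.
#' @param maxRestarts chain restarts before giving up.
#' @param id trace identifier.
#' @return a \linkS4class{ChainTrace}.
#' @export
makeRandomBackbone <- function(n, bond = 3.8, confinement = 14, seed = 1L,
                               excluded = 4.0, maxTries = 60L,
                               maxRestarts = 400L, id = NULL) {
  if (n < 12L) stop("n must be at least 12")
  rng <- .localRNG(seed)
  for (attempt in seq_len(maxRestarts)) {
    pts <- matrix(NA_real_, n, 3L)
    u <- rng$runif(3L) - 0.5
    pts[1L, ] <- u / sqrt(sum(u^2)) * rng$runif(1L) * confinement * 0.4
    ok <- TRUE
    for (i in 2L:n) {
      placed <- FALSE
      for (k in seq_len(maxTries)) {
        v <- rng$rnorm(3L)
        v <- v / sqrt(sum(v^2)) * bond
        cand <- pts[i - 1L, ] + v
        if (sum(cand^2) > confinement^2) next
        if (i > 2L) {
          prev <- pts[seq_len(i - 2L), , drop = FALSE]
          d2 <- (prev[, 1] - cand[1])^2 + (prev[, 2] - cand[2])^2 +
            (prev[, 3] - cand[3])^2
          if (any(d2 < excluded^2)) next
        }
        pts[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      if (is.null(id)) id <- sprintf("saw_n%d_s%d", n, seed)
      return(ChainTrace(pts, id = id,
                        residues = rng$sampleChar(aminoAcids(), n,
                                                  replace = TRUE),
                        meta = list(seed = seed, confinement = confinement)))
    }
  }
  stop("backbone placement failed after ", maxRestarts,
       " restarts (seed ", seed, ", confinement ", confinement, ")")
}

# Seed-local RNG: draws never touch (and always restore) the caller's
# .Random.seed, so generators are reproducible and side-effect free.
.localRNG <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, globalenv())
  draw <- function(fn) function(...) {
    outer <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(outer)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", outer, globalenv())
    out
  }
  list(rnorm = draw(stats::rnorm), runif = draw(stats::runif),
       sampleInt = draw(function(x, size, replace = FALSE, prob = NULL)
         sample.int(x, size, replace = replace, prob = prob)),
       sampleChar = draw(function(x, size, replace = FALSE, prob = NULL)
         sample(x, size, replace = replace, prob = prob)))
}
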