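#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib gentangle, .registration = TRUE
NULL

#' One-letter codes of the twenty canonical amino acids
#'
#' Alphabetical one-letter order; this is the row/column order of every
#' 20 x 20 count and potential matrix in the package.
#'
#' @export
aminoAcids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' ChainTrace: the Calpha trace of one protein domain
#'
#' Ordered Calpha coordinates for a single chain or domain, together with
#' per-residue heavy-atom and side-chain heavy-atom coordinate sets and
#' amino-acid labels.  Coordinates are in Angstrom.  Residue indexing is
#' 1-based and contiguous after filtering; the original author numbering,
#' if any, is kept in \code{meta$resno}.
#'
#' @slot id character identifier (e.g. a CATH domain name).
#' @slot calpha n x 3 numeric matrix of Calpha coordinates.
#' @slot residues character vector of one-letter amino-acid codes
#'   (\code{"X"} flags unknown/non-canonical residues).
#' @slot heavyAtoms list of per-residue matrices of non-hydrogen atom
#'   coordinates (the Calpha itself for synthetic traces).
#' @slot sidechainAtoms list of per-residue matrices of side-chain
#'   non-hydrogen atom coordinates (may have zero rows, e.g. glycine).
#' @slot meta list of free-form metadata.
#'
#' @exportClass ChainTrace
setClass("ChainTrace",
  representation(id = "character", calpha = "matrix",
                 residues = "character", heavyAtoms = "list",
                 sidechainAtoms = "list", meta = "list"))

setValidity("ChainTrace", function(object) {
  n <- nrow(object@calpha)
  msg <- character()
  if (is.null(n) || n < 2L)
    msg <- c(msg, "a ChainTrace needs at least 2 residues")
  if (ncol(object@calpha) != 3L)
    msg <- c(msg, "calpha must be an n x 3 matrix")
  if (length(object@residues) != n)
    msg <- c(msg, "length(residues) must equal nrow(calpha)")
  if (length(object@heavyAtoms) != n)
    msg <- c(msg, "heavyAtoms must have one entry per residue")
  if (length(object@sidechainAtoms) != n)
    msg <- c(msg, "sidechainAtoms must have one entry per residue")
  if (any(!is.finite(object@calpha)))
    msg <- c(msg, "calpha contains non-finite coordinates")
  if (length(msg)) msg else TRUE
})

#' Construct a ChainTrace
#'
#' @param calpha n x 3 matrix of Calpha coordinates (Angstrom).
#' @param id identifier string.
#' @param residues one-letter amino-acid labels; defaults to \code{"X"}.
#' @param heavyAtoms per-residue heavy-atom coordinate matrices; defaults
#'   to the Calpha positions (the convention for synthetic traces).
#' @param sidechainAtoms per-residue side-chain heavy-atom matrices;
#'   defaults to \code{heavyAtoms}.
#' @param meta metadata list.
#' @return a \linkS4class{ChainTrace}.
#' @export
ChainTrace <- function(calpha, id = "trace", residues = NULL,
                       heavyAtoms = NULL, sidechainAtoms = NULL,
                       meta = list()) {
  calpha <- as.matrix(calpha)
  storage.mode(calpha) <- "double"
  n <- nrow(calpha)
  if (is.null(residues)) residues <- rep("X", n)
  if (is.null(heavyAtoms))
    heavyAtoms <- lapply(seq_len(n), function(i) calpha[i, , drop = FALSE])
  if (is.null(sidechainAtoms)) sidechainAtoms <- heavyAtoms
  new("ChainTrace", id = id, calpha = calpha,
      residues = as.character(residues), heavyAtoms = heavyAtoms,
      sidechainAtoms = sidechainAtoms, meta = meta)
}

#' @describeIn ChainTrace number of residues
#' @param x,object a ChainTrace
#' @export
setMethod("length", "ChainTrace", function(x) nrow(x@calpha))

setMethod("show", "ChainTrace", function(object) {
  d <- apply(diff(object@calpha), 1L, function(v) sqrt(sum(v^2)))
  cat("ChainTrace '", object@id, "': ", nrow(object@calpha),
      " residues, Calpha-Calpha bonds ",
      sprintf("%.2f-%.2f", min(d), max(d)), " A\n", sep = "")
})

#' Calpha coordinates of a ChainTrace
#' @param trace a \linkS4class{ChainTrace}.
#' @return n x 3 numeric matrix.
#' @export
calpha <- function(trace) trace@calpha

#' Residue labels of a ChainTrace
#' @param trace a \linkS4class{ChainTrace}.
#' @return character vector of one-letter codes.
#' @export
residues <- function(trace) trace@residues

#' Identifier of a ChainTrace
#' @param trace a \linkS4class{ChainTrace}.
#' @return character scalar.
#' @export
traceId <- function(trace) trace@id

#' GaussKernel: precomputed pair contributions for one trace
#'
#' Holds the (n-1) x (n-1) symmetric matrix of discretized Gauss-integral
#' bond-pair contributions and its padded 2D prefix table, from which the
#' mutual winding of any two subchains is a single O(1) rectangle sum.
#'
#' @slot pair (n-1) x (n-1) contribution matrix (dimensionless).
#' @slot prefix n x n padded cumulative-sum table.
#' @slot n residue count of the source trace.
#' @exportClass GaussKernel
setClass("GaussKernel",
  representation(pair = "matrix", prefix = "matrix", n = "integer"))

setMethod("show", "GaussKernel", function(object) {
  cat("GaussKernel over", object@n, "residues (",
      object@n - 1L, "bonds )\n")
})

#' EntanglementResult: per-protein entanglement summary
#'
#' @slot id trace identifier.
#' @slot ge protein-level Gaussian entanglement G'c: the largest-modulus
#'   loop score, sign retained (NA if the trace hosts no loops).
#' @slot le linking entanglement L': the extreme score over pairs of
#'   disjoint contact-closed loops (NA if fewer than two disjoint loops).
#' @slot geLoop,geThread residue index pairs achieving \code{ge}.
#' @slot leLoops two residue index pairs achieving \code{le}.
#' @slot loops per-loop record table (see \code{\link{scanLoops}}).
#' @exportClass EntanglementResult
setClass("EntanglementResult",
  representation(id = "character", ge = "numeric", le = "numeric",
                 geLoop = "integer", geThread = "integer",
                 leLoops = "integer", loops = "data.frame"))

setMethod("show", "EntanglementResult", function(object) {
  cat("EntanglementResult '", object@id, "': G'c = ",
      formatC(object@ge, digits = 4, format = "fg"),
      ", L' = ", formatC(object@le, digits = 4, format = "fg"),
      ", ", nrow(object@loops), " loops (",
      sum(object@loops$entangled %in% TRUE), " entangled)\n", sep = "")
})

#' Protein-level Gaussian entanglement
#' @param result an \linkS4class{EntanglementResult}.
#' @return signed numeric scalar (NA when no loop exists).
#' @export
proteinGE <- function(result) result@ge

#' Protein-level linking entanglement
#' @param result an \linkS4class{EntanglementResult}.
#' @return signed numeric scalar (NA when no disjoint loop pair exists).
#' @export
proteinLE <- function(result) result@le

#' Per-loop record table of an EntanglementResult
#' @param result an \linkS4class{EntanglementResult}.
#' @return data.frame with one row per contact-closed loop.
#' @export
loopTable <- function(result) result@loops

#' PotentialMatrix: a 20 x 20 contact score matrix
#'
#' Symmetric knowledge-based score matrix over amino-acid pairs, with
#' bootstrap standard errors and a significance mask.
#'
#' @slot values symmetric 20 x 20 score matrix (NA where undefined).
#' @slot stderr bootstrap standard errors (NA when not computed).
#' @slot mask logical matrix, TRUE where |value| exceeds its stderr.
#' @slot tau the temperature-like scale factor of the log-odds score.
#' @slot kind one of "norm", "ge", "enrichment".
#' @exportClass PotentialMatrix
setClass("PotentialMatrix",
  representation(values = "matrix", stderr = "matrix", mask = "matrix",
                 tau = "numeric", kind = "character"))

setValidity("PotentialMatrix", function(object) {
  v <- object@values
  if (!all(dim(v) == c(20L, 20L)))
    return("values must be 20 x 20")
  ok <- is.na(v) | is.na(t(v)) | abs(v - t(v)) < 1e-9
  if (!all(ok)) return("values must be symmetric")
  TRUE
})

setMethod("show", "PotentialMatrix", function(object) {
  def <- sum(!is.na(object@values[upper.tri(object@values, diag = TRUE)]))
  cat("PotentialMatrix (", object@kind, "), tau = ", object@tau, ", ",
      def, "/210 pairs defined, range ",
      sprintf("[%.1f, %.1f]", suppressWarnings(min(object@values, na.rm = TRUE)),
              suppressWarnings(max(object@values, na.rm = TRUE))), "\n",
      sep = "")
})

#' Score values of a PotentialMatrix
#' @param pm a \linkS4class{PotentialMatrix}.
#' @return symmetric 20 x 20 numeric matrix.
#' @export
potentialValues <- function(pm) pm@values

#' Bootstrap standard errors of a PotentialMatrix
#' @param pm a \linkS4class{PotentialMatrix}.
#' @return 20 x 20 numeric matrix.
#' @export
potentialStderr <- function(pm) pm@stderr

#' Significance mask of a PotentialMatrix
#' @param pm a \linkS4class{PotentialMatrix}.
#' @return 20 x 20 logical matrix; TRUE where |value| > stderr.
#' @export
potentialMask <- function(pm) pm@mask
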