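# Parsing of PDB/mmCIF files into ChainTrace objects, the chain
# continuity filter, and ensemble streaming.  File parsing is delegated
# to bio3d; this module normalizes its atom tables into the per-residue
# representation the entanglement scan needs.

#' Read a structure file into a ChainTrace
#'
#' Parses a PDB or mmCIF file with bio3d, keeps one chain, drops
#' hydrogens and alternate locations beyond the first, maps common
#' non-canonical residues to their parent amino acid (via
#' \code{bio3d::aa321}; others are labeled \code{"X"} but kept in the
#' geometric trace), and discards residues lacking a Calpha atom.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or
#'   \code{"mmcif"}.
#' @param chain chain identifier; defaults to the first chain present.
#' @param id trace identifier; defaults to the file base name.
#' @return a \linkS4class{ChainTrace}; original residue numbers are in
#'   \code{meta$resno}.
#' @export
readStructure <- function(path, format = c("auto", "pdb", "mmcif"),
                          chain = NULL, id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  pdb <- tryCatch(
    if (format == "mmcif") bio3d::read.cif(path)
    else bio3d::read.pdb(path, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, ": ",
                             conditionMessage(e)))
  atoms <- pdb$atom
  atoms <- atoms[atoms$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (is.null(chain)) chain <- atoms$chain[1L]
  atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  # drop hydrogens
  elem <- atoms$elesy
  if (is.null(elem) || all(is.na(elem)))
    elem <- substr(gsub("^[0-9 ]+", "", atoms$elety), 1L, 1L)
  atoms <- atoms[!(toupper(trimws(elem)) %in% c("H", "D")), , drop = FALSE]
  # first alternate location only
  alt <- atoms$alt
  if (!is.null(alt)) {
    altUse <- atoms[!(alt %in% c("", " ", NA)), , drop = FALSE]
    firstAlt <- if (nrow(altUse)) sort(unique(altUse$alt))[1L] else NULL
    keep <- alt %in% c("", " ", NA) | alt %in% firstAlt
    atoms <- atoms[keep, , drop = FALSE]
  }
  if (nrow(atoms) == 0L) stop("no atoms in selected chain of ", path)
  ins <- atoms$insert
  if (is.null(ins)) ins <- ""
  ins[is.na(ins)] <- ""
  resKey <- paste(atoms$resno, ins, sep = "_")
  resOrder <- unique(resKey)
  calpha <- matrix(NA_real_, 0L, 3L)
  res <- character(); heavy <- list(); side <- list(); resno <- integer()
  backboneNames <- c("N", "CA", "C", "O", "OXT")
  for (rk in resOrder) {
    sub <- atoms[resKey == rk, , drop = FALSE]
    ca <- sub[trimws(sub$elety) == "CA", , drop = FALSE]
    if (nrow(ca) == 0L) next  # residue without Calpha is dropped
    xyz <- as.matrix(sub[, c("x", "y", "z")])
    storage.mode(xyz) <- "double"
    sc <- xyz[!(trimws(sub$elety) %in% backboneNames), , drop = FALSE]
    aa1 <- suppressWarnings(bio3d::aa321(sub$resid[1L]))
    if (is.na(aa1) || !aa1 %in% aminoAcids()) aa1 <- "X"
    calpha <- rbind(calpha, as.numeric(ca[1L, c("x", "y", "z")]))
    res <- c(res, aa1)
    heavy <- c(heavy, list(xyz))
    side <- c(side, list(sc))
    resno <- c(resno, sub$resno[1L])
  }
  if (nrow(calpha) == 0L)
    stop("no Calpha atoms found in ", path)
  if (nrow(calpha) < 2L)
    stop("fewer than 2 residues with Calpha atoms in ", path)
  if (is.null(id)) id <- sub("\\.(pdb|ent|cif)(\\.gz)?$", "",
                             basename(path), ignore.case = TRUE)
  ChainTrace(calpha, id = id, residues = res, heavyAtoms = heavy,
             sidechainAtoms = side,
             meta = list(resno = resno, chain = chain, path = path))
}

#' Chain continuity filter
#'
#' TRUE iff no consecutive Calpha-Calpha distance exceeds
#' \code{gapThreshold} (10 Angstrom by default).  Traces with larger
#' gaps would accrue artificial entanglement across the break and are
#' rejected from ensemble analyses.
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @param gapThreshold maximum allowed consecutive distance (Angstrom).
#' @return logical scalar.
#' @export
passesContinuityFilter <- function(trace, gapThreshold = 10) {
  d <- sqrt(rowSums(diff(calpha(trace))^2))
  all(d <= gapThreshold)
}

#' Load an ensemble of structures
#'
#' Reads every structure from a directory (or a plain-text list file of
#' paths, one per line), applies the continuity filter, and returns the
#' retained ChainTraces.  Unreadable or rejected entries are skipped
#' with a warning.
#'
#' @param source directory, vector of file paths, or a list file.
#' @param format passed to \code{\link{readStructure}}.
#' @param gapThreshold continuity threshold (Angstrom).
#' @return list of \linkS4class{ChainTrace}; skipped entries are
#'   recorded in \code{attr(, "skipped")}.
#' @export
loadEnsemble <- function(source, format = "auto", gapThreshold = 10) {
  paths <- if (length(source) == 1L && dir.exists(source)) {
    list.files(source, pattern = "\\.(pdb|ent|cif)(\\.gz)?$",
               full.names = TRUE, ignore.case = TRUE)
  } else if (length(source) == 1L && file.exists(source) &&
             !grepl("\\.(pdb|ent|cif)(\\.gz)?$", source,
                    ignore.case = TRUE)) {
    readLines(source, warn = FALSE)
  } else as.character(source)
  paths <- paths[nzchar(trimws(paths))]
  if (length(paths) == 0L) {
    warning("empty ensemble source: ", paste(source, collapse = ", "))
    return(list())
  }
  out <- list(); skipped <- character()
  for (p in paths) {
    tr <- tryCatch(readStructure(p, format = format),
                   error = function(e) {
                     warning("skipping ", p, ": ", conditionMessage(e),
                             call. = FALSE)
                     NULL
                   })
    if (is.null(tr)) { skipped <- c(skipped, p); next }
    if (!passesContinuityFilter(tr, gapThreshold)) {
      warning("skipping ", p, ": Calpha gap exceeds ", gapThreshold,
              " A", call. = FALSE)
      skipped <- c(skipped, p)
      next
    }
    out[[length(out) + 1L]] <- tr
  }
  attr(out, "skipped") <- skipped
  out
}

#' Write a ChainTrace as a minimal PDB file
#'
#' Emits one CA ATOM record per residue (plus the remaining heavy atoms
#' when present as distinct coordinates).  Intended for fixtures and
#' round-trip tests; coordinates are written at PDB precision (1e-3 A).
#'
#' @param trace a \linkS4class{ChainTrace}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeTracePDB <- function(trace, path) {
  aa3 <- vapply(residues(trace), function(a) {
    out <- suppressWarnings(bio3d::aa123(a))
    if (is.na(out) || a == "X") "UNK" else out
  }, character(1))
  lines <- character()
  serial <- 0L
  for (i in seq_len(length(trace))) {
    ca <- calpha(trace)[i, ]
    serial <- serial + 1L
    lines <- c(lines, sprintf(
      "ATOM  %5d  CA  %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
      serial, aa3[i], i, ca[1], ca[2], ca[3]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
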