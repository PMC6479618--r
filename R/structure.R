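## Structure container and PDB input/output.
##
## A `dsb_structure` is a light wrapper around an atom table in bio3d
## column conventions (chain, resno, insert, resid, elety, elesy, x, y,
## z, o, b), plus the SEQRES-derived sequence when present. Author
## (auth) residue numbering is the canonical coordinate system
## throughout: residue labels in the literature on this enzyme family
## (e.g. S127, C221) are author numbers.

#' Construct a structure object
#'
#' @param atoms data.frame with columns `chain`, `resno`, `insert`,
#'   `resid` (3-letter residue code), `elety` (PDB atom name), `elesy`
#'   (element symbol), `x`, `y`, `z` (Angstrom), `o` (occupancy), `b`
#'   (B-factor).
#' @param seqres optional named list (by chain) of 3-letter residue code
#'   vectors, as given by SEQRES records.
#' @param identifier free-text structure identifier.
#' @return object of class `dsb_structure`.
#' @export
new_structure <- function(atoms, seqres = NULL, identifier = "") {
  required <- c("chain", "resno", "insert", "resid", "elety", "elesy",
                "x", "y", "z", "o", "b")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) == 0L) stop("no atoms: structure must contain at least one atom")
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("non-finite atom coordinates")
  if (any(atoms$o < 0 | atoms$o > 1, na.rm = TRUE)) {
    stop("occupancy outside [0, 1]")
  }
  if (any(!nzchar(atoms$elety))) stop("empty atom name")
  atoms$insert[is.na(atoms$insert)] <- ""
  rownames(atoms) <- NULL
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety)
  if (anyDuplicated(key)) {
    stop("duplicate atom name within a residue after altloc collapsing")
  }
  structure(
    list(identifier = identifier, atoms = atoms, seqres = seqres),
    class = "dsb_structure"
  )
}

#' @export
print.dsb_structure <- function(x, ...) {
  res <- residue_table(x)
  cat(sprintf("<dsb_structure> %s: %d chain(s), %d residues, %d atoms\n",
              if (nzchar(x$identifier)) x$identifier else "(unnamed)",
              length(unique(x$atoms$chain)), nrow(res), nrow(x$atoms)))
  invisible(x)
}

#' Residue-level summary of a structure
#'
#' @param s a `dsb_structure`.
#' @return data.frame with one row per residue: `chain`, `resno`,
#'   `insert`, `resid`, in file order.
#' @export
residue_table <- function(s) {
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "\r")
  first <- !duplicated(key)
  out <- a[first, c("chain", "resno", "insert", "resid")]
  rownames(out) <- NULL
  out
}

## Coordinates of selected atoms as an N x 3 matrix (with atom metadata
## as attributes dropped). `resno`, `elety`, `chain` are optional
## filters; NULL means no restriction.
structure_coords <- function(s, chain = NULL, resno = NULL, elety = NULL) {
  a <- s$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain %in% chain
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(elety)) keep <- keep & a$elety %in% elety
  as.matrix(a[keep, c("x", "y", "z"), drop = FALSE])
}

## Single-atom lookup; returns the 3-vector or NULL when absent.
atom_xyz <- function(s, chain, resno, elety) {
  a <- s$atoms
  i <- which(a$chain == chain & a$resno == resno & a$elety == elety)
  if (length(i) == 0L) return(NULL)
  as.numeric(a[i[1L], c("x", "y", "z")])
}

## Fast pre-scan of ATOM/HETATM records so that malformed files fail
## with a line number rather than an opaque parser error downstream.
validate_pdb_records <- function(lines) {
  rec <- grepl("^(ATOM  |HETATM)", lines)
  idx <- which(rec)
  for (i in idx) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("unparseable PDB record at line %d: record too short", i))
    }
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords)))) {
      stop(sprintf("unparseable PDB record at line %d: non-numeric coordinates", i))
    }
  }
  invisible(length(idx))
}

## Collapse alternate locations: for each (chain, resno, insert, elety)
## keep the highest-occupancy altloc, ties broken by altloc character
## order. Deterministic and standard practice.
collapse_altlocs <- function(atoms) {
  alt <- atoms$alt
  alt[is.na(alt)] <- ""
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$elety, sep = "\r")
  occ <- atoms$o
  occ[is.na(occ)] <- 1
  ord <- order(key, -occ, alt)
  atoms <- atoms[ord, ]
  atoms <- atoms[!duplicated(key[ord]), ]
  ## restore original file order
  atoms[order(as.integer(rownames(atoms))), ]
}

#' Read a protein structure from a PDB file
#'
#' Reads ATOM records (waters and other HETATM ligands are stripped by
#' default), collapses alternate locations to the highest-occupancy
#' conformer, drops hydrogens, and captures SEQRES when present.
#'
#' @param path PDB file.
#' @param chain optional chain identifier filter (e.g. `"A"`).
#' @param model 1-based model index for multi-model files (default: first).
#' @param keep_hetero keep HETATM ligand/water records (default FALSE).
#' @return a [new_structure()] object.
#' @export
read_structure <- function(path, chain = NULL, model = 1L,
                           keep_hetero = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_records(lines)
  if (!any(grepl("^(ATOM  |HETATM)", lines))) {
    stop("no atoms: file contains no ATOM/HETATM records")
  }
  multi <- sum(grepl("^MODEL ", lines)) > 1L
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  )
  atoms <- pdb$atom
  if (multi) {
    nmod <- nrow(pdb$xyz)
    if (model > nmod) stop("model index ", model, " exceeds ", nmod, " models")
    xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
    atoms$x <- xyz[, 1L]; atoms$y <- xyz[, 2L]; atoms$z <- xyz[, 3L]
  }
  if (!keep_hetero) atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  ## hydrogens are never used by any criterion here
  atoms <- atoms[!(atoms$elesy %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no atoms: selection is empty")
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  rownames(atoms) <- seq_len(nrow(atoms))
  atoms <- collapse_altlocs(atoms)
  atoms <- atoms[, c("chain", "resno", "insert", "resid", "elety", "elesy",
                     "x", "y", "z", "o", "b")]

  seqres <- NULL
  if (!is.null(pdb$seqres) && length(pdb$seqres)) {
    sr <- pdb$seqres
    seqres <- split(unname(sr), names(sr))
    if (!is.null(chain)) seqres <- seqres[names(seqres) %in% chain]
    if (length(seqres) == 0L) seqres <- NULL
  }
  new_structure(atoms, seqres = seqres,
                identifier = sub("\\.pdb$", "", basename(path)))
}

#' Write a structure to a PDB file
#'
#' @param s a `dsb_structure`.
#' @param path output file.
#' @return `path`, invisibly. Coordinates are written at PDB fixed-width
#'   precision (3 decimals); values outside the `%8.3f` field trigger an
#'   error rather than silently corrupting the file.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  coords <- as.matrix(a[, c("x", "y", "z")])
  if (any(coords >= 1e4 | coords <= -1e3)) {
    stop("coordinate exceeds the PDB %8.3f field width")
  }
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(coords)),
                   type = rep("ATOM", nrow(a)),
                   resno = a$resno, resid = a$resid,
                   eleno = seq_len(nrow(a)), elety = a$elety,
                   chain = a$chain, insert = ifelse(nzchar(a$insert), a$insert, ""),
                   o = a$o, b = a$b, elesy = a$elesy)
  invisible(path)
}

#' Detect regions of missing (disordered) residues
#'
#' Residues present in the expected numbering but absent from the
#' coordinate record are crystallographically disordered. Returns the
#' maximal runs of expected-but-absent author residue numbers.
#'
#' @param s a `dsb_structure`.
#' @param expected expected author numbering, either an integer vector
#'   (applied to every chain), a named list of integer vectors per
#'   chain, or `"seqres"` to use `1:length(SEQRES)` per chain.
#' @return data.frame with columns `chain`, `start`, `end` (inclusive
#'   author numbers), sorted by chain then start; zero rows when nothing
#'   is missing.
#' @export
detect_missing_regions <- function(s, expected) {
  chains <- unique(s$atoms$chain)
  if (identical(expected, "seqres")) {
    if (is.null(s$seqres)) stop("structure has no SEQRES records")
    expected <- lapply(s$seqres, function(sr) seq_along(sr))
  }
  if (!is.list(expected)) {
    expected <- stats::setNames(rep(list(as.integer(expected)), length(chains)),
                                chains)
  }
  out <- data.frame(chain = character(), start = integer(), end = integer())
  for (ch in names(expected)) {
    exp_no <- sort(unique(as.integer(expected[[ch]])))
    obs <- unique(s$atoms$resno[s$atoms$chain == ch])
    outside <- setdiff(obs, exp_no)
    if (length(outside)) {
      warning(sprintf("chain %s: observed residue(s) outside expected range: %s",
                      ch, paste(utils::head(outside, 5L), collapse = ", ")))
    }
    missing <- setdiff(exp_no, obs)
    if (length(missing) == 0L) next
    missing <- sort(missing)
    run_start <- c(TRUE, diff(missing) != 1L)
    grp <- cumsum(run_start)
    for (g in unique(grp)) {
      m <- missing[grp == g]
      out <- rbind(out, data.frame(chain = ch, start = min(m), end = max(m)))
    }
  }
  out <- out[order(out$chain, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
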