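## Conformational ensembles: ordered coordinate frames over a fixed atom
## selection, read from multi-model PDB files (the portable stand-in for
## binary MD trajectories). Frame times are assigned from a configured
## saving interval because the PDB format carries no time records.

#' Construct an ensemble object
#'
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns
#'   in x1,y1,z1,x2,... order (bio3d trajectory layout).
#' @param atoms data.frame of per-atom metadata (`chain`, `resno`,
#'   `resid`, `elety`, `elesy`) matching the columns of `xyz`.
#' @param times frame times in ps, strictly increasing.
#' @param temperature temperature label in degrees C (e.g. 26.85, 70, 80).
#' @param reference optional `dsb_structure` used as the external RMSD
#'   reference.
#' @return object of class `dsb_ensemble`.
#' @export
new_ensemble <- function(xyz, atoms, times, temperature = NA_real_,
                         reference = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * nrow(atoms)) {
    stop("xyz column count does not match the atom table")
  }
  if (nrow(xyz) < 1L) stop("ensemble must contain at least one frame")
  if (length(times) != nrow(xyz)) stop("times must match the number of frames")
  if (nrow(xyz) > 1L && any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing")
  }
  rownames(atoms) <- NULL
  structure(
    list(xyz = xyz, atoms = atoms, times = as.numeric(times),
         temperature = temperature, reference = reference),
    class = "dsb_ensemble"
  )
}

#' @export
print.dsb_ensemble <- function(x, ...) {
  cat(sprintf("<dsb_ensemble> %d frames x %d atoms, t = %g..%g ps%s\n",
              n_frames(x), nrow(x$atoms), min(x$times), max(x$times),
              if (is.na(x$temperature)) "" else
                sprintf(", T = %g C", x$temperature)))
  invisible(x)
}

#' Number of frames in an ensemble
#' @param e a `dsb_ensemble`.
#' @export
n_frames <- function(e) nrow(e$xyz)

## N x 3 coordinates of frame i, optionally restricted to an atom index
## vector (rows of e$atoms).
frame_coords <- function(e, i, atom_idx = NULL) {
  m <- matrix(e$xyz[i, ], ncol = 3L, byrow = TRUE)
  if (!is.null(atom_idx)) m <- m[atom_idx, , drop = FALSE]
  m
}

## Indices of atoms matching name set / residue filter.
select_atoms <- function(e, elety = NULL, resno = NULL) {
  keep <- rep(TRUE, nrow(e$atoms))
  if (!is.null(elety)) keep <- keep & e$atoms$elety %in% elety
  if (!is.null(resno)) keep <- keep & e$atoms$resno %in% resno
  which(keep)
}

## Per-model record consistency check: every MODEL block must list the
## same atoms in the same order. Errors name the offending model.
validate_models <- function(lines) {
  model_starts <- grep("^MODEL ", lines)
  if (length(model_starts) <= 1L) return(invisible(1L))
  model_ends <- grep("^ENDMDL", lines)
  if (length(model_ends) != length(model_starts)) {
    stop("unbalanced MODEL/ENDMDL records")
  }
  sig <- function(k) {
    blk <- lines[model_starts[k]:model_ends[k]]
    rec <- blk[grepl("^(ATOM  |HETATM)", blk)]
    substr(rec, 13, 27)  # atom name + resname + chain + resno + icode
  }
  ref_sig <- sig(1L)
  for (k in seq_along(model_starts)[-1L]) {
    sk <- sig(k)
    if (length(sk) != length(ref_sig) || !all(sk == ref_sig)) {
      stop(sprintf("inconsistent atom records in MODEL %d (expected %d atoms matching MODEL 1)",
                   k, length(ref_sig)))
    }
  }
  invisible(length(model_starts))
}

#' Read a conformational ensemble from a multi-model PDB file
#'
#' All models must contain identical atom records in identical order;
#' otherwise the offending model is named in the error. Frame times are
#' assigned as `(0, 1, 2, ...) * frame_interval`.
#'
#' @param path multi-model PDB file (a single-model file yields a
#'   one-frame ensemble).
#' @param selection optional character vector of PDB atom names to
#'   retain (e.g. `c("N", "CA", "C")`); default keeps all heavy atoms.
#' @param frame_interval time between saved frames in ps (default 500).
#' @param temperature temperature label in degrees C.
#' @return a [new_ensemble()] object; `reference` is the first frame as
#'   a `dsb_structure`.
#' @export
read_ensemble <- function(path, selection = NULL, frame_interval = 500,
                          temperature = NA_real_) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_records(lines)
  validate_models(lines)
  multi <- sum(grepl("^MODEL ", lines)) > 1L
  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  )
  atoms <- pdb$atom
  xyz <- if (multi) unclass(pdb$xyz) else matrix(pdb$xyz, nrow = 1L)
  keep <- atoms$type == "ATOM" & !(atoms$elesy %in% c("H", "D"))
  if (!is.null(selection)) keep <- keep & atoms$elety %in% selection
  if (!any(keep)) stop("empty atom selection in ensemble")
  col_idx <- as.vector(rbind(3 * which(keep) - 2, 3 * which(keep) - 1,
                             3 * which(keep)))
  atoms <- atoms[keep, c("chain", "resno", "insert", "resid", "elety",
                         "elesy", "x", "y", "z", "o", "b")]
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  xyz <- xyz[, col_idx, drop = FALSE]
  times <- (seq_len(nrow(xyz)) - 1L) * frame_interval
  ref_atoms <- atoms
  ref_atoms$x <- xyz[1L, seq(1L, ncol(xyz), 3L)]
  ref_atoms$y <- xyz[1L, seq(2L, ncol(xyz), 3L)]
  ref_atoms$z <- xyz[1L, seq(3L, ncol(xyz), 3L)]
  reference <- new_structure(ref_atoms,
                             identifier = sub("\\.pdb$", "", basename(path)))
  new_ensemble(xyz, atoms, times, temperature = temperature,
               reference = reference)
}

#' Write an ensemble as a multi-model PDB file
#'
#' @param e a `dsb_ensemble`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ensemble <- function(e, path) {
  a <- e$atoms
  if (any(e$xyz >= 1e4 | e$xyz <= -1e3)) {
    stop("coordinate exceeds the PDB %8.3f field width")
  }
  con <- file(path, "w")
  on.exit(close(con))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  for (i in seq_len(n_frames(e))) {
    coords <- frame_coords(e, i)
    bio3d::write.pdb(file = tmp,
                     xyz = as.vector(t(coords)),
                     type = rep("ATOM", nrow(a)),
                     resno = a$resno, resid = a$resid,
                     eleno = seq_len(nrow(a)), elety = a$elety,
                     chain = a$chain, o = a$o, b = a$b, elesy = a$elesy)
    rec <- readLines(tmp, warn = FALSE)
    rec <- rec[!grepl("^END", rec)]
    writeLines(sprintf("MODEL     %4d", i), con)
    writeLines(rec, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

## Structure -> one-frame ensemble helper used by the synthetic module.
structure_to_xyz <- function(s) {
  as.vector(t(as.matrix(s$atoms[, c("x", "y", "z")])))
}
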