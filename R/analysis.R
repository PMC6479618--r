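## Stability metrics over conformational ensembles: superposed backbone
## RMSD, radius of gyration, and disulfide S-S distance retention.

.backbone_atoms <- c("N", "CA", "C")

#' Backbone RMSD series over an ensemble
#'
#' Per-frame least-squares (Kabsch) superposed RMSD of the backbone
#' selection against a reference: either the first frame or the
#' ensemble's external reference structure.
#'
#' @param e a `dsb_ensemble`.
#' @param reference_mode `"first_frame"` (default) or
#'   `"external_reference"` (uses `e$reference`).
#' @param selection atom names of the backbone selection (default
#'   `c("N", "CA", "C")`).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(e, reference_mode = c("first_frame",
                                              "external_reference"),
                        selection = .backbone_atoms) {
  reference_mode <- match.arg(reference_mode)
  idx <- select_atoms(e, elety = selection)
  if (length(idx) == 0L) stop("empty backbone selection")
  if (reference_mode == "first_frame") {
    ref <- frame_coords(e, 1L, idx)
  } else {
    if (is.null(e$reference)) stop("ensemble has no external reference")
    ref <- ref_selection_coords(e, selection)
  }
  vapply(seq_len(n_frames(e)), function(i) {
    kabsch_superpose(ref, frame_coords(e, i, idx))$rmsd
  }, numeric(1L))
}

## Reference-structure coordinates matched to the ensemble's atom order.
ref_selection_coords <- function(e, selection) {
  idx <- select_atoms(e, elety = selection)
  meta <- e$atoms[idx, ]
  out <- matrix(NA_real_, length(idx), 3L)
  for (k in seq_along(idx)) {
    p <- atom_xyz(e$reference, meta$chain[k], meta$resno[k], meta$elety[k])
    if (is.null(p)) {
      stop(sprintf("reference lacks atom %s of residue %s %d",
                   meta$elety[k], meta$chain[k], meta$resno[k]))
    }
    out[k, ] <- p
  }
  out
}

#' Radius-of-gyration series over an ensemble
#'
#' Mass-weighted by default (standard atomic masses by element); no
#' superposition is applied because Rg is a centre-of-mass-relative
#' quantity.
#'
#' @param e a `dsb_ensemble`.
#' @param mass_weighted use atomic masses (default TRUE) or uniform
#'   weights.
#' @return numeric vector, one Rg (Angstrom) per frame.
#' @export
rg_series <- function(e, mass_weighted = TRUE) {
  masses <- if (mass_weighted) element_mass(e$atoms$elesy) else
    rep(1, nrow(e$atoms))
  vapply(seq_len(n_frames(e)), function(i) {
    radius_of_gyration(frame_coords(e, i), masses)
  }, numeric(1L))
}

#' Disulfide S-S distance series
#'
#' Euclidean SG-SG distance per frame for each bond. No superposition:
#' interatomic distances are internal coordinates.
#'
#' @param e a `dsb_ensemble`; the SG atoms of both residues must be in
#'   the ensemble's atom selection.
#' @param bonds data.frame with columns `res_i`, `res_j` (author residue
#'   numbers; optional `chain_i`, `chain_j`), or a list of 2-vectors.
#' @return named list, one numeric distance vector (Angstrom) per bond;
#'   names are `"res_i-res_j"`.
#' @export
ss_distance_series <- function(e, bonds) {
  bonds <- as_bond_table(bonds)
  out <- list()
  for (k in seq_len(nrow(bonds))) {
    idx_i <- which(e$atoms$resno == bonds$res_i[k] & e$atoms$elety == "SG")
    idx_j <- which(e$atoms$resno == bonds$res_j[k] & e$atoms$elety == "SG")
    if (length(idx_i) == 0L) {
      stop(sprintf("SG atom missing for residue %d", bonds$res_i[k]))
    }
    if (length(idx_j) == 0L) {
      stop(sprintf("SG atom missing for residue %d", bonds$res_j[k]))
    }
    d <- vapply(seq_len(n_frames(e)), function(f) {
      m <- frame_coords(e, f, c(idx_i[1L], idx_j[1L]))
      vnorm(m[1L, ] - m[2L, ])
    }, numeric(1L))
    out[[sprintf("%d-%d", bonds$res_i[k], bonds$res_j[k])]] <- d
  }
  out
}

as_bond_table <- function(bonds) {
  if (is.data.frame(bonds)) return(bonds)
  if (is.numeric(bonds) && length(bonds) == 2L) {
    bonds <- list(bonds)
  }
  do.call(rbind, lapply(bonds, function(b) {
    data.frame(res_i = as.integer(b[[1L]]), res_j = as.integer(b[[2L]]))
  }))
}

#' Fraction of frames in which a disulfide is retained
#'
#' A bond is considered retained in a frame when its SG-SG distance is
#' at most `threshold`; a bond is "stable" over the ensemble iff the
#' retention fraction is exactly 1.
#'
#' @param series numeric vector of per-frame SG-SG distances (Angstrom).
#' @param threshold retention threshold in Angstrom (default 2.15).
#' @return fraction in \[0, 1\].
#' @export
ss_retention <- function(series, threshold = 2.15) {
  if (length(series) == 0L) stop("empty distance series")
  mean(series <= threshold)
}

#' Full stability report for one ensemble
#'
#' @param e a `dsb_ensemble`.
#' @param bonds optional disulfide bonds for [ss_distance_series()].
#' @param reference_mode passed to [rmsd_series()].
#' @param ss_threshold retention threshold (Angstrom, default 2.15).
#' @param label free-text structure label for summaries.
#' @return object of class `dsb_stability_report`: per-frame `rmsd`,
#'   `rg`, `ss` series, per-bond `ss_retention`, and summary
#'   statistics.
#' @export
stability_report <- function(e, bonds = NULL,
                             reference_mode = "first_frame",
                             ss_threshold = 2.15, label = "") {
  rmsd <- rmsd_series(e, reference_mode)
  rg <- rg_series(e)
  ss <- if (!is.null(bonds)) ss_distance_series(e, bonds) else list()
  retention <- vapply(ss, ss_retention, numeric(1L),
                      threshold = ss_threshold)
  structure(
    list(label = label, temperature = e$temperature, times = e$times,
         rmsd = rmsd, rg = rg, ss = ss, ss_retention = retention,
         ss_threshold = ss_threshold,
         n_frames = n_frames(e)),
    class = "dsb_stability_report"
  )
}

#' @export
print.dsb_stability_report <- function(x, ...) {
  cat(sprintf("<stability report> %s (%g C): %d frames, mean RMSD %.2f A, mean Rg %.2f A\n",
              if (nzchar(x$label)) x$label else "(unnamed)",
              x$temperature, x$n_frames, mean(x$rmsd), mean(x$rg)))
  if (length(x$ss_retention)) {
    for (b in names(x$ss_retention)) {
      cat(sprintf("  S-S %s: retention %.3f at %.2f A\n", b,
                  x$ss_retention[[b]], x$ss_threshold))
    }
  }
  invisible(x)
}

#' Summarise stability reports across structures and temperatures
#'
#' One row per report: mean/sd of RMSD and Rg, per-bond retention, and
#' an instability flag. The flag fires when the mean RMSD over the
#' final 20% of frames exceeds 1.5 times the mean over the first 20%
#' (a documented drift heuristic); single-frame ensembles are never
#' flagged and report zero spread.
#'
#' @param reports list of [stability_report()] objects.
#' @return data.frame comparison table.
#' @export
summarize_stability <- function(reports) {
  if (length(reports) == 0L) stop("need at least one report")
  if (inherits(reports, "dsb_stability_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    nf <- r$n_frames
    flag <- FALSE
    if (nf > 1L) {
      k <- max(1L, floor(0.2 * nf))
      head_mean <- mean(r$rmsd[seq_len(k)])
      tail_mean <- mean(r$rmsd[(nf - k + 1L):nf])
      flag <- tail_mean > 1.5 * head_mean
    }
    data.frame(
      label = r$label,
      temperature = r$temperature,
      n_frames = nf,
      rmsd_mean = mean(r$rmsd),
      rmsd_sd = if (nf > 1L) stats::sd(r$rmsd) else 0,
      rg_mean = mean(r$rg),
      rg_sd = if (nf > 1L) stats::sd(r$rg) else 0,
      ss_retention_min = if (length(r$ss_retention))
        min(r$ss_retention) else NA_real_,
      unstable = flag
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
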