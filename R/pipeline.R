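## End-to-end pipelines behind the command-line scripts in
## inst/scripts/: structure scan, ensemble stability analysis, and
## primer table checking. Reports are written as TSV plus a JSON
## companion that echoes the full configuration for provenance.

#' Scan a structure for disulfide candidates
#'
#' Runs the full design pipeline: read (or accept) a structure, detect
#' native disulfides and missing regions, enumerate Cbeta-Cbeta
#' feasible pairs, model each bridge over the chi1 grid, score with the
#' strain and interaction surrogates, classify quality, annotate
#' filters, and rank.
#'
#' @param structure a `dsb_structure` or a PDB file path.
#' @param cfg a [design_config()].
#' @param chain optional chain filter applied when reading from file.
#' @param expected_numbering optional expected author numbering for
#'   missing-region detection (`"seqres"`, integer vector, or NULL to
#'   use the observed min..max range).
#' @return list of class `dsb_scan` with `candidates` (ranked
#'   data.frame), `native` (native disulfide table), `disordered`
#'   (missing regions), and `config`.
#' @export
scan_disulfides <- function(structure, cfg = design_config(), chain = NULL,
                            expected_numbering = NULL) {
  s <- if (inherits(structure, "dsb_structure")) structure else
    read_structure(structure, chain = chain)
  native <- detect_native_disulfides(s, max_ss = cfg$native_ss_max)
  if (is.null(expected_numbering)) {
    rt <- residue_table(s)
    expected_numbering <- lapply(split(rt$resno, rt$chain),
                                 function(r) seq(min(r), max(r)))
  }
  disordered <- detect_missing_regions(s, expected_numbering)
  cands <- enumerate_pairs(s, cfg)
  if (nrow(cands)) {
    extra <- lapply(seq_len(nrow(cands)), function(k) {
      pair <- cands[k, ]
      m <- model_disulfide(s, pair, cfg)
      ei <- interaction_energy(s, m$sg_i, m$sg_j, pair, cfg)
      data.frame(d_ss = m$d_ss, chi1_i = m$chi1_i, chi1_j = m$chi1_j,
                 chi3 = m$chi3, e_strain = m$e_strain, e_interaction = ei,
                 quality = classify_quality(ei, m$e_strain))
    })
    cands <- cbind(cands, do.call(rbind, extra))
  } else {
    cands <- cbind(cands, data.frame(d_ss = numeric(), chi1_i = numeric(),
                                     chi1_j = numeric(), chi3 = numeric(),
                                     e_strain = numeric(),
                                     e_interaction = numeric(),
                                     quality = character()))
  }
  cands <- apply_filters(cands, s, cfg, disordered = disordered,
                         native = native)
  cands <- rank_candidates(cands)
  structure(list(structure = s, candidates = cands, native = native,
                 disordered = disordered, config = cfg),
            class = "dsb_scan")
}

#' @export
print.dsb_scan <- function(x, ...) {
  cat(sprintf("<dsb_scan> %s: %d candidate pair(s), %d native disulfide(s), %d missing region(s)\n",
              x$structure$identifier, nrow(x$candidates), nrow(x$native),
              nrow(x$disordered)))
  if (nrow(x$candidates)) {
    print(utils::head(x$candidates[, c("rank", "res_i", "aa_i", "res_j",
                                       "aa_j", "d_cb", "d_ss", "e_strain",
                                       "e_interaction", "quality")], 10L))
  }
  invisible(x)
}

#' Write a scan report as TSV and JSON
#'
#' @param scan a [scan_disulfides()] result.
#' @param out output stem; writes `<out>.tsv` (candidate table) and
#'   `<out>.json` (candidates plus native bonds, missing regions and the
#'   configuration echo).
#' @return named character vector of the paths written, invisibly.
#' @export
write_scan_report <- function(scan, out) {
  tsv <- paste0(out, ".tsv")
  json <- paste0(out, ".json")
  utils::write.table(scan$candidates, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(
    list(structure = scan$structure$identifier,
         candidates = scan$candidates,
         native_disulfides = scan$native,
         disordered_regions = scan$disordered,
         config = unclass(scan$config)),
    json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(tsv = tsv, json = json))
}

#' Analyse one or more ensembles for structural stability
#'
#' @param paths named character vector of multi-model PDB files (names
#'   become structure labels) or a list of `dsb_ensemble` objects.
#' @param bonds optional disulfide bond table for S-S retention.
#' @param reference optional external reference structure (or file)
#'   used for RMSD; default is each ensemble's first frame.
#' @param ss_threshold S-S retention threshold (Angstrom, default 2.15).
#' @param frame_interval frame spacing in ps for file input.
#' @param temperatures optional numeric vector of temperature labels
#'   matching `paths`.
#' @return list with `reports` (per-ensemble [stability_report()]) and
#'   `summary` (the [summarize_stability()] table).
#' @export
analyze_ensembles <- function(paths, bonds = NULL, reference = NULL,
                              ss_threshold = 2.15, frame_interval = 500,
                              temperatures = NULL) {
  if (!is.null(reference) && !inherits(reference, "dsb_structure")) {
    reference <- read_structure(reference)
  }
  labels <- names(paths)
  if (is.null(labels)) labels <- paste0("ensemble", seq_along(paths))
  reports <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    e <- paths[[k]]
    if (!inherits(e, "dsb_ensemble")) {
      e <- read_ensemble(e, frame_interval = frame_interval,
                         temperature = if (!is.null(temperatures))
                           temperatures[k] else NA_real_)
    }
    mode <- "first_frame"
    if (!is.null(reference)) {
      e$reference <- reference
      mode <- "external_reference"
    }
    reports[[k]] <- stability_report(e, bonds = bonds,
                                     reference_mode = mode,
                                     ss_threshold = ss_threshold,
                                     label = labels[k])
  }
  list(reports = reports, summary = summarize_stability(reports))
}

#' Write a stability analysis report as TSV and JSON
#'
#' @param analysis an [analyze_ensembles()] result.
#' @param out output stem; writes `<out>.tsv` (summary table) and
#'   `<out>.json` (summary plus per-frame series).
#' @return named character vector of the paths written, invisibly.
#' @export
write_analysis_report <- function(analysis, out) {
  tsv <- paste0(out, ".tsv")
  json <- paste0(out, ".json")
  utils::write.table(analysis$summary, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  series <- lapply(analysis$reports, function(r) {
    list(label = r$label, temperature = r$temperature, times = r$times,
         rmsd = r$rmsd, rg = r$rg, ss = r$ss,
         ss_retention = as.list(r$ss_retention),
         ss_threshold = r$ss_threshold)
  })
  jsonlite::write_json(list(summary = analysis$summary, series = series),
                       json, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(tsv = tsv, json = json))
}
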