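## Mutagenic primer table verification: strand consistency between
## forward and reverse primers and presence of a cysteine codon.
## Verdicts are always recomputed, never trusted from input.

.dna_complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Reverse complement of a DNA sequence
#'
#' Case-insensitive on input, uppercased on output. Only A/C/G/T are
#' accepted (these are DNA primers; U is rejected).
#'
#' @param seq character scalar, 5'-to-3' DNA.
#' @return the reverse-complemented sequence, 5'-to-3'.
#' @examples
#' reverse_complement("AACGT")  # "ACGTT"
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (!nzchar(s)) stop("empty sequence")
  chars <- strsplit(s, "")[[1L]]
  bad <- which(!(chars %in% names(.dna_complement)))
  if (length(bad)) {
    stop(sprintf("invalid DNA character '%s' at position %d",
                 chars[bad[1L]], bad[1L]))
  }
  paste(rev(.dna_complement[chars]), collapse = "")
}

#' Verify a forward/reverse mutagenic primer pair
#'
#' Recomputes two verdicts. `revcomp_exact` is strict string equality
#' `rev == reverse_complement(fwd)`. `is_revcomp_consistent` is
#' annealing consistency: one of the two strands is a contiguous
#' sub-sequence of the other's reverse complement, i.e. the pair anneals
#' perfectly over its full overlap even when the primers differ in
#' length by a few terminal bases (published primer tables commonly
#' truncate one strand). `has_cys_codon` checks the forward primer for a
#' TGT/TGC substring; the check is frame-agnostic because the gene
#' sequence, and hence the reading frame, is not part of the table (a
#' documented limitation).
#'
#' @param fwd,rev forward and reverse primer sequences (5'-to-3').
#' @param mutation optional mutation label (e.g. `"S127C"`).
#' @return list with `mutation`, `fwd`, `rev`, `revcomp_exact`,
#'   `is_revcomp_consistent`, `has_cys_codon`.
#' @export
verify_pair <- function(fwd, rev, mutation = "") {
  fwd <- toupper(fwd)
  rev <- toupper(rev)
  rc <- reverse_complement(fwd)
  ## validates rev's alphabet as a side effect
  invisible(reverse_complement(rev))
  exact <- identical(rev, rc)
  consistent <- exact || grepl(rev, rc, fixed = TRUE) ||
    grepl(rc, rev, fixed = TRUE)
  list(mutation = mutation, fwd = fwd, rev = rev,
       revcomp_exact = exact,
       is_revcomp_consistent = consistent,
       has_cys_codon = grepl("TGT", fwd, fixed = TRUE) ||
         grepl("TGC", fwd, fixed = TRUE))
}

#' Check a mutagenic primer table
#'
#' Reads a TSV with columns `mutation`, `primer_name`, `sequence`
#' (primer names carry `-fwd`/`-rev` suffixes; the mutation label may be
#' blank on continuation rows, as in published tables), pairs rows by
#' mutation, and recomputes all verdicts. Row order does not affect the
#' verdicts.
#'
#' @param path TSV file.
#' @return list with `n_pairs`, `n_consistent`, `n_exact`,
#'   `n_cys_codon`, and `pairs` (data.frame of per-pair verdicts).
#' @export
check_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("mutation", "primer_name", "sequence")
  if (!all(needed %in% names(tab))) {
    stop("primer table must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(tab) == 0L) {
    return(list(n_pairs = 0L, n_consistent = 0L, n_exact = 0L,
                n_cys_codon = 0L,
                pairs = data.frame(mutation = character(),
                                   is_revcomp_consistent = logical(),
                                   revcomp_exact = logical(),
                                   has_cys_codon = logical())))
  }
  ## fill blank mutation labels from the preceding row
  mut <- tab$mutation
  for (i in seq_along(mut)) {
    if (!nzchar(trimws(mut[i])) && i > 1L) mut[i] <- mut[i - 1L]
  }
  tab$mutation <- trimws(mut)
  tab$role <- ifelse(grepl("-fwd$", tab$primer_name), "fwd",
                     ifelse(grepl("-rev$", tab$primer_name), "rev", NA))
  if (anyNA(tab$role)) {
    stop("primer names must end in -fwd or -rev; offending: ",
         paste(tab$primer_name[is.na(tab$role)], collapse = ", "))
  }
  orphans <- character()
  rows <- list()
  for (m in unique(tab$mutation)) {
    sub <- tab[tab$mutation == m, ]
    f <- sub$sequence[sub$role == "fwd"]
    r <- sub$sequence[sub$role == "rev"]
    if (length(f) != 1L || length(r) != 1L) {
      orphans <- c(orphans, m)
      next
    }
    v <- verify_pair(f, r, mutation = m)
    rows[[m]] <- data.frame(mutation = m,
                            is_revcomp_consistent = v$is_revcomp_consistent,
                            revcomp_exact = v$revcomp_exact,
                            has_cys_codon = v$has_cys_codon)
  }
  if (length(orphans)) {
    stop("unpaired primer(s) for mutation(s): ",
         paste(orphans, collapse = ", "))
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  list(n_pairs = nrow(pairs),
       n_consistent = sum(pairs$is_revcomp_consistent),
       n_exact = sum(pairs$revcomp_exact),
       n_cys_codon = sum(pairs$has_cys_codon),
       pairs = pairs)
}
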