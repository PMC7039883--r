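.aa_alphabet <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Position frequency matrix of down-regulated phosphosites
#'
#' Extracts a sequence window around every fully localized S/T phosphosite of
#' the down-regulated peptides and tallies residues per position. Windows are
#' centered on the phosphosite and padded with the gap symbol `"-"` where
#' they run past a protein terminus; frequencies are computed per column
#' excluding gaps. With GSK3 substrates the matrix recovers the canonical
#' S/T-X-X-X-pS/pT consensus: S or T modal at the center (offset 0) and at
#' offset +4, the priming phosphosite.
#'
#' @param records phosphopeptide records.
#' @param regulated_down character vector of down-regulated peptide ids
#'   (e.g. `table$peptide_id[table$direction == "down"]`).
#' @param protein_sequences named character vector, accession -> full protein
#'   sequence.
#' @param window odd window length >= 9 (default 13, i.e. site +/- 6).
#' @return an object of class `"motif_matrix"`: list with `counts` and
#'   `frequencies` (residue x offset matrices, offsets `-6..+6` for the
#'   default window), `window`, `n_windows`, `n_skipped` (sites whose
#'   position fell outside their protein sequence, skipped with a warning).
#' @examples
#' seqs <- c(P1 = "AAAASGGGTPAAA")
#' rec <- tibble::tibble(
#'   peptide_id = "p1", sequence = "AAAASGGGT", protein_ids = list("P1"),
#'   gene_symbol = "G1",
#'   phosphosites = list(data.frame(residue = "S", position = 5L,
#'                                  localized = TRUE)),
#'   decoy = FALSE, experiment_ids = list(c("E1", "E2")))
#' extract_motif_matrix(rec, "p1", seqs)
#' @export
extract_motif_matrix <- function(records, regulated_down, protein_sequences,
                                 window = 13L) {
  if (window < 9L || window %% 2L == 0L) {
    abort("window must be an odd integer >= 9",
          class = "crmp2screen_argument_error")
  }
  half <- (window - 1L) %/% 2L
  offsets <- -half:half
  counts <- matrix(0L, nrow = length(.aa_alphabet) + 1L, ncol = window,
                   dimnames = list(c(.aa_alphabet, "-"), offsets))
  n_windows <- 0L
  n_skipped <- 0L
  idx <- which(records$peptide_id %in% regulated_down)
  for (i in idx) {
    accs <- records$protein_ids[[i]]
    acc <- accs[accs %in% names(protein_sequences)][1]
    if (is.na(acc)) {
      n_skipped <- n_skipped + 1L
      next
    }
    seq_chars <- strsplit(protein_sequences[[acc]], "")[[1]]
    ps <- records$phosphosites[[i]]
    ps <- ps[ps$localized & ps$residue %in% c("S", "T"), , drop = FALSE]
    for (j in seq_len(nrow(ps))) {
      pos <- ps$position[j]
      if (pos < 1L || pos > length(seq_chars)) {
        n_skipped <- n_skipped + 1L
        next
      }
      win <- vapply(pos + offsets, function(p) {
        if (p < 1L || p > length(seq_chars)) "-" else seq_chars[p]
      }, character(1))
      keep <- win %in% rownames(counts)
      for (k in which(keep)) {
        counts[win[k], k] <- counts[win[k], k] + 1L
      }
      n_windows <- n_windows + 1L
    }
  }
  if (n_skipped > 0L) {
    warn(paste0(n_skipped, " site(s) skipped (missing sequence or position ",
                "outside protein)"),
         class = "crmp2screen_motif_skip")
  }
  aa_counts <- counts[.aa_alphabet, , drop = FALSE]
  col_tot <- colSums(aa_counts)
  freqs <- sweep(aa_counts, 2L, pmax(col_tot, 1L), "/")
  freqs[, col_tot == 0L] <- NA_real_
  structure(list(counts = counts, frequencies = freqs, window = window,
                 n_windows = n_windows, n_skipped = n_skipped),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("Phospho-motif position frequency matrix\n")
  cat("  windows:", x$n_windows, " window length:", x$window,
      " skipped sites:", x$n_skipped, "\n")
  modal <- apply(x$frequencies, 2L, function(col) {
    if (all(is.na(col))) "-" else rownames(x$frequencies)[which.max(col)]
  })
  cat("  modal residues:", paste(modal, collapse = " "), "\n")
  invisible(x)
}

#' Write a motif matrix as position x residue TSV
#'
#' @param motif a `motif_matrix`.
#' @param path output TSV path.
#' @param what `"frequencies"` (default) or `"counts"`.
#' @return `path`, invisibly.
#' @export
write_motif_matrix <- function(motif, path,
                               what = c("frequencies", "counts")) {
  what <- match.arg(what)
  m <- t(motif[[what]])
  out <- data.frame(offset = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
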