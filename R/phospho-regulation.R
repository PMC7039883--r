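#' Median-normalize SILAC ratios into log2 space
#'
#' Transforms each treated/control ratio channel to log2 and centers it so
#' that the median over peptides quantified in that channel is exactly zero.
#' Missing cells stay missing. A channel with no quantified peptides is left
#' untouched with a warning.
#'
#' @param records filtered phosphopeptide tibble
#'   (see [filter_phosphopeptides()]).
#' @return a regulation table: a tibble with `peptide_id` and one
#'   `log2_<condition>_r<replicate>` column per channel, carrying the applied
#'   per-channel median shifts in attribute `"median_shift"`.
#' @examples
#' tbl <- generate_phospho_table(phospho_spec(n_peptides = 20, seed = 1))
#' reg <- normalize_ratios(filter_phosphopeptides(tbl$records))
#' @export
normalize_ratios <- function(records) {
  out <- tibble::tibble(peptide_id = records$peptide_id)
  shifts <- c()
  for (cond in .conditions) {
    for (rep_i in .replicates) {
      rc <- ratio_col(cond, rep_i)
      lc <- log2_col(cond, rep_i)
      lg <- log2(records[[rc]])
      if (all(is.na(lg))) {
        warn(paste0("channel ", rc, " has no quantified peptides; skipped"),
             class = "crmp2screen_empty_channel")
        out[[lc]] <- lg
        shifts[lc] <- NA_real_
        next
      }
      m <- median(lg, na.rm = TRUE)
      out[[lc]] <- lg - m
      shifts[lc] <- m
    }
  }
  structure(out, median_shift = shifts)
}

# Two-sided one-sample t-test of replicate log2 ratios against zero.
# Conventions for degenerate inputs: all values exactly 0 -> p = 1;
# zero spread around a nonzero mean -> p = 0 (|t| infinite).
one_sample_p <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2L) return(NA_real_)
  if (all(x == 0)) return(1)
  s <- sd(x)
  if (s == 0) return(0)
  tstat <- mean(x) / (s / sqrt(n))
  2 * pt(-abs(tstat), df = n - 1)
}

#' Call regulated phosphopeptides for one treatment condition
#'
#' Scores each peptide with a two-sided one-sample t-test of its replicate
#' normalized log2 ratios against zero, then controls the false discovery
#' rate over all scored peptides with Benjamini-Hochberg. Peptides with fewer
#' than two replicate values in the tested condition are flagged unscored
#' (`p_nom = NA`), never silently dropped; their `mean_log2` is still
#' reported from whatever replicates exist.
#'
#' With only two replicates the per-peptide t-test has a single degree of
#' freedom and little power (the nominal-significant set is far larger than
#' the corrected one). `method = "moderated"` swaps in limma's
#' empirical-Bayes moderated t-statistic, which borrows variance information
#' across peptides and restores power at this replicate depth.
#'
#' @param table regulation table from [normalize_ratios()].
#' @param condition condition to test (default `"CHIR_10uM"`).
#' @param alpha adjusted-significance level (default 0.05).
#' @param method `"t"` for the per-peptide one-sample t-test (default) or
#'   `"moderated"` for limma's moderated one-sample test.
#' @param p_adjust_method correction method passed to [stats::p.adjust()]
#'   (default `"BH"`).
#' @return `table` with columns `mean_log2`, `n_rep`, `p_nom`, `p_adj`,
#'   `significant` (`p_adj < alpha`) and `direction` (`"up"`, `"down"`, or
#'   `"none"` when not significant), plus attributes `"condition"` and
#'   `"alpha"`.
#' @examples
#' tbl <- generate_phospho_table(phospho_spec(n_peptides = 200, seed = 3))
#' reg <- test_regulation(normalize_ratios(filter_phosphopeptides(tbl$records)))
#' table(reg$significant)
#' @export
test_regulation <- function(table, condition = "CHIR_10uM", alpha = 0.05,
                            method = c("t", "moderated"),
                            p_adjust_method = "BH") {
  stopifnot(condition %in% .conditions)
  method <- match.arg(method)
  cols <- log2_col(condition)
  vals <- as.matrix(table[, cols])
  table$n_rep <- rowSums(!is.na(vals))
  table$mean_log2 <- rowMeans(vals, na.rm = TRUE)
  table$mean_log2[table$n_rep == 0L] <- NA_real_
  if (method == "t") {
    table$p_nom <- apply(vals, 1L, one_sample_p)
  } else {
    table$p_nom <- moderated_p(vals)
  }
  table$p_adj <- NA_real_
  scored <- !is.na(table$p_nom)
  table$p_adj[scored] <- p.adjust(table$p_nom[scored],
                                  method = p_adjust_method)
  table$significant <- !is.na(table$p_adj) & table$p_adj < alpha
  table$direction <- ifelse(!table$significant, "none",
                            ifelse(table$mean_log2 < 0, "down", "up"))
  structure(table, condition = condition, alpha = alpha,
            median_shift = attr(table, "median_shift"))
}

# limma one-sample moderated test on the replicate matrix; rows with < 2
# replicates come back NA (unscored), matching the plain t-test path.
moderated_p <- function(vals) {
  p <- rep(NA_real_, nrow(vals))
  scored <- rowSums(!is.na(vals)) >= 2L
  if (!any(scored)) return(p)
  fit <- limma::lmFit(vals[scored, , drop = FALSE],
                      design = matrix(1, ncol(vals), 1))
  fit <- limma::eBayes(fit)
  p[scored] <- fit$p.value[, 1]
  p
}

#' Count regulated phosphopeptides per protein
#'
#' Counts distinct regulated phosphopeptides for each protein, merging
#' configured accession groups into one key (by default GSK3A/GSK3B, whose
#' peptides are shared between the two paralogs). Peptides mapping to several
#' accessions outside any merge group are assigned to their first accession.
#'
#' @param table regulation table scored by [test_regulation()].
#' @param records the phosphopeptide records the table was derived from.
#' @param min_peptides only proteins with at least this many regulated
#'   peptides are returned (default 1; must be >= 1).
#' @param merge_groups list of character vectors of accessions to merge;
#'   group labels are the accessions joined with `"/"`.
#' @param criterion `"nominal"` counts peptides with `p_nom < level`;
#'   `"adjusted"` counts peptides flagged `significant`.
#' @param level nominal-p cut used when `criterion = "nominal"`
#'   (default 0.05).
#' @return a tibble with `protein_key`, `gene_symbol`, and
#'   `n_regulated_peptides`, sorted by count (decreasing) then key.
#' @export
count_regulated_per_protein <- function(table, records, min_peptides = 1L,
                                        merge_groups = list(c("GSK3A", "GSK3B")),
                                        criterion = c("nominal", "adjusted"),
                                        level = 0.05) {
  if (min_peptides < 1L) {
    abort("min_peptides must be >= 1", class = "crmp2screen_argument_error")
  }
  criterion <- match.arg(criterion)
  regulated_ids <- if (criterion == "nominal") {
    table$peptide_id[!is.na(table$p_nom) & table$p_nom < level]
  } else {
    table$peptide_id[table$significant]
  }
  idx <- match(regulated_ids, records$peptide_id)
  idx <- idx[!is.na(idx)]
  if (!length(idx)) {
    return(tibble::tibble(protein_key = character(),
                          gene_symbol = character(),
                          n_regulated_peptides = integer()))
  }
  assign_key <- function(accessions) {
    for (grp in merge_groups) {
      if (any(accessions %in% grp)) return(paste(grp, collapse = "/"))
    }
    accessions[1]
  }
  keys <- vapply(records$protein_ids[idx], assign_key, character(1))
  genes <- records$gene_symbol[idx]
  counts <- tapply(records$peptide_id[idx], keys,
                   function(ids) length(unique(ids)))
  gene_of <- tapply(genes, keys, function(g) g[1])
  out <- tibble::tibble(
    protein_key = names(counts),
    gene_symbol = as.character(gene_of[names(counts)]),
    n_regulated_peptides = as.integer(counts)
  )
  out <- out[out$n_regulated_peptides >= min_peptides, ]
  out[order(-out$n_regulated_peptides, out$protein_key), ]
}

#' Query normalized log2 ratios for a phosphosite
#'
#' Looks up all peptides mapped to a protein that carry a given phosphosite
#' and returns their per-channel normalized log2 ratios in long format. An
#' empty result (zero rows) is the typed "not found" outcome, not an error.
#'
#' @param table regulation table from [normalize_ratios()] (scored or not).
#' @param records matching phosphopeptide records.
#' @param protein_key accession or gene symbol to match.
#' @param site site given as `"S9"`-style string or a list/vector
#'   `(residue, position)`.
#' @return a tibble with `peptide_id`, `condition`, `replicate`,
#'   `log2_ratio` (quantified channels only).
#' @examples
#' tbl <- generate_phospho_table(phospho_spec(n_peptides = 20, seed = 1))
#' reg <- normalize_ratios(filter_phosphopeptides(tbl$records))
#' site_ratio_query(reg, tbl$records, "GSK3B", "S9")
#' @export
site_ratio_query <- function(table, records, protein_key, site) {
  if (is.character(site) && length(site) == 1L) {
    residue <- substr(site, 1, 1)
    position <- as.integer(substr(site, 2, nchar(site)))
  } else {
    residue <- as.character(site[[1]])
    position <- as.integer(site[[2]])
  }
  hit <- vapply(seq_len(nrow(records)), function(i) {
    prot_ok <- protein_key %in% records$protein_ids[[i]] ||
      identical(records$gene_symbol[i], protein_key)
    if (!prot_ok) return(FALSE)
    ps <- records$phosphosites[[i]]
    any(ps$residue == residue & ps$position == position)
  }, logical(1))
  ids <- records$peptide_id[hit]
  sub <- table[table$peptide_id %in% ids, c("peptide_id", log2_col())]
  long <- tidyr::pivot_longer(sub, cols = -"peptide_id",
                              names_to = "channel", values_to = "log2_ratio")
  long <- long[!is.na(long$log2_ratio), ]
  m <- regmatches(long$channel,
                  regexec("^log2_(.+)_r([0-9]+)$", long$channel))
  long$condition <- vapply(m, `[`, "", 2L)
  long$replicate <- as.integer(vapply(m, `[`, "", 3L))
  long[, c("peptide_id", "condition", "replicate", "log2_ratio")]
}

#' Write regulation and volcano tables
#'
#' `write_regulation_table()` writes the scored table as TSV;
#' `write_volcano_data()` writes the volcano-plot columns (`mean_log2`,
#' `neg_log10_p_nom`, `significant`).
#'
#' @param table scored regulation table.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_regulation_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_regulation_table
#' @export
write_volcano_data <- function(table, path) {
  out <- data.frame(
    peptide_id = table$peptide_id,
    mean_log2 = table$mean_log2,
    neg_log10_p_nom = -log10(table$p_nom),
    significant = table$significant
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
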