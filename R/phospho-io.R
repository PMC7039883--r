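#' Column-mapping dialect for phosphopeptide tables
#'
#' Search-engine exports name their columns differently (a Spectrum-Mill-style
#' site-comparison export versus a synthetic table written by
#' [write_phospho_table()]). A dialect maps the canonical column names used by
#' this package to the names found in the file. Unmapped columns default to
#' their canonical names.
#'
#' Canonical columns: `peptide_id`, `sequence`, `protein_ids` (`;`-separated
#' accessions), `gene_symbol`, `phosphosites` (`;`-separated `<residue><pos>:<0|1>`
#' tokens, e.g. `"S15:1"` for a fully localized serine at position 15),
#' `decoy` (logical or 0/1), `experiment_ids` (`;`-separated SILAC experiment
#' labels), and one ratio column per condition x replicate channel
#' (`ratio_CHIR_1uM_r1`, `ratio_CHIR_1uM_r2`, `ratio_CHIR_10uM_r1`,
#' `ratio_CHIR_10uM_r2`).
#'
#' @param ... named overrides, canonical name = file column name.
#' @return a named list with class `"phospho_dialect"`.
#' @examples
#' phospho_dialect(peptide_id = "id", gene_symbol = "gene")
#' @export
phospho_dialect <- function(...) {
  canonical <- c(
    "peptide_id", "sequence", "protein_ids", "gene_symbol",
    "phosphosites", "decoy", "experiment_ids", ratio_col()
  )
  dialect <- as.list(setNames(canonical, canonical))
  overrides <- list(...)
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), canonical)
    if (length(unknown)) {
      abort(paste0("unknown canonical column(s) in dialect: ",
                   paste(unknown, collapse = ", ")),
            class = "crmp2screen_dialect_error")
    }
    dialect[names(overrides)] <- overrides
  }
  structure(dialect, class = "phospho_dialect")
}

#' Read a dialect from a YAML or JSON file
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml`/`.json`).
#' @return a `phospho_dialect`.
#' @export
read_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort(paste0("unsupported dialect format: .", ext),
          class = "crmp2screen_dialect_error")
  )
  do.call(phospho_dialect, as.list(raw))
}

# "S15:1;T20:0" -> data.frame(residue, position, localized)
parse_phosphosites <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) {
      return(data.frame(residue = character(), position = integer(),
                        localized = logical()))
    }
    tok <- strsplit(s, ";", fixed = TRUE)[[1]]
    m <- regmatches(tok, regexec("^([A-Z])([0-9]+):([01])$", tok))
    bad <- vapply(m, length, 1L) != 4L
    if (any(bad)) {
      abort(paste0("malformed phosphosite token(s): ",
                   paste(tok[bad], collapse = ", ")),
            class = "crmp2screen_parse_error")
    }
    data.frame(
      residue   = vapply(m, `[`, "", 2L),
      position  = as.integer(vapply(m, `[`, "", 3L)),
      localized = vapply(m, `[`, "", 4L) == "1"
    )
  })
}

format_phosphosites <- function(sites) {
  vapply(sites, function(df) {
    if (!nrow(df)) return("")
    paste0(df$residue, df$position, ":", as.integer(df$localized),
           collapse = ";")
  }, character(1))
}

split_semi <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) character() else strsplit(s, ";", fixed = TRUE)[[1]]
  })
}

#' Validate a phosphopeptide table
#'
#' Enforces the record invariants: unique peptide ids, strictly positive
#' ratios wherever present, phosphosite residues in S/T/Y, positions >= 1.
#'
#' @param records a phosphopeptide tibble as returned by
#'   [load_phosphopeptide_table()].
#' @return `records`, invisibly, if valid; otherwise an error of class
#'   `"crmp2screen_validation_error"` naming the offending peptide ids.
#' @export
validate_phospho_table <- function(records) {
  if (anyDuplicated(records$peptide_id)) {
    dup <- unique(records$peptide_id[duplicated(records$peptide_id)])
    abort(paste0("duplicated peptide_id: ", paste(head(dup, 5), collapse = ", ")),
          class = "crmp2screen_validation_error")
  }
  rcols <- intersect(ratio_col(), names(records))
  for (col in rcols) {
    bad <- !is.na(records[[col]]) & records[[col]] <= 0
    if (any(bad)) {
      abort(paste0("non-positive ratio in column ", col, " for peptide_id: ",
                   paste(records$peptide_id[bad], collapse = ", ")),
            class = "crmp2screen_validation_error")
    }
  }
  for (i in seq_len(nrow(records))) {
    ps <- records$phosphosites[[i]]
    if (!nrow(ps)) next
    if (!all(ps$residue %in% c("S", "T", "Y"))) {
      abort(paste0("phosphosite residue outside S/T/Y for peptide_id: ",
                   records$peptide_id[i]),
            class = "crmp2screen_validation_error")
    }
    if (any(ps$position < 1L)) {
      abort(paste0("phosphosite position < 1 for peptide_id: ",
                   records$peptide_id[i]),
            class = "crmp2screen_validation_error")
    }
  }
  invisible(records)
}

#' Load a searched phosphopeptide quantification table
#'
#' Reads a TSV/CSV export (one row per quantified phosphopeptide) into the
#' tidy record format used by the rest of the pipeline. Missing ratio cells
#' become `NA`, never zeros. The table is validated on load.
#'
#' @param path path to a TSV (default) or CSV file.
#' @param dialect a [phospho_dialect()] mapping canonical to file columns.
#' @param sep field separator; guessed from the extension when `NULL`
#'   (`","` for `.csv`, tab otherwise).
#' @return a tibble with columns `peptide_id`, `sequence`, `protein_ids`
#'   (list of character), `gene_symbol`, `phosphosites` (list of data frames
#'   with `residue`, `position`, `localized`), `decoy` (logical),
#'   `experiment_ids` (list of character) and one numeric ratio column per
#'   channel. Zero rows for a header-only file.
#' @seealso [write_phospho_table()], [filter_phosphopeptides()]
#' @export
load_phosphopeptide_table <- function(path, dialect = phospho_dialect(),
                                      sep = NULL) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "crmp2screen_io_error")
  }
  sep <- sep %||% if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "")
  missing_cols <- setdiff(unlist(dialect, use.names = FALSE), names(raw))
  if (length(missing_cols)) {
    abort(paste0("required column(s) missing from ", basename(path), ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "crmp2screen_io_error")
  }
  get <- function(canon) raw[[dialect[[canon]]]]
  n <- nrow(raw)
  num <- function(x) {
    x[x %in% c("", "NA", "NaN")] <- NA_character_
    suppressWarnings(as.numeric(x))
  }
  records <- tibble::tibble(
    peptide_id     = get("peptide_id"),
    sequence       = toupper(get("sequence")),
    protein_ids    = split_semi(get("protein_ids")),
    gene_symbol    = get("gene_symbol"),
    phosphosites   = parse_phosphosites(get("phosphosites")),
    decoy          = toupper(trimws(get("decoy"))) %in% c("TRUE", "T", "1"),
    experiment_ids = split_semi(get("experiment_ids"))
  )
  for (col in ratio_col()) records[[col]] <- num(get(col))
  if (n == 0L) {
    records <- records[0, ]
  }
  validate_phospho_table(records)
  records
}

#' Write a phosphopeptide table as TSV
#'
#' Inverse of [load_phosphopeptide_table()] under the default dialect:
#' list columns are `;`-joined and phosphosites serialized as
#' `<residue><pos>:<0|1>` tokens.
#'
#' @param records phosphopeptide tibble.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_phospho_table <- function(records, path) {
  out <- data.frame(
    peptide_id     = records$peptide_id,
    sequence       = records$sequence,
    protein_ids    = vapply(records$protein_ids, paste, "", collapse = ";"),
    gene_symbol    = records$gene_symbol,
    phosphosites   = format_phosphosites(records$phosphosites),
    decoy          = records$decoy,
    experiment_ids = vapply(records$experiment_ids, paste, "", collapse = ";"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  for (col in ratio_col()) out[[col]] <- records[[col]]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
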