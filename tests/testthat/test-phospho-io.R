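test_that("header-only tables load as empty record sets", {
  f <- withr::local_tempfile(fileext = ".tsv")
  tpl <- generate_phospho_table(phospho_spec(n_peptides = 1, seed = 1))$records
  write_phospho_table(tpl[0, ], f)
  rec <- load_phosphopeptide_table(f)
  expect_identical(nrow(rec), 0L)
  expect_true(all(c("peptide_id", "decoy", "ratio_CHIR_10uM_r2") %in% names(rec)))
})

test_that("a generated table survives a write/load round trip field for field", {
  out <- generate_phospho_table(phospho_spec(n_peptides = 50, seed = 7))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phospho_table(out$records, f)
  rt <- load_phosphopeptide_table(f)
  expect_equal(rt$peptide_id, out$records$peptide_id)
  expect_equal(rt$protein_ids, out$records$protein_ids)
  expect_equal(rt$experiment_ids, out$records$experiment_ids)
  expect_equal(rt$decoy, out$records$decoy)
  for (i in seq_len(50)) {
    expect_equal(rt$phosphosites[[i]], out$records$phosphosites[[i]],
                 ignore_attr = TRUE)
  }
  for (col in grep("^ratio_", names(rt), value = TRUE)) {
    expect_equal(rt[[col]], out$records[[col]], tolerance = 1e-9)
  }
})

test_that("non-positive ratios are rejected naming the offending peptide", {
  out <- generate_phospho_table(phospho_spec(n_peptides = 3, seed = 1))
  bad <- out$records
  bad$ratio_CHIR_10uM_r1[2] <- -2.0
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phospho_table(bad, f)
  expect_error(load_phosphopeptide_table(f),
               class = "crmp2screen_validation_error",
               regexp = bad$peptide_id[2])
})

test_that("missing required columns produce a structured error naming them", {
  f <- withr::local_tempfile(fileext = ".tsv")
  out <- generate_phospho_table(phospho_spec(n_peptides = 3, seed = 1))
  write_phospho_table(out$records, f)
  tab <- read.delim(f, check.names = FALSE)
  tab$gene_symbol <- NULL
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_phosphopeptide_table(f),
               class = "crmp2screen_io_error", regexp = "gene_symbol")
})

test_that("dialects remap export column names and load from YAML or JSON", {
  out <- generate_phospho_table(phospho_spec(n_peptides = 5, seed = 2))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_phospho_table(out$records, f)
  tab <- read.delim(f, check.names = FALSE)
  names(tab)[names(tab) == "peptide_id"] <- "id"
  names(tab)[names(tab) == "sequence"] <- "pep_seq"
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_phosphopeptide_table(f), class = "crmp2screen_io_error")
  d <- phospho_dialect(peptide_id = "id", sequence = "pep_seq")
  rec <- load_phosphopeptide_table(f, dialect = d)
  expect_equal(rec$peptide_id, out$records$peptide_id)
  expect_equal(rec$sequence, out$records$sequence)

  y <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("peptide_id: id", "sequence: pep_seq"), y)
  expect_equal(read_dialect(y)$peptide_id, "id")
  j <- withr::local_tempfile(fileext = ".json")
  writeLines('{"peptide_id": "id"}', j)
  expect_equal(read_dialect(j)$peptide_id, "id")
  expect_error(phospho_dialect(nonsense = "x"),
               class = "crmp2screen_dialect_error")
})

test_that("duplicate peptide ids and malformed sites are rejected", {
  out <- generate_phospho_table(phospho_spec(n_peptides = 3, seed = 1))
  dup <- out$records
  dup$peptide_id[2] <- dup$peptide_id[1]
  expect_error(validate_phospho_table(dup),
               class = "crmp2screen_validation_error")
  badres <- out$records
  badres$phosphosites[[1]]$residue <- "A"
  expect_error(validate_phospho_table(badres),
               class = "crmp2screen_validation_error")
})
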