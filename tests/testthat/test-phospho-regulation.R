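reg_from_log2 <- function(l2_pairs) {
  # build a regulation table directly from 10 uM replicate log2 values
  tibble::tibble(
    peptide_id = paste0("p", seq_len(nrow(l2_pairs))),
    log2_CHIR_1uM_r1 = 0, log2_CHIR_1uM_r2 = 0,
    log2_CHIR_10uM_r1 = l2_pairs[, 1], log2_CHIR_10uM_r2 = l2_pairs[, 2]
  )
}

test_that("zero replicate ratios give p = 1 by the zero-effect convention", {
  reg <- test_regulation(reg_from_log2(cbind(0, 0)))
  expect_equal(reg$p_nom, 1)
  expect_false(reg$significant)
  expect_identical(reg$direction, "none")
})

test_that("the 1-df t-test matches the closed-form Cauchy tail", {
  # replicates (-1.0, -1.1): t = -21 on 1 df; two-sided Cauchy tail
  p_expected <- 2 * (0.5 - atan(21) / pi)
  reg <- test_regulation(reg_from_log2(cbind(-1.0, -1.1)))
  expect_equal(reg$p_nom, p_expected, tolerance = 1e-10)
  expect_equal(p_expected, 0.0303, tolerance = 1e-3)
})

test_that("peptides without two replicates are flagged unscored, not dropped", {
  reg <- test_regulation(reg_from_log2(rbind(c(-1, -1.1), c(-2, NA),
                                             c(NA, NA))))
  expect_identical(is.na(reg$p_nom), c(FALSE, TRUE, TRUE))
  expect_identical(nrow(reg), 3L)
  expect_equal(reg$mean_log2[2], -2)
  expect_true(is.na(reg$mean_log2[3]))
})

test_that("BH adjustment is monotone and the significant set shrinks with alpha", {
  out <- generate_phospho_table(phospho_spec(n_peptides = 400, seed = 17))
  reg <- test_regulation(normalize_ratios(filter_phosphopeptides(out$records)))
  scored <- reg[!is.na(reg$p_nom), ]
  ord <- order(scored$p_nom)
  expect_true(all(diff(scored$p_adj[ord]) >= -1e-12))
  expect_true(all(scored$p_adj >= scored$p_nom - 1e-12))
  sig05 <- scored$peptide_id[scored$p_adj < 0.05]
  sig01 <- scored$peptide_id[scored$p_adj < 0.01]
  expect_true(all(sig01 %in% sig05))
})

test_that("significant calls carry the direction of their mean shift", {
  out <- generate_phospho_table(phospho_spec(n_peptides = 500, seed = 23))
  reg <- test_regulation(normalize_ratios(filter_phosphopeptides(out$records)),
                         method = "moderated")
  sig <- reg[reg$significant, ]
  expect_gt(nrow(sig), 0)
  expect_identical(sig$direction == "down", sig$mean_log2 < 0)
  expect_true(all(reg$direction[!reg$significant] == "none"))
})

test_that("the moderated test recovers planted substrates across seeds", {
  sens <- fdr <- numeric(0)
  for (seed in 1:10) {
    out <- generate_phospho_table(phospho_spec(n_peptides = 1000,
                                               fraction_true_substrates = 0.2,
                                               noise_sd = 0.3, seed = 6 + seed))
    f <- filter_phosphopeptides(out$records)
    reg <- test_regulation(normalize_ratios(f), alpha = 0.05,
                           method = "moderated")
    called <- reg$peptide_id[reg$significant]
    truth <- intersect(out$truth, f$peptide_id)
    sens <- c(sens, length(intersect(called, truth)) / length(truth))
    fdr <- c(fdr, length(setdiff(called, truth)) / max(1, length(called)))
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdr), 0.1)
})

test_that("per-site queries return matching channels and typed empties", {
  out <- generate_phospho_table(phospho_spec(n_peptides = 30, seed = 3))
  f <- filter_phosphopeptides(out$records)
  reg <- normalize_ratios(f)
  expect_identical(nrow(site_ratio_query(reg, f, "NOPE", "S9")), 0L)
  ps <- f$phosphosites[[1]]
  q <- site_ratio_query(reg, f, f$protein_ids[[1]][1],
                        paste0(ps$residue[1], ps$position[1]))
  expect_gt(nrow(q), 0)
  expect_true(all(q$condition %in% c("CHIR_1uM", "CHIR_10uM")))
  # values must equal the normalized table entries for those peptides
  one <- q[1, ]
  expect_equal(one$log2_ratio,
               reg[[paste0("log2_", one$condition, "_r", one$replicate)]][
                 match(one$peptide_id, reg$peptide_id)])
})

test_that("a fixture site with a known shift is returned exactly", {
  rec <- filter_fixture()[5, ]
  rec$protein_ids <- list("GSK3B")
  rec$phosphosites <- list(data.frame(residue = "S", position = 9L,
                                      localized = TRUE))
  reg <- tibble::tibble(peptide_id = rec$peptide_id,
                        log2_CHIR_1uM_r1 = NA_real_,
                        log2_CHIR_1uM_r2 = NA_real_,
                        log2_CHIR_10uM_r1 = -0.5,
                        log2_CHIR_10uM_r2 = NA_real_)
  q <- site_ratio_query(reg, rec, "GSK3B", "S9")
  expect_equal(q$log2_ratio, -0.5)
  expect_identical(q$condition, "CHIR_10uM")
})
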