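# Shared fixtures and independent brute-force oracles.

# Hand-built six-record fixture exercising each filter rule:
# 1 decoy, 2 single-experiment, 3 no localized site, 4 only one replicate
# quantified per condition, 5 fully passing, 6 passing with only the 10 uM
# condition complete.
filter_fixture <- function() {
  site <- function(res, pos, loc) {
    data.frame(residue = res, position = pos, localized = loc)
  }
  rec <- tibble::tibble(
    peptide_id = paste0("f", 1:6),
    sequence = rep("AAASPAAK", 6),
    protein_ids = rep(list("P1"), 6),
    gene_symbol = rep("G1", 6),
    phosphosites = list(site("S", 4, TRUE), site("S", 4, TRUE),
                        site("S", 4, FALSE), site("S", 4, TRUE),
                        site("S", 4, TRUE), site("T", 4, TRUE)),
    decoy = c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE),
    experiment_ids = list(c("E1", "E2"), "E1", c("E1", "E2"),
                          c("E1", "E2"), c("E1", "E2"), c("E1", "E2"))
  )
  rec$ratio_CHIR_1uM_r1 <- c(1, 1, 1, 1, 1.2, NA)
  rec$ratio_CHIR_1uM_r2 <- c(1, 1, 1, NA, 0.9, NA)
  rec$ratio_CHIR_10uM_r1 <- c(1, 1, 1, NA, 0.5, 0.4)
  rec$ratio_CHIR_10uM_r2 <- c(1, 1, 1, 1, 0.6, 0.5)
  rec
}

# Brute-force filter: per-record loop, rules applied one at a time in the
# supplied order (the cascade must be order-invariant).
oracle_filter <- function(records, order = 1:4) {
  experiments <- sort(unique(unlist(records$experiment_ids)))
  keep <- rep(TRUE, nrow(records))
  for (rule in order) {
    for (i in seq_len(nrow(records))) {
      if (!keep[i]) next
      ok <- switch(rule,
        all(experiments %in% records$experiment_ids[[i]]),
        !records$decoy[i],
        {
          ps <- records$phosphosites[[i]]
          nrow(ps) > 0 && any(ps$localized)
        },
        {
          r <- records[i, ]
          (!is.na(r$ratio_CHIR_1uM_r1) && !is.na(r$ratio_CHIR_1uM_r2)) ||
            (!is.na(r$ratio_CHIR_10uM_r1) && !is.na(r$ratio_CHIR_10uM_r2))
        }
      )
      keep[i] <- ok
    }
  }
  records[keep, ]
}

# Brute-force per-protein counter with GSK3-style group merging.
oracle_count <- function(regulated_ids, records, min_peptides,
                         merge_groups = list(c("GSK3A", "GSK3B"))) {
  counts <- list()
  for (id in unique(regulated_ids)) {
    i <- which(records$peptide_id == id)
    if (!length(i)) next
    accs <- records$protein_ids[[i]]
    key <- accs[1]
    for (grp in merge_groups) {
      if (any(accs %in% grp)) {
        key <- paste(grp, collapse = "/")
        break
      }
    }
    counts[[key]] <- union(counts[[key]], id)
  }
  n <- vapply(counts, length, 1L)
  n <- n[n >= min_peptides]
  n[order(-n, names(n))]
}

# Match segmented cell classes back to generator ground truth by nearest
# centroid; unmatched truth objects count as errors.
truth_accuracy <- function(field, cells, max_dist = 8) {
  tr <- field$truth$objects
  map <- c(neuron = "neuron", `non-neuron` = "non-neuron",
           debris = "rejected-debris", clump = "rejected-clump")
  pred <- rep(NA_character_, nrow(tr))
  for (j in seq_len(nrow(tr))) {
    d <- sqrt((cells$centroid_y - tr$centroid_y[j])^2 +
                (cells$centroid_x - tr$centroid_x[j])^2)
    if (length(d) && min(d) < max_dist) pred[j] <- cells$class[which.min(d)]
  }
  ok <- !is.na(pred) & pred == map[tr$class]
  mean(ok)
}

# Run the full synthetic screen for one seed and return the fraction of
# planted labels recovered.
run_screen <- function(seed, image_size = c(144L, 144L),
                       cell_mix = c(neurons = 6L, non_neurons = 3L,
                                    debris = 2L, clumps = 1L)) {
  lay <- screen_layout()
  sp <- plate_spec(layout = lay, fields_per_well = 4L,
                   image_size = image_size, cell_mix = cell_mix, seed = seed)
  wells <- analyze_plate(generate_plate(sp))
  norm <- normalize_to_reference(wells, lay, "dmso")
  ref_count <- mean(wells$neuron_count[wells$role == "DMSO"])
  cmp <- tibble::tibble(
    compound = wells$compound,
    normalized_percent = norm$normalized_percent[match(wells$well, norm$well)],
    count_ratio = wells$neuron_count / ref_count,
    planted = wells$planted
  )
  hits <- call_hits(cmp[cmp$compound != "DMSO", ])
  merged <- merge(as.data.frame(hits),
                  unique(as.data.frame(cmp[, c("compound", "planted")])),
                  by = "compound")
  mean(merged$band == merged$planted)
}

# Tiny field: one nucleus disc plus an optional straight 3-px neurite,
# stamped the way the generator stamps paths.
straight_neurite_images <- function(len = 100L, with_neurite = TRUE,
                                    background = 600, map2_level = 9000) {
  nr <- 64L
  nc <- 180L
  nuc <- matrix(background, nr, nc)
  map2 <- matrix(background, nr, nc)
  cy <- 32
  cx <- 20
  r <- 8
  for (y in 1:nr) {
    for (x in 1:nc) {
      if ((y - cy)^2 + (x - cx)^2 <= r^2) nuc[y, x] <- 12000
    }
  }
  if (with_neurite) {
    path <- cbind(rep(cy, len), seq(cx + r + 4, by = 1, length.out = len))
    for (dd in list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      map2[cbind(path[, 1] + dd[1], path[, 2] + dd[2])] <- map2_level
    }
  }
  list(nuclear = nuc, map2 = map2,
       pcrmp2 = matrix(background, nr, nc))
}
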