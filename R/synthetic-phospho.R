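#' Specification for a synthetic SILAC phosphopeptide table
#'
#' Defines the statistical structure of a simulated phosphopeptide
#' quantification experiment: a fraction of peptides are true kinase
#' substrates whose log2 treated/control ratios are shifted down in a
#' dose-dependent way and whose sequence context carries the planted
#' S/T-X-X-X-S/T consensus; the remainder are centered at zero. Decoys,
#' unlocalized identifications, single-experiment identifications and
#' missing channels are injected at configurable rates so the filter cascade
#' has work to do.
#'
#' @param n_peptides number of peptide rows (default 1000).
#' @param fraction_true_substrates fraction of peptides that are true
#'   substrates (default 0.2).
#' @param effect_size named numeric, mean log2 shift per condition for true
#'   substrates (default `c(CHIR_1uM = -0.8, CHIR_10uM = -1.5)`).
#' @param noise_sd replicate noise sd on the log2 scale (default 0.3).
#' @param decoy_rate fraction of decoy rows (default 0.05).
#' @param unlocalized_rate fraction of rows whose phosphosites are all
#'   ambiguous (default 0.1).
#' @param missingness per-channel missing probability (default 0.1).
#' @param single_experiment_rate fraction of rows identified in only one
#'   SILAC experiment (default 0.05).
#' @param motif_plant_rate probability that a true substrate's context
#'   carries S/T at both the site and +4 positions (default 0.9).
#' @param peptides_per_protein average number of peptides sharing a protein
#'   (default 3).
#' @param seed RNG seed.
#' @return a validated list of class `"phospho_spec"`.
#' @export
phospho_spec <- function(n_peptides = 1000L,
                         fraction_true_substrates = 0.2,
                         effect_size = c(CHIR_1uM = -0.8, CHIR_10uM = -1.5),
                         noise_sd = 0.3,
                         decoy_rate = 0.05,
                         unlocalized_rate = 0.1,
                         missingness = 0.1,
                         single_experiment_rate = 0.05,
                         motif_plant_rate = 0.9,
                         peptides_per_protein = 3L,
                         seed = 1L) {
  rates <- c(fraction_true_substrates, decoy_rate, unlocalized_rate,
             missingness, single_experiment_rate, motif_plant_rate)
  if (any(rates < 0 | rates > 1)) {
    abort("rates must lie in [0, 1]", class = "crmp2screen_argument_error")
  }
  if (noise_sd < 0) {
    abort("noise_sd must be >= 0", class = "crmp2screen_argument_error")
  }
  stopifnot(all(.conditions %in% names(effect_size)), n_peptides >= 0)
  structure(list(
    n_peptides = as.integer(n_peptides),
    fraction_true_substrates = fraction_true_substrates,
    effect_size = effect_size,
    noise_sd = noise_sd,
    decoy_rate = decoy_rate,
    unlocalized_rate = unlocalized_rate,
    missingness = missingness,
    single_experiment_rate = single_experiment_rate,
    motif_plant_rate = motif_plant_rate,
    peptides_per_protein = as.integer(peptides_per_protein),
    seed = as.integer(seed)
  ), class = "phospho_spec")
}

#' Generate a synthetic phosphopeptide table with ground truth
#'
#' Fully deterministic given the spec's seed. True substrates receive the
#' planted S/T-X-X-X-S/T sequence context (at `motif_plant_rate`) and
#' down-shifted log2 ratios in both treatment conditions; everything else is
#' centered at zero. Several peptides can map to the same synthetic protein
#' so per-protein summaries are exercised.
#'
#' @param spec a [phospho_spec()].
#' @return a list with `records` (phosphopeptide tibble, loadable/writable
#'   via the table I/O functions), `truth` (peptide ids of planted true
#'   substrates), and `protein_sequences` (named character vector,
#'   accession -> sequence) for motif extraction.
#' @examples
#' out <- generate_phospho_table(phospho_spec(n_peptides = 10, seed = 42))
#' out$records$peptide_id
#' @export
generate_phospho_table <- function(spec) {
  stopifnot(inherits(spec, "phospho_spec"))
  n <- spec$n_peptides
  empty <- list(records = load_template(), truth = character(),
                protein_sequences = character())
  if (n == 0L) return(empty)
  with_seed(spec$seed, {
    n_prot <- max(1L, ceiling(n / spec$peptides_per_protein))
    prot_len <- 60L
    accs <- sprintf("SYNP%04d", seq_len(n_prot))
    genes <- sprintf("SYNG%04d", seq_len(n_prot))
    prot_seq <- vapply(seq_len(n_prot), function(i) {
      paste(sample(.aa_alphabet, prot_len, replace = TRUE), collapse = "")
    }, character(1))
    names(prot_seq) <- accs

    prot_of <- sample.int(n_prot, n, replace = TRUE)
    is_sub <- runif(n) < spec$fraction_true_substrates
    is_decoy <- runif(n) < spec$decoy_rate
    is_sub[is_decoy] <- FALSE
    is_unloc <- runif(n) < spec$unlocalized_rate
    one_exp <- runif(n) < spec$single_experiment_rate

    # distinct site positions per protein so planted contexts don't collide
    pos <- integer(n)
    slots <- seq(8L, prot_len - 8L, by = 6L)
    for (p in unique(prot_of)) {
      rows <- which(prot_of == p)
      pos[rows] <- sample(slots, length(rows),
                          replace = length(rows) > length(slots))
    }

    # plant site residues into the protein sequences
    put <- function(seq, at, ch) {
      substr(seq, at, at) <- ch
      seq
    }
    for (i in seq_len(n)) {
      acc <- accs[prot_of[i]]
      res <- sample(c("S", "T"), 1L)
      prot_seq[acc] <- put(prot_seq[acc], pos[i], res)
      if (is_sub[i] && runif(1) < spec$motif_plant_rate) {
        prot_seq[acc] <- put(prot_seq[acc], pos[i] + 4L,
                             sample(c("S", "T"), 1L))
      } else {
        # explicit non-S/T at +4 so the background motif stays flat
        prot_seq[acc] <- put(prot_seq[acc], pos[i] + 4L,
                             sample(setdiff(.aa_alphabet, c("S", "T")), 1L))
      }
    }

    pep_start <- pmax(1L, pos - 5L)
    pep_end <- pmin(prot_len, pos + 6L)
    peptide_seq <- unname(substr(prot_seq[accs[prot_of]], pep_start, pep_end))
    site_res <- unname(substr(prot_seq[accs[prot_of]], pos, pos))

    ids <- sprintf("PEP%05d", seq_len(n))
    shift <- function(cond) ifelse(is_sub, spec$effect_size[[cond]], 0)
    records <- tibble::tibble(
      peptide_id = ids,
      sequence = peptide_seq,
      protein_ids = lapply(prot_of, function(p) accs[p]),
      gene_symbol = genes[prot_of],
      phosphosites = lapply(seq_len(n), function(i) {
        data.frame(residue = site_res[i], position = pos[i],
                   localized = !is_unloc[i])
      }),
      decoy = is_decoy,
      experiment_ids = lapply(seq_len(n), function(i) {
        if (one_exp[i]) sample(c("E1", "E2"), 1L) else c("E1", "E2")
      })
    )
    for (cond in .conditions) {
      for (rep_i in .replicates) {
        lg <- shift(cond) + rnorm(n, 0, spec$noise_sd)
        lg[runif(n) < spec$missingness] <- NA_real_
        records[[ratio_col(cond, rep_i)]] <- 2^lg
      }
    }
    list(records = records, truth = ids[is_sub], protein_sequences = prot_seq)
  })
}

# zero-row record tibble with the full schema
load_template <- function() {
  tpl <- tibble::tibble(
    peptide_id = character(), sequence = character(),
    protein_ids = list(), gene_symbol = character(),
    phosphosites = list(), decoy = logical(), experiment_ids = list()
  )
  for (col in ratio_col()) tpl[[col]] <- numeric()
  tpl
}
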