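#' Normalize per-well readouts to a reference
#'
#' Expresses each well's percent p-CRMP2/MAP2 as a percentage of a
#' reference level: the DMSO-well mean (`"dmso"`), the mean over every well
#' (`"all_well_average"`, the primary-screen convention), or the mean of
#' lithium reference wells (`"lithium_1mM"`, used when re-testing hits with
#' lithium's effect set to 100%).
#'
#' @param wells per-well tibble with columns `well` and `percent_pcrmp2`
#'   (e.g. from [analyze_plate()]).
#' @param layout layout tibble with columns `well` and `role`.
#' @param mode reference mode; `"dmso"` needs wells with role `"DMSO"`,
#'   `"lithium_1mM"` wells with role `"lithium_ref"`.
#' @return a tibble `well`, `raw_percent`, `normalized_percent`, `mode`.
#'   Reference wells average to 100 under their own mode.
#' @export
normalize_to_reference <- function(wells, layout,
                                   mode = c("dmso", "all_well_average",
                                            "lithium_1mM")) {
  mode <- match.arg(mode)
  merged <- dplyr::left_join(wells[, c("well", "percent_pcrmp2")],
                             layout[, c("well", "role")], by = "well")
  ref_vals <- switch(mode,
    dmso = merged$percent_pcrmp2[merged$role == "DMSO"],
    all_well_average = merged$percent_pcrmp2,
    lithium_1mM = merged$percent_pcrmp2[merged$role == "lithium_ref"]
  )
  ref_vals <- ref_vals[!is.na(ref_vals)]
  if (!length(ref_vals) || mean(ref_vals) == 0) {
    abort(paste0("reference mean undefined or zero for mode '", mode, "'"),
          class = "crmp2screen_reference_error")
  }
  ref <- mean(ref_vals)
  tibble::tibble(well = merged$well,
                 raw_percent = merged$percent_pcrmp2,
                 normalized_percent = 100 * merged$percent_pcrmp2 / ref,
                 mode = mode)
}

#' Z-prime plate-quality factor
#'
#' `Z' = 1 - 3 (sd_pos + sd_neg) / |mean_pos - mean_neg|`, with sample
#' (n - 1) standard deviations. Values above ~0.5 indicate an assay
#' suitable for screening. Equal arm means make the statistic undefined;
#' that case returns `NA` with a warning rather than `-Inf`.
#'
#' @param positive,negative numeric vectors of control-well readouts
#'   (>= 2 values each).
#' @return the Z-prime value (always <= 1), or `NA` when undefined.
#' @examples
#' zprime(rnorm(8, 20, 2), rnorm(8, 100, 4))
#' @export
zprime <- function(positive, negative) {
  if (length(positive) < 2L || length(negative) < 2L) {
    abort("zprime needs >= 2 values per arm",
          class = "crmp2screen_argument_error")
  }
  denom <- abs(mean(positive) - mean(negative))
  if (denom == 0) {
    warn("equal control means; Z' undefined",
         class = "crmp2screen_zprime_undefined")
    return(NA_real_)
  }
  1 - 3 * (sd(positive) + sd(negative)) / denom
}

#' Banded hit calling with a toxicity counter-screen
#'
#' Averages normalized percent over replicates per compound and assigns a
#' band: `strong` below the strong edge (default 80, the GSK3-inhibitor-like
#' bracket), `candidate` from the strong edge up to the candidate edge
#' (default 90, the primary <90% rule), `inactive` otherwise. A compound
#' whose MAP2-positive neuron-count ratio falls below `tox_floor` is called
#' `toxic`, overriding any activity band.
#'
#' @param compounds data frame with columns `compound`,
#'   `normalized_percent` (one row per replicate well) and `count_ratio`
#'   (MAP2-positive neuron count relative to reference).
#' @param bands numeric `c(candidate = 90, strong = 80)`; edges must be
#'   strictly decreasing.
#' @param tox_floor toxicity cut on the count ratio (default 0.5).
#' @return a tibble `compound`, `mean_percent`, `n`, `count_ratio`, `band`.
#' @export
call_hits <- function(compounds, bands = c(candidate = 90, strong = 80),
                      tox_floor = 0.5) {
  if (length(bands) != 2L || !(bands[["strong"]] < bands[["candidate"]])) {
    abort("band edges must be strictly decreasing (candidate > strong)",
          class = "crmp2screen_config_error")
  }
  grp <- dplyr::summarise(
    dplyr::group_by(tibble::as_tibble(compounds), .data$compound),
    mean_percent = mean(.data$normalized_percent, na.rm = TRUE),
    n = dplyr::n(),
    count_ratio = mean(.data$count_ratio, na.rm = TRUE),
    .groups = "drop"
  )
  band <- ifelse(grp$count_ratio < tox_floor, "toxic",
          ifelse(grp$mean_percent < bands[["strong"]], "strong",
          ifelse(grp$mean_percent < bands[["candidate"]], "candidate",
                 "inactive")))
  grp$band <- band
  grp
}

#' Unpaired two-sample t-test with the star-band annotation
#'
#' Student's two-sided test (equal variances by default; `welch = TRUE` for
#' the unequal-variance form) with significance stars at the printed bands:
#' `*` for 0.01 <= p < 0.05, `**` for 0.001 <= p < 0.01, `***` for
#' 0.0001 <= p < 0.001, `****` for p < 0.0001 (lower edges inclusive).
#' Two identical constant groups give t = 0, p = 1 and no stars; constant
#' groups with different means give p = 0.
#'
#' @param group_a,group_b numeric vectors (>= 2 values each).
#' @param welch use the Welch test (default `FALSE`).
#' @return a list of class `"ttest_result"`: `t`, `df`, `p`, `stars`.
#' @examples
#' unpaired_ttest(c(1, 2, 3), c(4, 5, 6))
#' @export
unpaired_ttest <- function(group_a, group_b, welch = FALSE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("unpaired_ttest needs >= 2 values per group",
          class = "crmp2screen_argument_error")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      res <- list(t = 0, df = length(group_a) + length(group_b) - 2L, p = 1)
    } else {
      res <- list(t = Inf * sign(mean(group_a) - mean(group_b)),
                  df = length(group_a) + length(group_b) - 2L, p = 0)
    }
  } else {
    tt <- t.test(group_a, group_b, var.equal = !welch)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter),
                p = tt$p.value)
  }
  res$stars <- p_stars(res$p)
  structure(res, class = "ttest_result")
}

#' Map a p-value to significance stars
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of star strings.
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) "" else
    if (pp < 1e-4) "****" else
    if (pp < 1e-3) "***" else
    if (pp < 0.01) "**" else
    if (pp < 0.05) "*" else ""
  }, character(1))
}

#' @export
print.ttest_result <- function(x, ...) {
  cat(sprintf("t = %.4g, df = %.4g, p = %.4g %s\n", x$t, x$df, x$p, x$stars))
  invisible(x)
}

#' Write the per-compound screen report as TSV
#'
#' @param hits tibble from [call_hits()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
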