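#' @importFrom rlang abort warn .data
#' @importFrom stats median sd pt p.adjust rnorm runif t.test setNames
#' @importFrom utils head
NULL

# SILAC treatment conditions and replicate channels used throughout.
.conditions <- c("CHIR_1uM", "CHIR_10uM")
.replicates <- 1:2

#' Ratio / log2-ratio column names for a condition x replicate channel
#'
#' Channels are named `ratio_<condition>_r<replicate>` in peptide tables and
#' `log2_<condition>_r<replicate>` in regulation tables.
#'
#' @param condition treatment condition label, e.g. `"CHIR_10uM"`.
#' @param replicate replicate index (1 or 2).
#' @return a character vector of column names.
#' @keywords internal
ratio_col <- function(condition = .conditions, replicate = .replicates) {
  as.vector(t(outer(condition, replicate, function(co, re) {
    paste0("ratio_", co, "_r", re)
  })))
}

#' @rdname ratio_col
#' @keywords internal
log2_col <- function(condition = .conditions, replicate = .replicates) {
  sub("^ratio_", "log2_", ratio_col(condition, replicate))
}

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a child seed < 2^31 from a base seed and an index, for per-object
# streams that stay reproducible when objects are generated independently.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 48271 + as.numeric(index) * 1299709) %% 2147483647
}

`%||%` <- function(x, y) if (is.null(x)) y else x
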