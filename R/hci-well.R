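#' Analyze one imaging field
#'
#' Runs the full single-field pipeline: nuclear segmentation, four-criterion
#' classification, and neurite tracing.
#'
#' @param images list of matrices `nuclear`, `map2`, `pcrmp2` in camera
#'   counts (as produced by [generate_field()] or [read_plate_field()]).
#' @param pixel_size microns per pixel.
#' @param thresholds an [hci_thresholds()] list.
#' @param map2_threshold fixed neurite-mask threshold in counts, or `NULL`
#'   for Otsu.
#' @return list with `nuclei`, `cells` (classification tibble), `neurites`
#'   (`neurite_measurement`), `images`.
#' @export
analyze_field <- function(images, pixel_size = 0.65,
                          thresholds = hci_thresholds(),
                          map2_threshold = NULL) {
  nuclei <- segment_nuclei(images$nuclear, pixel_size = pixel_size)
  cells <- classify_cells(nuclei, images$nuclear, images$map2, thresholds)
  neurites <- trace_neurites(images$map2, nuclei, images$pcrmp2,
                             map2_threshold = map2_threshold)
  list(nuclei = nuclei, cells = cells, neurites = neurites, images = images)
}

#' Aggregate analyzed fields into a per-well result
#'
#' In `"high_content"` mode the field-level neurite p-CRMP2 and MAP2 mean
#' intensities (background-subtracted by default, restricted to fields
#' containing MAP2-positive neurons) are averaged over fields, and the well
#' readout is their ratio times 100 — the percent p-CRMP2/MAP2 statistic.
#' In `"whole_field"` mode, emulating a laser-scanning cytometer readout,
#' total above-background intensity over the whole field is used with no
#' per-cell gating. MAP2-positive neuron counts are summed over fields as
#' the toxicity readout.
#'
#' @param fields list of [analyze_field()] results (>= 1).
#' @param well well identifier to report.
#' @param mode `"high_content"` (default) or `"whole_field"`.
#' @param subtract_background subtract the per-channel median (an estimate
#'   of the constant background) before forming the ratio (default `TRUE`).
#' @return a one-row tibble: `well`, `n_fields`, `neuron_count`,
#'   `percent_pcrmp2` (`NA` when no field contains a neuron — a typed
#'   missing value, not an error), `mode`.
#' @export
measure_well <- function(fields, well = "well",
                         mode = c("high_content", "whole_field"),
                         subtract_background = TRUE) {
  mode <- match.arg(mode)
  stopifnot(length(fields) >= 1L)
  neuron_count <- sum(vapply(fields, function(f) {
    sum(f$cells$class == "neuron")
  }, numeric(1)))
  p_vals <- m_vals <- numeric(0)
  for (f in fields) {
    bg_m <- if (subtract_background) median(f$images$map2) else 0
    bg_p <- if (subtract_background) median(f$images$pcrmp2) else 0
    if (mode == "high_content") {
      has_neuron <- any(f$cells$class == "neuron")
      if (!has_neuron || f$neurites$n_pixels == 0L) next
      m_vals <- c(m_vals, f$neurites$map2_mean - bg_m)
      p_vals <- c(p_vals, f$neurites$pcrmp2_mean - bg_p)
    } else {
      m_vals <- c(m_vals, sum(pmax(f$images$map2 - bg_m, 0)))
      p_vals <- c(p_vals, sum(pmax(f$images$pcrmp2 - bg_p, 0)))
    }
  }
  percent <- if (length(m_vals) && mean(m_vals) > 0) {
    100 * mean(p_vals) / mean(m_vals)
  } else NA_real_
  if (mode == "high_content" && neuron_count == 0) percent <- NA_real_
  tibble::tibble(well = well, n_fields = length(fields),
                 neuron_count = neuron_count, percent_pcrmp2 = percent,
                 mode = mode)
}

#' Analyze a whole synthetic plate into per-well results
#'
#' @param plate a `synthetic_plate` from [generate_plate()].
#' @param thresholds an [hci_thresholds()] list.
#' @param mode,subtract_background passed to [measure_well()].
#' @return a tibble with one row per well (see [measure_well()]), plus the
#'   layout columns joined on `well`.
#' @export
analyze_plate <- function(plate, thresholds = hci_thresholds(),
                          mode = "high_content", subtract_background = TRUE) {
  stopifnot(inherits(plate, "synthetic_plate"))
  px <- plate$spec$pixel_size
  wells <- split(plate$fields, vapply(plate$fields, `[[`, "", "well"))
  res <- lapply(names(wells), function(w) {
    analyzed <- lapply(wells[[w]], function(fld) {
      analyze_field(fld$images, pixel_size = px, thresholds = thresholds)
    })
    measure_well(analyzed, well = w, mode = mode,
                 subtract_background = subtract_background)
  })
  out <- dplyr::bind_rows(res)
  dplyr::left_join(out, plate$spec$layout, by = "well")
}

#' Write per-cell and per-well CSV reports
#'
#' @param cells a classification tibble (or row-bound tibbles) from
#'   [classify_cells()].
#' @param wells a per-well tibble from [analyze_plate()] / [measure_well()].
#' @param cell_path,well_path output CSV paths.
#' @return the path, invisibly.
#' @export
write_cell_table <- function(cells, cell_path) {
  utils::write.csv(as.data.frame(cells), cell_path, row.names = FALSE)
  invisible(cell_path)
}

#' @rdname write_cell_table
#' @export
write_well_table <- function(wells, well_path) {
  utils::write.csv(as.data.frame(wells), well_path, row.names = FALSE)
  invisible(well_path)
}
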