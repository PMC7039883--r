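#' Segment nuclear objects from the nuclear channel
#'
#' Global threshold (Otsu unless given), hole filling, and seeded watershed
#' on the distance map to split touching nuclei. Areas are reported in
#' square microns.
#'
#' @param img nuclear-channel matrix in camera counts (16-bit scale).
#' @param pixel_size microns per pixel.
#' @param threshold absolute count threshold; Otsu on the image when `NULL`.
#' @param min_area_um2 objects smaller than this are discarded as
#'   segmentation noise (default 5; well below the debris band so debris is
#'   still classified, not lost here).
#' @param watershed_tolerance minimum object-separating depth of the
#'   distance map passed to [EBImage::watershed()] (default 1).
#' @return an object of class `"nuclear_objects"`: list with `table` (tibble:
#'   `label`, `area_um2`, `mean_intensity`, `centroid_y`, `centroid_x`),
#'   `labels` (integer label matrix), `pixel_size`. A blank or saturated
#'   image yields zero objects with a warning, never an error.
#' @export
segment_nuclei <- function(img, pixel_size = 0.65, threshold = NULL,
                           min_area_um2 = 5, watershed_tolerance = 1) {
  stopifnot(is.matrix(img), pixel_size > 0)
  scaled <- img / 65535
  if (diff(range(scaled)) < 1e-8) {
    warn("blank or saturated nuclear image; no objects segmented",
         class = "crmp2screen_blank_image")
    return(empty_nuclei(img, pixel_size))
  }
  thr <- if (is.null(threshold)) EBImage::otsu(EBImage::Image(scaled)) else
    threshold / 65535
  mask <- scaled > thr
  if (!any(mask) || all(mask)) {
    warn("thresholding left no separable foreground; no objects segmented",
         class = "crmp2screen_blank_image")
    return(empty_nuclei(img, pixel_size))
  }
  mask <- EBImage::fillHull(EBImage::Image(mask))
  dm <- EBImage::distmap(mask)
  labels <- EBImage::imageData(EBImage::watershed(dm,
                                                  tolerance = watershed_tolerance,
                                                  ext = 1))
  labels <- matrix(as.integer(labels), nrow(img), ncol(img))
  tab <- tabulate(labels)
  keep <- which(tab * pixel_size^2 >= min_area_um2)
  if (!length(keep)) return(empty_nuclei(img, pixel_size))
  relabel <- integer(max(labels))
  relabel[keep] <- seq_along(keep)
  labels[labels > 0] <- relabel[labels[labels > 0]]
  rows <- row(labels)[labels > 0]
  cols <- col(labels)[labels > 0]
  labs <- labels[labels > 0]
  vals <- img[labels > 0]
  table <- tibble::tibble(
    label = seq_along(keep),
    area_um2 = as.numeric(tapply(rep(1, length(labs)), labs, sum)) * pixel_size^2,
    mean_intensity = as.numeric(tapply(vals, labs, mean)),
    centroid_y = as.numeric(tapply(rows, labs, mean)),
    centroid_x = as.numeric(tapply(cols, labs, mean))
  )
  structure(list(table = table, labels = labels, pixel_size = pixel_size),
            class = "nuclear_objects")
}

empty_nuclei <- function(img, pixel_size) {
  structure(list(
    table = tibble::tibble(label = integer(), area_um2 = numeric(),
                           mean_intensity = numeric(), centroid_y = numeric(),
                           centroid_x = numeric()),
    labels = matrix(0L, nrow(img), ncol(img)),
    pixel_size = pixel_size
  ), class = "nuclear_objects")
}

#' @export
print.nuclear_objects <- function(x, ...) {
  cat("Segmented nuclei:", nrow(x$table), "objects,",
      x$pixel_size, "um/px\n")
  invisible(x)
}
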