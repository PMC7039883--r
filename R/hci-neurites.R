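shift_mat <- function(m, dr, dc) {
  nr <- nrow(m)
  nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Topological thinning (Zhang-Suen) of a binary mask
#'
#' Reduces a binary mask to its one-pixel-wide skeleton while preserving
#' connectivity. Used to turn the thresholded MAP2 neurite mask into a
#' traced skeleton whose pixel count approximates path length.
#'
#' @param mask logical or 0/1 matrix.
#' @param max_iter safety bound on thinning iterations (default 100).
#' @return a logical matrix, `TRUE` on skeleton pixels; always a subset of
#'   the input mask.
#' @export
thin_mask <- function(mask, max_iter = 100L) {
  m <- matrix(as.integer(mask > 0), nrow(mask), ncol(mask))
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (step in 1:2) {
      # neighbours in Zhang-Suen order P2..P9 (N, NE, E, SE, S, SW, W, NW)
      p2 <- shift_mat(m, 1, 0)   # value of the pixel above, seen from here
      p3 <- shift_mat(m, 1, -1)
      p4 <- shift_mat(m, 0, -1)
      p5 <- shift_mat(m, -1, -1)
      p6 <- shift_mat(m, -1, 0)
      p7 <- shift_mat(m, -1, 1)
      p8 <- shift_mat(m, 0, 1)
      p9 <- shift_mat(m, 1, 1)
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (step == 1) {
        cond <- p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      del <- m == 1 & b >= 2 & b <= 6 & a == 1 & cond
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# 8-connected component labels of a sparse mask, via labelling its
# 1-px dilation (merges diagonal neighbours; EBImage::bwlabel is 4-connected)
label8 <- function(mask) {
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(mask),
                                            EBImage::makeBrush(3, "box"))) > 0
  lab <- EBImage::bwlabel(EBImage::Image(dil))
  matrix(as.integer(EBImage::imageData(lab)), nrow(mask), ncol(mask)) *
    (mask > 0)
}

#' Trace neurites from the MAP2 channel
#'
#' Thresholds the MAP2 channel (Otsu unless a fixed threshold is supplied),
#' removes soma regions (nuclei dilated by `soma_dilate_um`), skeletonizes
#' the remaining neurite mask, and keeps only skeleton components connected
#' to a soma. p-CRMP2 and MAP2 intensities are measured on the retained
#' skeleton pixels.
#'
#' @param map2_img MAP2-channel matrix (camera counts).
#' @param nuclei `"nuclear_objects"` from [segment_nuclei()].
#' @param pcrmp2_img p-CRMP2-channel matrix (camera counts).
#' @param map2_threshold fixed absolute threshold in counts, or `NULL` for
#'   per-image Otsu.
#' @param soma_dilate_um soma exclusion zone beyond the nuclear boundary
#'   (default 2 um).
#' @return a list of class `"neurite_measurement"`: `skeleton` (logical
#'   matrix), `map2_mean`, `pcrmp2_mean` (counts over retained skeleton
#'   pixels; `NA` when no skeleton), `length_um`, `n_pixels`. No
#'   MAP2-positive pixels is a zero-length measurement, not an error.
#' @export
trace_neurites <- function(map2_img, nuclei, pcrmp2_img,
                           map2_threshold = NULL, soma_dilate_um = 2) {
  stopifnot(inherits(nuclei, "nuclear_objects"))
  px <- nuclei$pixel_size
  scaled <- map2_img / 65535
  thr <- if (is.null(map2_threshold)) {
    if (diff(range(scaled)) < 1e-8) 1.1 else EBImage::otsu(EBImage::Image(scaled))
  } else map2_threshold / 65535
  mask <- scaled > thr
  soma_px <- max(1L, round(soma_dilate_um / px))
  soma <- EBImage::imageData(EBImage::dilate(
    EBImage::Image(nuclei$labels > 0),
    EBImage::makeBrush(2L * soma_px + 1L, "disc"))) > 0
  neurite_mask <- mask & !soma
  empty <- structure(list(skeleton = matrix(FALSE, nrow(map2_img), ncol(map2_img)),
                          map2_mean = NA_real_, pcrmp2_mean = NA_real_,
                          length_um = 0, n_pixels = 0L),
                     class = "neurite_measurement")
  if (!any(neurite_mask)) return(empty)
  skel <- thin_mask(neurite_mask)
  if (!any(skel)) return(empty)
  # keep skeleton components adjacent to a soma
  labs <- label8(skel)
  soma_adj <- EBImage::imageData(EBImage::dilate(EBImage::Image(soma),
                                                 EBImage::makeBrush(5, "box"))) > 0
  keep_labs <- setdiff(unique(labs[soma_adj & labs > 0]), 0L)
  skel <- labs %in% keep_labs & labs > 0
  skel <- matrix(skel, nrow(map2_img), ncol(map2_img))
  if (!any(skel)) return(empty)
  structure(list(
    skeleton = skel,
    map2_mean = mean(map2_img[skel]),
    pcrmp2_mean = mean(pcrmp2_img[skel]),
    length_um = sum(skel) * px,
    n_pixels = sum(skel)
  ), class = "neurite_measurement")
}
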