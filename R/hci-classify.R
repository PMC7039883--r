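#' Classification thresholds for the four-criterion cell filter
#'
#' Defaults follow the published analysis criteria: nuclear size pass band
#' 50-160 (um^2, inclusive ends; smaller objects are debris, larger are
#' clumps), nuclear staining at least 2197 camera counts (mean over the
#' nucleus; the printed unit for this threshold is ambiguous and the value
#' is configurable), a collar-ring MAP2 floor estimated from the image
#' background (mean + 3 sd) unless overridden, and collar-ring MAP2
#' coefficient of variation above 1 for neurons. The CV direction is as
#' printed (high CV = neuron: a neuron's ring mixes bright neurite pixels
#' with background, giving high contrast); `cv_high_is_neuron = FALSE`
#' inverts it.
#'
#' @param size_min_um2,size_max_um2 nuclear size band (default 50, 160).
#' @param size_unit `"area"` interprets the band as um^2 of nuclear area;
#'   `"diameter"` as equivalent-circle diameter in um.
#' @param nuclear_min minimum mean nuclear intensity in counts (default
#'   2197).
#' @param map2_floor absolute ring-MAP2 floor in counts; `NULL` (default)
#'   estimates background mean + 3 sd per image.
#' @param cv_threshold ring-MAP2 CV cut (default 1).
#' @param cv_high_is_neuron direction of the CV criterion (default `TRUE`).
#' @param ring_width_um collar-ring width beyond the nuclear boundary
#'   (default 2 um).
#' @return a named list of class `"hci_thresholds"`.
#' @export
hci_thresholds <- function(size_min_um2 = 50, size_max_um2 = 160,
                           size_unit = c("area", "diameter"),
                           nuclear_min = 2197, map2_floor = NULL,
                           cv_threshold = 1, cv_high_is_neuron = TRUE,
                           ring_width_um = 2) {
  structure(list(size_min_um2 = size_min_um2, size_max_um2 = size_max_um2,
                 size_unit = match.arg(size_unit), nuclear_min = nuclear_min,
                 map2_floor = map2_floor, cv_threshold = cv_threshold,
                 cv_high_is_neuron = cv_high_is_neuron,
                 ring_width_um = ring_width_um),
            class = "hci_thresholds")
}

# collar ring pixel indices for one labelled object, clipped to the image
ring_indices <- function(labels, lab, ring_px, nr, nc) {
  which_obj <- which(labels == lab)
  ys <- ((which_obj - 1L) %% nr) + 1L
  xs <- ((which_obj - 1L) %/% nr) + 1L
  y0 <- max(1L, min(ys) - ring_px - 1L)
  y1 <- min(nr, max(ys) + ring_px + 1L)
  x0 <- max(1L, min(xs) - ring_px - 1L)
  x1 <- min(nc, max(xs) + ring_px + 1L)
  sub <- labels[y0:y1, x0:x1]
  obj <- sub == lab
  brush <- EBImage::makeBrush(2L * ring_px + 1L, shape = "disc")
  dil <- EBImage::imageData(EBImage::dilate(EBImage::Image(obj), brush)) > 0
  ring_local <- dil & sub == 0L # exclude every nucleus, not just this one
  loc <- which(ring_local)
  ly <- ((loc - 1L) %% nrow(sub)) + y0
  lx <- ((loc - 1L) %/% nrow(sub)) + x0
  (lx - 1L) * nr + ly
}

#' Classify segmented cells with the four collar-ring criteria
#'
#' Applies, in the published order: (1) nuclear size band (debris/clump),
#' (2) nuclear staining intensity (dim false objects), (3) collar-ring MAP2
#' level (MAP2-negative cells are not neurons), (4) collar-ring MAP2 CV.
#' A cell is a neuron iff all four pass; each rejection is labelled by the
#' first failing criterion. Rings that would extend past the image are
#' clipped to its bounds.
#'
#' @param nuclei a `"nuclear_objects"` result from [segment_nuclei()].
#' @param nuclear_img nuclear-channel matrix (camera counts).
#' @param map2_img MAP2-channel matrix (camera counts).
#' @param thresholds an [hci_thresholds()] list.
#' @return a tibble, one row per nucleus, with the nuclear measurements,
#'   `ring_map2_mean`, `ring_map2_cv`, the four criterion flags
#'   (`size_ok`, `nuclear_intensity_ok`, `map2_ok`, `cv_ok`) and `class`
#'   (`"neuron"`, `"non-neuron"`, `"rejected-debris"`, `"rejected-clump"`,
#'   `"rejected-dim"`). The estimated MAP2 floor is attached as attribute
#'   `"map2_floor"`.
#' @export
classify_cells <- function(nuclei, nuclear_img, map2_img,
                           thresholds = hci_thresholds()) {
  stopifnot(inherits(nuclei, "nuclear_objects"))
  tab <- nuclei$table
  nr <- nrow(map2_img)
  nc <- ncol(map2_img)
  px <- nuclei$pixel_size
  ring_px <- max(1L, round(thresholds$ring_width_um / px))
  floor_val <- thresholds$map2_floor %||% estimate_map2_floor(map2_img)

  n <- nrow(tab)
  ring_mean <- ring_cv <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- ring_indices(nuclei$labels, tab$label[i], ring_px, nr, nc)
    vals <- map2_img[idx]
    ring_mean[i] <- mean(vals)
    ring_cv[i] <- if (length(vals) > 1 && mean(vals) > 0)
      sd(vals) / mean(vals) else 0
  }
  size_metric <- if (thresholds$size_unit == "area") tab$area_um2 else
    2 * sqrt(tab$area_um2 / pi)
  size_small <- size_metric < thresholds$size_min_um2
  size_large <- size_metric > thresholds$size_max_um2
  size_ok <- !size_small & !size_large # 50 and 160 inclusive
  nuclear_ok <- tab$mean_intensity >= thresholds$nuclear_min
  map2_ok <- ring_mean >= floor_val
  cv_pass <- if (thresholds$cv_high_is_neuron)
    ring_cv > thresholds$cv_threshold else ring_cv < thresholds$cv_threshold

  cls <- rep("neuron", n)
  cls[!cv_pass] <- "non-neuron"
  cls[!map2_ok] <- "non-neuron"
  cls[!nuclear_ok] <- "rejected-dim"
  cls[size_large] <- "rejected-clump"
  cls[size_small] <- "rejected-debris"

  out <- tab
  out$ring_map2_mean <- ring_mean
  out$ring_map2_cv <- ring_cv
  out$size_ok <- size_ok
  out$nuclear_intensity_ok <- nuclear_ok
  out$map2_ok <- map2_ok
  out$cv_ok <- cv_pass
  out$class <- cls
  structure(out, map2_floor = floor_val)
}

# background model from sub-threshold pixels: mean + 3 sd
estimate_map2_floor <- function(map2_img) {
  thr <- EBImage::otsu(EBImage::Image(map2_img / 65535)) * 65535
  bg <- map2_img[map2_img <= thr]
  if (!length(bg)) bg <- as.vector(map2_img)
  mean(bg) + 3 * sd(bg)
}
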