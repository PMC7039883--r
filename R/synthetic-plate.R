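#' Hill-type lithium dose-response for p-CRMP2 suppression
#'
#' Maps a dose (mM) to the suppression factor `f` in (0, 1] applied to
#' neurite p-CRMP2 signal. Defaults are calibrated so a therapeutic 1 mM
#' dose leaves ~87.2% and 2.5 mM ~68.4% of the control signal, the
#' magnitudes this assay is validated against.
#'
#' @param dose dose in mM (vectorized).
#' @param ec50 half-maximal dose (default 1.5581033 mM).
#' @param bottom asymptotic minimum of `f` (default 0.5612562).
#' @param top value at dose 0 (default 1).
#' @param n Hill coefficient (default 2).
#' @return suppression factors in `(bottom, top]`.
#' @examples
#' hill_suppression(c(0, 1, 2.5))
#' @export
hill_suppression <- function(dose, ec50 = 1.5581033, bottom = 0.5612562,
                             top = 1, n = 2) {
  bottom + (top - bottom) / (1 + (dose / ec50)^n)
}

#' Plate layout constructor
#'
#' @param well well ids (e.g. `"A01"`).
#' @param compound compound label per well.
#' @param dose dose per well (arbitrary units; 0 for vehicle).
#' @param role one of `"DMSO"`, `"positive_control"`, `"lithium_ref"`,
#'   `"test"`.
#' @param f planted p-CRMP2 suppression factor in (0, 1] per well.
#' @param tox planted neuron-count multiplier in `[0, 1]` per well (toxicity).
#' @return a layout tibble.
#' @export
plate_layout <- function(well, compound, dose = 0, role = "test", f = 1,
                         tox = 1) {
  layout <- tibble::tibble(well = well, compound = compound, dose = dose,
                           role = role, f = f, tox = tox)
  if (any(layout$f <= 0 | layout$f > 1)) {
    abort("suppression factors f must lie in (0, 1]",
          class = "crmp2screen_argument_error")
  }
  layout
}

#' 96-well screen layout with planted hit classes
#'
#' Builds the synthetic screen scenario: DMSO and positive-control columns
#' plus test compounds planted as strong (`f_strong`), candidate
#' (`f_candidate`), inactive (f = 1) or toxic (low neuron-count multiplier).
#'
#' @param n_strong,n_candidate,n_inactive,n_toxic numbers of planted test
#'   wells per class (defaults 8/8/64/8; with 8 DMSO wells this fills a
#'   96-well plate).
#' @param n_dmso number of DMSO reference wells (default 8).
#' @param f_strong,f_candidate planted suppression for the two active
#'   classes (defaults 0.6, 0.85).
#' @param tox_toxic neuron-count multiplier for toxic wells (default 0.3).
#' @return a layout tibble with a `planted` column giving the true class.
#' @export
screen_layout <- function(n_strong = 8L, n_candidate = 8L, n_inactive = 64L,
                          n_dmso = 8L, n_toxic = 8L, f_strong = 0.6,
                          f_candidate = 0.85, tox_toxic = 0.3) {
  classes <- c(rep("dmso", n_dmso), rep("strong", n_strong),
               rep("candidate", n_candidate), rep("inactive", n_inactive),
               rep("toxic", n_toxic))
  n <- length(classes)
  rows <- LETTERS[1:8]
  wells <- paste0(rep(rows, each = 12), sprintf("%02d", rep(1:12, times = 8)))
  if (n > length(wells)) {
    abort("layout exceeds 96 wells", class = "crmp2screen_argument_error")
  }
  layout <- plate_layout(
    well = wells[seq_len(n)],
    compound = ifelse(classes == "dmso", "DMSO",
                      paste0("CPD", sprintf("%03d", seq_len(n)))),
    dose = ifelse(classes == "dmso", 0, 10),
    role = ifelse(classes == "dmso", "DMSO", "test"),
    f = c(dmso = 1, strong = f_strong, candidate = f_candidate,
          inactive = 1, toxic = 1)[classes],
    tox = ifelse(classes == "toxic", tox_toxic, 1)
  )
  layout$planted <- classes
  layout
}

#' Specification for a synthetic imaging plate
#'
#' Describes the microscope-and-biology model behind the simulated
#' three-channel fields: a plate layout with per-well suppression and
#' toxicity factors, the per-field cell mixture (neurons, MAP2-negative
#' non-neuronal cells, sub-threshold debris, over-sized clumps), and the
#' 16-bit intensity model (constant background plus additive Gaussian camera
#' noise). Nuclear areas are drawn inside the classifier's pass band for
#' neurons/non-neurons, below 50 um^2 for debris and above 160 um^2 for
#' clumps.
#'
#' @param layout a [plate_layout()] tibble.
#' @param fields_per_well images per well; must lie in 4..6 (default 4).
#' @param image_size `c(rows, cols)` in pixels (default 192 x 192).
#' @param pixel_size microns per pixel (default 0.65, a plausible 20x
#'   calibration).
#' @param cell_mix named counts per field:
#'   `c(neurons=, non_neurons=, debris=, clumps=)`.
#' @param intensity list: `nuclear_mean`, `nuclear_sd` (per-object),
#'   `map2_mean`, `background`, `noise_sd`, on the 16-bit camera-count
#'   scale.
#' @param neurite list: `n` per neuron, `length_px` range, `step_sd`
#'   (radians of direction noise per step).
#' @param seed RNG seed; everything downstream is a pure function of
#'   (spec, seed).
#' @return a list of class `"plate_spec"`.
#' @export
plate_spec <- function(layout = plate_layout(c("A01", "A02", "A03", "A04"),
                                             c("DMSO", "DMSO", "CHIR", "CHIR"),
                                             dose = c(0, 0, 10, 10),
                                             role = c("DMSO", "DMSO",
                                                      "positive_control",
                                                      "positive_control"),
                                             f = c(1, 1, 0.232, 0.232)),
                       fields_per_well = 4L,
                       image_size = c(192L, 192L),
                       pixel_size = 0.65,
                       cell_mix = c(neurons = 8L, non_neurons = 5L,
                                    debris = 3L, clumps = 1L),
                       intensity = list(nuclear_mean = 12000,
                                        nuclear_sd = 1500,
                                        map2_mean = 9000,
                                        background = 600,
                                        noise_sd = 150),
                       neurite = list(n = 3L, length_px = c(30L, 60L),
                                      step_sd = 0.25),
                       seed = 1L) {
  if (fields_per_well < 4L || fields_per_well > 6L) {
    abort("fields_per_well must lie in 4..6",
          class = "crmp2screen_argument_error")
  }
  if (pixel_size <= 0) {
    abort("pixel_size must be positive", class = "crmp2screen_argument_error")
  }
  if (any(cell_mix < 0)) {
    abort("cell_mix counts must be >= 0", class = "crmp2screen_argument_error")
  }
  structure(list(layout = layout, fields_per_well = as.integer(fields_per_well),
                 image_size = as.integer(image_size), pixel_size = pixel_size,
                 cell_mix = cell_mix, intensity = intensity, neurite = neurite,
                 seed = as.integer(seed)),
            class = "plate_spec")
}

# draw a filled disc into a matrix; returns linear pixel indices
disc_idx <- function(nr, nc, cy, cx, r) {
  ys <- max(1L, floor(cy - r)):min(nr, ceiling(cy + r))
  xs <- max(1L, floor(cx - r)):min(nc, ceiling(cx + r))
  grid <- expand.grid(y = ys, x = xs)
  keep <- (grid$y - cy)^2 + (grid$x - cx)^2 <= r^2
  (grid$x[keep] - 1L) * nr + grid$y[keep]
}

# persistent random walk from (y, x); stops at image borders and before
# entering the collar zone of any obstacle (other cells' nuclei), so
# per-cell ring statistics stay uncontaminated by foreign processes
random_walk <- function(y, x, theta, n_steps, step_sd, nr, nc,
                        obstacles = NULL, clearance = 5) {
  path <- matrix(0, nrow = n_steps, ncol = 2)
  for (i in seq_len(n_steps)) {
    theta <- theta + rnorm(1, 0, step_sd)
    y <- y + sin(theta)
    x <- x + cos(theta)
    if (y < 2 || y > nr - 1 || x < 2 || x > nc - 1) {
      path <- path[seq_len(i - 1L), , drop = FALSE]
      break
    }
    if (!is.null(obstacles) && nrow(obstacles) &&
        any(sqrt((obstacles[, 1] - y)^2 + (obstacles[, 2] - x)^2) <
              obstacles[, 3] + clearance)) {
      path <- path[seq_len(i - 1L), , drop = FALSE]
      break
    }
    path[i, ] <- c(y, x)
  }
  unique(round(path[path[, 1] > 0, , drop = FALSE]))
}

#' Generate one synthetic imaging field
#'
#' Places the spec's cell mixture without overlap (bounded retries), draws
#' the three channels and returns per-object ground truth. Neurons get a
#' nuclear blob, a MAP2-positive perinuclear patch plus random-walk
#' neurites, and p-CRMP2 signal equal to `f` times the MAP2 signal on those
#' pixels; non-neurons get nuclei only; debris is small and dim; clumps are
#' oversized blobs.
#'
#' @param spec a [plate_spec()].
#' @param f suppression factor for this field's well.
#' @param tox neuron-count multiplier for this field's well.
#' @param seed integer seed for this field.
#' @return list with `images` (list of matrices `nuclear`, `map2`,
#'   `pcrmp2`, camera counts), `truth` (list: `objects` tibble with `class`,
#'   `area_um2`, `centroid_y`, `centroid_x`; `skeletons` list of coordinate
#'   matrices per neuron; `f`).
#' @export
generate_field <- function(spec, f = 1, tox = 1, seed = spec$seed) {
  stopifnot(inherits(spec, "plate_spec"))
  nr <- spec$image_size[1]
  nc <- spec$image_size[2]
  px <- spec$pixel_size
  ints <- spec$intensity
  with_seed(seed, {
    n_neu <- round(spec$cell_mix[["neurons"]] * tox)
    counts <- c(neuron = n_neu,
                `non-neuron` = spec$cell_mix[["non_neurons"]],
                debris = spec$cell_mix[["debris"]],
                clump = spec$cell_mix[["clumps"]])
    # object radii (px) from target areas (um^2)
    area_of <- function(cls) {
      switch(cls,
        neuron = runif(1, 70, 140),
        `non-neuron` = runif(1, 70, 140),
        debris = runif(1, 15, 40),
        clump = runif(1, 180, 300))
    }
    nuc_sig <- matrix(0, nr, nc)
    map2_sig <- matrix(0, nr, nc)
    # phase 1: place every object before drawing, so neurite walks can
    # steer clear of all other cells' collar zones
    cls_vec <- rep(names(counts), counts)
    n_obj <- length(cls_vec)
    radii <- vapply(cls_vec, function(cls) sqrt(area_of(cls) / pi) / px,
                    numeric(1))
    ord <- order(radii, decreasing = TRUE) # big objects first pack better
    centers <- NULL
    for (restart in 1:50) {
      placed_all <- TRUE
      cen <- matrix(numeric(0), ncol = 3) # y, x, radius (px)
      for (r in radii[ord]) {
        placed <- FALSE
        for (try_i in 1:200) {
          cy <- runif(1, r + 6, nr - r - 6)
          cx <- runif(1, r + 6, nc - r - 6)
          # 8 px edge-to-edge keeps 2-um collar rings of neighbours disjoint
          if (!nrow(cen) ||
              all(sqrt((cen[, 1] - cy)^2 + (cen[, 2] - cx)^2) >
                    cen[, 3] + r + 8)) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          placed_all <- FALSE
          break
        }
        cen <- rbind(cen, c(cy, cx, r))
      }
      if (placed_all) {
        centers <- cen[order(ord), , drop = FALSE] # back to class order
        break
      }
    }
    if (is.null(centers)) {
      abort("could not place objects without overlap; enlarge the image or reduce cell_mix",
            class = "crmp2screen_placement_error")
    }
    # phase 2: draw nuclei and, for neurons, soma patches and neurites
    objects <- list()
    skeletons <- list()
    for (i in seq_len(n_obj)) {
      cls <- cls_vec[i]
      cy <- centers[i, 1]
      cx <- centers[i, 2]
      r <- centers[i, 3]
      idx <- disc_idx(nr, nc, cy, cx, r)
      level <- max(ints$nuclear_mean + rnorm(1, 0, ints$nuclear_sd), 500)
      nuc_sig[idx] <- level * (1 + rnorm(length(idx), 0, 0.05))
      objects[[length(objects) + 1L]] <- tibble::tibble(
        class = cls, area_um2 = length(idx) * px^2,
        centroid_y = cy, centroid_x = cx, nuclear_level = level
      )
      if (cls == "neuron") {
        obstacles <- centers[-i, , drop = FALSE]
        skel <- matrix(numeric(0), ncol = 2)
        thetas <- runif(1, 0, 2 * pi) +
          seq(0, 2 * pi, length.out = spec$neurite$n + 1L)[-1L]
        for (theta in thetas) {
          start_y <- cy + (r + 1.5) * sin(theta)
          start_x <- cx + (r + 1.5) * cos(theta)
          len <- round(runif(1, spec$neurite$length_px[1],
                             spec$neurite$length_px[2]))
          path <- random_walk(start_y, start_x, theta, len,
                              spec$neurite$step_sd, nr, nc,
                              obstacles = obstacles,
                              clearance = 2 / px + 3)
          if (!nrow(path)) next
          skel <- rbind(skel, path)
          # stamp a 3-px-wide tube along the path
          for (dd in list(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
            yy <- pmin(pmax(path[, 1] + dd[1], 1), nr)
            xx <- pmin(pmax(path[, 2] + dd[2], 1), nc)
            map2_sig[(xx - 1) * nr + yy] <-
              ints$map2_mean * (1 + rnorm(length(yy), 0, 0.1))
          }
        }
        # sparse punctate perinuclear MAP2 so the collar ring mixes bright
        # puncta with background (high CV, the neuron signature)
        soma_idx <- disc_idx(nr, nc, cy, cx, r + 2 / px)
        soma_idx <- setdiff(soma_idx, disc_idx(nr, nc, cy, cx, r))
        soma_idx <- soma_idx[runif(length(soma_idx)) < 0.15]
        map2_sig[soma_idx] <- ints$map2_mean *
          (1 + rnorm(length(soma_idx), 0, 0.1))
        skeletons[[length(skeletons) + 1L]] <- skel
      }
    }
    noise <- function() matrix(rnorm(nr * nc, 0, ints$noise_sd), nr, nc)
    clamp <- function(m) pmin(pmax(m, 0), 65535)
    images <- list(
      nuclear = clamp(ints$background + nuc_sig + noise()),
      map2    = clamp(ints$background + map2_sig + noise()),
      pcrmp2  = clamp(ints$background + f * map2_sig + noise())
    )
    truth <- list(
      objects = if (length(objects)) dplyr::bind_rows(objects) else
        tibble::tibble(class = character(), area_um2 = numeric(),
                       centroid_y = numeric(), centroid_x = numeric(),
                       nuclear_level = numeric()),
      skeletons = skeletons,
      f = f
    )
    list(images = images, truth = truth)
  })
}

#' Generate a full synthetic plate
#'
#' One image set per (well, field) of the layout, each generated under a
#' seed derived deterministically from the spec seed, so individual fields
#' can be regenerated independently and the whole plate is reproducible.
#'
#' @param spec a [plate_spec()].
#' @return an object of class `"synthetic_plate"`: list with `spec` and
#'   `fields`, a list of `list(well, field, images, truth)`.
#' @examples
#' sp <- plate_spec(plate_layout("A01", "DMSO", role = "DMSO"),
#'                  image_size = c(96L, 96L),
#'                  cell_mix = c(neurons = 2L, non_neurons = 1L,
#'                               debris = 1L, clumps = 0L))
#' plate <- generate_plate(sp)
#' length(plate$fields)
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  fields <- list()
  for (w in seq_len(nrow(spec$layout))) {
    row <- spec$layout[w, ]
    for (fi in seq_len(spec$fields_per_well)) {
      fld <- generate_field(spec, f = row$f, tox = row$tox,
                            seed = child_seed(spec$seed,
                                              (w - 1L) * spec$fields_per_well + fi))
      fields[[length(fields) + 1L]] <- c(list(well = row$well, field = fi), fld)
    }
  }
  structure(list(spec = spec, fields = fields), class = "synthetic_plate")
}

#' Write / read a synthetic plate on disk
#'
#' `write_plate()` writes one multi-page 16-bit TIFF per field (page order:
#' 1 nuclear, 2 MAP2, 3 p-CRMP2), the plate layout as CSV, and the ground
#' truth as JSON. `read_plate_field()` reads one such TIFF back into the
#' three-matrix camera-count representation.
#'
#' @param plate a `synthetic_plate`.
#' @param dir output directory (created if needed).
#' @return `write_plate()`: `dir`, invisibly. `read_plate_field()`: a list
#'   of matrices `nuclear`, `map2`, `pcrmp2`.
#' @export
write_plate <- function(plate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fld in plate$fields) {
    path <- file.path(dir, sprintf("%s_f%d.tif", fld$well, fld$field))
    pages <- lapply(fld$images, function(m) round(m) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  utils::write.csv(as.data.frame(plate$spec$layout),
                   file.path(dir, "layout.csv"), row.names = FALSE)
  truth <- lapply(plate$fields, function(fld) {
    list(well = fld$well, field = fld$field, f = fld$truth$f,
         objects = as.data.frame(fld$truth$objects))
  })
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @param path path to a field TIFF written by `write_plate()`.
#' @rdname write_plate
#' @export
read_plate_field <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) == 3L)
  setNames(lapply(pages, function(p) p * 65535), c("nuclear", "map2", "pcrmp2"))
}
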