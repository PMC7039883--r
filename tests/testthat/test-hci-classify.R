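# build a nuclear_objects container directly from a label matrix, so the
# criterion logic can be probed with exact areas and intensities
fake_nuclei <- function(labels, nuclear_img, pixel_size = 1) {
  labs <- sort(unique(labels[labels > 0]))
  tab <- tibble::tibble(
    label = labs,
    area_um2 = vapply(labs, function(l) sum(labels == l) * pixel_size^2, 1),
    mean_intensity = vapply(labs, function(l) mean(nuclear_img[labels == l]), 1),
    centroid_y = vapply(labs, function(l) mean(row(labels)[labels == l]), 1),
    centroid_x = vapply(labs, function(l) mean(col(labels)[labels == l]), 1)
  )
  structure(list(table = tab, labels = labels, pixel_size = pixel_size),
            class = "nuclear_objects")
}

rect_labels <- function(nr, nc, specs) {
  labels <- matrix(0L, nr, nc)
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    labels[s$y + seq_len(s$h) - 1, s$x + seq_len(s$w) - 1] <- i
  }
  labels
}

test_that("each criterion rejects its constructed violator in printed order", {
  nr <- nc <- 120
  # areas at pixel_size 1: 100 (pass), 30 (debris), 100 (dim), 200 (clump)
  labels <- rect_labels(nr, nc, list(
    list(y = 10, x = 10, h = 10, w = 10),
    list(y = 10, x = 60, h = 5, w = 6),
    list(y = 60, x = 10, h = 10, w = 10),
    list(y = 60, x = 60, h = 10, w = 20)
  ))
  nuclear <- matrix(600, nr, nc)
  nuclear[labels == 1] <- 3000
  nuclear[labels == 2] <- 3000
  nuclear[labels == 3] <- 1500
  nuclear[labels == 4] <- 3000
  # bright, patchy MAP2 ring around object 1 only (high mean AND high CV)
  map2 <- matrix(600, nr, nc)
  ring1 <- cbind(rep(8, 10), 10:19)
  map2[ring1] <- 9000
  nuclei <- fake_nuclei(labels, nuclear)
  cells <- classify_cells(nuclei, nuclear, map2,
                          hci_thresholds(map2_floor = 1000))
  expect_identical(cells$class,
                   c("neuron", "rejected-debris", "rejected-dim",
                     "rejected-clump"))
  expect_true(cells$ring_map2_cv[1] > 1)
})

test_that("the size band includes its 50 and 160 um2 boundaries", {
  labels <- rect_labels(60, 200, list(
    list(y = 20, x = 10, h = 5, w = 10),   # exactly 50
    list(y = 20, x = 60, h = 10, w = 16),  # exactly 160
    list(y = 20, x = 120, h = 7, w = 7)    # 49: below the band
  ))
  nuclear <- matrix(3000, 60, 200)
  map2 <- matrix(600, 60, 200)
  nuclei <- fake_nuclei(labels, nuclear)
  cells <- classify_cells(nuclei, nuclear, map2,
                          hci_thresholds(map2_floor = 1000))
  expect_identical(cells$size_ok, c(TRUE, TRUE, FALSE))
  labels49 <- rect_labels(60, 60, list(list(y = 20, x = 10, h = 7, w = 7)))
  cells49 <- classify_cells(fake_nuclei(labels49, matrix(3000, 60, 60)),
                            matrix(3000, 60, 60), matrix(600, 60, 60),
                            hci_thresholds(map2_floor = 1000))
  expect_identical(cells49$class, "rejected-debris")
})

test_that("the equivalent-diameter unit option changes the size metric", {
  labels <- rect_labels(60, 60, list(list(y = 20, x = 10, h = 10, w = 10)))
  nuclear <- matrix(3000, 60, 60)
  map2 <- matrix(600, 60, 60)
  nuclei <- fake_nuclei(labels, nuclear)
  as_area <- classify_cells(nuclei, nuclear, map2,
                            hci_thresholds(map2_floor = 1000))
  expect_true(as_area$size_ok) # 100 um2 inside [50, 160]
  as_diam <- classify_cells(nuclei, nuclear, map2,
                            hci_thresholds(map2_floor = 1000,
                                           size_unit = "diameter"))
  expect_false(as_diam$size_ok) # equivalent diameter 11.3 um < 50
})

test_that("classification of generated fields matches ground truth closely", {
  accs <- vapply(1:5, function(s) {
    fld <- generate_field(plate_spec(seed = 1), f = 0.8, seed = 200 + s)
    res <- analyze_field(fld$images)
    truth_accuracy(fld, res$cells)
  }, numeric(1))
  expect_gte(mean(accs), 0.95)
})

test_that("MAP2-positive neuron counts track ground truth within one", {
  for (s in 1:3) {
    fld <- generate_field(plate_spec(seed = 1), f = 1, seed = 300 + s)
    res <- analyze_field(fld$images)
    n_true <- sum(fld$truth$objects$class == "neuron")
    n_called <- sum(res$cells$class == "neuron")
    expect_lte(abs(n_called - n_true), 1)
  }
})

test_that("the inverted CV mode flips the fourth criterion", {
  labels <- rect_labels(60, 60, list(list(y = 20, x = 20, h = 10, w = 10)))
  nuclear <- matrix(3000, 60, 60)
  map2 <- matrix(2000, 60, 60) # flat ring: CV ~ 0, mean above floor
  nuclei <- fake_nuclei(labels, nuclear)
  std <- classify_cells(nuclei, nuclear, map2,
                        hci_thresholds(map2_floor = 1000))
  inv <- classify_cells(nuclei, nuclear, map2,
                        hci_thresholds(map2_floor = 1000,
                                       cv_high_is_neuron = FALSE))
  expect_identical(std$class, "non-neuron")
  expect_identical(inv$class, "neuron")
})
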