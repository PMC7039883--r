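wells_fixture <- function(percents, roles) {
  list(
    wells = tibble::tibble(well = paste0("W", seq_along(percents)),
                           percent_pcrmp2 = percents),
    layout = tibble::tibble(well = paste0("W", seq_along(percents)),
                            role = roles)
  )
}

test_that("reference normalization reproduces closed-form values", {
  fx <- wells_fixture(c(60, 60, 30), c("DMSO", "DMSO", "test"))
  norm <- normalize_to_reference(fx$wells, fx$layout, "dmso")
  expect_equal(norm$normalized_percent, c(100, 100, 50))
  # a well equal to the DMSO mean normalizes to exactly 100
  fx2 <- wells_fixture(c(50, 70, 60), c("DMSO", "DMSO", "test"))
  expect_equal(normalize_to_reference(fx2$wells, fx2$layout,
                                      "dmso")$normalized_percent[3], 100)
})

test_that("all-well-average normalization averages to exactly 100", {
  set.seed(3)
  fx <- wells_fixture(runif(96, 40, 120), rep("test", 96))
  norm <- normalize_to_reference(fx$wells, fx$layout, "all_well_average")
  expect_equal(mean(norm$normalized_percent), 100)
})

test_that("normalization is idempotent against the same reference", {
  fx <- wells_fixture(c(80, 120, 55), c("DMSO", "DMSO", "test"))
  once <- normalize_to_reference(fx$wells, fx$layout, "dmso")
  again <- normalize_to_reference(
    tibble::tibble(well = once$well, percent_pcrmp2 = once$normalized_percent),
    fx$layout, "dmso")
  expect_equal(again$normalized_percent, once$normalized_percent)
})

test_that("missing or zero references raise a typed error naming the mode", {
  fx <- wells_fixture(c(50, 60), c("test", "test"))
  expect_error(normalize_to_reference(fx$wells, fx$layout, "dmso"),
               class = "crmp2screen_reference_error", regexp = "dmso")
  expect_error(normalize_to_reference(fx$wells, fx$layout, "lithium_1mM"),
               class = "crmp2screen_reference_error")
})

test_that("Z-prime matches its closed forms and degenerate limits", {
  # sd_neg 4, sd_pos 2, window 80: 1 - 3*6/80
  neg <- c(96, 100, 104)
  pos <- c(18, 20, 22)
  expect_equal(zprime(pos, neg), 1 - 3 * (sd(pos) + sd(neg)) / 80)
  expect_equal(zprime(c(20, 20), c(100, 100)), 1)
  expect_warning(z <- zprime(c(50, 60), c(55, 55)),
                 class = "crmp2screen_zprime_undefined")
  expect_true(is.na(z))
  expect_error(zprime(1, c(1, 2)), class = "crmp2screen_argument_error")
})

test_that("Z-prime never exceeds one and decreases with spread", {
  set.seed(11)
  for (i in 1:20) {
    z <- zprime(rnorm(8, 20, runif(1, 0.1, 30)),
                rnorm(8, 100, runif(1, 0.1, 30)))
    expect_lte(z, 1)
  }
  base <- c(-1, 0, 1)
  z_narrow <- zprime(20 + base, 100 + base)
  z_wide <- zprime(20 + 5 * base, 100 + base)
  expect_lt(z_wide, z_narrow)
})

test_that("hit bands follow the configured edges with toxicity override", {
  cmp <- tibble::tibble(
    compound = rep(c("a", "b", "c", "d"), each = 3),
    normalized_percent = rep(c(100, 85, 60, 85), each = 3),
    count_ratio = rep(c(1.0, 0.9, 0.9, 0.3), each = 3)
  )
  hits <- call_hits(cmp)
  expect_identical(hits$band[match(c("a", "b", "c", "d"), hits$compound)],
                   c("inactive", "candidate", "strong", "toxic"))
  expect_error(call_hits(cmp, bands = c(candidate = 80, strong = 90)),
               class = "crmp2screen_config_error")
})

test_that("every non-toxic compound falls in exactly one monotone band", {
  set.seed(7)
  cmp <- tibble::tibble(compound = paste0("c", 1:60),
                        normalized_percent = runif(60, 40, 130),
                        count_ratio = 1)
  hits <- call_hits(cmp)
  expect_true(all(hits$band %in% c("strong", "candidate", "inactive")))
  ord <- order(hits$mean_percent)
  codes <- c(strong = 1, candidate = 2, inactive = 3)[hits$band[ord]]
  expect_true(all(diff(codes) >= 0))
})

test_that("the unpaired t-test matches its fixtures and star bands", {
  same <- unpaired_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_identical(same$stars, "")

  tt <- unpaired_ttest(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(tt$t), 3.674, tolerance = 1e-3)
  expect_equal(tt$df, 4)
  expect_equal(tt$p, 0.0214, tolerance = 1e-2)
  expect_identical(tt$stars, "*")
  # agreement with the stats t-test as an independent oracle
  oracle <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(tt$p, oracle$p.value)

  expect_identical(p_stars(5e-4), "***")
  expect_identical(unpaired_ttest(c(0, 0), c(5, 5))$p, 0)
})

test_that("stars form a non-increasing step function with inclusive edges", {
  ps <- c(0.2, 0.05, 0.049, 0.01, 0.0099, 0.001, 9e-4, 1e-4, 9e-5)
  stars <- p_stars(ps)
  expect_identical(stars, c("", "", "*", "*", "**", "**", "***", "***",
                            "****"))
  expect_true(all(diff(nchar(stars)) >= 0))
})
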