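test_that("canonical names: 150 total, 15 per cell-level feature, ordered", {
  nm <- feature_names()
  expect_length(nm, 150L)
  expect_equal(nm[11], "area_mean")
  expect_equal(nm[1:3], c("area_bin1", "area_bin2", "area_bin3"))
  expect_equal(sum(startsWith(nm, "ratio_")), 15L)
  expect_equal(nm[150], "distMin_entropy")
  expect_length(cell_feature_names(), 10L)
})

test_that("bin edges span the nearest-rank [P1, P99] range in equal widths", {
  scheme <- fit_bin_scheme(list(area = 1:100))
  expect_equal(scheme$area, seq(1, 99, by = 9.8))
  expect_length(scheme$area, 11L)
})

test_that("bin schemes round-trip through JSON bit-exactly", {
  set.seed(8)
  pooled <- setNames(lapply(1:10, function(i) rlnorm(500, 3, 0.7)),
                     cell_feature_names())
  scheme <- fit_bin_scheme(pooled)
  path <- tempfile(fileext = ".json")
  write_bin_scheme(scheme, path)
  expect_identical(read_bin_scheme(path), scheme)
})

test_that("degenerate or thin pooled values are rejected", {
  expect_error(fit_bin_scheme(list(area = rep(5, 200))), "degenerate")
  expect_error(fit_bin_scheme(list(area = 1:50)), ">= 100")
})

make_cells <- function(area, distMean = NULL) {
  n <- length(area)
  data.frame(area = area, major = area / 10, minor = area / 20,
             ratio = rep(2, n), rMean = rep(100, n), gMean = rep(100, n),
             bMean = rep(100, n),
             distMean = distMean %||% rep(10, n),
             distMax = rep(12, n), distMin = rep(8, n))
}

uniform_scheme <- function() {
  # edges 0..10 for every feature, bin width 1
  structure(setNames(rep(list(seq(0, 10, 1)), 10), cell_feature_names()),
            class = "bin_scheme")
}

test_that("one cell per bin gives a uniform histogram with maximal entropy", {
  cells <- make_cells(seq(0.5, 9.5, 1))
  v <- aggregate_patient(cells, uniform_scheme())
  expect_length(v, 150L)
  expect_identical(names(v), feature_names())
  expect_equal(unname(v[paste0("area_bin", 1:10)]), rep(0.1, 10))
  expect_equal(unname(v["area_entropy"]), log(10), tolerance = 1e-12)
})

test_that("all cells in one bin give a degenerate histogram, zero entropy", {
  cells <- make_cells(rep(3.5, 8))
  v <- aggregate_patient(cells, uniform_scheme())
  expect_equal(unname(v["area_bin4"]), 1)
  expect_equal(sum(v[paste0("area_bin", 1:10)]), 1)
  expect_equal(unname(v["area_entropy"]), 0)
  expect_equal(unname(v["area_std"]), 0)
})

test_that("out-of-range values clamp into the first and last bins", {
  cells <- make_cells(c(-5, -1, 15, 20))
  v <- aggregate_patient(cells, uniform_scheme())
  expect_equal(unname(v["area_bin1"]), 0.5)
  expect_equal(unname(v["area_bin10"]), 0.5)
})

test_that("statistics are computed on raw values with stated conventions", {
  x <- c(1, 2, 3, 4, 10)
  cells <- make_cells(x)
  v <- aggregate_patient(cells, uniform_scheme())
  m <- mean(x); d <- x - m
  expect_equal(unname(v["area_mean"]), m)
  expect_equal(unname(v["area_std"]), sqrt(mean(d^2)))       # population SD
  expect_equal(unname(v["area_skewness"]), mean(d^3) / mean(d^2)^1.5)
  expect_equal(unname(v["area_kurtosis"]), mean(d^4) / mean(d^2)^2)
})

test_that("histogram proportions sum to one for every feature", {
  set.seed(31)
  cells <- make_cells(runif(40, -3, 14), distMean = runif(40, 0, 30))
  v <- aggregate_patient(cells, uniform_scheme())
  for (f in cell_feature_names())
    expect_equal(sum(v[paste0(f, "_bin", 1:10)]), 1, tolerance = 1e-12)
})

test_that("aggregation is invariant to how cells are split across slides", {
  set.seed(13)
  cells <- make_cells(runif(60, 0, 10))
  split_idx <- sample(1:3, 60, replace = TRUE)
  slides <- lapply(1:3, function(k) cells[split_idx == k, ])
  expect_identical(aggregate_patient(cells, uniform_scheme()),
                   aggregate_patient(slides, uniform_scheme()))
})

test_that("a constant shift moves area mass up without touching ratio", {
  set.seed(41)
  base <- make_cells(runif(50, 1, 6))
  shifted <- base
  shifted$area <- shifted$area + 2
  v0 <- aggregate_patient(base, uniform_scheme())
  v1 <- aggregate_patient(shifted, uniform_scheme())
  expect_identical(v0[paste0("ratio_bin", 1:10)], v1[paste0("ratio_bin", 1:10)])
  mean_bin <- function(v) sum(seq_len(10) * v[paste0("area_bin", 1:10)])
  expect_gt(mean_bin(v1), mean_bin(v0))
})

test_that("isolated nuclei are excluded from distance features only", {
  cells <- make_cells(c(2, 4, 6))
  cells$distMean <- c(5, NA, 7)
  cells$distMax <- c(6, NA, 8)
  cells$distMin <- c(4, NA, 6)
  v <- aggregate_patient(cells, uniform_scheme())
  expect_equal(unname(v["distMean_mean"]), 6)
  expect_equal(sum(v[paste0("distMean_bin", 1:10)]), 1)
  expect_equal(unname(v["area_mean"]), 4)
})

test_that("an empty patient is an error", {
  expect_error(aggregate_patient(make_cells(numeric(0)), uniform_scheme()),
               "empty patient")
})
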