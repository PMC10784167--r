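test_that("tile partition covers the image exactly, padding ragged edges", {
  img <- matrix(0L, 16, 16)
  pt <- partition_tiles(img, clahe_config(2, 2))
  expect_length(pt$tiles, 4L)
  expect_equal(dim(pt$tiles[[1]]), c(8L, 8L))

  ragged <- matrix(seq_len(17 * 16) %% 256L, 17, 16)
  pt2 <- partition_tiles(ragged, clahe_config(2, 2))
  expect_equal(dim(pt2$padded), c(18L, 16L))
  # reflected bottom row equals the original's last row
  expect_equal(pt2$padded[18, ], ragged[17, ])
  expect_equal(sum(vapply(pt2$tiles, length, 0L)), 18L * 16L)

  single <- partition_tiles(img, clahe_config(1, 1))
  expect_identical(single$tiles[[1]], img)
  expect_error(partition_tiles(matrix(nrow = 0, ncol = 0), clahe_config()),
               "non-empty")
})

test_that("tile histograms count every pixel once", {
  expect_equal(tile_histogram(matrix(3L, 2, 2), L = 8),
               c(0, 0, 0, 4, 0, 0, 0, 0))
  set.seed(2)
  tile <- matrix(sample(0:15, 48, TRUE), 6, 8)
  H <- tile_histogram(tile, L = 16)
  expect_equal(sum(H), 48)
  expect_error(tile_histogram(matrix(300L, 2, 2), L = 256), "must lie")
})

test_that("histogram clipping caps bins and optionally conserves mass", {
  expect_equal(clip_histogram(c(5, 10, 2), 4), c(4, 4, 2))
  expect_equal(clip_histogram(c(5, 10, 2), 100), c(5, 10, 2))
  r <- clip_histogram(c(5, 10, 2), 4, redistribute = TRUE)
  expect_equal(sum(r), 17)
  # excess 7 over 3 bins: 2 everywhere plus 1 to the first bin
  expect_equal(r, c(4 + 3, 4 + 2, 2 + 2))
  expect_true(all(clip_histogram(c(5, 10, 2), 4) <= 4))
})

test_that("cumulative histograms and their rescaling behave as mappings", {
  expect_equal(histogram_cdf(c(1, 2, 3)), c(1, 3, 6))
  expect_equal(histogram_cdf(c(0, 0, 0)), c(0, 0, 0))
  C <- histogram_cdf(c(0, 4, 0))
  expect_equal(C, c(0, 4, 4))

  expect_equal(redistribute_cdf(16, L = 8, n_pixels = 16), 7)
  expect_equal(redistribute_cdf(0, L = 8, n_pixels = 16), 0)
  Cfull <- histogram_cdf(c(4, 4, 8))
  m <- redistribute_cdf(Cfull, L = 3, n_pixels = 16)
  expect_equal(m[3], 2)  # top level maps to L-1
  expect_error(redistribute_cdf(c(1, 2), 4, 0), "positive")
})

test_that("single-tile unclipped CLAHE equals global histogram equalization", {
  set.seed(5)
  img <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  cfg <- clahe_config(1, 1, clip_limit = 1e9, clip_unit = "count")
  expect_equal(clahe(img, cfg), global_hist_eq_oracle(img), tolerance = 1e-12)
})

test_that("CLAHE maps constant images to constant images and stays in range", {
  const <- matrix(7L, 32, 32)
  out <- clahe(const, clahe_config(2, 2, clip_limit = 1e9, clip_unit = "count"))
  expect_equal(max(out) - min(out), 0)

  set.seed(6)
  img <- matrix(sample(0:255, 40 * 40, TRUE), 40, 40)
  for (merge in c("bilinear", "nearest")) {
    out <- clahe(img, clahe_config(4, 4, clip_limit = 0.02, merge = merge))
    expect_equal(dim(out), dim(img))
    expect_gte(min(out), 0)
    expect_lte(max(out), 255)
  }
})

test_that("nearest merge on a two-tile image equals per-tile equalization", {
  set.seed(7)
  left <- matrix(sample(0:127, 16 * 16, TRUE), 16, 16)
  right <- matrix(sample(128:255, 16 * 16, TRUE), 16, 16)
  img <- cbind(left, right)
  cfg <- clahe_config(1, 2, clip_limit = 1e9, clip_unit = "count",
                      merge = "nearest")
  out <- clahe(img, cfg)
  expect_equal(out[, 1:16], global_hist_eq_oracle(left), tolerance = 1e-12)
  expect_equal(out[, 17:32], global_hist_eq_oracle(right), tolerance = 1e-12)
})

test_that("the literal clip mode leaves no tile histogram bin above the limit", {
  set.seed(8)
  img <- matrix(sample(0:63, 32 * 32, TRUE), 32, 32)
  cfg <- clahe_config(2, 2, clip_limit = 10, clip_unit = "count")
  pt <- partition_tiles(img, cfg)
  for (tile in pt$tiles) {
    H <- clip_histogram(tile_histogram(tile, 64), 10)
    expect_true(all(H <= 10))
  }
})
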