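test_that("one-hot encoding follows the A,C,G,T column convention", {
  expect_equal(unname(one_hot_encode("ACGT")), diag(4))
  expect_equal(unname(one_hot_encode("acgt")), diag(4))
  expect_equal(as.numeric(one_hot_encode("N")), rep(0, 4))
  expect_error(one_hot_encode("ACXG"), "position 3")
  expect_equal(one_hot_decode(one_hot_encode("ACGTNACGT")), "ACGTNACGT")
})

test_that("squash transform matches its printed two-branch form and inverts", {
  expect_equal(squash(0), 0)
  expect_equal(squash(16), 8)             # 16^(3/4) below the threshold
  # brute-force evaluation of the printed formula at a large value
  x <- 1e6
  y <- x^(3 / 4)
  expect_equal(squash(x), min(y, 384) + max(0, y - 384))
  expect_equal(squash(x), y)              # the two branches sum to x^(3/4)
  # monotone and invertible on a log-spaced grid
  grid <- c(0, 10^seq(-3, 7, length.out = 120))
  s <- squash(grid)
  expect_true(all(diff(s) > 0))
  expect_equal(unsquash(s), grid, tolerance = 1e-6)
  # optional soft-clip exponent compresses above the threshold only
  below <- 100; above <- 1e5
  expect_equal(squash(below, clip_exponent = 0.5), squash(below))
  expect_lt(squash(above, clip_exponent = 0.5), squash(above))
  expect_equal(unsquash(squash(above, clip_exponent = 0.5),
                        clip_exponent = 0.5), above, tolerance = 1e-6)
  expect_error(squash(-1), "nonnegative")
})

test_that("bin_coverage sum-pools and conserves total counts", {
  expect_equal(bin_coverage(rep(1, 64), 32), c(32, 32))
  expect_equal(bin_coverage(rep(0, 96), 32), c(0, 0, 0))
  imp <- rep(0, 128); imp[34] <- 5    # bp 33 in 0-based coordinates
  expect_equal(bin_coverage(imp, 32), c(0, 5, 0, 0))
  set.seed(1)
  v <- rpois(320, 3)
  expect_equal(sum(bin_coverage(v, 32)), sum(v))
  expect_error(bin_coverage(rep(1, 65), 32), "divisible")
})

test_that("crop_bins drops the configured bins from each end", {
  meta <- tiny_meta()
  ts <- track_set(matrix(seq_len(12288 * 4), 12288, 4), 32L, meta)
  expect_equal(nrow(crop_bins(ts, 2048)$values), 8192)
  expect_identical(crop_bins(ts, 0), ts)
  small <- track_set(matrix(1, 10, 4), 32L, meta)
  expect_error(crop_bins(small, 5), "crop")
})

test_that("revcomp augmentation reverses, complements and exchanges pairs", {
  win <- sequence_window("w", 0L, one_hot_encode("AAAC"))
  vals <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 2, 4)
  ts <- track_set(vals, 2L, tiny_meta())
  aug <- revcomp_augment(win, ts)
  expect_equal(one_hot_decode(aug$win$onehot), "GTTT")
  # FWD/REV pair exchanged and reversed
  expect_equal(aug$tracks$values[, 1], c(4, 3))
  expect_equal(aug$tracks$values[, 2], c(2, 1))
  # unstranded tracks reversed in bin order only
  expect_equal(aug$tracks$values[, 3], c(6, 5))
  twice <- revcomp_augment(aug$win, aug$tracks)
  expect_equal(twice$win$onehot, win$onehot)
  expect_equal(twice$tracks$values, ts$values)
})

test_that("revcomp augmentation is an involution on random instances", {
  meta <- tiny_meta()
  for (seed in 1:5) {
    set.seed(seed)
    win <- sequence_window("w", 0L, random_onehot(64))
    ts <- track_set(matrix(rpois(32 * 4, 3), 32, 4), 2L, meta)
    aug <- revcomp_augment(win, ts)
    back <- revcomp_augment(aug$win, aug$tracks)
    expect_equal(back$win$onehot, win$onehot)
    expect_equal(back$tracks$values, ts$values)
  }
})

test_that("broken strand pairing is rejected", {
  expect_error(track_meta("x", "CAGE", "FWD", NA), "pair_id")
  expect_error(track_meta(c("x", "y"), "CAGE", c("FWD", "FWD"),
                          c("p", "p")), "FWD/REV")
})

test_that("shift augmentation vacates exactly |shift| rows and is bounded", {
  win <- sequence_window("w", 0L, one_hot_encode("ACGTACGT"))
  expect_equal(shift_augment(win, 0L)$onehot, win$onehot)
  sh <- shift_augment(win, 3L)
  expect_equal(rowSums(sh$onehot)[1:3], c(0, 0, 0))
  expect_equal(sh$onehot[4:8, ], win$onehot[1:5, ])
  expect_equal(sum(win$onehot) - sum(sh$onehot), 3)
  shm <- shift_augment(win, -2L)
  expect_equal(rowSums(shm$onehot)[7:8], c(0, 0))
  expect_equal(shm$onehot[1:6, ], win$onehot[3:8, ])
  expect_error(shift_augment(win, 4L), "shift_max")
})

test_that("splits partition windows with near-equal folds and rotate tests", {
  cfg <- data_config(window_len = 64, bin_width = 32, crop_bins = 0,
                     n_folds = 6)
  splits <- make_splits(26, cfg, seed = 7)
  expect_length(splits, 4)
  fold <- splits[[1]]$fold_of_window
  expect_true(all(abs(table(fold) - 26 / 6) <= 1))
  test_folds <- vapply(splits, function(s) which(s$role_of_fold == "TEST"),
                       1L)
  val_folds <- vapply(splits, function(s) which(s$role_of_fold == "VAL"), 1L)
  expect_equal(anyDuplicated(test_folds), 0L)
  expect_equal(anyDuplicated(val_folds), 0L)
  for (s in splits) {
    expect_length(which(s$role_of_fold == "VAL"), 1)
    expect_length(which(s$role_of_fold == "TEST"), 1)
    parts <- lapply(c("TRAIN", "VAL", "TEST"), split_windows, split = s)
    expect_setequal(unlist(parts), seq_len(26))
    expect_equal(sum(lengths(parts)), 26)   # pairwise disjoint
  }
  expect_identical(make_splits(26, cfg, seed = 7), splits)  # determinism
  expect_false(identical(make_splits(26, cfg, seed = 8)[[1]]$fold_of_window,
                         fold))
  expect_error(make_splits(5, cfg), "at least")
})

test_that("12 windows over 6 folds give folds of exactly 2", {
  cfg <- data_config(window_len = 64, bin_width = 32, crop_bins = 0)
  s <- make_splits(12, cfg, seed = 1)[[1]]
  expect_true(all(table(s$fold_of_window) == 2))
})

test_that("data_config validates its invariants", {
  expect_error(data_config(window_len = 100, bin_width = 32), "window_len")
  expect_error(data_config(split_ratio = c(3, 1, 1)), "split_ratio")
  cfg <- data_config()
  expect_equal(cfg$window_len, 393216L)
  expect_equal(cfg$crop_bins, 2048L)
})
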