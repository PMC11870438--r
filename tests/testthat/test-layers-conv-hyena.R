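test_that("conv block halves the length and pools correctly", {
  set.seed(1)
  p <- conv_block_init(3, 5, 5)
  x <- matrix(rnorm(64 * 3), 64, 3)
  y <- conv_block_fwd(p, x)$y
  expect_equal(dim(y), c(32L, 5L))
  expect_error(conv_block_fwd(p, x[1:63, ]), "even")
  # max-pooling of a monotone signal preserves per-pair maxima
  mono <- matrix(seq_len(16), 16, 1)
  pl <- covscan:::maxpool2_fwd(mono)
  expect_equal(as.numeric(pl$y), seq(2, 16, 2))
})

test_that("five trunk blocks map full-scale input shape to (12288, 768)", {
  cfg <- model_config(window_len = 393216L, n_tracks = 4L, d_model = 768L)
  tr <- model_shape_trace(cfg)
  expect_equal(tr$trunk_positions, 12288L)
  expect_equal(tr$trunk_channels, 768L)
})

test_that("composed dilated kernels equal serial application", {
  # direct causal serial application as the independent oracle
  apply_dilated <- function(x, weights, dilation) {
    kd <- covscan:::dilate_kernel(weights, dilation)
    y <- numeric(length(x))
    for (t in seq_along(x)) {
      for (i in seq_along(kd)) {
        if (t - i + 1 >= 1) y[t] <- y[t] + kd[i] * x[t - i + 1]
      }
    }
    y
  }
  set.seed(2)
  ks <- list(list(weights = rnorm(3), dilation = 1L),
             list(weights = rnorm(3), dilation = 2L))
  k <- compose_dilated_kernels(ks)
  expect_length(k, 7)    # 1 + 1*(3-1) + 2*(3-1)
  x <- rnorm(80)
  serial <- apply_dilated(apply_dilated(x, ks[[1]]$weights, 1L),
                          ks[[2]]$weights, 2L)
  composed <- apply_dilated(x, k, 1L)
  expect_lt(max(abs(serial - composed)), 1e-10)
  # convolution commutes: reversed composition order gives the same kernel
  expect_equal(compose_dilated_kernels(rev(ks)), k)
  # identity kernel is neutral
  expect_equal(compose_dilated_kernels(list(list(weights = 1, dilation = 1L),
                                            ks[[2]])),
               covscan:::dilate_kernel(ks[[2]]$weights, 2L))
  expect_error(compose_dilated_kernels(list(list(weights = diag(2),
                                                 dilation = 1L))),
               "single-channel")
})

test_that("FFT long convolution matches direct convolution", {
  direct_centered <- function(x, k) {
    L <- nrow(x); c0 <- L %/% 2
    y <- matrix(0, L, ncol(x))
    for (t in seq_len(L)) {
      for (j in seq_len(L)) {
        src <- t - (j - 1 - c0)
        if (src >= 1 && src <= L) y[t, ] <- y[t, ] + k[j, ] * x[src, ]
      }
    }
    y
  }
  set.seed(3)
  worst <- 0
  for (L in c(16, 64, 257)) {
    x <- matrix(rnorm(L * 2), L, 2)
    k <- matrix(rnorm(L * 2), L, 2)
    worst <- max(worst, max(abs(fft_long_conv(x, k, causal = FALSE) -
                                  direct_centered(x, k))))
  }
  expect_lt(worst, 1e-5)
  # unit impulse at the center index is the identity map
  L <- 64
  x <- matrix(rnorm(L * 3), L, 3)
  ki <- matrix(0, L, 3); ki[L %/% 2 + 1, ] <- 1
  expect_equal(fft_long_conv(x, ki, causal = FALSE), x, tolerance = 1e-10)
  # causal: impulse response strictly zero before the impulse
  xi <- matrix(0, L, 1); xi[20, 1] <- 1
  y <- fft_long_conv(xi, matrix(rnorm(L), L, 1), causal = TRUE)
  expect_lt(max(abs(y[1:19, 1])), 1e-12)
  expect_error(fft_long_conv(x, ki[1:32, ]), "match")
})

test_that("SIREN kernels are deterministic and follow the 1/L variance rule", {
  set.seed(4)
  p <- siren_init(4)
  expect_equal(siren_filter(p, 128), siren_filter(p, 128))
  vars <- vapply(1:200, function(s) {
    set.seed(s)
    p <- siren_init(4)
    c(var(as.numeric(siren_filter(p, 256))),
      var(as.numeric(siren_filter(p, 1024))))
  }, numeric(2))
  ratio <- mean(vars[2, ]) / mean(vars[1, ])
  expect_gt(ratio, 0.25 * 0.7)
  expect_lt(ratio, 0.25 * 1.3)
  # unit-variance rule: kernel variance independent of L, so conv output
  # variance grows proportionally to L
  set.seed(5)
  pu <- siren_init(1, final_init = "unit")
  outvar <- vapply(c(256, 1024), function(L) {
    x <- matrix(rnorm(L), L, 1)
    var(as.numeric(fft_long_conv(x, siren_filter(pu, L), causal = FALSE)))
  }, numeric(1))
  expect_gt(outvar[2] / outvar[1], 2)
})

test_that("hyena layer preserves shape and reduces to identity at zero out-proj", {
  set.seed(6)
  p <- hyena_init(8)
  x <- matrix(rnorm(64 * 8), 64, 8)
  y <- hyena_fwd(p, x)
  expect_equal(dim(y), dim(x))
  p0 <- p; p0$W_out[] <- 0; p0$b_out[] <- 0
  expect_equal(hyena_fwd(p0, x), x)
  expect_error(hyena_fwd(p, cbind(x, x)), "mismatch")
  # channel mixing variant runs and keeps shape
  pm <- hyena_init(8, channel_mixing = TRUE)
  expect_equal(dim(hyena_fwd(pm, x)), dim(x))
})

test_that("the 1/L SIREN rule keeps 8 stacked hyena layers stable while
           unit-variance initialization blows activations up", {
  depth_ratio <- function(rule, L = 256, depth = 8, d = 16, seed = 11) {
    set.seed(seed)
    x <- matrix(rnorm(L * d), L, d)
    s0 <- sd(x)
    for (i in seq_len(depth)) {
      p <- hyena_init(d, final_init = rule)
      x <- hyena_fwd(p, x)
    }
    sd(x) / s0
  }
  good <- depth_ratio("invlen")
  expect_gt(good, 0.1)
  expect_lt(good, 10)
  bad <- depth_ratio("unit")
  expect_gt(bad, 10)
  # the pathology worsens with sequence length
  expect_gt(depth_ratio("unit", L = 512, depth = 4),
            depth_ratio("invlen", L = 512, depth = 4))
})
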