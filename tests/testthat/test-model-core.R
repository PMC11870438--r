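tiny_cfg <- function(stack = stack_striped(1, 1, N = 4, pos_mode = "ROPE")) {
  model_config(window_len = 1024L, n_tracks = 4L, d_model = 16L,
               trunk_blocks = 5L, stack = stack, attn_heads = 2L,
               attn_d_qk = 8L)
}

test_that("model builds deterministically and maps (L,4) to (L/32, T)", {
  cfg <- tiny_cfg()
  m1 <- build_model(cfg, seed = 3)
  m2 <- build_model(cfg, seed = 3)
  expect_identical(unlist(model_trainable(m1)), unlist(model_trainable(m2)))
  m3 <- build_model(cfg, seed = 4)
  expect_false(identical(unlist(model_trainable(m1)),
                         unlist(model_trainable(m3))))
  oh <- random_onehot(1024, seed = 1)
  r <- model_forward(m1, oh)$rates
  expect_equal(dim(r), c(32L, 4L))
  expect_true(all(r > 0))
  expect_error(model_forward(m1, oh[1:512, ]), "one-hot")
  expect_gt(count_model_params(m1), 0)
})

test_that("striped config builds the advertised layer counts", {
  cfg <- tiny_cfg(stack_striped(2, 2, N = 4))
  m <- build_model(cfg, seed = 1)
  kinds <- vapply(m$stack, `[[`, "", "kind")
  expect_equal(sum(kinds == "MAMBA"), 4)
  expect_equal(sum(kinds == "UNET"), 2)
  n_attn <- sum(vapply(m$stack[kinds == "UNET"], function(l)
    length(l$inner), 1L))
  expect_equal(n_attn, 2)
})

test_that("full-scale shape facts hold in the static trace", {
  cfg <- model_config(window_len = 393216L, n_tracks = 8L, d_model = 768L)
  tr <- model_shape_trace(cfg)
  expect_equal(tr$trunk_positions, 12288L)
  expect_equal(tr$trunk_channels, 768L)
  expect_equal(tr$output_bins, 12288L)
  # cropping 2048 bins per end leaves 8192 bins for the loss
  expect_equal(tr$output_bins - 2L * 2048L, 8192L)
})

test_that("composite loss behaves like independent Poisson at weight 1", {
  set.seed(5)
  B <- 64; Tr <- 3
  pred <- matrix(rexp(B * Tr) + 0.05, B, Tr)
  counts <- matrix(rpois(B * Tr, 3), B, Tr)
  g_comp <- poisson_multinomial_grad(pred, counts, w = 1)
  g_pois <- 1 - counts / pred          # per-bin Poisson NLL gradient
  expect_lt(max(abs(g_comp - g_pois)) / max(abs(g_pois)), 1e-12)
  # the losses differ only by a constant independent of the rates
  const1 <- poisson_multinomial_loss(pred, counts, w = 1) -
    sum(pred - counts * log(pred))
  pred2 <- matrix(rexp(B * Tr) + 0.05, B, Tr)
  const2 <- poisson_multinomial_loss(pred2, counts, w = 1) -
    sum(pred2 - counts * log(pred2))
  expect_equal(const1, const2)
  expect_error(poisson_multinomial_loss(pred, counts - 10), "negative")
})

test_that("the loss is stationary at the observed counts", {
  set.seed(6)
  counts <- matrix(rpois(40 * 2, 5) + 1, 40, 2)   # strictly positive
  g <- poisson_multinomial_grad(counts, counts, w = 4)
  expect_lt(max(abs(g)), 1e-10)
  # and the analytic gradient matches finite differences at w = 4
  pred <- counts + matrix(runif(80, 0.1, 0.5), 40, 2)
  num <- fd_grad(function(v)
    poisson_multinomial_loss(matrix(v, 40, 2), counts, w = 4),
    as.numeric(pred), eps = 1e-5)
  ana <- as.numeric(poisson_multinomial_grad(pred, counts, w = 4))
  expect_lt(max(abs(num - ana)) / max(abs(ana)), 1e-5)
})

test_that("equivariance gap is ~0 for an equivariant toy predictor and
           positive for a random model", {
  oh <- random_onehot(1024, seed = 7)
  meta <- tiny_meta()
  toy <- toy_equivariant_predictor(32L)
  expect_lt(equivariance_gap(toy, oh, meta), 1e-5)
  # symmetric in which strand is called forward
  gap1 <- equivariance_gap(toy, oh, meta)
  gap2 <- equivariance_gap(toy, covscan:::revcomp_onehot(oh), meta)
  expect_equal(gap1, gap2, tolerance = 1e-12)
  m <- build_model(tiny_cfg(), seed = 8)
  expect_gt(equivariance_gap(m, oh, meta), 0)
})

test_that("learning-rate schedule warms up linearly to the peak", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 0)
  expect_equal(lr_schedule(5000, cfg), 5e-5)
  expect_equal(lr_schedule(10000, cfg), 1e-4)
  expect_equal(lr_schedule(20000, cfg), 1e-4)
})

test_that("gradient clipping enforces block then global norms", {
  cfg <- train_config()
  # single block with norm 20 rescaled to 5
  b <- list(a = list(x = rep(2, 100)))   # norm 20
  out <- clip_gradients(b, 5, 10)
  expect_equal(sqrt(sum(unlist(out)^2)), 5)
  # compliant gradients unchanged (idempotence)
  small <- list(a = list(x = rep(0.1, 4)), b = list(y = 0.2))
  expect_equal(clip_gradients(small, 5, 10), small)
  expect_equal(clip_gradients(clip_gradients(b, 5, 10), 5, 10), out)
  # 8 blocks each at norm 5: global norm sqrt(200) ~ 14.1 -> rescale to 10
  blocks <- lapply(1:8, function(i) list(x = rep(5 / sqrt(25), 25)))
  names(blocks) <- paste0("b", 1:8)
  cl <- clip_gradients(blocks, 5, 10)
  expect_equal(sqrt(sum(unlist(cl)^2)), 10)
  expect_error(clip_gradients(list(a = NaN), 5, 10), "non-finite")
})

test_that("adding a zero-output-projection layer leaves the forward map
           unchanged exactly", {
  cfg <- tiny_cfg(stack_mamba(1, N = 4))
  m <- build_model(cfg, seed = 9)
  oh <- random_onehot(1024, seed = 10)
  base <- model_forward(m, oh)$rates
  extra <- covscan:::stack_layer_init(list(kind = "MAMBA", N = 4, E = 1),
                                      m$cfg)
  extra$params$W_out[] <- 0
  extra$params$b_out[] <- 0
  m$stack <- c(m$stack, list(extra))
  expect_equal(model_forward(m, oh)$rates, base)
})

test_that("end-to-end model gradients match finite differences", {
  cfg <- model_config(window_len = 256L, n_tracks = 3L, d_model = 8L,
                      trunk_blocks = 5L,
                      stack = stack_striped(1, 1, N = 2, pos_mode = "ROPE"),
                      attn_heads = 2L, attn_d_qk = 4L)
  m <- build_model(cfg, seed = 11)
  oh <- random_onehot(256, seed = 12)
  set.seed(13)
  counts <- matrix(rpois(8 * 3, 2), 8, 3)
  f <- model_forward(m, oh, want_cache = TRUE)
  g <- covscan:::model_grads_canon(
    m, model_backward(m, f$cache, poisson_multinomial_grad(f$rates, counts)))
  skel <- model_trainable(m)
  flat <- unlist(skel)
  gflat <- unlist(g)
  lossf <- function(v) {
    mm <- model_set_trainable(m, utils::relist(v, skel))
    poisson_multinomial_loss(model_forward(mm, oh)$rates, counts)
  }
  set.seed(14)
  idx <- sample(length(flat), 30)
  gnum <- vapply(idx, function(k) {
    vp <- flat; vp[k] <- vp[k] + 1e-5
    vm <- flat; vm[k] <- vm[k] - 1e-5
    (lossf(vp) - lossf(vm)) / 2e-5
  }, numeric(1))
  expect_lt(max(abs(gnum - gflat[idx])) / max(abs(gnum)), 1e-3)
})
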