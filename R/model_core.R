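# Architecture assembly, composite Poisson-multinomial loss, equivariance
# diagnostic, learning-rate schedule and two-level gradient clipping.

#' Stack specification helpers
#'
#' `stack_mamba(n)` gives `n` bidirectional Mamba layers; `stack_striped`
#' repeats `n_mamba` Mamba layers followed by a U-Net-wrapped attention
#' block (e.g. `stack_striped(2, 2)` is the striped
#' `[Mamba x2 + UNet(attention)] x2` pattern); `stack_attn` gives a
#' U-Net-wrapped stack of `n` attention blocks (the transformer path,
#' with two pool rounds).
#'
#' @param n,n_mamba,n_repeats layer counts.
#' @param N,E Mamba state dimension and expansion factor.
#' @param pos_mode positional-encoding mode for attention layers.
#' @param pool_rounds U-Net pool rounds around each attention group.
#' @return list of layer specs for [model_config].
#' @export
stack_mamba <- function(n = 6L, N = 8L, E = 1L) {
  rep(list(list(kind = "MAMBA", N = N, E = E)), n)
}

#' @rdname stack_mamba
#' @export
stack_striped <- function(n_mamba = 2L, n_repeats = 2L, N = 8L, E = 1L,
                          pos_mode = "ROPE", pool_rounds = 1L) {
  unlist(lapply(seq_len(n_repeats), function(i) {
    c(rep(list(list(kind = "MAMBA", N = N, E = E)), n_mamba),
      list(list(kind = "UNET", pool_rounds = pool_rounds,
                inner = list(list(kind = "ATTN", pos_mode = pos_mode)))))
  }), recursive = FALSE)
}

#' @rdname stack_mamba
#' @export
stack_attn <- function(n = 4L, pos_mode = "ENFORMER_REL", pool_rounds = 2L) {
  list(list(kind = "UNET", pool_rounds = pool_rounds,
            inner = rep(list(list(kind = "ATTN", pos_mode = pos_mode)), n)))
}

#' Model architecture configuration
#'
#' @param window_len input window length in bp.
#' @param n_tracks number of output coverage tracks.
#' @param d_model embedding width after the trunk (768 at full scale).
#' @param bin_width output bin width in bp (32).
#' @param trunk_blocks number of conv/pool trunk blocks; each halves the
#'   length, so `2^trunk_blocks` must equal `bin_width` for the head to
#'   emit one value per bin.
#' @param trunk_kernel_first,trunk_kernel_rest trunk conv widths.
#' @param stack list of layer specs (see [stack_mamba] and friends).
#' @param attn_heads,attn_d_qk attention hyperparameters.
#' @param rate_floor positivity floor added to predicted rates.
#' @return object of class `model_config`.
#' @export
model_config <- function(window_len = 393216L, n_tracks = 8L,
                         d_model = 768L, bin_width = 32L,
                         trunk_blocks = 5L,
                         trunk_kernel_first = 15L, trunk_kernel_rest = 5L,
                         stack = stack_mamba(6L),
                         attn_heads = 4L, attn_d_qk = 64L,
                         rate_floor = 1e-6) {
  if (2L^trunk_blocks != bin_width) {
    stop("trunk pools 2^", trunk_blocks, "-fold but bin width is ", bin_width)
  }
  if (window_len %% bin_width != 0L) stop("window_len not divisible by bin")
  structure(list(window_len = as.integer(window_len),
                 n_tracks = as.integer(n_tracks),
                 d_model = as.integer(d_model),
                 bin_width = as.integer(bin_width),
                 trunk_blocks = as.integer(trunk_blocks),
                 trunk_kernel_first = as.integer(trunk_kernel_first),
                 trunk_kernel_rest = as.integer(trunk_kernel_rest),
                 stack = stack,
                 attn_heads = as.integer(attn_heads),
                 attn_d_qk = as.integer(attn_d_qk),
                 rate_floor = rate_floor),
            class = "model_config")
}

#' Static shape trace of a model configuration
#'
#' Walks the architecture without running it and reports the tensor shape
#' after every stage: trunk output positions and channels, the coarsest
#' resolution seen by attention layers inside U-Net wraps, and the output
#' bin count.
#'
#' @param cfg a [model_config].
#' @return list with `stages` (data.frame of stage/length/channels),
#'   `trunk_positions`, `trunk_channels`, `output_bins`,
#'   `attn_resolution_bp` (NA if no wrapped attention), and
#'   `total_pool_rounds`.
#' @export
model_shape_trace <- function(cfg) {
  L <- cfg$window_len
  ch <- 4L
  stages <- data.frame(stage = "input", length = L, channels = ch)
  tc <- trunk_channels(cfg$trunk_blocks, cfg$d_model)
  for (i in seq_len(cfg$trunk_blocks)) {
    L <- L %/% 2L
    stages <- rbind(stages, data.frame(
      stage = paste0("conv_block_", i), length = L, channels = tc[i]))
  }
  trunk_positions <- L
  attn_res <- NA_real_
  pools <- cfg$trunk_blocks
  for (i in seq_along(cfg$stack)) {
    sp <- cfg$stack[[i]]
    if (sp$kind == "UNET") {
      inner_L <- L %/% (2L^sp$pool_rounds)
      pools <- pools + sp$pool_rounds
      attn_res <- cfg$window_len / inner_L
      stages <- rbind(stages, data.frame(
        stage = paste0("unet_inner_", i), length = inner_L,
        channels = cfg$d_model))
    }
    stages <- rbind(stages, data.frame(
      stage = paste0(tolower(sp$kind), "_", i), length = L,
      channels = cfg$d_model))
  }
  stages <- rbind(stages, data.frame(stage = "head", length = L,
                                     channels = cfg$n_tracks))
  list(stages = stages, trunk_positions = trunk_positions,
       trunk_channels = cfg$d_model, output_bins = L,
       attn_resolution_bp = attn_res, total_pool_rounds = pools)
}

# initialize one stack layer from its spec (uses the current RNG stream)
stack_layer_init <- function(sp, cfg) {
  switch(sp$kind,
    MAMBA = list(kind = "MAMBA",
                 params = mamba_init(cfg$d_model,
                                     N = if (is.null(sp$N)) 8L else sp$N,
                                     E = if (is.null(sp$E)) 1L else sp$E)),
    HYENA = list(kind = "HYENA",
                 params = hyena_init(cfg$d_model,
                                     channel_mixing = isTRUE(sp$channel_mixing))),
    ATTN = list(kind = "ATTN",
                params = attention_init(cfg$d_model, heads = cfg$attn_heads,
                                        d_qk = cfg$attn_d_qk,
                                        pos_mode = sp$pos_mode)),
    UNET = list(kind = "UNET",
                params = unet_init(cfg$d_model, sp$pool_rounds),
                inner = lapply(sp$inner, stack_layer_init, cfg = cfg)),
    stop("unknown layer kind ", sp$kind))
}

#' Build a model from a configuration
#'
#' Initialization is deterministic given the seed; two builds with the
#' same seed have identical parameter vectors.
#'
#' @param cfg a [model_config].
#' @param seed integer seed for parameter initialization.
#' @return object of class `covscan_model`.
#' @export
build_model <- function(cfg, seed = 1L) {
  with_seed(seed, {
    tc <- trunk_channels(cfg$trunk_blocks, cfg$d_model)
    inc <- c(4L, tc[-length(tc)])
    trunk <- lapply(seq_len(cfg$trunk_blocks), function(i) {
      conv_block_init(inc[i], tc[i],
                      if (i == 1L) cfg$trunk_kernel_first
                      else cfg$trunk_kernel_rest)
    })
    stack <- lapply(cfg$stack, stack_layer_init, cfg = cfg)
    head <- list(W = init_dense(cfg$d_model, cfg$n_tracks),
                 b = rep(softplus_inv(0.5), cfg$n_tracks))
    structure(list(cfg = cfg, trunk = trunk, stack = stack, head = head),
              class = "covscan_model")
  })
}

## ---- stack layer dispatch --------------------------------------------------

layer_fwd <- function(layer, x, want_cache = FALSE, chunk_len = NULL) {
  switch(layer$kind,
    MAMBA = mamba_fwd(layer$params, x, want_cache = want_cache),
    ATTN = attention_fwd(layer$params, x, want_cache = want_cache,
                         chunk_len = chunk_len),
    HYENA = list(y = hyena_fwd(layer$params, x), cache = NULL),
    UNET = {
      inner_fwd <- function(z, wc) {
        caches <- vector("list", length(layer$inner))
        for (i in seq_along(layer$inner)) {
          r <- layer_fwd(layer$inner[[i]], z, want_cache = wc,
                         chunk_len = chunk_len)
          caches[[i]] <- r$cache
          z <- r$y
        }
        list(y = z, cache = caches)
      }
      unet_fwd(layer$params, x, inner_fwd, want_cache = want_cache)
    })
}

layer_bwd <- function(layer, cache, dy) {
  switch(layer$kind,
    MAMBA = mamba_bwd(layer$params, cache, dy),
    ATTN = attention_bwd(layer$params, cache, dy),
    HYENA = stop("Hyena layers are analysis/inference components here; ",
                 "training them is not supported"),
    UNET = {
      inner_bwd <- function(caches, dz) {
        grads <- vector("list", length(layer$inner))
        for (i in rev(seq_along(layer$inner))) {
          r <- layer_bwd(layer$inner[[i]], caches[[i]], dz)
          grads[[i]] <- r$grads
          dz <- r$dx
        }
        list(dx = dz, grads = grads)
      }
      unet_bwd(layer$params, cache, dy, inner_bwd)
    })
}

## ---- model forward / backward ----------------------------------------------

#' Forward pass: one-hot window to per-bin predicted rates
#'
#' @param model a `covscan_model`.
#' @param onehot (L, 4) one-hot input.
#' @param want_cache keep intermediates for [model_backward].
#' @param chunk_len optional attention chunk length (inference only).
#' @return `list(rates = (L/bin_width, n_tracks) positive matrix,
#'   cache = ...)`.
#' @export
model_forward <- function(model, onehot, want_cache = FALSE,
                          chunk_len = NULL) {
  cfg <- model$cfg
  if (nrow(onehot) != cfg$window_len || ncol(onehot) != 4L) {
    stop("expected a (", cfg$window_len, ", 4) one-hot input")
  }
  x <- onehot
  tcache <- vector("list", length(model$trunk))
  for (i in seq_along(model$trunk)) {
    r <- conv_block_fwd(model$trunk[[i]], x, want_cache = want_cache)
    tcache[[i]] <- r$cache
    x <- r$y
  }
  scache <- vector("list", length(model$stack))
  for (i in seq_along(model$stack)) {
    r <- layer_fwd(model$stack[[i]], x, want_cache = want_cache,
                   chunk_len = chunk_len)
    scache[[i]] <- r$cache
    x <- r$y
  }
  pre <- sweep(x %*% model$head$W, 2, model$head$b, `+`)
  rates <- softplus(pre) + cfg$rate_floor
  cache <- if (want_cache) list(trunk = tcache, stack = scache,
                                emb = x, pre = pre)
  list(rates = rates, cache = cache)
}

#' Backward pass of the full model
#' @param model a `covscan_model`.
#' @param cache from `model_forward(..., want_cache = TRUE)`.
#' @param drates gradient of the loss w.r.t. predicted rates.
#' @return nested gradient list with components `trunk`, `stack`, `head`.
#' @export
model_backward <- function(model, cache, drates) {
  dpre <- drates * softplus_grad(cache$pre)
  hg <- list(W = crossprod(cache$emb, dpre), b = colSums(dpre))
  dx <- dpre %*% t(model$head$W)
  sg <- vector("list", length(model$stack))
  for (i in rev(seq_along(model$stack))) {
    r <- layer_bwd(model$stack[[i]], cache$stack[[i]], dx)
    sg[[i]] <- r$grads
    dx <- r$dx
  }
  tg <- vector("list", length(model$trunk))
  for (i in rev(seq_along(model$trunk))) {
    r <- conv_block_bwd(model$trunk[[i]], cache$trunk[[i]], dx)
    tg[[i]] <- r$grads
    dx <- r$dx
  }
  list(trunk = tg, stack = sg, head = hg)
}

## ---- trainable parameter plumbing ------------------------------------------

# canonical trainable views, shaped exactly like backward gradients
layer_trainable_get <- function(layer) {
  switch(layer$kind,
    MAMBA = {
      p <- layer$params
      dirn <- c("conv_W", "conv_b", "W_bc", "W_dt1", "W_dt2", "b_dt", "A", "D")
      out <- list(rms_g = p$rms_g, W_in = p$W_in, W_gate = p$W_gate,
                  fwd = p$fwd[dirn], W_out = p$W_out, b_out = p$b_out)
      if (p$bidirectional) out$bwd <- p$bwd[dirn]
      out
    },
    ATTN = {
      p <- layer$params
      p[c("ln1_g", "ln1_b", "Wq", "Wk", "Wv", "Wo", "bo", "rel_w",
          "ln2_g", "ln2_b", "W1", "b1", "W2", "b2")]
    },
    UNET = list(rounds = lapply(layer$params$rounds, function(r)
                  r[c("W_up", "W_skip", "b")]),
                inner = lapply(layer$inner, layer_trainable_get)),
    HYENA = stop("Hyena layers are not trainable here"))
}

# reorder backward grads into the canonical trainable layout
layer_grads_canon <- function(layer, g) {
  switch(layer$kind,
    MAMBA = {
      dirn <- c("conv_W", "conv_b", "W_bc", "W_dt1", "W_dt2", "b_dt", "A", "D")
      out <- list(rms_g = g$rms_g, W_in = g$W_in, W_gate = g$W_gate,
                  fwd = g$fwd[dirn], W_out = g$W_out, b_out = g$b_out)
      if (!is.null(g$bwd)) out$bwd <- g$bwd[dirn]
      out
    },
    ATTN = g[c("ln1_g", "ln1_b", "Wq", "Wk", "Wv", "Wo", "bo", "rel_w",
               "ln2_g", "ln2_b", "W1", "b1", "W2", "b2")],
    UNET = list(rounds = lapply(g$rounds, function(r)
                  r[c("W_up", "W_skip", "b")]),
                inner = lapply(seq_along(layer$inner), function(i)
                  layer_grads_canon(layer$inner[[i]], g$inner[[i]]))))
}

layer_trainable_set <- function(layer, v) {
  switch(layer$kind,
    MAMBA = {
      for (nm in c("rms_g", "W_in", "W_gate", "W_out", "b_out")) {
        layer$params[[nm]][] <- v[[nm]]
      }
      for (nm in names(v$fwd)) layer$params$fwd[[nm]][] <- v$fwd[[nm]]
      if (!is.null(v$bwd)) {
        for (nm in names(v$bwd)) layer$params$bwd[[nm]][] <- v$bwd[[nm]]
      }
      layer
    },
    ATTN = {
      for (nm in names(v)) layer$params[[nm]][] <- v[[nm]]
      layer
    },
    UNET = {
      for (r in seq_along(v$rounds)) {
        for (nm in names(v$rounds[[r]])) {
          layer$params$rounds[[r]][[nm]][] <- v$rounds[[r]][[nm]]
        }
      }
      for (i in seq_along(v$inner)) {
        layer$inner[[i]] <- layer_trainable_set(layer$inner[[i]], v$inner[[i]])
      }
      layer
    })
}

#' Trainable parameters of a model as a nested numeric structure
#' @param model a `covscan_model`.
#' @return nested list mirroring the gradient structure of
#'   [model_backward].
#' @export
model_trainable <- function(model) {
  list(trunk = lapply(model$trunk, conv_block_trainable),
       stack = lapply(model$stack, layer_trainable_get),
       head = model$head)
}

#' Write a trainable-parameter structure back into a model
#' @param model a `covscan_model`.
#' @param v structure from [model_trainable] (possibly updated).
#' @return the updated model.
#' @export
model_set_trainable <- function(model, v) {
  for (i in seq_along(model$trunk)) {
    for (nm in names(v$trunk[[i]])) model$trunk[[i]][[nm]][] <- v$trunk[[i]][[nm]]
  }
  for (i in seq_along(model$stack)) {
    model$stack[[i]] <- layer_trainable_set(model$stack[[i]], v$stack[[i]])
  }
  model$head$W[] <- v$head$W
  model$head$b[] <- v$head$b
  model
}

# canonicalize backward grads to the model_trainable layout
model_grads_canon <- function(model, g) {
  list(trunk = lapply(g$trunk, function(x) x[c("gamma", "beta", "W", "b")]),
       stack = lapply(seq_along(model$stack), function(i)
         layer_grads_canon(model$stack[[i]], g$stack[[i]])),
       head = g$head[c("W", "b")])
}

#' @describeIn count_params total trainable parameters of a model.
#' @export
count_model_params <- function(params) {
  if (inherits(params, "covscan_model")) params <- model_trainable(params)
  count_params(params)
}

## ---- loss ------------------------------------------------------------------

#' Composite Poisson-multinomial coverage loss
#'
#' Per track, with predicted rates `lambda_i` over bins, `Lambda` their
#' sum, observed counts `x_i` and total `X`:
#' `loss = (Lambda - X log Lambda) + w * (-sum_i x_i log(lambda_i / Lambda))`.
#' The Poisson term scores the window's total counts and the multinomial
#' term their distribution over bins; at `w = 1` the sum equals the
#' independent per-bin Poisson negative log-likelihood up to an additive
#' constant that does not depend on the rates.  The default `w = 4`
#' upweights the positional term.
#'
#' @param pred (B, T) strictly positive predicted rates.
#' @param counts (B, T) nonnegative observed counts.
#' @param w multinomial weight (default 4).
#' @return scalar loss (summed over tracks).
#' @export
poisson_multinomial_loss <- function(pred, counts, w = 4) {
  if (any(counts < 0)) stop("negative counts")
  if (any(pred <= 0)) stop("rates must be strictly positive")
  Lam <- colSums(pred)
  X <- colSums(counts)
  pois <- sum(Lam - X * log(Lam))
  multi <- -sum(counts * (log(pred) - matrix(log(Lam), nrow(pred),
                                             ncol(pred), byrow = TRUE)))
  pois + w * multi
}

#' Gradient of the composite loss w.r.t. predicted rates
#' @inheritParams poisson_multinomial_loss
#' @return (B, T) gradient matrix.
#' @export
poisson_multinomial_grad <- function(pred, counts, w = 4) {
  Lam <- matrix(colSums(pred), nrow(pred), ncol(pred), byrow = TRUE)
  X <- matrix(colSums(counts), nrow(pred), ncol(pred), byrow = TRUE)
  (1 - X / Lam) + w * (X / Lam - counts / pred)
}

## ---- equivariance diagnostic -----------------------------------------------

#' Predicted rate matrix for a one-hot window
#'
#' Generic over model-like objects so diagnostics run on both trained
#' models and constructed oracles.
#'
#' @param object a `covscan_model` or `rate_oracle`.
#' @param onehot (L, 4) one-hot input.
#' @param ... passed to methods.
#' @return (bins, tracks) matrix of predicted rates.
#' @export
predict_bins <- function(object, onehot, ...) UseMethod("predict_bins")

#' @export
predict_bins.covscan_model <- function(object, onehot, ...) {
  model_forward(object, onehot, ...)$rates
}

#' Wrap a function as a rate-predicting oracle
#' @param fn function mapping a one-hot matrix to a (bins, tracks) matrix.
#' @return object of class `rate_oracle`.
#' @export
rate_oracle <- function(fn) structure(list(fn = fn), class = "rate_oracle")

#' @export
predict_bins.rate_oracle <- function(object, onehot, ...) object$fn(onehot)

#' Reverse-complement equivariance gap of a predictor
#'
#' Measures how far predictions depart from transforming predictably
#' under reverse complementation:
#' `|| f(revcomp(x)) - revcomp_tracks(f(x)) || / || f(x) ||`
#' where `revcomp_tracks` reverses bin order and exchanges strand-paired
#' tracks.  Zero for a strictly equivariant predictor; usable as a weak
#' additive training penalty.
#'
#' @param object a predictor accepted by [predict_bins].
#' @param onehot (L, 4) one-hot window.
#' @param meta a [track_meta] describing the predictor's output tracks.
#' @return nonnegative scalar.
#' @export
equivariance_gap <- function(object, onehot, meta) {
  f1 <- predict_bins(object, onehot)
  f2 <- predict_bins(object, revcomp_onehot(onehot))
  expected <- revcomp_tracks(f1, meta)
  sqrt(sum((f2 - expected)^2)) / sqrt(sum(f1^2))
}

## ---- schedule and clipping -------------------------------------------------

#' Training configuration
#'
#' Defaults follow the full-scale recipe: Adam with `beta1 = 0.9`,
#' `beta2 = 0.999`, learning rate 1e-4 with 10,000 linear warm-up steps,
#' gradient clipping at 5.0 per block and 10.0 globally, batch size 2,
#' L2 coefficient 1e-6 and multinomial weight 4.  Desk-scale runs
#' override the learning rate and warm-up through the same fields.
#'
#' @param lr peak learning rate.
#' @param warmup_steps linear warm-up length in steps.
#' @param beta1,beta2,adam_eps Adam moment parameters.
#' @param clip_block,clip_global gradient-clipping norms.
#' @param batch_size windows per optimizer step.
#' @param l2_coeff L2 regularizer coefficient.
#' @param multinomial_weight weight of the multinomial loss term.
#' @param patience early-stopping patience in epochs on validation mean
#'   Pearson r.
#' @return object of class `train_config`.
#' @export
train_config <- function(lr = 1e-4, warmup_steps = 10000L,
                         beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                         clip_block = 5, clip_global = 10,
                         batch_size = 2L, l2_coeff = 1e-6,
                         multinomial_weight = 4, patience = 5L) {
  stopifnot(lr > 0, warmup_steps > 0, clip_block > 0, clip_global > 0,
            batch_size >= 1, multinomial_weight > 0)
  structure(list(lr = lr, warmup_steps = as.integer(warmup_steps),
                 beta1 = beta1, beta2 = beta2, adam_eps = adam_eps,
                 clip_block = clip_block, clip_global = clip_global,
                 batch_size = as.integer(batch_size), l2_coeff = l2_coeff,
                 multinomial_weight = multinomial_weight,
                 patience = as.integer(patience)),
            class = "train_config")
}

#' Learning rate at a given step
#'
#' Linear warm-up to the peak rate, constant thereafter:
#' `lr * min(1, step / warmup_steps)`.
#'
#' @param step step index (>= 0).
#' @param cfg a [train_config].
#' @return learning rate.
#' @export
lr_schedule <- function(step, cfg = train_config()) {
  stopifnot(step >= 0)
  cfg$lr * pmin(1, step / cfg$warmup_steps)
}

#' Two-level gradient clipping
#'
#' Rescales each block (named layer group) to norm at most `clip_block`,
#' then rescales everything to global norm at most `clip_global`.
#' Idempotent on already-compliant gradients.
#'
#' @param blocks list of gradient blocks (each a numeric vector, matrix or
#'   nested list of them).
#' @param clip_block per-block norm bound.
#' @param clip_global global norm bound.
#' @return the clipped blocks, same structure.
#' @export
clip_gradients <- function(blocks, clip_block = 5, clip_global = 10) {
  flat <- lapply(blocks, function(b) unlist(b, use.names = FALSE))
  if (any(!vapply(flat, function(v) all(is.finite(v)), logical(1)))) {
    stop("non-finite gradients; diverged or invalid loss")
  }
  scale_rec <- function(b, s) {
    if (is.list(b)) lapply(b, scale_rec, s = s) else b * s
  }
  for (i in seq_along(blocks)) {
    nrm <- sqrt(sum(flat[[i]]^2))
    if (nrm > clip_block) {
      blocks[[i]] <- scale_rec(blocks[[i]], clip_block / nrm)
      flat[[i]] <- flat[[i]] * (clip_block / nrm)
    }
  }
  gnorm <- sqrt(sum(vapply(flat, function(v) sum(v^2), numeric(1))))
  if (gnorm > clip_global) {
    blocks <- lapply(blocks, scale_rec, s = clip_global / gnorm)
  }
  blocks
}

# model gradients as a flat list of clipping blocks:
# each trunk block, each stack layer, the head
model_grad_blocks <- function(g) {
  c(stats::setNames(g$trunk, paste0("trunk_", seq_along(g$trunk))),
    stats::setNames(g$stack, paste0("stack_", seq_along(g$stack))),
    list(head = g$head))
}

model_blocks_to_grads <- function(blocks, g) {
  nt <- length(g$trunk); ns <- length(g$stack)
  list(trunk = blocks[seq_len(nt)],
       stack = blocks[nt + seq_len(ns)],
       head = blocks[[nt + ns + 1L]])
}
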