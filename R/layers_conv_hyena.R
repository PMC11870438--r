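# Convolutional trunk blocks, dilated-kernel composition, SIREN implicit
# long-convolution filters (with the 1/L initialization rule), FFT long
# convolution, and the bidirectional Hyena-style gated long-conv layer.

## ---- trunk conv block ------------------------------------------------------

#' Initialize a trunk convolution block
#'
#' One round of the convolutional trunk: channel normalization, GELU,
#' "same" convolution, twofold max-pooling.  Output length is half the
#' input length.
#'
#' @param in_channels,out_channels channel counts.
#' @param kernel_width convolution width in bp.
#' @return parameter list of class `conv_block_params`.
#' @export
conv_block_init <- function(in_channels, out_channels, kernel_width = 5L) {
  structure(list(in_channels = as.integer(in_channels),
                 out_channels = as.integer(out_channels),
                 kernel_width = as.integer(kernel_width),
                 gamma = rep(1, in_channels), beta = numeric(in_channels),
                 W = init_dense(kernel_width * in_channels, out_channels),
                 b = numeric(out_channels)),
            class = "conv_block_params")
}

#' Forward pass of a trunk convolution block
#'
#' Order of operations is exactly normalization, activation, convolution,
#' twofold max-pooling.
#'
#' @param params from [conv_block_init].
#' @param x (L, in_channels) input with even L.
#' @param want_cache keep intermediates for [conv_block_bwd].
#' @return `list(y = (L/2, out_channels) matrix, cache = ...)`.
#' @export
conv_block_fwd <- function(params, x, want_cache = FALSE) {
  if (nrow(x) %% 2L != 0L) stop("conv block needs even input length")
  if (ncol(x) != params$in_channels) stop("expected ", params$in_channels,
                                          " input channels")
  nrm <- batchnorm_fwd(x, params$gamma, params$beta)
  a <- gelu(nrm$y)
  cv <- conv1d_fwd(a, params$W, params$b, params$kernel_width)
  pl <- maxpool2_fwd(cv$y)
  cache <- if (want_cache) list(nrm = nrm$cache, xn = nrm$y, conv = cv$cache,
                                pool = pl$cache, L = nrow(x))
  list(y = pl$y, cache = cache)
}

#' Backward pass of a trunk convolution block
#' @param params,cache from the forward pass.
#' @param dy upstream gradient, (L/2, out_channels).
#' @return `list(dx = ..., grads = ...)`.
#' @export
conv_block_bwd <- function(params, cache, dy) {
  dcv <- maxpool2_bwd(cache$pool, dy, cache$L)
  cb <- conv1d_bwd(cache$conv, dcv)
  da <- cb$dx * gelu_grad(cache$xn)
  nb <- batchnorm_bwd(cache$nrm, da)
  list(dx = nb$dx,
       grads = list(gamma = nb$dgamma, beta = nb$dbeta, W = cb$dW, b = cb$db))
}

conv_block_trainable <- function(params) {
  params[c("gamma", "beta", "W", "b")]
}

#' Geometric channel schedule for the convolutional trunk
#'
#' Interpolates channel counts geometrically from the 4 input channels to
#' the embedding width over `n_blocks` blocks.  `min_channels` floors the
#' early blocks: the first convolution is the model's motif-detector bank,
#' and at small embedding widths the raw geometric schedule would leave it
#' too few filters to represent both orientations of several motifs.
#'
#' @param n_blocks number of trunk blocks.
#' @param d_model final embedding width.
#' @param in_channels input channels (4 for one-hot DNA).
#' @param min_channels floor on per-block channel counts.
#' @return integer vector of `n_blocks` output channel counts.
#' @export
trunk_channels <- function(n_blocks, d_model, in_channels = 4L,
                           min_channels = 16L) {
  ratio <- (d_model / in_channels)^(1 / n_blocks)
  ch <- round(in_channels * ratio^seq_len(n_blocks))
  ch[n_blocks] <- d_model
  as.integer(pmax(ch, min(min_channels, d_model)))
}

## ---- dilated-kernel composition --------------------------------------------

# insert (dilation - 1) zeros between taps
dilate_kernel <- function(weights, dilation) {
  if (dilation == 1L) return(weights)
  w <- numeric((length(weights) - 1L) * dilation + 1L)
  w[seq(1L, length(w), by = dilation)] <- weights
  w
}

# full (polynomial) product of two kernels
convolve_kernels <- function(k1, k2) {
  out <- numeric(length(k1) + length(k2) - 1L)
  for (i in seq_along(k1)) {
    out[i:(i + length(k2) - 1L)] <- out[i:(i + length(k2) - 1L)] + k1[i] * k2
  }
  out
}

#' Compose serial dilated convolutions into one long kernel
#'
#' For single-channel (depthwise) linear convolutions, applying several
#' dilated kernels in series is exactly equivalent to applying one long
#' kernel: the space of 1-D convolutions is closed under composition and
#' dilation.  The returned kernel has support width
#' `1 + sum(d_i * (w_i - 1))`.
#'
#' @param kernels list of kernels, each a list with numeric `weights` and
#'   integer `dilation`.
#' @return numeric vector, the composed kernel.
#' @export
compose_dilated_kernels <- function(kernels) {
  out <- 1
  for (k in kernels) {
    if (is.matrix(k$weights)) {
      stop("only single-channel (depthwise) kernels compose into one kernel")
    }
    out <- convolve_kernels(out, dilate_kernel(k$weights, as.integer(k$dilation)))
  }
  out
}

## ---- SIREN implicit filters ------------------------------------------------

#' Initialize a SIREN coordinate network for implicit long-conv kernels
#'
#' A small network with sinusoidal activations maps a position
#' `t in [0, 1)` to one filter value per channel.  Hidden layers use the
#' standard frequency scale `omega`; the final linear layer's
#' initialization follows either the usual unit-variance rule or the
#' `1/L` rule, under which the generated kernel's variance scales as
#' `c / L` so that long-convolution outputs keep bounded variance at any
#' length.
#'
#' @param d_model number of output channels (filter per channel).
#' @param hidden hidden width (default 32).
#' @param n_hidden number of hidden layers (default 2).
#' @param omega sinusoidal frequency scale for hidden layers (default 30).
#' @param final_init `"invlen"` (the 1/L rule, default) or `"unit"`.
#' @return parameter list of class `siren_params`.
#' @export
siren_init <- function(d_model, hidden = 32L, n_hidden = 2L, omega = 30,
                       final_init = c("invlen", "unit")) {
  final_init <- match.arg(final_init)
  layers <- list()
  fan <- 1L
  for (i in seq_len(n_hidden)) {
    bound <- if (i == 1L) 1 / fan else sqrt(6 / fan) / omega
    layers[[i]] <- list(W = matrix(stats::runif(fan * hidden, -bound, bound),
                                   fan, hidden),
                        b = stats::runif(hidden, -pi, pi))
    fan <- hidden
  }
  bound <- sqrt(6 / fan)
  structure(list(layers = layers, omega = omega,
                 W_final = matrix(stats::runif(fan * d_model, -bound, bound),
                                  fan, d_model),
                 b_final = numeric(d_model),
                 final_init = final_init),
            class = "siren_params")
}

#' Generate an implicit convolution kernel of length L
#'
#' Deterministic given the parameters.  Under the `"invlen"` rule the
#' final layer is scaled by `1/sqrt(L)`, so kernel-entry variance is
#' proportional to `1/L`.
#'
#' @param params from [siren_init].
#' @param L kernel length (= sequence length for a long convolution).
#' @return (L, d_model) kernel matrix.
#' @export
siren_filter <- function(params, L) {
  stopifnot(L >= 1L)
  h <- matrix(seq_len(L) - 1L, ncol = 1L) / L
  for (ly in params$layers) {
    h <- sin(params$omega * sweep(h %*% ly$W, 2, ly$b, `+`))
  }
  k <- sweep(h %*% params$W_final, 2, params$b_final, `+`)
  if (params$final_init == "invlen") k <- k / sqrt(L)
  if (any(!is.finite(k))) stop("non-finite SIREN kernel")
  k
}

## ---- FFT long convolution --------------------------------------------------

#' Per-channel linear convolution with a full-length kernel via FFT
#'
#' Zero-pads to length `>= 2L` so the transform implements linear (not
#' circular) convolution.  With `causal = TRUE`, kernel tap 1 is lag 0 and
#' output at position t sees only positions `t' <= t`.  With
#' `causal = FALSE` the kernel is centered: tap `floor(L/2) + 1` is lag 0,
#' so both flanks contribute.
#'
#' @param x (L, d) input.
#' @param kernel (L, d) per-channel kernels.
#' @param causal flag, see above.
#' @return (L, d) output matrix.
#' @export
fft_long_conv <- function(x, kernel, causal = FALSE) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1L)
  if (!is.matrix(kernel)) kernel <- matrix(kernel, ncol = 1L)
  L <- nrow(x)
  if (nrow(kernel) != L || ncol(kernel) != ncol(x)) {
    stop("kernel must match input shape (", L, ", ", ncol(x), ")")
  }
  M <- stats::nextn(2L * L, 2L)
  xp <- rbind(x, matrix(0, M - L, ncol(x)))
  kp <- rbind(kernel, matrix(0, M - L, ncol(x)))
  z <- Re(stats::mvfft(stats::mvfft(xp) * stats::mvfft(kp), inverse = TRUE)) / M
  if (causal) {
    z[seq_len(L), , drop = FALSE]
  } else {
    c0 <- L %/% 2L
    z[c0 + seq_len(L), , drop = FALSE]
  }
}

## ---- Hyena layer -----------------------------------------------------------

#' Initialize a bidirectional Hyena-style layer
#'
#' LayerNorm, linear projection to `order + 1` branches each passed
#' through a short nearest-neighbour convolution (depthwise by default,
#' with full channel mixing when `channel_mixing = TRUE`), then `order`
#' rounds of elementwise gating interleaved with bidirectional FFT long
#' convolutions whose kernels are SIREN-generated and windowed by a
#' learnable exponential-decay envelope, and finally an output projection
#' with a residual connection.  SiLU activations throughout.
#'
#' @param d_model feature dimension.
#' @param order number of gating recurrences (default 2).
#' @param short_width nearest-neighbour conv width (default 3).
#' @param channel_mixing mix channels in the short convolutions.
#' @param final_init SIREN final-layer rule, `"invlen"` or `"unit"`.
#' @return parameter list of class `hyena_params`.
#' @export
hyena_init <- function(d_model, order = 2L, short_width = 3L,
                       channel_mixing = FALSE,
                       final_init = c("invlen", "unit")) {
  final_init <- match.arg(final_init)
  nb <- order + 1L
  short <- lapply(seq_len(nb), function(i) {
    if (channel_mixing) {
      list(W = init_dense(short_width * d_model, d_model), b = numeric(d_model))
    } else {
      list(W = matrix(stats::rnorm(short_width * d_model,
                                   sd = 1 / sqrt(short_width)),
                      short_width, d_model),
           b = numeric(d_model))
    }
  })
  structure(list(d_model = as.integer(d_model), order = as.integer(order),
                 short_width = as.integer(short_width),
                 channel_mixing = isTRUE(channel_mixing),
                 ln_g = rep(1, d_model), ln_b = numeric(d_model),
                 W_proj = init_dense(d_model, nb * d_model),
                 b_proj = numeric(nb * d_model),
                 short = short,
                 sirens = lapply(seq_len(order), function(i)
                   siren_init(d_model, final_init = final_init)),
                 decay_raw = matrix(stats::runif(order * d_model, -1, 1),
                                    order, d_model),
                 W_out = init_dense(d_model, d_model),
                 b_out = numeric(d_model)),
            class = "hyena_params")
}

# short nearest-neighbour conv ("same" padding), depthwise or mixing
hyena_short_conv <- function(x, sp, width, mixing) {
  if (mixing) {
    conv1d_fwd(x, sp$W, sp$b, width)$y
  } else {
    L <- nrow(x)
    pad <- (width - 1L) %/% 2L
    y <- matrix(0, L, ncol(x))
    for (k in seq_len(width)) {
      off <- k - 1L - pad
      src <- seq_len(L) + off
      ok <- src >= 1L & src <= L
      y[ok, ] <- y[ok, ] + sweep(x[src[ok], , drop = FALSE], 2, sp$W[k, ], `*`)
    }
    sweep(y, 2, sp$b, `+`)
  }
}

#' Forward pass of the Hyena-style layer
#' @param params from [hyena_init].
#' @param x (L, d_model) input.
#' @return (L, d_model) output (input shape preserved by the residual).
#' @export
hyena_fwd <- function(params, x) {
  if (ncol(x) != params$d_model) stop("shape mismatch")
  L <- nrow(x)
  u <- layernorm_fwd(x, params$ln_g, params$ln_b)$y
  proj <- sweep(u %*% params$W_proj, 2, params$b_proj, `+`)
  d <- params$d_model
  branches <- lapply(seq_len(params$order + 1L), function(i) {
    silu(hyena_short_conv(proj[, ((i - 1L) * d + 1L):(i * d), drop = FALSE],
                          params$short[[i]], params$short_width,
                          params$channel_mixing))
  })
  v <- branches[[1L]]
  pos <- abs((seq_len(L) - 1L) - L %/% 2L) / L
  for (o in seq_len(params$order)) {
    k <- siren_filter(params$sirens[[o]], L)
    env <- exp(-outer(pos, softplus(params$decay_raw[o, ])))
    v <- branches[[o + 1L]] * fft_long_conv(v, k * env, causal = FALSE)
  }
  x + sweep(v %*% params$W_out, 2, params$b_out, `+`)
}
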