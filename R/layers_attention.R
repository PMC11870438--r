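# Multi-head attention with three positional-encoding modes, memory-tiled
# (chunked) attention numerically equal to dense attention, and the U-Net
# pool/upsample wrapper.

## ---- positional encodings --------------------------------------------------

rope_angles <- function(d_qk, positions, base = 10000) {
  half <- d_qk %/% 2L
  freqs <- base^(-(seq_len(half) - 1L) / half)
  outer(positions, freqs)   # (L, d_qk/2) angles
}

#' Rotary positional encoding (RoPE)
#'
#' Rotates consecutive feature pairs of a query or key matrix by
#' position-proportional angles, so that inner products between encoded
#' queries and keys depend only on the relative offset `t - s`.
#'
#' @param x (L, d_qk) query or key matrix; `d_qk` must be even.
#' @param positions integer positions (default `0:(L-1)`).
#' @param base frequency base (default 1e4).
#' @return the rotated matrix, same shape; rotations are isometries.
#' @export
rope_encode <- function(x, positions = seq_len(nrow(x)) - 1L, base = 10000) {
  d <- ncol(x)
  if (d %% 2L != 0L) stop("RoPE needs an even feature dimension")
  ang <- rope_angles(d, positions, base)
  co <- cos(ang); si <- sin(ang)
  i1 <- seq(1L, d, 2L); i2 <- seq(2L, d, 2L)
  out <- x
  out[, i1] <- x[, i1] * co - x[, i2] * si
  out[, i2] <- x[, i1] * si + x[, i2] * co
  out
}

# gradient of rope_encode: rotate by the opposite angle
rope_encode_bwd <- function(dx, positions, base = 10000) {
  rope_encode(dx, positions = -positions, base = base)
}

#' Geometrically-spaced threshold basis for relative positions
#'
#' Binary indicator features at geometrically spaced separation cutoffs:
#' a symmetric half activating once `|offset|` reaches each threshold
#' (monotone in `|offset|`), and a signed half carrying the direction.
#' Offset 0 activates only the smallest-threshold symmetric feature.
#'
#' @param offsets integer vector of relative offsets.
#' @param n_basis total number of features (half symmetric, half signed).
#' @param max_offset largest separation the thresholds span.
#' @return (length(offsets), n_basis) feature matrix.
#' @export
enformer_rel_basis <- function(offsets, n_basis = 32L, max_offset = 4096L) {
  half <- n_basis %/% 2L
  thr <- c(0, exp(seq(log(1), log(max_offset), length.out = half - 1L)))
  sym <- outer(abs(offsets), thr, `>=`) * 1
  sgn <- sym * sign(offsets)
  cbind(sym, sgn)
}

## ---- chunked attention -----------------------------------------------------

#' Softmax attention computed in key chunks (flash-style streaming)
#'
#' Processes keys/values in chunks of `chunk_len`, maintaining a running
#' row maximum and denominator so the result equals dense softmax
#' attention for every chunk length, at bounded working-set size.
#'
#' @param q (L_q, d) queries (already scaled if desired).
#' @param k,v (L_k, d) keys and values.
#' @param chunk_len chunk length (>= 1); `>= L_k` reduces to dense.
#' @param scale logit scale (default `1/sqrt(ncol(q))`).
#' @return (L_q, ncol(v)) attention output.
#' @export
chunked_attention <- function(q, k, v, chunk_len, scale = 1 / sqrt(ncol(q))) {
  stopifnot(chunk_len >= 1L)
  Lq <- nrow(q); Lk <- nrow(k)
  m <- rep(-Inf, Lq)            # running max
  l <- numeric(Lq)              # running denominator
  o <- matrix(0, Lq, ncol(v))   # running numerator
  s <- 1L
  while (s <= Lk) {
    e <- min(Lk, s + chunk_len - 1L)
    S <- (q %*% t(k[s:e, , drop = FALSE])) * scale
    m_new <- pmax(m, apply(S, 1L, max))
    corr <- exp(m - m_new)
    P <- exp(S - m_new)
    l <- l * corr + rowSums(P)
    o <- o * corr + P %*% v[s:e, , drop = FALSE]
    m <- m_new
    s <- e + 1L
  }
  o / l
}

## ---- attention layer -------------------------------------------------------

#' Initialize a pre-LayerNorm multi-head attention block
#'
#' Multi-head softmax attention with residual, followed by a pointwise
#' feed-forward sublayer (expansion 2, GELU) with residual.  Positional
#' information enters via `pos_mode`: `"NONE"`, `"ROPE"` (rotary encoding
#' of queries/keys), or `"ENFORMER_REL"` (additive relative-position
#' logits from a geometric threshold basis).
#'
#' @param d_model feature dimension (divisible by `heads`).
#' @param heads number of heads (default 4).
#' @param d_qk query/key dimension per head (default 64).
#' @param pos_mode positional-encoding mode.
#' @param n_basis basis size for `"ENFORMER_REL"`.
#' @return parameter list of class `attention_params`.
#' @export
attention_init <- function(d_model, heads = 4L, d_qk = 64L,
                           pos_mode = c("NONE", "ROPE", "ENFORMER_REL"),
                           n_basis = 32L) {
  pos_mode <- match.arg(pos_mode)
  if (d_model %% heads != 0L) stop("d_model must be divisible by heads")
  d_v <- d_model %/% heads
  ff <- 2L * d_model
  structure(list(d_model = as.integer(d_model), heads = as.integer(heads),
                 d_qk = as.integer(d_qk), d_v = as.integer(d_v),
                 pos_mode = pos_mode, n_basis = as.integer(n_basis),
                 ln1_g = rep(1, d_model), ln1_b = numeric(d_model),
                 Wq = init_dense(d_model, heads * d_qk),
                 Wk = init_dense(d_model, heads * d_qk),
                 Wv = init_dense(d_model, heads * d_v),
                 Wo = init_dense(heads * d_v, d_model),
                 bo = numeric(d_model),
                 rel_w = matrix(stats::rnorm(heads * n_basis, sd = 0.1),
                                heads, n_basis),
                 ln2_g = rep(1, d_model), ln2_b = numeric(d_model),
                 W1 = init_dense(d_model, ff), b1 = numeric(ff),
                 W2 = init_dense(ff, d_model), b2 = numeric(d_model)),
            class = "attention_params")
}

#' Forward pass of the attention block
#' @param params from [attention_init].
#' @param x (L, d_model) input.
#' @param want_cache keep intermediates for [attention_bwd].
#' @param chunk_len optional key-chunk length; when set, attention is
#'   computed with [chunked_attention] (inference path, same values).
#' @return `list(y = ..., cache = ...)`.
#' @export
attention_fwd <- function(params, x, want_cache = FALSE, chunk_len = NULL) {
  L <- nrow(x)
  H <- params$heads; dk <- params$d_qk; dv <- params$d_v
  n1 <- layernorm_fwd(x, params$ln1_g, params$ln1_b)
  xn <- n1$y
  Q <- xn %*% params$Wq
  K <- xn %*% params$Wk
  V <- xn %*% params$Wv
  pos <- seq_len(L) - 1L
  rel_basis <- NULL
  if (params$pos_mode == "ENFORMER_REL") {
    rel_basis <- enformer_rel_basis(-(L - 1L):(L - 1L), params$n_basis,
                                    max_offset = max(L, 2L))
  }
  off_idx <- if (!is.null(rel_basis)) outer(pos, pos, `-`) + L else NULL
  heads_out <- matrix(0, L, H * dv)
  hc <- vector("list", H)
  for (h in seq_len(H)) {
    qi <- Q[, ((h - 1L) * dk + 1L):(h * dk), drop = FALSE]
    ki <- K[, ((h - 1L) * dk + 1L):(h * dk), drop = FALSE]
    vi <- V[, ((h - 1L) * dv + 1L):(h * dv), drop = FALSE]
    if (params$pos_mode == "ROPE") {
      qi <- rope_encode(qi, pos); ki <- rope_encode(ki, pos)
    }
    P <- NULL
    if (!is.null(chunk_len) && is.null(rel_basis)) {
      # streaming inference path: identical values at any chunk length
      if (want_cache) stop("chunked attention is an inference path")
      A <- chunked_attention(qi, ki, vi, chunk_len, scale = 1 / sqrt(dk))
    } else {
      S <- (qi %*% t(ki)) / sqrt(dk)
      if (!is.null(rel_basis)) {
        R <- as.numeric(rel_basis %*% params$rel_w[h, ])
        S <- S + matrix(R[off_idx], L, L)
      }
      P <- exp(S - apply(S, 1L, max)); P <- P / rowSums(P)
      A <- P %*% vi
    }
    heads_out[, ((h - 1L) * dv + 1L):(h * dv)] <- A
    if (want_cache) hc[[h]] <- list(qi = qi, ki = ki, vi = vi, P = P)
  }
  attn <- sweep(heads_out %*% params$Wo, 2, params$bo, `+`)
  y1 <- x + attn
  n2 <- layernorm_fwd(y1, params$ln2_g, params$ln2_b)
  mid_pre <- sweep(n2$y %*% params$W1, 2, params$b1, `+`)
  mid <- gelu(mid_pre)
  y <- y1 + sweep(mid %*% params$W2, 2, params$b2, `+`)
  cache <- if (want_cache) {
    list(n1 = n1$cache, xn = xn, hc = hc, heads_out = heads_out,
         n2 = n2$cache, y1n = n2$y, mid_pre = mid_pre, mid = mid,
         pos = pos, rel_basis = rel_basis, off_idx = off_idx, L = L)
  }
  list(y = y, cache = cache)
}

#' Backward pass of the attention block
#' @param params,cache from the forward pass.
#' @param dy (L, d_model) upstream gradient.
#' @return `list(dx = ..., grads = ...)`.
#' @export
attention_bwd <- function(params, cache, dy) {
  L <- cache$L
  H <- params$heads; dk <- params$d_qk; dv <- params$d_v
  # feed-forward sublayer
  db2 <- colSums(dy)
  dW2 <- crossprod(cache$mid, dy)
  dmid <- dy %*% t(params$W2)
  dmid_pre <- dmid * gelu_grad(cache$mid_pre)
  db1 <- colSums(dmid_pre)
  dW1 <- crossprod(cache$y1n, dmid_pre)
  dn2 <- dmid_pre %*% t(params$W1)
  nb2 <- layernorm_bwd(cache$n2, dn2)
  dy1 <- dy + nb2$dx
  # attention sublayer
  dbo <- colSums(dy1)
  dWo <- crossprod(cache$heads_out, dy1)
  dheads <- dy1 %*% t(params$Wo)
  dQ <- matrix(0, L, H * dk); dK <- matrix(0, L, H * dk)
  dV <- matrix(0, L, H * dv)
  drel_w <- params$rel_w * 0
  for (h in seq_len(H)) {
    hcc <- cache$hc[[h]]
    dA <- dheads[, ((h - 1L) * dv + 1L):(h * dv), drop = FALSE]
    dvi <- crossprod(hcc$P, dA)
    dP <- dA %*% t(hcc$vi)
    dS <- hcc$P * (dP - rowSums(dP * hcc$P))
    if (!is.null(cache$rel_basis)) {
      ds_by_off <- tapply(as.numeric(dS), as.numeric(cache$off_idx), sum)
      dsvec <- numeric(2L * L - 1L)
      dsvec[as.integer(names(ds_by_off))] <- ds_by_off
      drel_w[h, ] <- as.numeric(crossprod(cache$rel_basis, dsvec))
    }
    dqi <- (dS %*% hcc$ki) / sqrt(dk)
    dki <- (t(dS) %*% hcc$qi) / sqrt(dk)
    if (params$pos_mode == "ROPE") {
      dqi <- rope_encode_bwd(dqi, cache$pos)
      dki <- rope_encode_bwd(dki, cache$pos)
    }
    dQ[, ((h - 1L) * dk + 1L):(h * dk)] <- dqi
    dK[, ((h - 1L) * dk + 1L):(h * dk)] <- dki
    dV[, ((h - 1L) * dv + 1L):(h * dv)] <- dvi
  }
  dxn <- dQ %*% t(params$Wq) + dK %*% t(params$Wk) + dV %*% t(params$Wv)
  dWq <- crossprod(cache$xn, dQ)
  dWk <- crossprod(cache$xn, dK)
  dWv <- crossprod(cache$xn, dV)
  nb1 <- layernorm_bwd(cache$n1, dxn)
  dx <- dy1 + nb1$dx
  list(dx = dx,
       grads = list(ln1_g = nb1$dgamma, ln1_b = nb1$dbeta,
                    Wq = dWq, Wk = dWk, Wv = dWv, Wo = dWo, bo = dbo,
                    rel_w = drel_w,
                    ln2_g = nb2$dgamma, ln2_b = nb2$dbeta,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

attention_trainable <- function(params) {
  keep <- c("ln1_g", "ln1_b", "Wq", "Wk", "Wv", "Wo", "bo",
            "ln2_g", "ln2_b", "W1", "b1", "W2", "b2")
  if (params$pos_mode == "ENFORMER_REL") keep <- c(keep, "rel_w")
  params[keep]
}

## ---- U-Net wrapper ---------------------------------------------------------

#' Initialize a U-Net pool/upsample wrapper
#'
#' Pools the sequence twofold `pool_rounds` times before an expensive
#' inner layer stack, then upsamples back with skip connections: each
#' round's upsample is a nearest-neighbour repeat followed by a pointwise
#' linear combination with the skip.
#'
#' @param d_model feature dimension.
#' @param pool_rounds number of twofold pool/upsample rounds (1 for
#'   striped stacks, 2 for the transformer path).
#' @return parameter list of class `unet_params`.
#' @export
unet_init <- function(d_model, pool_rounds = 1L) {
  rounds <- lapply(seq_len(pool_rounds), function(i)
    list(W_up = diag(d_model) + init_dense(d_model, d_model, sd = 0.01),
         W_skip = init_dense(d_model, d_model),
         b = numeric(d_model)))
  structure(list(d_model = as.integer(d_model),
                 pool_rounds = as.integer(pool_rounds),
                 rounds = rounds),
            class = "unet_params")
}

#' Forward pass of the U-Net wrapper around an inner layer stack
#' @param params from [unet_init].
#' @param x (L, d_model) input; L divisible by `2^pool_rounds`.
#' @param inner_fwd function `(x, want_cache) -> list(y, cache)` applied at
#'   the coarsest resolution.
#' @param want_cache keep intermediates for [unet_bwd].
#' @return `list(y = ..., cache = ...)`; output length equals input length.
#' @export
unet_fwd <- function(params, x, inner_fwd, want_cache = FALSE) {
  R <- params$pool_rounds
  if (nrow(x) %% (2L^R) != 0L) stop("input length not divisible by 2^rounds")
  skips <- vector("list", R)
  pools <- vector("list", R)
  lens <- integer(R)
  for (r in seq_len(R)) {
    skips[[r]] <- x
    lens[r] <- nrow(x)
    pl <- maxpool2_fwd(x)
    pools[[r]] <- pl$cache
    x <- pl$y
  }
  inner <- inner_fwd(x, want_cache)
  y <- inner$y
  ups <- vector("list", R)
  for (r in rev(seq_len(R))) {
    up <- upsample2(y)
    rp <- params$rounds[[r]]
    ynew <- sweep(up %*% rp$W_up + skips[[r]] %*% rp$W_skip, 2, rp$b, `+`)
    if (want_cache) ups[[r]] <- list(up = up)
    y <- ynew
  }
  cache <- if (want_cache) list(skips = skips, pools = pools, lens = lens,
                                inner = inner$cache, ups = ups)
  list(y = y, cache = cache)
}

#' Backward pass of the U-Net wrapper
#' @param params,cache from the forward pass.
#' @param dy upstream gradient at full resolution.
#' @param inner_bwd function `(cache, dy) -> list(dx, grads)` for the inner
#'   stack.
#' @return `list(dx = ..., grads = list(rounds = ..., inner = ...))`.
#' @export
unet_bwd <- function(params, cache, dy, inner_bwd) {
  R <- params$pool_rounds
  dround <- vector("list", R)
  dskip_direct <- vector("list", R)
  for (r in seq_len(R)) {
    rp <- params$rounds[[r]]
    up <- cache$ups[[r]]$up
    dround[[r]] <- list(W_up = crossprod(up, dy),
                        W_skip = crossprod(cache$skips[[r]], dy),
                        b = colSums(dy))
    dskip_direct[[r]] <- dy %*% t(rp$W_skip)
    dy <- upsample2_bwd(dy %*% t(rp$W_up))
  }
  inner <- inner_bwd(cache$inner, dy)
  dx <- inner$dx
  for (r in rev(seq_len(R))) {
    dx <- maxpool2_bwd(cache$pools[[r]], dx, cache$lens[r])
    dx <- dx + dskip_direct[[r]]
  }
  list(dx = dx, grads = list(rounds = dround, inner = inner$grads))
}
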