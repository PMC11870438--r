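# Low-level numeric kernels shared by the layer implementations.
# All sequence tensors are (L positions x C channels) base-R matrices.

#' Evaluate an expression with a temporary RNG state
#'
#' Saves and restores `.Random.seed` so that seeded model initialization and
#' data generation do not disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

## ---- activations -----------------------------------------------------------

# tanh approximation of GELU (standard in the models this package mirrors);
# matrix inputs take the compiled path
gelu <- function(x) {
  if (is.matrix(x)) return(gelu_cpp(x))
  inner <- sqrt(2 / pi) * (x + 0.044715 * x^3)
  0.5 * x * (1 + tanh(inner))
}

gelu_grad <- function(x) {
  if (is.matrix(x)) return(gelu_grad_cpp(x))
  c0 <- sqrt(2 / pi)
  inner <- c0 * (x + 0.044715 * x^3)
  t <- tanh(inner)
  dinner <- c0 * (1 + 3 * 0.044715 * x^2)
  0.5 * (1 + t) + 0.5 * x * (1 - t^2) * dinner
}

silu <- function(x) x * stats::plogis(x)

silu_grad <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

softplus_grad <- function(x) stats::plogis(x)

# inverse of softplus, used to set bias targets
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(pmax(y, 1e-12))))

## ---- normalization layers (forward + backward) -----------------------------

# Channel normalization over positions with learnable scale/shift.  Used in
# the convolutional trunk (batch-style statistics computed per sequence).
batchnorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xh <- sweep(xc, 2, istd, `*`)
  y <- sweep(sweep(xh, 2, gamma, `*`), 2, beta, `+`)
  list(y = y, cache = list(xh = xh, istd = istd, gamma = gamma))
}

batchnorm_bwd <- function(cache, dy) {
  xh <- cache$xh; istd <- cache$istd; gamma <- cache$gamma
  L <- nrow(xh)
  dgamma <- colSums(dy * xh)
  dbeta <- colSums(dy)
  dxh <- sweep(dy, 2, gamma, `*`)
  # standard batchnorm backward over the position axis
  dx <- sweep(dxh - matrix(colMeans(dxh), L, ncol(xh), byrow = TRUE) -
                xh * matrix(colMeans(dxh * xh), L, ncol(xh), byrow = TRUE),
              2, istd, `*`)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + eps)
  xh <- xc * istd
  y <- sweep(sweep(xh, 2, gamma, `*`), 2, beta, `+`)
  list(y = y, cache = list(xh = xh, istd = istd, gamma = gamma))
}

layernorm_bwd <- function(cache, dy) {
  xh <- cache$xh; istd <- cache$istd; gamma <- cache$gamma
  C <- ncol(xh)
  dgamma <- colSums(dy * xh)
  dbeta <- colSums(dy)
  dxh <- sweep(dy, 2, gamma, `*`)
  dx <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) * istd
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

rmsnorm_fwd <- function(x, g, eps = 1e-6) {
  ms <- rowMeans(x^2)
  inv <- 1 / sqrt(ms + eps)
  xh <- x * inv
  list(y = sweep(xh, 2, g, `*`), cache = list(x = x, inv = inv, g = g))
}

rmsnorm_bwd <- function(cache, dy) {
  x <- cache$x; inv <- cache$inv; g <- cache$g
  C <- ncol(x)
  dg <- colSums(dy * x * inv)
  dxh <- sweep(dy, 2, g, `*`)
  # y_i = x_i * inv, inv = (mean(x^2)+eps)^{-1/2}
  dot <- rowSums(dxh * x)
  dx <- dxh * inv - x * (dot * inv^3 / C)
  list(dx = dx, dg = dg)
}

## ---- convolution primitives ------------------------------------------------

# im2col for 1-D "same" convolution: rows are positions, columns stack the
# kernel taps for every input channel (tap-major, channel within tap)
im2col <- function(x, width) im2col_cpp(x, as.integer(width))

# scatter-back of im2col gradient
col2im <- function(dcols, L, C, width) {
  col2im_cpp(dcols, as.integer(L), as.integer(C), as.integer(width))
}

conv1d_fwd <- function(x, W, b, width) {
  cols <- im2col(x, width)
  y <- cols %*% W
  y <- sweep(y, 2, b, `+`)
  list(y = y, cache = list(cols = cols, W = W, width = width,
                           L = nrow(x), C = ncol(x)))
}

conv1d_bwd <- function(cache, dy) {
  dW <- crossprod(cache$cols, dy)
  db <- colSums(dy)
  dcols <- dy %*% t(cache$W)
  dx <- col2im(dcols, cache$L, cache$C, cache$width)
  list(dx = dx, dW = dW, db = db)
}

# depthwise causal conv of width w: y[t,c] = sum_k W[k,c] x[t-w+k,c] + b[c]
dwconv_causal_fwd <- function(x, W, b) dwconv_causal_fwd_cpp(x, W, b)

dwconv_causal_bwd <- function(x, W, dy) dwconv_causal_bwd_cpp(x, W, dy)

maxpool2_fwd <- function(x) {
  L <- nrow(x)
  stopifnot(L %% 2L == 0L)
  a <- x[seq(1L, L, 2L), , drop = FALSE]
  b <- x[seq(2L, L, 2L), , drop = FALSE]
  take_a <- a >= b
  list(y = ifelse(take_a, a, b), cache = take_a)
}

maxpool2_bwd <- function(cache, dy, L) {
  dx <- matrix(0, L, ncol(dy))
  dx[seq(1L, L, 2L), ][cache] <- dy[cache]
  dx[seq(2L, L, 2L), ][!cache] <- dy[!cache]
  dx
}

# nearest-neighbour 2x upsample (repeat each position)
upsample2 <- function(x) x[rep(seq_len(nrow(x)), each = 2L), , drop = FALSE]

upsample2_bwd <- function(dy) {
  L2 <- nrow(dy)
  dy[seq(1L, L2, 2L), , drop = FALSE] + dy[seq(2L, L2, 2L), , drop = FALSE]
}

## ---- initializers ----------------------------------------------------------

# Lecun normal: sd = 1/sqrt(fan_in)
init_dense <- function(fan_in, fan_out, sd = NULL) {
  if (is.null(sd)) sd <- 1 / sqrt(fan_in)
  matrix(stats::rnorm(fan_in * fan_out, sd = sd), fan_in, fan_out)
}

flatten_params <- function(p) unlist(p, use.names = TRUE)

unflatten_params <- function(v, skeleton) utils::relist(v, skeleton)
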