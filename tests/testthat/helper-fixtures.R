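# Shared fixtures: tiny random instances and a finite-difference checker.

random_dna <- function(L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
}

random_onehot <- function(L, seed = NULL) {
  one_hot_encode(random_dna(L, seed))
}

# random scan instance of given dimensions
random_scan_instance <- function(L, D, N) {
  list(x = matrix(rnorm(L * D), L, D),
       delta = matrix(runif(L * D, 0.01, 0.3), L, D),
       A = -matrix(runif(D * N, 0.1, 2), D, N),
       B = matrix(rnorm(L * N), L, N),
       C = matrix(rnorm(L * N), L, N))
}

# central finite-difference gradient of f at x (numeric vector)
fd_grad <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# paired FWD/REV + unstranded metadata for 4 tracks
tiny_meta <- function() {
  track_meta(c("a_f", "a_r", "d", "o"),
             assay = c("CAGE", "CAGE", "DNASE", "OTHER"),
             strand = c("FWD", "REV", "UNSTRANDED", "UNSTRANDED"),
             pair_id = c("p1", "p1", NA, NA))
}

# strictly revcomp-equivariant toy predictor: FWD track counts A per bin,
# REV track counts T per bin, unstranded tracks count A+T / G+C
toy_equivariant_predictor <- function(bin_width = 32L) {
  rate_oracle(function(onehot) {
    a <- bin_coverage(onehot[, 1], bin_width)
    t <- bin_coverage(onehot[, 4], bin_width)
    g <- bin_coverage(onehot[, 3], bin_width)
    c_ <- bin_coverage(onehot[, 2], bin_width)
    m <- cbind(a, t, a + t, g + c_) + 0.1
    colnames(m) <- c("a_f", "a_r", "d", "o")
    m
  })
}
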