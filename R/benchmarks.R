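# Self-contained desk-scale study drivers used by the test suite and the
# acceptance script: end-to-end learnability on the synthetic corpus, and
# parameter recovery of the variant-scoring pipeline.

#' Desk-scale striped-model configuration
#'
#' The small study configuration: 8,192-bp windows, 64-dim embedding,
#' 8 tracks, a five-block convolutional trunk and a striped stack of two
#' bidirectional Mamba layers plus one U-Net-wrapped RoPE attention block.
#'
#' @param window_len window length in bp.
#' @param d_model embedding width.
#' @param n_tracks output tracks.
#' @return a [model_config].
#' @export
desk_model_config <- function(window_len = 8192L, d_model = 64L,
                              n_tracks = 8L) {
  model_config(window_len = window_len, n_tracks = n_tracks,
               d_model = d_model, trunk_blocks = 5L,
               stack = stack_striped(2L, 1L, N = 8L, E = 1L,
                                     pos_mode = "ROPE", pool_rounds = 1L),
               attn_heads = 4L, attn_d_qk = 16L)
}

#' Desk-scale training configuration
#'
#' The full-scale optimizer recipe rescaled to the tiny model: higher peak
#' learning rate, short warm-up, and clipping bounds loose enough not to
#' distort the much larger relative gradient norms of a small model on a
#' desk-scale loss.
#'
#' @return a [train_config].
#' @export
desk_train_config <- function() {
  train_config(lr = 5e-3, warmup_steps = 50L, clip_block = 100,
               clip_global = 1000, patience = 1000L)
}

#' End-to-end learnability benchmark on the synthetic corpus
#'
#' Trains the desk-scale striped model on synthetic windows (Poisson
#' counts as targets, squash-transformed) and measures the mean per-track
#' Pearson r between predictions and the squashed ground-truth rates on
#' held-out windows.  A label-shuffled control -- identical training with
#' coverage targets permuted across windows, breaking the
#' sequence-coverage link -- is trained the same way.
#'
#' @param seed integer seed (corpus, initialization, training).
#' @param max_steps optimizer-step budget per run.
#' @param n_windows corpus size (last `n_val + n_eval` held out).
#' @param n_val held-out windows whose noisy counts drive best-checkpoint
#'   selection.
#' @param n_eval held-out windows for the final evaluation against the
#'   true rates.
#' @param control also train the label-shuffled control.
#' @param verbose print training log lines.
#' @return list with `r` (trained-model mean Pearson r vs true rates),
#'   `r_control`, `gap`, and the trained `model`.
#' @export
learnability_benchmark <- function(seed = 1L, max_steps = 1200L,
                                   n_windows = 48L, n_val = 4L,
                                   n_eval = 4L, control = TRUE,
                                   verbose = FALSE) {
  spec <- synthetic_spec(n_windows = n_windows, window_len = 8192L,
                         crop_bins = 8L, seed = seed)
  corpus <- generate_corpus(spec)
  data <- lapply(corpus$windows, function(w)
    list(onehot = w$onehot, target = squash(w$counts)))
  truth <- lapply(corpus$windows, function(w)
    list(onehot = w$onehot, target = squash(w$rates)))
  tr_idx <- seq_len(n_windows - n_val - n_eval)
  va_idx <- n_windows - n_val - n_eval + seq_len(n_val)
  ev_idx <- n_windows - n_eval + seq_len(n_eval)
  cfg <- desk_model_config()
  tcfg <- desk_train_config()
  run <- function(train_data, run_seed) {
    model <- build_model(cfg, seed = run_seed)
    train_model(model, train_data, corpus$meta, tcfg,
                val_data = data[va_idx], crop = spec$crop_bins,
                max_steps = max_steps, eval_every = max_steps,
                seed = run_seed, verbose = verbose)
  }
  fit <- run(data[tr_idx], seed + 1L)
  r <- eval_mean_pearson(fit$model, truth[ev_idx], spec$crop_bins)
  out <- list(r = r, model = fit$model, history = fit$history)
  if (control) {
    perm <- with_seed(seed + 2L, sample(tr_idx))
    shuffled <- lapply(seq_along(tr_idx), function(i)
      list(onehot = data[[tr_idx[i]]]$onehot,
           target = data[[perm[i]]]$target))
    fit0 <- run(shuffled, seed + 1L)
    out$r_control <- eval_mean_pearson(fit0$model, truth[ev_idx],
                                       spec$crop_bins)
    out$gap <- r - out$r_control
  }
  out
}

#' Variant-pipeline parameter-recovery benchmark
#'
#' Generates synthetic variants with known effects (motif-destroying
#' substitutions vs strictly neutral background substitutions), scores
#' them with the ground-truth rate oracle through the standard
#' reference/alternate prediction summaries, and asks the random-forest
#' classifier to separate large-effect from null variants.  A
#' permuted-label control checks the null behaviour of the AUROC.
#'
#' @param seed integer seed.
#' @param n_effect,n_null variant counts.
#' @param n_trees random-forest size.
#' @param permuted also compute the permuted-label AUROC.
#' @return list with `auroc`, `spearman` (score vs |true effect|),
#'   `auroc_permuted`, `scores`, `variants`.
#' @export
variant_benchmark <- function(seed = 1L, n_effect = 1000L, n_null = 1000L,
                              n_trees = 1000L, permuted = TRUE) {
  spec <- synthetic_spec(n_windows = 40L, window_len = 8192L,
                         crop_bins = 8L, seed = seed)
  corpus <- generate_corpus(spec)
  variants <- generate_variants(corpus, n_effect = n_effect,
                                n_null = n_null, seed = seed + 1L)
  oracle <- synthetic_oracle(spec)
  scores <- score_variant_table(list(oracle), corpus, variants,
                                crop = spec$crop_bins)
  feats <- variant_feature_matrix(scores)
  labels <- variants$label == "effect"
  fit <- snp_classifier(feats, labels, seed = seed + 2L,
                        target = abs(variants$true_effect),
                        n_trees = n_trees)
  out <- list(auroc = fit$auroc, spearman = fit$spearman,
              scores = fit$cv_scores, variants = variants)
  if (permuted) {
    perm_labels <- with_seed(seed + 3L, sample(labels))
    fit0 <- snp_classifier(feats, perm_labels, seed = seed + 4L,
                           n_trees = n_trees)
    out$auroc_permuted <- fit0$auroc
  }
  out
}
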