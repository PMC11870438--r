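# Adam optimizer and the training loop: shuffled epochs at batch size 2,
# reverse-complement and shift augmentation, L2 regularization, two-level
# gradient clipping, linear warm-up, early stopping on validation mean
# Pearson r.

adam_state_init <- function(flat) {
  list(m = numeric(length(flat)), v = numeric(length(flat)), t = 0L)
}

adam_update <- function(state, flat_g, lr, cfg) {
  state$t <- state$t + 1L
  state$m <- cfg$beta1 * state$m + (1 - cfg$beta1) * flat_g
  state$v <- cfg$beta2 * state$v + (1 - cfg$beta2) * flat_g^2
  mhat <- state$m / (1 - cfg$beta1^state$t)
  vhat <- state$v / (1 - cfg$beta2^state$t)
  list(state = state, delta = -lr * mhat / (sqrt(vhat) + cfg$adam_eps))
}

# elementwise a + b over identically-shaped nested lists
struct_add <- function(a, b) {
  if (is.list(a)) {
    for (nm in seq_along(a)) a[[nm]] <- struct_add(a[[nm]], b[[nm]])
    a
  } else a + b
}

struct_scale <- function(a, s) {
  if (is.list(a)) lapply(a, struct_scale, s = s) else a * s
}

#' Mean per-track Pearson correlation between predictions and targets
#'
#' Bins are concatenated across windows before correlating, per track;
#' zero-variance tracks are skipped.
#'
#' @param model predictor accepted by [predict_bins].
#' @param data list of examples, each with `onehot` and `target`
#'   (bins x tracks).
#' @param crop bins cropped from each end before correlating.
#' @return mean Pearson r across tracks.
#' @export
eval_mean_pearson <- function(model, data, crop = 0L) {
  preds <- lapply(data, function(ex) {
    p <- predict_bins(model, ex$onehot)
    if (crop > 0L) p[(crop + 1L):(nrow(p) - crop), , drop = FALSE] else p
  })
  obs <- lapply(data, function(ex) {
    t <- ex$target
    if (crop > 0L) t[(crop + 1L):(nrow(t) - crop), , drop = FALSE] else t
  })
  P <- do.call(rbind, preds)
  O <- do.call(rbind, obs)
  rs <- vapply(seq_len(ncol(P)), function(j) {
    if (stats::sd(O[, j]) == 0 || stats::sd(P[, j]) == 0) return(NA_real_)
    stats::cor(P[, j], O[, j])
  }, numeric(1))
  mean(rs, na.rm = TRUE)
}

# apply the two stochastic augmentations to one training example
augment_example <- function(ex, meta, shift_max, bin_width) {
  sh <- sample.int(2L * shift_max + 1L, 1L) - shift_max - 1L
  win <- sequence_window("w", 0L, ex$onehot)
  win <- shift_augment(win, sh, shift_max)
  target <- ex$target
  if (stats::runif(1) < 0.5) {
    aug <- revcomp_augment(win, track_set(target, bin_width, meta))
    win <- aug$win
    target <- aug$tracks$values
  }
  list(onehot = win$onehot, target = target)
}

#' Train a model on windows of (one-hot sequence, binned coverage)
#'
#' One epoch is a full pass over the shuffled training windows at the
#' configured batch size.  Each example receives a random sequence shift
#' (targets unchanged) and, with probability 1/2, reverse complementation
#' with strand-paired track exchange.  Gradients are averaged over the
#' batch, L2-regularized, clipped per block and globally, and applied
#' with Adam under the linear warm-up schedule.  Training stops after
#' `max_steps`, or earlier when the validation mean Pearson r has not
#' improved for `patience` epochs (the best-validation parameters are
#' restored).
#'
#' @param model a `covscan_model` from [build_model].
#' @param train_data list of examples with `onehot` (L, 4) and `target`
#'   (bins, tracks) count matrices on the modeling scale.
#' @param meta [track_meta] for the targets (drives augmentation pairing).
#' @param tcfg a [train_config].
#' @param val_data optional validation examples (same shape).
#' @param crop bins cropped from each end before the loss.
#' @param max_steps optimizer-step budget.
#' @param eval_every evaluate/log every this many steps.
#' @param seed integer seed for shuffling and augmentation draws.
#' @param shift_max maximum augmentation shift in bp.
#' @param verbose print per-evaluation log lines.
#' @return list with the trained `model`, a `history` data.frame
#'   (step, lr, loss, pois, multi, val_r) and `best_val_r`.
#' @export
train_model <- function(model, train_data, meta, tcfg = train_config(),
                        val_data = NULL, crop = 0L, max_steps = 1000L,
                        eval_every = 100L, seed = 1L, shift_max = 3L,
                        verbose = FALSE) {
  if (!length(train_data)) stop("empty training set")
  w <- tcfg$multinomial_weight
  bin_width <- model$cfg$bin_width
  B <- nrow(train_data[[1]]$target)
  keep <- (crop + 1L):(B - crop)
  hist_rows <- list()
  best <- list(val_r = -Inf, params = NULL)
  epochs_since_best <- 0L
  with_seed(seed, {
    flat0 <- unlist(model_trainable(model), use.names = FALSE)
    adam <- adam_state_init(flat0)
    skel <- model_trainable(model)
    step <- 0L
    epoch <- 0L
    done <- FALSE
    while (!done) {
      epoch <- epoch + 1L
      order_idx <- sample.int(length(train_data))
      bstart <- seq(1L, length(order_idx), by = tcfg$batch_size)
      for (bs in bstart) {
        idx <- order_idx[bs:min(bs + tcfg$batch_size - 1L, length(order_idx))]
        gacc <- NULL
        loss_acc <- 0
        for (i in idx) {
          ex <- augment_example(train_data[[i]], meta, shift_max, bin_width)
          fwd <- model_forward(model, ex$onehot, want_cache = TRUE)
          pred <- fwd$rates[keep, , drop = FALSE]
          obs <- ex$target[keep, , drop = FALSE]
          loss_acc <- loss_acc + poisson_multinomial_loss(pred, obs, w)
          dpred <- poisson_multinomial_grad(pred, obs, w)
          drates <- matrix(0, B, ncol(pred))
          drates[keep, ] <- dpred
          g <- model_grads_canon(model, model_backward(model, fwd$cache,
                                                       drates))
          gacc <- if (is.null(gacc)) g else struct_add(gacc, g)
        }
        gacc <- struct_scale(gacc, 1 / length(idx))
        # L2 penalty on all trainable parameters
        if (tcfg$l2_coeff > 0) {
          gacc <- struct_add(gacc, struct_scale(model_trainable(model),
                                                tcfg$l2_coeff))
        }
        blocks <- clip_gradients(model_grad_blocks(gacc),
                                 tcfg$clip_block, tcfg$clip_global)
        gacc <- model_blocks_to_grads(blocks, gacc)
        step <- step + 1L
        lr <- lr_schedule(step, tcfg)
        flat_g <- unlist(gacc, use.names = FALSE)
        upd <- adam_update(adam, flat_g, lr, tcfg)
        adam <- upd$state
        flat_p <- unlist(model_trainable(model), use.names = FALSE) +
          upd$delta
        model <- model_set_trainable(model, utils::relist(flat_p, skel))
        if (step %% eval_every == 0L || step >= max_steps) {
          val_r <- if (!is.null(val_data)) {
            eval_mean_pearson(model, val_data, crop)
          } else NA_real_
          hist_rows[[length(hist_rows) + 1L]] <-
            data.frame(step = step, epoch = epoch, lr = lr,
                       loss = loss_acc / length(idx), val_r = val_r)
          if (verbose) {
            message(sprintf("step %d lr %.2e loss %.3f val_r %.3f",
                            step, lr, loss_acc / length(idx), val_r))
          }
        }
        if (step >= max_steps) { done <- TRUE; break }
      }
      if (!is.null(val_data) && !done) {
        val_r <- eval_mean_pearson(model, val_data, crop)
        if (val_r > best$val_r) {
          best$val_r <- val_r
          best$params <- model_trainable(model)
          epochs_since_best <- 0L
        } else {
          epochs_since_best <- epochs_since_best + 1L
          if (epochs_since_best >= tcfg$patience) done <- TRUE
        }
      }
    }
    if (!is.null(best$params)) {
      final_r <- if (!is.null(val_data)) {
        eval_mean_pearson(model, val_data, crop)
      } else -Inf
      if (best$val_r > final_r) model <- model_set_trainable(model,
                                                             best$params)
      else best$val_r <- max(best$val_r, final_r)
    }
  })
  list(model = model,
       history = if (length(hist_rows)) do.call(rbind, hist_rows)
                 else data.frame(),
       best_val_r = best$val_r)
}
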