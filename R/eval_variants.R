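# Test-set metrics and the SNP-classification pipeline: reference/alternate
# prediction, difference and log-ratio summaries, ensemble feature
# assembly, random-forest classification, AUROC and Spearman reporting.

#' Per-track Pearson r and coefficient of determination
#'
#' Computes Pearson's r and `r^2 = 1 - SSE/SST` per track, by default over
#' bins concatenated across windows, and reports means overall and per
#' assay group.  Tracks with zero observed variance are flagged undefined
#' and excluded from the means (with a count).
#'
#' @param pred,obs (bins, tracks) matrices, or lists of such matrices (one
#'   per window).
#' @param meta optional [track_meta] providing assay grouping.
#' @param mode `"concat"` (default) correlates concatenated bins per
#'   track; `"per_window"` averages per-window correlations per track.
#' @return list with `per_track` data.frame (`track`, `assay`, `r`, `r2`),
#'   `mean_r`, `mean_r2`, `by_assay` data.frame, `n_undefined`.
#' @export
track_metrics <- function(pred, obs, meta = NULL,
                          mode = c("concat", "per_window")) {
  mode <- match.arg(mode)
  if (is.list(pred)) {
    stopifnot(is.list(obs), length(pred) == length(obs))
  } else {
    pred <- list(pred); obs <- list(obs)
  }
  Tn <- ncol(pred[[1]])
  stopifnot(all(vapply(pred, ncol, 1L) == Tn),
            all(vapply(obs, ncol, 1L) == Tn))
  one_pair <- function(p, o) {
    if (stats::sd(o) == 0) return(c(NA_real_, NA_real_))
    r <- stats::cor(p, o)
    r2 <- 1 - sum((o - p)^2) / sum((o - mean(o))^2)
    c(r, r2)
  }
  per_track <- t(vapply(seq_len(Tn), function(j) {
    if (mode == "concat") {
      one_pair(unlist(lapply(pred, function(m) m[, j])),
               unlist(lapply(obs, function(m) m[, j])))
    } else {
      vals <- vapply(seq_along(pred), function(k)
        one_pair(pred[[k]][, j], obs[[k]][, j]), numeric(2))
      rowMeans(vals, na.rm = TRUE)
    }
  }, numeric(2)))
  assay <- if (!is.null(meta)) meta$assay else rep("ALL", Tn)
  track <- if (!is.null(meta)) meta$track_id else paste0("track", seq_len(Tn))
  df <- data.frame(track = track, assay = assay,
                   r = per_track[, 1], r2 = per_track[, 2])
  ok <- !is.na(df$r)
  by_assay <- stats::aggregate(cbind(r, r2) ~ assay, data = df[ok, ], FUN = mean)
  list(per_track = df,
       mean_r = mean(df$r[ok]), mean_r2 = mean(df$r2[ok]),
       by_assay = by_assay, n_undefined = sum(!ok))
}

#' Area under the ROC curve by the rank statistic
#'
#' Probability that a random positive outscores a random negative
#' (Mann-Whitney U / n1 n0, ties counted half).  Invariant under strictly
#' monotone transforms of the scores.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (logical, or 0/1).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Score one variant against an ensemble of predictors
#'
#' Predicts all tracks for the window with the reference and with the
#' alternate allele, then summarizes per track: the signed log of the
#' bin-sum of prediction differences, `sign(S) * log(1 + |S|)` with
#' `S = sum_b (alt_b - ref_b)`, and the L2 norm of per-bin log-ratios,
#' `sqrt(sum_b (log(alt_b + eps) - log(ref_b + eps))^2)`.  Features are
#' concatenated across the ensemble members (the full-scale setup uses
#' the four data-split models).
#'
#' @param models list of predictors accepted by [predict_bins] (an
#'   ensemble; a single model may be passed as `list(model)`).
#' @param onehot one-hot window centered on the variant.
#' @param pos 0-based variant position within the window.
#' @param ref,alt single-base alleles; `ref` must match the window.
#' @param crop bins cropped from each end of the predictions.
#' @param eps pseudocount inside the log-ratios.
#' @return list of class `variant_score` with `features` (named numeric)
#'   and `per_track` data.frame.
#' @export
predict_variant <- function(models, onehot, pos, ref, alt, crop = 0L,
                            eps = 1e-6) {
  base_cols <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  L <- nrow(onehot)
  if (pos < 0L || pos >= L) stop("variant position outside the window")
  if (onehot[pos + 1L, base_cols[[ref]]] != 1) {
    stop("reference allele ", ref, " does not match the window at offset ",
         pos)
  }
  alt_onehot <- onehot
  alt_onehot[pos + 1L, ] <- 0
  alt_onehot[pos + 1L, base_cols[[alt]]] <- 1
  feats <- list()
  per_track <- list()
  for (m in seq_along(models)) {
    pr <- predict_bins(models[[m]], onehot)
    pa <- predict_bins(models[[m]], alt_onehot)
    if (crop > 0L) {
      keep <- (crop + 1L):(nrow(pr) - crop)
      pr <- pr[keep, , drop = FALSE]; pa <- pa[keep, , drop = FALSE]
    }
    S <- colSums(pa - pr)
    sld <- sign(S) * log1p(abs(S))
    l2 <- sqrt(colSums((log(pa + eps) - log(pr + eps))^2))
    tn <- if (!is.null(colnames(pr))) colnames(pr) else
      paste0("track", seq_along(S))
    feats[[m]] <- stats::setNames(c(sld, l2),
                                  c(paste0("m", m, "_sld_", tn),
                                    paste0("m", m, "_l2_", tn)))
    per_track[[m]] <- data.frame(model = m, track = tn, sum_diff = S,
                                 sld = sld, l2 = l2)
  }
  structure(list(features = unlist(feats),
                 per_track = do.call(rbind, per_track)),
            class = "variant_score")
}

#' Assemble a feature matrix from a list of variant scores
#' @param scores list of `variant_score` objects.
#' @return numeric matrix, one row per variant.
#' @export
variant_feature_matrix <- function(scores) {
  do.call(rbind, lapply(scores, `[[`, "features"))
}

#' Random-forest SNP classifier with cross-validated AUROC and Spearman
#'
#' Fits a random forest (1000 trees) on variant-score summary features.
#' AUROC is computed from out-of-fold scores under stratified k-fold
#' cross-validation; Spearman's rank correlation is computed between the
#' out-of-fold scores and `target` (the labels themselves, or a PIP-like
#' quantity such as the true effect magnitude).
#'
#' @param features numeric matrix (variants x features).
#' @param labels binary labels (TRUE/1 = causal).
#' @param seed integer seed for fold assignment and forests.
#' @param target numeric target for the Spearman statistic (default the
#'   labels).
#' @param n_folds stratified CV folds (default 5).
#' @param n_trees trees per forest (default 1000).
#' @return list with `auroc`, `spearman`, `cv_scores`, `fit` (forest on
#'   all data).
#' @export
snp_classifier <- function(features, labels, seed = 1L, target = NULL,
                           n_folds = 5L, n_trees = 1000L) {
  labels <- as.logical(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  if (is.null(target)) target <- as.numeric(labels)
  y <- factor(labels, levels = c(FALSE, TRUE))
  with_seed(seed, {
    fold <- integer(length(labels))
    for (cl in c(TRUE, FALSE)) {
      idx <- sample(which(labels == cl))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
    cv_scores <- numeric(length(labels))
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      fit <- randomForest::randomForest(features[tr, , drop = FALSE],
                                        y[tr], ntree = n_trees)
      cv_scores[!tr] <- stats::predict(fit, features[!tr, , drop = FALSE],
                                       type = "prob")[, "TRUE"]
    }
    fit_all <- randomForest::randomForest(features, y, ntree = n_trees)
    list(auroc = auroc(cv_scores, labels),
         spearman = stats::cor(cv_scores, target, method = "spearman"),
         cv_scores = cv_scores, fit = fit_all)
  })
}

#' Score a table of synthetic variants with an ensemble of predictors
#'
#' Convenience driver joining [generate_variants] output to its corpus
#' windows and running [predict_variant] on each.
#'
#' @param models list of predictors.
#' @param corpus from [generate_corpus].
#' @param variants from [generate_variants].
#' @param crop bins cropped from each end of predictions.
#' @return list of `variant_score` objects, in `variants` row order.
#' @export
score_variant_table <- function(models, corpus, variants, crop = 0L) {
  lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    w <- corpus$windows[[v$window_idx]]
    predict_variant(models, w$onehot, v$pos, v$ref, v$alt, crop = crop)
  })
}
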