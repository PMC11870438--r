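test_that("track metrics recover hand-computed r and r-squared", {
  pred <- cbind(c(1, 2, 3, 5))
  obs <- cbind(c(1, 2, 3, 4))
  tm <- track_metrics(pred, obs)
  # closed-form check against the standard formulas
  r_hand <- cor(c(1, 2, 3, 5), c(1, 2, 3, 4))
  r2_hand <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  expect_equal(tm$per_track$r, r_hand)
  expect_equal(tm$per_track$r2, r2_hand)
  # perfect prediction
  tm1 <- track_metrics(obs, obs)
  expect_equal(tm1$per_track$r, 1)
  expect_equal(tm1$per_track$r2, 1)
  # anti-correlated, mean-centered
  x <- cbind(c(-2, -1, 0, 1, 2))
  tmn <- track_metrics(-x, x)
  expect_equal(tmn$per_track$r, -1)
})

test_that("zero-variance tracks are flagged and excluded from means", {
  set.seed(1)
  pred <- cbind(rnorm(10), rnorm(10))
  obs <- cbind(rep(2, 10), rnorm(10))
  meta <- track_meta(c("flat", "ok"), "RNA", c("FWD", "REV"), c("p", "p"))
  tm <- track_metrics(pred, obs, meta)
  expect_equal(tm$n_undefined, 1)
  expect_true(is.na(tm$per_track$r[1]))
  expect_equal(tm$mean_r, tm$per_track$r[2])
})

test_that("metrics aggregate per assay and support per-window averaging", {
  set.seed(2)
  preds <- lapply(1:3, function(i) matrix(rnorm(40), 10, 4))
  obs <- lapply(preds, function(p) p + matrix(rnorm(40, sd = 0.3), 10, 4))
  tm <- track_metrics(preds, obs, tiny_meta())
  expect_setequal(tm$by_assay$assay, c("CAGE", "DNASE", "OTHER"))
  tm2 <- track_metrics(preds, obs, tiny_meta(), mode = "per_window")
  expect_equal(nrow(tm2$per_track), 4)
  expect_false(identical(tm$per_track$r, tm2$per_track$r))
})

test_that("rank AUROC equals the trapezoidal ROC integral", {
  trapezoid_auroc <- function(scores, labels) {
    th <- sort(unique(scores), decreasing = TRUE)
    tpr <- c(0, vapply(th, function(s) mean(scores[labels] >= s), 1), 1)
    fpr <- c(0, vapply(th, function(s) mean(scores[!labels] >= s), 1), 1)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  set.seed(3)
  for (i in 1:5) {
    scores <- rnorm(60)
    labels <- runif(60) < 0.4
    if (length(unique(labels)) < 2) next
    expect_equal(auroc(scores, labels), trapezoid_auroc(scores, labels),
                 tolerance = 1e-12)
  }
  # invariance under strictly monotone transforms
  scores <- rnorm(50); labels <- runif(50) < 0.5
  expect_equal(auroc(scores, labels), auroc(exp(scores), labels))
  expect_error(auroc(scores, rep(TRUE, 50)), "both classes")
})

test_that("rank AUROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(4)
  scores <- rnorm(80)
  labels <- runif(80) < 0.45
  expect_equal(auroc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              quiet = TRUE,
                                              direction = "<"))))
})

test_that("variant scoring has the advertised closed forms", {
  set.seed(5)
  onehot <- random_onehot(256)
  base <- matrix(runif(8 * 2, 0.5, 2), 8, 2)
  # predictor ignoring sequence except a marker base: ref -> base rates,
  # alt -> doubled rates
  marker <- onehot[100, ]
  pred <- rate_oracle(function(oh) {
    if (all(oh[100, ] == marker)) base else 2 * base
  })
  ref <- one_hot_decode(onehot[100, , drop = FALSE])
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  vs <- predict_variant(list(pred), onehot, 99L, ref, alt)
  # doubling all rates: L2 summary is sqrt(B) * log 2 per track (eps-free
  # up to the pseudocount)
  l2 <- vs$per_track$l2
  expect_equal(l2, rep(sqrt(8) * log(2), 2), tolerance = 1e-3)
  sld <- vs$per_track$sld
  expect_equal(sld, sign(colSums(base)) * log1p(colSums(base)),
               tolerance = 1e-6)
  # ref == alt: all features exactly zero
  vs0 <- predict_variant(list(pred), onehot, 99L, ref, ref)
  expect_true(all(vs0$features == 0))
  # errors: position outside window, allele mismatch
  expect_error(predict_variant(list(pred), onehot, 999L, "A", "C"),
               "outside")
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[2]
  expect_error(predict_variant(list(pred), onehot, 99L, wrong, alt),
               "does not match")
})

test_that("variant summaries are invariant to bin order", {
  set.seed(6)
  onehot <- random_onehot(128)
  r1 <- matrix(runif(4 * 2, 0.5, 2), 4, 2)
  r2 <- r1 + matrix(rnorm(8, sd = 0.2), 4, 2)
  perm <- c(3, 1, 4, 2)
  ref <- one_hot_decode(onehot[50, , drop = FALSE])
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mk <- function(a, b) rate_oracle(function(oh) {
    if (all(oh[50, ] == onehot[50, ])) a else b
  })
  v1 <- predict_variant(list(mk(r1, r2)), onehot, 49L, ref, alt)
  v2 <- predict_variant(list(mk(r1[perm, ], r2[perm, ])), onehot, 49L,
                        ref, alt)
  expect_equal(v1$features, v2$features)
})

test_that("ensemble features from identical models are identical copies", {
  set.seed(7)
  onehot <- random_onehot(128)
  oracle <- toy_equivariant_predictor(32L)
  ref <- one_hot_decode(onehot[60, , drop = FALSE])
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  vs <- predict_variant(list(oracle, oracle, oracle, oracle), onehot, 59L,
                        ref, alt)
  f <- matrix(vs$features, ncol = 4)
  for (m in 2:4) expect_equal(unname(f[, m]), unname(f[, 1]))
})

test_that("random forest separates separable features and is null on noise", {
  set.seed(8)
  n <- 120
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  feats <- cbind(ifelse(labels, 1, 0) + rnorm(n, sd = 0.05), rnorm(n))
  fit <- snp_classifier(feats, labels, seed = 1, n_trees = 200)
  expect_equal(fit$auroc, 1.0, tolerance = 0.01)
  expect_gt(fit$spearman, 0.8)
  expect_error(snp_classifier(feats, rep(TRUE, n), seed = 1), "both classes")
})
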