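separable_data <- function(n = 120, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("negative", "positive"), length.out = n),
              levels = c("negative", "positive"))
  data.frame(
    a = ifelse(y == "positive", 5, -5) + rnorm(n, sd = 0.3),
    b = rnorm(n))
}

test_that("metrics reproduce a hand-computed confusion matrix", {
  # TP = 4, FP = 1, TN = 3, FN = 2 at threshold 0.5
  labels <- c(rep("positive", 6), rep("negative", 4))
  post <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.1, 0.3, 0.25, 0.15, 0.55)
  m <- classification_metrics(labels, post)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$f_measure, 8 / 11)
  expect_equal(m$mcc, (4 * 3 - 1 * 2) / sqrt(5 * 6 * 4 * 5))
  # perfect, confident predictions
  p <- classification_metrics(c("positive", "negative"), c(0.99, 0.01))
  expect_equal(unlist(p), c(auc = 1, accuracy = 1, f_measure = 1, mcc = 1))
  # constant posteriors on balanced data: AUC 0.5
  expect_equal(classification_metrics(labels, rep(0.5, 10))$auc, 0.5)
  expect_error(classification_metrics(labels, post[-1]), "length")
})

test_that("rank-based AUC equals brute-force pairwise concordance", {
  set.seed(61)
  for (r in 1:15) {
    n <- sample(20:200, 1)
    labels <- sample(c("negative", "positive"), n, replace = TRUE,
                     prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), sample(1:3, 1))  # coarse grid forces ties
    expect_equal(classification_metrics(labels, scores)$auc,
                 oracle_auc(labels, scores))
  }
})

test_that("every classifier kind separates a separable fixture", {
  x <- separable_data()
  y <- factor(rep(c("negative", "positive"), length.out = nrow(x)),
              levels = c("negative", "positive"))
  for (kind in mirtarget:::MODEL_KINDS) {
    m <- train_model(kind, x, y, rng_seed = 3)
    p <- predict_posterior(m, x)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(classification_metrics(y, p)$accuracy, 1,
                 tolerance = 0.01)
  }
  expect_error(train_model("random_forest", x,
                           rep("positive", nrow(x))), "single class")
})

test_that("random-forest posteriors are vote fractions, reproducible", {
  x <- separable_data(80, seed = 4)
  y <- factor(rep(c("negative", "positive"), 40),
              levels = c("negative", "positive"))
  m1 <- train_model("random_forest", x, y, rng_seed = 9)
  m2 <- train_model("random_forest", x, y, rng_seed = 9)
  expect_equal(m1$fit$ntree, 100)
  expect_identical(predict_posterior(m1, x), predict_posterior(m2, x))
  p <- predict_posterior(m1, x)
  expect_true(all(abs(p * 100 - round(p * 100)) < 1e-9))  # /100 votes
})

test_that("nonlinear kinds solve XOR while linear kinds stay at chance", {
  set.seed(62)
  n <- 400
  a <- runif(n, -1, 1); b <- runif(n, -1, 1)
  y <- factor(ifelse(xor(a > 0, b > 0), "positive", "negative"),
              levels = c("negative", "positive"))
  x <- data.frame(a = a, b = b)
  rep <- crossvalidate(x, y, k = 5,
                       kinds = c("logistic_regression", "random_forest",
                                 "gaussian_svm"), rng_seed = 5)
  met <- rep$metrics
  expect_lt(abs(met$auc[met$kind == "logistic_regression"] - 0.5), 0.12)
  expect_gt(met$auc[met$kind == "random_forest"], 0.9)
  expect_gt(met$auc[met$kind == "gaussian_svm"], 0.9)
})

test_that("prediction validates features and batches consistently", {
  x <- separable_data(60, seed = 6)
  y <- factor(rep(c("negative", "positive"), 30),
              levels = c("negative", "positive"))
  m <- train_model("logistic_regression", x, y)
  expect_error(predict_posterior(m, x["b"]), "missing feature.*a")
  batch <- predict_posterior(m, x)
  single <- vapply(seq_len(10), function(i)
    predict_posterior(m, x[i, , drop = FALSE]), numeric(1))
  expect_equal(batch[1:10], single)
  # posterior is monotone in the informative feature for LR
  grid <- data.frame(a = seq(-5, 5, length.out = 20), b = 0)
  expect_true(all(diff(predict_posterior(m, grid)) >= 0))
})

test_that("cross-validation stratifies folds and pools posteriors", {
  x <- separable_data(105, seed = 7)
  y <- factor(rep(c("negative", "positive"), length.out = 105),
              levels = c("negative", "positive"))
  rep <- crossvalidate(x, y, k = 10, kinds = "logistic_regression",
                       rng_seed = 2)
  expect_equal(rep$metrics$auc, 1)
  sizes <- table(rep$folds)
  expect_lte(diff(range(sizes)), 2)  # each class differs by <= 1
  for (cl in levels(y))
    expect_lte(diff(range(table(rep$folds[y == cl]))), 1)
  expect_false(anyNA(rep$posteriors))
  expect_error(crossvalidate(x, y, k = 200), "folds")
})

test_that("label-permuted data score near chance", {
  set.seed(63)
  x <- separable_data(600, seed = 8)
  y <- factor(sample(rep(c("negative", "positive"), 300)),
              levels = c("negative", "positive"))
  rep <- crossvalidate(x, y, k = 5, kinds = "logistic_regression",
                       rng_seed = 3)
  expect_lt(abs(rep$metrics$auc - 0.5), 0.08)
})

test_that("per-fold CFS selects inside the training split only", {
  set.seed(64)
  d <- simulate_feature_dataset(n = 120, n_informative = 2, n_noise = 6,
                                effect_size = 3, rng_seed = 12)
  rep <- crossvalidate(d$features, d$labels, k = 5,
                       kinds = "logistic_regression",
                       per_fold_selection = TRUE, rng_seed = 4)
  expect_length(rep$selected, 5)
  for (f in seq_len(5)) {
    expect_true(all(rep$selected[[f]] %in% names(d$features)))
    # re-running CFS on the fold's training rows reproduces the choice:
    # the held-out rows demonstrably played no part
    tr <- rep$folds != f
    sel <- cfs_select(d$features[tr, ], d$labels[tr])
    if (length(sel$selected) >= 2)
      expect_identical(rep$selected[[f]], sel$selected)
  }
  expect_gt(rep$metrics$auc, 0.9)
})

test_that("the hold-out split is stratified at the requested fraction", {
  y <- rep(c("negative", "positive"), c(40, 60))
  tr <- holdout_split(y, 0.8, rng_seed = 13)
  expect_equal(sum(tr[y == "negative"]), 32)
  expect_equal(sum(tr[y == "positive"]), 48)
})

test_that("SVM tuning explores the prescribed grid", {
  x <- separable_data(60, seed = 14)
  y <- factor(rep(c("negative", "positive"), 30),
              levels = c("negative", "positive"))
  tuned <- tune_svm("linear_svm", x, y, costs = c(0.1, 1), k = 3,
                    rng_seed = 5)
  expect_true(tuned$cost %in% c(0.1, 1))
  expect_equal(nrow(tuned$grid), 2)
})

test_that("model bundles survive a save/load round trip", {
  x <- separable_data(40, seed = 15)
  y <- factor(rep(c("negative", "positive"), 20),
              levels = c("negative", "positive"))
  m <- train_model("naive_bayes", x, y)
  f <- withr::local_tempfile(fileext = ".rds")
  save_model(m, f)
  m2 <- load_model(f)
  expect_identical(predict_posterior(m2, x), predict_posterior(m, x))
})

# --- overlap protocols -----------------------------------------------------

sites_df <- function(start, end, score, mirna = "m1", gene = "g1")
  data.frame(mirna_id = mirna, gene_id = gene, utr_start = start,
             utr_end = end, score = score, stringsAsFactors = FALSE)

test_that("predictions identical to expected sites reach TPR 1", {
  exp_sites <- sites_df(c(10, 200), c(32, 222), score = c(1, 1))
  pred <- sites_df(c(10, 200), c(32, 222), score = c(0.9, 0.8))
  roc <- site_overlap_roc(pred, exp_sites)
  for (r in roc) expect_equal(max(r$tpr), 1)
  expect_error(site_overlap_roc(pred, exp_sites[0, ]), "empty")
})

test_that("a 60%-overlap prediction is a hit only at low thresholds", {
  exp_sites <- sites_df(100, 120, score = 1)          # length 20
  pred <- sites_df(108, 130, 0.9)                     # covers 12 / 20
  roc <- site_overlap_roc(pred, exp_sites)
  expect_equal(max(roc$overlap_0.25$tpr), 1)
  expect_equal(max(roc$overlap_0.5$tpr), 1)
  expect_equal(max(roc$overlap_0.75$tpr), 0)
  expect_equal(max(roc$overlap_0.95$tpr), 0)
})

test_that("each expected site is claimed by at most one prediction", {
  exp_sites <- sites_df(100, 120, score = 1)
  pred <- sites_df(c(100, 101), c(120, 121), score = c(0.9, 0.8))
  roc <- site_overlap_roc(pred, exp_sites)
  r <- roc$overlap_0.75
  expect_equal(max(r$tpr), 1)       # one claims it...
  expect_equal(max(r$fpr), 1)       # ...the other is a false positive
})

test_that("partial AUC follows trapezoid geometry on the diagonal", {
  fpr <- seq(0, 1, by = 0.01)
  expect_equal(partial_auc(fpr, fpr), 0.08, tolerance = 1e-9)
  expect_equal(partial_auc(c(0, 1), c(1, 1)), 0.4)  # perfect scorer
})

test_that("overlap histograms localize predictions around the site", {
  exp_sites <- sites_df(100, 120, score = 1)          # bin width 2
  h_exact <- overlap_histogram(sites_df(100, 120, 0.9), exp_sites)
  expect_length(h_exact, 20)
  expect_true(all(h_exact[6:15] > 0))
  expect_true(all(h_exact[c(1:5, 16:20)] == 0))
  # prediction fully upstream touches only upstream flank bins
  h_up <- overlap_histogram(sites_df(92, 98, 0.9), exp_sites)
  expect_true(all(h_up[1:5] >= 0) && sum(h_up[6:20]) == 0 &&
                sum(h_up) > 0)
  # first half coverage fills in-site bins 1-5 only
  h_half <- overlap_histogram(sites_df(100, 110, 0.9), exp_sites)
  expect_true(all(h_half[6:10] > 0))
  expect_true(all(h_half[11:15] == 0))
})
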