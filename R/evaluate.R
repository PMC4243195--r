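# Evaluation machinery: the four scalar metrics, stratified k-fold
# cross-validation (optionally with per-fold CFS so feature selection
# never sees test rows), hold-out evaluation, and the site-level
# overlap-threshold ROC / overlap-histogram protocols.

#' Binary classification metrics
#'
#' AUC uses the rank (Wilcoxon) formulation, equivalent to the
#' trapezoidal ROC area with midrank tie handling.  F-measure is the
#' positive-class F1.  MCC returns 0 when any confusion-matrix margin
#' is 0.
#'
#' @param labels factor/character `negative`/`positive`.
#' @param posteriors numeric scores in `[0, 1]`.
#' @param threshold classification cutoff for accuracy/F/MCC.
#' @return Named list: `auc`, `accuracy`, `f_measure`, `mcc`.
#' @export
classification_metrics <- function(labels, posteriors, threshold = 0.5) {
  y <- as.character(labels)
  if (length(y) != length(posteriors))
    stop("labels and posteriors differ in length")
  pos <- y == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- if (n1 > 0 && n0 > 0) {
    r <- rank(posteriors)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  pred <- posteriors >= threshold
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  tn <- sum(!pred & !pos); fn <- sum(!pred & pos)
  acc <- (tp + tn) / length(y)
  f <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  den <- prod(sqrt(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / den
  list(auc = auc, accuracy = acc, f_measure = f, mcc = mcc)
}

stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation
#'
#' Posteriors are pooled over folds before computing metrics.  With
#' `per_fold_selection`, CFS runs on each training split only and the
#' model is fit on the selected columns; the test rows of a fold are
#' never touched by selection or training (fold assignments are returned
#' so this can be audited).
#'
#' @param features data.frame of features.
#' @param labels `negative`/`positive` labels.
#' @param k folds (default 10); class counts per fold differ by <= 1.
#' @param kinds model kinds to evaluate (default all six).
#' @param per_fold_selection run CFS inside each fold.
#' @param hyperparams passed to [train_model()].
#' @param rng_seed integer seed.
#' @return List of class `evaluation_report`: `metrics` (one row per
#'   kind), `posteriors` (pooled, per kind), `folds`, `labels`.
#' @export
crossvalidate <- function(features, labels, k = 10L, kinds = MODEL_KINDS,
                          per_fold_selection = FALSE, hyperparams = list(),
                          rng_seed = 1L) {
  x <- as.data.frame(features)
  y <- factor(as.character(labels), levels = c("negative", "positive"))
  n <- nrow(x)
  if (k > n) stop("more folds than samples")
  fold <- with_seed(rng_seed, stratified_folds(as.character(y), k))
  post <- matrix(NA_real_, n, length(kinds),
                 dimnames = list(NULL, kinds))
  selected <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    xtr <- x[tr, , drop = FALSE]
    cols <- names(xtr)
    if (per_fold_selection) {
      sel <- cfs_select(xtr, y[tr])
      if (length(sel$selected) >= 2L) cols <- sel$selected
      selected[[f]] <- cols
    }
    for (kind in kinds) {
      m <- train_model(kind, xtr[, cols, drop = FALSE], y[tr],
                       hyperparams = hyperparams,
                       rng_seed = rng_seed + f)
      post[te, kind] <- predict_posterior(
        m, x[te, cols, drop = FALSE])
    }
  }
  metrics <- do.call(rbind, lapply(kinds, function(kind) {
    mm <- classification_metrics(y, post[, kind])
    data.frame(kind = kind, auc = mm$auc, accuracy = mm$accuracy,
               f_measure = mm$f_measure, mcc = mm$mcc,
               stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics, posteriors = post, folds = fold,
                 labels = y, selected = selected),
            class = "evaluation_report")
}

#' Stratified train / hold-out split
#'
#' @param labels class labels.
#' @param train_frac fraction assigned to training (default 0.8).
#' @param rng_seed integer seed.
#' @return Logical vector, `TRUE` for training rows.
#' @export
holdout_split <- function(labels, train_frac = 0.8, rng_seed = 1L) {
  y <- as.character(labels)
  tr <- logical(length(y))
  with_seed(rng_seed, for (cl in unique(y)) {
    idx <- which(y == cl)
    ntr <- round(length(idx) * train_frac)
    tr[sample(idx, ntr)] <- TRUE
  })
  tr
}

# --- site-level overlap protocols ------------------------------------------

overlap_len <- function(s1, e1, s2, e2) max(0, min(e1, e2) - max(s1, s2))

# greedy one-to-one matching of predictions (descending score) to expected
# sites within each (miRNA, gene) pair at a fractional overlap threshold;
# returns a logical "true site" label per prediction row
match_predictions <- function(pred, expected, threshold) {
  lab <- logical(nrow(pred))
  for (g in unique(paste(pred$mirna_id, pred$gene_id))) {
    pi <- which(paste(pred$mirna_id, pred$gene_id) == g)
    ei <- which(paste(expected$mirna_id, expected$gene_id) == g)
    if (!length(ei)) next
    taken <- logical(length(ei))
    for (i in pi[order(-pred$score[pi])]) {
      ov <- vapply(ei, function(e) overlap_len(
        pred$utr_start[i], pred$utr_end[i],
        expected$utr_start[e], expected$utr_end[e]), numeric(1))
      need <- threshold * (expected$utr_end[ei] - expected$utr_start[ei])
      cand <- which(!taken & ov >= need & ov > 0)
      if (length(cand)) {
        j <- cand[which.max(ov[cand])]
        taken[j] <- TRUE
        lab[i] <- TRUE
      }
    }
  }
  lab
}

#' Overlap-threshold ROC for site-level predictions
#'
#' A prediction counts as a true site at overlap threshold `t` if it
#' covers at least `t * length(expected site)` of an expected site of the
#' same (miRNA, gene) pair; each expected site can be claimed by at most
#' one prediction (greedy, by descending score).  The ROC is swept over
#' posterior cutoffs; TPR is relative to the number of expected sites, so
#' it may not reach 1.  The partial AUC integrates the curve over
#' `fpr_range` by trapezoid.
#'
#' @param pred data.frame of predictions: `mirna_id`, `gene_id`,
#'   `utr_start`, `utr_end`, `score` (ranking score for matching) and
#'   `posterior` (swept score; defaults to `score`).
#' @param expected data.frame of expected sites: `mirna_id`, `gene_id`,
#'   `utr_start`, `utr_end`.
#' @param overlap_thresholds fractional thresholds (default
#'   `c(.25, .5, .75, .95)`).
#' @param fpr_range FPR interval for the partial AUC (default `c(0, .4)`).
#' @return List of class `overlap_roc`: per threshold, the ROC points
#'   (`fpr`, `tpr`) and `partial_auc`.
#' @export
site_overlap_roc <- function(pred, expected,
                             overlap_thresholds = c(0.25, 0.5, 0.75, 0.95),
                             fpr_range = c(0, 0.4)) {
  if (nrow(expected) == 0L) stop("empty expected site set")
  if (is.null(pred$posterior)) pred$posterior <- pred$score
  out <- lapply(overlap_thresholds, function(t) {
    lab <- match_predictions(pred, expected, t)
    ord <- order(-pred$posterior)
    tp <- cumsum(lab[ord]); fp <- cumsum(!lab[ord])
    n_exp <- nrow(expected); n_neg <- sum(!lab)
    tpr <- c(0, tp / n_exp)
    fpr <- c(0, if (n_neg > 0) fp / n_neg else fp * 0)
    list(threshold = t, fpr = fpr, tpr = tpr,
         partial_auc = partial_auc(fpr, tpr, fpr_range))
  })
  names(out) <- paste0("overlap_", overlap_thresholds)
  structure(out, class = "overlap_roc")
}

#' Partial AUC of an ROC curve over an FPR interval
#'
#' @param fpr,tpr ROC points (monotone in `fpr`).
#' @param fpr_range interval, default `c(0, 0.4)`.
#' @return Trapezoidal area; at most `diff(fpr_range)`.
#' @export
partial_auc <- function(fpr, tpr, fpr_range = c(0, 0.4)) {
  lo <- fpr_range[1]; hi <- fpr_range[2]
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  if (length(unique(fpr)) < 2)  # vertical curve (e.g. no false positives)
    return(max(tpr) * (hi - max(lo, fpr[1])))
  # interpolate curve onto the clipped range
  xs <- sort(unique(c(lo, hi, fpr[fpr >= lo & fpr <= hi])))
  ys <- stats::approx(fpr, tpr, xout = xs, ties = max, rule = 2)$y
  sum(diff(xs) * (head(ys, -1) + ys[-1]) / 2)
}

#' Positional overlap histogram of predictions against expected sites
#'
#' Each expected site's span is divided into 10 equal bins, with 5
#' flanking bins of the same width on each side.  For every prediction of
#' an expected site's (miRNA, gene) pair, every coordinate the prediction
#' covers inside the binned span (site plus flanks) increments its bin.
#'
#' @param pred,expected data.frames as in [site_overlap_roc()].
#' @param n_site_bins bins across the expected site (default 10).
#' @param n_flank_bins bins per flank (default 5).
#' @return Integer vector of length
#'   `n_flank_bins + n_site_bins + n_flank_bins` (upstream, in-site,
#'   downstream).
#' @export
overlap_histogram <- function(pred, expected, n_site_bins = 10L,
                              n_flank_bins = 5L) {
  nb <- n_site_bins + 2L * n_flank_bins
  counts <- integer(nb)
  for (e in seq_len(nrow(expected))) {
    ei <- expected[e, ]
    len <- ei$utr_end - ei$utr_start
    bw <- len / n_site_bins
    span_lo <- ei$utr_start - n_flank_bins * bw
    pi <- which(pred$mirna_id == ei$mirna_id & pred$gene_id == ei$gene_id)
    for (i in pi) {
      lo <- max(pred$utr_start[i], ceiling(span_lo))
      hi <- min(pred$utr_end[i], ei$utr_end + n_flank_bins * bw)
      if (hi <= lo) next
      for (x in seq.int(lo, hi - 1L)) {
        b <- floor((x - span_lo) / bw) + 1L
        if (b >= 1L && b <= nb) counts[b] <- counts[b] + 1L
      }
    }
  }
  counts
}
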