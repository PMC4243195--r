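# End-to-end assembly: scan positives, generate mock negatives, extract
# site features, label by overlap with the known site coordinates, and
# aggregate to the UTR level.  These helpers drive the package's
# self-contained evaluation runs.

#' Build labeled site-level and UTR-level datasets
#'
#' Positive sites are CTSs found by scanning each positive miRNA-UTR pair
#' (threshold `pos_min_score`) that cover at least `min_overlap` of a
#' known site; negative sites come from mock miRNAs scanned at the
#' stringent `neg_min_score`.  Site features are extracted once and
#' reused for the UTR-level summaries, where each positive pair is kept
#' 1:1 with its mock pair (zero-site pairs retained, zero-filled).
#'
#' @param sim a [simulate_dataset()] result (or any list with `mirnas`,
#'   `utrs`, `pairs` of the same shape).
#' @param backend an [energy_backend()].
#' @param acc_params an [accessibility_params()].
#' @param pos_min_score,neg_min_score alignment thresholds for the
#'   positive-side and the mock (negative) scans.
#' @param min_overlap fraction of a known site a scanned CTS must cover
#'   to be labeled positive.
#' @param rng_seed integer seed (drives mock generation).
#' @return List of class `pipeline_data`: `site` (list: `features`
#'   data.frame, `labels` factor), `utr` (same shape), plus the
#'   intermediate `site_matrix`, `utr_matrix` and `negatives`.
#' @export
build_datasets <- function(sim, backend = energy_backend(),
                           acc_params = accessibility_params(),
                           pos_min_score = 140, neg_min_score = 155,
                           min_overlap = 0.5, rng_seed = 1L) {
  mirnas <- sim$mirnas; utrs <- sim$utrs; truth <- sim$pairs
  pos_pairs <- unique(truth[, c("mirna_id", "gene_id")])
  pos_sites <- list()
  for (i in seq_len(nrow(pos_pairs))) {
    hits <- scan_utr(mirnas[[pos_pairs$mirna_id[i]]],
                     utrs[[pos_pairs$gene_id[i]]],
                     scan_params(min_score = pos_min_score))
    tr <- truth[truth$mirna_id == pos_pairs$mirna_id[i] &
                truth$gene_id == pos_pairs$gene_id[i], ]
    keep <- vapply(hits, function(h) {
      ov <- vapply(seq_len(nrow(tr)), function(k) overlap_len(
        h$utr_start, h$utr_end, tr$site_start[k], tr$site_end[k]),
        numeric(1))
      any(ov >= min_overlap * (tr$site_end - tr$site_start))
    }, logical(1))
    pos_sites <- c(pos_sites, hits[keep])
  }
  neg <- build_negative_sites(pos_pairs, mirnas, utrs,
                              params = scan_params(min_score = neg_min_score),
                              rng_seed = rng_seed, mocks = sim$mocks)
  all_sites <- c(pos_sites, neg$sites)
  labels <- factor(rep(c("positive", "negative"),
                       c(length(pos_sites), length(neg$sites))),
                   levels = c("negative", "positive"))
  sf <- site_feature_matrix(all_sites, utrs, backend, acc_params)
  feat_cols <- site_feature_names()
  # UTR level: positive pairs with their positive sites, mock pairs with
  # their negative sites, 1:1
  utr_pairs <- rbind(
    data.frame(pos_pairs, label = "positive", stringsAsFactors = FALSE),
    neg$pairs[, c("mirna_id", "gene_id", "label")])
  sf_lab <- cbind(sf, .label = as.character(labels))
  um <- utr_feature_matrix(utr_pairs, sf, utrs)
  structure(list(
    site = list(features = sf[, feat_cols, drop = FALSE], labels = labels),
    utr = list(features = um[, utr_feature_names(), drop = FALSE],
               labels = factor(utr_pairs$label,
                               levels = c("negative", "positive"))),
    site_matrix = sf_lab, utr_matrix = um, negatives = neg,
    positive_sites = pos_sites), class = "pipeline_data")
}
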