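# The 624-dimensional UTR-level feature vector for one miRNA-gene pair:
# {sum, min, max, mean} over the pair's CTSs of each of the 151 site
# features plus the site posterior, alignment score and site start/end
# (155 x 4 = 620), plus UTR_length, number_sites, site_density and
# max_100_sites.

#' Canonical UTR-level feature names
#'
#' @return Character vector of the 624 names in canonical order.
#' @export
utr_feature_names <- function() {
  base <- c(site_feature_names(), "site_posterior", "miranda_score",
            "cts_start", "cts_end")
  stats <- c("sum", "min", "max", "mean")
  c(as.vector(vapply(base, function(f) paste0(f, "_", stats),
                     character(4))),
    "UTR_length", "number_sites", "site_density", "max_100_sites")
}

#' Summarize the CTSs of one miRNA-gene pair into UTR-level features
#'
#' Pairs with no CTS are retained with all 620 summaries zero-filled so
#' that negative pairs stay scorable.  When no site-level model posterior
#' is available the posterior column defaults to the alignment score
#' normalized by the maximum score in `site_rows` (or 0 with no sites).
#'
#' @param site_rows data.frame of this pair's sites: the 151 canonical
#'   feature columns plus `score`, `utr_start`, `utr_end` and optionally
#'   `posterior`; may have zero rows.
#' @param utr the pair's [utr_record()].
#' @param window window width for `max_100_sites` (default 100 nt).
#' @return Named numeric vector of length 624.
#' @export
summarize_pair <- function(site_rows, utr, window = 100L) {
  n <- nchar(utr$sequence)
  if (n == 0L) stop("UTR length is zero")
  base_names <- c(site_feature_names(), "site_posterior", "miranda_score",
                  "cts_start", "cts_end")
  k <- nrow(site_rows)
  if (k > 0L) {
    post <- if ("posterior" %in% names(site_rows)) site_rows$posterior
            else site_rows$score / max(site_rows$score)
    m <- as.matrix(cbind(site_rows[, site_feature_names(), drop = FALSE],
                         site_posterior = post,
                         miranda_score = site_rows$score,
                         cts_start = site_rows$utr_start,
                         cts_end = site_rows$utr_end))
    summ <- as.vector(apply(m, 2L, function(v)
      c(sum(v), min(v), max(v), mean(v))))
  } else {
    summ <- numeric(4L * length(base_names))
  }
  names(summ) <- as.vector(vapply(base_names, function(f)
    paste0(f, "_", c("sum", "min", "max", "mean")), character(4)))
  starts <- if (k > 0L) site_rows$utr_start else numeric()
  out <- c(summ, UTR_length = n, number_sites = k,
           site_density = k / n,
           max_100_sites = max_sites_in_window(starts, window))
  stopifnot(length(out) == 624L)
  out
}

#' Maximum number of CTS starts within a sliding window
#'
#' @param starts numeric vector of CTS start positions.
#' @param window window width in nt (closed window; default 100).
#' @return Integer count (0 for no sites).
#' @export
max_sites_in_window <- function(starts, window = 100L) {
  if (!length(starts)) return(0L)
  s <- sort(starts)
  best <- 1L
  j <- 1L
  for (i in seq_along(s)) {
    while (s[i] - s[j] > window) j <- j + 1L
    best <- max(best, i - j + 1L)
  }
  best
}

#' UTR-level feature matrix for a set of miRNA-gene pairs
#'
#' @param pairs data.frame with `mirna_id`, `gene_id` (one row per pair).
#' @param site_features data.frame from [site_feature_matrix()], with an
#'   optional `posterior` column from the site-level classifier.
#' @param utrs named list of [utr_record()]s.
#' @return data.frame: `mirna_id`, `gene_id`, then the 624 canonical
#'   UTR-level features.
#' @export
utr_feature_matrix <- function(pairs, site_features, utrs) {
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    sel <- site_features$mirna_id == pairs$mirna_id[i] &
      site_features$gene_id == pairs$gene_id[i]
    utr <- utrs[[pairs$gene_id[i]]]
    if (is.null(utr)) stop("no UTR record for gene '", pairs$gene_id[i], "'")
    summarize_pair(site_features[sel, , drop = FALSE], utr)
  })
  cbind(pairs[, c("mirna_id", "gene_id"), drop = FALSE],
        as.data.frame(do.call(rbind, rows)))
}
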