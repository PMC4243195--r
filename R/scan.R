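# Candidate-target-site discovery: a seed-weighted complementarity local
# alignment of the reversed miRNA (3'->5') against the UTR (5'->3'),
# returning non-overlapping local maxima above a score threshold.

#' Alignment scoring parameters for CTS scanning
#'
#' Defaults mirror the released complementarity aligner: +5 for a
#' Watson-Crick pair, +1 for a G:U wobble, -3 for a mismatch, affine gaps
#' -9/-4, and a x4 weight on pair scores at miRNA seed positions 2-8 (the
#' aligner's default scale; under a x2 weight even a perfect 22-nt duplex
#' scores only 145, which would make the stringent negative-set threshold
#' unreachable).  `min_score` defaults to 140 for positive-side scanning;
#' 155 is the stringent threshold used when generating negative sites.
#'
#' @param score_wc,score_gu,score_mismatch pair scores.
#' @param gap_open,gap_extend affine gap penalties (negative); `-Inf`
#'   disables gaps.
#' @param seed_scale multiplicative weight on pair scores at seed
#'   positions (>= 1).
#' @param seed_positions integer range of weighted miRNA positions.
#' @param seed_scale_gu also scale G:U wobbles inside the seed window
#'   (off by default).
#' @param min_score minimum alignment score for a reported site.
#' @param max_sites cap on sites returned per miRNA-UTR pair.
#' @return A list of class `scan_params`.
#' @export
scan_params <- function(score_wc = 5, score_gu = 1, score_mismatch = -3,
                        gap_open = -9, gap_extend = -4, seed_scale = 4,
                        seed_positions = 2:8, seed_scale_gu = FALSE,
                        min_score = 140, max_sites = 50L) {
  stopifnot(score_wc > score_gu, score_gu > score_mismatch,
            gap_open < 0, gap_extend < 0, seed_scale >= 1, min_score > 0)
  structure(list(score_wc = score_wc, score_gu = score_gu,
                 score_mismatch = score_mismatch,
                 gap_open = if (is.finite(gap_open)) gap_open else -1e12,
                 gap_extend = if (is.finite(gap_extend)) gap_extend else -1e12,
                 seed_scale = seed_scale,
                 seed_lo = as.integer(min(seed_positions)),
                 seed_hi = as.integer(max(seed_positions)),
                 seed_scale_gu = isTRUE(seed_scale_gu),
                 min_score = min_score, max_sites = as.integer(max_sites)),
            class = "scan_params")
}

#' Scan a UTR for candidate target sites of a miRNA
#'
#' The alignment favors, but does not require, seed pairing, so weak-seed
#' (3' compensatory, centered) sites can still score above threshold.
#' Sites are extracted greedily by descending score and never overlap on
#' the UTR; the result is sorted by `utr_start`.
#'
#' @param mirna a [mature_mirna()].
#' @param utr a [utr_record()].
#' @param params a [scan_params()].
#' @return A list of `cts` objects, each with fields `mirna_id`, `gene_id`,
#'   `utr_start`, `utr_end` (0-based half-open), `score`, `pair_states`
#'   (integer codes per miRNA position: 1 G-C, 2 A-U, 3 G:U, 4 mismatch,
#'   5 gap/unaligned), `mir_pos`/`utr_pos` (aligned columns),
#'   `target_gap_positions` and `site_sequence`.
#' @export
scan_utr <- function(mirna, utr, params = scan_params()) {
  stopifnot(inherits(mirna, "mature_mirna"), inherits(utr, "utr_record"))
  n <- nchar(utr$sequence)
  if (n == 0L) stop("empty UTR sequence")
  if (n < nchar(mirna$sequence)) return(list())
  hits <- cpp_scan(mirna$sequence, utr$sequence, unclass(params))
  sites <- lapply(hits, function(h)
    build_cts(h, mirna, utr, min_score = params$min_score))
  sites[order(vapply(sites, function(s) s$utr_start, numeric(1)))]
}

build_cts <- function(h, mirna, utr, min_score) {
  m <- nchar(mirna$sequence)
  mb <- strsplit(mirna$sequence, "")[[1]]
  ub <- strsplit(utr$sequence, "")[[1]]
  states <- rep(5L, m)
  for (k in seq_along(h$mir_pos)) {
    p <- h$mir_pos[k]; j <- h$utr_pos[k]
    if (p > 0L && j >= 0L) states[p] <- pair_state(mb[p], ub[j + 1L])
    # p > 0, j == -1: miRNA base opposite a gap -> stays 5
  }
  structure(list(
    mirna_id = mirna$id, gene_id = utr$gene_id,
    utr_start = h$utr_start, utr_end = h$utr_end, score = h$score,
    pair_states = states,
    mir_pos = h$mir_pos, utr_pos = h$utr_pos,
    target_gap_positions = h$utr_pos[h$mir_pos == 0L],
    site_sequence = substr(utr$sequence, h$utr_start + 1L, h$utr_end),
    mirna_sequence = mirna$sequence,
    min_score = min_score), class = "cts")
}

# 1: G-C, 2: A-U, 3: G-U wobble, 4: mismatch (bases are miRNA, target)
pair_state <- function(m, u) {
  if ((m == "G" && u == "C") || (m == "C" && u == "G")) return(1L)
  if ((m == "A" && u == "U") || (m == "U" && u == "A")) return(2L)
  if ((m == "G" && u == "U") || (m == "U" && u == "G")) return(3L)
  4L
}

#' Positional pairing encoding of a CTS
#'
#' State codes for the first `n_positions` miRNA positions
#' (`miR_match_P01` ...), coded 1 G-C, 2 A-U, 3 G:U wobble, 4 mismatch,
#' 5 gap.  Positions beyond the miRNA length are coded 5.
#'
#' @param cts a `cts` from [scan_utr()].
#' @param n_positions number of positions to encode (default 20).
#' @return Named integer vector of length `n_positions`.
#' @export
encode_pairing <- function(cts, n_positions = 20L) {
  s <- cts$pair_states
  out <- rep(5L, n_positions)
  k <- min(length(s), n_positions)
  out[seq_len(k)] <- s[seq_len(k)]
  names(out) <- sprintf("miR_match_P%02d", seq_len(n_positions))
  out
}

#' Convert a list of CTSs to a data.frame
#'
#' @param sites list of `cts` objects.
#' @return data.frame with one row per site (`pair_states` packed as a
#'   comma-separated string).
#' @export
cts_table <- function(sites) {
  if (length(sites) == 0L)
    return(data.frame(mirna_id = character(), gene_id = character(),
                      utr_start = integer(), utr_end = integer(),
                      score = numeric(), pair_states = character(),
                      stringsAsFactors = FALSE))
  data.frame(
    mirna_id = vapply(sites, `[[`, character(1), "mirna_id"),
    gene_id = vapply(sites, `[[`, character(1), "gene_id"),
    utr_start = vapply(sites, `[[`, numeric(1), "utr_start"),
    utr_end = vapply(sites, `[[`, numeric(1), "utr_end"),
    score = vapply(sites, `[[`, numeric(1), "score"),
    pair_states = vapply(sites, function(s)
      paste(s$pair_states, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
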