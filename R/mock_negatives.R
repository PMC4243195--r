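# Mock-miRNA negatives: shuffled permutations of real miRNAs whose seed
# 7mers collide with no real miRNA seed, paired with the real UTRs and
# scanned at a stringent alignment threshold.

#' Build the seed 7mer index of a miRNA set
#'
#' The seed region is positions 1-8; its two 7mers (offsets 1-7 and 2-8)
#' of every supplied miRNA enter the index.
#'
#' @param mirnas list of [mature_mirna()]s.
#' @return Character vector (a set) of 7mers, class `seed_kmer_index`.
#' @export
build_seed_index <- function(mirnas) {
  stopifnot(length(mirnas) > 0L)
  kmers <- unlist(lapply(mirnas, function(m) {
    if (nchar(m$sequence) < 8L)
      stop("miRNA '", m$id, "' is shorter than 8 nt")
    c(substr(m$sequence, 1L, 7L), substr(m$sequence, 2L, 8L))
  }))
  structure(unique(kmers), class = "seed_kmer_index")
}

seed_7mers <- function(sequence) {
  c(substr(sequence, 1L, 7L), substr(sequence, 2L, 8L))
}

# Fisher-Yates shuffle driven by the current RNG stream
fisher_yates <- function(x) {
  n <- length(x)
  for (i in n:2) {
    j <- floor(runif(1) * i) + 1
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  x
}

#' Generate a mock miRNA by constrained shuffling
#'
#' Repeats Fisher-Yates shuffles of the sequence until neither seed 7mer
#' of the permutation occurs in `index`.  The result has exactly the
#' original nucleotide multiset, id suffixed `_mock`, and is deterministic
#' given `rng_seed`.
#'
#' @param mirna a [mature_mirna()].
#' @param index a [build_seed_index()] result.
#' @param rng_seed integer seed.
#' @param max_attempts attempts before giving up.
#' @return A [mature_mirna()] mock.
#' @export
generate_mock <- function(mirna, index, rng_seed, max_attempts = 10000L) {
  if (nchar(mirna$sequence) < 8L)
    stop("miRNA '", mirna$id, "' is shorter than 8 nt")
  bases <- strsplit(mirna$sequence, "")[[1]]
  with_seed(rng_seed, {
    for (k in seq_len(max_attempts)) {
      perm <- paste(fisher_yates(bases), collapse = "")
      if (!any(seed_7mers(perm) %in% index))
        return(mature_mirna(paste0(mirna$id, "_mock"), perm))
    }
    stop("no seed-disjoint permutation of '", mirna$id, "' found in ",
         max_attempts, " attempts; the sequence may be too low-complexity")
  })
}

#' Build the negative site set from mock miRNA-gene pairs
#'
#' For each positive pair, the mock miRNA replaces the real one and the
#' real UTR is scanned at the stringent threshold (default 155); every
#' resulting CTS is labeled negative.  Pairs yielding no CTS are still
#' recorded (with zero sites) so the UTR level stays 1:1 balanced.
#'
#' @param pairs data.frame with `mirna_id`, `gene_id` (the positive pairs).
#' @param mirnas named list of [mature_mirna()]s.
#' @param utrs named list of [utr_record()]s.
#' @param index a [build_seed_index()]; defaults to the index of `mirnas`.
#' @param params a [scan_params()]; default threshold 155.
#' @param rng_seed integer seed driving all mock generation.
#' @param mocks optional named list (by real miRNA id) of pre-generated
#'   mock miRNAs (e.g. from [simulate_dataset()]); when absent, mocks are
#'   generated here.
#' @return List with `pairs` (mock pair table with a `number_sites`
#'   column), `sites` (list of negative `cts`), and `mocks` (named list of
#'   mock miRNAs, one per positive pair row).
#' @export
build_negative_sites <- function(pairs, mirnas, utrs, index = NULL,
                                 params = scan_params(min_score = 155),
                                 rng_seed = 1L, mocks = NULL) {
  if (is.null(index)) index <- build_seed_index(mirnas)
  sites <- list()
  given <- mocks
  mocks <- list()
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    real <- mirnas[[pairs$mirna_id[i]]]
    if (is.null(real)) stop("unknown miRNA '", pairs$mirna_id[i], "'")
    mock <- given[[pairs$mirna_id[i]]] %||%
      generate_mock(real, index, rng_seed + i - 1L)
    mocks[[mock$id]] <<- mock
    hits <- scan_utr(mock, utrs[[pairs$gene_id[i]]], params)
    sites <<- c(sites, hits)
    data.frame(mirna_id = mock$id, gene_id = pairs$gene_id[i],
               label = "negative", number_sites = length(hits),
               stringsAsFactors = FALSE)
  })
  list(pairs = do.call(rbind, rows), sites = sites, mocks = mocks)
}
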