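# Self-contained synthetic data: miRNAs, UTRs with planted complementary
# target sites of a controlled seed-match type, per-base conservation
# tracks with elevated signal at planted sites, and labeled pair tables.
# Everything any pipeline stage needs can be generated here.

#' Simulation configuration
#'
#' Defaults describe the standard study conditions of the package's
#' end-to-end checks: 50 miRNAs of 22 nt, 50 UTRs of 300-800 nt with one
#' planted perfect-seed (8mer) site per positive pair, a 5% point-mutation
#' rate outside the seed-paired part of the site, and beta-distributed
#' conservation averaging 0.9 at planted sites vs 0.2 background.
#'
#' @param n_mirnas,n_utrs counts.
#' @param utr_length_range length range in nt (min >= 60).
#' @param planted_site_types subset of the nine seed-match type names
#'   (without the `Seed_match_` prefix); one is drawn per planted site.
#' @param sites_per_positive_pair planted sites per positive pair.
#' @param mutation_rate per-base mutation probability outside the
#'   seed-paired bases of a planted site.
#' @param conservation_site,conservation_background mean per-base
#'   conservation at planted sites and elsewhere.
#' @param gc_bias background G+C probability.
#' @param mirna_length length of simulated miRNAs.
#' @param decoys_per_pair decoy regions planted per positive pair: each is
#'   the reverse complement of the pair's mock miRNA carrying a mismatch
#'   opposite mock seed position 3, so it aligns to the mock well above
#'   the stringent negative-set threshold while every seed-match flag
#'   stays off.  This emulates the well-aligned, weak-seed chance sites
#'   that stringent-threshold scans recover from real (kilobase-scale,
#'   low-complexity) UTRs but that are vanishingly rare in short uniform
#'   background sequence.
#' @param rng_seed integer seed; the simulation is byte-reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_mirnas = 50L, n_utrs = 50L,
                       utr_length_range = c(300L, 800L),
                       planted_site_types = "8mer",
                       sites_per_positive_pair = 1L,
                       mutation_rate = 0.05,
                       conservation_site = 0.9,
                       conservation_background = 0.2,
                       gc_bias = 0.5, mirna_length = 22L,
                       decoys_per_pair = 1L, rng_seed = 1L) {
  stopifnot(n_mirnas > 0, n_utrs > 0, utr_length_range[1] >= 60,
            mutation_rate >= 0, mutation_rate <= 1,
            sites_per_positive_pair >= 1, decoys_per_pair >= 0)
  types <- c("8mer", "8merA1", "7mer1", "7mer2", "7merA1", "6mer1",
             "6mer2", "6mer1GU", "6mer2GU")
  stopifnot(all(planted_site_types %in% types))
  structure(as.list(environment()), class = "sim_config")
}

random_rna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

RC <- c(A = "U", C = "G", G = "C", U = "A")
WOBBLE <- c(G = "U", U = "G")  # target base giving a G:U with the miRNA

# Build the planted target subsequence for a miRNA and a seed-match type.
# The target is the reverse complement of the miRNA (so the site reads
# 5'->3' on the UTR with the seed match at its 3' end), then edited at the
# target position opposite selected seed positions to realize the type,
# and point-mutated outside the seed at `rate`.  Returns NULL when the
# miRNA cannot carry the type (e.g. no G/U base where a wobble is asked).
planted_site <- function(mirna_seq, type, rate) {
  mb <- strsplit(mirna_seq, "")[[1]]
  m <- length(mb)
  tb <- rev(unname(RC[mb]))      # position k (1-based, from 5' of site)
  opp <- function(p) m - p + 1L  # site index opposite miRNA position p
  protect <- 1:8                 # seed positions kept under control
  switch(type,
    "8mer" = NULL,
    "8merA1" = { tb[opp(1L)] <- "A" },
    "7mer1" = NULL,
    "7mer2" = { tb[opp(1L)] <- mismatch_base(mb[1L]) },
    "7merA1" = { tb[opp(1L)] <- "A"
                 tb[opp(8L)] <- mismatch_base(mb[8L]) },
    "6mer1" = { tb[opp(7L)] <- mismatch_base(mb[7L])
                tb[opp(8L)] <- mismatch_base(mb[8L]) },
    "6mer2" = { tb[opp(1L)] <- mismatch_base(mb[1L])
                tb[opp(8L)] <- mismatch_base(mb[8L]) },
    "6mer1GU" = { p <- pick_wobble_pos(mb, 1:6); if (is.null(p)) return(NULL)
                  tb[opp(p)] <- WOBBLE[[mb[p]]] },
    "6mer2GU" = { p <- pick_wobble_pos(mb, 2:7); if (is.null(p)) return(NULL)
                  tb[opp(p)] <- WOBBLE[[mb[p]]] })
  # point mutations outside the protected seed-opposite positions
  free <- setdiff(seq_len(m), vapply(protect, opp, integer(1)))
  for (k in free) if (runif(1) < rate)
    tb[k] <- sample(setdiff(c("A", "C", "G", "U"), tb[k]), 1L)
  paste(tb, collapse = "")
}

mismatch_base <- function(mb) {
  setdiff(c("A", "C", "G", "U"), c(RC[[mb]], WOBBLE[mb]))[1L]
}

pick_wobble_pos <- function(mb, range) {
  ok <- range[mb[range] %in% c("G", "U")]
  if (!length(ok)) NULL else if (length(ok) == 1L) ok else sample(ok, 1L)
}

# Decoy region for a mock miRNA: reverse complement with a planted
# mismatch opposite mock position 3 (kills all nine seed-match flags) and
# background mutations outside the seed-opposite bases.
decoy_site <- function(mock_seq, rate) {
  mb <- strsplit(mock_seq, "")[[1]]
  m <- length(mb)
  tb <- rev(unname(RC[mb]))
  opp <- function(p) m - p + 1L
  tb[opp(3L)] <- mismatch_base(mb[3L])
  free <- setdiff(seq_len(m), vapply(1:8, opp, integer(1)))
  for (k in free) if (runif(1) < rate)
    tb[k] <- sample(setdiff(c("A", "C", "G", "U"), tb[k]), 1L)
  paste(tb, collapse = "")
}

#' Simulate a labeled miRNA-target dataset
#'
#' Each positive pair couples one miRNA with one UTR carrying planted
#' (near-)complementary sites of the requested seed-match type; planted
#' neighborhoods get elevated beta-distributed conservation.  Output is
#' deterministic per `config$rng_seed`.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_data`: `mirnas` and `utrs` (named lists of
#'   records, conservation attached), `pairs` (positive pair table with
#'   true `site_start`/`site_end` coordinates, one row per planted site),
#'   `mocks` (one mock miRNA per positive pair, named by the real miRNA
#'   id), and `decoys` (coordinates of the planted decoy regions).
#' @export
simulate_dataset <- function(config = sim_config()) {
  with_seed(config$rng_seed, {
    types <- config$planted_site_types
    mirnas <- list()
    for (i in seq_len(config$n_mirnas)) {
      repeat {
        s <- random_rna(config$mirna_length, config$gc_bias)
        mb <- strsplit(s, "")[[1]]
        # ensure every requested wobble type is plantable for this miRNA
        ok <- !(("6mer1GU" %in% types && !any(mb[1:6] %in% c("G", "U"))) ||
                ("6mer2GU" %in% types && !any(mb[2:7] %in% c("G", "U"))))
        if (ok) break
      }
      id <- sprintf("mir-%03d", i)
      mirnas[[id]] <- mature_mirna(id, s)
    }
    index <- build_seed_index(mirnas)
    utrs <- list()
    pairs <- list()
    decoys <- list()
    mocks <- list()
    n_pairs <- min(config$n_mirnas, config$n_utrs)
    for (i in seq_len(config$n_utrs)) {
      len <- sample(config$utr_length_range[1]:config$utr_length_range[2], 1L)
      seq <- random_rna(len, config$gc_bias)
      cons <- rbeta(len, config$conservation_background * 4,
                    (1 - config$conservation_background) * 4)
      gid <- sprintf("gene-%03d", i)
      if (i <= n_pairs) {
        mir <- mirnas[[i]]
        m <- nchar(mir$sequence)
        k <- config$sites_per_positive_pair
        kd <- config$decoys_per_pair
        if (len < (k + kd) * (m + 20L))
          stop("UTR of ", len, " nt too short for ", k + kd,
               " planted region(s)")
        mock <- generate_mock(mir, index,
                              (config$rng_seed + 7919L * i) %% 2147483647L)
        mocks[[mir$id]] <- mock
        # non-overlapping slots for positive sites then decoys
        slot <- floor(len / (k + kd))
        for (s_i in seq_len(k + kd)) {
          lo <- (s_i - 1L) * slot
          start <- lo + sample.int(slot - m - 1L, 1L) - 1L
          if (s_i <= k) {
            type <- if (length(types) == 1L) types else sample(types, 1L)
            site <- NULL
            while (is.null(site))
              site <- planted_site(mir$sequence, type, config$mutation_rate)
            substr(seq, start + 1L, start + m) <- site
            cons[(start + 1L):(start + m)] <-
              rbeta(m, config$conservation_site * 8,
                    (1 - config$conservation_site) * 8)
            pairs[[length(pairs) + 1L]] <- data.frame(
              mirna_id = mir$id, gene_id = gid, label = "positive",
              site_start = start, site_end = start + m,
              site_type = type, stringsAsFactors = FALSE)
          } else {
            substr(seq, start + 1L, start + m) <-
              decoy_site(mock$sequence, config$mutation_rate)
            decoys[[length(decoys) + 1L]] <- data.frame(
              mirna_id = mock$id, gene_id = gid, site_start = start,
              site_end = start + m, stringsAsFactors = FALSE)
          }
        }
      }
      utrs[[gid]] <- utr_record(gid, seq, pmin(pmax(cons, 0), 1))
    }
    structure(list(mirnas = mirnas, utrs = utrs,
                   pairs = do.call(rbind, pairs),
                   mocks = mocks,
                   decoys = if (length(decoys)) do.call(rbind, decoys),
                   config = config),
              class = "sim_data")
  })
}

#' Write a simulated dataset to a directory
#'
#' Emits `mirnas.fa`, `utrs.fa`, `pairs.tsv` and per-UTR conservation as
#' `conservation.bedgraph` (each UTR on its own pseudo-chromosome named by
#' gene id, 0-based starts).
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$mirnas, file.path(dir, "mirnas.fa"))
  write_fasta(sim$utrs, file.path(dir, "utrs.fa"))
  write_pair_table(sim$pairs, file.path(dir, "pairs.tsv"))
  con <- file(file.path(dir, "conservation.bedgraph"), "w")
  on.exit(close(con))
  for (u in sim$utrs) {
    v <- round(u$conservation, 4)
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    writeLines(sprintf("%s\t%d\t%d\t%g", u$gene_id, starts, ends,
                       r$values), con)
  }
  invisible(dir)
}

#' Simulate a plain feature matrix with labels
#'
#' Informative columns are Gaussian with a between-class mean shift of
#' `effect_size` standard deviations; noise columns are class-independent.
#' Exercises the feature-selection and model modules in isolation.
#'
#' @param n samples (>= 20), balanced classes.
#' @param n_informative,n_noise column counts.
#' @param effect_size standardized mean shift.
#' @param rng_seed integer seed.
#' @return List: `features` (data.frame), `labels` (factor).
#' @export
simulate_feature_dataset <- function(n = 200L, n_informative = 1L,
                                     n_noise = 19L, effect_size = 2,
                                     rng_seed = 1L) {
  stopifnot(n >= 20L)
  with_seed(rng_seed, {
    y <- factor(rep(c("negative", "positive"), length.out = n),
                levels = c("negative", "positive"))
    shift <- ifelse(y == "positive", effect_size, 0)
    cols <- c(
      lapply(seq_len(n_informative), function(i) rnorm(n) + shift),
      lapply(seq_len(n_noise), function(i) rnorm(n)))
    names(cols) <- c(sprintf("inf_%02d", seq_len(n_informative)),
                     sprintf("noise_%02d", seq_len(n_noise)))
    list(features = as.data.frame(cols), labels = y)
  })
}
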