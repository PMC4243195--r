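# The 151-dimensional site-level feature vector, in canonical order:
# Energy (6), seed-match flags (9), positional pairing (20), pairing
# summaries (18), accessibility (33), composition (61), conservation (3),
# location (1).

NUC <- c("A", "C", "G", "U")
DIMERS <- as.vector(outer(NUC, NUC, function(a, b) paste0(a, b)))

#' Canonical site-level feature names
#'
#' @return Character vector of the 151 feature names in canonical order.
#' @export
site_feature_names <- function() {
  energy <- c("Duplex_MFE", "Seed_MFE", "3p_MFE", "Local_target_MFE",
              "Local_cons_target_MFE", "Local_open_energy")
  seed <- c("Seed_match_8mer", "Seed_match_8merA1", "Seed_match_7mer1",
            "Seed_match_7mer2", "Seed_match_7merA1", "Seed_match_6mer1",
            "Seed_match_6mer2", "Seed_match_6mer1GU", "Seed_match_6mer2GU")
  pos <- sprintf("miR_match_P%02d", 1:20)
  summ <- as.vector(vapply(c("Seed", "3p", "Total"), function(r)
    paste0(r, "_", c("GC", "AU", "GU", "mismatch", "bulge", "bulge_nt")),
    character(6)))
  acc <- c("Seed_acc", "Seed_5p_acc", "Seed_3p_acc",
           sprintf("Seed_P%02d_acc", 1:8),
           "Up_seed_flank_acc", "Down_seed_flank_acc",
           sprintf("Up_seed_P%02d_acc", 1:10),
           sprintf("Down_seed_P%02d_acc", 1:10))
  comp <- as.vector(vapply(c("Target", "Up", "Down"), function(r)
    paste0(r, "_", c(NUC, DIMERS), "_comp"), character(20)))
  c(energy, seed, pos, summ, acc, comp, "Flanking_AU_score",
    "Seed_cons_score", "Target_cons_score", "Flank_cons_score",
    "Dist_to_end")
}

#' Seed-match type flags
#'
#' Nine independent binary predicates on the pairing states of miRNA
#' positions 1-8 and the target base opposite position 1.  "WC" means
#' state 1 or 2; the A1 variants require an adenine opposite position 1
#' regardless of pairing state; the GU variants require exactly one G:U
#' wobble with all remaining positions WC.
#'
#' @param cts a `cts` from [scan_utr()].
#' @return Named integer vector of 9 flags in `{0, 1}`.
#' @export
seed_match_flags <- function(cts) {
  s <- cts$pair_states
  wc <- function(r) all(s[r] %in% c(1L, 2L))
  one_gu <- function(r) sum(s[r] == 3L) == 1L && all(s[r] %in% c(1L, 2L, 3L))
  a1 <- identical(target_base_at(cts, 1L), "A")
  c(Seed_match_8mer = wc(1:8),
    Seed_match_8merA1 = a1 && wc(2:8),
    Seed_match_7mer1 = wc(1:7),
    Seed_match_7mer2 = wc(2:8),
    Seed_match_7merA1 = a1 && wc(2:7),
    Seed_match_6mer1 = wc(1:6),
    Seed_match_6mer2 = wc(2:7),
    Seed_match_6mer1GU = one_gu(1:6),
    Seed_match_6mer2GU = one_gu(2:7)) * 1L
}

# target (UTR) base aligned opposite miRNA position p, or NA
target_base_at <- function(cts, p) {
  k <- which(cts$mir_pos == p & cts$utr_pos >= 0L)
  if (!length(k)) return(NA_character_)
  substr(cts$site_sequence,
         cts$utr_pos[k[1]] - cts$utr_start + 1L,
         cts$utr_pos[k[1]] - cts$utr_start + 1L)
}

#' Pairing summaries over the seed, 3' and total miRNA regions
#'
#' Counts of G-C matches, A-U matches, G:U wobbles and mismatches per
#' region, plus bulges (maximal runs of gap columns on either strand) and
#' nucleotides in bulges.  Seed = miRNA positions 1-8, 3' = 9-end.
#'
#' @param cts a `cts` from [scan_utr()].
#' @return Named numeric vector of 18 counts.
#' @export
pairing_summaries <- function(cts) {
  m <- length(cts$pair_states)
  regions <- list(Seed = 1:8, `3p` = if (m >= 9L) 9:m else integer(),
                  Total = 1:m)
  # gap runs over the alignment path; each run is assigned to the miRNA
  # position at its boundary (for target insertions, the last aligned
  # miRNA position before the run, else the first after)
  runs <- gap_runs(cts)
  out <- numeric(0)
  for (rn in names(regions)) {
    r <- regions[[rn]]
    s <- cts$pair_states[r]
    inreg <- vapply(runs, function(g) g$pos %in% r, logical(1))
    out <- c(out, stats::setNames(c(
      sum(s == 1L), sum(s == 2L), sum(s == 3L), sum(s == 4L),
      sum(inreg), sum(vapply(runs[inreg], `[[`, numeric(1), "nt"))),
      paste0(rn, "_", c("GC", "AU", "GU", "mismatch", "bulge", "bulge_nt"))))
  }
  out
}

gap_runs <- function(cts) {
  mp <- cts$mir_pos; up <- cts$utr_pos
  if (!length(mp)) return(list())
  isgap <- mp == 0L | up < 0L
  runs <- list()
  k <- 1L
  while (k <= length(mp)) {
    if (isgap[k]) {
      j <- k
      while (j < length(mp) && isgap[j + 1L]) j <- j + 1L
      within <- mp[k:j]
      pos <- if (any(within > 0L)) min(within[within > 0L]) else {
        before <- mp[seq_len(k - 1L)]
        before <- before[before > 0L]
        # path runs 3'->5' on the miRNA, so earlier columns have larger p
        if (length(before)) min(before) else {
          after <- mp[j:length(mp)]; after <- after[after > 0L]
          if (length(after)) max(after) else 1L
        }
      }
      runs[[length(runs) + 1L]] <- list(pos = pos, nt = j - k + 1L)
      k <- j + 1L
    } else k <- k + 1L
  }
  runs
}

# UTR interval (0-based half-open) opposite miRNA positions `range`,
# clipped/backfilled at the site boundary when positions are unaligned
target_region <- function(cts, range) {
  j <- cts$utr_pos[cts$mir_pos %in% range & cts$utr_pos >= 0L]
  if (length(j)) return(c(min(j), max(j) + 1L))
  # seed entirely unaligned: take the site's 3'-most |range| bases
  w <- length(range)
  c(max(cts$utr_start, cts$utr_end - w), cts$utr_end)
}

#' Composition features of the site and its flanks
#'
#' Mononucleotide and overlapping-dimer frequencies of the site (`Target`)
#' and the 70-nt flanks (`Up` = 5' on the UTR, `Down` = 3'), plus the
#' distance-weighted flanking AU score: over the 30 nt on each side of the
#' target seed region, A/U bases count 1/d (d = distance from the seed
#' edge), normalized by the total available weight.
#'
#' @param cts a `cts`.
#' @param utr the matching [utr_record()].
#' @param flank_len flank length in nt (default 70).
#' @param au_window nt per side entering the flanking AU score.
#' @return Named numeric vector of 61 values.
#' @export
composition_features <- function(cts, utr, flank_len = 70L, au_window = 30L) {
  n <- nchar(utr$sequence)
  target <- cts$site_sequence
  up <- substr(utr$sequence, max(1L, cts$utr_start - flank_len + 1L),
               cts$utr_start)
  down <- substr(utr$sequence, cts$utr_end + 1L,
                 min(n, cts$utr_end + flank_len))
  out <- c(region_composition(target, "Target"),
           region_composition(up, "Up"),
           region_composition(down, "Down"))
  c(out, Flanking_AU_score = flanking_au_score(cts, utr, au_window))
}

region_composition <- function(seq, prefix) {
  L <- nchar(seq)
  mono <- stats::setNames(numeric(4), NUC)
  di <- stats::setNames(numeric(16), DIMERS)
  if (L >= 1L) {
    b <- strsplit(seq, "")[[1]]
    tb <- table(factor(b, levels = NUC))
    mono[] <- as.numeric(tb) / L
    if (L >= 2L) {
      d <- paste0(b[-L], b[-1L])
      td <- table(factor(d, levels = DIMERS))
      di[] <- as.numeric(td) / (L - 1L)
    }
  }
  stats::setNames(c(mono, di), paste0(prefix, "_", c(NUC, DIMERS), "_comp"))
}

flanking_au_score <- function(cts, utr, au_window = 30L) {
  n <- nchar(utr$sequence)
  seed <- target_region(cts, 1:8)
  b <- strsplit(utr$sequence, "")[[1]]
  num <- 0; den <- 0
  for (d in seq_len(au_window)) {
    w <- 1 / d
    left <- seed[1] - d + 1L       # 1-based position d nt 5' of the seed
    right <- seed[2] + d           # 1-based position d nt 3' of the seed
    if (left >= 1L) { den <- den + w
      if (b[left] %in% c("A", "U")) num <- num + w }
    if (right <= n) { den <- den + w
      if (b[right] %in% c("A", "U")) num <- num + w }
  }
  if (den == 0) 0 else num / den
}

#' Accessibility features of a CTS
#'
#' Region and single-position unpaired probabilities of the target seed
#' region (the UTR bases opposite miRNA positions 1-8), its 5' and 3'
#' halves, each seed position, and the 10-nt flanks immediately 5' (`Up`)
#' and 3' (`Down`) of the seed region, windowed per
#' [accessibility_params()].  Regions clipped at the UTR ends use the
#' available bases.
#'
#' @param cts a `cts`.
#' @param utr the matching [utr_record()].
#' @param params an [accessibility_params()].
#' @param backend an [energy_backend()].
#' @return Named numeric vector of 33 probabilities.
#' @export
accessibility_features <- function(cts, utr,
                                   params = accessibility_params(),
                                   backend = energy_backend()) {
  n <- nchar(utr$sequence)
  seed <- target_region(cts, 1:8)
  w <- seed[2] - seed[1]
  half <- w %/% 2L
  # seed positions p1..p8 map 3'->5' along the UTR within the seed region
  pos_of <- function(p) {
    j <- cts$utr_pos[cts$mir_pos == p & cts$utr_pos >= 0L]
    if (length(j)) j[1] else max(seed[1], seed[2] - p)  # backfill
  }
  iv <- list(Seed_acc = seed,
             Seed_5p_acc = c(seed[1], seed[1] + half),
             Seed_3p_acc = c(seed[2] - (w - half), seed[2]))
  for (p in 1:8) iv[[sprintf("Seed_P%02d_acc", p)]] <- {
    j <- pos_of(p); c(j, j + 1L) }
  up <- c(max(0L, seed[1] - 10L), seed[1])
  down <- c(seed[2], min(n, seed[2] + 10L))
  iv$Up_seed_flank_acc <- up
  iv$Down_seed_flank_acc <- down
  for (p in 1:10) {
    ju <- seed[1] - p            # p nt 5' of the seed region (0-based)
    jd <- seed[2] + p - 1L       # p nt 3' of the seed region
    iv[[sprintf("Up_seed_P%02d_acc", p)]] <- c(max(0L, ju),
                                               max(1L, ju + 1L))
    iv[[sprintf("Down_seed_P%02d_acc", p)]] <- c(min(n - 1L, jd),
                                                 min(n, jd + 1L))
  }
  iv <- lapply(iv, function(v) {
    v <- c(max(0L, v[1]), min(n, v[2]))
    if (v[2] <= v[1]) v <- c(max(0L, v[2] - 1L), min(n, v[1] + 1L))
    if (v[2] - v[1] > params$ulength) {
      # bulged target regions can exceed the computable unpaired length;
      # keep the central ulength bases
      mid <- (v[1] + v[2]) %/% 2L
      v <- c(mid - params$ulength %/% 2L, 0L)
      v[2] <- v[1] + params$ulength
    }
    v
  })
  p <- accessibility(utr, iv, params, backend)
  stats::setNames(p, names(iv))
}

#' Conservation features of a CTS
#'
#' Arithmetic means of the per-base conservation scores over the target
#' seed region, the whole site, and the pooled 70-nt flanks.  All three
#' are 0 when the UTR carries no conservation track.
#'
#' @param cts a `cts`.
#' @param utr the matching [utr_record()].
#' @param flank_len flank length (default 70 nt).
#' @return Named numeric vector: `Seed_cons_score`, `Target_cons_score`,
#'   `Flank_cons_score`.
#' @export
conservation_features <- function(cts, utr, flank_len = 70L) {
  cons <- utr$conservation
  if (is.null(cons))
    return(c(Seed_cons_score = 0, Target_cons_score = 0,
             Flank_cons_score = 0))
  n <- length(cons)
  seed <- target_region(cts, 1:8)
  mean0 <- function(idx) if (length(idx)) mean(cons[idx]) else 0
  up <- seq.int(max(1L, cts$utr_start - flank_len + 1L),
                length.out = min(flank_len, cts$utr_start))
  dn <- if (cts$utr_end < n)
    seq.int(cts$utr_end + 1L, min(n, cts$utr_end + flank_len)) else integer()
  c(Seed_cons_score = mean0(seq.int(seed[1] + 1L, seed[2])),
    Target_cons_score = mean0(seq.int(cts$utr_start + 1L, cts$utr_end)),
    Flank_cons_score = mean0(c(up, dn)))
}

#' Scaled distance of a site to the closest UTR end
#'
#' @param cts a `cts`.
#' @param utr the matching [utr_record()].
#' @return `min(utr_start, utr_len - utr_end) / utr_len`, in `[0, 0.5]`.
#' @export
dist_to_end <- function(cts, utr) {
  n <- nchar(utr$sequence)
  c(Dist_to_end = min(cts$utr_start, n - cts$utr_end) / n)
}

#' Extract the full 151-feature site-level vector for a CTS
#'
#' @param cts a `cts` from [scan_utr()].
#' @param utr the matching [utr_record()].
#' @param backend an [energy_backend()].
#' @param params an [accessibility_params()].
#' @return Named numeric vector of length 151 in canonical order.
#' @export
extract_site_features <- function(cts, utr, backend = energy_backend(),
                                  params = accessibility_params()) {
  mir <- cts$mirna_sequence
  site <- cts$site_sequence
  loc <- local_fold_mfe(utr, c(cts$utr_start, cts$utr_end), FALSE,
                        params, backend)
  loc_c <- local_fold_mfe(utr, c(cts$utr_start, cts$utr_end), TRUE,
                          params, backend)
  energy <- c(Duplex_MFE = backend$duplex_mfe(mir, site),
              Seed_MFE = backend$duplex_mfe(substr(mir, 1L, 8L), site),
              `3p_MFE` = if (nchar(mir) > 8L)
                backend$duplex_mfe(substr(mir, 9L, nchar(mir)), site) else 0,
              Local_target_MFE = loc,
              Local_cons_target_MFE = loc_c,
              Local_open_energy = loc_c - loc)
  out <- c(energy,
           seed_match_flags(cts),
           encode_pairing(cts, 20L),
           pairing_summaries(cts),
           accessibility_features(cts, utr, params, backend),
           composition_features(cts, utr),
           conservation_features(cts, utr),
           dist_to_end(cts, utr))
  out <- out[site_feature_names()]
  stopifnot(length(out) == 151L, !anyNA(out))
  out
}

#' Site feature matrix for a list of CTSs
#'
#' @param sites list of `cts` objects.
#' @param utrs named list of [utr_record()]s (by `gene_id`).
#' @param backend an [energy_backend()].
#' @param params an [accessibility_params()].
#' @return data.frame: identifier columns (`mirna_id`, `gene_id`,
#'   `utr_start`, `utr_end`, `score`) then the 151 canonical features.
#' @export
site_feature_matrix <- function(sites, utrs, backend = energy_backend(),
                                params = accessibility_params()) {
  rows <- lapply(sites, function(s) {
    utr <- utrs[[s$gene_id]]
    if (is.null(utr)) stop("no UTR record for gene '", s$gene_id, "'")
    extract_site_features(s, utr, backend, params)
  })
  feat <- as.data.frame(do.call(rbind, rows))
  cbind(cts_table(sites)[, c("mirna_id", "gene_id", "utr_start",
                             "utr_end", "score")],
        feat)
}
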