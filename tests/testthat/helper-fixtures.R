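# Shared fixtures, built in code and cached for the session.

.fixture_env <- new.env()

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

revcomp_rna <- function(s)
  paste(rev(strsplit(chartr("ACGU", "UGCA", s), "")[[1]]), collapse = "")

random_rna_str <- function(n, alphabet = c("A", "C", "G", "U"))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# A miRNA with its exact reverse complement planted in random flanks.
planted_pair <- function(mirna_seq, flank = 80L, gene = "g1") {
  rc <- revcomp_rna(mirna_seq)
  utr_seq <- paste0(random_rna_str(flank), rc, random_rna_str(flank))
  list(mirna = mature_mirna("m1", mirna_seq),
       utr = utr_record(gene, utr_seq),
       start = flank, end = flank + nchar(rc))
}

# Forge a gapless cts: miRNA position p pairs UTR base start + (m - p),
# exactly as the scanner lays out a contiguous duplex.
forge_cts <- function(mirna_seq, utr, start) {
  m <- nchar(mirna_seq)
  mir_pos <- m:1
  utr_pos <- start + seq_len(m) - 1L
  mb <- strsplit(mirna_seq, "")[[1]]
  ub <- strsplit(utr$sequence, "")[[1]]
  states <- vapply(1:m, function(p)
    mirtarget:::pair_state(mb[p], ub[start + (m - p) + 1L]), integer(1))
  structure(list(
    mirna_id = "forged", gene_id = utr$gene_id,
    utr_start = start, utr_end = start + m, score = 200,
    pair_states = states, mir_pos = mir_pos, utr_pos = utr_pos,
    target_gap_positions = integer(),
    site_sequence = substr(utr$sequence, start + 1L, start + m),
    mirna_sequence = mirna_seq, min_score = 140), class = "cts")
}

# Small end-to-end dataset reused by several files.
tiny_pipeline <- function() {
  fixture("tiny_pipeline", function() {
    sim <- simulate_dataset(sim_config(n_mirnas = 8L, n_utrs = 8L,
                                       utr_length_range = c(150L, 250L),
                                       rng_seed = 11L))
    list(sim = sim, ds = build_datasets(sim, rng_seed = 11L))
  })
}
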