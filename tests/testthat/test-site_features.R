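test_that("canonical feature names are 151, unique and stable", {
  nm <- site_feature_names()
  expect_length(nm, 151)
  expect_false(any(duplicated(nm)))
  expect_identical(nm, site_feature_names())
})

# helper: forge a cts for a given seed pairing layout
seed_variant_cts <- function(edit = identity) {
  set.seed(77)
  mir_seq <- "UGAGGUAGUAGGUUGUAUAGUU"
  site <- strsplit(revcomp_rna(mir_seq), "")[[1]]
  site <- edit(site)
  utr <- utr_record("g", paste0(strrep("A", 40),
                                paste(site, collapse = ""),
                                strrep("A", 40)))
  forge_cts(mir_seq, utr, 40L)
}

opp <- function(p) 22 - p + 1   # site index opposite miRNA position p

test_that("seed-match flags follow their independent definitions", {
  # perfect WC over p1-p8: all pure-WC flags on, GU variants off
  f <- seed_match_flags(seed_variant_cts())
  expect_equal(unname(f[c("Seed_match_8mer", "Seed_match_7mer1",
                          "Seed_match_7mer2", "Seed_match_6mer1",
                          "Seed_match_6mer2")]), rep(1L, 5))
  expect_equal(unname(f[c("Seed_match_6mer1GU", "Seed_match_6mer2GU")]),
               c(0L, 0L))
  # p1 opposite A (and p1 = U so A:U is WC): A1 variants fire
  expect_equal(unname(f[c("Seed_match_8merA1", "Seed_match_7merA1")]),
               c(1L, 1L))

  # WC p2-p8, adenine opposite p1 breaking the p1 pair
  # (miRNA p1 is U here, so force a non-pairing target base: p1 state
  # must not be WC -> use A only if it mismatches; U:A pairs, so instead
  # check a miRNA starting with G)
  mir2 <- "GGAGGUAGUAGGUUGUAUAGUU"
  site <- strsplit(revcomp_rna(mir2), "")[[1]]
  site[opp(1)] <- "A"   # G opposite A: mismatch, but target base is A
  utr <- utr_record("g", paste0(strrep("A", 40),
                                paste(site, collapse = ""), strrep("A", 40)))
  f2 <- seed_match_flags(forge_cts(mir2, utr, 40L))
  expect_equal(unname(f2[c("Seed_match_8merA1", "Seed_match_7mer2",
                           "Seed_match_7merA1", "Seed_match_6mer2")]),
               rep(1L, 4))
  expect_equal(unname(f2[c("Seed_match_8mer", "Seed_match_7mer1",
                           "Seed_match_6mer1")]), rep(0L, 3))
})

test_that("GU seed variants require exactly one wobble", {
  # replace the pair at p4 (miRNA G) by a G:U wobble
  cts <- seed_variant_cts(function(site) {
    site[opp(4)] <- "U"  # miRNA p4 = G -> G:U
    site
  })
  expect_equal(cts$pair_states[4], 3L)
  f <- seed_match_flags(cts)
  expect_equal(unname(f["Seed_match_6mer2GU"]), 1L)
  expect_equal(unname(f["Seed_match_6mer1GU"]), 1L)
  # every pure-WC flag whose window spans p4 is off
  expect_equal(unname(f[c("Seed_match_8mer", "Seed_match_7mer1",
                          "Seed_match_7mer2", "Seed_match_6mer1",
                          "Seed_match_6mer2")]), rep(0L, 5))
  # two wobbles are no longer "exactly one"
  cts2 <- seed_variant_cts(function(site) {
    site[opp(4)] <- "U"; site[opp(6)] <- "G"  # G:U at p4, U:G at p6
    site
  })
  f2 <- seed_match_flags(cts2)
  expect_equal(unname(f2[c("Seed_match_6mer1GU", "Seed_match_6mer2GU")]),
               c(0L, 0L))
})

test_that("pairing summaries count states and partition Seed + 3p = Total", {
  cts <- seed_variant_cts()
  s <- pairing_summaries(cts)
  expect_equal(unname(s["Seed_GC"] + s["Seed_AU"]), 8)
  expect_equal(unname(s["Total_mismatch"]), 0)
  expect_equal(unname(s["Seed_bulge"]), 0)
  for (st in c("GC", "AU", "GU", "mismatch", "bulge", "bulge_nt"))
    expect_equal(unname(s[paste0("Seed_", st)] + s[paste0("3p_", st)]),
                 unname(s[paste0("Total_", st)]))
})

test_that("a 2-nt target bulge inside the seed is one bulge of two nt", {
  base <- seed_variant_cts()
  # splice a 2-nt insertion into the alignment between p4 and p5
  k <- which(base$mir_pos == 5)
  cts <- base
  cts$mir_pos <- append(base$mir_pos, c(0L, 0L), after = k)
  cts$utr_pos <- append(base$utr_pos, c(base$utr_pos[k] + 1L,
                                        base$utr_pos[k] + 2L), after = k)
  s <- pairing_summaries(cts)
  expect_equal(unname(s["Seed_bulge"]), 1)
  expect_equal(unname(s["Seed_bulge_nt"]), 2)
})

test_that("composition features normalize and bound correctly", {
  # site of all A: Target_A_comp = 1, Target_AA_comp = 1, rest 0
  mir <- strrep("U", 22)
  utr <- utr_record("g", paste0(strrep("G", 40), strrep("A", 22),
                                strrep("G", 40)))
  cts <- forge_cts(mir, utr, 40L)
  comp <- composition_features(cts, utr)
  expect_equal(unname(comp["Target_A_comp"]), 1)
  expect_equal(unname(comp["Target_AA_comp"]), 1)
  expect_equal(sum(comp[paste0("Target_", c("A", "C", "G", "U"),
                               "_comp")]), 1)
  # all-G/C surroundings of the seed give an AU score of 0 (the score is
  # seed-region-relative, so the site's own 5' bases count as well)
  utr_gc <- utr_record("g", paste0(strrep("C", 40), strrep("G", 22),
                                   strrep("C", 40)))
  comp_gc <- composition_features(forge_cts(strrep("C", 22), utr_gc, 40L),
                                  utr_gc)
  expect_equal(unname(comp_gc["Flanking_AU_score"]), 0)
  utr_au <- utr_record("g", paste0(strrep("U", 40), strrep("A", 22),
                                   strrep("U", 40)))
  comp_au <- composition_features(forge_cts(mir, utr_au, 40L), utr_au)
  expect_equal(unname(comp_au["Flanking_AU_score"]), 1)
  # mono and dimer sums are 1 on random regions
  set.seed(88)
  for (r in 1:5) {
    u <- utr_record("g", random_rna_str(250))
    cts_r <- forge_cts(random_rna_str(22), u, 100L)
    cc <- composition_features(cts_r, u)
    for (reg in c("Target", "Up", "Down")) {
      expect_equal(sum(cc[paste0(reg, "_", c("A", "C", "G", "U"),
                                 "_comp")]), 1)
      expect_equal(sum(cc[grep(paste0("^", reg, "_[ACGU]{2}_comp$"),
                               names(cc))]), 1)
    }
  }
})

test_that("conservation features average the stated intervals", {
  mir <- random_rna_str(22)
  utr <- utr_record("g", random_rna_str(160), conservation = rep(0.8, 160))
  cts <- forge_cts(mir, utr, 60L)
  cons <- conservation_features(cts, utr)
  expect_equal(unname(cons), rep(0.8, 3))
  # no track -> zeros
  utr0 <- utr_record("g", utr$sequence)
  expect_equal(unname(conservation_features(cts, utr0)), rep(0, 3))
  # hand-built track: seed region = site positions opposite p1..p8
  track <- rep(0, 160)
  track[61:82] <- 0.5                       # whole site [60, 82)
  track[(60 + 22 - 8 + 1):82] <- 1          # seed-opposite bases
  utr2 <- utr_record("g", utr$sequence, conservation = track)
  cons2 <- conservation_features(cts, utr2)
  expect_equal(unname(cons2["Seed_cons_score"]), 1)
  expect_equal(unname(cons2["Target_cons_score"]), (14 * 0.5 + 8 * 1) / 22)
  expect_equal(unname(cons2["Flank_cons_score"]), 0)
})

test_that("distance to UTR end is scaled into [0, 0.5]", {
  utr <- utr_record("g", random_rna_str(100))
  cts <- forge_cts(random_rna_str(22), utr, 10L)
  expect_equal(unname(dist_to_end(cts, utr)), 10 / 100)
  cts0 <- forge_cts(random_rna_str(22), utr, 0L)
  expect_equal(unname(dist_to_end(cts0, utr)), 0)
  cts_end <- forge_cts(random_rna_str(22), utr, 78L)
  expect_equal(unname(dist_to_end(cts_end, utr)), 0)
})

test_that("the assembled vector is complete, deterministic and in range", {
  px <- planted_pair(random_rna_str(22))
  px$utr$conservation <- runif(nchar(px$utr$sequence))
  cts <- scan_utr(px$mirna, px$utr)[[1]]
  f1 <- extract_site_features(cts, px$utr)
  f2 <- extract_site_features(cts, px$utr)
  expect_identical(f1, f2)
  expect_identical(names(f1), site_feature_names())
  flags <- f1[grep("^Seed_match_", names(f1))]
  expect_true(all(flags %in% c(0, 1)))
  acc <- f1[grep("_acc$", names(f1))]
  expect_true(all(acc >= 0 & acc <= 1 + 1e-12))
  expect_true(f1[["Dist_to_end"]] >= 0 && f1[["Dist_to_end"]] <= 0.5)
  expect_gte(f1[["Local_open_energy"]], 0)
  expect_lte(f1[["Duplex_MFE"]], 0)
})
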