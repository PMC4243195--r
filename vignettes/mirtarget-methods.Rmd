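---
title: "mirtarget: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirtarget: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its methods: what is
computed, under which assumptions, which knobs matter, and where a design
was genuinely open and had to be decided. Nothing here states an
empirical result that the test-suite or `scripts/acceptance.R` does not
itself compute.

## The two-level model

miRNA targeting is predicted at two granularities. At the **site level**,
candidate target sites (CTSs) on a 3′ UTR are proposed by sequence
complementarity and each is scored by a classifier on a 151-dimensional
descriptor. At the **UTR level**, the set of CTSs of one miRNA–gene pair
is reduced to a 624-dimensional summary vector and a second classifier
scores the pair as a whole. The site posterior feeds the UTR summaries,
but the UTR classifier also works without a trained site model (the
posterior column then falls back to the normalized alignment score,
which keeps the two levels decoupled for feature extraction).

Only 3′ UTR sites are modeled. Coordinates are uniformly 0-based,
half-open `[start, end)` on the UTR, 5′→3′, so a site's length is always
`end − start`; miRNA positions are numbered from the 5′ end (p1), and the
seed region is p1–p8 (forced by the `Seed_P01..P08_acc` feature naming).

## CTS discovery

The scanner is a Smith–Waterman local alignment of the *reversed* miRNA
(3′→5′) against the UTR (5′→3′) under a complementarity scoring scheme:

| parameter | default | unit / meaning |
|---|---|---|
| `score_wc` | +5 | Watson–Crick pair |
| `score_gu` | +1 | G:U wobble |
| `score_mismatch` | −3 | mismatch |
| `gap_open`, `gap_extend` | −9, −4 | affine gaps (either strand) |
| `seed_scale` | ×4 | weight on pair scores at p2–p8 |
| `min_score` | 140 (scan), 155 (negatives) | acceptance threshold |

The seed weighting makes seed pairing favored but not required, so
weak-seed (3′ compensatory, centered) sites can still clear the
threshold on the strength of their 3′ pairing. Wobbles inside the seed
window are *not* weighted by default (`seed_scale_gu = FALSE`); both the
weight and the flag are exposed.

**Why ×4 and not ×2.** The seed weight is the one parameter on which the
thresholds hinge. Under a ×2 weight, a perfect 22-nt duplex tops out at
5·22 + 5·7 = 145, i.e. *below* the stringent 155 threshold used to admit
negative sites — the negative-generation protocol would be vacuous. The
released complementarity aligner's default scale is 4.0, under which a
perfect 22-mer scores 215 and 155 corresponds to a strong-but-imperfect
alignment. We therefore default to ×4.

Multiple sites per UTR are extracted greedily: the best local maximum is
reported, its UTR columns are masked, and the DP re-runs until the score
drops below `min_score` — sites never overlap, and raising the threshold
can only remove sites. Ties and traceback are deterministic.

Each alignment is encoded as per-miRNA-position pairing states (1 G-C,
2 A-U, 3 G:U, 4 mismatch, 5 gap); positions outside the local alignment
or beyond the miRNA length are coded 5. Bulges are maximal runs of gap
columns on either strand; a run is attributed to the miRNA region
(seed p1–8, 3′ p9–end) at its boundary.

## Thermodynamics

The default backend (`nn-simple`) is a compact nearest-neighbor model
chosen so that every quantity the features need — duplex MFE, local MFE
with and without unpaired constraints, and windowed unpaired
probabilities — comes from one internally consistent parameter set:

* stacking energies for the six pair types, built additively
  (`s0 + f(outer) + f(inner)`, f per pair class: GC −1.3, AU −0.55,
  GU −0.25, s0 −0.6 kcal/mol), which makes the table exactly symmetric
  under strand reversal (so `duplex_mfe(a, b) == duplex_mfe(b, a)` holds
  structurally, not approximately);
* hairpins `5.0 + 0.3·(L − 3)` (minimum loop 3), interior/bulge loops
  `3.0 + 0.4·u` capped at `max_loop = 20` unpaired nucleotides, linear
  multiloops `3.4 + 0.4·branches + 0.1·unpaired`;
* kT = 0.616 kcal/mol (37 °C) for partition functions.

This is deliberately *not* a full Turner parameterization (a non-goal):
feature learning needs energies that rank duplexes and structures
sensibly and reproducibly, not chemical accuracy, and the compact model
can be verified exhaustively — the suite checks the duplex DP, the
Zuker-style fold and the McCaskill partition function against brute-force
enumeration of all structures on small inputs with the same parameter
table. An `external` backend delegating to the ViennaRNA programs is
provided for users who want Turner energies; a hashed `mock` backend
keeps pipeline tests fast.

Accessibility follows the windowed-partition-function convention:
windows of `winsize = 80` nt, pairs limited to `span = 40` nt, queried
unpaired regions up to `ulength = 10` nt, probabilities averaged over
the windows that contain the region. Windows are sampled every
`stride = 10` nt (always including the terminal windows) rather than at
every offset; the average over this sample converges to the full average
quickly and cuts the partition-function count an order of magnitude. A
region's probability is computed exactly as `Q(region forced open)/Q`,
which also yields the event-inclusion invariant (region ≤ pointwise
minimum) by construction. Local folding uses a 100-nt window centered on
the CTS midpoint (the center-vs-5′-end choice was open; centered keeps
the site's context symmetric), truncated — not padded — at UTR ends.
Opening energy is defined as `constrained − unconstrained ≥ 0`, the
ΔΔG-open sign convention of accessibility-energy methods; the raw
difference of the two local MFEs would merely flip the sign.

## Site and UTR features

The 151 site features are, in canonical order: 6 energies, 9 seed-match
flags, 20 positional pairing states, 18 pairing summaries, 33
accessibilities, 61 composition values, 3 conservation means, and the
scaled distance to the nearest UTR end. Decisions embedded there:

* Seed-match flags are *independent* predicates, not a hierarchy; the
  single-wobble 6mer variants require exactly one G:U with all remaining
  positions Watson–Crick; the A1 variants test for an adenine opposite
  p1 regardless of its pairing state.
* Dimer compositions use overlapping dimers normalized by `len − 1`;
  mono compositions by `len`. Flanks are 70 nt, clipped at UTR ends;
  upstream means 5′ on the UTR.
* The flanking AU score weights A/U bases within 30 nt of each seed-region
  edge by 1/distance and normalizes by the total available weight, so it
  is 1 in an all-AU neighborhood and 0 in an all-GC one.
* Conservation features average per-base scores (track gaps are read as
  0 — absence of evidence — so means are always defined); without any
  track all three features are 0.
* Accessibility flanks are taken relative to the *target seed region*
  (the UTR bases opposite p1–p8), the natural reading of "upstream of
  the seed region"; bulged seed regions wider than `ulength` are trimmed
  to their central 10 nt before querying.

UTR-level vectors apply {sum, min, max, mean} to the 151 site features
plus site posterior, alignment score and site start/end (155 × 4 = 620),
then append UTR length, site count, raw site density
(`number_sites / UTR_length`; per-kilobase scaling was considered and
rejected as a needless unit change) and `max_100_sites`, the largest
number of site *start positions* within any closed 100-nt window.
Zero-site pairs are kept with zero-filled summaries — dropping them
would make negative pairs unscorable.

## Negative data

Mock miRNAs are Fisher–Yates permutations of real miRNAs, accepted only
if *neither* seed 7mer (offsets 1–7 and 2–8 of positions 1–8) occurs in
the seed 7mer index of the supplied real miRNAs — the stricter
two-offset reading; it can only make decoys cleaner. Generation is
deterministic given its seed, errors out after `max_attempts = 10000`
(low-complexity sequences), and preserves the nucleotide multiset
exactly. Each positive miRNA–gene pair begets one mock pair (1:1,
keeping classes balanced); negative CTSs are whatever the scanner finds
for the mock at threshold 155.

## Feature selection

Mutual information is the plug-in (maximum-likelihood) estimator in
nats on discretized columns; continuous features are binned by
Freedman–Diaconis (`h = 2·IQR·n^{−1/3}`, edges spanning [min, max], a
single bin when the IQR vanishes), while integer-coded columns (flags,
state codes) pass through unbinned. Linfoot's `r = sqrt(1 − e^{−2I})`
normalizes MI onto [0, 1] and is the relevance reported everywhere.

CFS maximizes the merit `k·r̄_cf / sqrt(k + k(k−1)·r̄_ff)` by forward
best-first search over subsets, expanding the best open node and
stopping after 5 consecutive expansions that fail to improve the best
merit (the patience convention of the data-mining suite that popularized
CFS; exposed as a parameter). Ties break lexicographically on feature
name, making the search deterministic and column-order invariant. One
consequence of the Linfoot normalization worth knowing: an exact binary
duplicate has feature–feature correlation ≈ 0.866, not 1, so the merit
does not strictly forbid selecting both copies of a duplicated feature —
the exhaustive-search oracle in the test-suite behaves identically.

mRMR uses the difference (MID) form — relevance minus mean MI to the
already-selected — and returns a full ranking; the quotient form is a
one-line change but the difference form is the common default. Per-fold
selection is available in cross-validation so that held-out rows never
influence the chosen subset.

## Classifiers and evaluation

Six kinds are wrapped behind one `train`/`predict` surface: logistic
regression, Fisher LDA, naive Bayes, linear and Gaussian SVMs (Platt
sigmoid posteriors), and a random forest of 100 trees whose posterior is
the vote fraction. Zero-variance columns are dropped at training.
SVM hyperparameters default to cost 1 / gamma 1/p; `tune_svm` runs the
{0.1, 1, 10} × {0.01, 0.1, 1} grid on cross-validated AUC when tuning is
wanted (tuning inside every training call would dominate runtime for no
benefit on the package's workloads).

Metrics: rank-based AUC (equivalent to the trapezoidal ROC with midrank
ties), accuracy, positive-class F1 (the macro-vs-positive convention was
open; positive-class is implemented), and MCC with the 0-on-degenerate
convention. Cross-validation is stratified with pooled posteriors.

The site-level benchmark protocol treats a prediction as a true site at
overlap threshold *t* if it covers ≥ *t*·length of an expected site of
the same pair, each expected site claimable by at most one prediction
(greedy by descending score; the matching cardinality was unstated and
one-to-one is the conservative choice). ROC curves are swept over
posterior cutoffs with TPR relative to the number of expected sites (so
curves may saturate below 1), and partial AUC integrates FPR 0–0.4 by
trapezoid. The overlap histogram splits each expected site into 10
equal bins plus 5 flanking bins per side at the same width and
increments a bin for every covered coordinate.

## What the generator emulates — and what it does not

`simulate_dataset` produces miRNAs (uniform 22-mers), UTRs (i.i.d.
uniform with configurable GC bias), planted reverse-complement sites of
a requested seed-match type with point mutations outside the seed
(default rate 0.05), beta-distributed conservation elevated at planted
sites (mean 0.9 vs 0.2 background), and a mock miRNA per pair. Because
short uniform UTRs essentially never yield chance alignments at score
155 — on real, kilobase-scale, low-complexity UTRs such chance hits are
common — the generator also plants one *decoy region* per pair: the
reverse complement of the pair's mock with a mismatch opposite mock seed
position 3, which clears the stringent threshold while extinguishing all
nine seed-match flags. The standard study used by the end-to-end checks
and `scripts/acceptance.R` is 50 miRNAs × 50 UTRs of 300–800 nt with one
planted 8mer site and one decoy per pair (~100 site-level and 100
UTR-level examples), sizes at which the full pipeline runs in about a
minute on one core.

Passing end-to-end checks on this fixture demonstrates that the plumbing
is correct — sites are recovered where they were planted, decoys carry
the intended negative signature, features separate the classes, and the
classifiers learn them. It does *not* demonstrate real-data accuracy:
planted sites are cleaner than biological ones, uniform background lacks
repeat structure and compositional bias, the conservation signal is
idealized, and mock decoys are easier negatives than unvalidated real
pairs. Numbers on real collections must be established on real
collections.

## Numerical choices and degenerate inputs

* Alignment DP in C++ (Rcpp); `-Inf` gap penalties are clamped to a
  finite sentinel, giving exact gapless behavior.
* Partition functions are computed in plain double precision; with the
  span cap at 40 nt the largest Boltzmann sums stay far below overflow.
* Empty composition regions yield 0 for all their fractions; zero-length
  queried accessibility intervals are widened to one base; UTRs shorter
  than the miRNA scan to an empty site list (not an error), while empty
  sequences error.
* All stochastic steps (shuffles, folds, forests, simulations) consume
  seeds explicitly and restore the caller's RNG state.

## Known limitations

* The nn-simple energies are ordinal, not chemically calibrated; duplex
  initiation and dangling ends are omitted.
* The scanner reports non-overlapping sites greedily; two genuinely
  overlapping binding modes collapse to the higher-scoring one.
* CFS's best-first search is exact on small instances (verified
  exhaustively up to 12 features) but heuristic in principle on 151.
* The CLI's `features-site` recomputes alignments from the scan table
  rather than deserializing alignments, so it requires the same scan
  parameters to be reproducible.
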