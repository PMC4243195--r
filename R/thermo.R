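# RNA thermodynamics behind a pluggable backend contract.  A backend is a
# list with fields `name`, `duplex_mfe(a, b)`, `fold_mfe(seq, constraint)`
# and `unpaired_prob(seq, intervals, params)`.  The default "nn-simple"
# backend runs a compact nearest-neighbor model (Watson-Crick and G:U
# stacks, linear loop penalties) implemented in C++; "external" shells out
# to the ViennaRNA command-line suite when present; "mock" returns
# deterministic pseudo-energies for fast pipeline tests.

#' Parameters of the compact nearest-neighbor energy model
#'
#' Stacking energies are additive over the two stacked pairs
#' (`stack(p, q) = s0 + f(p) + f(q)`, f depending on pair class), which
#' keeps the table exactly symmetric under strand reversal.  Loop terms are
#' linear; multiloops use the standard linear (a, b, c) model.  All
#' energies in kcal/mol at 37 degrees C (kT = 0.616).
#'
#' @param stack_s0,stack_gc,stack_au,stack_gu stacking table generators.
#' @param hairpin_init,hairpin_slope hairpin loop penalty (min loop 3).
#' @param interior_init,interior_slope interior/bulge loop penalty per
#'   unpaired nucleotide, loops capped at `max_loop` unpaired.
#' @param ml_init,ml_branch,ml_unpaired linear multiloop coefficients.
#' @param kT thermal energy, kcal/mol.
#' @param max_loop maximum unpaired nucleotides in an interior/bulge loop.
#' @param min_hairpin minimum hairpin loop size.
#' @return Parameter list consumed by the `nn-simple` backend and by the
#'   enumeration oracles in the test-suite.
#' @export
nn_params <- function(stack_s0 = -0.6, stack_gc = -1.3, stack_au = -0.55,
                      stack_gu = -0.25, hairpin_init = 5.0,
                      hairpin_slope = 0.3, interior_init = 3.0,
                      interior_slope = 0.4, ml_init = 3.4, ml_branch = 0.4,
                      ml_unpaired = 0.1, kT = 0.616, max_loop = 20L,
                      min_hairpin = 3L) {
  types <- c("CG", "GC", "AU", "UA", "GU", "UG")
  f <- c(CG = stack_gc, GC = stack_gc, AU = stack_au, UA = stack_au,
         GU = stack_gu, UG = stack_gu)
  stack <- outer(f[types], f[types], `+`) + stack_s0
  dimnames(stack) <- list(types, types)
  list(stack = stack, hairpin_init = hairpin_init,
       hairpin_slope = hairpin_slope, interior_init = interior_init,
       interior_slope = interior_slope, ml_init = ml_init,
       ml_branch = ml_branch, ml_unpaired = ml_unpaired, kT = kT,
       max_loop = as.integer(max_loop), min_hairpin = as.integer(min_hairpin))
}

#' Accessibility / local-folding window parameters
#'
#' @param winsize sliding window length for the windowed partition
#'   function (nt).
#' @param span maximum base-pair span within a window (nt).
#' @param ulength maximum queried unpaired-region length (nt).
#' @param local_window window length for local MFE folding around a CTS
#'   (nt).
#' @param stride step between successive sampled windows; probabilities
#'   are averaged over all sampled windows containing the queried region.
#' @return List of class `accessibility_params`.
#' @export
accessibility_params <- function(winsize = 80L, span = 40L, ulength = 10L,
                                 local_window = 100L, stride = 10L) {
  stopifnot(span <= winsize, ulength <= span, local_window > 0, stride >= 1)
  structure(list(winsize = as.integer(winsize), span = as.integer(span),
                 ulength = as.integer(ulength),
                 local_window = as.integer(local_window),
                 stride = as.integer(stride)),
            class = "accessibility_params")
}

#' Energy backends
#'
#' @param name one of `"nn-simple"`, `"external"`, `"mock"`.
#' @param params an [nn_params()] list (nn-simple only).
#' @return A backend list satisfying the energy-backend contract.
#' @export
energy_backend <- function(name = c("nn-simple", "external", "mock"),
                           params = nn_params()) {
  name <- match.arg(name)
  switch(name,
         "nn-simple" = nn_simple_backend(params),
         "external" = external_backend(),
         "mock" = mock_backend())
}

check_rna <- function(s) {
  if (!nzchar(s) || grepl("[^ACGU]", s))
    stop("sequence must be non-empty RNA over {A,C,G,U}: ", s)
  s
}

nn_simple_backend <- function(params = nn_params()) {
  list(
    name = "nn-simple",
    params = params,
    duplex_mfe = function(a, b) {
      cpp_duplex_mfe(check_rna(a), check_rna(b), params)
    },
    fold_mfe = function(seq, constraint = NULL) {
      check_rna(seq)
      mask <- rep(FALSE, nchar(seq))
      if (!is.null(constraint)) mask[constraint] <- TRUE
      cpp_fold_mfe(seq, mask, params)
    },
    # probability that each queried interval (list of integer vectors of
    # 1-based positions) is entirely unpaired, in one window
    pf_unpaired = function(seq, intervals, span) {
      check_rna(seq)
      n <- nchar(seq)
      q0 <- cpp_pf(seq, rep(FALSE, n), span, params)
      vapply(intervals, function(iv) {
        mask <- rep(FALSE, n); mask[iv] <- TRUE
        cpp_pf(seq, mask, span, params) / q0
      }, numeric(1))
    })
}

# Deterministic pseudo-energies keyed by a sequence hash; fast stand-in
# for pipeline tests that do not depend on energy values.
mock_backend <- function() {
  h <- function(s) sum(utf8ToInt(s) * seq_len(nchar(s))) %% 997L
  list(
    name = "mock",
    duplex_mfe = function(a, b) -((h(a) + h(b)) %% 200L) / 10,
    fold_mfe = function(seq, constraint = NULL)
      -((h(seq) %% 150L) / 10) + if (is.null(constraint)) 0 else
        0.01 * length(constraint),
    pf_unpaired = function(seq, intervals, span)
      vapply(intervals, function(iv)
        1 / (1 + length(iv) * ((h(seq) %% 7L) + 1L) / 40), numeric(1)))
}

# Thin wrappers over the ViennaRNA command-line programs, when installed.
external_backend <- function() {
  need <- function(tool) {
    if (!nzchar(Sys.which(tool)))
      stop("external backend requires '", tool, "' on PATH")
    tool
  }
  list(
    name = "external",
    duplex_mfe = function(a, b) {
      need("RNAduplex")
      out <- system2("RNAduplex", stdout = TRUE,
                     input = c(check_rna(a), check_rna(b)))
      as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", out[length(out)]))
    },
    fold_mfe = function(seq, constraint = NULL) {
      need("RNAfold")
      check_rna(seq)
      if (is.null(constraint)) {
        out <- system2("RNAfold", args = "--noPS", stdout = TRUE, input = seq)
      } else {
        cons <- rep(".", nchar(seq)); cons[constraint] <- "x"
        out <- system2("RNAfold", args = c("--noPS", "-C"), stdout = TRUE,
                       input = c(seq, paste(cons, collapse = "")))
      }
      as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", out[2]))
    },
    pf_unpaired = function(seq, intervals, span) {
      stop("per-interval probabilities are not wired for the external ",
           "backend; use the nn-simple backend")
    })
}

#' Duplex minimum free energy of two RNA strands
#'
#' Intermolecular-only MFE (no intramolecular pairs) under the backend's
#' nearest-neighbor model.  0 when no base pair can form.
#'
#' @param strand_a,strand_b RNA sequences, 5'->3'.
#' @param backend an [energy_backend()].
#' @return Energy in kcal/mol (<= 0).
#' @export
duplex_mfe <- function(strand_a, strand_b, backend = energy_backend()) {
  backend$duplex_mfe(strand_a, strand_b)
}

# the window of `width` nt centered on [start, end) (0-based half-open),
# clipped at the UTR ends; returns 1-based [lo, hi]
center_window <- function(start, end, n, width) {
  mid <- (start + end) / 2
  lo <- max(0L, as.integer(floor(mid - width / 2)))
  hi <- min(n, lo + width)
  lo <- max(0L, hi - width)
  c(lo + 1L, hi)
}

#' Locally folded MFE around a target site
#'
#' Folds the `local_window`-nt window centered on the site (clipped at the
#' UTR ends); with `constrain_site_unpaired` the site bases are forbidden
#' from pairing, which can only raise the MFE.
#'
#' @param utr a [utr_record()].
#' @param site integer vector `c(start, end)`, 0-based half-open.
#' @param constrain_site_unpaired logical.
#' @param params an [accessibility_params()].
#' @param backend an [energy_backend()].
#' @return Energy in kcal/mol.
#' @export
local_fold_mfe <- function(utr, site, constrain_site_unpaired = FALSE,
                           params = accessibility_params(),
                           backend = energy_backend()) {
  n <- nchar(utr$sequence)
  stopifnot(site[1] >= 0, site[2] <= n, site[2] > site[1])
  w <- center_window(site[1], site[2], n, params$local_window)
  seq <- substr(utr$sequence, w[1], w[2])
  if (!nzchar(seq)) stop("empty folding window")
  constraint <- NULL
  if (constrain_site_unpaired)
    constraint <- (site[1] + 1L):site[2] - w[1] + 1L
  backend$fold_mfe(seq, constraint)
}

#' Opening energy of a target site
#'
#' Free-energy cost of forcing the site single-stranded: constrained minus
#' unconstrained local MFE, always >= 0.
#'
#' @inheritParams local_fold_mfe
#' @return Energy in kcal/mol (>= 0).
#' @export
opening_energy <- function(utr, site, params = accessibility_params(),
                           backend = energy_backend()) {
  local_fold_mfe(utr, site, TRUE, params, backend) -
    local_fold_mfe(utr, site, FALSE, params, backend)
}

#' Windowed unpaired probabilities (accessibility)
#'
#' Probability that each queried interval of the UTR is entirely unpaired
#' under a windowed Boltzmann ensemble: sliding windows of
#' `params$winsize` nt (sampled every `params$stride` nt, always including
#' the first and last window), base pairs limited to `params$span`, and
#' the per-window probabilities averaged over all sampled windows that
#' fully contain the interval.
#'
#' @param utr a [utr_record()] or RNA string.
#' @param intervals list of integer vectors `c(start, end)` (0-based,
#'   half-open) of length at most `params$ulength` each.
#' @param params an [accessibility_params()].
#' @param backend an [energy_backend()].
#' @return Numeric vector in `[0, 1]`, one value per interval.
#' @export
accessibility <- function(utr, intervals, params = accessibility_params(),
                          backend = energy_backend()) {
  seq <- if (inherits(utr, "utr_record")) utr$sequence else utr
  check_rna(seq)
  n <- nchar(seq)
  lens <- vapply(intervals, function(iv) iv[2] - iv[1], numeric(1))
  if (any(lens < 1) || any(lens > params$ulength))
    stop("queried interval length must be in [1, ulength = ",
         params$ulength, "]")
  if (n <= params$winsize) {
    starts <- 0L
  } else {
    starts <- unique(c(seq(0L, n - params$winsize, by = params$stride),
                       n - params$winsize))
  }
  acc <- numeric(length(intervals))
  cnt <- numeric(length(intervals))
  for (s0 in starts) {
    wseq <- substr(seq, s0 + 1L, s0 + min(params$winsize, n))
    wlen <- nchar(wseq)
    inside <- which(vapply(intervals, function(iv)
      iv[1] >= s0 && iv[2] <= s0 + wlen, logical(1)))
    if (!length(inside)) next
    ivs <- lapply(intervals[inside], function(iv)
      (iv[1] + 1L):iv[2] - s0)
    p <- backend$pf_unpaired(wseq, ivs, params$span)
    acc[inside] <- acc[inside] + p
    cnt[inside] <- cnt[inside] + 1
  }
  uncovered <- cnt == 0
  if (any(uncovered)) {
    # interval never fully inside a sampled window (clipped at an end):
    # fall back to the window anchored at the nearest UTR end
    for (k in which(uncovered)) {
      iv <- intervals[[k]]
      s0 <- max(0L, min(iv[1], n - params$winsize))
      wseq <- substr(seq, s0 + 1L, min(n, s0 + params$winsize))
      pos <- ((iv[1] + 1L):min(iv[2], s0 + nchar(wseq))) - s0
      pos <- pos[pos >= 1L]
      acc[k] <- backend$pf_unpaired(wseq, list(pos), params$span)
      cnt[k] <- 1
    }
  }
  acc / cnt
}
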