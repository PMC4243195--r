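# Independent oracles used across the suite: brute-force implementations
# kept deliberately separate from the package's DP / search code paths.

# ---- ungapped alignment oracle --------------------------------------------
# Best local ungapped score: for every diagonal offset, Kadane's maximum
# subarray over the per-position pair scores (seed-weighted).
oracle_ungapped_best <- function(mirna, utr, params) {
  mb <- rev(strsplit(mirna, "")[[1]])   # aligned 3'->5'
  ub <- strsplit(utr, "")[[1]]
  m <- length(mb); n <- length(ub)
  porig <- m:1                           # original miRNA position per row
  score1 <- function(a, b, p) {
    wc <- (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "A" && b == "U") || (a == "U" && b == "A")
    gu <- (a == "G" && b == "U") || (a == "U" && b == "G")
    s <- if (wc) params$score_wc else if (gu) params$score_gu
         else params$score_mismatch
    w <- if (p >= params$seed_lo && p <= params$seed_hi &&
             (!gu || params$seed_scale_gu)) params$seed_scale else 1
    s * w
  }
  best <- 0
  for (off in (-(m - 1)):(n - 1)) {
    i <- max(1, 1 - off); j <- i + off
    v <- c()
    while (i <= m && j <= n) {
      v <- c(v, score1(mb[i], ub[j], porig[i]))
      i <- i + 1; j <- j + 1
    }
    run <- 0
    for (x in v) { run <- max(0, run + x); best <- max(best, run) }
  }
  best
}

# ---- shared energy rules (independent re-implementation) ------------------
o_ptype <- function(x, y) {
  key <- paste0(x, y)
  idx <- c(CG = "CG", GC = "GC", AU = "AU", UA = "UA", GU = "GU", UG = "UG")
  if (key %in% idx) key else NA_character_
}

o_stack <- function(par, p1, p2) par$stack[p1, p2]

# ---- duplex enumeration ---------------------------------------------------
# All antiparallel chains of pairs (ascending on a, descending on b) with
# every consecutive step's unpaired total <= max_loop; min energy, 0 if no
# pair can form.
oracle_duplex_mfe <- function(a, b, par) {
  ab <- strsplit(a, "")[[1]]; bb <- strsplit(b, "")[[1]]
  n <- length(ab); m <- length(bb)
  pairs <- list()
  for (i in seq_len(n)) for (j in seq_len(m))
    if (!is.na(o_ptype(ab[i], bb[j])))
      pairs[[length(pairs) + 1]] <- c(i, j)
  if (!length(pairs)) return(0)
  best <- 0
  extend <- function(i, j, e) {
    if (e < best) best <<- e
    for (p in pairs) {
      if (p[1] <= i || p[2] >= j) next
      u <- (p[1] - i - 1) + (j - p[2] - 1)
      if (u > par$max_loop) next
      step <- if (u == 0)
        o_stack(par, o_ptype(ab[i], bb[j]), o_ptype(ab[p[1]], bb[p[2]]))
      else par$interior_init + par$interior_slope * u
      extend(p[1], p[2], e + step)
    }
  }
  for (p in pairs) extend(p[1], p[2], 0)
  best
}

# ---- nested structure enumeration -----------------------------------------
# All nested structures (lists of pairs) over seq with min hairpin loop 3.
oracle_structures <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  memo <- new.env(hash = TRUE)
  rec <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- rec(i + 1, j)                       # i unpaired
    if (j >= i + 4) for (k in (i + 4):j) {
      if (is.na(o_ptype(b[i], b[k]))) next
      inner <- rec(i + 1, k - 1)
      outer <- rec(k + 1, j)
      for (A in inner) for (B in outer)
        out[[length(out) + 1]] <- c(list(c(i, k)), A, B)
    }
    memo[[key]] <- out
    out
  }
  rec(1L, n)
}

# Energy of one explicit nested structure under the nn-simple rules;
# Inf marks structures the model disallows (oversized interior loops).
oracle_structure_energy <- function(seq, pairs, par, mask = NULL) {
  if (!length(pairs)) return(0)
  b <- strsplit(seq, "")[[1]]
  P <- do.call(rbind, pairs)
  if (!is.null(mask) && any(P %in% mask)) return(Inf)
  e <- 0
  for (r in seq_len(nrow(P))) {
    i <- P[r, 1]; j <- P[r, 2]
    # children: pairs directly inside (i, j)
    inside <- P[, 1] > i & P[, 2] < j
    ch <- which(inside)
    if (length(ch) > 1) {
      nested <- sapply(ch, function(a) any(
        P[ch, 1] < P[a, 1] & P[ch, 2] > P[a, 2]))
      ch <- ch[!nested]
    }
    if (!length(ch)) {
      L <- j - i - 1
      if (L < 3) return(Inf)
      e <- e + par$hairpin_init + par$hairpin_slope * (L - 3)
    } else if (length(ch) == 1) {
      p <- P[ch, 1]; q <- P[ch, 2]
      u <- (p - i - 1) + (j - q - 1)
      if (u == 0) {
        e <- e + o_stack(par, o_ptype(b[i], b[j]), o_ptype(b[p], b[q]))
      } else {
        if (u > par$max_loop) return(Inf)
        e <- e + par$interior_init + par$interior_slope * u
      }
    } else {
      unp <- (j - i - 1) - sum(P[ch, 2] - P[ch, 1] + 1)
      e <- e + par$ml_init + par$ml_branch * (length(ch) + 1) +
        par$ml_unpaired * unp
    }
  }
  e
}

oracle_fold_mfe <- function(seq, par, mask = NULL) {
  es <- vapply(oracle_structures(seq), function(s)
    oracle_structure_energy(seq, s, par, mask), numeric(1))
  min(0, es[is.finite(es)])
}

# Boltzmann: probability that every base of `interval` (1-based) is
# unpaired, exact over the enumerated ensemble.
oracle_unpaired_prob <- function(seq, interval, par) {
  ss <- oracle_structures(seq)
  es <- vapply(ss, function(s) oracle_structure_energy(seq, s, par),
               numeric(1))
  w <- exp(-es[is.finite(es)] / par$kT)
  free <- vapply(ss, function(s) {
    if (!length(s)) return(TRUE)
    !any(unlist(s) %in% interval)
  }, logical(1))[is.finite(es)]
  sum(w[free]) / sum(w)
}

# ---- CFS exhaustive oracle ------------------------------------------------
# Own plug-in MI + Linfoot + merit, full subset search (p <= 12).
o_mi <- function(x, y) {
  jt <- table(x, y) / length(x)
  px <- rowSums(jt); py <- colSums(jt)
  s <- 0
  for (a in seq_along(px)) for (b in seq_along(py))
    if (jt[a, b] > 0) s <- s + jt[a, b] * log(jt[a, b] / (px[a] * py[b]))
  max(0, s)
}

oracle_cfs_best <- function(features, labels) {
  p <- ncol(features)
  lin <- function(i) sqrt(1 - exp(-2 * i))
  rcf <- vapply(features, function(f) lin(o_mi(f, labels)), numeric(1))
  rff <- matrix(0, p, p)
  for (a in seq_len(p)) for (b in seq_len(p)) if (a < b)
    rff[a, b] <- rff[b, a] <- lin(o_mi(features[[a]], features[[b]]))
  best <- list(merit = 0, set = character())
  for (code in seq_len(2^p - 1)) {
    s <- which(bitwAnd(code, 2^(seq_len(p) - 1)) > 0)
    k <- length(s)
    rb_cf <- mean(rcf[s])
    rb_ff <- if (k > 1) mean(rff[s, s][upper.tri(rff[s, s])]) else 0
    m <- k * rb_cf / sqrt(k + k * (k - 1) * rb_ff)
    if (m > best$merit + 1e-12) best <- list(merit = m,
                                             set = names(features)[s])
  }
  best
}

# ---- AUC brute force ------------------------------------------------------
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels != "positive"]
  s <- 0
  for (a in pos) s <- s + sum(a > neg) + 0.5 * sum(a == neg)
  s / (length(pos) * length(neg))
}
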