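# Mutual-information feature selection: Freedman-Diaconis discretization,
# plug-in MI in nats, Linfoot normalization to [0, 1], CFS subset search
# (best-first with a patience stop) and mRMR greedy ranking.

#' Freedman-Diaconis discretization of a numeric column
#'
#' Bin width `h = 2 * IQR * n^(-1/3)`; edges span `[min, max]`.  Columns
#' that are already integer-coded (binary flags, categorical state codes)
#' are passed through unbinned; an IQR of 0 yields a single bin.
#'
#' @param values numeric vector, `n >= 2`.
#' @return List of class `discretized_column`: integer `labels` in
#'   `[0, n_bins)`, `edges`, `n_bins`.
#' @export
discretize_fd <- function(values) {
  stopifnot(length(values) >= 2L)
  if (all(values == round(values))) {
    lev <- sort(unique(values))
    return(structure(list(labels = match(values, lev) - 1L,
                          edges = lev, n_bins = length(lev)),
                     class = "discretized_column"))
  }
  iqr <- IQR(values)
  h <- 2 * iqr * length(values)^(-1 / 3)
  lo <- min(values); hi <- max(values)
  if (iqr == 0 || h <= 0 || hi == lo) {
    return(structure(list(labels = rep(0L, length(values)),
                          edges = c(lo, hi), n_bins = 1L),
                     class = "discretized_column"))
  }
  n_bins <- max(1L, as.integer(ceiling((hi - lo) / h)))
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  labels <- pmin(findInterval(values, edges, rightmost.closed = TRUE),
                 n_bins) - 1L
  structure(list(labels = as.integer(labels), edges = edges,
                 n_bins = n_bins), class = "discretized_column")
}

as_labels <- function(x) {
  if (inherits(x, "discretized_column")) return(x$labels)
  if (is.character(x)) x <- factor(x)
  if (is.factor(x)) return(as.integer(x) - 1L)
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) return(discretize_fd(x)$labels)
  stop("cannot discretize object of class ", paste(class(x), collapse = "/"))
}

#' Plug-in mutual information of two discretized columns
#'
#' Maximum-likelihood estimator
#' `I = sum p(x, y) * ln(p(x, y) / (p(x) p(y)))`, in nats.
#'
#' @param x,y discretized columns, factors, or numeric vectors (numeric
#'   input is discretized with [discretize_fd()]).
#' @return Mutual information in nats (>= 0).
#' @export
mutual_information <- function(x, y) {
  lx <- as_labels(x); ly <- as_labels(y)
  if (length(lx) != length(ly))
    stop("length mismatch: ", length(lx), " vs ", length(ly))
  joint <- table(lx, ly) / length(lx)
  px <- rowSums(joint); py <- colSums(joint)
  ind <- outer(px, py)
  nz <- joint > 0
  max(0, sum(joint[nz] * log(joint[nz] / ind[nz])))
}

#' Linfoot normalization of mutual information
#'
#' Computes `sqrt(1 - exp(-2 * I))`, mapping MI in nats onto `[0, 1]`.
#'
#' @param I mutual information in nats (>= 0).
#' @return Normalized correlation in `[0, 1]`.
#' @export
linfoot <- function(I) {
  if (any(I < 0)) stop("mutual information must be non-negative")
  sqrt(1 - exp(-2 * I))
}

# Linfoot feature-class and feature-feature correlations with caching
correlation_cache <- function(features, labels) {
  cols <- lapply(features, as_labels)
  cls <- as_labels(labels)
  p <- length(cols)
  rcf <- vapply(cols, function(c) linfoot(mutual_information(c, cls)),
                numeric(1))
  rff <- matrix(NA_real_, p, p)
  diag(rff) <- 1
  get_ff <- function(i, j) {
    if (is.na(rff[i, j])) {
      v <- linfoot(mutual_information(cols[[i]], cols[[j]]))
      rff[i, j] <<- v; rff[j, i] <<- v
    }
    rff[i, j]
  }
  list(rcf = rcf, get_ff = get_ff, names = names(features))
}

#' CFS merit of a feature subset
#'
#' `M(S) = k * rcf_bar / sqrt(k + k (k - 1) * rff_bar)` with `k = |S|`,
#' `rcf_bar` the mean feature-class and `rff_bar` the mean pairwise
#' feature-feature Linfoot correlation.
#'
#' @param rcf numeric vector of feature-class correlations for the subset.
#' @param rff_sum sum of pairwise feature-feature correlations (each
#'   unordered pair once).
#' @return The merit (0 for an empty subset).
#' @export
cfs_merit <- function(rcf, rff_sum) {
  k <- length(rcf)
  if (k == 0L) return(0)
  rbar_cf <- mean(rcf)
  rbar_ff <- if (k > 1L) rff_sum / (k * (k - 1) / 2) else 0
  k * rbar_cf / sqrt(k + k * (k - 1) * rbar_ff)
}

#' Correlation-based feature selection (CFS)
#'
#' Forward best-first search over feature subsets maximizing the CFS
#' merit; the search keeps an open list of evaluated states, always
#' expands the best unexpanded one, and stops after `patience`
#' consecutive expansions that fail to improve the best merit found.
#' Ties break lexicographically on feature name, so the result is
#' deterministic and invariant to column order.
#'
#' @param features data.frame of feature columns.
#' @param labels binary class vector/factor (both classes present).
#' @param patience consecutive non-improving expansions before stopping.
#' @return List of class `selection_result`: `method = "cfs"`, `selected`
#'   (feature names), `merit`, and `relevance` (named Linfoot MI of every
#'   feature with the class).
#' @export
cfs_select <- function(features, labels, patience = 5L) {
  stopifnot(ncol(features) >= 2L)
  if (length(unique(as_labels(labels))) < 2L)
    stop("labels must contain both classes")
  cc <- correlation_cache(features, labels)
  p <- length(cc$rcf)
  ord <- order(cc$names)  # lexicographic expansion order for ties
  key <- function(s) paste0("s", paste(sort(s), collapse = ","))
  # state: integer feature index set; score via cached pair sums
  pair_sum <- function(s) {
    if (length(s) < 2L) return(0)
    tot <- 0
    for (a in seq_along(s)) for (b in seq_len(a - 1L))
      tot <- tot + cc$get_ff(s[a], s[b])
    tot
  }
  merit_of <- function(s) cfs_merit(cc$rcf[s], pair_sum(s))
  open <- list(list(set = integer(), merit = 0))
  seen <- new.env(hash = TRUE)
  assign(key(integer()), TRUE, envir = seen)
  best_set <- integer(); best_merit <- 0
  stale <- 0L
  while (length(open) > 0L && stale < patience) {
    scores <- vapply(open, `[[`, numeric(1), "merit")
    i <- which.max(scores)
    node <- open[[i]]; open[[i]] <- NULL
    improved <- FALSE
    for (f in ord) {
      if (f %in% node$set) next
      s2 <- c(node$set, f)
      k2 <- key(s2)
      if (!is.null(seen[[k2]])) next
      assign(k2, TRUE, envir = seen)
      m2 <- merit_of(s2)
      open[[length(open) + 1L]] <- list(set = s2, merit = m2)
      if (m2 > best_merit + 1e-12) {
        best_merit <- m2; best_set <- s2; improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  structure(list(method = "cfs",
                 selected = sort(cc$names[best_set]),
                 merit = best_merit,
                 relevance = stats::setNames(cc$rcf, cc$names)),
            class = "selection_result")
}

#' mRMR feature ranking
#'
#' Greedy minimum-redundancy maximum-relevance ranking (MID scheme): the
#' first feature maximizes `I(f; class)`; each next feature maximizes
#' `I(f; class) - mean over selected s of I(f; s)`.  Ties break
#' lexicographically.  The full permutation of features is returned.
#'
#' @param features data.frame of feature columns.
#' @param labels binary class vector/factor.
#' @return List of class `selection_result`: `method = "mrmr"`, `ranking`
#'   (all feature names, best first), `relevance` (Linfoot-normalized).
#' @export
mrmr_rank <- function(features, labels) {
  stopifnot(ncol(features) >= 2L)
  if (length(unique(as_labels(labels))) < 2L)
    stop("labels must contain both classes")
  cols <- lapply(features, as_labels)
  cls <- as_labels(labels)
  p <- length(cols)
  nm <- names(features)
  rel <- vapply(cols, function(c) mutual_information(c, cls), numeric(1))
  mi_ff <- matrix(NA_real_, p, p)
  remaining <- seq_len(p)
  chosen <- integer()
  while (length(remaining) > 0L) {
    crit <- vapply(remaining, function(f) {
      if (!length(chosen)) return(rel[f])
      for (s in chosen) if (is.na(mi_ff[f, s])) {
        v <- mutual_information(cols[[f]], cols[[s]])
        mi_ff[f, s] <<- v; mi_ff[s, f] <<- v
      }
      rel[f] - mean(mi_ff[f, chosen])
    }, numeric(1))
    # max criterion, lexicographic tie-break
    top <- remaining[crit >= max(crit) - 1e-12]
    pick <- top[order(nm[top])][1L]
    chosen <- c(chosen, pick)
    remaining <- setdiff(remaining, pick)
  }
  structure(list(method = "mrmr", ranking = nm[chosen],
                 relevance = stats::setNames(linfoot(rel), nm)),
            class = "selection_result")
}
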