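test_that("Freedman-Diaconis binning follows the bin-width formula", {
  # constant column: one bin
  d <- discretize_fd(rep(3.7, 50))
  expect_equal(d$n_bins, 1L)
  expect_true(all(d$labels == 0L))
  # uniform grid 0..99 (as continuous values): h = 2 * 49.5 * 100^(-1/3)
  x <- seq(0, 99, by = 1) + 0.5  # non-integer so binning applies
  h <- 2 * IQR(x) * 100^(-1 / 3)
  d2 <- discretize_fd(x)
  expect_equal(d2$n_bins, as.integer(ceiling((max(x) - min(x)) / h)))
  expect_equal(length(d2$edges), d2$n_bins + 1L)
  expect_true(all(d2$labels >= 0 & d2$labels < d2$n_bins))
  # integer-coded categorical columns pass through unbinned
  flags <- c(0, 1, 1, 0, 1, 0)
  d3 <- discretize_fd(flags)
  expect_equal(d3$n_bins, 2L)
  expect_equal(d3$labels, as.integer(flags))
})

test_that("plug-in mutual information matches closed forms", {
  # independent fair coins, joint counts 25/25/25/25
  x <- rep(c(0, 0, 1, 1), each = 25)
  y <- rep(c(0, 1, 0, 1), each = 25)
  expect_equal(mutual_information(x, y), 0, tolerance = 1e-12)
  # identical balanced binary columns: I = H = ln 2
  z <- rep(c(0, 1), 50)
  expect_equal(mutual_information(z, z), log(2), tolerance = 1e-12)
  # symmetry on random discrete columns
  set.seed(31)
  for (r in 1:10) {
    a <- sample(0:3, 80, replace = TRUE)
    b <- sample(0:2, 80, replace = TRUE)
    expect_equal(mutual_information(a, b), mutual_information(b, a))
    expect_gte(mutual_information(a, b), 0)
  }
  expect_error(mutual_information(1:10, 1:9), "length mismatch")
})

test_that("Linfoot normalization maps nats onto [0, 1] monotonically", {
  expect_equal(linfoot(0), 0)
  expect_equal(linfoot(log(2)), sqrt(3) / 2, tolerance = 1e-12)
  i <- seq(0, 4, by = 0.25)
  r <- linfoot(i)
  expect_true(all(diff(r) > 0))
  expect_true(all(r >= 0 & r <= 1))
  expect_error(linfoot(-0.1), "non-negative")
})

make_instance <- function(n, p_noise, seed, dup = FALSE) {
  set.seed(seed)
  y <- rep(c("negative", "positive"), length.out = n)
  x <- list(signal = ifelse(y == "positive", 1L, 0L))
  # slightly noisy copy keeps the class link strong but imperfect
  flip <- sample(n, round(0.1 * n))
  x$signal[flip] <- 1L - x$signal[flip]
  if (dup) x$dupe <- x$signal
  for (k in seq_len(p_noise))
    x[[paste0("noise_", letters[k])]] <- sample(0:2, n, replace = TRUE)
  list(x = as.data.frame(x), y = y)
}

test_that("CFS keeps the informative feature and drops its duplicate", {
  inst <- make_instance(200, 5, seed = 42)
  sel <- cfs_select(inst$x, inst$y)
  expect_identical(sel$selected, "signal")
  inst2 <- make_instance(200, 4, seed = 43, dup = TRUE)
  sel2 <- cfs_select(inst2$x, inst2$y)
  # a redundant copy never displaces the signal, and the search still
  # agrees with exhaustive merit maximization on the duplicated instance
  expect_true("signal" %in% sel2$selected ||
                "dupe" %in% sel2$selected)
  oracle2 <- oracle_cfs_best(inst2$x, inst2$y)
  expect_equal(sel2$merit, oracle2$merit, tolerance = 1e-9)
  expect_setequal(sel2$selected, oracle2$set)
  expect_error(cfs_select(inst$x, rep("positive", 200)), "single|classes")
})

test_that("CFS equals exhaustive merit maximization on small instances", {
  for (seed in 1:15) {
    set.seed(seed)
    n <- 60; p <- sample(4:8, 1)
    x <- as.data.frame(lapply(seq_len(p), function(k)
      sample(0:2, n, replace = TRUE)))
    names(x) <- paste0("f", sprintf("%02d", seq_len(p)))
    y <- sample(c("negative", "positive"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    sel <- cfs_select(x, y)
    oracle <- oracle_cfs_best(x, y)
    expect_equal(sel$merit, oracle$merit, tolerance = 1e-9)
    expect_setequal(sel$selected, oracle$set)
  }
})

test_that("relevance scores are the Linfoot-normalized class MI", {
  inst <- make_instance(150, 3, seed = 7)
  sel <- cfs_select(inst$x, inst$y)
  for (f in names(inst$x))
    expect_equal(unname(sel$relevance[f]),
                 linfoot(mutual_information(inst$x[[f]], inst$y)))
})

test_that("mRMR ranks by relevance first and demotes redundancy", {
  inst <- make_instance(200, 4, seed = 44, dup = TRUE)
  rk <- mrmr_rank(inst$x, inst$y)
  expect_setequal(rk$ranking, names(inst$x))  # full permutation
  rel <- vapply(inst$x, function(f)
    mutual_information(f, inst$y), numeric(1))
  # first-ranked feature attains maximal relevance (ties break by name)
  expect_equal(rel[[rk$ranking[1]]], max(rel))
  # the exact duplicate of the top feature is demoted below the noise
  other <- setdiff(c("signal", "dupe"), rk$ranking[1])
  expect_gt(match(other, rk$ranking), 2)
})

test_that("selection is invariant to feature column order", {
  inst <- make_instance(150, 5, seed = 45)
  perm <- sample(ncol(inst$x))
  sel_a <- cfs_select(inst$x, inst$y)
  sel_b <- cfs_select(inst$x[, perm], inst$y)
  expect_identical(sel_a$selected, sel_b$selected)
  rk_a <- mrmr_rank(inst$x, inst$y)
  rk_b <- mrmr_rank(inst$x[, perm], inst$y)
  expect_identical(rk_a$ranking, rk_b$ranking)
})
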