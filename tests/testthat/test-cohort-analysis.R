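test_that("tier pair grouping partitions the unique pairs", {
  # 2 SPs + 2 NPs: {SP-SP: 1, SP-NP: 4, NP-NP: 1}, total C(4,2) = 6
  v <- matrix(stats::runif(16), 4, 4); v <- (v + t(v)) / 2; diag(v) <- 0
  td <- tier_pair_distributions(dm_fixture(v, c("SP", "SP", "NP", "NP")))
  counts <- stats::setNames(td$n_pairs, td$pair_class)
  expect_equal(counts[["SP-SP"]], 1L)
  expect_equal(counts[["SP-NP"]], 4L)
  expect_equal(counts[["NP-NP"]], 1L)
  expect_equal(sum(td$n_pairs), choose(4, 2))

  # constant matrix: every median equals the constant, sd 0
  vc <- matrix(0.3, 5, 5); diag(vc) <- 0
  tdc <- tier_pair_distributions(dm_fixture(vc, c("SP", "SP", "JP", "NP", "NP")))
  expect_true(all(tdc$median == 0.3))
  expect_true(all(tdc$sd == 0))

  # random tiered matrices match a direct grouping oracle
  set.seed(111)
  for (rep_i in 1:10) {
    n <- sample(4:9, 1)
    v <- matrix(stats::runif(n * n), n, n); v <- (v + t(v)) / 2; diag(v) <- 0
    tiers <- sample(c("SP", "JP", "NP", "AL"), n, replace = TRUE)
    td <- tier_pair_distributions(dm_fixture(v, tiers))
    expect_equal(sum(td$n_pairs), choose(n, 2))
    lv <- c("SP", "JP", "NP", "AL")
    oracle <- list()
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      key <- paste(lv[sort(match(c(tiers[i], tiers[j]), lv))], collapse = "-")
      oracle[[key]] <- c(oracle[[key]], v[i, j])
    }
    for (k in seq_len(nrow(td))) {
      expect_equal(td$median[k], stats::median(oracle[[td$pair_class[k]]]))
    }
  }
})

test_that("Mann-Whitney test matches enumeration and handles no-shift cases", {
  r <- rank_test_unpaired(c(1, 2, 3), c(4, 5, 6), alternative = "less")
  expect_equal(r$statistic, 0)
  expect_equal(r$p.value, 1 / 20)     # exact: 1 of C(6,3) assignments
  expect_equal(rank_test_unpaired(c(1, 2, 3), c(4, 5, 6))$p.value, 2 / 20)
  # identical samples: no shift detectable
  expect_equal(rank_test_unpaired(c(1, 2, 3), c(1, 2, 3))$p.value, 1)
  expect_error(rank_test_unpaired(numeric(0), 1), "non-empty")

  set.seed(121)
  for (rep_i in 1:30) {
    n1 <- sample(2:5, 1); n2 <- sample(2:5, 1)
    x <- sample(1:6, n1, replace = TRUE)      # ties guaranteed possible
    y <- sample(1:6, n2, replace = TRUE)
    alt <- sample(c("two.sided", "less", "greater"), 1)
    got <- rank_test_unpaired(x, y, alternative = alt)
    ora <- mw_enum_oracle(x, y, alternative = alt)
    expect_equal(got$statistic, ora$statistic)
    expect_equal(got$p.value, ora$p.value)
  }
  # tie-free inputs also agree with the standard library implementation
  for (rep_i in 1:10) {
    x <- stats::rnorm(5); y <- stats::rnorm(6)
    expect_equal(rank_test_unpaired(x, y)$p.value,
                 stats::wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("normal approximation tracks exact Mann-Whitney p-values at moderate n", {
  # enumerate every achievable U (tie-free data) and compare exact vs
  # approximate p; at 6+6 observations the one-sided error stays below 1e-2,
  # and the smallest groups (3+3) bound the envelope at about 0.02 / 0.04
  worst_for <- function(n1, n2) {
    w <- c(0, 0)
    for (ii in utils::combn(n1 + n2, n1, simplify = FALSE)) {
      x <- as.numeric(ii); y <- setdiff(seq_len(n1 + n2), ii)
      w[1] <- max(w[1], abs(rank_test_unpaired(x, y, "greater", exact = TRUE)$p.value -
                            rank_test_unpaired(x, y, "greater", exact = FALSE)$p.value))
      w[2] <- max(w[2], abs(rank_test_unpaired(x, y, exact = TRUE)$p.value -
                            rank_test_unpaired(x, y, exact = FALSE)$p.value))
    }
    w
  }
  w66 <- worst_for(6, 6)
  expect_lt(w66[1], 0.01)
  expect_lt(w66[2], 0.02)
  w33 <- worst_for(3, 3)
  expect_lt(w33[1], 0.02)
  expect_lt(w33[2], 0.04)
})

test_that("Wilcoxon signed-rank test matches sign-pattern enumeration", {
  # 5 pairs, all differences positive: two-sided p = 2/32
  r <- rank_test_paired(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(r$statistic, 15)
  expect_equal(r$p.value, 2 / 32)
  # identical vectors degenerate to p = 1 with a flag
  rz <- rank_test_paired(1:4, 1:4)
  expect_true(rz$degenerate)
  expect_equal(rz$p.value, 1)
  expect_equal(rz$n_zero, 4L)
  expect_error(rank_test_paired(1:3, 1:4), "equal length")

  set.seed(141)
  for (rep_i in 1:30) {
    n <- sample(3:10, 1)
    x <- sample(0:5, n, replace = TRUE)
    y <- sample(0:5, n, replace = TRUE)
    if (all(x == y)) x[1] <- x[1] + 1
    alt <- sample(c("two.sided", "less", "greater"), 1)
    got <- rank_test_paired(x, y, alternative = alt)
    ora <- wsr_enum_oracle(x, y, alternative = alt)
    expect_equal(got$statistic, ora$statistic)
    expect_equal(got$p.value, ora$p.value)
  }
  # tie-free, zero-free inputs agree with the standard implementation
  for (rep_i in 1:10) {
    x <- stats::rnorm(8); y <- stats::rnorm(8)
    expect_equal(rank_test_paired(x, y)$p.value,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  }
})

test_that("biclustering groups block structure contiguously and ignores input order", {
  set.seed(151)
  n <- 8
  tiers <- c(rep("SP", 4), rep("NP", 4))
  v <- matrix(0.9, n, n)
  v[1:4, 1:4] <- 0.1; v[5:8, 5:8] <- 0.1
  diag(v) <- 0
  v <- v + matrix(stats::runif(n * n, 0, 0.01), n, n); v <- (v + t(v)) / 2
  diag(v) <- 0
  ids <- sprintf("p%02d", 1:n)
  ord <- bicluster_order(dm_fixture(v, tiers, ids))
  blocks <- ifelse(match(ord, ids) <= 4, "A", "B")
  expect_equal(length(rle(blocks)$values), 2)   # blocks contiguous

  # permutation invariance of the grouped blocks
  perm <- sample(n)
  ord2 <- bicluster_order(dm_fixture(v[perm, perm], tiers[perm], ids[perm]))
  blocks2 <- ifelse(match(ord2, ids) <= 4, "A", "B")
  expect_equal(length(rle(blocks2)$values), 2)
  expect_setequal(ord2, ord)

  # n = 2: lexicographic tie-break
  v2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(bicluster_order(dm_fixture(v2, c("SP", "NP"), c("b", "a"))),
               c("a", "b"))
  expect_error(bicluster_order(dm_fixture(matrix(0, 1, 1), "SP", "a")), "at least 2")
})

test_that("classical MDS reconstructs Euclidean-realizable distances", {
  d345 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3)
  emb <- mds_embed(dm_fixture(d345, rep("SP", 3), c("a", "b", "c")))
  rec <- as.matrix(stats::dist(cbind(emb$coordinates$x, emb$coordinates$y)))
  expect_lt(max(abs(rec - d345)), 1e-6)
  expect_lt(emb$stress, 1e-6)

  # zero matrix: all points at the origin
  emb0 <- mds_embed(dm_fixture(matrix(0, 4, 4), rep("SP", 4)))
  expect_true(all(emb0$coordinates$x == 0 & emb0$coordinates$y == 0))
  expect_equal(emb0$stress, 0)

  # two-cluster matrix: between-cluster embedded distances exceed within
  v <- matrix(0.8, 6, 6); v[1:3, 1:3] <- 0.1; v[4:6, 4:6] <- 0.1; diag(v) <- 0
  emb2 <- mds_embed(dm_fixture(v, rep(c("SP", "NP"), each = 3)))
  co <- cbind(emb2$coordinates$x, emb2$coordinates$y)
  D <- as.matrix(stats::dist(co))
  within <- c(D[1:3, 1:3][upper.tri(diag(3))], D[4:6, 4:6][upper.tri(diag(3))])
  between <- as.vector(D[1:3, 4:6])
  expect_gt(min(between), max(within))

  # non-symmetric input rejected
  bad <- matrix(stats::runif(9), 3, 3); diag(bad) <- 0
  expect_error(mds_embed(dm_fixture(bad, rep("SP", 3))), "symmetric")
})
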