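test_that("Dice discordance reproduces hand-computed and limiting cases", {
  I <- matrix(2L, 4, 4); I[1:2, ] <- 1L        # 8 tumor + 8 stroma
  J <- I; J[1, 1:2] <- 2L                      # 2 tumor px flipped to stroma
  mi <- label_mask(I, tax8); mj <- label_mask(J, tax8)
  expect_equal(dice_discordance(mi, mj, c("tumor", "stroma")),
               1 - 2 * (6 + 8) / (8 + 6 + 8 + 10))   # 0.125
  expect_equal(dice_discordance(mi, mi), 0)
  # disjoint support: all tumor vs all necrosis
  a <- label_mask(matrix(1L, 4, 4), tax8)
  b <- label_mask(matrix(4L, 4, 4), tax8)
  expect_equal(dice_discordance(a, b, c("tumor", "necrosis")), 1)
  # vacuous case: subset absent from both masks -> 0 with flag and warning
  expect_warning(v <- dice_discordance(a, b, "blood"), "vacuous")
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "vacuous"))
  expect_error(dice_discordance(a, b, character(0)), "non-empty")
  expect_error(dice_discordance(a, label_mask(matrix(1L, 3, 3), tax8)))
})

test_that("Dice discordance equals the counting oracle and satisfies metric axioms", {
  set.seed(51)
  for (i in 1:60) {
    n_cls <- sample(2:6, 1)
    codes <- sample(tax8$label_code, n_cls)
    I <- random_mask(16, 16, codes)
    J <- random_mask(16, 16, codes)
    subset <- sample(tax8$class_name, sample(2:5, 1))
    got <- suppressWarnings(dice_discordance(I, J, subset))
    expect_equal(as.numeric(got), dice_oracle(I, J, subset), tolerance = 1e-12)
    expect_equal(as.numeric(got),
                 as.numeric(suppressWarnings(dice_discordance(J, I, subset))))
    expect_gte(as.numeric(got), 0)
    expect_lte(as.numeric(got), 1)
    expect_equal(suppressWarnings(as.numeric(dice_discordance(I, I, subset))), 0)
  }
})

test_that("label-0 pixels are excluded from all counts", {
  I <- matrix(1L, 4, 4); J <- matrix(1L, 4, 4)
  I[1, ] <- 0L
  J[1, ] <- 4L                       # disagreement only where I is outside-ROI
  expect_equal(dice_discordance(label_mask(I, tax8), label_mask(J, tax8),
                                c("tumor", "necrosis")), 0)
})

test_that("single-class discordance matches binary Sorensen-Dice and handles absence", {
  a <- label_mask(matrix(2L, 4, 4), tax8)
  v <- per_class_discordance(a, a, "tumor")          # absent from both
  expect_equal(as.numeric(v), 0)
  expect_true(attr(v, "vacuous"))
  b <- a; b$labels[1:2, 1:2] <- 1L
  expect_equal(per_class_discordance(a, b, "tumor"), 1)  # present in one only
  expect_error(per_class_discordance(a, b, "martian_tissue"), "not in")

  set.seed(61)
  for (i in 1:25) {
    I <- random_mask(12, 12, c(1L, 2L))
    J <- random_mask(12, 12, c(1L, 2L))
    A <- I$labels == 1L; B <- J$labels == 1L
    direct <- 1 - 2 * sum(A & B) / (sum(A) + sum(B))
    expect_equal(as.numeric(per_class_discordance(I, J, "tumor")), direct)
    # cross-check vs an independent segmentation-metric route: Dice = 1 - delta
    sm <- score_map(list(tumor = 1 * (J$labels == 1L),
                         stroma = 1 * (J$labels == 2L)))
    mr <- evaluate_prediction(sm, I)
    expect_equal(mr$per_class$dice[mr$per_class$class == "tumor"],
                 1 - as.numeric(per_class_discordance(I, J, "tumor")))
  }
})

test_that("pooled aggregation equals the statistic on concatenated masks", {
  set.seed(71)
  masks <- list()
  for (pid in c("a", "b", "c")) {
    masks[[pid]] <- list(r1 = random_mask(10, 10, c(1L, 2L, 4L)),
                         r2 = random_mask(10, 10, c(1L, 2L, 4L)))
  }
  dm <- pairwise_discordance(masks, c("tumor", "stroma", "necrosis"))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    I <- label_mask(rbind(masks[[pair[1]]]$r1$labels,
                          masks[[pair[1]]]$r2$labels), tax8)
    J <- label_mask(rbind(masks[[pair[2]]]$r1$labels,
                          masks[[pair[2]]]$r2$labels), tax8)
    expect_equal(dm$values[pair[1], pair[2]],
                 dice_discordance(I, J, c("tumor", "stroma", "necrosis")))
  }
  # per-ROI median route agrees with direct per-ROI evaluation
  dmm <- pairwise_discordance(masks, c("tumor", "stroma", "necrosis"),
                              aggregation = "per_roi_median")
  d1 <- dice_discordance(masks$a$r1, masks$b$r1, c("tumor", "stroma", "necrosis"))
  d2 <- dice_discordance(masks$a$r2, masks$b$r2, c("tumor", "stroma", "necrosis"))
  expect_equal(dmm$values["a", "b"], stats::median(c(d1, d2)))
})

test_that("pairwise matrix invariants hold and missing masks are named", {
  set.seed(81)
  masks <- list()
  for (pid in sprintf("p%02d", 1:5)) {
    masks[[pid]] <- list(r1 = random_mask(8, 8, c(1L, 2L)),
                         r2 = random_mask(8, 8, c(1L, 2L)))
  }
  dm <- pairwise_discordance(masks)
  expect_equal(dm$values, t(dm$values))
  expect_true(all(diag(dm$values) == 0))
  expect_true(all(dm$values >= 0 & dm$values <= 1))

  # identical masks everywhere -> zero matrix
  same <- lapply(masks, function(x) list(r1 = masks[[1]]$r1, r2 = masks[[1]]$r2))
  expect_true(all(pairwise_discordance(same)$values == 0))

  masks$p05$r2 <- NULL
  expect_error(pairwise_discordance(masks), "p05.*r2")
})

test_that("correction discordance is 0 without corrections and grows with patched area", {
  base <- label_mask(matrix(2L, 12, 12), tax8)
  expect_equal(correction_discordance(base, apply_corrections(base, list())), 0)
  # relabel a k-pixel patch stroma -> necrosis; closed form from the counts:
  # num = (144 - k) stroma agreement, den = 2*144
  corr <- polygon_annotation("necrosis",
                             rbind(c(1, 1), c(4, 1), c(4, 3), c(1, 3)),
                             "rev", is_correction = TRUE)
  post <- apply_corrections(base, list(corr))
  k <- sum(post$labels == 4L)
  expect_identical(k, 12L)
  expect_equal(correction_discordance(base, post, c("stroma", "necrosis")),
               1 - 2 * (144 - k) / (2 * 144))
  # discordance restricted to an untouched class never exceeds the pooled value
  expect_lte(as.numeric(suppressWarnings(
    correction_discordance(base, post, "tumor"))),
    correction_discordance(base, post))
})

test_that("disagreement maps average label mismatches over cross pairs", {
  a <- label_mask(matrix(2L, 6, 6), tax8)
  b <- a; b$labels[3, 3] <- 1L
  # identical groups of identical masks -> all zero
  expect_true(all(disagreement_map(list(a, a), list(a, a))$values == 0))
  # single differing pixel -> 1 there, 0 elsewhere
  dmp <- disagreement_map(list(a), list(b))
  expect_equal(dmp$values[3, 3], 1)
  expect_equal(sum(dmp$values), 1)
  expect_error(disagreement_map(list(), list(a)), "non-empty")

  set.seed(91)
  ga <- lapply(1:3, function(i) random_mask(7, 7, c(1L, 2L)))
  gb <- lapply(1:2, function(i) random_mask(7, 7, c(1L, 2L)))
  got <- disagreement_map(ga, gb)$values
  oracle <- matrix(0, 7, 7)
  for (a_ in ga) for (b_ in gb) oracle <- oracle + (a_$labels != b_$labels)
  expect_equal(got, oracle / 6)
})

test_that("disagreement after 1-px erosion is confined to the region boundary", {
  lab <- matrix(2L, 20, 20)
  lab[5:15, 5:15] <- 1L
  m <- label_mask(lab, tax8)
  lab2 <- matrix(2L, 20, 20)
  lab2[6:14, 6:14] <- 1L              # eroded by one pixel
  m2 <- label_mask(lab2, tax8)
  dmp <- disagreement_map(list(m), list(m2))$values
  inner <- dmp[7:13, 7:13]            # strict interior
  outer <- dmp[c(1:3, 17:20), ]       # far outside
  expect_true(all(inner == 0))
  expect_true(all(outer == 0))
  ring <- which(lab == 1L & lab2 != 1L)
  expect_true(all(dmp[ring] == 1))
})
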