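# Experience-tier analysis of a discordance matrix: tier-pair distributions,
# rank tests, biclustered heatmap ordering, and 2-D classical MDS.

TIER_LEVELS <- c("SP", "JP", "NP", "AL")

#' Discordance distributions by participant-tier pair
#'
#' Assigns every unique off-diagonal entry of the matrix to exactly one
#' pair class (SP-SP, SP-NP, NP-NP, ...; order-insensitive), so group sizes
#' sum to `choose(n, 2)`.
#'
#' @param m a `discordance_matrix` whose participants carry tiers.
#' @return data frame with columns `pair_class`, `n_pairs`, `median`, `sd`
#'   and a list column `values`.
#' @export
tier_pair_distributions <- function(m) {
  stopifnot(inherits(m, "discordance_matrix"))
  tiers <- m$participants$tier
  if (anyNA(tiers)) stopf("participants must carry tiers")
  n <- nrow(m$values)
  if (n < 2L) stopf("need at least 2 participants")
  pc <- character(0); vv <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      t2 <- sort(factor(c(tiers[i], tiers[j]), levels = TIER_LEVELS))
      pc <- c(pc, paste(t2, collapse = "-"))
      vv <- c(vv, m$values[i, j])
    }
  }
  groups <- split(vv, pc)
  out <- data.frame(
    pair_class = names(groups),
    n_pairs = vapply(groups, length, 0L),
    median = vapply(groups, stats::median, 0),
    sd = vapply(groups, function(v) if (length(v) > 1L) stats::sd(v) else 0, 0),
    stringsAsFactors = FALSE)
  out$values <- I(unname(groups))
  rownames(out) <- NULL
  out
}

#' Mann-Whitney rank test for two unpaired samples
#'
#' The statistic is the Mann-Whitney U for `x` (number of `(x, y)` pairs
#' with `x > y`, ties counting one half). For small samples
#' (`length(x) + length(y) <= 12` by default) the p-value comes from exact
#' enumeration of all group assignments conditional on the observed midranks
#' (so ties are handled exactly); otherwise from the tie-corrected,
#' continuity-corrected normal approximation.
#'
#' @param x,y numeric vectors, each non-empty.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`
#'   (direction of the shift of `x` relative to `y`).
#' @param exact force (`TRUE`) or suppress (`FALSE`) exact enumeration.
#' @return list with `statistic` (U), `p.value`, `exact`, `alternative`,
#'   `method`.
#' @examples
#' rank_test_unpaired(c(1, 2, 3), c(4, 5, 6), alternative = "less")$p.value # 1/20
#' @export
rank_test_unpaired <- function(x, y,
                               alternative = c("two.sided", "less", "greater"),
                               exact = NULL) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stopf("x and y must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (is.null(exact)) exact <- N <= 12
  eps <- 1e-9
  if (exact) {
    sets <- utils::combn(N, n1)
    Us <- colSums(matrix(r[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    p_greater <- mean(Us >= U - eps)
    p_less <- mean(Us <= U + eps)
  } else {
    mu <- n1 * n2 / 2
    tie <- table(r)
    sig <- sqrt(n1 * n2 / 12 * (N + 1 - sum(tie^3 - tie) / (N * (N - 1))))
    if (sig == 0) {           # everything tied
      p_greater <- p_less <- 1
    } else {
      p_greater <- stats::pnorm((U - mu - 0.5) / sig, lower.tail = FALSE)
      p_less <- stats::pnorm((U - mu + 0.5) / sig)
    }
  }
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_greater, p_less)),
              less = p_less, greater = p_greater)
  list(statistic = U, p.value = p, exact = exact, alternative = alternative,
       method = if (exact) "Mann-Whitney U, exact enumeration"
                else "Mann-Whitney U, tie- and continuity-corrected normal approximation")
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (their count is reported). The statistic is
#' the sum of the midranks of positive differences. For `n <= 15` nonzero
#' differences the exact null distribution is computed by convolving the
#' doubled ranks (exact under ties); otherwise the tie-corrected,
#' continuity-corrected normal approximation is used. If every difference
#' is zero the test is degenerate: `p = 1` with `degenerate = TRUE`.
#'
#' @param x,y numeric vectors of equal length.
#' @inheritParams rank_test_unpaired
#' @return list with `statistic` (V), `p.value`, `n_zero`, `degenerate`,
#'   `exact`, `alternative`, `method`.
#' @export
rank_test_paired <- function(x, y,
                             alternative = c("two.sided", "less", "greater"),
                             exact = NULL) {
  alternative <- match.arg(alternative)
  if (length(x) != length(y)) stopf("x and y must have equal length")
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = NA_real_, p.value = 1, n_zero = n_zero,
                degenerate = TRUE, exact = TRUE, alternative = alternative,
                method = "Wilcoxon signed-rank (degenerate: all differences zero)"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (is.null(exact)) exact <- n <= 15
  if (exact) {
    r2 <- as.integer(round(2 * r))          # doubled midranks are integers
    f <- c(1, rep(0, sum(r2)))              # f[k] = P(2V = k - 1)
    for (ri in r2) {
      g <- f / 2
      g[(ri + 1L):length(f)] <- g[(ri + 1L):length(f)] + f[seq_len(length(f) - ri)] / 2
      f <- g
    }
    V2 <- as.integer(round(2 * V))
    p_greater <- sum(f[(V2 + 1L):length(f)])
    p_less <- sum(f[seq_len(V2 + 1L)])
  } else {
    mu <- n * (n + 1) / 4
    tie <- table(r)
    sig <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48)
    p_greater <- stats::pnorm((V - mu - 0.5) / sig, lower.tail = FALSE)
    p_less <- stats::pnorm((V - mu + 0.5) / sig)
  }
  p <- switch(alternative,
              two.sided = min(1, 2 * min(p_greater, p_less)),
              less = p_less, greater = p_greater)
  list(statistic = V, p.value = p, n_zero = n_zero, degenerate = FALSE,
       exact = exact, alternative = alternative,
       method = if (exact) "Wilcoxon signed-rank, exact convolution"
                else "Wilcoxon signed-rank, tie- and continuity-corrected normal approximation")
}

#' Biclustered heatmap leaf order of a discordance matrix
#'
#' Agglomerative hierarchical clustering (average linkage) on the Euclidean
#' distances between participants' discordance profiles (matrix rows).
#' Participants are pre-sorted lexicographically by id so the leaf order is
#' deterministic and invariant to the input row order.
#'
#' @param m a `discordance_matrix` with at least 2 participants.
#' @return character vector: participant ids in leaf order.
#' @export
bicluster_order <- function(m) {
  stopifnot(inherits(m, "discordance_matrix"))
  ids <- m$participants$participant_id
  if (length(ids) < 2L) stopf("need at least 2 participants to cluster")
  o <- order(ids)
  v <- m$values[o, o]
  hc <- stats::hclust(stats::dist(v), method = "average")
  ids[o][hc$order]
}

#' Classical (Torgerson) MDS embedding of a discordance matrix
#'
#' Treats discordance values as distances: double-centering, top-2
#' eigenpairs, coordinates `eigenvector * sqrt(eigenvalue)`. Deterministic
#' (no random initialization). Negative eigenvalues (non-Euclidean part of
#' the discordances) are truncated and their mass reported. Kruskal stress-1
#' of the 2-D configuration is computed against the input.
#'
#' @param m a `discordance_matrix` (symmetric, zero diagonal).
#' @return an `mds_embedding`: list with `coordinates` (data frame
#'   `participant_id`, `x`, `y`), `stress`, `eig`,
#'   `negative_eigenvalue_mass`.
#' @export
mds_embed <- function(m) {
  stopifnot(inherits(m, "discordance_matrix"))
  d <- m$values
  if (!isTRUE(all.equal(d, t(d)))) stopf("discordance matrix must be symmetric")
  n <- nrow(d)
  ids <- m$participants$participant_id
  if (all(d == 0)) {
    coords <- matrix(0, n, 2L)
    eig <- rep(0, n)
  } else {
    fit <- stats::cmdscale(d, k = min(2L, n - 1L), eig = TRUE)
    coords <- fit$points
    if (ncol(coords) < 2L) {
      coords <- cbind(coords, matrix(0, n, 2L - ncol(coords)))
    }
    coords[is.na(coords)] <- 0
    eig <- fit$eig
  }
  emb <- as.matrix(stats::dist(coords))
  stress <- if (sum(d^2) == 0) 0 else sqrt(sum((emb - d)^2) / sum(d^2))
  structure(list(
    coordinates = data.frame(participant_id = ids,
                             x = coords[, 1L], y = coords[, 2L],
                             stringsAsFactors = FALSE),
    stress = stress, eig = eig,
    negative_eigenvalue_mass = sum(abs(pmin(eig, 0)))),
    class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("<mds_embedding> %d participants, stress %.4f\n",
              nrow(x$coordinates), x$stress))
  invisible(x)
}

#' @export
plot.mds_embedding <- function(x, tiers = NULL, ...) {
  co <- x$coordinates
  pch <- 19
  col <- "black"
  if (!is.null(tiers)) {
    f <- factor(tiers, levels = TIER_LEVELS)
    col <- c("#D62728", "#FF7F0E", "#1F77B4", "#2CA02C")[as.integer(f)]
  }
  graphics::plot(co$x, co$y, pch = pch, col = col,
                 xlab = "MDS 1", ylab = "MDS 2", ...)
  graphics::text(co$x, co$y, co$participant_id, pos = 3, cex = 0.6)
  invisible(x)
}
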