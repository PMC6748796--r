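# Independent brute-force oracles and fixture builders. Every oracle here
# recomputes its quantity from first principles, along a different code path
# than the package implementation it checks.

tax8 <- default_taxonomy()

# -- fixtures ---------------------------------------------------------------

random_mask <- function(h, w, codes, taxonomy = tax8) {
  label_mask(matrix(sample(codes, h * w, replace = TRUE), h, w), taxonomy)
}

# star-shaped simple polygon around a random center
random_star_polygon <- function(grid = 64, n_range = 5:12,
                                r_range = c(3, grid * 0.45)) {
  nv <- sample(n_range, 1)
  ang <- sort(stats::runif(nv, 0, 2 * pi))
  rad <- stats::runif(nv, r_range[1], r_range[2])
  cx <- stats::runif(1, grid * 0.2, grid * 0.8)
  cy <- stats::runif(1, grid * 0.2, grid * 0.8)
  cbind(x = cx + rad * cos(ang), y = cy + rad * sin(ang))
}

# -- Eq. counting oracle ----------------------------------------------------

dice_oracle <- function(I, J, class_subset) {
  codes <- I$taxonomy$label_code[match(class_subset, I$taxonomy$class_name)]
  valid <- I$labels > 0 & J$labels > 0
  num <- 0; den <- 0
  for (code in codes) {
    Ic <- I$labels == code & valid
    Jc <- J$labels == code & valid
    num <- num + sum(Ic & Jc)
    den <- den + sum(Ic) + sum(Jc)
  }
  if (den == 0) 0 else 1 - 2 * num / den
}

# -- point-in-polygon oracle (pracma, boundary-inclusive) -------------------

pip_oracle_mask <- function(v, h, w) {
  px <- rep(0:(w - 1), each = h)
  py <- rep(0:(h - 1), w)
  hit <- pracma::inpolygon(px, py, v[, 1], v[, 2], boundary = TRUE)
  m <- matrix(FALSE, h, w)
  m[px * h + py + 1] <- hit
  m
}

# -- connected components by literal flood fill -----------------------------

count_components_oracle <- function(bin, connectivity = 8) {
  h <- nrow(bin); w <- ncol(bin)
  seen <- matrix(FALSE, h, w)
  offs <- if (connectivity == 8) {
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  n <- 0
  for (start in which(bin & !seen)) {
    if (seen[start]) next
    n <- n + 1
    stack <- start
    while (length(stack)) {
      cur <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[cur]) next
      seen[cur] <- TRUE
      r <- (cur - 1) %% h + 1; cc <- (cur - 1) %/% h + 1
      for (k in seq_len(nrow(offs))) {
        r2 <- r + offs[k, 1]; c2 <- cc + offs[k, 2]
        if (r2 >= 1 && r2 <= h && c2 >= 1 && c2 <= w &&
            bin[r2, c2] && !seen[r2, c2]) {
          stack <- c(stack, (c2 - 1) * h + r2)
        }
      }
    }
  }
  as.integer(n)
}

# -- rank-test oracles by literal enumeration -------------------------------

# U recomputed by direct pair counting for every assignment of the pooled
# values into groups of sizes (n1, n2).
mw_enum_oracle <- function(x, y, alternative = "two.sided") {
  pool <- c(x, y)
  n1 <- length(x); N <- length(pool)
  count_u <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U_obs <- count_u(x, y)
  idx <- utils::combn(N, n1)
  Us <- apply(idx, 2, function(ii) count_u(pool[ii], pool[-ii]))
  eps <- 1e-9
  pg <- mean(Us >= U_obs - eps); pl <- mean(Us <= U_obs + eps)
  p <- switch(alternative, two.sided = min(1, 2 * min(pg, pl)),
              less = pl, greater = pg)
  list(statistic = U_obs, p.value = p)
}

# W recomputed per sign pattern from the midranks of |d|.
wsr_enum_oracle <- function(x, y, alternative = "two.sided") {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Vs <- apply(signs, 1, function(s) sum(r[s]))
  eps <- 1e-9
  pg <- mean(Vs >= V_obs - eps); pl <- mean(Vs <= V_obs + eps)
  p <- switch(alternative, two.sided = min(1, 2 * min(pg, pl)),
              less = pl, greater = pg)
  list(statistic = V_obs, p.value = p)
}

# -- AUC by O(n^2) pairwise comparison --------------------------------------

auc_pairwise_oracle <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  if (!length(sp) || !length(sn)) return(NA_real_)
  cmp <- outer(sp, sn, ">") + 0.5 * outer(sp, sn, "==")
  mean(cmp)
}

# -- cohort helpers ---------------------------------------------------------

# roster at the calibration used for tier-recovery checks: SP boundary
# jitter 1 px, NP jitter 4 px with 0.5 miss rate on non-predominant classes
two_tier_roster <- function(n_sp = 4, n_np = 8) {
  sp <- annotator_error_model("SP", boundary_jitter_sigma = 1)
  np <- annotator_error_model("NP", boundary_jitter_sigma = 4,
                              miss_prob = c(predominant = 0,
                                            non_predominant = 0.5,
                                            challenging = 0.5))
  data.frame(
    participant_id = c(sprintf("SP_%02d", seq_len(n_sp)),
                       sprintf("NP_%02d", seq_len(n_np))),
    tier = c(rep("SP", n_sp), rep("NP", n_np)),
    model = I(c(replicate(n_sp, sp, simplify = FALSE),
                replicate(n_np, np, simplify = FALSE))),
    stringsAsFactors = FALSE)
}

# tiny discordance_matrix builder for unit tests
dm_fixture <- function(values, tiers, ids = sprintf("p%02d", seq_len(nrow(values)))) {
  dimnames(values) <- list(ids, ids)
  structure(list(values = values,
                 participants = data.frame(participant_id = ids, tier = tiers,
                                           stringsAsFactors = FALSE),
                 class_subset = "tumor", aggregation = "pooled"),
            class = "discordance_matrix")
}
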