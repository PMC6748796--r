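# Pixel-level evaluation of semantic segmentation predictions and the
# scale-dependent learning-curve harness with a pluggable patch classifier.

#' Per-class score maps for a prediction
#'
#' One real-valued score plane per class on the truth grid; the per-pixel
#' argmax over planes defines the hard prediction.
#'
#' @param scores named list of numeric matrices (one per class), values in
#'   \[0, 1\], all the same shape.
#' @return a `score_map` list with `scores`, `class_names`.
#' @export
score_map <- function(scores) {
  stopifnot(is.list(scores), length(scores) >= 1L, !is.null(names(scores)))
  dims <- dim(scores[[1L]])
  for (s in scores) stopifnot(is.matrix(s), all(dim(s) == dims))
  structure(list(scores = scores, class_names = names(scores)),
            class = "score_map")
}

# Midrank (tie-aware) one-vs-rest AUC of score vector s against logical pos.
rank_auc <- function(s, pos) {
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(s)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' One-vs-rest pixel ROC AUC for one class
#'
#' Rank statistic with midrank tie handling; pixels labeled 0 (outside the
#' ROI) are excluded. A class absent from the truth (or covering it
#' entirely) has no ROC and is reported as `NA`, never 0.
#'
#' @param scores a [score_map()].
#' @param truth a [label_mask()] of the same shape.
#' @param class_name class to evaluate.
#' @return AUC in \[0, 1\], or `NA`.
#' @export
class_auc <- function(scores, truth, class_name) {
  if (!class_name %in% scores$class_names) {
    stopf("no score plane for class '%s'", class_name)
  }
  s <- scores$scores[[class_name]]
  stopifnot(all(dim(s) == dim(truth$labels)))
  valid <- truth$labels > 0L
  rank_auc(s[valid], truth$labels[valid] == tax_code(truth$taxonomy, class_name))
}

argmax_mask <- function(scores, taxonomy) {
  cls <- scores$class_names
  dims <- dim(scores$scores[[1L]])
  best <- matrix(1L, dims[1L], dims[2L])
  bestv <- scores$scores[[1L]]
  for (k in seq_along(cls)[-1L]) {
    s <- scores$scores[[k]]
    upd <- s > bestv
    best[upd] <- k
    bestv[upd] <- s[upd]
  }
  label_mask(matrix(tax_code(taxonomy, cls)[best], dims[1L], dims[2L]),
             taxonomy)
}

#' Evaluate a segmentation prediction against a truth mask
#'
#' Per-class one-vs-rest AUC, Dice and binary accuracy of the argmax
#' prediction; micro-average AUC (all pixel-class score/indicator pairs
#' pooled) and macro-average AUC (unweighted mean of per-class AUCs); and
#' the confusion matrix as percentages of total (in-ROI) pixel count,
#' summing to 100 over all cells.
#'
#' @param scores a [score_map()] whose class names are taxonomy classes.
#' @param truth a [label_mask()] of the same shape.
#' @return a `metrics_report`: list with `per_class` (data frame `class`,
#'   `auc`, `dice`, `accuracy`), `micro_auc`, `macro_auc`, `confusion_pct`.
#' @export
evaluate_prediction <- function(scores, truth) {
  stopifnot(inherits(scores, "score_map"), inherits(truth, "label_mask"))
  stopifnot(all(dim(scores$scores[[1L]]) == dim(truth$labels)))
  tax <- truth$taxonomy
  cls <- scores$class_names
  codes <- tax_code(tax, cls)
  pred <- argmax_mask(scores, tax)
  valid <- truth$labels > 0L
  tv <- truth$labels[valid]; pv <- pred$labels[valid]
  per <- data.frame(class = cls, auc = NA_real_, dice = NA_real_,
                    accuracy = NA_real_, stringsAsFactors = FALSE)
  pooled_s <- numeric(0); pooled_i <- logical(0)
  for (k in seq_along(cls)) {
    sv <- scores$scores[[k]][valid]
    pos <- tv == codes[k]
    per$auc[k] <- rank_auc(sv, pos)
    inter <- sum(pos & pv == codes[k])
    den <- sum(pos) + sum(pv == codes[k])
    per$dice[k] <- if (den == 0L) NA_real_ else 2 * inter / den
    per$accuracy[k] <- mean(pos == (pv == codes[k]))
    pooled_s <- c(pooled_s, sv); pooled_i <- c(pooled_i, pos)
  }
  conf <- table(factor(tv, levels = codes, labels = cls),
                factor(pv, levels = codes, labels = cls))
  conf <- 100 * conf / sum(conf)
  structure(list(per_class = per,
                 micro_auc = rank_auc(pooled_s, pooled_i),
                 macro_auc = mean(per$auc, na.rm = TRUE),
                 confusion_pct = conf),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_class, digits = 3)
  cat(sprintf("micro AUC %.3f | macro AUC %.3f\n", x$micro_auc, x$macro_auc))
  invisible(x)
}

#' Collapse a taxonomy mask to the five-way evaluation scheme
#'
#' Tumor, stroma, inflammatory infiltrates, necrosis, other: every taxonomy
#' class outside the four named tissue classes maps to `"other"`. The
#' mapping is overridable.
#'
#' @param mask a [label_mask()].
#' @param mapping named character vector `taxonomy class -> five-way class`;
#'   defaults to the canonical collapse.
#' @return a [label_mask()] over the five-class taxonomy (stroma default).
#' @export
map_to_five <- function(mask, mapping = NULL) {
  tax <- mask$taxonomy
  five <- five_class_taxonomy()
  if (is.null(mapping)) {
    mapping <- stats::setNames(rep("other", nrow(tax)), tax$class_name)
    for (cn in c("tumor", "stroma", "necrosis")) {
      if (cn %in% tax$class_name) mapping[cn] <- cn
    }
    if ("lymphocytic_infiltrate" %in% tax$class_name) {
      mapping["lymphocytic_infiltrate"] <- "inflammatory"
    }
  }
  lut <- integer(256)
  lut[tax$label_code + 1L] <- tax_code(five, mapping[tax$class_name])
  labels <- matrix(lut[mask$labels + 1L], nrow(mask$labels), ncol(mask$labels))
  label_mask(labels, five)
}

#' @rdname map_to_five
#' @export
five_class_taxonomy <- function() {
  class_taxonomy(
    class_name = c("tumor", "stroma", "inflammatory", "necrosis", "other"),
    tier = c("predominant", "predominant", "predominant", "predominant",
             "non_predominant"),
    label_code = 1:5,
    color = c("#FF0000", "#FFC8C8", "#00FFFF", "#FFFF00", "#808080"),
    default_class = "stroma")
}

#' Render a label mask as a synthetic RGB image
#'
#' Each class gets its taxonomy color plus i.i.d. Gaussian pixel noise and
#' an optional per-image (stain-like) channel shift; values clipped to
#' \[0, 1\]. A deliberately simple stand-in for H&E appearance used by the
#' learning-curve harness.
#'
#' @param mask a [label_mask()].
#' @param noise_sd pixel noise standard deviation.
#' @param channel_shift length-3 additive shift emulating slide-level stain
#'   variation.
#' @param seed integer seed.
#' @return `height x width x 3` numeric array in \[0, 1\].
#' @export
render_rgb <- function(mask, noise_sd = 0.1, channel_shift = c(0, 0, 0),
                       seed = NULL) {
  tax <- mask$taxonomy
  rgbm <- grDevices::col2rgb(tax$color) / 255
  with_local_seed(seed, {
    h <- nrow(mask$labels); w <- ncol(mask$labels)
    idx <- match(mask$labels, tax$label_code)
    idx[is.na(idx)] <- which(tax$is_default)   # outside-ROI: default color
    img <- array(0, c(h, w, 3L))
    for (ch in 1:3) {
      img[, , ch] <- pmin(1, pmax(0, rgbm[ch, idx] + channel_shift[ch] +
                                    stats::rnorm(h * w, 0, noise_sd)))
    }
    img
  })
}

#' Extract labeled patches from an image/mask pair
#'
#' Tiles the grid (stride defaults to the patch size), labels each patch
#' with the modal in-ROI class of its mask window, and keeps patches whose
#' modal-class fraction is at least `purity`.
#'
#' @param image `H x W x 3` array.
#' @param mask a [label_mask()] on the same grid.
#' @param patch_px patch side in pixels (>= 8).
#' @param purity minimal modal-class fraction in \[0, 1\].
#' @param stride tiling stride in pixels.
#' @return list with `patches` (list of arrays), `labels` (character),
#'   `x0`, `y0` (0-based top-left corners).
#' @export
extract_patches <- function(image, mask, patch_px, purity = 0.9,
                            stride = patch_px) {
  stopifnot(patch_px >= 8, all(dim(image)[1:2] == dim(mask$labels)))
  h <- nrow(mask$labels); w <- ncol(mask$labels)
  ys <- seq(1L, h - patch_px + 1L, by = stride)
  xs <- seq(1L, w - patch_px + 1L, by = stride)
  patches <- list(); labels <- character(0); px0 <- integer(0); py0 <- integer(0)
  for (y in ys) {
    for (x in xs) {
      win <- mask$labels[y:(y + patch_px - 1L), x:(x + patch_px - 1L)]
      win <- win[win > 0L]
      if (!length(win)) next
      tab <- table(win)
      frac <- max(tab) / length(win)
      if (frac < purity) next
      code <- as.integer(names(tab)[which.max(tab)])
      patches[[length(patches) + 1L]] <-
        image[y:(y + patch_px - 1L), x:(x + patch_px - 1L), , drop = FALSE]
      labels <- c(labels, tax_class(mask$taxonomy, code))
      px0 <- c(px0, x - 1L); py0 <- c(py0, y - 1L)
    }
  }
  list(patches = patches, labels = labels, x0 = px0, y0 = py0)
}

#' Shift-and-crop augmentation of a patch
#'
#' Random integer translation up to `max_shift_px` in each axis, then a
#' center crop back to the original size (borders filled by edge
#' replication). Deterministic given `seed`.
#'
#' @param patch `h x w x c` array.
#' @param max_shift_px maximal absolute shift.
#' @param seed integer seed.
#' @return array of the same dimensions.
#' @export
shift_crop_augment <- function(patch, max_shift_px, seed = NULL) {
  with_local_seed(seed, {
    if (max_shift_px == 0) return(patch)
    h <- dim(patch)[1L]; w <- dim(patch)[2L]
    dx <- sample(-max_shift_px:max_shift_px, 1L)
    dy <- sample(-max_shift_px:max_shift_px, 1L)
    ri <- pmin(pmax(seq_len(h) + dy, 1L), h)
    ci <- pmin(pmax(seq_len(w) + dx, 1L), w)
    patch[ri, ci, , drop = FALSE]
  })
}

# Pooled color + gradient features of one patch: channel means, channel
# standard deviations, mean absolute gradient per channel.
patch_features <- function(patch) {
  f <- numeric(0)
  for (ch in seq_len(dim(patch)[3L])) {
    p <- patch[, , ch]
    grad <- mean(abs(diff(p))) + mean(abs(t(diff(t(p)))))
    f <- c(f, mean(p), stats::sd(p), grad)
  }
  f
}

#' Baseline regularized multinomial patch classifier
#'
#' A deliberately shallow reference classifier for the learning-curve
#' harness: pooled color + gradient features fed to a ridge-regularized
#' multinomial linear model (glmnet). Implements the pluggable interface
#' `fit(x, y) -> model`, `score(model, x) -> score matrix`.
#'
#' @param lambda ridge penalty.
#' @return list with functions `fit` and `score`.
#' @export
baseline_patch_classifier <- function(lambda = 0.01) {
  list(
    fit = function(x, y) {
      all_levels <- sort(unique(y))
      tab <- table(y)
      keep <- names(tab)[tab >= 2L]        # glmnet needs >= 2 obs per class
      if (length(keep) < 2L) {
        return(list(constant = TRUE, levels = all_levels))
      }
      sel <- y %in% keep
      list(fit = suppressWarnings(                 # tiny classes are expected
             glmnet::glmnet(x[sel, , drop = FALSE], factor(y[sel]),
                            family = "multinomial", alpha = 0,
                            lambda = lambda)),
           fitted_levels = keep, levels = all_levels)
    },
    score = function(model, x) {
      out <- matrix(0, nrow(x), length(model$levels),
                    dimnames = list(NULL, model$levels))
      if (isTRUE(model$constant)) return(out)
      pr <- predict(model$fit, x, type = "response")[, , 1L]
      if (is.null(dim(pr))) {
        pr <- matrix(pr, nrow = 1L, dimnames = list(NULL, model$fitted_levels))
      }
      out[, colnames(pr)] <- pr            # unseen classes score 0
      out
    })
}

# Macro-average one-vs-rest AUC of a score matrix against labels.
macro_auc_scores <- function(scores, labels) {
  cls <- union(colnames(scores), unique(labels))
  aucs <- vapply(cls, function(cn) {
    s <- if (cn %in% colnames(scores)) scores[, cn] else rep(0, length(labels))
    rank_auc(s, labels == cn)
  }, 0)
  mean(aucs, na.rm = TRUE)
}

#' Learning curve: accuracy vs number of training slides
#'
#' Emulates the scale-dependent experiment: for each training-set size `n`
#' and replicate, `n` slides are sampled without replacement from the
#' training institutes, a patch classifier is fitted on their patches, and
#' macro-average AUC is measured on patches from held-out slides. Train and
#' test slides are strictly separated by institute, mirroring the design
#' where generalization across contributing institutions is the quantity of
#' interest.
#'
#' @param bundle a [simulate_cohort()] bundle with core ROIs (one ROI per
#'   slide); truth masks are collapsed with [map_to_five()] and rendered to
#'   RGB with slide-level stain shifts.
#' @param classifier a classifier interface such as
#'   [baseline_patch_classifier()].
#' @param slide_counts integer vector of training-set sizes.
#' @param replicates replicates per size.
#' @param seed master seed (slide sampling, rendering noise).
#' @param patch_px,purity,stride passed to [extract_patches()].
#' @param noise_sd,stain_sd pixel noise and slide-level stain-shift sds for
#'   [render_rgb()].
#' @param test_fraction approximate fraction of slides held out (whole
#'   institutes are held out until this fraction is reached).
#' @return data frame with columns `n_slides`, `replicate`, `macro_auc`.
#' @export
learning_curve <- function(bundle, classifier = baseline_patch_classifier(),
                           slide_counts = c(2, 4, 8, 16), replicates = 10,
                           seed = 1, patch_px = 16, purity = 0.8,
                           stride = patch_px, noise_sd = 0.12,
                           stain_sd = 0.06, test_fraction = 0.25) {
  rois <- bundle$rois[bundle$rois$set_membership == "core", ]
  if (!nrow(rois)) stopf("bundle has no core ROIs")
  insts <- sort(unique(rois$institute_id))
  n_test_target <- ceiling(test_fraction * nrow(rois))
  test_inst <- character(0)
  for (ins in rev(insts)) {
    if (sum(rois$institute_id %in% test_inst) >= n_test_target) break
    test_inst <- c(test_inst, ins)
  }
  test_ids <- rois$roi_id[rois$institute_id %in% test_inst]
  train_pool <- setdiff(rois$roi_id, test_ids)
  if (max(slide_counts) > length(train_pool)) {
    stopf("largest slide count (%d) exceeds the %d available training slides",
          max(slide_counts), length(train_pool))
  }
  # per-slide feature tables, computed once
  feats <- list(); labs <- list()
  for (i in seq_len(nrow(rois))) {
    rid <- rois$roi_id[i]
    m5 <- map_to_five(bundle$truth_masks[[rid]])
    shift <- with_local_seed(derive_seed(seed, 4L, i),
                             stats::rnorm(3, 0, stain_sd))
    img <- render_rgb(m5, noise_sd = noise_sd, channel_shift = shift,
                      seed = derive_seed(seed, 5L, i))
    pc <- extract_patches(img, m5, patch_px, purity = purity, stride = stride)
    if (!length(pc$patches)) next
    feats[[rid]] <- t(vapply(pc$patches, patch_features,
                             numeric(3L * dim(pc$patches[[1L]])[3L])))
    labs[[rid]] <- pc$labels
  }
  test_x <- do.call(rbind, feats[test_ids])
  test_y <- unlist(labs[test_ids], use.names = FALSE)
  out <- data.frame(n_slides = integer(0), replicate = integer(0),
                    macro_auc = numeric(0))
  for (n in slide_counts) {
    for (rep_i in seq_len(replicates)) {
      tr <- with_local_seed(derive_seed(seed, 6L, n, rep_i),
                            sample(train_pool, n))
      x <- do.call(rbind, feats[tr])
      y <- unlist(labs[tr], use.names = FALSE)
      model <- classifier$fit(x, y)
      sc <- classifier$score(model, test_x)
      out <- rbind(out, data.frame(n_slides = n, replicate = rep_i,
                                   macro_auc = macro_auc_scores(sc, test_y)))
    }
  }
  out
}
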