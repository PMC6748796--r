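# Multi-class Dice discordance between label masks.
#
# For masks I, J viewed as binary channels I_c, J_c over a class subset,
#   discordance = 1 - 2 * sum_c |I_c & J_c| / sum_c (|I_c| + |J_c|),
# in [0, 1], 0 meaning no discordance. Pixels labeled 0 (outside the ROI)
# in either mask are excluded from all counts.

# Raw Eq. counts; the building block every aggregation reuses.
dice_counts <- function(I, J, codes) {
  stopifnot(all(dim(I$labels) == dim(J$labels)))
  valid <- I$labels > 0L & J$labels > 0L
  a <- I$labels[valid]; b <- J$labels[valid]
  ina <- a %in% codes
  list(num = sum(ina & a == b), den = sum(ina) + sum(b %in% codes))
}

#' Multi-class Dice discordance between two masks
#'
#' @param I,J [label_mask()]s of the same shape and taxonomy.
#' @param class_subset character vector of class names to pool over; the
#'   default class is an ordinary channel when listed. Defaults to every
#'   non-meta class.
#' @return discordance in \[0, 1\]; 0 iff the masks agree at every pixel of
#'   the subset's channels. When neither mask contains any subset pixel the
#'   value is 0 (vacuous agreement), flagged with attribute `vacuous` and a
#'   warning.
#' @examples
#' tax <- default_taxonomy()
#' m <- label_mask(matrix(1L, 4, 4), tax)
#' dice_discordance(m, m)                       # 0
#' @export
dice_discordance <- function(I, J, class_subset = classes_preset(I$taxonomy)) {
  if (!length(class_subset)) stopf("class_subset must be non-empty")
  codes <- tax_code(I$taxonomy, class_subset)
  ct <- dice_counts(I, J, codes)
  if (ct$den == 0L) {
    warning("no pixels of the class subset in either mask; discordance 0 (vacuous)")
    return(structure(0, vacuous = TRUE))
  }
  1 - 2 * ct$num / ct$den
}

#' Single-class (binary) discordance
#'
#' Eq. restricted to one channel: `1 - 2|A n B| / (|A| + |B|)`, i.e. one
#' minus the Sorensen-Dice similarity of the binary class masks. A class
#' absent from both masks gives 0 with a `vacuous` attribute; absent from
#' exactly one gives 1.
#'
#' @inheritParams dice_discordance
#' @param class_name a single taxonomy class.
#' @return discordance in \[0, 1\].
#' @export
per_class_discordance <- function(I, J, class_name) {
  stopifnot(length(class_name) == 1L)
  ct <- dice_counts(I, J, tax_code(I$taxonomy, class_name))
  if (ct$den == 0L) return(structure(0, vacuous = TRUE))
  1 - 2 * ct$num / ct$den
}

#' Discordance between pre- and post-correction masks
#'
#' Measures how much expert correction overlays changed a participant's
#' rendered mask: the Dice discordance of the mask before vs after
#' [apply_corrections()]. No corrections gives 0.
#'
#' @param pre,post [label_mask()]s before and after patching.
#' @param class_subset classes to pool over (default all non-meta).
#' @return discordance in \[0, 1\].
#' @export
correction_discordance <- function(pre, post,
                                   class_subset = classes_preset(pre$taxonomy)) {
  dice_discordance(pre, post, class_subset)
}

#' Pairwise inter-participant discordance matrix
#'
#' @param masks named list: `participant_id -> named list: roi_id ->`
#'   [label_mask()]. Every participant must supply a mask for every shared
#'   ROI (a missing mask is an error naming the participant and ROI).
#' @param class_subset classes to pool over.
#' @param aggregation `"pooled"` sums the Eq. numerator and denominator over
#'   all ROIs before taking the ratio (the literal reading of the statistic
#'   applied to stacked channels); `"per_roi_median"` takes the median of
#'   per-ROI values.
#' @param participants optional data frame with columns `participant_id`,
#'   `tier` (needed downstream by [tier_pair_distributions()]).
#' @return a `discordance_matrix`: list with `values` (symmetric, zero
#'   diagonal, entries in \[0, 1\]), `participants`, `class_subset`,
#'   `aggregation`.
#' @export
pairwise_discordance <- function(masks, class_subset = NULL,
                                 aggregation = c("pooled", "per_roi_median"),
                                 participants = NULL) {
  aggregation <- match.arg(aggregation)
  ids <- names(masks)
  if (is.null(ids) || anyDuplicated(ids)) {
    stopf("masks must be a named list with unique participant ids")
  }
  roi_ids <- Reduce(union, lapply(masks, names))
  for (id in ids) {
    missing <- setdiff(roi_ids, names(masks[[id]]))
    if (length(missing)) {
      stopf("participant '%s' has no mask for ROI '%s'", id, missing[1L])
    }
  }
  tax <- masks[[1L]][[1L]]$taxonomy
  if (is.null(class_subset)) class_subset <- classes_preset(tax)
  codes <- tax_code(tax, class_subset)
  n <- length(ids)
  vals <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      num <- 0; den <- 0; per_roi <- numeric(length(roi_ids))
      for (k in seq_along(roi_ids)) {
        ct <- dice_counts(masks[[i]][[roi_ids[k]]], masks[[j]][[roi_ids[k]]],
                          codes)
        num <- num + ct$num; den <- den + ct$den
        per_roi[k] <- if (ct$den == 0L) 0 else 1 - 2 * ct$num / ct$den
      }
      vals[i, j] <- vals[j, i] <-
        if (aggregation == "pooled") {
          if (den == 0L) 0 else 1 - 2 * num / den
        } else stats::median(per_roi)
    }
  }
  if (is.null(participants)) {
    participants <- data.frame(participant_id = ids, tier = NA_character_,
                               stringsAsFactors = FALSE)
  }
  participants <- participants[match(ids, participants$participant_id), ,
                               drop = FALSE]
  structure(list(values = vals, participants = participants,
                 class_subset = class_subset, aggregation = aggregation),
            class = "discordance_matrix")
}

#' @export
print.discordance_matrix <- function(x, ...) {
  n <- nrow(x$values)
  cat(sprintf("<discordance_matrix> %d participants, %d unique pairs (%s, classes: %s)\n",
              n, choose(n, 2), x$aggregation,
              paste(x$class_subset, collapse = ", ")))
  ut <- x$values[upper.tri(x$values)]
  cat(sprintf("  discordance: median %.3f, range [%.3f, %.3f]\n",
              stats::median(ut), min(ut), max(ut)))
  invisible(x)
}

#' Plot a biclustered discordance heatmap
#'
#' Rows and columns reordered by [bicluster_order()] so participants with
#' similar discordance profiles sit together.
#'
#' @param x a `discordance_matrix`.
#' @param ... passed to [graphics::image()].
#' @export
plot.discordance_matrix <- function(x, ...) {
  ord <- match(bicluster_order(x), x$participants$participant_id)
  v <- x$values[ord, ord]
  n <- nrow(v)
  graphics::image(seq_len(n), seq_len(n), t(v[n:1, ]),
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "", ...)
  graphics::axis(1, seq_len(n), colnames(v), las = 2, cex.axis = 0.7)
  graphics::axis(2, seq_len(n), rev(rownames(v)), las = 2, cex.axis = 0.7)
  invisible(x)
}

#' Pixel-wise disagreement map between two participant groups
#'
#' For every pixel, the fraction of cross pairs (one mask from each group)
#' whose labels differ there. Highlights whether discordance concentrates at
#' region boundaries or follows a diffuse spatial pattern.
#'
#' @param group_a,group_b non-empty lists of [label_mask()]s of one ROI
#'   (many participants), all sharing a shape.
#' @return a `disagreement_map`: list with `values` (matrix in \[0, 1\]) and
#'   `pair_population` (description string).
#' @export
disagreement_map <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b)) stopf("groups must be non-empty")
  dims <- dim(group_a[[1L]]$labels)
  acc <- matrix(0, dims[1L], dims[2L])
  for (a in group_a) {
    stopifnot(all(dim(a$labels) == dims))
    for (b in group_b) {
      stopifnot(all(dim(b$labels) == dims))
      acc <- acc + (a$labels != b$labels)
    }
  }
  structure(list(values = acc / (length(group_a) * length(group_b)),
                 pair_population = sprintf("%d x %d cross pairs",
                                           length(group_a), length(group_b))),
            class = "disagreement_map")
}
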