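# Synthetic multi-annotator cohorts: ground-truth tissue scenes, per-tier
# annotator error models (boundary jitter, class confusion, region misses),
# simulated reviewer corrections, and full study bundles.

#' Specification of a synthetic ground-truth tissue scene
#'
#' Scenes emulate a breast-tumor ROI: smooth connected blobs of the
#' predominant classes over a default-class (stroma) background, plus a few
#' small non-predominant regions to exercise miss-rate machinery. Defaults
#' reflect tumor-dense ROI selection: tumor is the largest non-default
#' component.
#'
#' @param height,width scene size in pixels.
#' @param class_mixture named numeric vector of target area fractions per
#'   class (fractions in \[0, 1\], summing to <= 1; remainder is the default
#'   class).
#' @param region_scale characteristic blob size in pixels (> 0).
#' @param n_nonpredominant_regions number of small rare-class blobs to
#'   inject.
#' @param rare_class class used for those blobs; default: the taxonomy's
#'   first non-predominant class.
#' @param rare_radius blob radius in pixels.
#' @param min_region_px connected components smaller than this are melted
#'   back into the default class (annotators do not trace few-pixel
#'   slivers).
#' @param seed integer seed making the scene reproducible.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(height = 96, width = 96,
                       class_mixture = c(tumor = 0.35,
                                         lymphocytic_infiltrate = 0.15,
                                         necrosis = 0.10),
                       region_scale = 20, n_nonpredominant_regions = 2,
                       rare_class = NULL, rare_radius = 4,
                       min_region_px = 16, seed = NULL) {
  stopifnot(region_scale > 0, height > 0, width > 0)
  if (length(class_mixture)) {
    stopifnot(!is.null(names(class_mixture)),
              all(class_mixture >= 0), all(class_mixture <= 1))
    if (sum(class_mixture) > 1) {
      stopf("infeasible mixture: fractions sum to %.3f > 1", sum(class_mixture))
    }
  }
  structure(list(height = as.integer(height), width = as.integer(width),
                 class_mixture = class_mixture,
                 region_scale = region_scale,
                 n_nonpredominant_regions = as.integer(n_nonpredominant_regions),
                 rare_class = rare_class, rare_radius = rare_radius,
                 min_region_px = as.integer(min_region_px), seed = seed),
            class = "scene_spec")
}

#' Tier-dependent annotator error model
#'
#' Models the three dominant error types of region annotation: (i) imprecise
#' region boundaries (smoothed Gaussian vertex jitter along boundary
#' normals), (ii) region misclassification (a row-stochastic confusion
#' matrix over class names), and (iii) missing annotations, with a miss
#' probability per class tier (rarer classes get missed more by less
#' experienced annotators).
#'
#' @param tier `"SP"`, `"JP"` or `"NP"`.
#' @param boundary_jitter_sigma jitter standard deviation in pixels.
#' @param vertex_spacing boundary resampling interval in pixels.
#' @param confusion named row-stochastic matrix over class names, or `NULL`
#'   for the identity (no misclassification).
#' @param miss_prob named numeric: probability of omitting a region of a
#'   `predominant` / `non_predominant` / `challenging` class entirely.
#' @param seed integer seed.
#' @return an `annotator_error_model` list.
#' @export
annotator_error_model <- function(tier = c("SP", "JP", "NP"),
                                  boundary_jitter_sigma = 1,
                                  vertex_spacing = 3,
                                  confusion = NULL,
                                  miss_prob = c(predominant = 0,
                                                non_predominant = 0,
                                                challenging = 0),
                                  seed = NULL) {
  tier <- match.arg(tier)
  stopifnot(boundary_jitter_sigma >= 0, vertex_spacing > 0,
            all(miss_prob >= 0), all(miss_prob <= 1))
  if (!is.null(confusion)) {
    stopifnot(is.matrix(confusion), nrow(confusion) == ncol(confusion))
    if (any(abs(rowSums(confusion) - 1) > 1e-8)) {
      stopf("confusion rows must sum to 1")
    }
  }
  structure(list(tier = tier, boundary_jitter_sigma = boundary_jitter_sigma,
                 vertex_spacing = vertex_spacing, confusion = confusion,
                 miss_prob = miss_prob, seed = seed),
            class = "annotator_error_model")
}

# Confusion matrix that leaks probability p from every non-default class
# toward the default class (under-calling, the commonest simulated mistake).
confusion_toward_default <- function(taxonomy, p) {
  cls <- taxonomy$class_name
  cm <- diag(length(cls))
  dimnames(cm) <- list(cls, cls)
  if (p > 0) {
    dflt <- default_class_name(taxonomy)
    for (cn in setdiff(cls, dflt)) {
      cm[cn, cn] <- 1 - p
      cm[cn, dflt] <- cm[cn, dflt] + p
    }
  }
  cm
}

#' Default simulated participant roster
#'
#' 3 SPs, 3 JPs and 6 NPs with tier-graded error levels: boundary jitter 1,
#' 2 and 4 px; non-predominant miss rates 0.05, 0.2 and 0.5; challenging
#' miss rates 0.2, 0.6 and 0.9; and mild confusion toward the default class
#' (0, 0.02, 0.05).
#'
#' @param n_sp,n_jp,n_np participants per tier.
#' @param taxonomy the [class_taxonomy()] confusion matrices are built over.
#' @return data frame with columns `participant_id`, `tier` and a list
#'   column `model` of [annotator_error_model()]s.
#' @export
default_roster <- function(n_sp = 3, n_jp = 3, n_np = 6,
                           taxonomy = default_taxonomy()) {
  mk <- function(tier, n, jitter, miss, conf_p) {
    conf <- confusion_toward_default(taxonomy, conf_p)
    lapply(seq_len(n), function(i) {
      list(participant_id = sprintf("%s_%02d", tier, i), tier = tier,
           model = annotator_error_model(tier, boundary_jitter_sigma = jitter,
                                         confusion = conf, miss_prob = miss))
    })
  }
  rows <- c(
    mk("SP", n_sp, 1, c(predominant = 0, non_predominant = 0.05,
                        challenging = 0.2), 0),
    mk("JP", n_jp, 2, c(predominant = 0, non_predominant = 0.2,
                        challenging = 0.6), 0.02),
    mk("NP", n_np, 4, c(predominant = 0, non_predominant = 0.5,
                        challenging = 0.9), 0.05))
  data.frame(
    participant_id = vapply(rows, `[[`, "", "participant_id"),
    tier = vapply(rows, `[[`, "", "tier"),
    model = I(lapply(rows, `[[`, "model")),
    stringsAsFactors = FALSE)
}

# Smoothed standard-normal random field (separable Gaussian blur of white
# noise, circularly padded), standardized to mean 0 / sd 1.
gaussian_field <- function(h, w, scale) {
  sigma <- max(scale / 3, 0.75)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-half:half, sd = sigma)
  kern <- kern / sum(kern)
  z <- matrix(stats::rnorm(h * w), h, w)
  z <- stats::filter(z, kern, circular = TRUE)              # down columns
  z <- t(stats::filter(t(z), kern, circular = TRUE))        # along rows
  z <- matrix(as.numeric(z), h, w)
  (z - mean(z)) / stats::sd(z)
}

#' Generate a ground-truth tissue scene
#'
#' Thresholded smoothed-noise blob process: for each class in the mixture a
#' fresh smooth random field is generated and the class claims its target
#' fraction of the still-unassigned pixels with the highest field values
#' (realized fractions are exact up to ties). Remaining pixels are the
#' default class. Small rare-class disks are then injected.
#'
#' @param spec a [scene_spec()].
#' @param taxonomy a [class_taxonomy()].
#' @return a [label_mask()]; deterministic given `spec$seed`.
#' @export
generate_scene <- function(spec, taxonomy = default_taxonomy()) {
  stopifnot(inherits(spec, "scene_spec"))
  with_local_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    labels <- matrix(default_code(taxonomy), h, w)
    avail <- matrix(TRUE, h, w)
    total <- h * w
    for (cn in names(spec$class_mixture)) {
      n_target <- round(spec$class_mixture[[cn]] * total)
      if (n_target == 0) next
      n_target <- min(n_target, sum(avail))
      field <- gaussian_field(h, w, spec$region_scale)
      vals <- field[avail]
      thr <- sort(vals, decreasing = TRUE)[n_target]
      sel <- avail & field >= thr
      labels[sel] <- tax_code(taxonomy, cn)
      avail[sel] <- FALSE
    }
    if (spec$min_region_px > 1L) {
      dflt <- default_code(taxonomy)
      for (code in setdiff(unique(as.vector(labels)), dflt)) {
        comp <- label_components(labels == code, connectivity = 8)
        if (max(comp) == 0L) next
        sizes <- tabulate(comp[comp > 0L])
        small <- which(sizes < spec$min_region_px)
        if (length(small)) labels[comp %in% small] <- dflt
      }
    }
    if (spec$n_nonpredominant_regions > 0) {
      rare <- spec$rare_class %||%
        taxonomy$class_name[taxonomy$tier == "non_predominant"][1L]
      if (is.na(rare)) stopf("taxonomy has no non-predominant class for rare blobs")
      code <- tax_code(taxonomy, rare)
      xg <- matrix(rep(0:(w - 1L), each = h), h, w)
      yg <- matrix(rep(0:(h - 1L), w), h, w)
      for (k in seq_len(spec$n_nonpredominant_regions)) {
        cx <- stats::runif(1, spec$rare_radius, w - 1 - spec$rare_radius)
        cy <- stats::runif(1, spec$rare_radius, h - 1 - spec$rare_radius)
        labels[(xg - cx)^2 + (yg - cy)^2 <= spec$rare_radius^2] <- code
      }
    }
    label_mask(labels, taxonomy)
  })
}

#' Trace a scene into ground-truth annotations
#'
#' Extracts the connected regions of every non-default class and turns
#' their boundary polygons into an [annotation_set()] (larger regions drawn
#' first so nested regions overwrite correctly under later-drawn-wins).
#' Rendering the result reproduces the scene up to boundary pixels.
#'
#' @param mask a [label_mask()] scene.
#' @param roi optional [roi()]; synthesized from the mask dimensions if
#'   omitted.
#' @param participant_id id for the synthetic "truth" annotator.
#' @return an [annotation_set()].
#' @export
scene_to_truth_annotations <- function(mask, roi = NULL,
                                       participant_id = "truth") {
  regs <- extract_regions(mask)
  if (is.null(roi)) {
    roi <- roi("scene", width = ncol(mask$labels), height = nrow(mask$labels),
               set_membership = "evaluation")
  }
  p <- participant(participant_id, "SP")
  if (!nrow(regs)) return(annotation_set(roi, p, list()))
  ord <- order(regs$area_px, decreasing = TRUE)
  polys <- lapply(seq_along(ord), function(i) {
    k <- ord[i]
    polygon_annotation(regs$class_name[k], regs$polygon[[k]], participant_id,
                       draw_order = i - 1L)
  })
  annotation_set(roi, p, polys)
}

# Resample a closed polygon at roughly even arclength spacing.
resample_polygon <- function(v, spacing) {
  vc <- rbind(v, v[1L, ])
  seg <- sqrt(diff(vc[, 1])^2 + diff(vc[, 2])^2)
  per <- sum(seg)
  if (per == 0) return(v)
  s <- c(0, cumsum(seg))
  n_new <- max(4L, round(per / spacing))
  t_new <- seq(0, per, length.out = n_new + 1L)[-(n_new + 1L)]
  cbind(x = stats::approx(s, vc[, 1], t_new)$y,
        y = stats::approx(s, vc[, 2], t_new)$y)
}

# Does any pair of non-adjacent edges intersect? (vectorized orientation test)
is_simple_polygon <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(TRUE)
  a <- v; b <- v[c(2:n, 1L), ]
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  adj <- (j - i == 1L) | (i == 1L & j == n)
  i <- i[!adj]; j <- j[!adj]
  if (!length(i)) return(TRUE)
  o <- function(px, py, qx, qy, rx, ry) {
    sign((qx - px) * (ry - py) - (qy - py) * (rx - px))
  }
  d1 <- o(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
  d2 <- o(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
  d3 <- o(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
  d4 <- o(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
  !any(d1 != d2 & d3 != d4)
}

# Circular moving average, then rescale back to the target marginal sd so
# smoothing does not shrink the jitter amplitude.
smooth_circular <- function(e, k = 5L, target_sd = stats::sd(e)) {
  n <- length(e)
  if (n < 3L || k < 2L) return(e)
  k <- min(k, n)
  kern <- rep(1 / k, k)
  sm <- stats::filter(e, kern, circular = TRUE)
  sm <- as.numeric(sm)
  s <- stats::sd(sm)
  if (s > 0 && target_sd > 0) sm <- sm * (target_sd / s)
  sm
}

# Outward unit normals at each vertex of a closed polygon (from the central
# difference tangent).
vertex_normals <- function(v) {
  n <- nrow(v)
  nx <- v[c(2:n, 1L), ] - v[c(n, 1:(n - 1L)), ]
  len <- sqrt(rowSums(nx^2))
  len[len == 0] <- 1
  cbind(nx[, 2] / len, -nx[, 1] / len)
}

#' Simulate one annotator's rendition of ground-truth annotations
#'
#' For each truth polygon: drop it with the miss probability of its class's
#' tier; otherwise relabel it by sampling the confusion row of its true
#' class; then perturb the boundary by resampling vertices at
#' `vertex_spacing` and displacing them along vertex normals by smoothed
#' Gaussian noise (sd = `boundary_jitter_sigma`). Perturbations producing a
#' self-intersecting polygon are redrawn (up to 5 attempts, then the
#' original boundary is kept jitter-free). Deterministic given `seed`.
#'
#' @param truth an [annotation_set()] of ground-truth polygons.
#' @param model an [annotator_error_model()].
#' @param taxonomy a [class_taxonomy()] (supplies class tiers).
#' @param participant the simulated [participant()]; defaults to an id
#'   derived from the model tier.
#' @param seed integer seed (defaults to `model$seed`).
#' @return an [annotation_set()] for the simulated participant.
#' @export
simulate_annotator <- function(truth, model, taxonomy = default_taxonomy(),
                               participant = NULL, seed = model$seed) {
  stopifnot(inherits(truth, "annotation_set"),
            inherits(model, "annotator_error_model"))
  if (is.null(participant)) {
    participant <- participant(paste0("sim_", model$tier), model$tier)
  }
  with_local_seed(seed, {
    polys <- list()
    ord <- order(vapply(truth$polygons, function(p) p$draw_order, 0L))
    for (p in truth$polygons[ord]) {
      tier_of_class <- taxonomy$tier[match(p$class_name, taxonomy$class_name)]
      pm <- model$miss_prob[[tier_of_class]] %||% 0
      if (stats::runif(1) < pm) next
      cls <- p$class_name
      if (!is.null(model$confusion) && cls %in% rownames(model$confusion)) {
        cls <- sample(colnames(model$confusion), 1L,
                      prob = model$confusion[cls, ])
      }
      v <- p$vertices
      if (model$boundary_jitter_sigma > 0) {
        v0 <- resample_polygon(p$vertices, model$vertex_spacing)
        v <- v0
        # self-intersecting draws are rejected and redrawn; the amplitude is
        # damped on successive retries so high-curvature boundaries still
        # receive jitter instead of silently coming out perfect
        for (try in seq_len(8L)) {
          sig <- model$boundary_jitter_sigma * 0.75^(try - 1L)
          e <- smooth_circular(stats::rnorm(nrow(v0), 0, sig),
                               target_sd = sig)
          cand <- v0 + vertex_normals(v0) * e
          if (is_simple_polygon(cand)) { v <- cand; break }
        }
      }
      polys[[length(polys) + 1L]] <-
        polygon_annotation(cls, v, participant$participant_id,
                           draw_order = length(polys))
    }
    annotation_set(truth$roi, participant, polys)
  })
}

#' Simulate reviewer corrections against ground truth
#'
#' Connected components of the disagreement set between an annotator's mask
#' and the truth become correction polygons labeled with the truth class;
#' each is independently dropped with probability `reviewer_miss` (an
#' imperfect reviewer). Traced polygons are verified by re-rasterization and
#' replaced by pixel-exact run rectangles when the trace is ambiguous, so
#' applying the corrections with [apply_corrections()] moves the mask
#' toward truth (discordance to truth non-increasing; zero when
#' `reviewer_miss = 0`).
#'
#' @param annotated,truth [label_mask()]s of the same shape.
#' @param reviewer_miss per-component drop probability in \[0, 1\].
#' @param reviewer_id participant id stamped on the corrections.
#' @param seed integer seed for the drop draws.
#' @return list of [polygon_annotation()]s with `is_correction = TRUE`.
#' @export
simulate_correction <- function(annotated, truth, reviewer_miss = 0,
                                reviewer_id = "reviewer", seed = NULL) {
  stopifnot(all(dim(annotated$labels) == dim(truth$labels)))
  tax <- truth$taxonomy
  diff <- annotated$labels != truth$labels
  out <- list()
  with_local_seed(seed, {
    for (code in sort(intersect(unique(truth$labels[diff]), tax$label_code))) {
      comp <- label_components(diff & truth$labels == code, connectivity = 4)
      for (k in seq_len(max(comp))) {
        if (stats::runif(1) < reviewer_miss) next
        bin <- comp == k
        poly <- trace_region_polygon(bin)
        ok <- !is.null(poly) && nrow(poly) >= 3L
        if (ok) {
          hit <- rasterize_polygon(poly, nrow(bin), ncol(bin))
          ok <- identical(hit, bin)
        }
        vlist <- if (ok) list(poly) else runs_to_polygons(bin)
        for (v in vlist) {
          out[[length(out) + 1L]] <-
            polygon_annotation(tax_class(tax, code), v, reviewer_id,
                               is_correction = TRUE,
                               draw_order = length(out))
        }
      }
    }
  })
  out
}

#' Simulate a full structured-crowdsourcing study
#'
#' Builds the study design at desk scale: `n_eval_rois` evaluation ROIs
#' annotated by every participant (no reviewer feedback, to keep the
#' concordance analysis unbiased) and `n_core_rois` core ROIs partitioned
#' among participants (each core ROI annotated by exactly one participant)
#' with simulated reviewer corrections. Byte-identical given `seed`.
#'
#' @param scene a [scene_spec()] shared by all ROIs (each ROI gets its own
#'   derived seed).
#' @param roster a [default_roster()]-shaped data frame.
#' @param n_eval_rois,n_core_rois ROI counts.
#' @param seed master integer seed.
#' @param taxonomy a [class_taxonomy()].
#' @param reviewer_miss reviewer component-drop probability on core ROIs.
#' @param n_institutes slides are assigned round-robin to this many
#'   simulated contributing institutes (used for train/test separation in
#'   the learning-curve harness).
#' @return a `cohort_bundle` list: `taxonomy`, `rois` (data frame),
#'   `participants`, `truth_masks`, `truth_annotations`, `annotations`
#'   (`participant_id -> roi_id -> annotation_set`), `corrections`
#'   (`roi_id ->` list of correction polygons), `assignment`, `seed`.
#' @export
simulate_cohort <- function(scene = scene_spec(), roster = default_roster(),
                            n_eval_rois = 10, n_core_rois = 0, seed = 1,
                            taxonomy = default_taxonomy(),
                            reviewer_miss = 0.1, n_institutes = 4) {
  n_p <- nrow(roster)
  stopifnot(n_p >= 1L, n_eval_rois >= 0L, n_core_rois >= 0L)
  rois_df <- data.frame(
    roi_id = c(sprintf("eval_%02d", seq_len(n_eval_rois)),
               sprintf("core_%03d", seq_len(n_core_rois))),
    slide_id = c(sprintf("slide_e%02d", seq_len(n_eval_rois)),
                 sprintf("slide_c%03d", seq_len(n_core_rois))),
    institute_id = c(rep("inst_eval", n_eval_rois),
                     sprintf("inst_%02d",
                             (seq_len(n_core_rois) - 1L) %% n_institutes + 1L)),
    set_membership = c(rep("evaluation", n_eval_rois),
                       rep("core", n_core_rois)),
    stringsAsFactors = FALSE)
  truth_masks <- list(); truth_ann <- list()
  for (i in seq_len(nrow(rois_df))) {
    sp <- scene
    sp$seed <- derive_seed(seed, 1L, i)
    m <- generate_scene(sp, taxonomy)
    rid <- rois_df$roi_id[i]
    truth_masks[[rid]] <- m
    truth_ann[[rid]] <- scene_to_truth_annotations(
      m, roi = roi(rid, width = sp$width, height = sp$height,
                   slide_id = rois_df$slide_id[i],
                   institute_id = rois_df$institute_id[i],
                   set_membership = rois_df$set_membership[i]))
  }
  # core ROIs partitioned round-robin; evaluation ROIs go to everyone
  core_ids <- rois_df$roi_id[rois_df$set_membership == "core"]
  eval_ids <- rois_df$roi_id[rois_df$set_membership == "evaluation"]
  assignment <- data.frame(
    participant_id = c(rep(roster$participant_id, each = length(eval_ids)),
                       if (length(core_ids))
                         roster$participant_id[(seq_along(core_ids) - 1L) %% n_p + 1L]),
    roi_id = c(rep(eval_ids, times = n_p), core_ids),
    stringsAsFactors = FALSE)
  annotations <- stats::setNames(vector("list", n_p), roster$participant_id)
  corrections <- list()
  for (pi in seq_len(n_p)) {
    pid <- roster$participant_id[pi]
    pobj <- participant(pid, roster$tier[pi])
    my_rois <- assignment$roi_id[assignment$participant_id == pid]
    annotations[[pid]] <- stats::setNames(vector("list", length(my_rois)),
                                          my_rois)
    for (rid in my_rois) {
      ri <- match(rid, rois_df$roi_id)
      annotations[[pid]][[rid]] <- simulate_annotator(
        truth_ann[[rid]], roster$model[[pi]], taxonomy,
        participant = pobj, seed = derive_seed(seed, 2L, pi, ri))
    }
  }
  for (rid in core_ids) {
    pid <- assignment$participant_id[assignment$roi_id == rid]
    rendered <- render_annotation_set(annotations[[pid]][[rid]], taxonomy)
    corrections[[rid]] <- simulate_correction(
      rendered, truth_masks[[rid]], reviewer_miss = reviewer_miss,
      seed = derive_seed(seed, 3L, match(rid, rois_df$roi_id)))
  }
  structure(list(taxonomy = taxonomy, rois = rois_df,
                 participants = roster[, c("participant_id", "tier")],
                 roster = roster,
                 truth_masks = truth_masks, truth_annotations = truth_ann,
                 annotations = annotations, corrections = corrections,
                 assignment = assignment, scene = scene, seed = seed),
            class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat(sprintf("<cohort_bundle> %d participants (%s), %d evaluation + %d core ROIs, seed %s\n",
              nrow(x$participants),
              paste(sprintf("%d %s", table(x$participants$tier)[unique(x$participants$tier)],
                            unique(x$participants$tier)), collapse = ", "),
              sum(x$rois$set_membership == "evaluation"),
              sum(x$rois$set_membership == "core"), x$seed))
  invisible(x)
}

#' Render a cohort's annotation sets into masks
#'
#' @param bundle a [simulate_cohort()] bundle.
#' @param which `"evaluation"` (default: the all-participant concordance
#'   set) or `"core"`.
#' @return named list `participant_id -> roi_id ->` [label_mask()], ready
#'   for [pairwise_discordance()].
#' @export
cohort_masks <- function(bundle, which = c("evaluation", "core")) {
  which <- match.arg(which)
  keep <- bundle$rois$roi_id[bundle$rois$set_membership == which]
  out <- list()
  for (pid in names(bundle$annotations)) {
    sets <- bundle$annotations[[pid]]
    rids <- intersect(names(sets), keep)
    if (!length(rids)) next
    out[[pid]] <- lapply(stats::setNames(rids, rids), function(rid) {
      render_annotation_set(sets[[rid]], bundle$taxonomy)
    })
  }
  out
}
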