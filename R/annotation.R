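#' Study participant
#'
#' @param participant_id unique identifier string.
#' @param tier experience tier: `"SP"` (senior pathologist), `"JP"` (junior
#'   pathology resident), `"NP"` (non-pathologist, e.g. medical student), or
#'   `"AL"` (an algorithmic "participant" whose prediction masks enter the
#'   discordance analysis alongside the humans).
#' @return a `participant` list.
#' @export
participant <- function(participant_id, tier = c("SP", "JP", "NP", "AL")) {
  tier <- match.arg(tier)
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  structure(list(participant_id = participant_id, tier = tier),
            class = "participant")
}

#' Region of interest geometry
#'
#' A rectangular sub-area of a whole-slide image. `core` ROIs are uniquely
#' assigned to one participant (model training data); `evaluation` ROIs are
#' annotated by everyone to measure inter-participant concordance.
#'
#' @param roi_id,slide_id,institute_id identifier strings.
#' @param origin integer `(x, y)` of the ROI's top-left corner in the slide
#'   frame (pixels).
#' @param width,height ROI size in pixels, both positive.
#' @param set_membership `"core"` or `"evaluation"`.
#' @return an `roi` list.
#' @export
roi <- function(roi_id, width, height, slide_id = roi_id,
                institute_id = "unknown", origin = c(0L, 0L),
                set_membership = c("core", "evaluation")) {
  set_membership <- match.arg(set_membership)
  stopifnot(is_count(width), width > 0, is_count(height), height > 0,
            length(origin) == 2L)
  structure(list(roi_id = roi_id, slide_id = slide_id,
                 institute_id = institute_id,
                 origin = as.integer(origin),
                 width = as.integer(width), height = as.integer(height),
                 set_membership = set_membership),
            class = "roi")
}

#' One labeled closed polygon drawn by one participant
#'
#' Vertices are real-valued `(x, y)` points in ROI-local pixel-center
#' coordinates (0-based: pixel column `c` has center `x = c`, row `r` center
#' `y = r`). The polygon is closed implicitly (last vertex joins the first).
#' `draw_order` strictly orders all polygons of one participant on one ROI
#' and resolves overlaps at render time (later-drawn wins).
#'
#' @param class_name taxonomy class the region is labeled with.
#' @param vertices numeric matrix with >= 3 rows and 2 columns (x, y).
#' @param participant_id who drew it.
#' @param is_correction `TRUE` for expert correction overlays patched on top
#'   of the original annotations.
#' @param draw_order non-negative integer.
#' @return a `polygon_annotation` list.
#' @export
polygon_annotation <- function(class_name, vertices, participant_id,
                               is_correction = FALSE, draw_order = 0L) {
  vertices <- as.matrix(vertices)
  if (!is.numeric(vertices) || ncol(vertices) != 2L || nrow(vertices) < 3L) {
    stopf("vertices must be a numeric matrix with >= 3 rows and 2 columns")
  }
  dimnames(vertices) <- list(NULL, c("x", "y"))
  structure(list(class_name = class_name, vertices = vertices,
                 participant_id = participant_id,
                 is_correction = isTRUE(is_correction),
                 draw_order = as.integer(draw_order)),
            class = "polygon_annotation")
}

#' One participant's polygon set on one ROI
#'
#' @param roi an [roi()].
#' @param participant a [participant()].
#' @param polygons list of [polygon_annotation()]s, all sharing the
#'   participant's id; vertices may extend past the ROI box (clipped when
#'   rendered).
#' @return an `annotation_set` list.
#' @export
annotation_set <- function(roi, participant, polygons = list()) {
  stopifnot(inherits(roi, "roi"), inherits(participant, "participant"))
  pid <- vapply(polygons, function(p) p$participant_id, "")
  if (length(pid) && !all(pid == participant$participant_id)) {
    stopf("all polygons must carry participant_id '%s'",
          participant$participant_id)
  }
  ord <- vapply(polygons, function(p) p$draw_order, 0L)
  if (anyDuplicated(ord)) stopf("draw_order must strictly order the polygons")
  structure(list(roi = roi, participant = participant, polygons = polygons),
            class = "annotation_set")
}

#' Class label mask over an ROI grid
#'
#' A height x width integer matrix of taxonomy label codes. 0 marks pixels
#' outside the ROI / undefined; every nonzero value must be a taxonomy code.
#' The binary per-class channel views `I_c` partition the nonzero pixels:
#' each pixel belongs to exactly one class.
#'
#' @param labels integer matrix (rows = y, columns = x).
#' @param taxonomy the [class_taxonomy()] the codes refer to.
#' @return a `label_mask` list with elements `labels`, `taxonomy`.
#' @export
label_mask <- function(labels, taxonomy) {
  stopifnot(is.matrix(labels), inherits(taxonomy, "class_taxonomy"))
  storage.mode(labels) <- "integer"
  bad <- setdiff(unique(as.vector(labels)), c(0L, taxonomy$label_code))
  if (length(bad)) {
    stopf("labels contain codes absent from the taxonomy: %s",
          paste(sort(bad), collapse = ", "))
  }
  structure(list(labels = labels, taxonomy = taxonomy), class = "label_mask")
}

#' Binary channel view of one class
#'
#' @param mask a [label_mask()].
#' @param class_name taxonomy class.
#' @return logical matrix, `TRUE` where the mask carries that class.
#' @export
mask_channel <- function(mask, class_name) {
  mask$labels == tax_code(mask$taxonomy, class_name)
}

#' @export
print.label_mask <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels),
                      levels = c(0L, x$taxonomy$label_code),
                      labels = c("<outside>", x$taxonomy$class_name)))
  cat(sprintf("<label_mask> %d x %d px\n", nrow(x$labels), ncol(x$labels)))
  print(tab[tab > 0])
  invisible(x)
}

# ---------------------------------------------------------------------------
# Annotation document I/O.
#
# One JSON document per (participant, ROI). Elements mirror a web slide
# viewer's annotation model: closed polylines with "points" [[x, y], ...],
# "group" = class name, "correction" flag. Element order defines draw_order.

#' Read an annotation document
#'
#' @param path path to the JSON annotation document.
#' @param taxonomy a [class_taxonomy()]; unknown class names are an error,
#'   never a silent drop.
#' @return an [annotation_set()] with `draw_order` equal to document position
#'   (0-based).
#' @export
read_annotation_document <- function(path, taxonomy) {
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stopf("malformed annotation JSON in '%s': %s",
                          path, conditionMessage(e))
                  })
  for (f in c("roi", "participant", "elements")) {
    if (is.null(doc[[f]])) stopf("annotation document lacks '%s'", f)
  }
  r <- doc$roi
  the_roi <- roi(roi_id = r$roi_id, width = r$width, height = r$height,
                 slide_id = r$slide_id %||% r$roi_id,
                 institute_id = r$institute_id %||% "unknown",
                 origin = unlist(r$origin %||% c(0L, 0L)),
                 set_membership = r$set_membership %||% "core")
  p <- participant(doc$participant$participant_id, doc$participant$tier)
  polys <- vector("list", length(doc$elements))
  for (i in seq_along(doc$elements)) {
    el <- doc$elements[[i]]
    if (is.null(el$group) || !el$group %in% taxonomy$class_name) {
      stopf("element %d: class '%s' is not in the taxonomy",
            i, el$group %||% "<missing>")
    }
    pts <- el$points
    if (length(pts) < 3L) {
      stopf("element %d (class '%s'): polygon needs >= 3 vertices, has %d",
            i, el$group, length(pts))
    }
    v <- do.call(rbind, lapply(pts, function(q) as.numeric(unlist(q)[1:2])))
    polys[[i]] <- polygon_annotation(el$group, v, p$participant_id,
                                     is_correction = isTRUE(el$correction),
                                     draw_order = i - 1L)
  }
  annotation_set(the_roi, p, polys)
}

#' Write an annotation document
#'
#' Inverse of [read_annotation_document()]: the written file reads back with
#' identical content (vertices to double precision).
#'
#' @param set an [annotation_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation_document <- function(set, path) {
  stopifnot(inherits(set, "annotation_set"))
  ord <- order(vapply(set$polygons, function(p) p$draw_order, 0L))
  els <- lapply(set$polygons[ord], function(p) {
    list(group = p$class_name,
         correction = p$is_correction,
         points = lapply(seq_len(nrow(p$vertices)),
                         function(i) as.numeric(p$vertices[i, ])))
  })
  r <- set$roi
  doc <- list(
    roi = list(roi_id = r$roi_id, slide_id = r$slide_id,
               institute_id = r$institute_id, origin = as.integer(r$origin),
               width = r$width, height = r$height,
               set_membership = r$set_membership),
    participant = list(participant_id = set$participant$participant_id,
                       tier = set$participant$tier),
    elements = els)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Label mask I/O: 8-bit single-channel PNG whose pixel values are label
# codes, plus a sidecar JSON label map (code <-> class name, colors).

#' Read / write a label mask image
#'
#' The mask is stored as an 8-bit grayscale PNG whose raw pixel values are
#' the taxonomy label codes (lossless for codes 0..255), with a sidecar JSON
#' label map. Reading validates that every code in the image has a label-map
#' entry.
#'
#' @param path PNG path.
#' @param labelmap_path sidecar JSON path (a serialized taxonomy).
#' @return [read_label_mask()] returns a [label_mask()];
#'   `write_label_mask()` returns `path` invisibly.
#' @export
read_label_mask <- function(path, labelmap_path) {
  taxonomy <- read_taxonomy(labelmap_path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  labels <- matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
  bad <- setdiff(unique(as.vector(labels)), c(0L, taxonomy$label_code))
  if (length(bad)) {
    stopf("mask '%s' contains codes with no label-map entry: %s",
          path, paste(sort(bad), collapse = ", "))
  }
  label_mask(labels, taxonomy)
}

#' @rdname read_label_mask
#' @param mask a [label_mask()] to serialize.
#' @export
write_label_mask <- function(mask, path, labelmap_path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 255L) stopf("label codes > 255 do not fit 8-bit PNG")
  png::writePNG(mask$labels / 255, path)
  write_taxonomy(mask$taxonomy, labelmap_path)
  invisible(path)
}
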