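#' Rendering policy for polygon rasterization
#'
#' Overlaps are always resolved "later-drawn wins" (draw order is the only
#' precedence signal an annotation stream carries); the fill rule is the
#' nonzero winding rule by default, with even-odd available. Pixels are
#' included by a pixel-center test; points exactly on a polygon edge count
#' as inside. Vertices outside the ROI grid are clipped at render time.
#'
#' @param fill_rule `"nonzero"` or `"evenodd"`.
#' @param clip_to_roi kept for completeness; masks are ROI-sized so clipping
#'   is inherent.
#' @return a `render_policy` list.
#' @export
render_policy <- function(fill_rule = c("nonzero", "evenodd"),
                          clip_to_roi = TRUE) {
  structure(list(overlap_rule = "later-drawn wins",
                 fill_rule = match.arg(fill_rule),
                 clip_to_roi = isTRUE(clip_to_roi)),
            class = "render_policy")
}

shoelace_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Rasterize one polygon onto an ROI grid
#'
#' Pixel (row r, col c), 1-based in the matrix, has center
#' `(x, y) = (c - 1, r - 1)`. A pixel is set when its center lies inside the
#' closed polygon under the policy's fill rule, or exactly on its boundary.
#'
#' @param p a [polygon_annotation()] (or a bare 2-column vertex matrix).
#' @param height,width grid size in pixels.
#' @param policy a [render_policy()].
#' @return logical `height x width` matrix. A degenerate (zero-area) polygon
#'   yields an empty mask with a warning.
#' @examples
#' p <- polygon_annotation("tumor", rbind(c(1, 1), c(4, 1), c(4, 3), c(1, 3)), "a")
#' sum(rasterize_polygon(p, 6, 6))   # 12 pixels: columns 1..4 x rows 1..3
#' @export
rasterize_polygon <- function(p, height, width, policy = render_policy()) {
  v <- if (inherits(p, "polygon_annotation")) p$vertices else as.matrix(p)
  out <- matrix(FALSE, height, width)
  if (abs(shoelace_area(v)) < 1e-12) {
    warning("degenerate (zero-area) polygon; rasterized as empty")
    return(out)
  }
  xs <- v[, 1]; ys <- v[, 2]
  x0 <- max(0L, floor(min(xs))); x1 <- min(width - 1L, ceiling(max(xs)))
  y0 <- max(0L, floor(min(ys))); y1 <- min(height - 1L, ceiling(max(ys)))
  if (x0 > x1 || y0 > y1) return(out)
  n <- length(xs)
  nxt <- c(2:n, 1L)
  ax <- xs; ay <- ys; bx <- xs[nxt]; by <- ys[nxt]
  pxs <- x0:x1
  # scanline pass: per pixel row, signed edge crossings sorted by x; the
  # winding number right of x is the cumulative crossing direction
  for (py in y0:y1) {
    up <- (ay <= py) & (by > py)
    dn <- (by <= py) & (ay > py)
    str <- which(up | dn)
    if (!length(str)) next
    xint <- ax[str] + (py - ay[str]) * (bx[str] - ax[str]) / (by[str] - ay[str])
    dir <- ifelse(up[str], 1L, -1L)
    o <- order(xint)
    xint <- xint[o]; dir <- dir[o]
    k <- findInterval(pxs, xint)
    cs <- cumsum(dir)
    inside <- if (policy$fill_rule == "nonzero") {
      c(0L, cs)[k + 1L] != 0L
    } else {
      k %% 2L == 1L
    }
    out[pxs[inside] * height + py + 1L] <- TRUE
  }
  # boundary pass: pixel centers lying exactly on an edge count as inside
  tol <- 1e-9
  for (k in seq_len(n)) {
    dxe <- bx[k] - ax[k]; dye <- by[k] - ay[k]
    if (dxe == 0 && dye == 0) {
      if (abs(ax[k] - round(ax[k])) < tol && abs(ay[k] - round(ay[k])) < tol) {
        px <- round(ax[k]); py <- round(ay[k])
        if (px >= x0 && px <= x1 && py >= y0 && py <= y1) {
          out[px * height + py + 1L] <- TRUE
        }
      }
      next
    }
    if (abs(dxe) >= abs(dye)) {
      lo <- max(x0, ceiling(min(ax[k], bx[k]) - tol))
      hi <- min(x1, floor(max(ax[k], bx[k]) + tol))
      if (lo > hi) next
      px <- lo:hi
      yy <- ay[k] + (px - ax[k]) * dye / dxe
      py <- round(yy)
      hit <- abs(yy - py) < tol & py >= y0 & py <= y1
      if (any(hit)) out[px[hit] * height + py[hit] + 1L] <- TRUE
    } else {
      lo <- max(y0, ceiling(min(ay[k], by[k]) - tol))
      hi <- min(y1, floor(max(ay[k], by[k]) + tol))
      if (lo > hi) next
      py <- lo:hi
      xx <- ax[k] + (py - ay[k]) * dxe / dye
      px <- round(xx)
      hit <- abs(xx - px) < tol & px >= x0 & px <= x1
      if (any(hit)) out[px[hit] * height + py[hit] + 1L] <- TRUE
    }
  }
  out
}

#' Render an annotation set into a label mask
#'
#' Pixels covered by no polygon receive the taxonomy's default class (the
#' tissue "defined by absence of annotations"); overlapping polygons are
#' resolved by draw order, later wins. Correction overlays are excluded by
#' default and applied separately with [apply_corrections()].
#'
#' @param set an [annotation_set()].
#' @param taxonomy a [class_taxonomy()].
#' @param policy a [render_policy()].
#' @param include_corrections render correction polygons in draw order along
#'   with the originals (they still outrank earlier polygons).
#' @return a [label_mask()] of the ROI's size.
#' @export
render_annotation_set <- function(set, taxonomy, policy = render_policy(),
                                  include_corrections = FALSE) {
  stopifnot(inherits(set, "annotation_set"))
  h <- set$roi$height; w <- set$roi$width
  labels <- matrix(default_code(taxonomy), h, w)
  polys <- set$polygons
  if (!include_corrections) {
    polys <- Filter(function(p) !p$is_correction, polys)
  }
  ord <- order(vapply(polys, function(p) p$draw_order, 0L))
  for (p in polys[ord]) {
    hit <- rasterize_polygon(p, h, w, policy)
    labels[hit] <- tax_code(taxonomy, p$class_name)
  }
  label_mask(labels, taxonomy)
}

#' Patch correction overlays on top of a rendered mask
#'
#' Every pixel covered by a correction polygon takes the correction's class;
#' overlapping corrections are resolved later-drawn wins; all other pixels
#' are untouched (conservation).
#'
#' @param base a [label_mask()].
#' @param corrections list of [polygon_annotation()]s, all with
#'   `is_correction = TRUE` (anything else is a validation error).
#' @param policy a [render_policy()].
#' @return the patched [label_mask()].
#' @export
apply_corrections <- function(base, corrections, policy = render_policy()) {
  stopifnot(inherits(base, "label_mask"))
  if (!all(vapply(corrections, function(p) p$is_correction, TRUE))) {
    stopf("all polygons passed to apply_corrections must have is_correction = TRUE")
  }
  labels <- base$labels
  h <- nrow(labels); w <- ncol(labels)
  ord <- order(vapply(corrections, function(p) p$draw_order, 0L))
  for (p in corrections[ord]) {
    hit <- rasterize_polygon(p, h, w, policy)
    labels[hit] <- tax_code(base$taxonomy, p$class_name)
  }
  label_mask(labels, base$taxonomy)
}

# Connected-component labeling of a logical matrix via a pixel-adjacency
# graph (igraph does the union-find work). Returns an integer matrix of
# component ids, 0 = background.
label_components <- function(bin, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  h <- nrow(bin); w <- ncol(bin)
  idx <- which(bin)
  lab <- matrix(0L, h, w)
  if (!length(idx)) return(lab)
  offs <- list(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) offs <- c(offs, list(c(1L, 1L), c(-1L, 1L)))
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  edges <- integer(0)
  rank_of <- integer(h * w)
  rank_of[idx] <- seq_along(idx)
  for (o in offs) {
    r2 <- r + o[1L]; c2 <- cc + o[2L]
    ok <- r2 >= 1L & r2 <= h & c2 <= w
    idx2 <- (c2[ok] - 1L) * h + r2[ok]
    keep <- bin[idx2]
    if (any(keep)) {
      edges <- c(edges, rbind(rank_of[idx[ok][keep]], rank_of[idx2[keep]]))
    }
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  lab[idx] <- igraph::components(g)$membership
  lab
}

# Trace the outer boundary of a logical component as a closed polygon in
# pixel-center coordinates, via the 0.5 level set of the padded indicator
# (the contour runs along pixel borders, halfway between centers).
trace_region_polygon <- function(bin) {
  h <- nrow(bin); w <- ncol(bin)
  z <- matrix(0, h + 2L, w + 2L)
  z[2:(h + 1L), 2:(w + 1L)] <- bin * 1
  cl <- grDevices::contourLines(x = seq(-1, w), y = seq(-1, h),
                                z = t(z), levels = 0.5)
  if (!length(cl)) return(NULL)
  areas <- vapply(cl, function(co) abs(shoelace_area(cbind(co$x, co$y))), 0)
  co <- cl[[which.max(areas)]]
  v <- cbind(x = co$x, y = co$y)
  # contourLines closes the loop by repeating the first point; drop it
  if (nrow(v) > 3L && all(v[1L, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  v
}

# Pixel-exact polygon cover of a logical matrix: one axis-aligned rectangle
# per maximal horizontal run. Fallback for components whose traced contour
# does not reproduce them exactly.
runs_to_polygons <- function(bin) {
  out <- list()
  for (r in seq_len(nrow(bin))) {
    row <- bin[r, ]
    if (!any(row)) next
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    for (i in which(rl$values)) {
      x0 <- starts[i] - 1.5; x1 <- ends[i] - 0.5   # pixel-corner coords
      y0 <- r - 1.5; y1 <- r - 0.5
      out[[length(out) + 1L]] <-
        cbind(x = c(x0, x1, x1, x0), y = c(y0, y0, y1, y1))
    }
  }
  out
}

#' Extract polygonal regions from a label mask
#'
#' One entry per connected component of each non-default class (the default
#' class is "defined by absence" and is excluded), with its traced boundary
#' polygon and pixel area. Components are 8-connected by default; per class,
#' summed `area_px` equals the class's pixel count.
#'
#' @param mask a [label_mask()].
#' @param connectivity 4 or 8 (default 8, conventional for object masks).
#' @return data frame with columns `class_name`, `region_id`, `area_px` and
#'   a list column `polygon` of 2-column vertex matrices.
#' @export
extract_regions <- function(mask, connectivity = 8) {
  stopifnot(inherits(mask, "label_mask"))
  tax <- mask$taxonomy
  codes <- setdiff(intersect(unique(as.vector(mask$labels)), tax$label_code),
                   default_code(tax))
  rows <- list()
  for (code in sort(codes)) {
    comp <- label_components(mask$labels == code, connectivity)
    for (k in seq_len(max(comp))) {
      bin <- comp == k
      poly <- trace_region_polygon(bin)
      if (is.null(poly)) next
      rows[[length(rows) + 1L]] <- list(class_name = tax_class(tax, code),
                                        region_id = k,
                                        area_px = sum(bin),
                                        polygon = poly)
    }
  }
  data.frame(
    class_name = vapply(rows, `[[`, "", "class_name"),
    region_id = vapply(rows, `[[`, 0L, "region_id"),
    area_px = vapply(rows, `[[`, 0L, "area_px"),
    polygon = I(lapply(rows, `[[`, "polygon")),
    stringsAsFactors = FALSE)
}
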