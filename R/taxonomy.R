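#' Class taxonomy for tissue region annotation
#'
#' A taxonomy assigns every annotatable tissue class a stable integer label
#' code, an experience tier (how hard the class is to recognize), and a
#' display color. Label code 0 is reserved for "outside ROI / undefined" and
#' can never be assigned to a class. Exactly one class is the *default*
#' class: the tissue assumed wherever a participant drew nothing (stroma in
#' breast-cancer region annotation, where it is the most prevalent
#' component). The default class must belong to the `predominant` tier.
#'
#' @param class_name character vector of unique class names
#'   (case-insensitively unique).
#' @param tier character vector, one of `"predominant"`, `"non_predominant"`,
#'   `"challenging"`, `"meta"` per class.
#' @param label_code integer vector of unique positive codes (<= 255 so masks
#'   fit an 8-bit indexed image).
#' @param color colors, anything [grDevices::col2rgb()] accepts; stored as
#'   hex strings.
#' @param default_class name of the single default class.
#' @return A `class_taxonomy`: a data frame with columns `class_name`,
#'   `tier`, `label_code`, `color`, `is_default`.
#' @examples
#' tax <- default_taxonomy()
#' tax$class_name[tax$is_default]   # "stroma"
#' @export
class_taxonomy <- function(class_name, tier, label_code,
                           color = grDevices::rainbow(length(class_name)),
                           default_class) {
  tiers <- c("predominant", "non_predominant", "challenging", "meta")
  n <- length(class_name)
  stopifnot(length(tier) == n, length(label_code) == n, length(color) == n)
  if (!all(tier %in% tiers)) {
    stopf("unknown tier(s): %s", paste(setdiff(tier, tiers), collapse = ", "))
  }
  if (anyDuplicated(tolower(class_name))) {
    stopf("duplicate class names (case-insensitive): %s",
          paste(class_name[duplicated(tolower(class_name))], collapse = ", "))
  }
  label_code <- as.integer(label_code)
  if (any(label_code <= 0L)) stopf("label_code must be positive; 0 is reserved")
  if (any(label_code > 255L)) stopf("label_code must be <= 255")
  if (anyDuplicated(label_code)) {
    stopf("duplicate label codes: %s",
          paste(label_code[duplicated(label_code)], collapse = ", "))
  }
  if (length(default_class) != 1L || !default_class %in% class_name) {
    stopf("default_class must name exactly one taxonomy class")
  }
  if (tier[match(default_class, class_name)] != "predominant") {
    stopf("the default class must have tier 'predominant'")
  }
  hex <- apply(grDevices::col2rgb(color), 2L,
               function(v) grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255))
  out <- data.frame(class_name = as.character(class_name), tier = tier,
                    label_code = label_code, color = hex,
                    is_default = class_name == default_class,
                    stringsAsFactors = FALSE)
  class(out) <- c("class_taxonomy", "data.frame")
  out
}

#' Default breast-tumor microenvironment taxonomy
#'
#' Predominant classes (tumor, stroma, lymphocytic infiltrate, necrosis),
#' a few non-predominant classes, and one challenging class, with stroma as
#' the default class. Mirrors the class structure used in crowdsourced
#' TNBC region annotation studies.
#'
#' @return a [class_taxonomy()].
#' @export
default_taxonomy <- function() {
  class_taxonomy(
    class_name = c("tumor", "stroma", "lymphocytic_infiltrate", "necrosis",
                   "blood_vessel", "adipose", "blood", "plasma_cells"),
    tier = c("predominant", "predominant", "predominant", "predominant",
             "non_predominant", "non_predominant", "non_predominant",
             "challenging"),
    label_code = c(1L, 2L, 3L, 4L, 5L, 6L, 7L, 8L),
    color = c("#FF0000", "#FFC8C8", "#0000FF", "#FFFF00",
              "#800080", "#FFA500", "#8B0000", "#00FFFF"),
    default_class = "stroma")
}

# code <-> name lookups (error on unknowns so mistakes never pass silently)
tax_code <- function(taxonomy, class_name) {
  i <- match(class_name, taxonomy$class_name)
  if (anyNA(i)) {
    stopf("class(es) not in taxonomy: %s",
          paste(unique(class_name[is.na(i)]), collapse = ", "))
  }
  taxonomy$label_code[i]
}

tax_class <- function(taxonomy, code) {
  i <- match(code, taxonomy$label_code)
  if (anyNA(i)) {
    stopf("label code(s) not in taxonomy: %s",
          paste(unique(code[is.na(i)]), collapse = ", "))
  }
  taxonomy$class_name[i]
}

default_code <- function(taxonomy) taxonomy$label_code[taxonomy$is_default]
default_class_name <- function(taxonomy) taxonomy$class_name[taxonomy$is_default]

#' Named class subsets used throughout the discordance analysis
#'
#' `"all"` is every non-meta class (the default class included),
#' `"predominant"` the four predominant tissue classes, and `"tumor"` the
#' binary tumor-only view.
#'
#' @param taxonomy a [class_taxonomy()].
#' @param preset one of `"all"`, `"predominant"`, `"tumor"`.
#' @return character vector of class names.
#' @export
classes_preset <- function(taxonomy, preset = c("all", "predominant", "tumor")) {
  preset <- match.arg(preset)
  switch(preset,
         all = taxonomy$class_name[taxonomy$tier != "meta"],
         predominant = taxonomy$class_name[taxonomy$tier == "predominant"],
         tumor = "tumor")
}

#' Read / write a class taxonomy file
#'
#' JSON layout: `{"classes": [{"name", "tier", "label_code",
#' "color": [r,g,b], "default": bool}, ...]}`. A `.csv` path uses columns of
#' the same names with `color` as `r;g;b`.
#'
#' @param path file path (`.json` or `.csv`).
#' @return [read_taxonomy()] returns a `class_taxonomy`;
#'   `write_taxonomy()` returns `path` invisibly.
#' @export
read_taxonomy <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    rgbm <- do.call(rbind, lapply(strsplit(df$color, ";"), as.integer))
    col <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3], maxColorValue = 255)
    return(class_taxonomy(df$name, df$tier, df$label_code, col,
                          default_class = df$name[as.logical(df$default)]))
  }
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  cls <- doc$classes
  if (is.null(cls)) stopf("taxonomy file '%s' has no 'classes' entry", path)
  nm <- vapply(cls, function(e) e$name, "")
  col <- vapply(cls, function(e) {
    v <- unlist(e$color)
    grDevices::rgb(v[1], v[2], v[3], maxColorValue = 255)
  }, "")
  class_taxonomy(
    class_name = nm,
    tier = vapply(cls, function(e) e$tier, ""),
    label_code = vapply(cls, function(e) as.integer(e$label_code), 1L),
    color = col,
    default_class = nm[vapply(cls, function(e) isTRUE(e$default), TRUE)])
}

#' @rdname read_taxonomy
#' @param taxonomy a [class_taxonomy()] to serialize.
#' @export
write_taxonomy <- function(taxonomy, path) {
  rgbm <- grDevices::col2rgb(taxonomy$color)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- data.frame(name = taxonomy$class_name, tier = taxonomy$tier,
                     label_code = taxonomy$label_code,
                     color = apply(rgbm, 2L, paste, collapse = ";"),
                     default = taxonomy$is_default)
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  cls <- lapply(seq_len(nrow(taxonomy)), function(i) {
    list(name = taxonomy$class_name[i], tier = taxonomy$tier[i],
         label_code = taxonomy$label_code[i],
         color = as.integer(rgbm[, i]),
         default = taxonomy$is_default[i])
  })
  jsonlite::write_json(list(classes = cls), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
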