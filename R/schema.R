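# UPDRS motor attribute schema: which items are assessed and how laterality
# expands them into per-side / per-limb delta attributes.

# The 13 motor items usable in a schema. Laterality classes:
#   "none"  - axial or global item, one attribute
#   "hands" - assessed per hand            -> RH, LH
#   "feet"  - assessed per leg             -> RF, LF
#   "limbs" - assessed per limb (tremor)   -> RH, LH, RF, LF
.updrs_item_universe <- c(13L, 14L, 20L, 21L, 23L, 24L, 25L, 26L, 28L, 29L, 31L, 32L, 39L)

.laterality_suffixes <- list(
  none  = "",
  hands = c("RH", "LH"),
  feet  = c("RF", "LF"),
  limbs = c("RH", "LH", "RF", "LF")
)

#' Default UPDRS motor item set
#'
#' The 13 motor-section items used for deterioration assessment, with the
#' laterality class that expands them into 21 delta attributes: items
#' 13 (falling), 14 (freezing when walking), 28 (posture), 29 (gait),
#' 31 (body bradykinesia), 32 (dyskinesia duration) and 39 (off time) are
#' axial/global; item 20 (rest tremor) is scored on all four limbs; items
#' 21 (action tremor), 23 (finger taps), 24 (hand movements) and 25 (rapid
#' alternating movements) per hand; item 26 (leg agility) per leg.
#'
#' @return A data frame with columns `item` (integer) and `laterality`
#'   (one of `"none"`, `"hands"`, `"feet"`, `"limbs"`).
#' @export
default_updrs_items <- function() {
  data.frame(
    item = c(13L, 14L, 20L, 21L, 23L, 24L, 25L, 26L, 28L, 29L, 31L, 32L, 39L),
    laterality = c("none", "none", "limbs", "hands", "hands", "hands", "hands",
                   "feet", "none", "none", "none", "none", "none"),
    stringsAsFactors = FALSE
  )
}

#' Construct a UPDRS attribute schema
#'
#' Expands a set of UPDRS motor items into the ordered list of lateralized
#' delta attributes over which decision tables and rules are defined.
#' Attribute names are `d<item><suffix>`, e.g. `d13`, `d23RH`, `d26LF`.
#'
#' @param items Data frame with columns `item` and `laterality`, as returned
#'   by [default_updrs_items()]. Items must come from the 13-item motor set
#'   (13, 14, 20, 21, 23, 24, 25, 26, 28, 29, 31, 32, 39).
#' @return An object of class `updrs_schema`: a list with elements `items`
#'   (the input data frame) and `attributes` (character vector of attribute
#'   names, in schema order).
#' @examples
#' sch <- updrs_schema()
#' length(sch$attributes) # 21 for the default item set
#' @export
updrs_schema <- function(items = default_updrs_items()) {
  stopifnot(is.data.frame(items), all(c("item", "laterality") %in% names(items)))
  items$item <- as.integer(items$item)
  if (anyNA(items$item) || !all(items$item %in% .updrs_item_universe)) {
    stop("schema items must be drawn from the 13-item UPDRS motor set: ",
         paste(.updrs_item_universe, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(items$item)) {
    stop("duplicated UPDRS item in schema", call. = FALSE)
  }
  bad <- setdiff(items$laterality, names(.laterality_suffixes))
  if (length(bad)) {
    stop("unknown laterality class: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  attrs <- unlist(lapply(seq_len(nrow(items)), function(i) {
    paste0("d", items$item[i], .laterality_suffixes[[items$laterality[i]]])
  }), use.names = FALSE)
  stopifnot(!anyDuplicated(attrs))
  structure(list(items = items, attributes = attrs), class = "updrs_schema")
}

#' @export
print.updrs_schema <- function(x, ...) {
  cat("UPDRS attribute schema: ", nrow(x$items), " items -> ",
      length(x$attributes), " attributes\n", sep = "")
  cat(paste(x$attributes, collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a schema as YAML
#'
#' The YAML config lists one entry per item with its laterality flag, e.g.
#' `- {item: 23, laterality: hands}`.
#'
#' @param path File path.
#' @return `read_schema_yaml()` returns an `updrs_schema`;
#'   `write_schema_yaml()` returns `path` invisibly.
#' @export
read_schema_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  items <- do.call(rbind, lapply(raw, function(e) {
    data.frame(item = as.integer(e$item),
               laterality = as.character(e$laterality),
               stringsAsFactors = FALSE)
  }))
  updrs_schema(items)
}

#' @rdname read_schema_yaml
#' @param schema An `updrs_schema`.
#' @export
write_schema_yaml <- function(schema, path) {
  stopifnot(inherits(schema, "updrs_schema"))
  entries <- lapply(seq_len(nrow(schema$items)), function(i) {
    list(item = schema$items$item[i], laterality = schema$items$laterality[i])
  })
  yaml::write_yaml(entries, path)
  invisible(path)
}

# Display name used in rule rendering: d23RH -> "ΔUPDRS23RH"
attr_display_name <- function(attr) {
  sub("^d", "\u0394UPDRS", attr)
}

# Decision class labels, indexed by class value 0, 1, 2.
decision_labels <- function() c("stable", "warning", "alarm")
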