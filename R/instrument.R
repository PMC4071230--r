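#' Frequency scale
#'
#' An ordered consumption-frequency scale. Each category carries a
#' per-day event multiplier; the first category must be "never" (multiplier
#' 0) and multipliers must be nondecreasing, so that scoring is monotone in
#' the reported category.
#'
#' @param labels Character vector of category labels, in scale order.
#' @param multipliers Numeric vector of events/day, same length as `labels`.
#' @return An object of class `ffq_frequency_scale`.
#' @export
#' @examples
#' frequency_scale(c("never", "1 per day"), c(0, 1))
frequency_scale <- function(labels, multipliers) {
  if (length(labels) != length(multipliers))
    stop("labels and multipliers must have equal length")
  if (length(labels) < 2)
    stop("a frequency scale needs at least 2 categories")
  multipliers <- as.numeric(multipliers)
  if (anyNA(multipliers) || any(multipliers < 0))
    stop("multipliers must be nonnegative numbers")
  if (multipliers[1] != 0)
    stop("first frequency category must be 'never' with multiplier 0")
  if (is.unsorted(multipliers))
    stop("frequency multipliers must be nondecreasing in category order")
  structure(list(labels = as.character(labels), multipliers = multipliers),
            class = "ffq_frequency_scale")
}

#' Default nine-level frequency scale
#'
#' The conventional EPIC-style nine-category scale from "never (<1 per
#' month)" to "6+ per day", scored by the midpoint-of-range convention:
#' 1--3/month as 2 events per mean month (30.44 d), 2--4/week as 3/week,
#' 5--6/week as 5.5/week, 2--3/day as 2.5/day, 4--5/day as 4.5/day. The
#' open-ended top category is scored as 6/day. All multipliers can be
#' overridden in the instrument file.
#'
#' @return An `ffq_frequency_scale` with 9 categories.
#' @export
default_frequency_scale <- function() {
  frequency_scale(
    labels = c(
      "never (<1 per month)", "1-3 per month", "once a week",
      "2-4 per week", "5-6 per week", "once a day", "2-3 per day",
      "4-5 per day", "6+ per day"
    ),
    multipliers = c(0, 2 / 30.44, 1 / 7, 3 / 7, 5.5 / 7, 1, 2.5, 4.5, 6)
  )
}

#' Portion-size series
#'
#' An ordered set of gram amounts per eating occasion that a respondent
#' chooses from, anchored at the 25th, 50th and 75th percentile of intake in
#' a reference population (small, medium, large portions). Anchors must
#' appear among the options.
#'
#' @param options Numeric vector of grams per occasion, nondecreasing, all
#'   positive. Default length is 7.
#' @param anchors Numeric vector `c(p25, p50, p75)`.
#' @return An object of class `ffq_portion_series`.
#' @export
portion_series <- function(options, anchors = options[c(2L, 4L, 6L)]) {
  options <- as.numeric(options)
  anchors <- as.numeric(anchors)
  if (length(options) < 3) stop("portion series needs at least 3 options")
  if (anyNA(options) || any(options <= 0))
    stop("portion options must be positive grams")
  if (is.unsorted(options))
    stop("portion options must be nondecreasing")
  if (length(anchors) != 3 || is.unsorted(anchors))
    stop("anchors must be c(p25, p50, p75) with p25 <= p50 <= p75")
  if (!all(anchors %in% options))
    stop("anchors must appear among the portion options")
  structure(list(options = options, anchors = anchors),
            class = "ffq_portion_series")
}

#' Assemble an FFQ instrument
#'
#' @param name Instrument name (used to guard against scoring a response
#'   file with the wrong instrument).
#' @param categories Ordered character vector of questionnaire categories.
#' @param frequency_scale An [frequency_scale()] object.
#' @param items Data frame with columns `item_id`, `name`, `category`,
#'   `composition_ref`, `food_group` and optionally `fixture` (logical,
#'   marks placeholder items in packaged fixtures).
#' @param portions Named list of [portion_series()] objects, one per
#'   `item_id`.
#' @return A validated object of class `ffq_instrument`.
#' @seealso [food4me_instrument()], [epic_norfolk_instrument()],
#'   [load_instrument()]
#' @export
ffq_instrument <- function(name, categories, frequency_scale, items, portions) {
  if (!"fixture" %in% names(items)) items$fixture <- FALSE
  items <- as.data.frame(items, stringsAsFactors = FALSE)
  rownames(items) <- NULL
  x <- structure(
    list(name = as.character(name), schema_version = "1.0",
         categories = as.character(categories),
         frequency_scale = frequency_scale,
         items = as.data.frame(items, stringsAsFactors = FALSE),
         portions = portions),
    class = "ffq_instrument")
  validate_instrument(x)
}

#' Validate an instrument
#'
#' Checks the structural invariants: unique item ids, every item's category
#' registered, a total food-group map with nonempty labels, a well-formed
#' frequency scale, and one valid portion series per item. Errors name the
#' offending item.
#'
#' @param x An `ffq_instrument`.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_instrument <- function(x) {
  if (!inherits(x, "ffq_instrument")) stop("not an ffq_instrument")
  items <- x$items
  if (nrow(items) == 0) stop("invalid instrument: empty item list")
  needed <- c("item_id", "name", "category", "composition_ref", "food_group")
  missing_cols <- setdiff(needed, names(items))
  if (length(missing_cols))
    stop("invalid instrument: missing item field(s) ",
         paste(missing_cols, collapse = ", "))
  dup <- unique(items$item_id[duplicated(items$item_id)])
  if (length(dup))
    stop("invalid instrument: duplicate item_id ", paste(dup, collapse = ", "))
  bad_cat <- items$item_id[!items$category %in% x$categories]
  if (length(bad_cat))
    stop("invalid instrument: unknown category for item(s) ",
         paste(bad_cat, collapse = ", "))
  if (any(!nzchar(items$food_group)) || anyNA(items$food_group))
    stop("invalid instrument: empty food_group label for item(s) ",
         paste(items$item_id[!nzchar(items$food_group) | is.na(items$food_group)],
               collapse = ", "))
  if (!inherits(x$frequency_scale, "ffq_frequency_scale"))
    stop("invalid instrument: frequency_scale is not an ffq_frequency_scale")
  no_series <- setdiff(items$item_id, names(x$portions))
  if (length(no_series))
    stop("invalid instrument: missing portion series for item(s) ",
         paste(no_series, collapse = ", "))
  for (id in items$item_id) {
    ps <- x$portions[[id]]
    if (!inherits(ps, "ffq_portion_series"))
      stop("invalid instrument: portion series for item ", id,
           " is not an ffq_portion_series")
  }
  invisible(x)
}

#' @export
print.ffq_instrument <- function(x, ...) {
  cat("FFQ instrument '", x$name, "'\n", sep = "")
  cat("  items:      ", nrow(x$items), "\n", sep = "")
  cat("  categories: ", length(x$categories), "\n", sep = "")
  cat("  frequency scale: ", length(x$frequency_scale$labels),
      " levels\n", sep = "")
  cat("  food groups:", length(unique(x$items$food_group)), "\n")
  invisible(x)
}

#' Food-group map of an instrument
#'
#' @param instrument An `ffq_instrument`.
#' @return Named character vector mapping `item_id` to food-group label;
#'   total over the instrument's items by construction.
#' @export
food_group_map <- function(instrument) {
  stats::setNames(instrument$items$food_group, instrument$items$item_id)
}

#' Write an instrument definition file
#'
#' Serializes an instrument to a YAML file with an explicit
#' `schema_version` field. [load_instrument()] round-trips the file to an
#' identical object (numeric fields are written at 17 significant digits).
#'
#' @param instrument An `ffq_instrument`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_instrument <- function(instrument, path) {
  validate_instrument(instrument)
  doc <- list(
    schema_version = instrument$schema_version,
    name = instrument$name,
    categories = as.list(instrument$categories),
    frequency_scale = list(
      labels = as.list(instrument$frequency_scale$labels),
      multipliers = as.list(instrument$frequency_scale$multipliers)
    ),
    items = lapply(seq_len(nrow(instrument$items)), function(i) {
      it <- instrument$items[i, ]
      ps <- instrument$portions[[it$item_id]]
      list(item_id = it$item_id, name = it$name, category = it$category,
           composition_ref = it$composition_ref, food_group = it$food_group,
           fixture = it$fixture,
           portion_options = as.list(ps$options),
           portion_anchors = as.list(ps$anchors))
    })
  )
  writeLines(yaml::as.yaml(doc, precision = 17L), path)
  invisible(path)
}

#' Load an instrument definition file
#'
#' Reads a YAML instrument definition (see [write_instrument()] for the
#' dialect), reconstructs the object, validates it, and logs item and
#' category counts.
#'
#' @param path Path to the definition file.
#' @param quiet Suppress the load log line.
#' @return A validated `ffq_instrument`.
#' @export
load_instrument <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("instrument file not found: ", path)
  doc <- yaml::read_yaml(path)
  needed <- c("schema_version", "name", "categories", "frequency_scale", "items")
  missing_fields <- setdiff(needed, names(doc))
  if (length(missing_fields))
    stop("invalid instrument file: missing field(s) ",
         paste(missing_fields, collapse = ", "))
  if (length(doc$items) == 0) stop("invalid instrument: empty item list")
  items <- do.call(rbind, lapply(doc$items, function(it) {
    for (f in c("item_id", "name", "category", "composition_ref",
                "food_group", "portion_options"))
      if (is.null(it[[f]]))
        stop("invalid instrument file: item missing field '", f, "'",
             if (!is.null(it$item_id)) paste0(" (item ", it$item_id, ")"))
    data.frame(item_id = it$item_id, name = it$name, category = it$category,
               composition_ref = it$composition_ref,
               food_group = it$food_group,
               fixture = isTRUE(it$fixture), stringsAsFactors = FALSE)
  }))
  portions <- stats::setNames(lapply(doc$items, function(it) {
    tryCatch(
      portion_series(unlist(it$portion_options), unlist(it$portion_anchors)),
      error = function(e) stop("invalid portion series for item ",
                               it$item_id, ": ", conditionMessage(e)))
  }), items$item_id)
  x <- ffq_instrument(doc$name, unlist(doc$categories),
                      frequency_scale(unlist(doc$frequency_scale$labels),
                                      unlist(doc$frequency_scale$multipliers)),
                      items, portions)
  x$schema_version <- as.character(doc$schema_version)
  if (!quiet)
    message("loaded instrument '", x$name, "': ", nrow(x$items),
            " items in ", length(x$categories), " categories")
  x
}
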