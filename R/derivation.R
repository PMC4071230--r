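#' Derive per-item nutrient composition from consumption-survey records
#'
#' For every FFQ item, the consumption-survey foods mapped to it are ranked
#' by how often they were consumed (number of records), the `k` most
#' frequently consumed are selected, and the item's per-100 g composition is
#' the unweighted arithmetic mean of their per-100 g nutrient vectors. Items
#' mapped to fewer than `k` distinct foods average all of them. Ties in
#' occurrence count are broken lexicographically by `food_code` so the
#' selection is deterministic.
#'
#' @param records Data frame of consumption records with columns
#'   `respondent_id`, `food_code`, `item_id`, `amount` (grams/day, > 0).
#' @param foods Data frame of per-100 g food composition entries: column
#'   `food_code` plus the full [nutrient_panel()] columns, all nonnegative.
#' @param k Number of top foods to average (default 3).
#' @param items Optional character vector of item ids that must be covered;
#'   an item with zero mapped records raises an error rather than receiving
#'   a silent zero composition.
#' @param rank_by `"occurrences"` (default) ranks foods by record count;
#'   `"consumers"` ranks by number of distinct respondents consuming them.
#' @return An object of class `ffq_composition`: a data frame with column
#'   `item_id` and one column per nutrient, with a `provenance` attribute
#'   listing the selected food codes per item.
#' @export
#' @examples
#' foods <- data.frame(food_code = c("f1", "f2"),
#'                     matrix(1:2, 2, 24,
#'                            dimnames = list(NULL, nutrient_panel()$key)))
#' recs <- data.frame(respondent_id = c("r1", "r1", "r2"),
#'                    food_code = c("f1", "f1", "f2"),
#'                    item_id = "item", amount = 100)
#' derive_composition(recs, foods, k = 1)
derive_composition <- function(records, foods, k = 3, items = NULL,
                               rank_by = c("occurrences", "consumers")) {
  rank_by <- match.arg(rank_by)
  stopifnot(k >= 1)
  check_records(records)
  nut <- nutrient_keys()
  missing_nut <- setdiff(nut, names(foods))
  if (length(missing_nut))
    stop("food composition table missing nutrient column(s): ",
         paste(missing_nut, collapse = ", "))
  if (any(as.matrix(foods[, nut]) < 0, na.rm = TRUE))
    stop("food composition values must be nonnegative")
  unknown <- setdiff(records$food_code, foods$food_code)
  if (length(unknown))
    stop("records reference food_code(s) with no composition entry: ",
         paste(unique(unknown), collapse = ", "))
  if (!is.null(items)) {
    uncovered <- setdiff(items, records$item_id)
    if (length(uncovered))
      stop("item(s) with zero mapped consumption records: ",
           paste(uncovered, collapse = ", "))
  }
  item_ids <- if (is.null(items)) unique(records$item_id) else items
  provenance <- list()
  rows <- lapply(item_ids, function(id) {
    recs <- records[records$item_id == id, ]
    counts <- if (rank_by == "occurrences") {
      tapply(recs$food_code, recs$food_code, length)
    } else {
      tapply(recs$respondent_id, recs$food_code,
             function(r) length(unique(r)))
    }
    ord <- order(-as.numeric(counts), names(counts))
    top <- names(counts)[ord][seq_len(min(k, length(counts)))]
    provenance[[id]] <<- top
    vecs <- foods[match(top, foods$food_code), nut, drop = FALSE]
    colMeans(as.matrix(vecs))
  })
  out <- data.frame(item_id = item_ids, do.call(rbind, rows),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, provenance = provenance, class = c("ffq_composition",
                                                    "data.frame"))
}

check_records <- function(records) {
  needed <- c("respondent_id", "food_code", "item_id", "amount")
  if (!all(needed %in% names(records)))
    stop("consumption records must have columns ",
         paste(needed, collapse = ", "))
  if (anyNA(records$amount) || any(!is.finite(records$amount)) ||
      any(records$amount <= 0))
    stop("record amounts must be finite and positive")
  invisible(records)
}

#' Derive a portion-size series from consumption-survey records
#'
#' Portion anchors are the 25th, 50th and 75th percentiles of intake of the
#' item in the survey population (small, medium and large portions),
#' computed by linear interpolation between order statistics
#' ([stats::quantile()] type 7). The packaged default follows the
#' daily-intake convention (amounts summed per respondent before taking
#' percentiles); `per = "occasion"` uses raw per-record amounts instead.
#' The 7-option series adds options below, above and between the anchors:
#' `0.5*p25, p25, (p25+p50)/2, p50, (p50+p75)/2, p75, 1.5*p75`, rounded to
#' 0.1 g. If rounding collapses adjacent options (including the fully
#' degenerate constant-amount case), the series falls back to the
#' multiplicative grid `{0.5, 0.75, 0.9, 1, 1.1, 1.25, 1.5} * p50` so the
#' result always has `n_options` nondecreasing options.
#'
#' @param records Consumption-record data frame (see
#'   [derive_composition()]).
#' @param item_id Item to derive a series for; at least one record needed.
#' @param n_options Series length (default 7).
#' @param per `"daily"` (default) or `"occasion"`.
#' @return An `ffq_portion_series`.
#' @export
derive_portion_series <- function(records, item_id, n_options = 7,
                                  per = c("daily", "occasion")) {
  per <- match.arg(per)
  check_records(records)
  recs <- records[records$item_id == item_id, ]
  if (nrow(recs) == 0)
    stop("no consumption records for item ", item_id)
  amounts <- if (per == "daily") {
    as.numeric(tapply(recs$amount, recs$respondent_id, sum))
  } else {
    recs$amount
  }
  q <- unname(stats::quantile(amounts, c(0.25, 0.5, 0.75), type = 7))
  opts <- round(c(0.5 * q[1], q[1], mean(q[1:2]), q[2], mean(q[2:3]),
                  q[3], 1.5 * q[3]), 1)
  anchors <- opts[c(2L, 4L, 6L)]
  if (anyDuplicated(opts) || length(opts) != n_options) {
    opts <- round(q[2] * c(0.5, 0.75, 0.9, 1, 1.1, 1.25, 1.5), 1)[
      seq_len(n_options)]
    anchors <- opts[c(2L, 4L, 6L)]
  }
  portion_series(opts, anchors)
}
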