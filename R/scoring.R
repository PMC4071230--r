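#' Per-day multiplier for a frequency category
#'
#' @param scale An [frequency_scale()] object.
#' @param category_index 1-based index into the scale.
#' @return Events per day (numeric).
#' @export
#' @examples
#' frequency_multiplier(default_frequency_scale(), 6)  # "once a day" -> 1
frequency_multiplier <- function(scale, category_index) {
  stopifnot(inherits(scale, "ffq_frequency_scale"))
  n <- length(scale$multipliers)
  if (any(category_index < 1 | category_index > n |
          category_index != round(category_index)))
    stop("frequency category index out of range 1..", n)
  scale$multipliers[category_index]
}

# Core scoring engine shared by score_response() and score_cohort().
# resp: long data frame respondent_id/item_id/frequency_index/portion_index,
# assumed validated. Returns list(grams = respondents x items matrix,
# nutrients = respondents x nutrient matrix, groups = respondents x group).
score_engine <- function(instrument, composition, resp) {
  items <- instrument$items$item_id
  resp_ids <- unique(resp$respondent_id)
  miss_comp <- setdiff(items, composition$item_id)
  if (length(miss_comp))
    stop("composition table missing item(s): ",
         paste(miss_comp, collapse = ", "))
  mult <- instrument$frequency_scale$multipliers
  # portion grams chosen for each row of the long table
  item_pos <- match(resp$item_id, items)
  grams_row <- mult[resp$frequency_index] *
    mapply(function(pos, pi) instrument$portions[[items[pos]]]$options[pi],
           item_pos, resp$portion_index)
  G <- matrix(0, nrow = length(resp_ids), ncol = length(items),
              dimnames = list(resp_ids, items))
  G[cbind(match(resp$respondent_id, resp_ids), item_pos)] <- grams_row
  nut <- nutrient_keys()
  C <- as.matrix(composition[match(items, composition$item_id), nut])
  rownames(C) <- items
  nutrients <- G %*% C / 100
  groups <- aggregate_food_groups(G, food_group_map(instrument))
  list(grams = G, nutrients = nutrients, groups = groups)
}

#' Score one response set into daily intakes
#'
#' Per item, grams/day = frequency multiplier x chosen portion grams; per
#' nutrient, intake/day = sum over items of grams/day x per-100 g value /
#' 100. Food-group intakes are the gram sums over each group's member
#' items. Scoring is deterministic and linear in the per-item grams.
#'
#' @param instrument An `ffq_instrument`.
#' @param composition An `ffq_composition` (or data frame with `item_id`
#'   plus the nutrient panel columns) covering every instrument item.
#' @param response An `ffq_response_set` that passes
#'   [validate_response()] with an empty report.
#' @return An object of class `ffq_intake`: list with `respondent_id`,
#'   `nutrients` (named vector, daily units of [nutrient_panel()]),
#'   `pct_te` (named vector, see [percent_energy()]), `groups` (named
#'   grams/day vector over [food_groups()]) and `per_item_grams` (audit
#'   trail).
#' @export
score_response <- function(instrument, composition, response) {
  report <- validate_response(instrument, response)
  if (nrow(report) > 0)
    stop("response for ", response$respondent_id, " is not scoreable: ",
         nrow(report), " validation problem(s); first: ",
         report$item_id[1], " (", report$problem[1], ")")
  resp <- data.frame(respondent_id = response$respondent_id,
                     response$answers, stringsAsFactors = FALSE)
  eng <- score_engine(instrument, composition, resp)
  nutrients <- eng$nutrients[1, ]
  structure(list(respondent_id = response$respondent_id,
                 nutrients = nutrients,
                 pct_te = pct_te_vector(nutrients),
                 groups = eng$groups[1, ],
                 per_item_grams = stats::setNames(as.numeric(eng$grams[1, ]),
                                                  colnames(eng$grams))),
            class = "ffq_intake")
}

#' @export
print.ffq_intake <- function(x, ...) {
  cat("FFQ intake for respondent ", x$respondent_id, "\n", sep = "")
  cat("  energy: ", round(x$nutrients[["energy_kcal"]], 1), " kcal/day\n",
      sep = "")
  cat("  nutrients: ", length(x$nutrients), ", food groups: ",
      length(x$groups), "\n", sep = "")
  invisible(x)
}

#' Score a cohort of responses into an intake table
#'
#' Vectorized scoring of a long-format response table; each respondent must
#' completely answer the instrument. Returns one row per respondent with
#' nutrient columns (daily units as in [nutrient_panel()]), percent-energy
#' columns (`pct_te_*`) and food-group gram columns (`fg_*`).
#'
#' @param instrument An `ffq_instrument`.
#' @param composition Composition table covering all items.
#' @param responses Long data frame (see [responses_from_long()]) or a list
#'   of `ffq_response_set` objects.
#' @return Data frame of class `ffq_intake_table`.
#' @export
score_cohort <- function(instrument, composition, responses) {
  if (is.list(responses) && !is.data.frame(responses))
    responses <- responses_to_long(responses)
  sets <- responses_from_long(responses)
  for (r in sets) {
    if (is.na(r$instrument_name)) r$instrument_name <- instrument$name
    rep <- validate_response(instrument, r)
    if (nrow(rep) > 0)
      stop("response for ", r$respondent_id, " is not scoreable (",
           rep$problem[1], ": ", rep$item_id[1], ")")
  }
  eng <- score_engine(instrument, composition, responses)
  pct <- t(apply(eng$nutrients, 1, pct_te_vector))
  groups <- eng$groups
  colnames(groups) <- paste0("fg_", colnames(groups))
  out <- data.frame(respondent_id = rownames(eng$nutrients),
                    eng$nutrients, pct, groups,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- NULL
  class(out) <- c("ffq_intake_table", "data.frame")
  out
}

# %TE vector from a nutrient vector; NA when energy is zero (undefined,
# never reported as 0).
pct_te_vector <- function(nutrients, factors = energy_factors()) {
  te <- te_nutrients()
  energy <- nutrients[["energy_kcal"]]
  vals <- vapply(names(te), function(nk) {
    if (energy <= 0) return(NA_real_)
    factors[[te[[nk]]]] * nutrients[[nk]] * 100 / energy
  }, numeric(1))
  stats::setNames(vals, pct_te_column(names(te)))
}

#' Percent of total energy from macronutrients
#'
#' Computes %TE = factor x grams x 100 / energy for fat (and its saturated,
#' mono- and polyunsaturated fractions), protein and carbohydrate, using
#' the conversion factors of [energy_factors()]. With
#' `energy_from_components = TRUE` energy is recomputed as the sum of the
#' fat, protein, carbohydrate and alcohol contributions (in which case fat
#' + protein + carbohydrate + alcohol %TE is exactly 100); by default the
#' composition-table energy field is used, as in database-driven scoring.
#' Rows with zero energy get `NA` %TE (undefined, not 0).
#'
#' @param intakes An `ffq_intake_table` (or data frame with the nutrient
#'   columns).
#' @param factors kcal/g conversion factors, as [energy_factors()].
#' @param energy_from_components Recompute energy from macronutrients.
#' @return `intakes` with the `pct_te_*` columns (re)computed.
#' @export
percent_energy <- function(intakes, factors = energy_factors(),
                           energy_from_components = FALSE) {
  energy <- if (energy_from_components) {
    factors[["fat"]] * intakes$fat_g + factors[["protein"]] * intakes$protein_g +
      factors[["carbohydrate"]] * intakes$carbohydrate_g +
      factors[["alcohol"]] * intakes$alcohol_g
  } else {
    intakes$energy_kcal
  }
  te <- te_nutrients()
  for (nk in names(te)) {
    v <- factors[[te[[nk]]]] * intakes[[nk]] * 100 / energy
    v[energy <= 0] <- NA_real_
    intakes[[pct_te_column(nk)]] <- v
  }
  if (energy_from_components) {
    v <- factors[["alcohol"]] * intakes$alcohol_g * 100 / energy
    v[energy <= 0] <- NA_real_
    intakes[["pct_te_alcohol"]] <- v
  }
  intakes
}

#' Aggregate per-item grams into food-group intakes
#'
#' @param per_item_grams Named numeric vector (one respondent) or a
#'   respondents x items matrix of grams/day.
#' @param map Named character vector `item_id -> group` covering every item
#'   present (see [food_group_map()]); an unmapped item is an error.
#' @param groups Group universe; groups with no member items present are 0.
#' @return Named vector (or respondents x groups matrix) of grams/day.
#' @export
aggregate_food_groups <- function(per_item_grams, map,
                                  groups = food_groups()) {
  vec <- !is.matrix(per_item_grams)
  G <- if (vec) matrix(per_item_grams, nrow = 1,
                       dimnames = list(NULL, names(per_item_grams)))
       else per_item_grams
  unmapped <- setdiff(colnames(G), names(map))
  if (length(unmapped))
    stop("item(s) missing from food-group map: ",
         paste(unmapped, collapse = ", "))
  item_groups <- map[colnames(G)]
  groups <- union(groups, item_groups)
  out <- matrix(0, nrow = nrow(G), ncol = length(groups),
                dimnames = list(rownames(G), groups))
  for (g in unique(item_groups)) {
    out[, g] <- rowSums(G[, item_groups == g, drop = FALSE])
  }
  if (vec) out[1, ] else out
}

#' Write an intake table with a units header
#'
#' Writes the cohort intake table as CSV preceded by a commented units
#' line (nutrient units per [nutrient_panel()], `%` for `pct_te_*`,
#' `g/day` for food groups).
#'
#' @param intakes An `ffq_intake_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_intakes <- function(intakes, path) {
  panel <- nutrient_panel()
  units <- vapply(names(intakes), function(cn) {
    if (cn %in% panel$key) panel$unit[match(cn, panel$key)]
    else if (startsWith(cn, "pct_te_")) "%"
    else if (startsWith(cn, "fg_")) "g/day"
    else ""
  }, character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", paste(names(intakes), units, sep = "=",
                                       collapse = ";")), con)
  utils::write.csv(intakes, con, row.names = FALSE)
  invisible(path)
}

#' Read an intake table written by [write_intakes()]
#'
#' @param path CSV path.
#' @return Data frame of class `ffq_intake_table`.
#' @export
read_intakes <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                        check.names = FALSE)
  class(df) <- c("ffq_intake_table", "data.frame")
  df
}
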