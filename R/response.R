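#' A respondent's answers to an FFQ
#'
#' One frequency category and one portion option per food item. The online
#' delivery system enforces completeness, so a scoreable response set covers
#' every item of its instrument; [validate_response()] reports any gap.
#'
#' @param respondent_id Respondent identifier.
#' @param instrument_name Name of the instrument the answers belong to.
#' @param completion_date Completion date, ISO-8601 (`"YYYY-MM-DD"`).
#' @param answers Data frame with columns `item_id`, `frequency_index`,
#'   `portion_index` (1-based indices into the instrument's frequency scale
#'   and the item's portion series).
#' @return An object of class `ffq_response_set`.
#' @export
response_set <- function(respondent_id, instrument_name, completion_date,
                         answers) {
  answers <- as.data.frame(answers, stringsAsFactors = FALSE)
  needed <- c("item_id", "frequency_index", "portion_index")
  if (!all(needed %in% names(answers)))
    stop("answers must have columns ", paste(needed, collapse = ", "))
  if (anyDuplicated(answers$item_id))
    stop("duplicate item_id in answers for respondent ", respondent_id)
  structure(list(respondent_id = as.character(respondent_id),
                 instrument_name = as.character(instrument_name),
                 completion_date = as.character(completion_date),
                 answers = answers[, needed]),
            class = "ffq_response_set")
}

#' Validate a response set against an instrument
#'
#' Checks instrument identity, completeness (every item answered), and that
#' every frequency and portion index is within bounds. An empty report means
#' the response is scoreable; [score_response()] succeeds exactly when this
#' report is empty.
#'
#' @param instrument An `ffq_instrument`.
#' @param response An `ffq_response_set` claiming the same instrument name.
#' @return A data frame with columns `item_id` and `problem`; zero rows when
#'   the response is valid.
#' @export
validate_response <- function(instrument, response) {
  stopifnot(inherits(instrument, "ffq_instrument"),
            inherits(response, "ffq_response_set"))
  if (!identical(response$instrument_name, instrument$name))
    stop("response claims instrument '", response$instrument_name,
         "' but was validated against '", instrument$name, "'")
  ans <- response$answers
  report <- list()
  missing_items <- setdiff(instrument$items$item_id, ans$item_id)
  if (length(missing_items))
    report$missing <- data.frame(item_id = missing_items,
                                 problem = "missing", stringsAsFactors = FALSE)
  unknown <- setdiff(ans$item_id, instrument$items$item_id)
  if (length(unknown))
    report$unknown <- data.frame(item_id = unknown,
                                 problem = "unknown_item",
                                 stringsAsFactors = FALSE)
  known <- ans[ans$item_id %in% instrument$items$item_id, ]
  n_freq <- length(instrument$frequency_scale$multipliers)
  bad_f <- known$item_id[is.na(known$frequency_index) |
                           known$frequency_index < 1 |
                           known$frequency_index > n_freq |
                           known$frequency_index != round(known$frequency_index)]
  if (length(bad_f))
    report$freq <- data.frame(item_id = bad_f,
                              problem = "frequency_index_out_of_range",
                              stringsAsFactors = FALSE)
  n_opt <- vapply(instrument$portions[known$item_id],
                  function(ps) length(ps$options), integer(1))
  bad_p <- known$item_id[is.na(known$portion_index) |
                           known$portion_index < 1 |
                           known$portion_index > n_opt |
                           known$portion_index != round(known$portion_index)]
  if (length(bad_p))
    report$portion <- data.frame(item_id = bad_p,
                                 problem = "portion_index_out_of_range",
                                 stringsAsFactors = FALSE)
  out <- if (length(report)) do.call(rbind, unname(report)) else
    data.frame(item_id = character(0), problem = character(0),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Read a long-format response table
#'
#' Responses travel as a delimited table with one row per (respondent,
#' item): columns `respondent_id`, `item_id`, `frequency_index`,
#' `portion_index`, plus `instrument_name` and `completion_date`
#' (constant per respondent).
#'
#' @param path CSV file path.
#' @return A list of `ffq_response_set` objects, named by respondent id.
#' @export
read_responses <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  responses_from_long(df)
}

#' Split a long response data frame into response sets
#'
#' @param df Data frame with columns `respondent_id`, `item_id`,
#'   `frequency_index`, `portion_index` and optionally `instrument_name`,
#'   `completion_date`.
#' @return Named list of `ffq_response_set` objects.
#' @export
responses_from_long <- function(df) {
  needed <- c("respondent_id", "item_id", "frequency_index", "portion_index")
  if (!all(needed %in% names(df)))
    stop("response table must have columns ", paste(needed, collapse = ", "))
  if (!"instrument_name" %in% names(df)) df$instrument_name <- NA_character_
  if (!"completion_date" %in% names(df)) df$completion_date <- NA_character_
  split_df <- split(df, df$respondent_id)
  out <- lapply(split_df, function(d)
    response_set(d$respondent_id[1], d$instrument_name[1],
                 d$completion_date[1],
                 d[, c("item_id", "frequency_index", "portion_index")]))
  out[unique(df$respondent_id)]
}

#' Flatten response sets to a long data frame
#'
#' Inverse of [responses_from_long()]; used to write response files.
#'
#' @param responses List of `ffq_response_set` objects.
#' @return Long-format data frame.
#' @export
responses_to_long <- function(responses) {
  if (inherits(responses, "ffq_response_set")) responses <- list(responses)
  do.call(rbind, lapply(responses, function(r) {
    cbind(data.frame(respondent_id = r$respondent_id,
                     instrument_name = r$instrument_name,
                     completion_date = r$completion_date,
                     stringsAsFactors = FALSE),
          r$answers)
  }))
}

#' Read a demographics table
#'
#' Expects columns `respondent_id`, `sex` (`"male"`/`"female"`), `age_y`,
#' `weight_kg`, `height_cm`, and one ISO-8601 completion-date column per
#' instrument (`date_a`, `date_b`).
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_demographics <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("respondent_id", "sex", "age_y", "weight_kg", "height_cm")
  if (!all(needed %in% names(df)))
    stop("demographics table must have columns ",
         paste(needed, collapse = ", "))
  df
}
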