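KCAL_PER_MJ <- 239.005736

#' Henry BMR coefficient table
#'
#' The published adult weight-and-height basal metabolic rate equations,
#' shipped as a versioned data file
#' (`inst/extdata/henry_coefficients.csv`): per sex and age band,
#' BMR (MJ/day) = weight_coef x weight (kg) + height_coef x height (m) +
#' intercept. Bands are lower-inclusive (`[age_min, age_max)`), so age 30
#' falls in the 30--60 band.
#'
#' @return Data frame with columns `sex`, `age_min`, `age_max`,
#'   `weight_coef`, `height_coef`, `intercept`.
#' @export
henry_coefficients <- function() {
  path <- system.file("extdata", "henry_coefficients.csv",
                      package = "ffqtools")
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Basal metabolic rate by the Henry weight-and-height equations
#'
#' Evaluates the sex- and age-band coefficients of
#' [henry_coefficients()] and converts MJ/day to kcal/day
#' (x 239.005736). Vectorized over respondents. Ages below the lowest band
#' (18 y) are an error, not an extrapolation.
#'
#' @param sex `"male"` or `"female"` (vector ok).
#' @param age Age in years.
#' @param weight_kg Body weight, kg.
#' @param height_cm Height, cm.
#' @param coefficients Coefficient table; defaults to the packaged file.
#' @return BMR in kcal/day.
#' @export
#' @examples
#' bmr_henry("male", 30, 77.3, 178)
bmr_henry <- function(sex, age, weight_kg, height_cm,
                      coefficients = henry_coefficients()) {
  n <- max(length(sex), length(age), length(weight_kg), length(height_cm))
  sex <- rep_len(as.character(sex), n); age <- rep_len(age, n)
  weight_kg <- rep_len(weight_kg, n); height_cm <- rep_len(height_cm, n)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  if (anyNA(age) || anyNA(weight_kg) || anyNA(height_cm) ||
      any(weight_kg <= 0) || any(height_cm <= 0))
    stop("age, weight and height must be positive and non-missing")
  vapply(seq_len(n), function(i) {
    band <- coefficients[coefficients$sex == sex[i] &
                           age[i] >= coefficients$age_min &
                           age[i] < coefficients$age_max, ]
    if (nrow(band) == 0)
      stop("age ", age[i], " is below the lowest coefficient band (",
           min(coefficients$age_min[coefficients$sex == sex[i]]),
           " y); refusing to extrapolate")
    mj <- band$weight_coef * weight_kg[i] +
      band$height_coef * height_cm[i] / 100 + band$intercept
    mj * KCAL_PER_MJ
  }, numeric(1))
}

#' Classify under-reporting of energy intake
#'
#' The lowest plausible estimated energy requirement (EER floor) is 1.1 x
#' BMR; a respondent reporting a daily energy intake strictly lower than
#' this floor is flagged as an under-reporter. Intake exactly at the floor
#' is not flagged.
#'
#' @param energy_intake Reported energy, kcal/day (> 0).
#' @param bmr Basal metabolic rate, kcal/day (> 0).
#' @param floor_factor EER floor multiplier (default 1.1).
#' @return Logical vector of under-reporter flags.
#' @export
#' @examples
#' classify_under_reporter(1600, 1500)  # floor 1650 -> TRUE
classify_under_reporter <- function(energy_intake, bmr, floor_factor = 1.1) {
  if (anyNA(bmr) || any(bmr <= 0)) stop("bmr must be positive")
  if (anyNA(energy_intake) || any(energy_intake <= 0))
    stop("energy intake must be positive")
  energy_intake < floor_factor * bmr
}

#' Energy-plausibility screening report
#'
#' Computes, per respondent, the Henry BMR, the EER floor (1.1 x BMR), and
#' the per-instrument under-reporter flag, plus the concordance between the
#' two instruments' flags (share of instrument-B under-reporters also
#' flagged by instrument A).
#'
#' @param demographics Data frame as in [read_demographics()].
#' @param energy_a,energy_b Named or demographics-aligned vectors of daily
#'   energy (kcal) for instruments A and B.
#' @return List with `table` (per-respondent data frame: `bmr`,
#'   `eer_floor`, `under_reporter_a`, `under_reporter_b`), `n_under_a`,
#'   `n_under_b`, and `concordance_b_in_a` (percentage, `NA` when B flags
#'   nobody).
#' @export
screen_under_reporting <- function(demographics, energy_a, energy_b) {
  bmr <- bmr_henry(demographics$sex, demographics$age_y,
                   demographics$weight_kg, demographics$height_cm)
  ua <- classify_under_reporter(energy_a, bmr)
  ub <- classify_under_reporter(energy_b, bmr)
  list(
    table = data.frame(respondent_id = demographics$respondent_id,
                       bmr = bmr, eer_floor = 1.1 * bmr,
                       under_reporter_a = ua, under_reporter_b = ub,
                       stringsAsFactors = FALSE),
    n_under_a = sum(ua), n_under_b = sum(ub),
    concordance_b_in_a = if (sum(ub) > 0) 100 * sum(ua & ub) / sum(ub)
                         else NA_real_
  )
}

#' Participant-flow exclusion filters
#'
#' Applies the paired-administration exclusion rules: respondents with more
#' than `gap_days` calendar days between completing the two instruments are
#' excluded (strictly greater; a gap of exactly `gap_days` is retained),
#' and respondents reporting implausibly high energy (strictly above
#' `energy_max` kcal/day) on the configured instrument(s) are excluded. A
#' respondent with a missing completion date is excluded with reason
#' `"incomplete"`, never silently dropped. The filter is idempotent and
#' order-stable.
#'
#' @param demographics Data frame with `respondent_id`, `date_a`, `date_b`
#'   (ISO-8601 completion dates).
#' @param energy_a,energy_b Daily energy (kcal) per instrument, aligned
#'   with `demographics` rows.
#' @param gap_days Maximum allowed completion gap (default 28 = 4 weeks).
#' @param energy_max Energy exclusion threshold, kcal/day (default 4500).
#' @param energy_rule Which instrument(s) the energy rule applies to:
#'   `"b"` (default, the online instrument), `"a"`, or `"both"`.
#' @return List with `retained` (respondent ids, input order) and
#'   `exclusions` (data frame `respondent_id`, `reasons`
#'   (semicolon-joined from `gap_gt_4_weeks`, `energy_gt_threshold`,
#'   `incomplete`)).
#' @export
apply_exclusions <- function(demographics, energy_a, energy_b,
                             gap_days = 28, energy_max = 4500,
                             energy_rule = c("b", "a", "both")) {
  energy_rule <- match.arg(energy_rule)
  ids <- demographics$respondent_id
  da <- as.Date(demographics$date_a)
  db <- as.Date(demographics$date_b)
  reasons <- lapply(seq_along(ids), function(i) {
    r <- character(0)
    if (is.na(da[i]) || is.na(db[i])) {
      r <- c(r, "incomplete")
    } else if (abs(as.numeric(db[i] - da[i])) > gap_days) {
      r <- c(r, "gap_gt_4_weeks")
    }
    high <- switch(energy_rule,
                   b = energy_b[i] > energy_max,
                   a = energy_a[i] > energy_max,
                   both = energy_a[i] > energy_max | energy_b[i] > energy_max)
    if (isTRUE(high)) r <- c(r, "energy_gt_threshold")
    r
  })
  excluded <- lengths(reasons) > 0
  list(
    retained = ids[!excluded],
    exclusions = data.frame(
      respondent_id = ids[excluded],
      reasons = vapply(reasons[excluded], paste, character(1),
                       collapse = ";"),
      stringsAsFactors = FALSE)
  )
}
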