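#' Specification of a synthetic paired-FFQ cohort
#'
#' Collects the generator's study conditions: cohort size, per-method
#' multiplicative reporting bias, lognormal reporting noise, the fraction
#' of designated under-reporters, per-item consumption probability, the
#' respondent-level daily-energy distribution, and the distribution of the
#' gap between the two completion dates. The seed fixes the full output
#' stream: identical spec + seed gives byte-identical outputs.
#'
#' @param n_respondents Cohort size (>= 0).
#' @param bias_a,bias_b Multiplicative reporting bias of each method
#'   (> 0; 1 = unbiased).
#' @param noise_sd SD of lognormal reporting noise on each observed
#'   item amount (0 = noise-free).
#' @param under_reporter_fraction Fraction of respondents whose reported
#'   intake is scaled below their EER floor (in `[0, 1]`).
#' @param consume_prob Probability a respondent consumes a given item at
#'   all (non-consumers answer "never").
#' @param energy_median,energy_sdlog Lognormal parameters of true daily
#'   energy intake across respondents (kcal/day).
#' @param gap_mean_days Mean (Poisson) gap between the two completion
#'   dates.
#' @param seed Default seed used when the generator functions are not
#'   given one explicitly.
#' @return Object of class `ffq_cohort_spec`.
#' @export
cohort_spec <- function(n_respondents = 100, bias_a = 1, bias_b = 1,
                        noise_sd = 0.25, under_reporter_fraction = 0.1,
                        consume_prob = 0.8, energy_median = 2300,
                        energy_sdlog = 0.22, gap_mean_days = 7,
                        seed = 1L) {
  stopifnot(n_respondents >= 0, bias_a > 0, bias_b > 0, noise_sd >= 0,
            under_reporter_fraction >= 0, under_reporter_fraction <= 1,
            consume_prob >= 0, consume_prob <= 1, energy_median > 0)
  structure(as.list(environment()), class = "ffq_cohort_spec")
}

# plausible per-100 g energy density ranges (kcal) by questionnaire category
category_energy_range <- function(category) {
  switch(category,
         "cereal" = c(330, 400),
         "bread and savory biscuits" = c(230, 320),
         "potatoes, rice, and pasta" = c(90, 180),
         "meat and fish" = c(110, 260),
         "dairy products" = c(60, 350),
         "fats and spreads" = c(380, 750),
         "sweets and snacks" = c(330, 550),
         "soups, sauces, and spreads" = c(40, 150),
         "drinks" = c(5, 90),
         "fruit" = c(40, 90),
         "vegetables" = c(15, 80),
         c(50, 300))
}

#' Generate a plausible per-item composition table
#'
#' Draws a per-100 g nutrient vector for every instrument item:
#' category-typical energy density, macronutrient shares consistent with
#' that energy under the [energy_factors()] conversions (alcohol only for
#' the alcoholic-beverages group), a saturated/mono/polyunsaturated split
#' of total fat, sugars as a fraction of carbohydrate, salt tied to sodium
#' (x2.5/1000), and micronutrients from broad plausible ranges. Values are
#' synthetic and seeded; they stand in for a survey-derived table in
#' simulations.
#'
#' @param instrument An `ffq_instrument`.
#' @param seed Integer seed.
#' @return An `ffq_composition` data frame (item_id + nutrient panel).
#' @export
generate_composition <- function(instrument, seed = 1L) {
  set.seed(seed)
  items <- instrument$items
  n <- nrow(items)
  fac <- energy_factors()
  e <- vapply(items$category, function(cat) {
    r <- category_energy_range(cat); stats::runif(1, r[1], r[2])
  }, numeric(1))
  alcoholic <- items$food_group == "alcoholic_beverages"
  fat_sh <- stats::runif(n, 0.15, 0.45)
  pro_sh <- stats::runif(n, 0.10, 0.30)
  alc_sh <- ifelse(alcoholic, stats::runif(n, 0.6, 0.9), 0)
  carb_sh <- pmax(1 - fat_sh - pro_sh - alc_sh, 0.02)
  tot <- fat_sh + pro_sh + carb_sh + alc_sh
  fat_sh <- fat_sh / tot; pro_sh <- pro_sh / tot
  carb_sh <- carb_sh / tot; alc_sh <- alc_sh / tot
  fat_g <- fat_sh * e / fac[["fat"]]
  protein_g <- pro_sh * e / fac[["protein"]]
  carbohydrate_g <- carb_sh * e / fac[["carbohydrate"]]
  alcohol_g <- alc_sh * e / fac[["alcohol"]]
  sfa_frac <- stats::runif(n, 0.25, 0.5)
  pufa_frac <- stats::runif(n, 0.1, 0.3)
  sodium <- stats::runif(n, 10, 800)
  out <- data.frame(
    item_id = items$item_id,
    energy_kcal = e, fat_g = fat_g, sfa_g = sfa_frac * fat_g,
    mufa_g = (1 - sfa_frac - pufa_frac) * fat_g,
    pufa_g = pufa_frac * fat_g, protein_g = protein_g,
    carbohydrate_g = carbohydrate_g,
    sugars_g = stats::runif(n, 0.1, 0.6) * carbohydrate_g,
    alcohol_g = alcohol_g,
    calcium_mg = stats::runif(n, 5, 250),
    folate_ug = stats::runif(n, 2, 120),
    iron_mg = stats::runif(n, 0.1, 4),
    carotene_ug = stats::runif(n, 0, 3000),
    riboflavin_mg = stats::runif(n, 0.01, 0.5),
    thiamin_mg = stats::runif(n, 0.01, 0.5),
    vitamin_b6_mg = stats::runif(n, 0.02, 0.6),
    vitamin_b12_ug = stats::runif(n, 0, 3),
    vitamin_c_mg = stats::runif(n, 0, 60),
    vitamin_a_re_ug = stats::runif(n, 0, 500),
    retinol_ug = stats::runif(n, 0, 300),
    vitamin_d_ug = stats::runif(n, 0, 3),
    vitamin_e_mg = stats::runif(n, 0.05, 3),
    sodium_mg = sodium, salt_g = sodium * 2.5 / 1000,
    stringsAsFactors = FALSE)
  structure(out, class = c("ffq_composition", "data.frame"))
}

#' Generate synthetic consumption-survey records and food entries
#'
#' Emulates the national-survey input of the derivation module: for every
#' instrument item, `foods_per_item` candidate survey foods with distinct
#' occurrence counts (`records_per_food * foods_per_item` down to
#' `records_per_food`) and per-100 g compositions jittered around the
#' item's plausible composition; one consumption record per occurrence,
#' with daily amounts lognormal around `amount_median` (default: the
#' item's medium portion anchor). `n_respondents = 0` returns empty
#' tables.
#'
#' @param instrument An `ffq_instrument`.
#' @param n_respondents Size of the respondent pool amounts are drawn for.
#' @param foods_per_item Candidate foods per item (>= 1).
#' @param records_per_food Base occurrence count (the j-th ranked food of
#'   an item has `records_per_food * (foods_per_item - j + 1)` records).
#' @param amount_median Optional common median daily amount (grams); the
#'   default uses each item's p50 portion anchor.
#' @param amount_sdlog Lognormal spread of amounts.
#' @param seed Integer seed.
#' @return List with `records` (respondent_id, food_code, item_id, amount)
#'   and `foods` (food_code + nutrient panel).
#' @export
generate_consumption_survey <- function(instrument, n_respondents = 200,
                                        foods_per_item = 5,
                                        records_per_food = 6,
                                        amount_median = NULL,
                                        amount_sdlog = 0.5, seed = 1L) {
  stopifnot(foods_per_item >= 1, records_per_food >= 1)
  empty_records <- data.frame(respondent_id = character(0),
                              food_code = character(0),
                              item_id = character(0), amount = numeric(0),
                              stringsAsFactors = FALSE)
  if (n_respondents == 0)
    return(list(records = empty_records,
                foods = cbind(data.frame(food_code = character(0)),
                              stats::setNames(as.data.frame(
                                matrix(numeric(0), 0, 24)), nutrient_keys()))))
  set.seed(seed)
  base_comp <- generate_composition(instrument, seed = seed)
  pool <- sprintf("R%04d", seq_len(n_respondents))
  nut <- nutrient_keys()
  recs <- list(); foods <- list()
  for (i in seq_len(nrow(instrument$items))) {
    id <- instrument$items$item_id[i]
    m <- if (is.null(amount_median))
      instrument$portions[[id]]$anchors[2] else amount_median
    base_vec <- as.numeric(base_comp[base_comp$item_id == id, nut])
    for (j in seq_len(foods_per_item)) {
      code <- sprintf("%s_f%d", id, j)
      jit <- stats::runif(length(nut), 0.7, 1.3)
      foods[[code]] <- data.frame(food_code = code,
                                  as.list(stats::setNames(base_vec * jit, nut)),
                                  stringsAsFactors = FALSE)
      count <- records_per_food * (foods_per_item - j + 1L)
      recs[[code]] <- data.frame(
        respondent_id = sample(pool, count, replace = TRUE),
        food_code = code, item_id = id,
        amount = stats::rlnorm(count, log(m), amount_sdlog),
        stringsAsFactors = FALSE)
    }
  }
  list(records = do.call(rbind, c(recs, list(make.row.names = FALSE))),
       foods = do.call(rbind, c(foods, list(make.row.names = FALSE))))
}

# nearest-(frequency, portion) quantization of observed grams/day.
# Products are compared in log space; ties go to the lower product; among
# equal products the lower frequency then portion index wins. Zero observed
# amounts map to the "never" category (portion option 1 by convention).
quantize_amounts <- function(obs, multipliers, options) {
  grid <- expand.grid(f = which(multipliers > 0), p = seq_along(options))
  prod <- multipliers[grid$f] * options[grid$p]
  o <- order(prod, grid$f, grid$p)
  prod <- prod[o]; grid <- grid[o, ]
  keep <- !duplicated(prod)
  prod <- prod[keep]; grid <- grid[keep, , drop = FALSE]
  lp <- log(prod)
  mids <- (lp[-1] + lp[-length(lp)]) / 2
  idx <- rep(1L, length(obs))
  pos <- obs > 0
  idx[pos] <- findInterval(log(obs[pos]), mids, left.open = TRUE) + 1L
  list(frequency_index = ifelse(pos, grid$f[idx], 1L),
       portion_index = ifelse(pos, grid$p[idx], 1L))
}

#' Generate paired questionnaire responses with known ground truth
#'
#' Simulates the paired-administration design: each respondent carries a
#' latent true daily gram amount per food item; method m observes
#' `bias_m x truth x exp(noise)` and reports the frequency category and
#' portion option whose product is nearest the observed amount in log
#' space (ties to the lower option). True daily energy is scaled to a
#' lognormal respondent-level target; designated under-reporters are then
#' scaled to 0.85 x their EER floor (so both instruments flag them,
#' leaving margin for quantization), and all other respondents are kept at
#' or above 1.25 x the floor, making under-reporting status exact ground
#' truth. Demographics (sex-balanced, age 18-60, sex-specific weight and
#' height) and the two completion dates are generated alongside.
#'
#' @param spec An [cohort_spec()].
#' @param instrument_a,instrument_b Validated instruments (may be the
#'   same object); each must start with a "never" category.
#' @param composition Optional composition table covering the union of
#'   items; defaults to [generate_composition()] on that union.
#' @param seed Integer seed; default `spec$seed`.
#' @return List with `responses_a`, `responses_b` (long data frames ready
#'   for [score_cohort()]), `demographics`, `composition`, and `truth`
#'   (list: `grams` matrix, `energy`, `under_reporters` ids, biases).
#' @export
generate_paired_responses <- function(spec, instrument_a, instrument_b,
                                      composition = NULL,
                                      seed = spec$seed) {
  stopifnot(inherits(spec, "ffq_cohort_spec"))
  validate_instrument(instrument_a); validate_instrument(instrument_b)
  for (ins in list(instrument_a, instrument_b))
    if (ins$frequency_scale$multipliers[1] != 0)
      stop("instrument '", ins$name, "' has no 'never' category")
  set.seed(seed)
  n <- spec$n_respondents
  union_ids <- union(instrument_a$items$item_id, instrument_b$items$item_id)
  # one composition over the union so shared items score identically
  if (is.null(composition)) {
    ref <- if (length(setdiff(union_ids, instrument_b$items$item_id)) == 0)
      instrument_b else instrument_a
    composition <- generate_composition(ref, seed = seed)
  }
  miss <- setdiff(union_ids, composition$item_id)
  if (length(miss))
    stop("composition does not cover item(s): ", paste(miss, collapse = ", "))
  ids <- sprintf("P%04d", seq_len(n))
  if (n == 0)
    return(list(responses_a = NULL, responses_b = NULL,
                demographics = NULL, composition = composition,
                truth = NULL))
  sex <- sample(rep(c("male", "female"), length.out = n))
  age <- stats::runif(n, 18, 60)
  weight <- ifelse(sex == "male", stats::rnorm(n, 77, 11),
                   stats::rnorm(n, 62, 9))
  weight <- pmax(weight, 42)
  height <- ifelse(sex == "male", stats::rnorm(n, 178, 7),
                   stats::rnorm(n, 164, 6))
  height <- pmax(height, 145)
  date_a <- as.Date("2026-03-01") + sample(0:45, n, replace = TRUE)
  gap <- stats::rpois(n, spec$gap_mean_days) *
    sample(c(-1, 1), n, replace = TRUE)
  date_b <- date_a + gap
  bmr <- bmr_henry(sex, age, weight, height)
  eer_floor <- 1.1 * bmr

  # latent true grams/day, item pattern centred on the medium portion at
  # ~0.5 eating occasions/day, then scaled per respondent to an energy target
  port_ref <- c(instrument_b$portions, instrument_a$portions)[union_ids]
  mu_item <- vapply(port_ref, function(ps) ps$anchors[2] * 0.5, numeric(1))
  consume <- matrix(stats::rbinom(n * length(union_ids), 1,
                                  spec$consume_prob),
                    n, length(union_ids))
  T_grams <- consume * matrix(
    stats::rlnorm(n * length(union_ids),
                  rep(log(mu_item), each = n), 0.6),
    n, length(union_ids))
  dimnames(T_grams) <- list(ids, union_ids)
  edens <- composition$energy_kcal[match(union_ids, composition$item_id)]
  energy_now <- as.numeric(T_grams %*% edens) / 100
  energy_now[energy_now == 0] <- 1  # all-"never" respondent: nothing to scale
  target <- stats::rlnorm(n, log(spec$energy_median), spec$energy_sdlog)
  bmax <- max(spec$bias_a, spec$bias_b)
  bmin <- min(spec$bias_a, spec$bias_b)
  n_under <- round(spec$under_reporter_fraction * n)
  under_ids <- if (n_under > 0) sample(ids, n_under) else character(0)
  is_under <- ids %in% under_ids
  target[is_under] <- 0.85 * eer_floor[is_under] / bmax
  low <- !is_under & (bmin * target < 1.25 * eer_floor)
  target[low] <- 1.25 * eer_floor[low] / bmin
  T_grams <- T_grams * (target / energy_now)

  observe <- function(bias) {
    noise <- if (spec$noise_sd > 0)
      matrix(exp(stats::rnorm(length(T_grams), 0, spec$noise_sd)),
             nrow(T_grams), ncol(T_grams))
    else 1
    bias * T_grams * noise
  }
  obs_a <- observe(spec$bias_a)
  obs_b <- observe(spec$bias_b)

  make_responses <- function(instrument, obs, dates) {
    item_ids <- instrument$items$item_id
    mult <- instrument$frequency_scale$multipliers
    out <- vector("list", length(item_ids))
    for (k in seq_along(item_ids)) {
      q <- quantize_amounts(obs[, item_ids[k]], mult,
                            instrument$portions[[item_ids[k]]]$options)
      out[[k]] <- data.frame(respondent_id = ids,
                             instrument_name = instrument$name,
                             completion_date = as.character(dates),
                             item_id = item_ids[k],
                             frequency_index = q$frequency_index,
                             portion_index = q$portion_index,
                             stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, out)
    df[order(match(df$respondent_id, ids)), ]
  }
  responses_a <- make_responses(instrument_a, obs_a, date_a)
  responses_b <- make_responses(instrument_b, obs_b, date_b)
  demographics <- data.frame(respondent_id = ids, sex = sex,
                             age_y = age, weight_kg = weight,
                             height_cm = height,
                             date_a = as.character(date_a),
                             date_b = as.character(date_b),
                             stringsAsFactors = FALSE)
  list(responses_a = responses_a, responses_b = responses_b,
       demographics = demographics, composition = composition,
       truth = list(grams = T_grams, energy = target,
                    under_reporters = under_ids,
                    bias_a = spec$bias_a, bias_b = spec$bias_b))
}
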