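test_that("cohort specs validate their parameters", {
  expect_s3_class(cohort_spec(), "ffq_cohort_spec")
  expect_error(cohort_spec(bias_b = 0))
  expect_error(cohort_spec(under_reporter_fraction = 1.2))
})

test_that("an empty survey request returns empty tables without error", {
  ins <- toy_instrument(2)
  out <- generate_consumption_survey(ins, n_respondents = 0)
  expect_equal(nrow(out$records), 0)
  expect_equal(nrow(out$foods), 0)
  expect_true(all(nutrient_panel()$key %in% names(out$foods)))
})

test_that("identical seeds give byte-identical generator output", {
  ins <- toy_instrument(3)
  s1 <- generate_consumption_survey(ins, n_respondents = 20, seed = 14)
  s2 <- generate_consumption_survey(ins, n_respondents = 20, seed = 14)
  expect_identical(s1, s2)
  spec <- cohort_spec(n_respondents = 15, seed = 14)
  p1 <- generate_paired_responses(spec, ins, ins)
  p2 <- generate_paired_responses(spec, ins, ins)
  expect_identical(p1, p2)
  p3 <- generate_paired_responses(spec, ins, ins, seed = 15)
  expect_false(identical(p1$responses_a, p3$responses_a))
})

test_that("survey amounts hit the configured lognormal median", {
  ins <- toy_instrument(1)
  out <- generate_consumption_survey(ins, n_respondents = 500,
                                     foods_per_item = 1,
                                     records_per_food = 10000,
                                     amount_median = 120, seed = 8)
  expect_equal(nrow(out$records), 10000)
  expect_lt(abs(median(out$records$amount) - 120) / 120, 0.05)
})

test_that("generated surveys feed the derivation module end to end", {
  ins <- toy_instrument(2)
  out <- generate_consumption_survey(ins, n_respondents = 50,
                                     foods_per_item = 4, seed = 3)
  # occurrence counts are distinct per item by construction
  counts <- table(out$records$food_code[out$records$item_id == "it01"])
  expect_equal(length(unique(as.numeric(counts))), 4)
  comp <- derive_composition(out$records, out$foods, k = 3,
                             items = ins$items$item_id)
  expect_equal(sort(comp$item_id), sort(ins$items$item_id))
  ps <- derive_portion_series(out$records, "it01")
  expect_length(ps$options, 7)
  expect_false(is.unsorted(ps$options))
})

test_that("zero noise and identical instruments reproduce the fixed point", {
  ins <- toy_instrument(6)
  spec <- cohort_spec(n_respondents = 25, noise_sd = 0,
                      under_reporter_fraction = 0, seed = 12)
  sim <- generate_paired_responses(spec, ins, ins)
  expect_identical(sim$responses_a[, c("item_id", "frequency_index",
                                       "portion_index")],
                   sim$responses_b[, c("item_id", "frequency_index",
                                       "portion_index")])
  ia <- score_cohort(ins, sim$composition, sim$responses_a)
  ib <- score_cohort(ins, sim$composition, sim$responses_b)
  expect_equal(ia$energy_kcal, ib$energy_kcal)
  cc <- cross_classify(ia$energy_kcal, ib$energy_kcal)
  expect_equal(cc$pct_exact, 100)
})

test_that("quantization error is bounded by half the log-grid gap", {
  ins <- toy_instrument(1)
  mult <- ins$frequency_scale$multipliers
  opts <- ins$portions$it01$options
  prods <- sort(unique(as.vector(outer(mult[mult > 0], opts))))
  max_half_gap <- max(diff(log(prods))) / 2
  spec <- cohort_spec(n_respondents = 200, noise_sd = 0,
                      under_reporter_fraction = 0, seed = 2)
  sim <- generate_paired_responses(spec, ins, ins)
  f <- sim$responses_a$frequency_index; p <- sim$responses_a$portion_index
  got <- mult[f] * opts[p]
  truth <- sim$truth$grams[, 1]
  inside <- truth >= min(prods) & truth <= max(prods)
  expect_true(all(abs(log(got[inside]) - log(truth[inside])) <=
                    max_half_gap + 1e-9))
  # amounts outside the representable range clamp to its endpoints
  expect_true(all(got[truth > max(prods)] == max(prods)))
  expect_true(all(got[truth > 0] > 0))
})

test_that("an instrument without a 'never' category is rejected", {
  ins <- toy_instrument(2)
  ins$frequency_scale$multipliers[1] <- 0.5
  class(ins$frequency_scale) <- "ffq_frequency_scale"
  spec <- cohort_spec(n_respondents = 5, seed = 1)
  expect_error(generate_paired_responses(spec, ins, ins), "never")
})

test_that("reporting noise degrades between-method rank agreement", {
  ins <- toy_instrument(8)
  rho <- vapply(c(0.05, 0.8), function(ns) {
    spec <- cohort_spec(n_respondents = 150, noise_sd = ns,
                        under_reporter_fraction = 0, seed = 19)
    sim <- generate_paired_responses(spec, ins, ins)
    ia <- score_cohort(ins, sim$composition, sim$responses_a)
    ib <- score_cohort(ins, sim$composition, sim$responses_b)
    correlations(ia$energy_kcal, ib$energy_kcal, "spearman")$estimate
  }, numeric(1))
  expect_gt(rho[1], rho[2])
})

test_that("injected multiplicative bias is recovered from scored intakes", {
  ins <- epic_norfolk_instrument()
  spec <- cohort_spec(n_respondents = 250, bias_b = 1.3, noise_sd = 0.2,
                      under_reporter_fraction = 0, seed = 27)
  sim <- generate_paired_responses(spec, ins, ins)
  ia <- score_cohort(ins, sim$composition, sim$responses_a)
  ib <- score_cohort(ins, sim$composition, sim$responses_b)
  ratio <- mean(ib$energy_kcal) / mean(ia$energy_kcal)
  expect_lt(abs(ratio - 1.3), 0.07)
  ba <- bland_altman(ia$energy_kcal, ib$energy_kcal)
  expect_lt(ba$mean_diff, 0)  # reference minus online is negative
})

test_that("designated under-reporters sit below the EER floor per design", {
  ins <- toy_instrument(10)
  spec <- cohort_spec(n_respondents = 120, under_reporter_fraction = 0.25,
                      noise_sd = 0.15, seed = 31)
  sim <- generate_paired_responses(spec, ins, ins)
  ib <- score_cohort(ins, sim$composition, sim$responses_b)
  dem <- sim$demographics
  bmr <- bmr_henry(dem$sex, dem$age_y, dem$weight_kg, dem$height_cm)
  flags <- classify_under_reporter(ib$energy_kcal, bmr)
  designated <- dem$respondent_id %in% sim$truth$under_reporters
  expect_equal(sum(designated), 30)
  agree <- mean(flags == designated)
  expect_gt(agree, 0.95)
})
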