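test_that("frequency multipliers follow the packaged midpoint convention", {
  sc <- default_frequency_scale()
  expect_equal(frequency_multiplier(sc, 1), 0)           # never
  expect_equal(frequency_multiplier(sc, 6), 1)           # once a day
  expect_equal(frequency_multiplier(sc, 4), 3 / 7)       # 2-4 per week
  expect_equal(frequency_multiplier(sc, 2), 2 / 30.44)   # 1-3 per month
  expect_error(frequency_multiplier(sc, 10), "out of range")
  expect_error(frequency_multiplier(sc, 0), "out of range")
})

test_that("a one-item instrument scores by hand arithmetic", {
  ins <- toy_instrument(1)
  comp <- toy_composition(ins, energy = 200)
  # frequency once/day, portion option 7 = 1.5 * 80 = 120 g... use explicit
  ins$portions$it01 <- portion_series(c(50, 75, 90, 150, 165, 190, 225))
  r <- response_set("r1", "toy", "2026-04-01",
                    data.frame(item_id = "it01", frequency_index = 6,
                               portion_index = 4))
  intake <- score_response(ins, comp, r)
  expect_equal(unname(intake$nutrients["energy_kcal"]), 150 * 200 / 100) # 300
  expect_equal(unname(intake$per_item_grams["it01"]), 150)
})

test_that("an all-never response scores exactly zero everywhere", {
  ins <- toy_instrument(4)
  comp <- toy_composition(ins)
  r <- full_response(ins, frequency_index = 1)
  intake <- score_response(ins, comp, r)
  expect_true(all(intake$nutrients == 0))
  expect_true(all(intake$groups == 0))
  expect_true(all(is.na(intake$pct_te)))  # undefined at zero energy, not 0
})

test_that("scoring matches the brute-force enumerator on small instruments", {
  set.seed(101)
  for (n_items in c(1, 3, 5)) {
    ins <- toy_instrument(n_items, groups = c("ga", "gb"))
    comp <- toy_composition(ins)
    comp$energy_kcal <- runif(n_items, 50, 400)
    comp$fat_g <- runif(n_items, 1, 30)
    for (rep_i in 1:5) {
      r <- full_response(ins,
                         frequency_index = sample(1:9, n_items, TRUE),
                         portion_index = sample(1:7, n_items, TRUE))
      got <- score_response(ins, comp, r)
      want <- brute_score(ins, comp, r)
      expect_equal(got$nutrients, want$nutrients)
      for (g in names(want$groups))
        expect_equal(unname(got$groups[g]), want$groups[[g]])
    }
  }
})

test_that("scoring is linear in portion grams and additive over items", {
  ins <- toy_instrument(5)
  comp <- toy_composition(ins)
  r <- full_response(ins, frequency_index = 6, portion_index = 2)
  ins2 <- ins
  for (id in names(ins2$portions))
    ins2$portions[[id]] <- portion_series(2 * ins2$portions[[id]]$options)
  a <- score_response(ins, comp, r)
  b <- score_response(ins2, comp, r)
  expect_equal(b$nutrients, 2 * a$nutrients)
  expect_equal(b$groups, 2 * a$groups)
})

test_that("group totals conserve item mass", {
  ins <- food4me_instrument()
  comp <- generate_composition(ins, seed = 2)
  spec <- cohort_spec(n_respondents = 8, seed = 2)
  sim <- generate_paired_responses(spec, ins, ins, composition = comp)
  intakes <- score_cohort(ins, comp, sim$responses_b)
  fg <- as.matrix(intakes[, grep("^fg_", names(intakes))])
  # recompute per-item grams independently for one respondent
  r1 <- responses_from_long(sim$responses_b)[[1]]
  intake1 <- score_response(ins, comp, r1)
  expect_equal(sum(intake1$groups), sum(intake1$per_item_grams),
               tolerance = 1e-9)
  expect_equal(unname(rowSums(fg)[1]), sum(intake1$per_item_grams),
               tolerance = 1e-9)
})

test_that("percent energy follows the conversion-factor arithmetic", {
  ins <- toy_instrument(1)
  comp <- toy_composition(ins)
  r <- full_response(ins)
  intake <- score_response(ins, comp, r)
  df <- score_cohort(ins, comp, responses_to_long(r))
  # hand oracle: fat 10 g at 900 kcal -> 9*10*100/900 = 10 %TE
  df$fat_g <- 10; df$energy_kcal <- 900
  df <- percent_energy(df)
  expect_equal(df$pct_te_fat, 10)
  df$fat_g <- 0
  expect_equal(percent_energy(df)$pct_te_fat, 0)
  # normalization identity when energy is the sum of component energies
  df2 <- score_cohort(ins, comp, responses_to_long(r))
  df2 <- percent_energy(df2, energy_from_components = TRUE)
  expect_equal(df2$pct_te_fat + df2$pct_te_protein +
                 df2$pct_te_carbohydrate + df2$pct_te_alcohol, 100)
})

test_that("doubling chosen portions doubles every intake", {
  ins <- toy_instrument(3)
  comp <- toy_composition(ins)
  r1 <- full_response(ins, frequency_index = 7, portion_index = 2)
  # options are m*c(.5,.75,.9,1,1.1,1.25,1.5); option 7 = 2 * option 2
  r2 <- full_response(ins, frequency_index = 7, portion_index = 7)
  a <- score_response(ins, comp, r1)
  b <- score_response(ins, comp, r2)
  expect_equal(b$nutrients, 2 * a$nutrients)
})

test_that("food-group aggregation sums members and errors on unmapped items", {
  g <- aggregate_food_groups(c(itA = 90), map = c(itA = "milk"))
  expect_equal(unname(g["milk"]), 90)
  g2 <- aggregate_food_groups(c(itA = 50, itB = 70),
                              map = c(itA = "milk", itB = "milk"))
  expect_equal(unname(g2["milk"]), 120)
  expect_equal(sum(g2), 120)
  expect_true(all(g2[setdiff(names(g2), "milk")] == 0))
  expect_error(aggregate_food_groups(c(itC = 10), map = c(itA = "milk")),
               "itC")
})

test_that("intake tables round-trip through the units-header CSV", {
  ins <- toy_instrument(3)
  comp <- toy_composition(ins)
  intakes <- score_cohort(ins, comp, responses_to_long(list(
    full_response(ins, "r1"), full_response(ins, "r2", frequency_index = 3))))
  path <- withr::local_tempfile(fileext = ".csv")
  write_intakes(intakes, path)
  expect_match(readLines(path, n = 1), "^# units: .*energy_kcal=kcal")
  back <- read_intakes(path)
  expect_equal(back$energy_kcal, intakes$energy_kcal)
  expect_equal(names(back), names(intakes))
})

test_that("missing composition entries are named in the error", {
  ins <- toy_instrument(2)
  comp <- toy_composition(ins)
  comp <- comp[comp$item_id != "it02", ]
  expect_error(score_response(ins, comp, full_response(ins)),
               "missing item\\(s\\): it02")
})
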