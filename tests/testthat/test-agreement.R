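test_that("Bland-Altman on identical methods is the zero fixed point", {
  x <- c(3, 7, 1, 9, 4.5)
  ba <- bland_altman(x, x)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 0)
  expect_equal(ba$pct_within, 100)
  expect_true(ba$comparable)
})

test_that("Bland-Altman matches the hand oracle on four points", {
  x <- c(1, -1, 1, -1); y <- rep(0, 4)
  ba <- bland_altman(x, y)
  # sample SD with n-1 denominator: sqrt((1+1+1+1)/3)
  expect_equal(ba$mean_diff, 0, tolerance = 1e-12)
  expect_equal(ba$sd_diff, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_low, -2 * sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(ba$loa_high, 2 * sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(ba$n_outside, 0)
  expect_equal(ba$means, (x + y) / 2)
})

test_that("limit counting is strict and k_sd is configurable", {
  x <- c(0, 0, 0, 0, 10); y <- rep(0, 5)
  ba1 <- bland_altman(x, y, k_sd = 1)
  hand_sd <- sd(x - y)
  expect_equal(ba1$loa_high, mean(x) + hand_sd)
  expect_equal(ba1$n_outside, sum(x - y > mean(x) + hand_sd |
                                    x - y < mean(x) - hand_sd))
})

test_that("cross-classification of identical rankings is 100% exact", {
  x <- c(5, 1, 9, 3, 7, 2, 8, 6)
  cc <- cross_classify(x, x)
  expect_equal(cc$pct_exact, 100)
  expect_equal(cc$pct_disagreement_combined, 0)
})

test_that("reversed ranking splits into adjacent and extreme quartiles", {
  x <- as.numeric(1:8)
  cc <- cross_classify(x, -x)
  expect_equal(cc$pct_exact, 0)
  expect_equal(cc$pct_adjacent_only, 50)
  expect_equal(cc$pct_extreme, 50)
  expect_equal(cc$pct_two_apart, 0)
})

test_that("cross-class percentages total 100 and survive monotone maps", {
  set.seed(21)
  for (rep_i in 1:10) {
    n <- sample(c(12, 37, 101), 1)
    x <- rnorm(n); y <- x + rnorm(n)
    cc <- cross_classify(x, y)
    expect_equal(cc$pct_exact + cc$pct_adjacent_only + cc$pct_two_apart +
                   cc$pct_extreme, 100, tolerance = 1e-9)
    expect_gte(cc$pct_exact_plus_adjacent, cc$pct_exact)
    cc2 <- cross_classify(exp(x), y^3)
    expect_equal(cc2$pct_exact, cc$pct_exact)
    expect_equal(cc2$pct_extreme, cc$pct_extreme)
  }
})

test_that("heavy ties refuse to stratify, naming the variable", {
  expect_error(cross_classify(rep(1, 12), rnorm(12)), "strata for x")
})

test_that("correlations match the textbook formula on a 5-point toy", {
  x <- c(1, 4, 2, 8, 5); y <- c(2, 3, 1, 9, 6)
  expect_equal(correlations(x, y, "pearson")$estimate, oracle_pearson(x, y),
               tolerance = 1e-12)
  expect_equal(correlations(x, y, "spearman")$estimate,
               oracle_pearson(rank(x), rank(y)), tolerance = 1e-12)
  expect_equal(correlations(x, x, "pearson")$estimate, 1)
  expect_equal(correlations(x, x, "spearman")$estimate, 1)
  # monotone transform: spearman invariant, pearson below 1
  expect_equal(correlations(x, exp(x), "spearman")$estimate, 1)
  expect_lt(correlations(x, exp(x), "pearson")$estimate, 1)
  expect_error(correlations(rep(1, 5), y), "zero variance")
})

test_that("group t test matches the hand Welch formula and is antisymmetric", {
  x <- c(10, 12, 9, 14, 11); y <- c(8, 9, 7, 10)
  tt <- group_ttest(x, y)
  expect_equal(tt$t, oracle_welch_t(x, y), tolerance = 1e-12)
  rev <- group_ttest(y, x)
  expect_equal(rev$t, -tt$t, tolerance = 1e-12)
  expect_equal(rev$p_value, tt$p_value, tolerance = 1e-12)
  same <- group_ttest(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_error(group_ttest(rep(1, 3), rep(1, 3)), "zero pooled variance")
})

test_that("adjusted comparison equals the normal-equations solution", {
  dat <- data.frame(intake = c(10, 12, 11, 15, 16, 14),
                    method = rep(c("A", "B"), each = 3),
                    energy = c(2000, 2100, 1900, 2500, 2600, 2400))
  fit <- adjusted_comparison(dat, interactions = FALSE)
  X <- cbind(1, rep(c(0, 1), each = 3), dat$energy)
  beta <- oracle_ols(X, dat$intake)
  expect_equal(unname(fit$estimate), beta[2, 1], tolerance = 1e-10)
})

test_that("identical method values give a zero method effect", {
  dat <- data.frame(intake = rep(c(10, 12, 14, 11), 2),
                    method = rep(c("A", "B"), each = 4),
                    energy = rep(c(2000, 2200, 2400, 2100), 2))
  # a zero method effect makes the fit exact, which lm warns about
  fit <- suppressWarnings(adjusted_comparison(dat, interactions = TRUE))
  expect_equal(unname(fit$estimate), 0, tolerance = 1e-12)
  expect_equal(fit$interactions$term, "method:energy")
})

test_that("a constant energy covariate reduces to the two-sample difference", {
  x <- c(10, 12, 9, 14); y <- c(13, 15, 12, 16)
  dat <- data.frame(intake = c(x, y),
                    method = rep(c("A", "B"), each = 4), energy = 2000)
  expect_message(fit <- adjusted_comparison(dat, interactions = FALSE),
                 "constant covariate")
  expect_equal(unname(fit$estimate), mean(y) - mean(x), tolerance = 1e-12)
  expect_equal(unname(fit$estimate), -group_ttest(x, y)$mean_diff,
               tolerance = 1e-12)
})

test_that("collinear covariates raise an error naming the column", {
  dat <- data.frame(intake = rnorm(8), method = rep(c("A", "B"), 4),
                    energy = 1:8, energy2 = 2 * (1:8))
  expect_error(adjusted_comparison(dat, covariates = c("energy", "energy2"),
                                   interactions = FALSE),
               "collinear.*energy2")
})

test_that("the injected method effect is recovered with nominal CI coverage", {
  set.seed(33)
  beta <- 5
  hits <- 0L
  n_rep <- 500
  for (i in seq_len(n_rep)) {
    n <- 20
    energy <- rnorm(2 * n, 2200, 300)
    eff <- rep(c(0, beta), each = n)
    intake <- 10 + 0.01 * energy + eff + rnorm(2 * n, 0, 2)
    dat <- data.frame(intake = intake,
                      method = rep(c("A", "B"), each = n), energy = energy)
    fit <- adjusted_comparison(dat, interactions = FALSE)
    ci <- fit$estimate + c(-1, 1) * qt(0.975, 2 * n - 3) * fit$se
    if (ci[1] <= beta && beta <= ci[2]) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.93)
})

test_that("the full report reproduces the self-comparison fixed point", {
  ins <- toy_instrument(6, groups = c("milk", "cheeses", "fish"))
  comp <- toy_composition(ins)
  set.seed(4)
  responses <- responses_to_long(lapply(1:12, function(i)
    full_response(ins, sprintf("p%02d", i),
                  frequency_index = sample(2:9, 6, TRUE),
                  portion_index = sample(1:7, 6, TRUE))))
  intakes <- score_cohort(ins, comp, responses)
  # self-comparison is a perfect fit for the adjusted model, which lm
  # rightly warns about; the fixed point itself is what matters here
  rep <- suppressWarnings(suppressMessages(
    compare_instruments(intakes, intakes)))
  expect_s3_class(rep, "ffq_agreement_report")
  expect_true(all(rep$bland_altman$mean_diff == 0))
  expect_true(all(rep$bland_altman$pct_within == 100))
  ok <- !is.na(rep$nutrients$correlation)
  expect_true(any(ok))
  expect_true(all(abs(rep$nutrients$correlation[ok] - 1) < 1e-9))
  ok_cc <- !is.na(rep$nutrients$pct_exact)
  expect_true(all(rep$nutrients$pct_exact[ok_cc] == 100))
})

test_that("misaligned respondent sets report the symmetric difference", {
  ins <- toy_instrument(2)
  comp <- toy_composition(ins)
  ia <- score_cohort(ins, comp, responses_to_long(list(
    full_response(ins, "p1"), full_response(ins, "p2"))))
  ib <- score_cohort(ins, comp, responses_to_long(list(
    full_response(ins, "p2"), full_response(ins, "p3"))))
  expect_error(compare_instruments(ia, ib), "p1.*p3")
})

test_that("report rows cover the nutrient panel and the 35 food groups", {
  ins <- food4me_instrument()
  comp <- generate_composition(ins, seed = 6)
  spec <- cohort_spec(n_respondents = 30, seed = 6)
  sim <- generate_paired_responses(spec, ins, ins, composition = comp)
  ia <- score_cohort(ins, comp, sim$responses_a)
  ib <- score_cohort(ins, comp, sim$responses_b)
  rep <- compare_instruments(ia, ib)
  expect_setequal(rep$nutrients$variable,
                  c(nutrient_panel()$key,
                    paste0("pct_te_", c("fat", "sfa", "mufa", "pufa",
                                        "protein", "carbohydrate"))))
  expect_setequal(rep$food_groups$food_group, food_groups())
})
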