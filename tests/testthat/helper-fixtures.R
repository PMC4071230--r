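# Shared fixtures: tiny instruments, composition tables, and independent
# oracles (brute-force scorer, textbook statistics) used across test files.

`%or%` <- function(a, b) if (is.null(a)) b else a

toy_series <- function(m = 100) {
  portion_series(m * c(0.5, 0.75, 0.9, 1, 1.1, 1.25, 1.5))
}

toy_instrument <- function(n_items = 3, name = "toy",
                           groups = paste0("group_", seq_len(n_items))) {
  ids <- sprintf("it%02d", seq_len(n_items))
  items <- data.frame(item_id = ids, name = paste("item", ids),
                      category = "food", composition_ref = ids,
                      food_group = rep_len(groups, n_items),
                      stringsAsFactors = FALSE)
  portions <- stats::setNames(
    lapply(seq_len(n_items), function(i) toy_series(60 + 20 * i)), ids)
  ffq_instrument(name, "food", default_frequency_scale(), items, portions)
}

# flat composition: every nutrient value the same per item unless overridden
toy_composition <- function(instrument, energy = 200, fat = 10,
                            protein = 8, carb = 25, alcohol = 0) {
  ids <- instrument$items$item_id
  nut <- nutrient_panel()$key
  df <- data.frame(item_id = ids, stringsAsFactors = FALSE)
  for (k in nut) df[[k]] <- 1
  df$energy_kcal <- energy
  df$fat_g <- fat
  df$protein_g <- protein
  df$carbohydrate_g <- carb
  df$alcohol_g <- alcohol
  df$sfa_g <- fat * 0.4
  df$mufa_g <- fat * 0.4
  df$pufa_g <- fat * 0.2
  df
}

full_response <- function(instrument, respondent_id = "r1",
                          frequency_index = 6, portion_index = 4,
                          date = "2026-04-01") {
  ids <- instrument$items$item_id
  response_set(respondent_id, instrument$name, date,
               data.frame(item_id = ids,
                          frequency_index = rep_len(frequency_index,
                                                    length(ids)),
                          portion_index = rep_len(portion_index,
                                                  length(ids))))
}

# independent brute-force scorer: one item at a time, plain loops
brute_score <- function(instrument, composition, response) {
  nut_keys <- nutrient_panel()$key
  nut <- stats::setNames(numeric(length(nut_keys)), nut_keys)
  groups <- list()
  for (i in seq_len(nrow(response$answers))) {
    row <- response$answers[i, ]
    mult <- instrument$frequency_scale$multipliers[row$frequency_index]
    g <- mult * instrument$portions[[row$item_id]]$options[row$portion_index]
    comp <- composition[composition$item_id == row$item_id, nut_keys]
    nut <- nut + g * as.numeric(comp) / 100
    fg <- instrument$items$food_group[instrument$items$item_id == row$item_id]
    groups[[fg]] <- (groups[[fg]] %or% 0) + g
  }
  list(nutrients = nut, groups = groups)
}

# textbook Pearson correlation, written out longhand
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# textbook Welch t statistic
oracle_welch_t <- function(x, y) {
  (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
}

# normal-equations least squares
oracle_ols <- function(X, y) solve(t(X) %*% X, t(X) %*% y)
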