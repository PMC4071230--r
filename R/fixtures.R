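#' The 35 standard food groups
#'
#' The standard grouping used to aggregate FFQ items for food-group level
#' analysis: 35 groups spanning starches, breads, dairy, fats, vegetables,
#' fruit, fish and meat, beverages and composite/miscellaneous foods.
#'
#' @return Character vector of 35 group labels.
#' @export
food_groups <- function() {
  c("rice_pasta_grains", "savories", "white_bread", "wholemeal_bread",
    "breakfast_cereals", "biscuits", "cakes_pastries", "milk", "cheeses",
    "yoghurts", "ice_cream_desserts", "eggs", "fats_oils", "potatoes",
    "chipped_potatoes", "peas_beans_lentils", "green_vegetables", "carrots",
    "salad_vegetables", "other_vegetables", "tinned_fruit_veg", "bananas",
    "other_fruits", "nuts_seeds", "fish", "bacon_ham", "red_meat",
    "poultry", "meat_products", "alcoholic_beverages", "sugars_preserves",
    "confectionery_snacks", "soups_sauces_misc", "teas_coffees",
    "other_beverages")
}

# Per-category item counts: the 130-item base list and the 27 additional
# items of the expanded 157-item instrument, the food groups each category's
# items cycle through, and a typical per-occasion gram amount used for the
# placeholder portion series.
ffq_category_table <- function() {
  data.frame(
    category = c("cereal", "bread and savory biscuits",
                 "potatoes, rice, and pasta", "meat and fish",
                 "dairy products", "fats and spreads", "sweets and snacks",
                 "soups, sauces, and spreads", "drinks", "fruit",
                 "vegetables"),
    n_base  = c(8, 8, 7, 20, 12, 8, 16, 10, 12, 11, 18),
    n_extra = c(2, 3, 2, 6, 3, 1, 2, 2, 3, 1, 2),
    groups = I(list(
      "breakfast_cereals",
      c("white_bread", "wholemeal_bread"),
      c("rice_pasta_grains", "potatoes", "chipped_potatoes", "savories"),
      c("fish", "red_meat", "poultry", "bacon_ham", "meat_products"),
      c("milk", "cheeses", "yoghurts", "ice_cream_desserts", "eggs"),
      "fats_oils",
      c("biscuits", "cakes_pastries", "confectionery_snacks",
        "sugars_preserves", "nuts_seeds"),
      "soups_sauces_misc",
      c("teas_coffees", "other_beverages", "alcoholic_beverages"),
      c("other_fruits", "bananas", "tinned_fruit_veg"),
      c("other_vegetables", "green_vegetables", "carrots",
        "salad_vegetables", "peas_beans_lentils"))),
    typical_grams = c(45, 60, 150, 120, 120, 10, 40, 150, 250, 120, 80),
    stringsAsFactors = FALSE
  )
}

# Build a placeholder portion series around a typical medium portion m:
# options are a fixed multiplicative grid so anchors (options 2, 4, 6)
# always satisfy p25 <= p50 <= p75 and sit among the options.
placeholder_series <- function(m) {
  portion_series(round(m * c(0.5, 0.75, 0.9, 1, 1.1, 1.25, 1.5), 1))
}

build_fixture_instrument <- function(name, use_extra) {
  tab <- ffq_category_table()
  rows <- list(); portions <- list()
  for (i in seq_len(nrow(tab))) {
    n <- tab$n_base[i] + if (use_extra) tab$n_extra[i] else 0L
    grp <- tab$groups[[i]]
    slug <- gsub("[^a-z]+", "_", tolower(tab$category[i]))
    for (j in seq_len(n)) {
      id <- sprintf("%s_%02d", slug, j)
      rows[[id]] <- data.frame(
        item_id = id,
        name = sprintf("%s item %02d (placeholder)", tab$category[i], j),
        category = tab$category[i],
        composition_ref = id,
        food_group = grp[((j - 1L) %% length(grp)) + 1L],
        fixture = TRUE, stringsAsFactors = FALSE)
      # vary portion magnitude a little across items, deterministically
      m <- tab$typical_grams[i] * (0.8 + 0.1 * ((j - 1L) %% 5L))
      portions[[id]] <- placeholder_series(m)
    }
  }
  ffq_instrument(name, tab$category, default_frequency_scale(),
                 do.call(rbind, rows), portions)
}

#' Packaged 157-item online instrument fixture
#'
#' The structure of the online Food4Me-style questionnaire: 157 food items
#' in 11 categories, a 9-level frequency scale, and a 7-option portion
#' series per item, built as the 130-item EPIC-Norfolk base list expanded by
#' 27 additional items. Item names are documented placeholders (flagged
#' `fixture = TRUE`): the published material reports counts and category
#' structure, not the full item text, so this fixture carries the structure
#' only.
#'
#' @return An `ffq_instrument` with 157 items.
#' @export
#' @examples
#' food4me_instrument()
food4me_instrument <- function() {
  build_fixture_instrument("food4me", use_extra = TRUE)
}

#' Packaged 130-item printed-instrument fixture
#'
#' The EPIC-Norfolk-style base list: 130 items in the same 11 categories,
#' same frequency scale and placeholder portion series as
#' [food4me_instrument()]. The two fixtures differ by exactly the 27
#' additional items of the expanded instrument.
#'
#' @return An `ffq_instrument` with 130 items.
#' @export
epic_norfolk_instrument <- function() {
  build_fixture_instrument("epic_norfolk", use_extra = FALSE)
}
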