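#' Nutrient panel
#'
#' The fixed panel of nutrients carried by composition tables and intake
#' records: energy, macronutrients (including the saturated, mono- and
#' polyunsaturated fatty-acid fractions), total sugars, alcohol, and the
#' micronutrients routinely reported by FFQ processing systems built on the
#' McCance & Widdowson composition tables. Composition values are expressed
#' per 100 g edible portion; intakes are per day.
#'
#' @return A data frame with columns `key` (column name used throughout the
#'   package), `label` (display name) and `unit`.
#' @export
#' @examples
#' nutrient_panel()
nutrient_panel <- function() {
  data.frame(
    key = c(
      "energy_kcal", "fat_g", "sfa_g", "mufa_g", "pufa_g", "protein_g",
      "carbohydrate_g", "sugars_g", "alcohol_g", "calcium_mg", "folate_ug",
      "iron_mg", "carotene_ug", "riboflavin_mg", "thiamin_mg",
      "vitamin_b6_mg", "vitamin_b12_ug", "vitamin_c_mg", "vitamin_a_re_ug",
      "retinol_ug", "vitamin_d_ug", "vitamin_e_mg", "sodium_mg", "salt_g"
    ),
    label = c(
      "Energy", "Total fat", "Saturated fatty acids",
      "Monounsaturated fatty acids", "Polyunsaturated fatty acids",
      "Protein", "Carbohydrate", "Total sugars", "Alcohol", "Calcium",
      "Total folate", "Iron", "Total carotene", "Riboflavin", "Thiamin",
      "Vitamin B6", "Vitamin B12", "Vitamin C", "Vitamin A (RE)",
      "Retinol", "Vitamin D", "Vitamin E", "Sodium", "Salt"
    ),
    unit = c(
      "kcal", "g", "g", "g", "g", "g", "g", "g", "g", "mg", "ug", "mg",
      "ug", "mg", "mg", "mg", "ug", "mg", "ug", "ug", "ug", "mg", "mg", "g"
    ),
    stringsAsFactors = FALSE
  )
}

nutrient_keys <- function() nutrient_panel()$key

#' Energy conversion factors
#'
#' kcal per gram used to convert macronutrient grams into percent of total
#' energy (%TE). Defaults follow the UK convention of the McCance & Widdowson
#' tables: fat 9, protein 4, carbohydrate 3.75 (as monosaccharide
#' equivalents), alcohol 7 kcal/g.
#'
#' @return Named numeric vector with elements `fat`, `protein`,
#'   `carbohydrate`, `alcohol`.
#' @export
energy_factors <- function() {
  c(fat = 9, protein = 4, carbohydrate = 3.75, alcohol = 7)
}

# nutrients that get a %TE column, with the factor family each one uses
te_nutrients <- function() {
  c(fat_g = "fat", sfa_g = "fat", mufa_g = "fat", pufa_g = "fat",
    protein_g = "protein", carbohydrate_g = "carbohydrate")
}

pct_te_column <- function(nutrient_key) {
  paste0("pct_te_", sub("_g$", "", nutrient_key))
}
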