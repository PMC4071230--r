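#' Full two-instrument agreement report
#'
#' Orchestrates the whole method-comparison battery on two screened,
#' aligned cohort intake tables (instrument A = reference/printed,
#' instrument B = candidate/online). Per nutrient (and percent-energy
#' field): energy-adjusted linear-model comparison, correlation of the
#' configured kind, and quartile cross-classification. Per food group:
#' independent-samples t test, Spearman correlation, cross-classification
#' and Bland-Altman limits of agreement. Bland-Altman summaries are also
#' produced for energy and the macronutrients on both gram and
#' percent-energy scales. Energy itself is excluded from the
#' energy-adjusted model. When demographics are supplied the
#' under-reporting screen and its between-instrument concordance are
#' included. Variables whose ties are too heavy to stratify are reported
#' with `NA` cross-classification percentages and listed in `notes`.
#'
#' @param intakes_a,intakes_b `ffq_intake_table`s for the same respondents
#'   (misaligned respondent sets are an error reporting the symmetric
#'   difference of ids).
#' @param demographics Optional demographics table (see
#'   [read_demographics()]) for the under-reporting screen.
#' @param config List of options: `correlation_kind_nutrients`
#'   (`"spearman"`), `correlation_kind_groups` (`"spearman"`), `k_sd` (2),
#'   `n_strata` (4), `var_equal` (`FALSE`), `covariates` (extra
#'   demographics columns for the adjusted model, e.g. `c("center",
#'   "gender")`).
#' @return Object of class `ffq_agreement_report`: list with data frames
#'   `nutrients`, `food_groups`, `bland_altman`, list `plot_data`
#'   (Bland-Altman coordinates per macronutrient), `under_reporting`
#'   (or `NULL`), `notes`, `n`.
#' @export
compare_instruments <- function(intakes_a, intakes_b, demographics = NULL,
                                config = list()) {
  cfg <- utils::modifyList(
    list(correlation_kind_nutrients = "spearman",
         correlation_kind_groups = "spearman",
         k_sd = 2, n_strata = 4, var_equal = FALSE,
         covariates = character(0)),
    config)
  ids_a <- intakes_a$respondent_id
  ids_b <- intakes_b$respondent_id
  sym <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(sym))
    stop("misaligned respondent sets; ids in only one table: ",
         paste(sym, collapse = ", "))
  intakes_b <- intakes_b[match(ids_a, ids_b), ]
  notes <- character(0)

  xclass <- function(x, y, label) {
    tryCatch(cross_classify(x, y, cfg$n_strata),
             error = function(e) {
               notes <<- c(notes, paste0(label, ": ", conditionMessage(e)))
               list(pct_exact = NA_real_, pct_adjacent_only = NA_real_,
                    pct_two_apart = NA_real_, pct_extreme = NA_real_,
                    pct_exact_plus_adjacent = NA_real_,
                    pct_disagreement_combined = NA_real_)
             })
  }
  corr <- function(x, y, kind, label) {
    tryCatch(correlations(x, y, kind),
             error = function(e) {
               notes <<- c(notes, paste0(label, ": ", conditionMessage(e)))
               list(estimate = NA_real_, p_value = NA_real_)
             })
  }

  extra_cov <- cfg$covariates
  if (length(extra_cov) && is.null(demographics))
    stop("covariates ", paste(extra_cov, collapse = ", "),
         " requested but no demographics supplied")
  cov_df <- if (length(extra_cov))
    demographics[match(ids_a, demographics$respondent_id), extra_cov,
                 drop = FALSE]
  else NULL

  nutrient_cols <- c(nutrient_keys(), pct_te_column(names(te_nutrients())))
  nutrient_cols <- intersect(nutrient_cols,
                             intersect(names(intakes_a), names(intakes_b)))
  nut_rows <- lapply(nutrient_cols, function(nc) {
    x <- intakes_a[[nc]]; y <- intakes_b[[nc]]
    adj <- if (nc == "energy_kcal") {
      list(estimate = NA_real_, p_value = NA_real_)
    } else {
      long <- data.frame(
        intake = c(x, y),
        method = rep(c("A", "B"), each = length(x)),
        energy = c(intakes_a$energy_kcal, intakes_b$energy_kcal))
      if (!is.null(cov_df))
        long <- cbind(long, rbind(cov_df, cov_df))
      tryCatch(
        adjusted_comparison(long, covariates = c("energy", extra_cov),
                            interactions = FALSE),
        error = function(e) {
          notes <<- c(notes, paste0(nc, ": ", conditionMessage(e)))
          list(estimate = NA_real_, p_value = NA_real_)
        })
    }
    cc <- xclass(x, y, nc)
    cr <- corr(x, y, cfg$correlation_kind_nutrients, nc)
    data.frame(variable = nc, mean_a = mean(x), sd_a = stats::sd(x),
               mean_b = mean(y), sd_b = stats::sd(y),
               adj_estimate = adj$estimate, adj_p = adj$p_value,
               correlation = cr$estimate, correlation_p = cr$p_value,
               pct_exact = cc$pct_exact,
               pct_exact_plus_adjacent = cc$pct_exact_plus_adjacent,
               pct_two_apart = cc$pct_two_apart,
               pct_extreme = cc$pct_extreme, stringsAsFactors = FALSE)
  })
  nutrients <- do.call(rbind, nut_rows)

  group_cols <- intersect(grep("^fg_", names(intakes_a), value = TRUE),
                          names(intakes_b))
  grp_rows <- lapply(group_cols, function(gc) {
    x <- intakes_a[[gc]]; y <- intakes_b[[gc]]
    tt <- tryCatch(group_ttest(x, y, var_equal = cfg$var_equal),
                   error = function(e) {
                     notes <<- c(notes, paste0(gc, ": ", conditionMessage(e)))
                     list(t = NA_real_, p_value = NA_real_)
                   })
    cr <- corr(x, y, cfg$correlation_kind_groups, gc)
    cc <- xclass(x, y, gc)
    ba <- bland_altman(x, y, cfg$k_sd)
    data.frame(food_group = sub("^fg_", "", gc),
               mean_a = mean(x), sd_a = stats::sd(x),
               mean_b = mean(y), sd_b = stats::sd(y),
               t = tt$t, t_p = tt$p_value,
               correlation = cr$estimate, correlation_p = cr$p_value,
               pct_exact = cc$pct_exact,
               pct_exact_plus_adjacent = cc$pct_exact_plus_adjacent,
               pct_two_apart = cc$pct_two_apart,
               ba_mean_diff = ba$mean_diff, ba_pct_within = ba$pct_within,
               ba_comparable = ba$comparable, stringsAsFactors = FALSE)
  })
  food_groups_df <- do.call(rbind, grp_rows)

  macro_cols <- intersect(
    c("energy_kcal", "fat_g", "sfa_g", "mufa_g", "pufa_g", "protein_g",
      "carbohydrate_g", pct_te_column(names(te_nutrients()))),
    nutrient_cols)
  plot_data <- list()
  ba_rows <- lapply(macro_cols, function(mc) {
    ba <- bland_altman(intakes_a[[mc]], intakes_b[[mc]], cfg$k_sd)
    plot_data[[mc]] <<- data.frame(mean = ba$means, diff = ba$diffs)
    data.frame(variable = mc, mean_diff = ba$mean_diff,
               sd_diff = ba$sd_diff, loa_low = ba$loa_low,
               loa_high = ba$loa_high, n_outside = ba$n_outside,
               pct_within = ba$pct_within, comparable = ba$comparable,
               stringsAsFactors = FALSE)
  })
  ba_df <- do.call(rbind, ba_rows)

  under <- NULL
  if (!is.null(demographics)) {
    dem <- demographics[match(ids_a, demographics$respondent_id), ]
    under <- screen_under_reporting(dem, intakes_a$energy_kcal,
                                    intakes_b$energy_kcal)
  }

  structure(list(nutrients = nutrients, food_groups = food_groups_df,
                 bland_altman = ba_df, plot_data = plot_data,
                 under_reporting = under, notes = notes,
                 n = length(ids_a)),
            class = "ffq_agreement_report")
}

#' @export
print.ffq_agreement_report <- function(x, ...) {
  cat("Two-instrument agreement report (n = ", x$n, " respondents)\n",
      sep = "")
  cat("  nutrients compared:   ", nrow(x$nutrients), "\n", sep = "")
  cat("  food groups compared: ", nrow(x$food_groups), "\n", sep = "")
  ok <- stats::complete.cases(x$nutrients$correlation)
  cat("  mean nutrient correlation: ",
      round(mean(x$nutrients$correlation[ok]), 2), "\n", sep = "")
  cat("  mean food-group correlation: ",
      round(mean(x$food_groups$correlation, na.rm = TRUE), 2), "\n",
      sep = "")
  if (!is.null(x$under_reporting))
    cat("  under-reporters: ", x$under_reporting$n_under_a, " (A) vs ",
        x$under_reporting$n_under_b, " (B); concordance B-in-A: ",
        round(x$under_reporting$concordance_b_in_a, 1), "%\n", sep = "")
  if (length(x$notes))
    cat("  notes: ", length(x$notes), " variable(s) degenerate\n", sep = "")
  invisible(x)
}

#' Write an agreement report as delimited tables
#'
#' Writes `nutrients.csv`, `food_groups.csv`, `bland_altman.csv` and (per
#' macronutrient) `ba_points_<variable>.csv` plot coordinates into a
#' directory.
#'
#' @param report An `ffq_agreement_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_agreement_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$nutrients, file.path(dir, "nutrients.csv"),
                   row.names = FALSE)
  utils::write.csv(report$food_groups, file.path(dir, "food_groups.csv"),
                   row.names = FALSE)
  utils::write.csv(report$bland_altman, file.path(dir, "bland_altman.csv"),
                   row.names = FALSE)
  for (v in names(report$plot_data))
    utils::write.csv(report$plot_data[[v]],
                     file.path(dir, paste0("ba_points_", v, ".csv")),
                     row.names = FALSE)
  if (!is.null(report$under_reporting))
    utils::write.csv(report$under_reporting$table,
                     file.path(dir, "under_reporting.csv"),
                     row.names = FALSE)
  invisible(dir)
}
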