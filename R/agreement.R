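#' Bland-Altman limits of agreement
#'
#' For paired measurements of the same quantity by two methods, the
#' differences `x - y` are summarized by their mean (bias) and sample
#' standard deviation (n - 1 denominator), with limits of agreement at
#' mean difference +/- `k_sd` standard deviations. Following common FFQ
#' comparison practice the default is the literal mean +/- 2 SD (not
#' 1.96 SD). Methods are considered comparable when strictly more than 95%
#' of the paired differences lie within the limits. With zero-variance
#' differences the limits collapse onto the mean and 100% of points are
#' within them (documented behaviour, not an error).
#'
#' @param x,y Paired numeric vectors (method A and method B), length >= 3.
#' @param k_sd Width of the limits in SDs (default 2).
#' @return An object of class `ffq_bland_altman`: list with `n`,
#'   `mean_diff`, `sd_diff`, `loa_low`, `loa_high`, `n_outside` (strictly
#'   outside the limits), `pct_within`, `comparable`, and plot-ready
#'   `means` ((x+y)/2) and `diffs` (x-y).
#' @export
#' @examples
#' ba <- bland_altman(c(10, 12, 9, 14), c(9, 13, 8, 15))
#' ba$mean_diff
bland_altman <- function(x, y, k_sd = 2) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("Bland-Altman needs at least 3 pairs")
  if (anyNA(x) || anyNA(y)) stop("paired series must have no missing values")
  d <- x - y
  m <- mean(d)
  s <- stats::sd(d)
  lo <- m - k_sd * s
  hi <- m + k_sd * s
  outside <- sum(d < lo | d > hi)
  pct <- 100 * (length(d) - outside) / length(d)
  structure(list(n = length(d), mean_diff = m, sd_diff = s,
                 loa_low = lo, loa_high = hi, n_outside = outside,
                 pct_within = pct, comparable = pct > 95,
                 means = (x + y) / 2, diffs = d, k_sd = k_sd),
            class = "ffq_bland_altman")
}

#' @export
print.ffq_bland_altman <- function(x, digits = 3, ...) {
  cat("Bland-Altman agreement (n = ", x$n, ")\n", sep = "")
  cat("  bias (mean diff): ", signif(x$mean_diff, digits),
      "  SD: ", signif(x$sd_diff, digits), "\n", sep = "")
  cat("  limits of agreement (mean +/- ", x$k_sd, " SD): [",
      signif(x$loa_low, digits), ", ", signif(x$loa_high, digits), "]\n",
      sep = "")
  cat("  within limits: ", round(x$pct_within, 1), "% (", x$n_outside,
      " outside); comparable: ", x$comparable, "\n", sep = "")
  invisible(x)
}

# quantile-stratum assignment: average-rank ties, cuts at ranks
# n/4, n/2, 3n/4 (upper-inclusive), generalized to n_strata.
quantile_strata <- function(v, n_strata = 4, label = "variable") {
  n <- length(v)
  r <- rank(v, ties.method = "average")
  cuts <- n * seq_len(n_strata - 1) / n_strata
  s <- 1L + rowSums(outer(r, cuts, ">"))
  if (length(unique(s)) < n_strata)
    stop("ties too heavy to form ", n_strata, " strata for ", label)
  s
}

#' Quartile cross-classification of two rankings
#'
#' Each method's values are ranked (average ranks for ties) and cut into
#' `n_strata` near-equal strata at ranks n/4, n/2, 3n/4 (upper-inclusive).
#' Agreement is reported as the percentage of respondents whose stratum
#' labels differ by 0 (exact agreement), exactly 1 (adjacent), exactly 2,
#' and the maximum `n_strata - 1` (extreme/opposite quartiles), plus the
#' combined figure for 2-or-more apart. Being rank-based, the result is
#' invariant to strictly monotone transforms of either series.
#'
#' @param x,y Paired numeric vectors, length >= `n_strata`.
#' @param n_strata Number of strata (default 4 = quartiles).
#' @return Object of class `ffq_cross_class`: `counts` (n_strata x
#'   n_strata matrix, rows = x-stratum), `pct_exact`, `pct_adjacent_only`,
#'   `pct_two_apart`, `pct_extreme`, `pct_exact_plus_adjacent`,
#'   `pct_disagreement_combined` (>= 2 apart), `n`.
#' @export
cross_classify <- function(x, y, n_strata = 4) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < n_strata) stop("need at least ", n_strata, " pairs")
  sx <- quantile_strata(x, n_strata, "x")
  sy <- quantile_strata(y, n_strata, "y")
  counts <- table(factor(sx, levels = seq_len(n_strata)),
                  factor(sy, levels = seq_len(n_strata)))
  d <- abs(sx - sy)
  pct <- function(cond) 100 * sum(cond) / n
  structure(list(
    counts = unclass(counts), n = n,
    pct_exact = pct(d == 0),
    pct_adjacent_only = pct(d == 1),
    pct_two_apart = pct(d == 2),
    pct_extreme = pct(d == n_strata - 1),
    pct_exact_plus_adjacent = pct(d <= 1),
    pct_disagreement_combined = pct(d >= 2)
  ), class = "ffq_cross_class")
}

#' @export
print.ffq_cross_class <- function(x, ...) {
  cat("Quartile cross-classification (n = ", x$n, ")\n", sep = "")
  cat("  exact: ", round(x$pct_exact, 1), "%  exact+adjacent: ",
      round(x$pct_exact_plus_adjacent, 1), "%  >=2 apart: ",
      round(x$pct_disagreement_combined, 1), "%  extreme: ",
      round(x$pct_extreme, 1), "%\n", sep = "")
  invisible(x)
}

#' Correlation between two methods
#'
#' Thin wrapper around [stats::cor.test()] for the two correlation kinds
#' used in method comparison: Pearson on raw intakes and Spearman on ranks
#' (the usual choice for food-group intakes). Zero variance on either side
#' is an error.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @param kind `"spearman"` (default) or `"pearson"`.
#' @return List with `estimate` (in `[-1, 1]`), `p_value` (two-sided),
#'   `kind`, `n`.
#' @export
correlations <- function(x, y, kind = c("spearman", "pearson")) {
  kind <- match.arg(kind)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined")
  ct <- stats::cor.test(x, y, method = kind, exact = FALSE)
  list(estimate = unname(ct$estimate), p_value = ct$p.value, kind = kind,
       n = length(x))
}

#' Energy-adjusted comparison of intakes between two methods
#'
#' Ordinary least-squares fit of `intake ~ method + energy [+ center +
#' gender + randomization]` on the stacked (long) intake table, treating
#' rows as independent observations. Returns the method effect (the
#' expected intake difference between methods at equal covariate values),
#' its two-sided p-value, and, when requested, p-values for the
#' method-by-covariate interactions (each tested by adding one interaction
#' to the main-effects model). Covariates with zero variance are dropped
#' with a message; genuinely collinear covariates are an error naming the
#' aliased columns.
#'
#' @param data Long data frame with the outcome column, a two-level
#'   `method` column, and covariate columns.
#' @param outcome Name of the outcome column (default `"intake"`).
#' @param covariates Covariate column names (default `"energy"`).
#' @param interactions Also test method x covariate interactions.
#' @return List with `estimate`, `se`, `p_value`, `term` (the method
#'   contrast), `model` (the `lm` fit), `dropped` (zero-variance
#'   covariates), `interactions` (data frame of term and p-value).
#' @export
adjusted_comparison <- function(data, outcome = "intake",
                                covariates = "energy",
                                interactions = TRUE) {
  if (!"method" %in% names(data)) stop("data must have a 'method' column")
  data$method <- factor(data$method)
  if (nlevels(data$method) != 2)
    stop("method must be a two-level factor")
  missing_cov <- setdiff(c(outcome, covariates), names(data))
  if (length(missing_cov))
    stop("missing column(s): ", paste(missing_cov, collapse = ", "))
  const <- covariates[vapply(covariates, function(cv) {
    v <- data[[cv]]
    length(unique(v)) < 2
  }, logical(1))]
  if (length(const))
    message("dropping constant covariate(s): ", paste(const, collapse = ", "))
  covariates <- setdiff(covariates, const)
  rhs <- paste(c("method", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- stats::lm(fml, data = data)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased))
    stop("rank-deficient design; collinear column(s): ",
         paste(aliased, collapse = ", "))
  sm <- stats::summary.lm(fit)$coefficients
  term <- grep("^method", rownames(sm), value = TRUE)[1]
  inter <- NULL
  if (interactions && length(covariates)) {
    inter <- do.call(rbind, lapply(covariates, function(cv) {
      f2 <- stats::as.formula(paste(outcome, "~", rhs, "+ method:", cv))
      fit2 <- stats::lm(f2, data = data)
      a <- stats::anova(fit, fit2)
      data.frame(term = paste0("method:", cv),
                 p_value = a[["Pr(>F)"]][2], stringsAsFactors = FALSE)
    }))
  }
  list(estimate = sm[term, "Estimate"], se = sm[term, "Std. Error"],
       p_value = sm[term, "Pr(>|t|)"], term = term, model = fit,
       dropped = const, interactions = inter)
}

#' Two-sample t test on food-group intakes
#'
#' Independent-samples t test comparing daily intakes reported by the two
#' instruments, Welch's unequal-variance form by default
#' (`var_equal = TRUE` gives the pooled-variance test). Zero variance on
#' both sides is an error.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param var_equal Pooled-variance test instead of Welch.
#' @return List with `t`, `df`, `p_value`, `mean_diff` (mean(x) -
#'   mean(y)).
#' @export
group_ttest <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("zero pooled variance: t statistic undefined")
  tt <- stats::t.test(x, y, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(x) - mean(y))
}
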