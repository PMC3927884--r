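## Demographic time-series analysis: Theil-Sen slopes, Mann-Kendall trend
## tests, run-size normalization, and species/stock comparisons of slopes.

#' Construct a demographic time series
#'
#' @param river_code river code.
#' @param variable one of "mean_length", "run_count", "run_cpue".
#' @param sex "F", "M" or "pooled".
#' @param years integer years (strictly increasing after sorting; gaps
#'   allowed, duplicates rejected).
#' @param values observations.
#' @return object of class `time_series`.
#' @export
time_series <- function(river_code, variable, sex, years, values) {
  if (!variable %in% c("mean_length", "run_count", "run_cpue"))
    stop("unknown variable '", variable, "'")
  ord <- order(years)
  years <- as.integer(years[ord]); values <- as.numeric(values[ord])
  if (anyDuplicated(years)) stop("duplicate years in series ", river_code)
  structure(list(river_code = river_code, variable = variable, sex = sex,
                 years = years, values = values),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(x$river_code, x$variable, x$sex, ":", length(x$years), "records,",
      min(x$years), "-", max(x$years), "\n")
  invisible(x)
}

#' Normalize a series to mean 0, SD 1
#'
#' Uses the sample (n-1) SD over the observed years; the convention is
#' recorded in the `normalization` attribute.
#'
#' @param ts a [time_series()].
#' @export
normalize_series <- function(ts) {
  if (length(ts$values) < 2L) stop("need at least 2 records to normalize")
  s <- sd(ts$values)
  if (!isTRUE(s > 0)) stop("constant series cannot be normalized")
  out <- ts
  out$values <- (ts$values - mean(ts$values)) / s
  attr(out, "normalization") <- "(x - mean) / sample SD (n-1)"
  out
}

#' Theil-Sen slope
#'
#' Median of all pairwise slopes \eqn{(v_j - v_i)/(y_j - y_i)} over record
#' pairs (same-year pairs, impossible after ingestion, would be skipped).
#'
#' @param ts a [time_series()].
#' @return slope in value units per year.
#' @export
theil_sen <- function(ts) {
  n <- length(ts$years)
  if (n < 2L) stop("need at least 2 records")
  ij <- combn(n, 2L)
  dy <- ts$years[ij[2L, ]] - ts$years[ij[1L, ]]
  dv <- ts$values[ij[2L, ]] - ts$values[ij[1L, ]]
  median(dv[dy != 0] / dy[dy != 0])
}

## exact null distribution of Mann-Kendall S for n untied observations:
## S = n(n-1)/2 - 2 * (number of inversions); inversion counts come from
## convolving uniform{0..i} blocks.
mk_exact_tail <- function(n, s_abs) {
  counts <- 1
  for (i in seq_len(n - 1L))
    counts <- convolve_full(counts, rep(1, i + 1L))
  n0 <- n * (n - 1L) / 2L
  s_vals <- n0 - 2L * (seq_along(counts) - 1L)
  sum(counts[abs(s_vals) >= s_abs]) / sum(counts)
}

convolve_full <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1L)
  for (i in seq_along(b)) {
    ix <- seq_along(a) + i - 1L
    out[ix] <- out[ix] + a * b[i]
  }
  out
}

#' Mann-Kendall trend test
#'
#' \eqn{S = \sum_{i<j} \mathrm{sgn}(v_j - v_i)} over year-ordered records;
#' tau is the tie-corrected (tau-b) coefficient.  For n <= 10 with no tied
#' values the exact two-sided null distribution of S is used; otherwise the
#' normal approximation with tie-corrected variance and continuity
#' correction.  The trend category combines the Theil-Sen slope sign with
#' p vs `alpha` into the five classes significant/nonsignificant
#' decline/increase and "no change" (|slope| < 1e-12).
#'
#' @param ts a [time_series()].
#' @param alpha significance level for the category.
#' @return object of class `trend_result`.
#' @export
mann_kendall <- function(ts, alpha = 0.05) {
  n <- length(ts$years)
  if (n < 3L) stop("need at least 3 records")
  v <- ts$values[order(ts$years)]
  ij <- combn(n, 2L)
  S <- sum(sign(v[ij[2L, ]] - v[ij[1L, ]]))
  ties <- table(v)
  ties <- ties[ties > 1L]
  varS <- (n * (n - 1) * (2 * n + 5) -
             sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  n0 <- n * (n - 1) / 2
  tie_v <- sum(ties * (ties - 1) / 2)
  tau <- if (n0 - tie_v > 0) S / sqrt(n0 * (n0 - tie_v)) else 0
  if (all(v == v[1L])) {
    p <- 1; S <- 0L; tau <- 0
  } else if (n <= 10L && length(ties) == 0L) {
    p <- mk_exact_tail(n, abs(S))
  } else {
    z <- if (S > 0) (S - 1) / sqrt(varS)
         else if (S < 0) (S + 1) / sqrt(varS) else 0
    p <- 2 * pnorm(-abs(z))
  }
  slope <- theil_sen(ts)
  category <- if (abs(slope) < 1e-12) "no change"
    else if (slope < 0 && p < alpha) "significant decline"
    else if (slope < 0) "nonsignificant decline"
    else if (p < alpha) "significant increase"
    else "nonsignificant increase"
  structure(list(river_code = ts$river_code, variable = ts$variable,
                 sex = ts$sex, n = n, slope = slope, mk_S = S, tau = tau,
                 p_value = p, category = category),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(x$river_code, x$variable, x$sex, ": slope =", signif(x$slope, 4),
      " S =", x$mk_S, " tau =", round(x$tau, 3),
      " p =", format(x$p_value, digits = 3), "->", x$category, "\n")
  invisible(x)
}

#' Trend summary over a set of series
#'
#' Runs [mann_kendall()] on every series and tallies the five trend
#' categories.  Run-size series are normalized first when
#' `normalize_run_size` is TRUE (mean-length series stay in raw units), so
#' run-size slopes come out in dimensionless SD units per year.
#'
#' @param series list of [time_series()].
#' @param alpha significance level.
#' @param normalize_run_size normalize run_count/run_cpue series first.
#' @return list with `per_series` data.frame and `counts` per category.
#' @export
trend_table <- function(series, alpha = 0.05, normalize_run_size = TRUE) {
  cats <- c("significant decline", "nonsignificant decline", "no change",
            "nonsignificant increase", "significant increase")
  if (length(series) == 0L)
    return(list(per_series = data.frame(), counts = setNames(rep(0L, 5), cats)))
  rows <- lapply(series, function(ts) {
    if (normalize_run_size && ts$variable %in% c("run_count", "run_cpue"))
      ts <- normalize_series(ts)
    tr <- mann_kendall(ts, alpha)
    data.frame(river = tr$river_code, variable = tr$variable, sex = tr$sex,
               n = tr$n, slope = tr$slope, S = tr$mk_S, tau = tr$tau,
               p = tr$p_value, category = tr$category,
               stringsAsFactors = FALSE)
  })
  per_series <- do.call(rbind, rows)
  counts <- setNames(integer(5L), cats)
  tab <- table(per_series$category)
  counts[names(tab)] <- as.integer(tab)
  list(per_series = per_series, counts = counts)
}

#' Compare trend slopes between groups (species, stocks, sexes)
#'
#' Fits the fixed-effects linear model `slope ~ factor1 [+ factor2 ...]`,
#' reports the ANOVA F tests, and runs Tukey HSD (Tukey-Kramer for unequal
#' n) pairwise comparisons for each factor.
#'
#' @param slopes data.frame with a `slope` column and factor columns.
#' @param factors character vector of factor column names.
#' @return list with `model` (aov fit), `anova` table and `tukey` (a
#'   `TukeyHSD` object).
#' @export
slope_comparison <- function(slopes, factors) {
  if (!"slope" %in% names(slopes)) stop("need a 'slope' column")
  for (f in factors) {
    if (!f %in% names(slopes)) stop("missing factor column '", f, "'")
    slopes[[f]] <- droplevels(factor(slopes[[f]]))
    if (nlevels(slopes[[f]]) < 2L)
      stop("factor '", f, "' has a single level after dropping empties")
  }
  form <- stats::as.formula(paste("slope ~", paste(factors, collapse = " + ")))
  fit <- aov(form, data = slopes)
  list(model = fit, anova = anova(fit), tukey = TukeyHSD(fit, which = factors))
}
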