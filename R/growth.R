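# Exponential population growth by budding: ln(n/n0) = k t.
#
# The growth constant k (per day) is the regression slope of the log count
# ratio on time; the population doubling time is T2 = ln(2)/k.

#' Log count-ratio series of one replicate
#'
#' Transforms daily population counts into `(t, y)` pairs with
#' `y = ln(n/n0)`, `n0` the day-0 founder count, so that exponential growth
#' is linear through the origin.
#'
#' @param day integer vector of observation days, including day 0.
#' @param n integer counts (>= 1) matching `day`.
#' @return data frame `t, y`, sorted by `t`; `y[t == 0]` is exactly 0.
#' @export
log_ratio_series <- function(day, n) {
  if (length(day) != length(n)) stop("day and n must have equal length")
  if (any(n < 1)) stop("population counts must be >= 1")
  if (!any(day == 0)) stop("missing day-0 founder count")
  o <- order(day)
  day <- day[o]; n <- n[o]
  n0 <- n[day == 0][1]
  data.frame(t = day, y = log(n / n0))
}

#' Fit the exponential growth model
#'
#' Least-squares fit of `y = ln(n/n0)` on `t`. Through-origin (default, the
#' model has no intercept: `k = sum(t y)/sum(t^2)`) or free-intercept by
#' flag. The doubling time `T2 = ln(2)/k` is defined for `k > 0` only; for
#' non-growing populations it is reported `NA` with a flag.
#'
#' @param series data frame with columns `t` and `y`
#'   ([log_ratio_series()] output).
#' @param through_origin logical, default `TRUE`.
#' @return list of class `growth_fit`: `k` (per day), `T2` (days),
#'   `intercept`, `r2`, `se_k`, `residuals`, `n_obs`, `growing`.
#' @examples
#' s <- log_ratio_series(0:7, round(4 * exp(0.2 * (0:7))))
#' fit_growth(s)
#' @export
fit_growth <- function(series, through_origin = TRUE) {
  t <- series$t; y <- series$y
  if (length(unique(t)) < 2) stop("need >= 2 distinct days")
  if (!through_origin && length(unique(t)) < 3)
    stop("free-intercept fit needs >= 3 distinct days")
  if (through_origin) {
    # day-0 rows are identities (y(0) = 0 by construction), not
    # observations: they carry no slope information and must not count
    # toward residual degrees of freedom
    keep <- t != 0
    if (sum(keep) < 1) stop("need >= 1 post-founding observation")
    t <- t[keep]; y <- y[keep]
  }
  fit <- if (through_origin) stats::lm(y ~ 0 + t) else stats::lm(y ~ t)
  co <- stats::coef(fit)
  k <- unname(co[["t"]])
  intercept <- if (through_origin) 0 else unname(co[["(Intercept)"]])
  # R^2 about the model actually fitted (no intercept: uncentred)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- if (through_origin) sum(y^2) else sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  se_k <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["t", "Std. Error"]),
    error = function(e) NA_real_)
  structure(list(k = k,
                 T2 = if (k > 0) log(2) / k else NA_real_,
                 intercept = intercept, r2 = r2, se_k = se_k,
                 residuals = unname(stats::residuals(fit)),
                 n_obs = length(t), growing = k > 0),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Exponential growth fit: k = %.4g /day", x$k))
  if (x$growing) cat(sprintf(", doubling time T2 = %.3g days", x$T2))
  else cat(" (non-growing; doubling time undefined)")
  cat(sprintf("\n  intercept = %.4g, R^2 = %.4f, n = %d\n",
              x$intercept, x$r2, x$n_obs))
  invisible(x)
}

#' Test equality of growth constants between two populations
#'
#' Slope-heterogeneity F-test: the two log-ratio series are pooled into one
#' regression with a group indicator and the time-by-group interaction is
#' tested against the common-slope model (ANCOVA interaction). Two
#' noiseless series with different slopes give a zero residual; the p-value
#' is then reported as 0.
#'
#' @param seriesA,seriesB data frames with columns `t`, `y`.
#' @param through_origin share the no-intercept parameterisation of
#'   [fit_growth()] (default `TRUE`); otherwise each group gets its own
#'   intercept.
#' @return list: `slope_diff` (kA - kB), `F`, `df` (numerator, denominator),
#'   `p_value`, and the per-group fits.
#' @export
compare_growth <- function(seriesA, seriesB, through_origin = TRUE) {
  fitA <- fit_growth(seriesA, through_origin)
  fitB <- fit_growth(seriesB, through_origin)
  d <- rbind(data.frame(t = seriesA$t, y = seriesA$y, g = 0),
             data.frame(t = seriesB$t, y = seriesB$y, g = 1))
  if (through_origin) d <- d[d$t != 0, , drop = FALSE]  # identity rows
  if (through_origin) {
    full <- stats::lm(y ~ 0 + t + t:g, data = d)
    reduced <- stats::lm(y ~ 0 + t, data = d)
  } else {
    full <- stats::lm(y ~ t * g, data = d)
    reduced <- stats::lm(y ~ t + g, data = d)
  }
  ss_full <- sum(stats::residuals(full)^2)
  ss_red <- sum(stats::residuals(reduced)^2)
  df1 <- full$rank - reduced$rank
  df2 <- nrow(d) - full$rank
  if (df2 < 1) stop("degenerate design: no residual degrees of freedom")
  slope_diff <- fitA$k - fitB$k
  if (ss_full <= 1e-12 * max(1, ss_red)) {
    # noiseless case: any slope difference is infinitely significant
    Fstat <- if (ss_red <= 1e-12) 0 else Inf
    p <- if (is.infinite(Fstat)) 0 else 1
  } else {
    Fstat <- ((ss_red - ss_full) / df1) / (ss_full / df2)
    p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  }
  list(slope_diff = slope_diff, F = Fstat, df = c(df1, df2), p_value = p,
       fitA = fitA, fitB = fitB)
}

#' Per-replicate growth fits from a population table
#'
#' @param population a validated `population` data frame
#'   (see [load_table()]).
#' @param through_origin passed to [fit_growth()].
#' @return data frame with one row per replicate: `replicate_id, label, k,
#'   T2, r2, n_obs`.
#' @export
growth_by_replicate <- function(population, through_origin = TRUE) {
  ids <- unique(population$replicate_id)
  rows <- lapply(ids, function(id) {
    d <- population[population$replicate_id == id, ]
    s <- log_ratio_series(d$day, d$n)
    f <- fit_growth(s, through_origin)
    data.frame(replicate_id = id, label = d$label[1], k = f$k, T2 = f$T2,
               r2 = f$r2, n_obs = f$n_obs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
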