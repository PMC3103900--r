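# Trimmed Spearman-Karber estimation of LC50 / LT50.
#
# The estimator works on log10(dose in nM) or log10(time in hr). The
# observed dead fractions are first made monotone non-decreasing by weighted
# pool-adjacent-violators (weights = group sizes), optionally trimmed at
# (alpha, 1 - alpha), and the log-median is the probability-weighted mean of
# interval midpoints. Confidence bounds use the classic delta-method
# variance and a normal quantile on the log scale, back-transformed.

#' Monotone smoothing of a quantal response curve
#'
#' Weighted least-squares monotone (non-decreasing) fit of the observed dead
#' fractions by pool-adjacent-violators, with group sizes as weights. Groups
#' not involved in any violation are left unchanged; pooled blocks take the
#' weighted mean of their members.
#'
#' @param series a [quantal_series()].
#' @return An object of class `smoothed_curve`: list with `x` (log10 axis
#'   values), `p_raw`, `p_adj`, `n`, `axis`, `label`.
#' @export
smooth_monotone <- function(series) {
  stopifnot(inherits(series, "quantal_series"))
  g <- series$groups
  p <- g$n_dead / g$n_exposed
  structure(list(x = log10(g$value),
                 p_raw = p,
                 p_adj = pava(p, g$n_exposed),
                 n = g$n_exposed,
                 axis = series$axis,
                 label = series$label),
            class = "smoothed_curve")
}

#' Weighted pool-adjacent-violators
#'
#' Isotonic (non-decreasing) weighted least-squares regression on an ordered
#' sequence: adjacent values violating monotonicity are repeatedly pooled
#' into blocks carrying their weighted mean.
#'
#' @param y numeric values in sequence order.
#' @param w positive weights.
#' @return Fitted non-decreasing vector of `length(y)`.
#' @export
pava <- function(y, w = rep(1, length(y))) {
  stopifnot(length(y) == length(w), all(w > 0))
  n <- length(y)
  if (n <= 1) return(y)
  # blocks as (value, weight, size) stacks
  val <- numeric(n); wt <- numeric(n); sz <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    top <- top + 1L
    val[top] <- y[i]; wt[top] <- w[i]; sz[top] <- 1L
    while (top > 1L && val[top - 1L] > val[top]) {
      val[top - 1L] <- (wt[top - 1L] * val[top - 1L] + wt[top] * val[top]) /
        (wt[top - 1L] + wt[top])
      wt[top - 1L] <- wt[top - 1L] + wt[top]
      sz[top - 1L] <- sz[top - 1L] + sz[top]
      top <- top - 1L
    }
  }
  rep(val[seq_len(top)], sz[seq_len(top)])
}

# append/prepend pseudo-groups so the smoothed curve spans 0..1: assume 0%
# response one log-step below the lowest group and 100% one log-step above
# the highest (step = spacing of the adjacent interval).
.extend_curve <- function(curve) {
  x <- curve$x; p <- curve$p_adj; praw <- curve$p_raw; n <- curve$n
  step_lo <- if (length(x) > 1) x[2] - x[1] else 1
  step_hi <- if (length(x) > 1) x[length(x)] - x[length(x) - 1] else 1
  if (p[1] > 0) {
    x <- c(x[1] - step_lo, x); p <- c(0, p); praw <- c(0, praw)
    n <- c(n[1], n)
  }
  if (p[length(p)] < 1) {
    x <- c(x, x[length(x)] + step_hi); p <- c(p, 1); praw <- c(praw, 1)
    n <- c(n, n[length(n)])
  }
  structure(list(x = x, p_raw = praw, p_adj = p, n = n, axis = curve$axis,
                 label = curve$label), class = "smoothed_curve")
}

.not_estimable <- function(reason) {
  structure(class = c("hydratox_not_estimable", "error", "condition"),
            list(message = reason, call = NULL))
}

#' Trim a smoothed response curve
#'
#' Discards the tails of the smoothed curve below `alpha` and above
#' `1 - alpha` and rescales the retained response to `[0, 1]`:
#' `p' = (p_adj - alpha) / (1 - 2 alpha)`. The axis positions where the
#' curve crosses `alpha` and `1 - alpha` are found by linear interpolation
#' on the (x, p_adj) polyline and inserted as new endpoints with `p' = 0`
#' and `p' = 1`. With `alpha = 0` the curve is returned unchanged.
#'
#' @param curve a `smoothed_curve`.
#' @param alpha trim fraction in `[0, 0.5)`.
#' @return A trimmed `smoothed_curve`.
#' @export
trim_curve <- function(curve, alpha) {
  stopifnot(inherits(curve, "smoothed_curve"))
  if (alpha < 0 || alpha >= 0.5) stop("trim fraction must lie in [0, 0.5)")
  if (alpha == 0) return(curve)
  p <- curve$p_adj; x <- curve$x; n <- curve$n
  if (p[1] > alpha || p[length(p)] < 1 - alpha)
    stop(.not_estimable(sprintf(
      "smoothed response spans [%.3f, %.3f]; cannot trim at alpha = %g",
      p[1], p[length(p)], alpha)))
  x_lo <- .cross_x(x, p, alpha)
  x_hi <- .cross_x_upper(x, p, 1 - alpha)
  keep <- which(p > alpha & p < 1 - alpha & x > x_lo & x < x_hi)
  x_new <- c(x_lo, x[keep], x_hi)
  p_new <- c(alpha, p[keep], 1 - alpha)
  p_new <- pmin(pmax((p_new - alpha) / (1 - 2 * alpha), 0), 1)
  n_new <- c(if (length(keep)) n[min(keep)] else n[1],
             n[keep],
             if (length(keep)) n[max(keep)] else n[length(n)])
  structure(list(x = x_new, p_raw = p_new, p_adj = p_new, n = n_new,
                 axis = curve$axis, label = curve$label),
            class = "smoothed_curve")
}

# last x at which the non-decreasing polyline (x, p) sits at level q
# (lower trim boundary), interpolating within the crossing interval
.cross_x <- function(x, p, q) {
  k <- length(p)
  i <- max(which(p <= q))             # last point at or below the level
  if (i == k) return(x[k])
  if (p[i] == q) return(x[i])
  x[i] + (q - p[i]) / (p[i + 1] - p[i]) * (x[i + 1] - x[i])
}

# first x at which the polyline attains level q (upper trim boundary)
.cross_x_upper <- function(x, p, q) {
  i <- min(which(p >= q))
  if (i == 1) return(x[1])
  if (p[i] == q) return(x[i])
  x[i - 1] + (q - p[i - 1]) / (p[i] - p[i - 1]) * (x[i] - x[i - 1])
}

#' Spearman-Karber log-scale median
#'
#' Point estimate of the log10 median of the tolerance distribution from a
#' smoothed (and possibly trimmed) quantal curve spanning 0..1:
#' \deqn{m = \sum_i (p_{i+1} - p_i)\,(x_i + x_{i+1})/2.}
#'
#' @param curve a `smoothed_curve` with `p_adj[1] == 0` and
#'   `p_adj[last] == 1`.
#' @return The log10 median `m`.
#' @export
sk_log_median <- function(curve) {
  stopifnot(inherits(curve, "smoothed_curve"))
  p <- curve$p_adj; x <- curve$x
  if (abs(p[1]) > 1e-12 || abs(p[length(p)] - 1) > 1e-12)
    stop(.not_estimable(sprintf(
      "smoothed response spans [%.3f, %.3f]; median not estimable without the endpoint extension",
      p[1], p[length(p)])))
  k <- length(p)
  sum(diff(p) * (x[-k] + x[-1]) / 2)
}

#' Delta-method variance and confidence interval for the log median
#'
#' \deqn{V = \sum_{i\ \mathrm{interior}} p_i(1-p_i)
#'           (x_{i+1}-x_{i-1})^2 / (4(n_i-1))}
#' with bounds \eqn{10^{m \pm z\sqrt V}}. The two terminal groups carry
#' `p(1-p) = 0` on an estimable curve and are omitted.
#'
#' @param curve a `smoothed_curve` spanning 0..1.
#' @param m log10 median from [sk_log_median()].
#' @param level confidence level in (0, 1).
#' @return list with `variance`, `ci_low`, `ci_high` (back-transformed).
#' @export
sk_confidence <- function(curve, m, level = 0.95) {
  stopifnot(inherits(curve, "smoothed_curve"))
  p <- curve$p_adj; x <- curve$x; n <- curve$n
  k <- length(p)
  interior <- setdiff(seq_len(k), c(1L, k))
  active <- interior[p[interior] > 0 & p[interior] < 1]
  if (any(n[interior] < 2))
    stop("variance undefined: an interior group has n < 2")
  V <- if (length(active) == 0) 0 else
    sum(p[active] * (1 - p[active]) *
          (x[active + 1L] - x[active - 1L])^2 / (4 * (n[active] - 1)))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(variance = V,
       ci_low = 10^(m - z * sqrt(V)),
       ci_high = 10^(m + z * sqrt(V)))
}

# shared driver behind estimate_lc50 / estimate_lt50
.sk_estimate <- function(series, config, axis) {
  if (series$axis != axis)
    stop(sprintf("series axis is '%s'; expected '%s'", series$axis, axis))
  curve <- smooth_monotone(series)
  if (isTRUE(config$extend)) curve <- .extend_curve(curve)
  result <- tryCatch({
    trimmed <- trim_curve(curve, config$trim)
    m <- sk_log_median(trimmed)
    ci <- sk_confidence(trimmed, m, config$confidence)
    list(m = m, point = 10^m, variance = ci$variance,
         se_log10 = sqrt(ci$variance),
         ci_low = ci$ci_low, ci_high = ci$ci_high,
         estimable = TRUE, reason = NULL, curve = trimmed)
  }, hydratox_not_estimable = function(e) {
    list(m = NA_real_, point = NA_real_, variance = NA_real_,
         se_log10 = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
         estimable = FALSE, reason = conditionMessage(e), curve = curve)
  })
  structure(c(result,
              list(trim = config$trim, confidence = config$confidence,
                   extend = isTRUE(config$extend), axis = axis,
                   label = series$label)),
            class = "sk_estimate")
}

#' Estimate the median lethal concentration (LC50)
#'
#' Trimmed Spearman-Karber estimate from a quantal dose series at one
#' observation time: monotone smoothing, optional trimming, log10 median and
#' delta-method confidence interval. A response curve that never reaches 0%
#' or 100% mortality at the tested doses yields a not-estimable result
#' (reported, not an error) unless `config$extend` assumes the conventional
#' 0%/100% anchors one log-step outside the tested range.
#'
#' @param series a dose-axis [quantal_series()].
#' @param config a [run_config()].
#' @return An `sk_estimate`: point estimate in nM, log10 median `m`,
#'   `se_log10`, confidence bounds, `estimable` flag and parameters used.
#' @examples
#' qs <- quantal_series(c(50, 100, 200, 400), rep(20, 4), c(0, 4, 16, 20))
#' estimate_lc50(qs, run_config())
#' @export
estimate_lc50 <- function(series, config = run_config()) {
  .sk_estimate(series, config, "dose")
}

#' Estimate the median lethal time (LT50)
#'
#' Identical algorithm on the log10 time axis. The series must hold
#' cumulative dead counts at increasing observation times for one fixed
#' concentration; any non-monotonicity (recovered animals) is pooled by the
#' same monotone smoothing step.
#'
#' @param series a time-axis [quantal_series()] of cumulative dead counts.
#' @inheritParams estimate_lc50
#' @return An `sk_estimate` with the point estimate in hours.
#' @export
estimate_lt50 <- function(series, config = run_config()) {
  .sk_estimate(series, config, "time")
}

#' @export
print.sk_estimate <- function(x, ...) {
  unit <- if (x$axis == "dose") "nM" else "hr"
  what <- if (x$axis == "dose") "LC50" else "LT50"
  lab <- if (nzchar(x$label)) paste0(" [", x$label, "]") else ""
  if (!x$estimable) {
    cat(sprintf("%s%s: not estimable (%s)\n", what, lab, x$reason))
  } else {
    cat(sprintf("%s%s = %.4g %s, %g%% CI (%.4g, %.4g), SE(log10) = %.4g%s\n",
                what, lab, x$point, unit, 100 * x$confidence,
                x$ci_low, x$ci_high, x$se_log10,
                if (x$trim > 0) sprintf(", trim = %g", x$trim) else ""))
  }
  invisible(x)
}

# flat one-row summary used by CSV/JSON emitters
.sk_row <- function(est) {
  data.frame(label = est$label, axis = est$axis, trim = est$trim,
             m = est$m, point = est$point, se_log10 = est$se_log10,
             ci_low = est$ci_low, ci_high = est$ci_high,
             estimable = est$estimable,
             reason = if (is.null(est$reason)) "" else est$reason,
             stringsAsFactors = FALSE)
}
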