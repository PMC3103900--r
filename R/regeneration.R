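# Tentacle regeneration index (TRI) after bisection in the gastric region.
#
# Regenerating tentacles are binned daily into 5 relative-length classes
# (1/8, 1/4, 1/2, 3/4, 1 of full length). The TRI of a polyp is the
# length-weighted tentacle count relative to the physiological maximum of 8
# tentacles: 0 = nothing regenerated, 1 = regeneration complete.

#' TRI class weights
#'
#' The five relative length classes and their weights. By default the weight
#' of a class equals its nominal relative length, so the TRI reads as the
#' average tentacle length per polyp relative to the maximum; alternative
#' weights support sensitivity analysis.
#'
#' @param class_lengths the 5 nominal relative lengths (strictly
#'   increasing, in (0, 1]).
#' @param p_k weight per class; defaults to `class_lengths`.
#' @param n_max maximal tentacle count of a single polyp under
#'   physiological conditions (default 8).
#' @return list of class `tri_weights`.
#' @export
tri_weights <- function(class_lengths = c(1/8, 1/4, 1/2, 3/4, 1),
                        p_k = class_lengths, n_max = 8) {
  if (length(class_lengths) != 5 || length(p_k) != 5)
    stop("exactly 5 length classes are defined")
  if (any(diff(p_k) <= 0)) stop("class weights must be strictly increasing")
  if (n_max < 1) stop("n_max must be >= 1")
  structure(list(class_lengths = class_lengths, p_k = p_k, n_max = n_max),
            class = "tri_weights")
}

#' Assign a relative tentacle length to its class
#'
#' Returns the class whose nominal length is nearest to the measured
#' relative length; an exact midpoint between two classes goes to the lower
#' class.
#'
#' @param relative_length fraction(s) in (0, 1] of full tentacle length.
#' @param weights a [tri_weights()].
#' @return integer class index (1..5), vectorised.
#' @export
length_class <- function(relative_length, weights = tri_weights()) {
  if (any(relative_length <= 0 | relative_length > 1))
    stop("relative_length must lie in (0, 1]")
  vapply(relative_length, function(l) {
    d <- abs(l - weights$class_lengths)
    which.min(d)  # which.min takes the first (lower) class on exact ties
  }, integer(1))
}

#' Tentacle regeneration index of one polyp
#'
#' \deqn{R = \sum_{K=1}^{5} p_K\, n_K / n_{max}} where \eqn{n_K} is the
#' tentacle count in length class K. With more than `n_max` tentacles the
#' index may exceed 1; it is reported with a warning, not clamped, since
#' `n_max` is a physiological reference, not an algebraic bound.
#'
#' @param counts 5 non-negative integers, tentacles per length class.
#' @param weights a [tri_weights()].
#' @return The TRI value.
#' @examples
#' tri(c(0, 0, 0, 0, 8))   # regeneration complete -> 1
#' tri(c(2, 0, 2, 0, 4))
#' @export
tri <- function(counts, weights = tri_weights()) {
  if (length(counts) != 5 || any(counts < 0))
    stop("counts must be 5 non-negative values")
  if (sum(counts) > weights$n_max)
    warning(sprintf("total tentacle count %d exceeds n_max = %d; TRI may exceed 1",
                    sum(counts), weights$n_max))
  sum(weights$p_k * counts) / weights$n_max
}

#' Per-polyp TRI regeneration profiles
#'
#' @param tentacles a validated `tentacles` data frame (see [load_table()]).
#' @param weights a [tri_weights()].
#' @return data frame `polyp_id, label, day, tri`, sorted by polyp and day.
#' @export
tri_profiles <- function(tentacles, weights = tri_weights()) {
  cls <- paste0("c", 1:5)
  out <- tentacles[, c("polyp_id", "label", "day")]
  out$tri <- apply(as.matrix(tentacles[, cls]), 1, tri, weights = weights)
  out[order(out$label, out$polyp_id, out$day), , drop = FALSE]
}

#' Group mean TRI at one observation day
#'
#' @param profiles data frame from [tri_profiles()] (one group).
#' @param day observation day; every polyp must have a value at it.
#' @return list with `mean`, `sd` (sample SD), `n`.
#' @export
mean_tri <- function(profiles, day) {
  ids <- unique(profiles$polyp_id)
  if (length(ids) == 0) stop("empty group")
  vals <- vapply(ids, function(id) {
    v <- profiles$tri[profiles$polyp_id == id & profiles$day == day]
    if (length(v) == 0)
      stop(sprintf("polyp '%s' has no TRI value at day %g", id, day))
    v[1]
  }, numeric(1))
  list(mean = mean(vals), sd = stats::sd(vals), n = length(vals))
}

#' Group mean TRI profile over all observed days
#'
#' @inheritParams mean_tri
#' @return data frame `day, mean_tri, sd, n`.
#' @export
mean_tri_profile <- function(profiles) {
  days <- sort(unique(profiles$day))
  do.call(rbind, lapply(days, function(d) {
    s <- mean_tri(profiles, d)
    data.frame(day = d, mean_tri = s$mean, sd = s$sd, n = s$n)
  }))
}

#' Compare TRI values between two treatment groups
#'
#' Unpaired two-sample t-test, pooled-variance by default (Welch by flag),
#' two-sided. Two groups with zero variance and equal means return `t = 0`,
#' `p = 1` by convention.
#'
#' @param groupA,groupB numeric vectors of TRI values (each `n >= 2`).
#' @param var_equal `TRUE` for the pooled-variance test (default), `FALSE`
#'   for Welch.
#' @return list with `t`, `df`, `p_value`, `mean_diff`.
#' @export
compare_tri <- function(groupA, groupB, var_equal = TRUE) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs n >= 2")
  if (stats::var(groupA) == 0 && stats::var(groupB) == 0) {
    if (mean(groupA) == mean(groupB))
      return(list(t = 0, df = length(groupA) + length(groupB) - 2,
                  p_value = 1, mean_diff = 0))
    return(list(t = sign(mean(groupA) - mean(groupB)) * Inf,
                df = length(groupA) + length(groupB) - 2,
                p_value = 0, mean_diff = mean(groupA) - mean(groupB)))
  }
  tt <- stats::t.test(groupA, groupB, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = mean(groupA) - mean(groupB))
}

#' Day-by-day TRI comparison of two groups
#'
#' Runs [compare_tri()] at every shared observation day and reports raw and
#' Holm-adjusted p-values.
#'
#' @param profilesA,profilesB per-polyp TRI profiles of the two groups
#'   ([tri_profiles()] output).
#' @param var_equal passed to [compare_tri()].
#' @return data frame `day, t, df, p_value, p_holm, mean_diff`.
#' @export
compare_tri_profiles <- function(profilesA, profilesB, var_equal = TRUE) {
  days <- intersect(unique(profilesA$day), unique(profilesB$day))
  days <- sort(days)
  rows <- lapply(days, function(d) {
    a <- profilesA$tri[profilesA$day == d]
    b <- profilesB$tri[profilesB$day == d]
    r <- compare_tri(a, b, var_equal)
    data.frame(day = d, t = r$t, df = r$df, p_value = r$p_value,
               mean_diff = r$mean_diff)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out[, c("day", "t", "df", "p_value", "p_holm", "mean_diff")]
}
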