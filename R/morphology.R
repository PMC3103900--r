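# Ordinal morphology (Wilby) score summaries, death classification and the
# Friedman rank test used to compare median scores across concentrations.
#
# Scores run 1..10 (10 = fully extended healthy polyp). Because Hydra can
# recover from sublethal damage, death is classified per observation time
# from the score at that time, never latched across times.

#' Median morphology score in one (dose, time) cell
#'
#' @param scores a validated `scores` data frame (see [load_table()]).
#' @param dose concentration in nM.
#' @param time observation time in hours.
#' @return list with `median` (midpoint convention for even n) and `n`.
#' @export
median_score <- function(scores, dose, time) {
  s <- scores$score[scores$dose_nM == dose & scores$time_hr == time]
  if (length(s) == 0)
    stop(sprintf("no score records at dose %g nM, time %g hr", dose, time))
  list(median = stats::median(s), n = length(s))
}

#' Classify death from an ordinal morphology score
#'
#' An animal is considered dead when its score is strictly lower than the
#' threshold (default 4): at or above the threshold the damage is regarded
#' as recoverable.
#'
#' @param score integer score(s) in 1..10.
#' @param threshold death threshold (default 4).
#' @return logical vector, `TRUE` for dead.
#' @export
is_dead <- function(score, threshold = 4) {
  if (any(score < 1 | score > 10)) stop("scores must lie in 1..10")
  score < threshold
}

#' Derive a quantal mortality series from morphology scores
#'
#' Counts, per dose at one observation time, the animals scored and the
#' animals classified dead under the score threshold, yielding the quantal
#' table that feeds LC50 estimation.
#'
#' @inheritParams median_score
#' @param time observation time in hours.
#' @param threshold death threshold passed to [is_dead()].
#' @param label label for the resulting series; defaults to the label of the
#'   first matching record.
#' @return A [quantal_series()] on the dose axis.
#' @export
quantal_from_scores <- function(scores, time, threshold = 4, label = NULL) {
  s <- scores[scores$time_hr == time, , drop = FALSE]
  if (nrow(s) == 0) stop(sprintf("no score records at time %g hr", time))
  doses <- sort(unique(s$dose_nM))
  doses <- doses[doses > 0]
  if (length(doses) < 2)
    stop("need records at >= 2 positive doses to build a quantal series")
  n_exposed <- vapply(doses, function(d) sum(s$dose_nM == d), integer(1))
  n_dead <- vapply(doses, function(d)
    sum(is_dead(s$score[s$dose_nM == d], threshold)), integer(1))
  if (is.null(label)) label <- s$label[1]
  quantal_series(doses, n_exposed, n_dead, axis = "dose", label = label)
}

#' Friedman rank test on a block-by-treatment table
#'
#' Rank-based test that k treatments share a location, with observations
#' blocked (here: median scores per concentration, blocked by observation
#' time). Within-block ties receive mid-ranks and the statistic carries the
#' standard tie correction:
#' \deqn{\chi^2_F = (k-1)\sum_j (R_j - b(k+1)/2)^2 \Big/
#'       \left(\sum_{ij} r_{ij}^2 - bk(k+1)^2/4\right)}
#' which reduces to \eqn{12\sum R_j^2/(bk(k+1)) - 3b(k+1)} without ties.
#' The p-value comes from the chi-square distribution with k-1 degrees of
#' freedom; for small designs (`b*k <= 12` by default) an exact permutation
#' p-value is also computed by enumerating all within-block orderings.
#'
#' @param x numeric matrix, blocks in rows and treatments in columns, one
#'   aggregate observation per cell. `NA` cells are rejected (the design
#'   must be complete).
#' @param exact logical; force (`TRUE`) or suppress (`FALSE`) exact
#'   permutation. Default `NULL`: exact when `b*k <= 12`.
#' @return list of class `friedman_rank_test`: `statistic`, `df`, `p_value`,
#'   `p_exact` (or `NULL`), `ranks` (mid-rank matrix), `b`, `k`.
#' @export
friedman_rank_test <- function(x, exact = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop(sprintf("incomplete design: missing cell at block %d, treatment %d",
                 idx[1], idx[2]))
  }
  b <- nrow(x); k <- ncol(x)
  if (k < 2) stop("need at least 2 treatments")
  if (b < 2) stop("need at least 2 blocks")
  r <- t(apply(x, 1, rank))
  stat <- .friedman_stat(r, b, k)
  df <- k - 1
  p_asym <- stats::pchisq(stat, df, lower.tail = FALSE)
  if (is.null(exact)) exact <- (b * k <= 12)
  p_exact <- if (exact) .friedman_exact_p(r, stat) else NULL
  structure(list(statistic = stat, df = df, p_value = p_asym,
                 p_exact = p_exact, ranks = r, b = b, k = k),
            class = "friedman_rank_test")
}

# tie-corrected Friedman statistic from a mid-rank matrix
.friedman_stat <- function(r, b, k) {
  Rj <- colSums(r)
  denom <- sum(r^2) - b * k * (k + 1)^2 / 4
  if (denom <= .Machine$double.eps) return(0)  # all tied in every block
  (k - 1) * sum((Rj - b * (k + 1) / 2)^2) / denom
}

# exact permutation p-value: permute observations within each block; with
# ties this enumerates the k! equally likely orderings of the block's
# mid-rank vector.
.friedman_exact_p <- function(r, observed) {
  b <- nrow(r); k <- ncol(r)
  perms <- .permutations(k)          # k! x k index matrix
  P <- nrow(perms)
  if (P^b > 2e6) stop("exact permutation infeasible for this design size")
  # accumulate the column-sum distribution block by block: after block i the
  # matrix holds the rank sums of all P^i joint within-block orderings
  sums <- matrix(r[1, ][perms], nrow = P)   # P x k
  for (i in seq_len(b)[-1]) {
    blk <- matrix(r[i, ][perms], nrow = P)
    n0 <- nrow(sums)
    sums <- sums[rep(seq_len(n0), times = P), , drop = FALSE] +
      blk[rep(seq_len(P), each = n0), , drop = FALSE]
  }
  denom <- sum(r^2) - b * k * (k + 1)^2 / 4
  if (denom <= .Machine$double.eps) return(1)
  stats_all <- (k - 1) *
    rowSums((sums - b * (k + 1) / 2)^2) / denom
  mean(stats_all >= observed - 1e-12)
}

# all permutations of 1..k as a k! x k matrix
.permutations <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(k - 1)
  do.call(rbind, lapply(seq_len(k), function(first) {
    rest <- setdiff(seq_len(k), first)
    cbind(first, matrix(rest[sub], nrow(sub)))
  }))
}

#' @export
print.friedman_rank_test <- function(x, ...) {
  cat(sprintf("Friedman rank test: chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  if (!is.null(x$p_exact))
    cat(sprintf("  exact permutation p = %.4g (%d blocks x %d treatments)\n",
                x$p_exact, x$b, x$k))
  invisible(x)
}

#' Friedman comparison of median scores across concentrations
#'
#' Builds the block-by-treatment table of cell medians from a scores data
#' frame — blocks default to observation times, treatments to
#' concentrations — and runs [friedman_rank_test()].
#'
#' @inheritParams median_score
#' @param blocks column name giving the blocking factor (default
#'   `"time_hr"`).
#' @param treatments column name giving the treatment factor (default
#'   `"dose_nM"`).
#' @param exact passed to [friedman_rank_test()].
#' @return A `friedman_rank_test` object with the cell-median table attached
#'   as `$table`.
#' @export
friedman_scores <- function(scores, blocks = "time_hr",
                            treatments = "dose_nM", exact = NULL) {
  bvals <- sort(unique(scores[[blocks]]))
  tvals <- sort(unique(scores[[treatments]]))
  if (length(tvals) < 2) stop("need at least 2 treatment levels")
  tab <- matrix(NA_real_, length(bvals), length(tvals),
                dimnames = list(as.character(bvals), as.character(tvals)))
  for (i in seq_along(bvals)) for (j in seq_along(tvals)) {
    s <- scores$score[scores[[blocks]] == bvals[i] &
                        scores[[treatments]] == tvals[j]]
    if (length(s) == 0)
      stop(sprintf("incomplete design: no scores for %s = %s, %s = %s",
                   blocks, bvals[i], treatments, tvals[j]))
    tab[i, j] <- stats::median(s)
  }
  out <- friedman_rank_test(tab, exact = exact)
  out$table <- tab
  out
}
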