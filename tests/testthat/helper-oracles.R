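# Independent oracles used to check the estimators against brute force.
# These deliberately share no code with the package implementation.

# Exhaustive weighted isotonic regression: enumerate every partition of the
# sequence into contiguous blocks, set each block to its weighted mean,
# keep monotone candidates, return the one minimising weighted SSE.
oracle_isotonic <- function(y, w) {
  n <- length(y)
  best <- NULL
  best_sse <- Inf
  # each of the 2^(n-1) cut patterns defines a contiguous partition
  for (code in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(code, 2^(0:(n - 2))) > 0)
    bounds <- c(0, cuts, n)
    fit <- numeric(n)
    ok <- TRUE
    prev <- -Inf
    for (b in seq_len(length(bounds) - 1)) {
      idx <- (bounds[b] + 1):bounds[b + 1]
      m <- sum(w[idx] * y[idx]) / sum(w[idx])
      if (m < prev - 1e-12) { ok <- FALSE; break }
      fit[idx] <- m
      prev <- m
    }
    if (!ok) next
    sse <- sum(w * (y - fit)^2)
    if (sse < best_sse - 1e-12) { best_sse <- sse; best <- fit }
  }
  best
}

# Independent Friedman machinery: mid-ranks, tie-corrected statistic, and
# the exact permutation distribution by explicit nested enumeration.
oracle_friedman_stat <- function(x) {
  b <- nrow(x); k <- ncol(x)
  r <- t(apply(x, 1, rank))
  denom <- sum(r^2) - b * k * (k + 1)^2 / 4
  if (denom <= 1e-12) return(0)
  (k - 1) * sum((colSums(r) - b * (k + 1) / 2)^2) / denom
}

oracle_perms <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (p in oracle_perms(k - 1)) for (pos in seq_len(k)) {
    out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  }
  out
}

oracle_friedman_exact_p <- function(x) {
  b <- nrow(x); k <- ncol(x)
  observed <- oracle_friedman_stat(x)
  perms <- oracle_perms(k)
  # walk the full product space of within-block orderings
  count <- 0L; total <- 0L
  idx <- rep(1L, b)
  repeat {
    xp <- x
    for (i in seq_len(b)) xp[i, ] <- x[i, perms[[idx[i]]]]
    if (oracle_friedman_stat(xp) >= observed - 1e-12) count <- count + 1L
    total <- total + 1L
    pos <- b
    while (pos >= 1) {
      idx[pos] <- idx[pos] + 1L
      if (idx[pos] <= length(perms)) break
      idx[pos] <- 1L
      pos <- pos - 1L
    }
    if (pos < 1) break
  }
  count / total
}

# Trapezoid rule without package code (checks the summation-by-parts
# identity for the Spearman-Karber median).
oracle_trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

# random monotone quantal curve spanning 0..1 on a log axis
random_monotone_curve <- function(n_groups) {
  x <- sort(stats::runif(n_groups, 0, 3))
  while (any(diff(x) < 1e-3)) x <- sort(stats::runif(n_groups, 0, 3))
  p <- sort(stats::runif(n_groups))
  p[1] <- 0; p[n_groups] <- 1
  structure(list(x = x, p_raw = p, p_adj = p,
                 n = rep(20L, n_groups), axis = "dose", label = "rnd"),
            class = "smoothed_curve")
}
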