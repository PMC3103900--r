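# Trimmed Spearman-Karber: smoothing, trimming, median, variance.

curve_from <- function(x, p, n = rep(20L, length(x)), axis = "dose") {
  structure(list(x = x, p_raw = p, p_adj = p, n = n, axis = axis,
                 label = ""), class = "smoothed_curve")
}

test_that("weighted PAVA matches the frozen pooled solutions", {
  expect_equal(pava(c(0, .6, .4, 1)), c(0, .5, .5, 1))
  expect_equal(pava(c(.6, .2), c(10, 30)), c(.3, .3))   # (6+6)/40
  p <- c(0, .1, .4, .9, 1)
  expect_equal(pava(p), p)                              # monotone unchanged
})

test_that("PAVA is idempotent and conserves pooled weighted means", {
  set.seed(3)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    y <- runif(n); w <- sample(5:40, n, replace = TRUE)
    fit <- pava(y, w)
    expect_true(all(diff(fit) >= -1e-12))
    expect_equal(pava(fit, w), fit, tolerance = 1e-12)
    # block-wise weighted mean conservation: same overall weighted mean
    expect_equal(sum(w * fit), sum(w * y), tolerance = 1e-9)
  }
})

test_that("PAVA equals exhaustive search over monotone pooled solutions", {
  set.seed(5)
  for (i in 1:100) {
    n <- sample(2:6, 1)
    y <- round(runif(n), 2)
    w <- sample(c(5, 10, 20, 40), n, replace = TRUE)
    expect_equal(pava(y, w), oracle_isotonic(y, w), tolerance = 1e-9)
  }
})

test_that("smooth_monotone leaves monotone series unchanged", {
  qs <- quantal_series(c(50, 100, 200, 400), rep(20, 4), c(0, 4, 16, 20))
  sm <- smooth_monotone(qs)
  expect_equal(sm$p_adj, sm$p_raw)
  expect_equal(sm$x, log10(c(50, 100, 200, 400)))
})

test_that("trimming rescales and interpolates crossing endpoints", {
  cv <- curve_from(c(1, 2, 3), c(0, .5, 1))
  expect_identical(trim_curve(cv, 0), cv)               # identity trim
  tr <- trim_curve(cv, 0.1)
  expect_equal(tr$x, c(1.2, 2, 2.8))
  expect_equal(tr$p_adj, c(0, .5, 1))
  shallow <- curve_from(c(1, 2), c(0, .3))
  expect_error(sk_log_median(shallow), "not estimable")
  expect_error(trim_curve(curve_from(c(1, 2), c(.2, .3)), 0.1),
               "cannot trim")
})

test_that("the log median reproduces the frozen worked examples", {
  cv <- smooth_monotone(quantal_series(c(50, 100, 200, 400), rep(20, 4),
                                       c(0, 4, 16, 20)))
  m <- sk_log_median(cv)
  expect_equal(m, 2.150515, tolerance = 1e-6)
  expect_equal(10^m, sqrt(100 * 200), tolerance = 1e-6)  # geometric mean
  cv2 <- curve_from(log10(c(1, 2)), c(0, 1))
  expect_equal(10^sk_log_median(cv2), sqrt(2), tolerance = 1e-12)
  cv3 <- smooth_monotone(quantal_series(c(12, 24, 48, 72), rep(20, 4),
                                        c(0, 5, 15, 20), axis = "time"))
  expect_equal(sk_log_median(cv3), 1.51511, tolerance = 1e-5)
  expect_equal(10^sk_log_median(cv3), 32.7, tolerance = 2e-3)
})

test_that("median equals the summation-by-parts trapezoid identity", {
  set.seed(31)
  for (i in 1:200) {
    cv <- random_monotone_curve(sample(3:8, 1))
    m <- sk_log_median(cv)
    ident <- cv$x[length(cv$x)] - oracle_trapz(cv$x, cv$p_adj)
    expect_equal(m, ident, tolerance = 1e-9)
  }
})

test_that("variance and CI match the frozen delta-method example", {
  cv <- smooth_monotone(quantal_series(c(50, 100, 200, 400), rep(20, 4),
                                       c(0, 4, 16, 20)))
  m <- sk_log_median(cv)
  ci <- sk_confidence(cv, m, 0.95)
  expect_equal(ci$variance, 0.0015262, tolerance = 1e-4)
  expect_equal(ci$ci_low, 118.6, tolerance = 1e-3)
  expect_equal(ci$ci_high, 168.7, tolerance = 1e-3)
  # degenerate step curve: V = 0, CI collapses to the point
  step <- curve_from(log10(c(50, 100)), c(0, 1))
  ms <- sk_log_median(step)
  cs <- sk_confidence(step, ms)
  expect_equal(cs$variance, 0)
  expect_equal(cs$ci_low, cs$ci_high)
  expect_equal(cs$ci_low, 10^ms)
  # doubling n halves V up to the (n-1) correction
  cv40 <- smooth_monotone(quantal_series(c(50, 100, 200, 400), rep(40, 4),
                                         c(0, 8, 32, 40)))
  ci40 <- sk_confidence(cv40, sk_log_median(cv40))
  expect_equal(ci40$variance / ci$variance, 19 / 39, tolerance = 1e-9)
  expect_error(sk_confidence(curve_from(log10(c(1, 2, 4)), c(0, .5, 1),
                                        n = c(20, 1, 20)), 0.3),
               "n < 2")
})

test_that("estimate_lc50 composes the stages and reports parameters", {
  qs <- quantal_series(c(50, 100, 200, 400), rep(20, 4), c(0, 4, 16, 20))
  cfg <- run_config()
  est <- estimate_lc50(qs, cfg)
  cv <- smooth_monotone(qs)
  m <- sk_log_median(trim_curve(cv, 0))
  ci <- sk_confidence(trim_curve(cv, 0), m, 0.95)
  expect_true(est$estimable)
  expect_equal(est$m, m)
  expect_equal(est$point, 10^m)
  expect_equal(est$ci_low, ci$ci_low)
  expect_true(est$ci_low <= est$point && est$point <= est$ci_high)
  expect_equal(est$trim, 0)
})

test_that("all-zero or partial mortality is not estimable by default", {
  none <- quantal_series(c(50, 100, 200), rep(20, 3), c(0, 0, 0))
  est <- estimate_lc50(none, run_config())
  expect_false(est$estimable)
  expect_true(is.na(est$point))
  partial <- quantal_series(c(50, 100, 200), rep(20, 3), c(0, 2, 6))
  expect_false(estimate_lc50(partial, run_config())$estimable)
  # with the endpoint extension the same curve becomes estimable
  ext <- estimate_lc50(partial, run_config(extend = TRUE))
  expect_true(ext$estimable)
  expect_gt(ext$point, 200)   # median beyond the highest tested dose
})

test_that("dose-scale equivariance: scaling doses scales the LC50", {
  qs1 <- quantal_series(c(50, 100, 200, 400), rep(20, 4), c(0, 4, 16, 20))
  qs2 <- quantal_series(c(50, 100, 200, 400) * 7.5, rep(20, 4),
                        c(0, 4, 16, 20))
  e1 <- estimate_lc50(qs1, run_config())
  e2 <- estimate_lc50(qs2, run_config())
  expect_equal(e2$point, 7.5 * e1$point, tolerance = 1e-9)
  expect_equal(e2$variance, e1$variance, tolerance = 1e-9)
})

test_that("LT50 runs the identical algorithm on log10 time", {
  qs <- quantal_series(c(12, 24, 48, 72), rep(20, 4), c(0, 5, 15, 20),
                       axis = "time")
  est <- estimate_lt50(qs, run_config())
  expect_equal(est$point, 32.74, tolerance = 1e-3)
  expect_error(estimate_lt50(quantal_series(c(1, 2), c(5, 5), c(0, 5)),
                             run_config()),
               "axis")
  # mortality complete at the first observation cannot be bracketed
  early <- quantal_series(c(24, 48), c(20, 20), c(20, 20), axis = "time")
  expect_false(estimate_lt50(early, run_config())$estimable)
})

test_that("trimmed estimate is close to untrimmed on a clean curve", {
  qs <- quantal_series(c(50, 100, 200, 400, 800), rep(20, 5),
                       c(0, 2, 10, 18, 20))
  e0 <- estimate_lc50(qs, run_config(trim = 0))
  e1 <- estimate_lc50(qs, run_config(trim = 0.1))
  expect_true(e1$estimable)
  expect_equal(e1$m, e0$m, tolerance = 0.05)
})
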