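# Synthetic bioassay generators: determinism, model structure, and
# cross-consistency between the score and lifetime processes.

tol233 <- function() tolerance_model(lc50 = 233, hill = 3)
hz_default <- function() hazard_model(lt50_ref = 36, dose_ref = 300,
                                      dose_exponent = 0.8, shape = 4)

test_that("tolerance models put exactly half the deaths at the median", {
  expect_equal(tolerance_p(233, tol233()), 0.5)
  expect_equal(tolerance_p(233, tolerance_model(233, 2, "probit")), 0.5)
  steep <- tolerance_model(233, 400)
  expect_lt(tolerance_p(220, steep), 1e-6)     # near-step response
  expect_gt(tolerance_p(245, steep), 1 - 1e-6)
  expect_equal(tolerance_p(0, tol233()), 0)
  expect_error(tolerance_model(-1, 3), "lc50")
  expect_error(tolerance_model(233, 0), "hill")
})

test_that("generators are pure functions of parameters and seed", {
  a <- sim_quantal(c(50, 100, 400), 20, tol233(), seed = 99)
  b <- sim_quantal(c(50, 100, 400), 20, tol233(), seed = 99)
  expect_identical(a, b)
  c <- sim_quantal(c(50, 100, 400), 20, tol233(), seed = 100)
  expect_false(identical(a$groups$n_dead, c$groups$n_dead))
  r1 <- sim_regeneration(4, 0:14, regen_model(), seed = 5)
  r2 <- sim_regeneration(4, 0:14, regen_model(), seed = 5)
  expect_identical(r1, r2)
  p1 <- sim_population(budding_model(0.3), 14, seed = 5)
  expect_identical(p1, sim_population(budding_model(0.3), 14, seed = 5))
  # generators do not disturb the global RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(sim_quantal(c(50, 100), 20, tol233(), seed = 2))
  expect_equal(runif(1), before)
})

test_that("lifetime medians follow the dose power law", {
  hz <- hz_default()
  expect_equal(median_lifetime(300, hz), 36)
  expect_equal(median_lifetime(600, hz), 36 * 2^(-0.8))
  expect_equal(median_lifetime(0, hz), Inf)
  expect_equal(hazard_lc50_at(36, hz), 300)
  # empirical median at the reference dose approaches lt50_ref
  tc <- sim_timecourse(300, c(1, 36, 1000), 4000, hz, seed = 7)
  expect_equal(median(tc$lifetimes), 36, tolerance = 0.1)
})

test_that("timecourse marginals are consistent and cumulative", {
  tc <- sim_timecourse(c(100, 300, 900), c(12, 24, 48, 72), 20,
                       hz_default(), seed = 11)
  for (qs in tc$per_dose)
    expect_true(all(diff(qs$groups$n_dead) >= 0))   # cumulative in time
  # same animals: per-time and per-dose tables agree cell by cell
  for (i in seq_along(tc$times)) for (j in seq_along(tc$doses)) {
    expect_equal(tc$per_time[[i]]$groups$n_dead[j],
                 tc$per_dose[[j]]$groups$n_dead[i])
  }
  # stochastically shorter lifetimes at higher dose
  expect_lt(median(tc$lifetimes[, 3]), median(tc$lifetimes[, 1]))
})

test_that("score panels are consistent with the latent lifetimes", {
  doses <- c(100, 300, 900)
  times <- c(12, 24, 48, 72)
  tc <- sim_timecourse(doses, times, 20, hz_default(), seed = 13)
  panel <- sim_scores(doses, times, 20, hz_default(), seed = 13)
  for (t in times) {
    qs <- quantal_from_scores(panel, t, threshold = 4)
    dead_true <- colSums(tc$lifetimes <= t)
    expect_equal(qs$groups$n_dead, as.integer(dead_true))
  }
  # untreated controls keep a median score of 10 at all times
  ctrl <- sim_scores(c(0, 300), times, 20, hz_default(), seed = 17)
  for (t in times)
    expect_equal(median_score(ctrl, 0, t)$median, 10)
  expect_true(all(ctrl$score >= 1 & ctrl$score <= 10))
})

test_that("median scores decline with dose in expectation", {
  doses <- c(50, 300, 900)
  meds <- rowMeans(sapply(1:50, function(s) {
    panel <- sim_scores(doses, 48, 20, hz_default(), seed = s)
    vapply(doses, function(d) median_score(panel, d, 48)$median, numeric(1))
  }))
  expect_true(all(diff(meds) < 0))
})

test_that("regeneration starts bare and treatment delays early TRI", {
  ctrl <- sim_regeneration(4, c(0, 3, 14), regen_model(), seed = 19,
                           label = "c")
  expect_true(all(ctrl[ctrl$day == 0, paste0("c", 1:5)] == 0))
  # delay_factor = 1 is exactly the control distribution
  same <- sim_regeneration(4, c(0, 3, 14), regen_model(delay_factor = 1),
                           seed = 19, label = "c")
  expect_identical(ctrl, same)
  lower <- replicate(60, {
    s <- sample.int(1e6, 1)
    a <- sim_regeneration(4, 3, regen_model(), seed = s)
    b <- sim_regeneration(4, 3, regen_model(delay_factor = 2), seed = s + 1)
    mean(tri_profiles(b)$tri) <= mean(tri_profiles(a)$tri)
  })
  expect_gt(mean(lower), 0.9)
})

test_that("budding schemes grow as n0 exp(k t)", {
  det <- sim_population(budding_model(0.25, scheme = "deterministic-rounded"),
                        30, seed = 1)
  f <- fit_growth(log_ratio_series(det$day, det$n))
  expect_equal(f$k, 0.25, tolerance = 0.05 * 0.25)  # rounding error only
  zero <- sim_population(budding_model(0, scheme = "birth-process"), 10,
                         seed = 1)
  expect_true(all(zero$n == 4))
  # Yule process expectation at day 10
  counts <- vapply(1:300, function(s)
    sim_population(budding_model(0.2), 10, seed = s)$n[11], numeric(1))
  expected <- 4 * exp(0.2 * 10)
  se <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
  expect_true(all(diff(sim_population(budding_model(0.4), 12,
                                      seed = 3)$n) >= 0))
})

test_that("scenario files drive a full consistent simulation", {
  sc <- read_scenario(system.file("extdata", "scenario_tga_qd.yaml",
                                  package = "hydratox"))
  expect_equal(sc$label, "TGA-QDs")
  expect_equal(sc$lt50_ref, 36)
  out <- withr::local_tempdir()
  sim <- simulate_scenario(sc, seed = 123, outdir = out)
  for (f in c("quantal.csv", "scores.csv", "tentacles.csv",
              "population.csv"))
    expect_true(file.exists(file.path(out, f)))
  q <- load_table(file.path(out, "quantal.csv"), "quantal")
  expect_setequal(unique(q$axis), c("dose", "time"))
  # scores and the quantal table derive from the same lifetimes
  s <- load_table(file.path(out, "scores.csv"), "scores")
  qs <- quantal_from_scores(s, 48)
  ref <- q[q$axis == "dose" & q$time_hr == 48, ]
  expect_equal(qs$groups$n_dead, ref$n_dead)
})
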