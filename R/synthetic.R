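# Synthetic bioassay generator with known ground truth.
#
# Emulates the statistical structure the analyses assume: binomial quantal
# mortality from a smooth tolerance distribution, dose-dependent
# log-logistic lifetimes (so LC50 falls with observation time and LT50
# falls with dose), ordinal score decay tied to the latent lifetimes,
# stochastic tentacle emergence/elongation, and budding population growth.
# Every generator is a pure function of (parameters, seed).

#' Tolerance distribution for quantal mortality at a fixed time
#'
#' @param lc50 true median lethal concentration (nM, > 0).
#' @param hill slope parameter (> 0) on the log-concentration scale.
#' @param form `"log-logistic"` (default) or `"probit"`; both have median
#'   exactly `lc50`.
#' @return list of class `tolerance_model`.
#' @export
tolerance_model <- function(lc50, hill, form = c("log-logistic", "probit")) {
  form <- match.arg(form)
  if (lc50 <= 0) stop("lc50 must be > 0")
  if (hill <= 0) stop("hill must be > 0")
  structure(list(lc50 = lc50, hill = hill, form = form),
            class = "tolerance_model")
}

#' Death probability under a tolerance model
#'
#' Log-logistic: `p(d) = 1/(1 + (lc50/d)^hill)`; probit:
#' `p(d) = pnorm(hill * log10(d/lc50))`. Both give `p(lc50) = 0.5` exactly.
#'
#' @param dose concentration(s) in nM (>= 0; dose 0 has p = 0).
#' @param model a [tolerance_model()].
#' @return death probabilities.
#' @export
tolerance_p <- function(dose, model) {
  ifelse(dose <= 0, 0,
         switch(model$form,
                "log-logistic" = 1 / (1 + (model$lc50 / dose)^model$hill),
                "probit" = stats::pnorm(model$hill *
                                          log10(dose / model$lc50))))
}

#' Dose-dependent lifetime model
#'
#' Individual lifetimes are log-logistic with shape `shape` and a median
#' that decreases with dose as a power law:
#' `median(d) = lt50_ref * (d / dose_ref)^(-dose_exponent)`. Dose 0 gives an
#' infinite median (controls never die).
#'
#' @param lt50_ref median lifetime (hr) at the reference dose.
#' @param dose_ref reference concentration (nM).
#' @param dose_exponent power-law exponent gamma > 0.
#' @param shape log-logistic shape (> 0); larger = steeper mortality in
#'   time.
#' @return list of class `hazard_model`.
#' @export
hazard_model <- function(lt50_ref, dose_ref, dose_exponent, shape = 4) {
  if (lt50_ref <= 0 || dose_ref <= 0) stop("reference values must be > 0")
  if (dose_exponent <= 0) stop("dose_exponent must be > 0")
  if (shape <= 0) stop("shape must be > 0")
  structure(list(lt50_ref = lt50_ref, dose_ref = dose_ref,
                 dose_exponent = dose_exponent, shape = shape),
            class = "hazard_model")
}

#' Median lifetime at given doses
#' @param dose concentration(s) in nM.
#' @param model a [hazard_model()].
#' @return median lifetimes in hours (`Inf` at dose 0).
#' @export
median_lifetime <- function(dose, model) {
  ifelse(dose <= 0, Inf,
         model$lt50_ref * (dose / model$dose_ref)^(-model$dose_exponent))
}

#' True LC50 at a given observation time under a hazard model
#'
#' The dose at which half the animals have died by time `t`, i.e. the dose
#' whose median lifetime equals `t`:
#' `lc50(t) = dose_ref * (t / lt50_ref)^(-1/dose_exponent)`.
#'
#' @param time observation time(s) in hours.
#' @param model a [hazard_model()].
#' @return concentrations in nM.
#' @export
hazard_lc50_at <- function(time, model) {
  model$dose_ref * (time / model$lt50_ref)^(-1 / model$dose_exponent)
}

# lifetimes matrix (n_per_group x doses) drawn from the hazard model; the
# draw order is fixed so generators sharing a seed share lifetimes
.draw_lifetimes <- function(doses, n_per_group, model) {
  med <- median_lifetime(doses, model)
  L <- matrix(0, n_per_group, length(doses))
  for (j in seq_along(doses)) {
    u <- stats::runif(n_per_group)
    L[, j] <- med[j] * (u / (1 - u))^(1 / model$shape)
  }
  L
}

#' Simulate a quantal mortality assay at one observation time
#'
#' Per dose group, `n_dead ~ Binomial(n_per_group, p(dose))` under the
#' tolerance model.
#'
#' @param doses concentrations in nM (> 0).
#' @param n_per_group animals per dose group.
#' @param model a [tolerance_model()].
#' @param seed integer seed; the same seed reproduces the series exactly.
#' @param label series label.
#' @return A dose-axis [quantal_series()].
#' @export
sim_quantal <- function(doses, n_per_group, model, seed, label = "sim") {
  stopifnot(inherits(model, "tolerance_model"), all(doses > 0),
            n_per_group >= 1)
  withr::with_seed(seed, {
    p <- tolerance_p(doses, model)
    dead <- stats::rbinom(length(doses), n_per_group, p)
    quantal_series(doses, rep(n_per_group, length(doses)), dead,
                   axis = "dose", label = label)
  })
}

#' Simulate a joint dose-by-time mortality experiment
#'
#' Each animal draws one latent lifetime from the dose-dependent
#' log-logistic; cumulative dead counts are tallied at each observation
#' time. The per-time dose series and per-dose time series are marginals of
#' the same animals, so they are mutually consistent and cumulative counts
#' never decrease.
#'
#' @param doses concentrations in nM (> 0).
#' @param times increasing observation times in hours.
#' @param n_per_group animals per dose group.
#' @param model a [hazard_model()].
#' @param seed integer seed.
#' @param label series label.
#' @return list with `per_time` (one dose-axis [quantal_series()] per
#'   observation time), `per_dose` (one cumulative time-axis series per
#'   dose), and the latent `lifetimes` matrix (animals x doses).
#' @export
sim_timecourse <- function(doses, times, n_per_group, model, seed,
                           label = "sim") {
  stopifnot(inherits(model, "hazard_model"), all(doses > 0),
            all(diff(times) > 0), n_per_group >= 1)
  L <- withr::with_seed(seed, .draw_lifetimes(doses, n_per_group, model))
  dead_at <- function(t) colSums(L <= t)      # cumulative by construction
  # marginal series are only formed where the axis has >= 2 groups
  per_time <- if (length(doses) >= 2) {
    out <- lapply(times, function(t)
      quantal_series(doses, rep(n_per_group, length(doses)), dead_at(t),
                     axis = "dose", label = label))
    names(out) <- paste0(times, "hr")
    out
  }
  per_dose <- if (length(times) >= 2) {
    out <- lapply(seq_along(doses), function(j)
      quantal_series(times, rep(n_per_group, length(times)),
                     vapply(times, function(t) sum(L[, j] <= t),
                            numeric(1)),
                     axis = "time", label = sprintf("%s %g nM", label,
                                                    doses[j])))
    names(out) <- paste0(doses, "nM")
    out
  }
  list(per_time = per_time, per_dose = per_dose, lifetimes = L,
       doses = doses, times = times, label = label)
}

#' Simulate ordinal morphology score trajectories
#'
#' Each animal's score starts at 10 and decays toward 1 as its latent
#' lifetime (drawn from the same hazard model, same stream order as
#' [sim_timecourse()]) is approached: the score drops below 4 exactly at
#' the death time, so the score-derived death sets coincide with the
#' lifetime-based ones. Ordinal noise of +/-1 is added without crossing the
#' alive/dead boundary. Dose-0 animals keep score 10 up to transient noise.
#'
#' @inheritParams sim_timecourse
#' @param doses concentrations in nM (>= 0; dose 0 = untreated control).
#' @param noise_p probability of a +/-1 ordinal observation error.
#' @return A `scores` data frame (columns `animal_id, label, dose_nM,
#'   time_hr, score`).
#' @export
sim_scores <- function(doses, times, n_per_group, model, seed,
                       label = "sim", noise_p = 0.15) {
  stopifnot(inherits(model, "hazard_model"), all(doses >= 0))
  withr::with_seed(seed, {
    pos <- doses[doses > 0]
    L <- matrix(Inf, n_per_group, length(doses))
    if (length(pos)) L[, doses > 0] <- .draw_lifetimes(pos, n_per_group,
                                                       model)
    rows <- vector("list", length(doses) * length(times))
    idx <- 1L
    for (j in seq_along(doses)) for (t in times) {
      life <- L[, j]
      frac <- ifelse(is.finite(life), pmin(t / life, Inf), 0)
      alive <- t < life
      base <- ifelse(alive,
                     4 + round(6 * pmax(0, 1 - frac)),
                     pmax(1, 3 - round(2 * pmin(1, frac - 1))))
      eps <- sample(c(-1L, 0L, 1L), n_per_group, replace = TRUE,
                    prob = c(noise_p / 2, 1 - noise_p, noise_p / 2))
      score <- base + eps
      score <- ifelse(alive, pmin(pmax(score, 4L), 10L),
                      pmin(pmax(score, 1L), 3L))
      rows[[idx]] <- data.frame(
        animal_id = sprintf("a%02d_d%g", seq_len(n_per_group), doses[j]),
        label = label, dose_nM = doses[j], time_hr = t,
        score = as.integer(score))
      idx <- idx + 1L
    }
    do.call(rbind, rows)
  })
}

#' Tentacle regeneration kinetics model
#'
#' @param emergence_rate mean tentacle emergence rate (tentacles/day) of
#'   untreated polyps.
#' @param growth_rate logistic elongation rate (1/day) of an emerged
#'   tentacle.
#' @param delay_factor treatment multiplier (>= 1) on emergence spacing;
#'   1 reproduces the control distribution exactly.
#' @param n_target tentacle count a polyp regenerates toward (default 8).
#' @param half_age age (days since emergence) at which a tentacle reaches
#'   half of full length.
#' @return list of class `regen_model`.
#' @export
regen_model <- function(emergence_rate = 1.2, growth_rate = 1.2,
                        delay_factor = 1, n_target = 8, half_age = 2) {
  if (emergence_rate <= 0 || growth_rate <= 0) stop("rates must be > 0")
  if (delay_factor < 1) stop("delay_factor must be >= 1")
  if (n_target < 1) stop("n_target must be >= 1")
  structure(list(emergence_rate = emergence_rate, growth_rate = growth_rate,
                 delay_factor = delay_factor, n_target = n_target,
                 half_age = half_age),
            class = "regen_model")
}

#' Simulate tentacle regeneration profiles
#'
#' Per polyp, `n_target` tentacle emergence times are drawn as cumulative
#' exponential spacings (mean spacing `delay_factor / emergence_rate`);
#' each emerged tentacle's relative length grows logistically with age and
#' is binned into the 5 length classes by [length_class()].
#'
#' @param n_polyps polyps per group.
#' @param days observation days (day 0 = just bisected).
#' @param model a [regen_model()].
#' @param seed integer seed.
#' @param label group label.
#' @param weights a [tri_weights()] used for binning.
#' @return A `tentacles` data frame (`polyp_id, label, day, c1..c5`).
#' @export
sim_regeneration <- function(n_polyps, days = 0:14, model = regen_model(),
                             seed = 1, label = "sim",
                             weights = tri_weights()) {
  stopifnot(inherits(model, "regen_model"), n_polyps >= 1)
  withr::with_seed(seed, {
    rows <- vector("list", n_polyps)
    for (i in seq_len(n_polyps)) {
      spacing <- stats::rexp(model$n_target,
                             rate = model$emergence_rate) *
        model$delay_factor
      emerge <- cumsum(spacing)
      counts <- t(vapply(days, function(d) {
        age <- d - emerge
        len <- stats::plogis(model$growth_rate * (age - model$half_age))
        len <- len[age > 0]
        out <- integer(5)
        if (length(len)) {
          cls <- length_class(pmin(len, 1), weights)
          for (k in cls) out[k] <- out[k] + 1L
        }
        out
      }, integer(5)))
      rows[[i]] <- data.frame(polyp_id = sprintf("%s_p%02d", label, i),
                              label = label, day = days,
                              c1 = counts[, 1], c2 = counts[, 2],
                              c3 = counts[, 3], c4 = counts[, 4],
                              c5 = counts[, 5])
    }
    do.call(rbind, rows)
  })
}

#' Budding population growth model
#'
#' @param k_true growth constant (per day).
#' @param n0 founder count (default 4).
#' @param scheme `"birth-process"` (each individual buds independently at
#'   rate `k_true`; a Yule process with `E[n(t)] = n0 exp(k t)`) or
#'   `"deterministic-rounded"` (`n(t) = round(n0 exp(k t))`).
#' @return list of class `budding_model`.
#' @export
budding_model <- function(k_true, n0 = 4,
                          scheme = c("birth-process",
                                     "deterministic-rounded")) {
  scheme <- match.arg(scheme)
  if (k_true < 0) stop("k_true must be >= 0")
  if (n0 < 1) stop("n0 must be >= 1")
  structure(list(k_true = k_true, n0 = as.integer(n0), scheme = scheme),
            class = "budding_model")
}

#' Simulate daily population counts
#'
#' @param model a [budding_model()].
#' @param days number of days observed (counts at days 0..days).
#' @param seed integer seed (unused by the deterministic scheme).
#' @param replicate_id,label identifiers for the output table.
#' @return A `population` data frame (`replicate_id, label, day, n`),
#'   counts non-decreasing.
#' @export
sim_population <- function(model, days, seed = 1, replicate_id = "r1",
                           label = "sim") {
  stopifnot(inherits(model, "budding_model"), days >= 2)
  dvec <- 0:days
  n <- if (model$scheme == "deterministic-rounded") {
    pmax(1L, as.integer(round(model$n0 * exp(model$k_true * dvec))))
  } else {
    withr::with_seed(seed, {
      counts <- integer(length(dvec))
      counts[1] <- model$n0
      m <- model$n0
      tnow <- 0
      if (model$k_true > 0) {
        tnext <- tnow + stats::rexp(1, rate = m * model$k_true)
        for (di in seq_along(dvec)[-1]) {
          while (tnext <= dvec[di]) {
            m <- m + 1L
            tnext <- tnext + stats::rexp(1, rate = m * model$k_true)
          }
          counts[di] <- m
        }
      } else counts[] <- model$n0
      counts
    })
  }
  data.frame(replicate_id = replicate_id, label = label, day = dvec, n = n)
}
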