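# Scenario files: flat key-value YAML describing one treatment arm of a
# full bioassay (mortality time course, morphology scores, regeneration,
# population growth). simulate_scenario() turns a scenario plus a seed into
# the four CSV interchange tables.

#' Read a simulation scenario file
#'
#' A scenario is a flat key-value YAML file. Recognised keys (with
#' defaults): `label`; mortality — `doses` (nM), `times` (hr),
#' `n_per_group`, `lt50_ref`, `dose_ref`, `dose_exponent`, `shape`;
#' scores — `score_noise_p`; regeneration — `n_polyps`, `regen_days`,
#' `emergence_rate`, `growth_rate`, `delay_factor`; population —
#' `k_true`, `n0`, `pop_days`, `pop_replicates`, `scheme`.
#'
#' @param path YAML file path.
#' @return list of class `hydratox_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  raw <- yaml::read_yaml(path)
  defaults <- list(label = "sim",
                   doses = c(50, 100, 200, 300, 500, 750, 1000),
                   times = c(12, 24, 48, 72, 96), n_per_group = 20,
                   lt50_ref = 36, dose_ref = 300, dose_exponent = 0.8,
                   shape = 4, score_noise_p = 0.15,
                   n_polyps = 4, regen_days = 0:14,
                   emergence_rate = 1.2, growth_rate = 1.2,
                   delay_factor = 1,
                   k_true = 0.3, n0 = 4, pop_days = 14, pop_replicates = 3,
                   scheme = "birth-process")
  sc <- utils::modifyList(defaults, raw)
  for (key in c("doses", "times", "regen_days"))
    sc[[key]] <- .parse_num_list(sc[[key]])
  structure(sc, class = "hydratox_scenario")
}

# accept YAML lists, single numbers, or comma-separated strings
.parse_num_list <- function(x) {
  if (is.character(x)) x <- strsplit(x, ",")[[1]]
  as.numeric(unlist(x))
}

#' Simulate a full bioassay from a scenario
#'
#' Generates the four interchange tables (quantal mortality, morphology
#' scores, tentacle counts, population counts) from one scenario and seed.
#' Stage seeds are derived deterministically from `seed`.
#'
#' @param scenario a [read_scenario()] result (or an equivalent list).
#' @param seed integer master seed.
#' @param outdir optional directory; when given, `quantal.csv`,
#'   `scores.csv`, `tentacles.csv` and `population.csv` are written there.
#' @return invisible list with elements `quantal`, `scores`, `tentacles`,
#'   `population` (data frames) and `timecourse` (the raw
#'   [sim_timecourse()] output).
#' @export
simulate_scenario <- function(scenario, seed, outdir = NULL) {
  sc <- scenario
  hz <- hazard_model(sc$lt50_ref, sc$dose_ref, sc$dose_exponent, sc$shape)
  seeds <- (as.integer(seed) + 0:9) %% .Machine$integer.max

  tc <- sim_timecourse(sc$doses, sc$times, sc$n_per_group, hz, seeds[1],
                       label = sc$label)
  quantal <- rbind(
    do.call(rbind, lapply(seq_along(sc$times), function(i) {
      g <- tc$per_time[[i]]$groups
      data.frame(label = sc$label, axis = "dose", value = g$value,
                 n_exposed = g$n_exposed, n_dead = g$n_dead,
                 time_hr = sc$times[i])
    })),
    do.call(rbind, lapply(tc$per_dose, function(qs) {
      g <- qs$groups
      data.frame(label = qs$label, axis = "time", value = g$value,
                 n_exposed = g$n_exposed, n_dead = g$n_dead,
                 time_hr = NA_real_)
    }))
  )
  scores <- sim_scores(sc$doses, sc$times, sc$n_per_group, hz, seeds[1],
                       label = sc$label, noise_p = sc$score_noise_p)
  rg <- regen_model(sc$emergence_rate, sc$growth_rate, sc$delay_factor)
  tentacles <- sim_regeneration(sc$n_polyps, sc$regen_days, rg, seeds[2],
                                label = sc$label)
  bm <- budding_model(sc$k_true, sc$n0, sc$scheme)
  population <- do.call(rbind, lapply(seq_len(sc$pop_replicates),
    function(r) sim_population(bm, sc$pop_days, seeds[2 + r],
                               replicate_id = sprintf("%s_r%d", sc$label, r),
                               label = sc$label)))

  out <- list(quantal = quantal, scores = scores, tentacles = tentacles,
              population = population, timecourse = tc)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    utils::write.csv(quantal, file.path(outdir, "quantal.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(scores, file.path(outdir, "scores.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(tentacles, file.path(outdir, "tentacles.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(population, file.path(outdir, "population.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(out)
}
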