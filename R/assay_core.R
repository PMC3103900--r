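# Core data model, tabular I/O and run configuration for the Hydra
# bioassay pipeline. All concentrations are carried in nM and all times in
# hours; log10 transforms happen only inside the estimators.

#' Quantal response series
#'
#' Construct an ordered series of quantal (dead / alive) dose or time groups,
#' the substrate of Spearman-Karber estimation. Groups sharing the same axis
#' value (replicate wells at one concentration) are pooled by summing
#' `n_exposed` and `n_dead`: replicates at one concentration form a single
#' binomial group.
#'
#' @param value numeric vector of axis values: concentrations in nM
#'   (`axis = "dose"`) or observation times in hours (`axis = "time"`).
#'   Must be positive.
#' @param n_exposed integer vector of animals exposed per group (>= 1).
#' @param n_dead integer vector of animals dead per group,
#'   `0 <= n_dead <= n_exposed`.
#' @param axis `"dose"` or `"time"`.
#' @param label free-text series label (e.g. the quantum-dot type).
#' @return An object of class `quantal_series`: a list with a data frame
#'   `groups` (columns `value`, `n_exposed`, `n_dead`, sorted by `value`),
#'   the `axis` and the `label`.
#' @examples
#' qs <- quantal_series(c(50, 100, 200, 400), rep(20, 4), c(0, 4, 16, 20))
#' qs
#' @export
quantal_series <- function(value, n_exposed, n_dead,
                           axis = c("dose", "time"), label = "") {
  axis <- match.arg(axis)
  if (length(value) != length(n_exposed) || length(value) != length(n_dead))
    stop("value, n_exposed and n_dead must have equal length")
  if (any(!is.finite(value)) || any(value <= 0))
    stop("axis values must be positive and finite")
  if (any(n_exposed < 1)) stop("n_exposed must be >= 1 in every group")
  if (any(n_dead < 0) || any(n_dead > n_exposed))
    stop("n_dead must satisfy 0 <= n_dead <= n_exposed")
  g <- data.frame(value = as.numeric(value),
                  n_exposed = as.integer(round(n_exposed)),
                  n_dead = as.integer(round(n_dead)))
  # pool replicate groups at identical axis values
  if (anyDuplicated(g$value)) {
    g <- aggregate(cbind(n_exposed, n_dead) ~ value, data = g, FUN = sum)
  }
  g <- g[order(g$value), , drop = FALSE]
  rownames(g) <- NULL
  if (nrow(g) < 2) stop("a quantal series needs at least 2 distinct groups")
  structure(list(groups = g, axis = axis, label = as.character(label)[1]),
            class = "quantal_series")
}

#' @export
print.quantal_series <- function(x, ...) {
  unit <- if (x$axis == "dose") "nM" else "hr"
  cat(sprintf("Quantal %s series%s: %d groups, %d animals\n", x$axis,
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              nrow(x$groups), sum(x$groups$n_exposed)))
  g <- x$groups
  g$p <- round(g$n_dead / g$n_exposed, 3)
  names(g)[1] <- paste0(x$axis, "_", unit)
  print(g, row.names = FALSE)
  invisible(x)
}

#' Run configuration
#'
#' Bundle the parameters shared by all pipeline stages, so a full analysis is
#' reproducible from one object (or one flat config file via the CLI).
#'
#' @param trim Spearman-Karber trim fraction in `[0, 0.5)`. Default 0
#'   (untrimmed estimate).
#' @param death_threshold ordinal score below which an animal is classified
#'   dead (strict `<`). Default 4.
#' @param confidence confidence level for interval estimates, in (0, 1).
#' @param through_origin logical; fit population growth through the origin
#'   (the model `ln(n/n0) = k t` has no intercept). Default `TRUE`.
#' @param extend logical; if the smoothed mortality curve does not reach 0
#'   (or 1) at its extremes, assume 0% response one log-step below the lowest
#'   group and 100% one log-step above the highest. Default `FALSE`: without
#'   the assumption the median is reported not estimable.
#' @param seed integer seed used by simulation stages, or `NULL`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(trim = 0, death_threshold = 4, confidence = 0.95,
                       through_origin = TRUE, extend = FALSE, seed = NULL) {
  if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)")
  if (death_threshold < 1 || death_threshold > 10)
    stop("death_threshold must lie in 1..10")
  if (confidence <= 0 || confidence >= 1)
    stop("confidence must lie in (0, 1)")
  structure(list(trim = trim,
                 death_threshold = as.integer(death_threshold),
                 confidence = confidence,
                 through_origin = isTRUE(through_origin),
                 extend = isTRUE(extend),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "run_config")
}

# Column contracts for the four CSV interchange schemas.
.schema_columns <- list(
  quantal    = c("label", "axis", "value", "n_exposed", "n_dead", "time_hr"),
  scores     = c("animal_id", "label", "dose_nM", "time_hr", "score"),
  tentacles  = c("polyp_id", "label", "day", "c1", "c2", "c3", "c4", "c5"),
  population = c("replicate_id", "label", "day", "n")
)

.stop_row <- function(row, msg) {
  stop(sprintf("row %d: %s", row, msg), call. = FALSE)
}

#' Load and validate a bioassay table
#'
#' Read one of the four CSV interchange schemas, check every row against the
#' schema's invariants, sort by the natural key, and (for `quantal`) pool
#' duplicate groups within each (label, axis, time) series by summing counts.
#'
#' Schemas and columns:
#' \describe{
#'   \item{quantal}{`label, axis, value, n_exposed, n_dead, time_hr` — one
#'     dose (or time) group per row; `axis` is `dose` or `time`; `time_hr`
#'     may be empty for time-axis rows.}
#'   \item{scores}{`animal_id, label, dose_nM, time_hr, score` — one ordinal
#'     morphology score (1–10) per animal and observation time.}
#'   \item{tentacles}{`polyp_id, label, day, c1..c5` — tentacle counts in the
#'     five relative-length classes per polyp and regeneration day.}
#'   \item{population}{`replicate_id, label, day, n` — daily animal counts
#'     per replicate culture.}
#' }
#'
#' @param path path to a CSV file with a single header row.
#' @param schema one of `"quantal"`, `"scores"`, `"tentacles"`,
#'   `"population"`.
#' @return A validated data frame with the schema's columns.
#' @export
load_table <- function(path,
                       schema = c("quantal", "scores", "tentacles",
                                  "population")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- .schema_columns[[schema]]
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop(sprintf("schema '%s': missing column(s): %s", schema,
                 paste(missing, collapse = ", ")))
  df <- df[, want, drop = FALSE]
  if (nrow(df) == 0) stop("empty data section in ", path)
  validator <- switch(schema,
                      quantal = .validate_quantal,
                      scores = .validate_scores,
                      tentacles = .validate_tentacles,
                      population = .validate_population)
  validator(df)
}

.validate_quantal <- function(df) {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!r$axis %in% c("dose", "time"))
      .stop_row(i, sprintf("axis must be 'dose' or 'time', got '%s'", r$axis))
    if (!is.finite(r$value) || r$value <= 0)
      .stop_row(i, "value must be positive")
    if (is.na(r$n_exposed) || r$n_exposed < 1)
      .stop_row(i, "n_exposed must be >= 1")
    if (is.na(r$n_dead) || r$n_dead < 0 || r$n_dead > r$n_exposed)
      .stop_row(i, "n_dead must satisfy 0 <= n_dead <= n_exposed")
  }
  # pool duplicate groups within each series (time-axis rows carry no
  # time_hr; an NA key level must not drop them)
  key <- interaction(df$label, df$axis,
                     ifelse(is.na(df$time_hr), "", df$time_hr), drop = TRUE)
  parts <- lapply(split(df, key), function(d) {
    if (anyDuplicated(d$value)) {
      agg <- aggregate(cbind(n_exposed, n_dead) ~ value, data = d, FUN = sum)
      d <- merge(unique(d[, c("label", "axis", "time_hr")]), agg)
      d <- d[, c("label", "axis", "value", "n_exposed", "n_dead", "time_hr")]
    }
    d[order(d$value), , drop = FALSE]
  })
  out <- do.call(rbind, parts)
  out <- out[order(out$label, out$axis, out$time_hr, out$value), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.validate_scores <- function(df) {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$score) || r$score < 1 || r$score > 10 ||
        r$score != round(r$score))
      .stop_row(i, sprintf("score must be an integer in 1..10, got %s",
                           format(r$score)))
    if (!is.finite(r$dose_nM) || r$dose_nM < 0)
      .stop_row(i, "dose_nM must be >= 0")
    if (!is.finite(r$time_hr) || r$time_hr < 0)
      .stop_row(i, "time_hr must be >= 0")
  }
  df <- df[order(df$label, df$time_hr, df$dose_nM, df$animal_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

.validate_tentacles <- function(df) {
  cls <- paste0("c", 1:5)
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    cnt <- as.numeric(r[cls])
    if (any(is.na(cnt)) || any(cnt < 0) || any(cnt != round(cnt)))
      .stop_row(i, "tentacle class counts must be non-negative integers")
    if (is.na(r$day) || r$day < 0)
      .stop_row(i, "day must be >= 0")
  }
  df <- df[order(df$label, df$polyp_id, df$day), , drop = FALSE]
  rownames(df) <- NULL
  df
}

.validate_population <- function(df) {
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (is.na(r$n) || r$n < 1 || r$n != round(r$n))
      .stop_row(i, "n must be an integer >= 1")
    if (is.na(r$day) || r$day < 0 || r$day != round(r$day))
      .stop_row(i, "day must be a non-negative integer")
  }
  # every replicate needs its founder count at day 0
  for (id in unique(df$replicate_id)) {
    d <- df[df$replicate_id == id, ]
    if (!any(d$day == 0))
      stop(sprintf("replicate '%s' has no day-0 founder count", id),
           call. = FALSE)
  }
  df <- df[order(df$label, df$replicate_id, df$day), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Write a stage result to CSV or JSON
#'
#' CSV output is restricted to tabular results (data frames); JSON output
#' serialises any stage result together with its method metadata (trim,
#' confidence, seed) so that a result file is self-describing. Numeric
#' fields round-trip at full precision.
#'
#' @param results a data frame (csv) or any pipeline stage output (json).
#' @param path output file path.
#' @param format `"csv"` or `"json"`.
#' @param params optional `run_config` (or plain list) recorded under
#'   `$params` in JSON output.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("csv", "json"),
                          params = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!is.data.frame(results))
      stop("csv output requires a data frame result")
    utils::write.csv(results, path, row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(
      stage = class(results)[1],
      params = if (is.null(params)) NULL else unclass(params),
      results = .jsonable(results)
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

# strip S3 classes recursively so jsonlite serialises plainly
.jsonable <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), .jsonable))
  x
}
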