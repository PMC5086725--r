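# Configuration parsing, layout and trajectory serialization, and the
# simulate pipeline behind the command-line interface.

.CONFIG_FIELDS <- c("scenario", "seed", "dt", "horizon", "anchor",
                    "parameters", "output", "sensitivity")

#' Build and validate a run configuration
#'
#' Fills defaults and validates a configuration list describing one
#' simulation run. Recognised fields:
#' * `scenario`: `"tianjin"` (the built-in preset) or a path to a layout CSV
#'   (see [write_layout_csv()]). Default `"tianjin"`.
#' * `seed`: integer seed for scenario generation. Default 1.
#' * `dt`, `horizon`: integration step and horizon, hours. Defaults 1
#'   and 120.
#' * `anchor`: list `community`/`type`/`count` (see [initial_state()]).
#' * `parameters`: named list of scalar overrides applied with
#'   [set_model_param()].
#' * `output`: list with optional `trajectory` (CSV path) and `summary`
#'   (JSON path).
#' * `sensitivity`: optional list with `param`, `range`, `n_grid`, and
#'   optionally `times`, `rel_step`.
#'
#' @param x A named list (e.g. parsed from YAML or JSON).
#' @return An object of class `run_config`.
#' @export
as_run_config <- function(x = list()) {
  if (!is.list(x)) stop("a configuration must be a named list")
  unknown <- setdiff(names(x), .CONFIG_FIELDS)
  if (length(unknown) > 0L)
    stop(sprintf("unknown configuration field(s): %s",
                 paste(unknown, collapse = ", ")))
  cfg <- list(
    scenario = if (is.null(x$scenario)) "tianjin" else x$scenario,
    seed = if (is.null(x$seed)) 1L else as.integer(x$seed),
    dt = if (is.null(x$dt)) 1 else x$dt,
    horizon = if (is.null(x$horizon)) 120 else x$horizon,
    anchor = if (is.null(x$anchor))
      list(community = 1, type = 1, count = 150) else x$anchor,
    parameters = x$parameters,
    output = x$output,
    sensitivity = x$sensitivity
  )
  if (!is.numeric(cfg$dt) || cfg$dt <= 0)
    stop("configuration field `dt` must be positive")
  if (!is.numeric(cfg$horizon) || cfg$horizon <= 0)
    stop("configuration field `horizon` must be positive")
  if (cfg$horizon < cfg$dt)
    stop("configuration field `horizon` must be at least one step")
  if (!is.character(cfg$scenario) ||
      (cfg$scenario != "tianjin" && !file.exists(cfg$scenario)))
    stop(sprintf("scenario '%s' is neither a known preset nor an existing file",
                 cfg$scenario))
  if (!is.null(cfg$sensitivity)) {
    need <- c("param", "range", "n_grid")
    miss <- setdiff(need, names(cfg$sensitivity))
    if (length(miss) > 0L)
      stop(sprintf("sensitivity block is missing field(s): %s",
                   paste(miss, collapse = ", ")))
  }
  structure(cfg, class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `run_config` (see [as_run_config()]).
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("configuration file '%s' not found", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop(sprintf("unsupported configuration format '.%s' (use YAML or JSON)", ext)))
  as_run_config(raw)
}

#' Write a run configuration to YAML
#'
#' Serializes the configuration so that [load_run_config()] round-trips it.
#'
#' @param cfg A `run_config`.
#' @param path Output `.yaml` path.
#' @return Invisibly, `path`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Write / read a community layout as CSV
#'
#' Plain-text layout serialization with one row per community and columns
#' `community`, `dist_to_source`, `x`, `y`, `q1`, `q2`, `q3`. Pairwise
#' distances are reconstructed from the coordinates on reading, so layouts
#' without coordinates cannot be written.
#'
#' @param layout A [community_layout()] with coordinates.
#' @param path CSV path.
#' @return `write_layout_csv()` invisibly returns `path`;
#'   `read_layout_csv()` returns a [community_layout()].
#' @export
write_layout_csv <- function(layout, path) {
  stopifnot(inherits(layout, "community_layout"))
  if (is.null(layout$coords))
    stop("layout has no coordinates; cannot serialize to CSV")
  df <- data.frame(community = seq_len(layout$n),
                   dist_to_source = layout$dist_to_source,
                   x = layout$coords[, 1], y = layout$coords[, 2],
                   q1 = layout$populations[1, ],
                   q2 = layout$populations[2, ],
                   q3 = layout$populations[3, ])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_layout_csv
#' @export
read_layout_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("dist_to_source", "x", "y", "q1", "q2", "q3")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("layout CSV is missing column(s): %s",
                 paste(miss, collapse = ", ")))
  coords <- cbind(df$x, df$y)
  community_layout(dist_to_source = df$dist_to_source,
                   pairwise = as.matrix(stats::dist(coords)),
                   populations = rbind(df$q1, df$q2, df$q3),
                   coords = coords)
}

#' Export a trajectory as tidy CSV
#'
#' One row per (time, community, type) with columns `t`, `community`,
#' `type`, `I`, `S` and `fraction` (of the group population).
#'
#' @param traj An `evac_trajectory`.
#' @param path CSV path.
#' @return Invisibly, `path`.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "evac_trajectory"))
  n <- traj$layout$n; m <- length(traj$times)
  Q <- traj$layout$populations
  I <- as.vector(traj$I)
  Qv <- rep(as.vector(Q), times = m)
  df <- data.frame(
    t = rep(traj$times, each = 3L * n),
    community = rep(rep(seq_len(n), each = 3L), times = m),
    type = rep(TYPE_LABELS, times = n * m),
    I = I,
    S = Qv - I,
    fraction = ifelse(Qv > 0, I / Qv, 0))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.resolve_scenario <- function(cfg) {
  if (identical(cfg$scenario, "tianjin")) {
    sc <- tianjin_like_scenario(cfg$seed)
    layout <- sc$layout
    params <- sc$params
  } else {
    layout <- read_layout_csv(cfg$scenario)
    params <- reference_parameters("table1")
  }
  if (!is.null(cfg$parameters)) {
    for (nm in names(cfg$parameters))
      params <- set_model_param(params, nm, cfg$parameters[[nm]])
  }
  list(layout = layout, params = params, anchor = cfg$anchor)
}

#' Summarize a trajectory for machine consumption
#'
#' @param traj An `evac_trajectory`.
#' @param cfg Optional `run_config` echoed into the summary for
#'   reproducibility.
#' @return A list (total curve, hourly increments, final per-type fractions,
#'   clamp events, parameter echo, configuration echo) suitable for
#'   [jsonlite::write_json()].
#' @export
trajectory_summary <- function(traj, cfg = NULL) {
  agg <- aggregate_demand(traj)
  m <- length(traj$times)
  final_by_type <- agg$by_type[agg$by_type$t == traj$times[m], ]
  p <- traj$params
  list(
    n_communities = traj$layout$n,
    total_population = sum(traj$layout$populations),
    dt = traj$dt,
    horizon = traj$horizon,
    clamp_events = traj$clamp_events,
    initial_fraction = agg$total$fraction[1],
    final_fraction = agg$total$fraction[m],
    total_curve = agg$total,
    hourly_increments = agg$increments,
    final_fraction_by_type = stats::setNames(as.list(final_by_type$fraction),
                                             final_by_type$type),
    parameters = list(gamma = p$gamma,
                      kernel = unclass(p$kernel),
                      location = unclass(p$location),
                      warning = unclass(p$warning)),
    config = if (is.null(cfg)) NULL else unclass(cfg)
  )
}

#' Run a configured simulation
#'
#' Resolves the scenario (preset or layout file, plus parameter overrides),
#' computes the initial state from the anchor, integrates over the
#' configured horizon, and writes the requested artifacts. Runs are
#' deterministic in the configuration and seed.
#'
#' @param cfg A `run_config` (see [as_run_config()], [load_run_config()]).
#' @param quiet Suppress the one-line progress message.
#' @return Invisibly, a list with the `trajectory`, its
#'   [aggregate_demand()] `aggregate`, the `summary` list and the paths of
#'   any `files` written.
#' @export
run_simulate <- function(cfg, quiet = TRUE) {
  stopifnot(inherits(cfg, "run_config"))
  sc <- .resolve_scenario(cfg)
  init <- initial_state(sc$layout, sc$params, anchor = sc$anchor)
  traj <- simulate_evacuation(sc$layout, sc$params, init,
                              dt = cfg$dt, horizon = cfg$horizon)
  summary <- trajectory_summary(traj, cfg)
  files <- character(0)
  if (!is.null(cfg$output$trajectory)) {
    write_trajectory_csv(traj, cfg$output$trajectory)
    files <- c(files, trajectory = cfg$output$trajectory)
  }
  if (!is.null(cfg$output$summary)) {
    jsonlite::write_json(summary, cfg$output$summary,
                         auto_unbox = TRUE, digits = NA, null = "null")
    files <- c(files, summary = cfg$output$summary)
  }
  if (!quiet)
    message(sprintf("simulated %d communities over %g h: %.1f%% -> %.1f%% evacuated",
                    sc$layout$n, cfg$horizon,
                    100 * summary$initial_fraction,
                    100 * summary$final_fraction))
  invisible(list(trajectory = traj, aggregate = aggregate_demand(traj),
                 summary = summary, files = files))
}
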