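# Dimensionless single-factor local sensitivity analysis: the model output
# is the total demand curve sampled at five instants; the sensitivity
# function (SF) is the relative Euclidean norm of the output change divided
# by the relative parameter perturbation.

#' Sensitivity-analysis configuration
#'
#' @param times Five strictly increasing positive evaluation instants
#'   (hours) at which the total demand curve is sampled. Default
#'   `(24, 48, 72, 96, 120)`: an even spread over the case's 120-h horizon.
#' @param rel_step Relative finite-difference perturbation (dimensionless),
#'   `0 < rel_step << 1`. Default `1e-3`.
#' @param method `"forward"` (default) or `"central"` difference.
#' @param dt Integration step used for the underlying simulations, hours.
#'   All `times` must lie on the resulting grid.
#' @return An object of class `sensitivity_config`.
#' @export
sensitivity_config <- function(times = c(24, 48, 72, 96, 120),
                               rel_step = 1e-3,
                               method = c("forward", "central"),
                               dt = 1) {
  method <- match.arg(method)
  if (length(times) != 5L || any(times <= 0) || any(diff(times) <= 0))
    stop("`times` must be five strictly increasing positive instants")
  if (!is.numeric(rel_step) || rel_step <= 0 || rel_step >= 1)
    stop("`rel_step` must lie in (0, 1)")
  if (dt <= 0) stop("`dt` must be positive")
  structure(list(times = times, rel_step = rel_step, method = method, dt = dt),
            class = "sensitivity_config")
}

#' Five-point model output
#'
#' Runs a full simulation and returns the total evacuated count at the
#' configured evaluation instants — the output vector `O` of the
#' sensitivity analysis.
#'
#' @param layout A [community_layout()].
#' @param params A [model_parameters()].
#' @param init An `evac_state` ([initial_state()]) or an anchor list, in
#'   which case the initial state is recomputed from it under `params`.
#' @param cfg A [sensitivity_config()].
#' @return Numeric vector of total evacuated counts at `cfg$times`.
#' @export
model_output <- function(layout, params, init, cfg = sensitivity_config()) {
  stopifnot(inherits(cfg, "sensitivity_config"))
  if (!inherits(init, "evac_state"))
    init <- initial_state(layout, params, anchor = init)
  horizon <- max(cfg$times)
  traj <- simulate_evacuation(layout, params, init, dt = cfg$dt,
                              horizon = horizon)
  idx <- vapply(cfg$times, function(tt) {
    i <- which.min(abs(traj$times - tt))
    if (abs(traj$times[i] - tt) > 1e-8)
      stop(sprintf("output time t = %g does not lie on the integration grid",
                   tt))
    i
  }, integer(1))
  apply(traj$I[, , idx, drop = FALSE], 3L, sum)
}

#' Relative Euclidean norm of an output change
#'
#' Componentwise relative change between two output vectors combined in a
#' Euclidean-style norm:
#' `sqrt(sum(((o_new - o_old) / o_old)^2))`.
#'
#' @param o_new,o_old Output vectors of equal length; `o_old` must be
#'   strictly positive componentwise.
#' @return Non-negative scalar.
#' @export
relative_norm <- function(o_new, o_old) {
  if (length(o_new) != length(o_old))
    stop("output vectors must have equal length")
  if (any(o_old <= 0))
    stop("reference output has a non-positive component; the relative norm is undefined")
  sqrt(sum(((o_new - o_old) / o_old)^2))
}

#' Finite-difference sensitivity of an output function
#'
#' Generic building block: given any function `f(beta)` returning an output
#' vector, approximates the sensitivity function
#' `SF(beta) = lim ||dO / O|| / |dbeta / beta|`
#' by a relative finite difference with step `rel_step * beta`.
#'
#' @param f Function of a single positive scalar returning a strictly
#'   positive output vector.
#' @param beta Parameter value at which to evaluate, > 0.
#' @param rel_step Relative perturbation.
#' @param method `"forward"` or `"central"`.
#' @return Non-negative SF scalar.
#' @export
sensitivity_fd <- function(f, beta, rel_step = 1e-3,
                           method = c("forward", "central")) {
  method <- match.arg(method)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0)
    stop("`beta` must be a single positive value (relative perturbation)")
  db <- rel_step * beta
  o0 <- f(beta)
  if (method == "forward") {
    relative_norm(f(beta + db), o0) / rel_step
  } else {
    op <- f(beta + db); om <- f(beta - db)
    if (any(o0 <= 0)) stop("reference output has a non-positive component")
    sqrt(sum(((op - om) / o0)^2)) / (2 * rel_step)
  }
}

#' Set a named scalar parameter of the model
#'
#' Rebuilds a [model_parameters()] object with one named entry changed; all
#' construction-time constraints (gamma ordering, warning jump-up property,
#' non-negativity) are re-validated, so an out-of-range value errors.
#' Recognised names: `"lambda0"`, `"alpha"`, `"sigma"`, `"gamma1"`,
#' `"gamma2"`, `"gamma3"`, `"a1"`, `"b1"`, `"a2"`, `"b2"`, and warning
#' coefficients `"a3"`, `"b3"`, `"a4"`, `"b4"`, ... mapping to pieces
#' 1, 2, ... of the schedule (the case-study naming).
#'
#' @param params A [model_parameters()].
#' @param name Parameter name.
#' @param value New value.
#' @return A new [model_parameters()] object.
#' @export
set_model_param <- function(params, name, value) {
  stopifnot(inherits(params, "model_parameters"))
  g <- params$gamma; k <- params$kernel; l <- params$location
  w <- params$warning
  m <- regmatches(name, regexec("^([ab])([0-9]+)$", name))[[1]]
  if (name %in% c("lambda0", "alpha", "sigma")) {
    k[[name]] <- value
  } else if (name %in% c("gamma1", "gamma2", "gamma3")) {
    g[as.integer(substring(name, 6))] <- value
  } else if (name %in% c("a1", "b1", "a2", "b2")) {
    l[[name]] <- value
  } else if (length(m) == 3L && as.integer(m[3]) >= 3L) {
    piece <- as.integer(m[3]) - 2L
    if (piece > length(w$breakpoints))
      stop(sprintf("`%s` refers to warning piece %d but the schedule has %d",
                   name, piece, length(w$breakpoints)))
    if (m[2] == "a") w$a[piece] <- value else w$b[piece] <- value
  } else {
    stop(sprintf("unknown parameter name '%s'", name))
  }
  model_parameters(
    gamma = g,
    kernel = kernel_params(k$lambda0, k$alpha, k$sigma),
    location = location_params(l$a1, l$b1, l$a2, l$b2,
                               f_form = l$f_form, h_cap = l$h_cap),
    warning = warning_schedule(w$breakpoints, w$a, w$b, mode = w$mode))
}

#' Sensitivity of the demand curve to one parameter
#'
#' Evaluates the sensitivity function at `value`: the named parameter is
#' perturbed by `rel_step * value`, the full pipeline (initial state from
#' the anchor, then simulation) is rerun, and the relative norm of the
#' five-point output change is divided by the relative perturbation.
#'
#' @param name Parameter name (see [set_model_param()]).
#' @param value Parameter value at which to evaluate, > 0.
#' @param layout A [community_layout()].
#' @param params Reference [model_parameters()]; all other entries stay at
#'   their reference values.
#' @param anchor Anchor initial condition (see [initial_state()]); the
#'   initial state is recomputed under each perturbed parameter vector,
#'   since it depends on the transformation rates.
#' @param cfg A [sensitivity_config()].
#' @return Non-negative SF scalar.
#' @export
sensitivity_at <- function(name, value, layout, params,
                           anchor = list(community = 1, type = 1, count = 150),
                           cfg = sensitivity_config()) {
  f <- function(b) {
    p2 <- set_model_param(params, name, b)
    model_output(layout, p2, anchor, cfg)
  }
  sensitivity_fd(f, value, rel_step = cfg$rel_step, method = cfg$method)
}

#' Scan the sensitivity function over a parameter range
#'
#' Evaluates [sensitivity_at()] on an even grid over `range` and reports the
#' maximum and average SF. Grid points at which the relative perturbation is
#' undefined (values <= 0) are dropped; a range whose values violate a
#' construction constraint (e.g. the gamma ordering, or the warning jump-up
#' property) is rejected.
#'
#' @param name Parameter name.
#' @param range Length-2 numeric range.
#' @param n_grid Number of grid points, >= 2.
#' @inheritParams sensitivity_at
#' @return An object of class `sensitivity_result`: list with `parameter`,
#'   `values`, `sf`, `max` and `average`.
#' @export
sensitivity_scan <- function(name, range, n_grid, layout, params,
                             anchor = list(community = 1, type = 1, count = 150),
                             cfg = sensitivity_config()) {
  if (n_grid < 2) stop("`n_grid` must be at least 2")
  if (length(range) != 2L || range[1] >= range[2])
    stop("`range` must be an increasing length-2 interval")
  grid <- seq(range[1], range[2], length.out = n_grid)
  grid <- grid[grid > 0]
  if (length(grid) < 2L)
    stop("fewer than two positive grid points in `range`")
  for (v in grid) {
    ok <- tryCatch({set_model_param(params, name, v); TRUE},
                   error = function(e) conditionMessage(e))
    if (!isTRUE(ok))
      stop(sprintf("range violates parameter constraints at %s = %g: %s",
                   name, v, ok))
  }
  sf <- vapply(grid, function(v)
    sensitivity_at(name, v, layout, params, anchor, cfg), numeric(1))
  structure(list(parameter = name, values = grid, sf = sf,
                 max = max(sf), average = mean(sf)),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("<sensitivity_result: %s over [%g, %g], %d points>\n",
              x$parameter, min(x$values), max(x$values), length(x$values)))
  cat(sprintf("  maximum SF = %.4f, average SF = %.4f\n", x$max, x$average))
  invisible(x)
}

#' @export
as.data.frame.sensitivity_result <- function(x, ...) {
  data.frame(parameter = x$parameter, value = x$values, sf = x$sf)
}

#' Plot a sensitivity scan
#'
#' @param x A `sensitivity_result`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.sensitivity_result <- function(x, ...) {
  graphics::plot(x$values, x$sf, type = "l", xlab = x$parameter,
                 ylab = "sensitivity SF",
                 main = sprintf("Sensitivity of the demand curve to %s",
                                x$parameter), ...)
  invisible(x)
}

#' Reference parameter presets
#'
#' Two published reference parameterizations of the case study. `"table1"`
#' is the simulation preset (`alpha = 0.01`, `h(d) = d + 0.1`,
#' `a2 = b2 = 0.01`, warning pieces `(0.01, 0.001)` and `(0.2, 0.01)`);
#' `"table3"` is the sensitivity-analysis reference set, which differs in
#' `alpha = 0.1`, `a1 = 0.1`, `a2 = 0.1`, `b2 = 0.02`, and first warning
#' piece `(0.1, 0.002)`.
#'
#' @param preset `"table1"` or `"table3"`.
#' @return A [model_parameters()] object.
#' @export
reference_parameters <- function(preset = c("table1", "table3")) {
  preset <- match.arg(preset)
  if (preset == "table1") {
    model_parameters(
      gamma = c(0.5, 0.3, 0.2),
      kernel = kernel_params(0.25, 0.01, 1),
      location = location_params(a1 = 1, b1 = 0.1, a2 = 0.01, b2 = 0.01),
      warning = warning_schedule(c(0, 60), a = c(0.01, 0.2),
                                 b = c(0.001, 0.01)))
  } else {
    model_parameters(
      gamma = c(0.5, 0.3, 0.2),
      kernel = kernel_params(0.25, 0.1, 1),
      location = location_params(a1 = 0.1, b1 = 0.1, a2 = 0.1, b2 = 0.02),
      warning = warning_schedule(c(0, 60), a = c(0.1, 0.2),
                                 b = c(0.002, 0.01)))
  }
}

#' Reference scan ranges of the sensitivity analysis
#'
#' The published value ranges scanned for each parameter in the
#' sensitivity-analysis reference set. Note that some full published ranges
#' conflict with construction constraints under the reference values (a
#' `gamma1` grid crossing `gamma2`, or an `a3` large enough to break the
#' warning jump-up at the second issuance) and must be narrowed before
#' scanning.
#'
#' @return Named list of length-2 ranges.
#' @export
reference_ranges <- function() {
  list(lambda0 = c(0, 1), gamma1 = c(0, 1), alpha = c(0, 10),
       sigma = c(0, 10), a1 = c(0, 10), b1 = c(0, 10), a2 = c(0, 2),
       b2 = c(0, 2), a3 = c(0, 2), b3 = c(0, 0.2))
}
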