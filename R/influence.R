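# Influence functions of the evacuation-contagion model: the between-community
# contact kernel, the location-influence weight, the geographic-decay forcing
# and the piecewise warning-degree forcing. All distances are in km, all times
# in hours, and every function returns an hour^-1 rate scale (the location
# weight is dimensionless).

#' Between-community contact kernel parameters
#'
#' Parameters of the Gaussian contact kernel that couples communities:
#' the per-hour contact frequency between residents of two communities a
#' distance `d` apart is modelled as a scaled normal density in `d`, so that
#' contact decays smoothly with separation.
#'
#' @param lambda0 Within-community contact frequency, contacts per hour.
#'   The default 0.25 means an evacuated resident contacts, on average, one
#'   person inside the community every four hours.
#' @param alpha Dimensionless scaling of between-community contact relative
#'   to within-community contact.
#' @param sigma Kernel width in km; larger values extend social contact to
#'   more distant communities.
#' @return An object of class `kernel_params`.
#' @seealso [contact_kernel()]
#' @export
kernel_params <- function(lambda0 = 0.25, alpha = 0.01, sigma = 1) {
  if (!is.numeric(lambda0) || length(lambda0) != 1L || lambda0 < 0)
    stop("`lambda0` must be a single non-negative number")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0)
    stop("`alpha` must be a single non-negative number")
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be a single positive number")
  structure(list(lambda0 = lambda0, alpha = alpha, sigma = sigma),
            class = "kernel_params")
}

#' Location-influence parameters
#'
#' Coefficients of the two location-driven influence functions:
#' * the influence weight `h(d) = a1 * d + b1`, which makes evacuation
#'   messages originating from communities far from the risk source (low
#'   risk, hence more surprising and persuasive) carry more weight, and
#' * the geographic-decay forcing `f(d, t)`, the direct location-driven
#'   evacuation pressure, decreasing in both the distance `d` to the risk
#'   source and elapsed time `t`.
#'
#' Two algebraic forms of `f` are provided. The default `"combined"` form is
#' `f(d, t) = a2 / (d^2 + b2 * t + 10)`; the `"separable"` alternative is
#' `a2 / d^2 * 1 / (b2 * t + 10)` (undefined at `d = 0`). Both decrease
#' monotonically in `d` and `t`.
#'
#' @param a1 Slope of `h`, per km.
#' @param b1 Intercept of `h`, dimensionless.
#' @param a2 Numerator of `f`.
#' @param b2 Time coefficient of `f`, per hour.
#' @param f_form Form of the geographic decay, `"combined"` (default) or
#'   `"separable"`.
#' @param h_cap Optional ceiling applied to `h(d)`, which otherwise grows
#'   without bound in `d`. Off (`Inf`) by default.
#' @return An object of class `location_params`.
#' @export
location_params <- function(a1 = 1, b1 = 0.1, a2 = 0.01, b2 = 0.01,
                            f_form = c("combined", "separable"),
                            h_cap = Inf) {
  f_form <- match.arg(f_form)
  vals <- c(a1 = a1, b1 = b1, a2 = a2, b2 = b2)
  if (!is.numeric(vals) || any(vals < 0) || anyNA(vals))
    stop("`a1`, `b1`, `a2`, `b2` must all be non-negative numbers")
  if (!is.numeric(h_cap) || length(h_cap) != 1L || h_cap <= 0)
    stop("`h_cap` must be a single positive number (Inf to disable)")
  structure(list(a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                 f_form = f_form, h_cap = h_cap),
            class = "location_params")
}

#' Between-community contact kernel
#'
#' Per-hour contact frequency between residents of communities separated by
#' distance `d`:
#' `lambda(d) = lambda0 * alpha / (sqrt(2 * pi) * sigma) * exp(-d^2 / (2 * sigma^2))`.
#' Strictly decreasing in `d` and vanishing as `d -> Inf`; integrates over
#' `d in [0, Inf)` to `lambda0 * alpha / 2` (half-Gaussian mass).
#'
#' @param d Distance(s) between communities, km (vector or matrix, all >= 0).
#' @param params A [kernel_params()] object.
#' @return Contact rate(s), per hour, same shape as `d`.
#' @examples
#' contact_kernel(0, kernel_params(0.25, 0.01, 1)) # ~9.9736e-4
#' @export
contact_kernel <- function(d, params) {
  stopifnot(inherits(params, "kernel_params"))
  if (any(d < 0)) stop("distances must be non-negative")
  params$lambda0 * params$alpha / (sqrt(2 * pi) * params$sigma) *
    exp(-d^2 / (2 * params$sigma^2))
}

#' Location-influence weight
#'
#' The weight `h(d) = a1 * d + b1` applied to evacuated counts in a source
#' community at distance `d` from the risk source: messages from low-risk
#' (distant) communities are more persuasive, so `h` is non-decreasing in
#' `d`. An optional ceiling (`h_cap` in [location_params()]) truncates the
#' unbounded growth; it is off by default.
#'
#' @param d Distance(s) from the source community to the risk source, km.
#' @param params A [location_params()] object.
#' @return Dimensionless weight(s), same shape as `d`.
#' @export
location_weight <- function(d, params) {
  stopifnot(inherits(params, "location_params"))
  if (any(d < 0)) stop("distances must be non-negative")
  pmin(params$a1 * d + params$b1, params$h_cap)
}

#' Geographic-decay forcing
#'
#' Direct location-driven evacuation pressure `f(d, t)`, non-increasing in
#' both the distance `d` of the community to the risk source and elapsed
#' time `t` (the disaster is assumed not to change over time, so its
#' location effect only weakens). See [location_params()] for the two forms.
#'
#' @param d Distance(s) to the risk source, km.
#' @param t Time(s) since the first evacuation order, hours.
#' @param params A [location_params()] object.
#' @return Rate(s), per hour.
#' @export
geo_decay <- function(d, t, params) {
  stopifnot(inherits(params, "location_params"))
  if (any(d < 0)) stop("distances must be non-negative")
  if (any(t < 0)) stop("times must be non-negative")
  switch(params$f_form,
    combined  = params$a2 / (d^2 + params$b2 * t + 10),
    separable = (params$a2 / d^2) * (1 / (params$b2 * t + 10))
  )
}

.w_piece_value <- function(s, i, t) {
  switch(s$mode,
    hyperbolic_reset  = s$a[i] / ((t - s$breakpoints[i]) + 10) + s$b[i],
    hyperbolic_global = s$a[i] / (t + 10) + s$b[i],
    linear            = s$a[i] * t + s$b[i]
  )
}

#' Warning-degree schedule
#'
#' A piecewise forcing `w(t)` representing the succession of official
#' warning degrees (or evacuation orders). Each issuance at time `t_i`
#' starts a new piece with coefficients `(a_i, b_i)`; within a piece the
#' warning effect weakens over time (like the injection effect of a drug),
#' while a new, stronger order jumps the effect upward. Three algebraic
#' modes are supported:
#'
#' * `"hyperbolic_reset"` (default): `a_i / ((t - t_i) + 10) + b_i`; the
#'   decay clock restarts at each issuance, so every new order injects a
#'   fresh effect.
#' * `"hyperbolic_global"`: `a_i / (t + 10) + b_i`; the decay clock runs
#'   from `t = 0` throughout.
#' * `"linear"`: `a_i * t + b_i` (see [validate_linear_schedule()] for the
#'   ordering constraints this mode is conventionally subject to).
#'
#' At every interior breakpoint the new piece's starting value must exceed
#' the previous piece's left limit (higher degree, stronger effect);
#' schedules violating this jump-up property are rejected.
#'
#' @param breakpoints Strictly increasing issuance times `t_1 < t_2 < ...`
#'   in hours; the first must be 0 (time zero is the first order's
#'   issuance). A pre-order constant level can be encoded as a zero-slope
#'   first piece.
#' @param a,b Per-piece coefficient vectors, same length as `breakpoints`.
#'   In the hyperbolic modes both must be non-negative.
#' @param mode One of `"hyperbolic_reset"`, `"hyperbolic_global"`,
#'   `"linear"`.
#' @return An object of class `warning_schedule`.
#' @examples
#' # the two evacuation orders of the Tianjin case, issued at t = 0 and 60 h
#' warning_schedule(c(0, 60), a = c(0.01, 0.2), b = c(0.001, 0.01))
#' @export
warning_schedule <- function(breakpoints, a, b,
                             mode = c("hyperbolic_reset", "hyperbolic_global",
                                      "linear")) {
  mode <- match.arg(mode)
  if (length(breakpoints) < 1L || anyNA(breakpoints))
    stop("at least one warning piece is required")
  if (length(a) != length(breakpoints) || length(b) != length(breakpoints))
    stop("`a` and `b` must have one coefficient per breakpoint")
  if (breakpoints[1L] != 0)
    stop("the first breakpoint must be 0 (issuance of the first order)")
  if (any(diff(breakpoints) <= 0))
    stop("breakpoints must be strictly increasing")
  if (mode != "linear" && (any(a < 0) || any(b < 0)))
    stop("hyperbolic modes require non-negative `a` and `b`")
  s <- structure(list(breakpoints = breakpoints, a = a, b = b, mode = mode),
                 class = "warning_schedule")
  np <- length(breakpoints)
  if (np > 1L) {
    for (i in seq_len(np - 1L)) {
      t_next <- breakpoints[i + 1L]
      left_limit <- .w_piece_value(s, i, t_next)
      new_start <- .w_piece_value(s, i + 1L, t_next)
      if (!(new_start > left_limit))
        stop(sprintf(paste0(
          "warning schedule is not jump-up at t = %g: piece %d starts at %g ",
          "but piece %d decays to %g (a stronger order must raise the effect)"),
          t_next, i + 1L, new_start, i, left_limit))
    }
  }
  s
}

#' Evaluate the warning forcing
#'
#' Evaluates `w(t)` for a [warning_schedule()]. Right-continuous at the
#' breakpoints: at an issuance time the new (stronger) piece applies.
#'
#' @param t Time(s) in hours, all >= 0.
#' @param schedule A [warning_schedule()] object.
#' @return Warning rate(s), per hour, same length as `t`.
#' @export
warning_level <- function(t, schedule) {
  stopifnot(inherits(schedule, "warning_schedule"))
  if (any(t < 0)) stop("times must be non-negative")
  idx <- findInterval(t, schedule$breakpoints)
  out <- switch(schedule$mode,
    hyperbolic_reset  = schedule$a[idx] / ((t - schedule$breakpoints[idx]) + 10) +
                        schedule$b[idx],
    hyperbolic_global = schedule$a[idx] / (t + 10) + schedule$b[idx],
    linear            = schedule$a[idx] * t + schedule$b[idx]
  )
  if (any(out < 0))
    stop("warning forcing w(t) must be non-negative over the requested times")
  out
}

#' Check the ordering constraints of a linear warning schedule
#'
#' For a schedule in `"linear"` mode, checks the conventional ordering
#' constraints on successive warning degrees: the per-piece slopes must be
#' strictly increasing (`a_1 < a_2 < ...`) and the value of `w` at each
#' issuance time must be strictly increasing across degrees. A single-piece
#' schedule passes vacuously.
#'
#' @param schedule A [warning_schedule()] object with `mode = "linear"`.
#' @return A list of class `schedule_validation` with elements `ok`
#'   (logical) and `violation` (`NULL`, or a string naming the first
#'   violated inequality).
#' @export
validate_linear_schedule <- function(schedule) {
  stopifnot(inherits(schedule, "warning_schedule"))
  if (schedule$mode != "linear")
    stop("`validate_linear_schedule()` applies to linear-mode schedules only")
  np <- length(schedule$breakpoints)
  violation <- NULL
  if (np > 1L) {
    for (i in seq_len(np - 1L)) {
      if (!(schedule$a[i] < schedule$a[i + 1L])) {
        violation <- sprintf("slope ordering violated: a[%d] = %g is not < a[%d] = %g",
                             i, schedule$a[i], i + 1L, schedule$a[i + 1L])
        break
      }
    }
    if (is.null(violation)) {
      issuance <- schedule$a * schedule$breakpoints + schedule$b
      for (i in seq_len(np - 1L)) {
        if (!(issuance[i] < issuance[i + 1L])) {
          violation <- sprintf(
            "issuance-value ordering violated: w(t%d) = %g is not < w(t%d) = %g",
            i, issuance[i], i + 1L, issuance[i + 1L])
          break
        }
      }
    }
  }
  structure(list(ok = is.null(violation), violation = violation),
            class = "schedule_validation")
}

#' @export
print.warning_schedule <- function(x, ...) {
  cat(sprintf("<warning_schedule: %d piece(s), mode '%s'>\n",
              length(x$breakpoints), x$mode))
  print(data.frame(t_issue = x$breakpoints, a = x$a, b = x$b,
                   w_at_issue = warning_level(x$breakpoints, x)))
  invisible(x)
}
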