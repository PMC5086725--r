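# Core metapopulation SI model: layout and parameter containers, the 3xN
# right-hand side, the fixed-step integrator with clamping, the logistic
# closed form used as a reduced-limit oracle, and demand-curve aggregation.

TYPE_LABELS <- c("impressionable", "neutral", "standpat")

#' Community layout of the risk area
#'
#' Container for the spatial and demographic description of the risk area:
#' distances of each community to the risk source, pairwise inter-community
#' distances, and the population of each of the three individual types
#' (Impressionable, Neutral, Standpat) in each community.
#'
#' @param dist_to_source Length-`n` vector of distances to the risk source,
#'   km, strictly positive.
#' @param pairwise `n x n` symmetric matrix of inter-community distances,
#'   km, zero diagonal.
#' @param populations `3 x n` non-negative matrix of group populations
#'   `Q[k, j]`; row `k = 1` is the Impressionable type, `2` Neutral,
#'   `3` Standpat.
#' @param coords Optional `n x 2` matrix of planar coordinates (km, risk
#'   source at the origin), kept for serialization and plotting.
#' @return An object of class `community_layout`.
#' @export
community_layout <- function(dist_to_source, pairwise, populations,
                             coords = NULL) {
  n <- length(dist_to_source)
  if (n < 1L) stop("at least one community is required")
  if (any(!is.finite(dist_to_source)) || any(dist_to_source <= 0))
    stop("`dist_to_source` must be strictly positive and finite")
  pairwise <- as.matrix(pairwise)
  if (!all(dim(pairwise) == c(n, n)))
    stop(sprintf("`pairwise` must be a %d x %d matrix", n, n))
  if (any(pairwise < 0)) stop("pairwise distances must be non-negative")
  if (any(abs(diag(pairwise)) > 1e-12))
    stop("`pairwise` must have a zero diagonal")
  if (!isSymmetric(unname(pairwise), tol = 1e-8))
    stop("`pairwise` must be symmetric")
  populations <- as.matrix(populations)
  if (nrow(populations) != 3L || ncol(populations) != n)
    stop(sprintf("`populations` must be a 3 x %d matrix (types x communities)", n))
  if (any(populations < 0)) stop("populations must be non-negative")
  rownames(populations) <- TYPE_LABELS
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != n || ncol(coords) != 2L)
      stop("`coords` must be an n x 2 matrix")
  }
  structure(list(n = n,
                 dist_to_source = as.numeric(dist_to_source),
                 pairwise = unname(pairwise),
                 populations = populations,
                 coords = coords),
            class = "community_layout")
}

#' @export
print.community_layout <- function(x, ...) {
  cat(sprintf("<community_layout: %d communities, %s residents>\n",
              x$n, format(round(sum(x$populations)), big.mark = ",")))
  cat(sprintf("  distance to source: %.2f - %.2f km\n",
              min(x$dist_to_source), max(x$dist_to_source)))
  invisible(x)
}

#' Model parameters
#'
#' Bundles the effective transformation rates of the three individual types
#' with the influence-function parameters. The transformation rates must be
#' strictly ordered `gamma1 > gamma2 > gamma3 > 0`: Impressionable people
#' respond more strongly than Neutral, who respond more strongly than
#' Standpat, to the same total influence.
#'
#' @param gamma Length-3 vector `(gamma1, gamma2, gamma3)` of effective
#'   transformation rates (dimensionless multipliers on the hour^-1
#'   influence sum).
#' @param kernel A [kernel_params()] object.
#' @param location A [location_params()] object.
#' @param warning A [warning_schedule()] object.
#' @return An object of class `model_parameters`.
#' @export
model_parameters <- function(gamma = c(0.5, 0.3, 0.2),
                             kernel = kernel_params(),
                             location = location_params(),
                             warning = warning_schedule(c(0, 60),
                                                        a = c(0.01, 0.2),
                                                        b = c(0.001, 0.01))) {
  if (length(gamma) != 3L || any(!is.finite(gamma)))
    stop("`gamma` must be a finite length-3 vector")
  if (!(gamma[1] > gamma[2] && gamma[2] > gamma[3] && gamma[3] > 0))
    stop("`gamma` must satisfy gamma1 > gamma2 > gamma3 > 0")
  stopifnot(inherits(kernel, "kernel_params"),
            inherits(location, "location_params"),
            inherits(warning, "warning_schedule"))
  structure(list(gamma = as.numeric(gamma), kernel = kernel,
                 location = location, warning = warning),
            class = "model_parameters")
}

#' @export
print.model_parameters <- function(x, ...) {
  cat("<model_parameters>\n")
  cat(sprintf("  gamma: %g > %g > %g\n", x$gamma[1], x$gamma[2], x$gamma[3]))
  cat(sprintf("  kernel: lambda0 = %g, alpha = %g, sigma = %g km\n",
              x$kernel$lambda0, x$kernel$alpha, x$kernel$sigma))
  cat(sprintf("  location: h(d) = %g d + %g; f '%s' with a2 = %g, b2 = %g\n",
              x$location$a1, x$location$b1, x$location$f_form,
              x$location$a2, x$location$b2))
  cat(sprintf("  warning: %d piece(s), mode '%s'\n",
              length(x$warning$breakpoints), x$warning$mode))
  invisible(x)
}

#' Initial evacuated counts
#'
#' Spreads a single observed anchor count across all `3 x n` groups. With an
#' anchor of `count` evacuated people in group `(j*, k*)` at `t = 0`, the
#' initial count in group `(j, k)` is
#' `I[j,k](0) = (gamma_k / gamma_k*) * (d[j*,0] / d[j,0])^p * (Q[j,k] / Q[j*,k*]) * count`,
#' i.e. initial evacuated fractions are proportional to the type's
#' transformation rate and inversely proportional to the `p`-th power of the
#' community's distance to the risk source (risk perception falls off
#' sharply with distance). Counts are continuous (continuum model) and
#' clamped to `[0, Q[j,k]]`.
#'
#' @param layout A [community_layout()].
#' @param params A [model_parameters()].
#' @param anchor List with elements `community` (index `j*`), `type`
#'   (index `k*`) and `count` (evacuated people in that group at `t = 0`).
#' @param p Distance exponent, default 3 (1 or 2 for a weaker distance
#'   effect).
#' @return An object of class `evac_state`: list with `t = 0` and the
#'   `3 x n` matrix `I`.
#' @export
initial_state <- function(layout, params,
                          anchor = list(community = 1, type = 1, count = 150),
                          p = 3) {
  stopifnot(inherits(layout, "community_layout"),
            inherits(params, "model_parameters"))
  j0 <- anchor$community; k0 <- anchor$type; c0 <- anchor$count
  if (is.null(j0) || is.null(k0) || is.null(c0))
    stop("`anchor` must have elements `community`, `type`, `count`")
  if (j0 < 1 || j0 > layout$n) stop("anchor community index out of range")
  if (!k0 %in% 1:3) stop("anchor type must be 1, 2 or 3")
  Q <- layout$populations
  if (c0 < 0 || c0 > Q[k0, j0])
    stop(sprintf("anchor count %g exceeds the group population %g",
                 c0, Q[k0, j0]))
  if (!is.numeric(p) || length(p) != 1L || p < 0)
    stop("`p` must be a single non-negative exponent")
  ratio_gamma <- params$gamma / params$gamma[k0]
  ratio_dist <- (layout$dist_to_source[j0] / layout$dist_to_source)^p
  I0 <- outer(ratio_gamma, ratio_dist) * (Q / Q[k0, j0]) * c0
  I0 <- pmin(pmax(I0, 0), Q)
  rownames(I0) <- TYPE_LABELS
  structure(list(t = 0, I = I0), class = "evac_state")
}

# Time-independent between-community weight matrix:
# W[i, j] = lambda(d_ij) * h(d_i0), zero diagonal. Influence received by j
# from i is I_i,total * W[i, j].
.between_weights <- function(layout, params) {
  W <- contact_kernel(layout$pairwise, params$kernel) *
    location_weight(layout$dist_to_source, params$location)
  diag(W) <- 0
  W
}

.rhs_core <- function(I, t, layout, params, W) {
  Q <- layout$populations
  Qj <- colSums(Q)
  S <- Q - I
  Itot <- colSums(I)
  social <- params$kernel$lambda0 * Itot + as.vector(crossprod(W, Itot))
  social_pc <- ifelse(Qj > 0, social / Qj, 0)
  common <- social_pc + geo_decay(layout$dist_to_source, t, params$location) +
    warning_level(t, params$warning)
  dI <- S * rep(common, each = 3L) * params$gamma
  dI
}

#' Right-hand side of the evacuation model
#'
#' Instantaneous rate of change of the evacuated counts for every group
#' `(k, j)`:
#' \deqn{dI_{jk}/dt = \gamma_k [\lambda_0 (S_{jk}/Q_j) I_j
#'   + (S_{jk}/Q_j) \sum_k \sum_{i \ne j} I_{ik}\, \lambda(d_{ij})\, h(d_{i0})
#'   + S_{jk} f(d_{j0}, t) + S_{jk} w(t)]}
#' The four bracketed terms are within-community contagion,
#' between-community contagion, geographic decay and warning forcing. All
#' entries are non-negative, and groups with no susceptibles left
#' (`S[k, j] = 0`) have exactly zero derivative.
#'
#' @param state An `evac_state` (from [initial_state()]), or a `3 x n`
#'   matrix of evacuated counts (then `t` must be given).
#' @param layout A [community_layout()].
#' @param params A [model_parameters()].
#' @param t Time in hours; taken from `state` when it is an `evac_state`.
#' @return `3 x n` matrix of derivatives `dI[k, j]/dt`, per hour.
#' @export
evac_rhs <- function(state, layout, params, t = NULL) {
  stopifnot(inherits(layout, "community_layout"),
            inherits(params, "model_parameters"))
  if (inherits(state, "evac_state")) {
    I <- state$I
    if (is.null(t)) t <- state$t
  } else {
    I <- as.matrix(state)
    if (is.null(t)) stop("`t` must be supplied when `state` is a bare matrix")
  }
  if (nrow(I) != 3L || ncol(I) != layout$n)
    stop(sprintf("state must be 3 x %d to match the layout", layout$n))
  if (any(I < -1e-9) || any(I > layout$populations + 1e-9))
    stop("state violates 0 <= I <= Q")
  .rhs_core(I, t, layout, params, .between_weights(layout, params))
}

#' Integrate the evacuation model
#'
#' Fixed-step forward-Euler integration of the `3 x n` system:
#' `I <- I + dt * rhs(I, t)`, with the state clamped to `[0, Q]` after every
#' step. Every warning issuance time within the horizon must lie on the time
#' grid, so that the discontinuous jump in `w(t)` is resolved exactly at the
#' issuance; otherwise an error asks for a compatible `dt`.
#'
#' @param layout A [community_layout()].
#' @param params A [model_parameters()].
#' @param init An `evac_state` from [initial_state()] (or a `3 x n` matrix).
#' @param dt Step size, hours (default 1).
#' @param horizon Total simulated time, hours; must be a multiple of `dt`.
#' @return An object of class `evac_trajectory`: list with `times`
#'   (length `m`), `I` (`3 x n x m` array of evacuated counts), the `layout`,
#'   `params`, `dt`, `horizon` and the number of clamping events
#'   (`clamp_events`; steps on which the Euler update overshot a group
#'   population and was truncated).
#' @export
simulate_evacuation <- function(layout, params, init, dt = 1, horizon = 120) {
  stopifnot(inherits(layout, "community_layout"),
            inherits(params, "model_parameters"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number")
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < dt)
    stop("`horizon` must be at least one step long")
  n_steps <- round(horizon / dt)
  if (abs(n_steps * dt - horizon) > 1e-8)
    stop("`horizon` must be an integer multiple of `dt`")
  times <- (0:n_steps) * dt
  bp <- params$warning$breakpoints
  bp <- bp[bp > 0 & bp <= horizon + 1e-8]
  for (tb in bp) {
    if (min(abs(times - tb)) > 1e-8)
      stop(sprintf(paste0("warning issuance time t = %g does not lie on the ",
                          "integration grid; adjust `dt` so the grid contains ",
                          "every issuance time"), tb))
  }
  I <- if (inherits(init, "evac_state")) init$I else as.matrix(init)
  if (nrow(I) != 3L || ncol(I) != layout$n)
    stop(sprintf("initial state must be 3 x %d to match the layout", layout$n))
  Q <- layout$populations
  W <- .between_weights(layout, params)
  out <- array(NA_real_, dim = c(3L, layout$n, n_steps + 1L))
  out[, , 1L] <- I
  clamp_events <- 0L
  for (s in seq_len(n_steps)) {
    dI <- .rhs_core(I, times[s], layout, params, W)
    I_new <- I + dt * dI
    if (any(I_new > Q + 1e-9)) clamp_events <- clamp_events + 1L
    I <- pmin(pmax(I_new, 0), Q)
    out[, , s + 1L] <- I
  }
  structure(list(times = times, I = out, layout = layout, params = params,
                 dt = dt, horizon = horizon, clamp_events = clamp_events),
            class = "evac_trajectory")
}

#' @export
print.evac_trajectory <- function(x, ...) {
  Qtot <- sum(x$layout$populations)
  m <- length(x$times)
  Iend <- sum(x$I[, , m])
  cat(sprintf("<evac_trajectory: %d communities, %g h horizon, dt = %g h>\n",
              x$layout$n, x$horizon, x$dt))
  cat(sprintf("  evacuated: %.0f (%.1f%%) at t = 0  ->  %.0f (%.1f%%) at t = %g\n",
              sum(x$I[, , 1]), 100 * sum(x$I[, , 1]) / Qtot,
              Iend, 100 * Iend / Qtot, x$horizon))
  invisible(x)
}

#' Logistic closed form of the reduced model
#'
#' With a single community, a single type and only within-community
#' contagion active, the model reduces to the classical SI logistic
#' equation, whose solution is
#' `I(t) = Q / (1 + (Q / I0 - 1) * exp(-rate * t))`. Used as the analytic
#' oracle for the integrator in its reduced limit, where
#' `rate = gamma * lambda0`.
#'
#' @param t Time(s), hours.
#' @param Q Total population.
#' @param I0 Initial evacuated count, strictly inside `(0, Q)`.
#' @param rate Logistic growth rate, per hour, >= 0.
#' @return Evacuated count(s) at `t`.
#' @export
closed_form_logistic <- function(t, Q, I0, rate) {
  if (!(I0 > 0 && I0 < Q)) stop("`I0` must lie strictly inside (0, Q)")
  if (rate < 0) stop("`rate` must be non-negative")
  Q / (1 + (Q / I0 - 1) * exp(-rate * t))
}

#' Aggregate a trajectory into demand curves
#'
#' Collapses the per-group trajectory into the standard demand curves: the
#' total curve `I(t)`, per-type curves `I_k(t)`, per-community curves
#' `I_j(t)` (each also as a fraction of the corresponding population), and
#' hourly increments of the total curve. The three groupings sum to the same
#' total at every grid point by construction.
#'
#' @param traj An `evac_trajectory` from [simulate_evacuation()].
#' @return A list of class `evac_demand` with data frames `total`
#'   (`t`, `I`, `fraction`), `by_type` (`t`, `type`, `I`, `fraction`),
#'   `by_community` (`t`, `community`, `I`, `fraction`) and `increments`
#'   (`hour`, `dI`, `d_fraction`; `NULL` if the grid does not contain the
#'   integer hours).
#' @export
aggregate_demand <- function(traj) {
  stopifnot(inherits(traj, "evac_trajectory"))
  Q <- traj$layout$populations
  Qtot <- sum(Q); Qk <- rowSums(Q); Qj <- colSums(Q)
  times <- traj$times
  m <- length(times)
  total <- apply(traj$I, 3L, sum)
  mat_k <- apply(traj$I, c(1L, 3L), sum)            # 3 x m
  mat_j <- apply(traj$I, c(2L, 3L), sum)            # n x m
  by_type <- data.frame(
    t = rep(times, each = 3L),
    type = rep(TYPE_LABELS, times = m),
    I = as.vector(mat_k),
    fraction = as.vector(mat_k / ifelse(Qk > 0, Qk, 1)))
  by_community <- data.frame(
    t = rep(times, each = traj$layout$n),
    community = rep(seq_len(traj$layout$n), times = m),
    I = as.vector(mat_j),
    fraction = as.vector(mat_j / ifelse(Qj > 0, Qj, 1)))
  hours <- seq(0, floor(max(times)))
  idx <- vapply(hours, function(h) which.min(abs(times - h)), integer(1))
  increments <- NULL
  if (all(abs(times[idx] - hours) < 1e-8) && length(hours) > 1L) {
    dI <- diff(total[idx])
    increments <- data.frame(hour = hours[-1L], dI = dI,
                             d_fraction = dI / Qtot)
  }
  structure(list(
    total = data.frame(t = times, I = total, fraction = total / Qtot),
    by_type = by_type,
    by_community = by_community,
    increments = increments,
    Q_total = Qtot),
    class = "evac_demand")
}

#' Plot a simulated trajectory
#'
#' Draws the total cumulative demand curve (as a fraction of the risk-area
#' population) and, when available, the hourly increments.
#'
#' @param x An `evac_trajectory`.
#' @param which `"total"`, `"increments"` or `"both"` (default).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the [aggregate_demand()] of `x`.
#' @export
plot.evac_trajectory <- function(x, which = c("both", "total", "increments"),
                                 ...) {
  which <- match.arg(which)
  agg <- aggregate_demand(x)
  if (which == "both" && !is.null(agg$increments)) {
    old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  }
  if (which %in% c("both", "total")) {
    graphics::plot(agg$total$t, agg$total$fraction, type = "l",
                   xlab = "time (h)", ylab = "evacuated fraction",
                   main = "Total evacuation demand", ...)
  }
  if (which %in% c("both", "increments") && !is.null(agg$increments)) {
    graphics::plot(agg$increments$hour, agg$increments$d_fraction, type = "h",
                   xlab = "time (h)", ylab = "hourly increase (fraction)",
                   main = "Hourly increments", ...)
  }
  invisible(agg)
}
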