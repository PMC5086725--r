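# Seeded synthetic scenario generation, including a 61-community preset
# emulating the published facts of the 2015 Tianjin-explosions evacuation
# (the true community map is unpublished, so a seeded synthetic layout
# reproducing the printed anchor distances stands in).

#' Specification for a synthetic risk-area scenario
#'
#' @param n Number of communities.
#' @param total_population Total residents in the risk area.
#' @param dist_range Length-2 range (km) of community distances to the risk
#'   source; min must be positive.
#' @param type_split Proportions of the three individual types; must sum
#'   to 1. Default: equal thirds.
#' @param population_mode `"equal"` (every community holds
#'   `total_population / n` residents) or `"random"` (seeded random
#'   proportions).
#' @param anchor Anchor initial condition passed to [initial_state()].
#' @param seed Integer seed; the same spec always generates the same layout.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(n = 61, total_population = 115350,
                          dist_range = c(0.67, 6.10),
                          type_split = c(1, 1, 1) / 3,
                          population_mode = c("equal", "random"),
                          anchor = list(community = 1, type = 1, count = 150),
                          seed = 1) {
  population_mode <- match.arg(population_mode)
  if (n < 1) stop("`n` must be at least 1")
  if (total_population <= 0) stop("`total_population` must be positive")
  if (length(dist_range) != 2L || dist_range[1] <= 0)
    stop("`dist_range` must be a length-2 range with a positive minimum")
  if (dist_range[1] > dist_range[2])
    stop("`dist_range` is infeasible (min > max)")
  if (length(type_split) != 3L || any(type_split < 0) ||
      abs(sum(type_split) - 1) > 1e-8)
    stop("`type_split` must be three non-negative proportions summing to 1")
  structure(list(n = as.integer(n), total_population = total_population,
                 dist_range = dist_range, type_split = type_split,
                 population_mode = population_mode, anchor = anchor,
                 seed = as.integer(seed)),
            class = "scenario_spec")
}

.populations_for <- function(n, total, split, mode) {
  qj <- if (mode == "equal") rep(total / n, n) else {
    w <- stats::rgamma(n, shape = 5)
    total * w / sum(w)
  }
  outer(split, qj)
}

#' Generate a synthetic community layout
#'
#' Places `n` communities at seeded random planar positions around the risk
#' source (at the origin): radial distances are drawn uniformly over
#' `dist_range` and sorted ascending, so community labels increase with
#' distance to the source; angles are uniform. Pairwise distances are
#' Euclidean (hence symmetric and metric). Populations are split across
#' communities per `population_mode` and across types per `type_split`.
#'
#' @param spec A [scenario_spec()].
#' @return A [community_layout()].
#' @export
synthetic_layout <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$seed)
  r <- sort(stats::runif(spec$n, spec$dist_range[1], spec$dist_range[2]))
  theta <- stats::runif(spec$n, 0, 2 * pi)
  coords <- cbind(r * cos(theta), r * sin(theta))
  pop <- .populations_for(spec$n, spec$total_population, spec$type_split,
                          spec$population_mode)
  community_layout(dist_to_source = r,
                   pairwise = as.matrix(stats::dist(coords)),
                   populations = pop,
                   coords = coords)
}

#' Tianjin-like case scenario
#'
#' A seeded synthetic instantiation of the 2015 Tianjin-explosions
#' evacuation case: 61 communities labelled by increasing distance to the
#' explosion source, about 115,350 residents split equally into the three
#' individual types, communities 1, 10, 27, 31 and 61 pinned to distances
#' 0.67, 2.06, 4.12, 4.21 and 6.10 km, and community 27 placed in an
#' otherwise empty angular sector so that its only nearby community is
#' community 41 (emulating its single adjacent community). Parameters follow
#' the case's reference values: `lambda0 = 0.25`,
#' `gamma = (0.5, 0.3, 0.2)`, `alpha = 0.01`, `sigma = 1`, `h(d) = d + 0.1`,
#' `f` with `a2 = b2 = 0.01`, and two warning pieces
#' `(a = 0.01, b = 0.001)` from `t = 0` and `(a = 0.2, b = 0.01)` from
#' `t = 60` h. The anchor is 150 evacuated Impressionable residents in
#' community 1 at `t = 0`.
#'
#' The true community map is unpublished; only the pinned distances, counts
#' and parameter values above are reproduced, while all remaining positions
#' are seeded-random.
#'
#' @param seed Integer seed for the unpinned coordinates.
#' @return List with elements `layout` ([community_layout()]), `params`
#'   ([model_parameters()]) and `anchor`.
#' @export
tianjin_like_scenario <- function(seed = 1) {
  set.seed(as.integer(seed))
  n <- 61L
  pins <- c(1L, 10L, 27L, 31L, 61L)
  pin_r <- c(0.67, 2.06, 4.12, 4.21, 6.10)
  r <- numeric(n)
  r[pins] <- pin_r
  fill <- function(labels, lo, hi) sort(stats::runif(length(labels), lo, hi))
  r[2:9]   <- fill(2:9,   0.67, 2.06)
  r[11:26] <- fill(11:26, 2.06, 4.12)
  r[28:30] <- fill(28:30, 4.12, 4.21)
  r[32:60] <- fill(32:60, 4.21, 6.10)
  # isolate community 27: everyone else (except its one neighbour, 41) is
  # kept out of an angular sector around it
  th_iso <- stats::runif(1, 0, 2 * pi)
  sector <- 0.7
  theta <- th_iso + stats::runif(n, sector, 2 * pi - sector)
  theta[27L] <- th_iso
  theta[41L] <- th_iso + 0.05
  coords <- cbind(r * cos(theta), r * sin(theta))
  pop <- .populations_for(n, 115350, c(1, 1, 1) / 3, "equal")
  layout <- community_layout(dist_to_source = r,
                             pairwise = as.matrix(stats::dist(coords)),
                             populations = pop,
                             coords = coords)
  params <- model_parameters(
    gamma = c(0.5, 0.3, 0.2),
    kernel = kernel_params(lambda0 = 0.25, alpha = 0.01, sigma = 1),
    location = location_params(a1 = 1, b1 = 0.1, a2 = 0.01, b2 = 0.01),
    warning = warning_schedule(c(0, 60), a = c(0.01, 0.2), b = c(0.001, 0.01),
                               mode = "hyperbolic_reset"))
  list(layout = layout, params = params,
       anchor = list(community = 1, type = 1, count = 150))
}

#' Two-community test fixture
#'
#' A minimal controlled layout of two identical communities at equal
#' distance to the risk source, separated by `d_between`. Useful for
#' isolating the between-community contagion term: as `d_between` grows the
#' Gaussian contact kernel drives the coupling to zero.
#'
#' @param d_between Separation between the two communities, km.
#' @param d_source Common distance of both communities to the risk source,
#'   km.
#' @param pop_per_type Population of each type in each community.
#' @return A [community_layout()] with `n = 2`.
#' @export
two_community_fixture <- function(d_between, d_source = 1, pop_per_type = 100) {
  if (d_between <= 0) stop("`d_between` must be positive")
  community_layout(
    dist_to_source = rep(d_source, 2L),
    pairwise = matrix(c(0, d_between, d_between, 0), 2L, 2L),
    populations = matrix(pop_per_type, 3L, 2L))
}
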