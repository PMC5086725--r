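# Layout/parameter containers, initial-condition rule, right-hand side,
# integrator and aggregation.

test_that("layout and parameter containers enforce their invariants", {
  expect_error(community_layout(c(1, -2), matrix(0, 2, 2), matrix(1, 3, 2)),
               "strictly positive")
  D <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(community_layout(c(1, 2), D, matrix(1, 3, 2)), "symmetric")
  D2 <- matrix(c(1, 2, 2, 0), 2, 2)
  expect_error(community_layout(c(1, 2), D2, matrix(1, 3, 2)), "diagonal")
  expect_error(community_layout(1, matrix(0, 1, 1), matrix(-1, 3, 1)),
               "non-negative")
  expect_error(model_parameters(gamma = c(0.3, 0.5, 0.2)), "gamma1 > gamma2")
  expect_error(model_parameters(gamma = c(0.5, 0.3, 0)), "gamma1 > gamma2")
})

test_that("initial-condition rule: anchor identity, gamma scaling, inverse-power distance", {
  lay <- community_layout(c(1, 2), matrix(c(0, 1, 1, 0), 2, 2),
                          matrix(630, 3, 2))
  par <- reference_parameters("table1")
  st <- initial_state(lay, par, list(community = 1, type = 1, count = 150))
  expect_equal(unname(st$I[1, 1]), 150)
  expect_equal(unname(st$I[3, 1]), 150 * 0.2 / 0.5)         # gamma ratio
  expect_equal(unname(st$I[1, 2]), 150 / 8)                 # doubled distance, p = 3
  st2 <- initial_state(lay, par, list(community = 1, type = 1, count = 150),
                       p = 1)
  expect_equal(unname(st2$I[1, 2]), 75)
  # anchor in a non-impressionable type keeps the identity
  st3 <- initial_state(lay, par, list(community = 1, type = 2, count = 80))
  expect_equal(unname(st3$I[2, 1]), 80)
  expect_error(
    initial_state(lay, par, list(community = 1, type = 1, count = 1e6)),
    "exceeds")
  # values are clamped into [0, Q]
  near <- community_layout(c(1, 10), matrix(c(0, 9, 9, 0), 2, 2),
                           matrix(c(100, 100, 100, 1, 1, 1), 3, 2))
  st4 <- initial_state(near, par, list(community = 2, type = 1, count = 1))
  expect_true(all(st4$I <= near$populations + 1e-12) && all(st4$I >= 0))
})

test_that("right-hand side matches hand arithmetic and annihilation cases", {
  lay <- single_type_layout(100)
  par <- logistic_limit_params()
  dI <- evac_rhs(as_state(matrix(c(20, 0, 0), 3, 1)), lay, par)
  expect_equal(unname(dI[1, 1]), 0.5 * 0.25 * (80 / 100) * 20,
               tolerance = 1e-12)
  expect_true(all(dI[2:3, ] == 0))
  # no infectives, no forcing -> zero field
  expect_true(all(evac_rhs(as_state(matrix(0, 3, 1)), lay, par) == 0))
  # saturated state -> zero field even with forcing on
  sc <- tianjin_like_scenario(3)
  full <- as_state(sc$layout$populations)
  expect_true(all(evac_rhs(full, sc$layout, sc$params) == 0))
  # everything is non-negative mid-course
  mid <- as_state(sc$layout$populations / 2)
  expect_true(all(evac_rhs(mid, sc$layout, sc$params) >= 0))
  expect_error(evac_rhs(as_state(matrix(0, 3, 2)), lay, par), "3 x 1")
})

test_that("closed-form logistic honours its boundary behaviour and domain", {
  expect_equal(closed_form_logistic(0, 100, 5, 0.3), 5)
  expect_equal(closed_form_logistic(1e6, 100, 5, 0.3), 100)
  expect_equal(closed_form_logistic(c(0, 10, 50), 100, 5, 0), rep(5, 3))
  expect_error(closed_form_logistic(1, 100, 0, 0.3), "strictly inside")
  expect_error(closed_form_logistic(1, 100, 100, 0.3), "strictly inside")
})

test_that("integrator is exact on a zero field and snaps warning breakpoints", {
  lay <- single_type_layout(100)
  par <- logistic_limit_params()
  init <- as_state(matrix(0, 3, 1))       # I = 0 and no forcing: frozen
  tr <- simulate_evacuation(lay, par, init, dt = 1, horizon = 10)
  expect_true(all(tr$I == 0))
  # a breakpoint off the grid is refused with advice
  par2 <- model_parameters(warning = warning_schedule(
    c(0, 7.5), a = c(0.01, 0.2), b = c(0.001, 0.01)))
  expect_error(
    simulate_evacuation(lay, par2, init, dt = 1, horizon = 10),
    "adjust `dt`")
  expect_error(simulate_evacuation(lay, par, init, dt = 1, horizon = 10.4),
               "multiple")
  expect_error(simulate_evacuation(lay, par, init, dt = 0, horizon = 10),
               "positive")
})

test_that("trajectories conserve population and never decrease", {
  for (seed in 1:5) {
    spec <- scenario_spec(n = 10 + 3 * seed, total_population = 30000,
                          dist_range = c(0.5, 8),
                          population_mode = if (seed %% 2) "equal" else "random",
                          seed = seed)
    lay <- synthetic_layout(spec)
    par <- reference_parameters("table1")
    init <- initial_state(lay, par,
                          list(community = 1, type = 1,
                               count = 0.2 * lay$populations[1, 1]))
    tr <- simulate_evacuation(lay, par, init, dt = 1, horizon = 120)
    expect_true(all(tr$I >= 0) && all(tr$I <= array(lay$populations,
                                                    dim = dim(tr$I)) + 1e-12))
    mono <- apply(tr$I, c(1, 2), function(z) all(diff(z) >= -1e-12))
    expect_true(all(mono))
  }
})

test_that("relabelling communities permutes the trajectory and keeps the total", {
  lay <- synthetic_layout(scenario_spec(n = 6, total_population = 6000,
                                        dist_range = c(0.5, 5), seed = 7))
  par <- reference_parameters("table1")
  perm <- c(3, 1, 6, 2, 5, 4)
  lay2 <- community_layout(lay$dist_to_source[perm],
                           lay$pairwise[perm, perm],
                           lay$populations[, perm])
  anchor <- list(community = 2, type = 1, count = 50)
  anchor2 <- list(community = which(perm == 2), type = 1, count = 50)
  tr <- simulate_evacuation(lay, par, initial_state(lay, par, anchor),
                            dt = 1, horizon = 60)
  tr2 <- simulate_evacuation(lay2, par, initial_state(lay2, par, anchor2),
                             dt = 1, horizon = 60)
  expect_equal(tr2$I, tr$I[, perm, ], tolerance = 1e-12)
  expect_equal(apply(tr2$I, 3, sum), apply(tr$I, 3, sum), tolerance = 1e-12)
})

test_that("aggregation regroups the same counts consistently", {
  sc <- tianjin_like_scenario(2)
  tr <- simulate_evacuation(sc$layout, sc$params,
                            initial_state(sc$layout, sc$params, sc$anchor),
                            dt = 1, horizon = 48)
  agg <- aggregate_demand(tr)
  m <- length(tr$times)
  tot_k <- tapply(agg$by_type$I, agg$by_type$t, sum)
  tot_j <- tapply(agg$by_community$I, agg$by_community$t, sum)
  expect_equal(as.vector(tot_k), agg$total$I, tolerance = 1e-12)
  expect_equal(as.vector(tot_j), agg$total$I, tolerance = 1e-12)
  expect_equal(sum(agg$increments$dI), agg$total$I[m] - agg$total$I[1],
               tolerance = 1e-9)
  # constant trajectory -> all increments zero
  lay <- single_type_layout(100)
  tr0 <- simulate_evacuation(lay, logistic_limit_params(),
                             as_state(matrix(0, 3, 1)), dt = 1, horizon = 12)
  expect_true(all(aggregate_demand(tr0)$increments$dI == 0))
})
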