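# Influence functions: contact kernel, location weight, geographic decay,
# warning forcing.

test_that("contact kernel evaluates the scaled Gaussian and decays with distance", {
  p <- kernel_params(lambda0 = 0.25, alpha = 0.01, sigma = 1)
  expect_equal(contact_kernel(0, p), 9.97355701e-4, tolerance = 1e-8)
  expect_equal(contact_kernel(3, kernel_params(1, 1, 2)),
               1 / (sqrt(2 * pi) * 2) * exp(-9 / 8), tolerance = 1e-12)
  expect_equal(contact_kernel(5, kernel_params(0.25, alpha = 0, sigma = 1)), 0)
  expect_lt(contact_kernel(100, p), 1e-300)
  d <- seq(0, 10, by = 0.25)
  expect_true(all(diff(contact_kernel(d, p)) < 0))
  expect_error(contact_kernel(-1, p), "non-negative")
})

test_that("contact kernel carries half-Gaussian mass over [0, Inf)", {
  for (p in list(kernel_params(0.25, 0.01, 1), kernel_params(2, 0.5, 3))) {
    mass <- stats::integrate(contact_kernel, 0, Inf, params = p,
                             rel.tol = 1e-10)$value
    expect_equal(mass, p$lambda0 * p$alpha / 2, tolerance = 1e-8)
  }
})

test_that("location weight is the linear h(d), non-decreasing, with optional cap", {
  p <- location_params(a1 = 1, b1 = 0.1)
  expect_equal(location_weight(0, p), 0.1)
  expect_equal(location_weight(4.12, p), 4.22)
  flat <- location_params(a1 = 0, b1 = 0.7)
  expect_equal(location_weight(c(0, 1, 50), flat), rep(0.7, 3))
  capped <- location_params(a1 = 1, b1 = 0.1, h_cap = 2)
  expect_equal(location_weight(10, capped), 2)
  expect_error(location_weight(-0.1, p), "non-negative")
})

test_that("geographic decay is non-increasing in distance and time, both forms", {
  p <- location_params(a2 = 0.01, b2 = 0.01)
  expect_equal(geo_decay(0, 0, p), 0.001)
  expect_equal(geo_decay(c(1, 2), 0, location_params(a2 = 0)), c(0, 0))
  d <- seq(0, 8, by = 0.5); t <- seq(0, 200, by = 10)
  expect_true(all(diff(geo_decay(d, 0, p)) <= 0))
  expect_true(all(diff(geo_decay(2, t, p)) < 0))
  sep <- location_params(a2 = 0.01, b2 = 0.01, f_form = "separable")
  expect_equal(geo_decay(2, 0, sep), 0.01 / 4 / 10)
  expect_true(all(diff(geo_decay(d[-1], 5, sep)) < 0))
  expect_true(all(diff(geo_decay(2, t, sep)) < 0))
  expect_error(geo_decay(1, -1, p), "non-negative")
})

test_that("warning forcing follows its piece algebra and is right-continuous", {
  s <- warning_schedule(c(0, 60), a = c(0.01, 0.2), b = c(0.001, 0.01))
  expect_equal(warning_level(0, s), 0.01 / 10 + 0.001)
  expect_equal(warning_level(60, s), 0.2 / 10 + 0.01)
  # decreasing within each piece, jump up at the issuance
  expect_true(all(diff(warning_level(seq(0, 59.9, by = 0.1), s)) < 0))
  expect_gt(warning_level(60, s), warning_level(59.999, s))
  expect_lt(warning_level(60, s) - warning_level(60 + 1e-9, s), 1e-8)
  g <- warning_schedule(c(0, 60), a = c(0.01, 0.2), b = c(0.001, 0.01),
                        mode = "hyperbolic_global")
  expect_equal(warning_level(60, g), 0.2 / 70 + 0.01)
  expect_equal(warning_level(c(0, 10), warning_schedule(0, a = 0, b = 0.5)),
               c(0.5, 0.5))
  expect_error(warning_level(-1, s), "non-negative")
})

test_that("schedules violating the jump-up property are rejected at construction", {
  expect_error(
    warning_schedule(c(0, 60), a = c(0.2, 0.01), b = c(0.01, 0.001)),
    "jump-up")
  # the reverse ordering of the same pieces is fine
  expect_s3_class(
    warning_schedule(c(0, 60), a = c(0.01, 0.2), b = c(0.001, 0.01)),
    "warning_schedule")
  expect_error(warning_schedule(c(0, 60, 30), a = rep(0, 3), b = 1:3),
               "strictly increasing")
  expect_error(warning_schedule(c(5, 60), a = c(0, 0), b = c(1, 2)),
               "first breakpoint")
})

test_that("linear schedule validation reports ordering violations", {
  ok <- warning_schedule(c(0, 10, 20), a = c(0.01, 0.02, 0.03),
                         b = c(0.1, 0.2, 0.3), mode = "linear")
  v <- validate_linear_schedule(ok)
  expect_true(v$ok)
  expect_null(v$violation)
  bad <- warning_schedule(c(0, 10), a = c(0.02, 0.01), b = c(0, 1),
                          mode = "linear")
  v2 <- validate_linear_schedule(bad)
  expect_false(v2$ok)
  expect_match(v2$violation, "slope ordering")
  single <- warning_schedule(0, a = 0.01, b = 0.1, mode = "linear")
  expect_true(validate_linear_schedule(single)$ok)
  expect_error(validate_linear_schedule(
    warning_schedule(0, a = 0.01, b = 0.1)), "linear")
})

test_that("influence functions stay finite and non-negative across scan ranges", {
  set.seed(42)
  rng <- reference_ranges()
  for (i in 1:25) {
    kp <- kernel_params(runif(1, 0, rng$lambda0[2]),
                        runif(1, 0, rng$alpha[2]),
                        runif(1, 1e-3, rng$sigma[2]))
    lp <- location_params(runif(1, 0, rng$a1[2]), runif(1, 0, rng$b1[2]),
                          runif(1, 0, rng$a2[2]), runif(1, 0, rng$b2[2]))
    ws <- warning_schedule(0, a = runif(1, 0, rng$a3[2]),
                           b = runif(1, 0, rng$b3[2]))
    d <- runif(5, 0, 8); t <- runif(5, 0, 150)
    vals <- c(contact_kernel(d, kp), location_weight(d, lp),
              geo_decay(d, t, lp), warning_level(t, ws))
    expect_true(all(is.finite(vals) & vals >= 0))
  }
})
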