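# Shared fixtures, all built in code.

# single community whose population sits entirely in type 1
single_type_layout <- function(Q = 100) {
  community_layout(dist_to_source = 1,
                   pairwise = matrix(0, 1, 1),
                   populations = matrix(c(Q, 0, 0), 3, 1))
}

# parameters with the between-community, geographic and warning terms off:
# the model reduces to the logistic SI limit with rate gamma * lambda0
logistic_limit_params <- function(lambda0 = 0.25, gamma = c(0.5, 0.3, 0.2)) {
  model_parameters(
    gamma = gamma,
    kernel = kernel_params(lambda0 = lambda0, alpha = 0, sigma = 1),
    location = location_params(a1 = 0, b1 = 0, a2 = 0, b2 = 0),
    warning = warning_schedule(0, a = 0, b = 0))
}

as_state <- function(I) structure(list(t = 0, I = I), class = "evac_state")

# m - 1 mutually close communities plus one far from all, all at the same
# distance to the risk source
isolation_layout <- function(m = 5, d_near = 0.5, d_far = 20, d_source = 2,
                             pop_per_type = 100) {
  D <- matrix(d_near, m, m)
  D[m, ] <- D[, m] <- d_far
  diag(D) <- 0
  community_layout(rep(d_source, m), D, matrix(pop_per_type, 3, m))
}
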