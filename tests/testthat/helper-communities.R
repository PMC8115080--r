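# small fixture builders used across test files

make_pair <- function(kappa_n = c(1.2, 0.8), kappa_t = 3, rho = 0.76,
                      Phi = 0.4, q = 0.05, tau = 1, K = c(1, 0.5),
                      xi = c(2, 3), s = c(1, 1)) {
  sp <- species_params(rho = rho, kappa_t = kappa_t, q = q, Phi = Phi, tau = tau)
  res <- lapply(seq_along(kappa_n), function(i)
    resource_params(kappa_n[i], K[i], xi[i], s[i]))
  community_params(list(sp), res)
}

# random valid state on the constraint for given params
random_state <- function(params, seed = 1) {
  with_seed_test(seed, {
    c0 <- stats::runif(params$n_resources, 0.2, 2)
    m0 <- stats::runif(params$n_species, 0.1, 1)
    targets <- matrix(stats::rexp(params$n_species * params$n_resources),
                      params$n_species)
    targets <- targets / rowSums(targets)
    phi0 <- phi_initial_on_constraint(targets, c0, params)
    community_state(m0, c0, phi0, params = params, constraint_tol = 1e-10)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# one-species-one-resource community with maintenance set from Theta
single_community <- function(Theta = 1.5, kappa_n = 1.2, kappa_t = 3,
                             rho = 0.76, Phi = 0.4, tau = 1e4, K = 1,
                             xi = 2, s = 1) {
  sp <- maintenance_from_theta(
    species_params(rho = rho, kappa_t = kappa_t, Phi = Phi, tau = tau), Theta)
  community_params(list(sp), list(resource_params(kappa_n, K, xi, s)))
}
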