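three_res <- function(tau = 1, q = 0.05)
  make_pair(kappa_n = c(1.2, 0.8, 2.1), K = c(1, 0.5, 0.2), xi = c(2, 3, 1),
            s = c(1, 1, 1), tau = tau, q = q)

test_that("constraint gradients match their closed forms and a finite difference", {
  p <- three_res()
  st <- random_state(p, seed = 2)
  g <- grad_constraint(st, p)
  r <- monod(st$c, p$K)
  expect_equal(g$grad_phi, 1 + sweep(p$gamma, 2, r, "*"))
  expect_true(all(g$grad_phi >= 1))
  expect_true(all(g$grad_c >= 0))
  # finite difference of F in c
  h <- 1e-7
  for (i in 1:3) {
    cp <- st$c; cp[i] <- cp[i] + h
    cm <- st$c; cm[i] <- cm[i] - h
    stp <- st; stp$c <- cp
    stm <- st; stm$c <- cm
    fd <- (constraint_residual(stp, p) - constraint_residual(stm, p)) / (2 * h)
    expect_equal(g$grad_c[, i], fd, tolerance = 1e-6)
  }
  # gamma = 0 freezes the constraint's c-dependence entirely
  p0 <- three_res()
  p0$gamma[] <- 0
  g0 <- grad_constraint(st, p0)
  expect_true(all(g0$grad_phi == 1))
  expect_true(all(g0$grad_c == 0))
  # single resource, gamma = 0.4, r = 0.5
  p1 <- make_pair(kappa_n = 1.2, K = 1, xi = 2, s = 1)
  st1 <- community_state(1, 1, matrix(0.2, 1, 1), p1, constraint_tol = Inf)
  expect_equal(grad_constraint(st1, p1)$grad_phi[1, 1], 1 + p1$gamma[1, 1] * 0.5)
})

test_that("slow drift conserves the constraint and is parallel to its normal", {
  p <- three_res()
  for (seed in 1:10) {
    st <- random_state(p, seed = seed)
    cdot <- with_seed_test(seed + 100, rnorm(3))
    d <- phi_drift_slow(st, cdot, p)
    g <- grad_constraint(st, p)
    # F_dot = phi_dot . grad_phi + c_dot . grad_c = 0
    fdot <- rowSums(d * g$grad_phi) + as.numeric(g$grad_c %*% cdot)
    expect_lt(max(abs(fdot)), 1e-12)
    # parallel to grad_phi: cross terms vanish
    ratio <- d / g$grad_phi
    expect_lt(max(abs(ratio - ratio[, 1])), 1e-12)
  }
  st <- random_state(p, seed = 1)
  expect_true(all(phi_drift_slow(st, c(0, 0, 0), p) == 0))
})

test_that("integrating the slow drift reproduces the single-resource closed form", {
  # prescribe c(t) and integrate d(phi)/dt; the allocation must track
  # Phi / (1 + gamma r(c(t)))
  p <- make_pair(kappa_n = 1.2, K = 1, xi = 2, s = 1)
  gam <- p$gamma[1, 1]
  c_of_t <- function(t) 1 + 0.8 * sin(t / 2)
  cdot_of_t <- function(t) 0.4 * cos(t / 2)
  phi0 <- single_resource_phi(p$Phi[1], gam, monod(c_of_t(0), 1))
  rhs <- function(t, y, parms) {
    st <- community_state(1, c_of_t(t), matrix(y, 1, 1), p,
                          constraint_tol = Inf)
    list(as.numeric(phi_drift_slow(st, cdot_of_t(t), p)))
  }
  ts <- seq(0, 10, length.out = 51)
  sol <- deSolve::ode(phi0, ts, rhs, NULL, rtol = 1e-10, atol = 1e-12)
  expected <- sapply(ts, function(t)
    single_resource_phi(p$Phi[1], gam, monod(c_of_t(t), 1)))
  expect_equal(unname(sol[, 2]), expected, tolerance = 1e-6)
})

test_that("adaptive drift reduces to the slow law when adaptation is off", {
  p <- three_res(tau = 1e12)   # above the infinite-tau threshold
  st <- random_state(p, seed = 4)
  cdot <- c(0.1, -0.2, 0.05)
  expect_equal(phi_drift_adaptive(st, cdot, p, drift_options()),
               phi_drift_slow(st, cdot, p))
  # single resource: the tangent space is trivial, so any tau gives slow
  p1 <- make_pair(kappa_n = 1.2, K = 1, xi = 2, s = 1, tau = 0.01)
  st1 <- random_state(p1, seed = 5)
  expect_equal(phi_drift_adaptive(st1, -0.3, p1, drift_options()),
               phi_drift_slow(st1, -0.3, p1), tolerance = 1e-12)
})

test_that("adaptive drift conserves the constraint and climbs the growth gradient", {
  p <- three_res(tau = 0.5)
  for (seed in 1:10) {
    st <- random_state(p, seed = seed)
    cdot <- with_seed_test(seed + 200, rnorm(3))
    d <- phi_drift_adaptive(st, cdot, p, drift_options())
    g <- grad_constraint(st, p)
    fdot <- rowSums(d * g$grad_phi) + as.numeric(g$grad_c %*% cdot)
    expect_lt(max(abs(fdot)), 1e-10)
    # the difference from the slow drift is orthogonal to the normal
    dd <- d - phi_drift_slow(st, cdot, p)
    expect_lt(max(abs(rowSums(dd * g$grad_phi))), 1e-10)
    # with static c, the tangential component increases growth
    d0 <- phi_drift_adaptive(st, c(0, 0, 0), p, drift_options())
    gg <- sweep(p$eta, 2, monod(st$c, p$K), "*")
    expect_gte(sum(d0 * gg), -1e-12)
  }
})

test_that("positivity correction freezes outward boundary components only", {
  p <- three_res()
  st <- random_state(p, seed = 6)
  cdot <- c(-0.2, 0.1, 0)
  d <- phi_drift_adaptive(st, cdot, p, drift_options())
  # interior state: unchanged
  expect_equal(apply_positivity(d, st, p), d)
  # put one component at the boundary with outward raw drift
  st$phi[1, 2] <- 0
  d2 <- matrix(c(0.01, -0.05, 0.02), 1)
  dc <- apply_positivity(d2, st, p)
  expect_equal(dc[1, 2], 0)
  gp <- grad_constraint(st, p)$grad_phi
  # the corrected drift changes F at the same rate as the raw drift
  expect_equal(sum(dc * gp), sum(d2 * gp), tolerance = 1e-12)
  # inward drift at the boundary is left alone
  d3 <- matrix(c(0.01, 0.05, 0.02), 1)
  expect_equal(apply_positivity(d3, st, p), d3)
})

test_that("fast optimum is the best-payoff vertex with deterministic ties", {
  p <- three_res()
  cc <- c(0.5, 1.5, 0.1)
  phi <- fast_optimal_phi(cc, p, 1)
  r <- monod(cc, p$K)
  payoff <- p$eta[1, ] * r / (1 + p$gamma[1, ] * r)
  j <- which.max(payoff)
  expect_equal(which(phi > 0), j)
  st <- community_state(1, cc, matrix(phi, 1), p)
  expect_equal(constraint_residual(st, p)[1], 0, tolerance = 1e-14)
  # enumeration oracle: no other vertex does better
  vert_growth <- sapply(1:3, function(i) {
    v <- rep(0, 3); v[i] <- p$Phi[1] / (1 + p$gamma[1, i] * r[i])
    sum(p$eta[1, ] * r * v)
  })
  expect_equal(sum(p$eta[1, ] * r * phi), max(vert_growth), tolerance = 1e-14)
  # exact tie breaks to the lowest resource index
  pt <- make_pair(kappa_n = c(1, 1), K = c(1, 1), xi = c(1, 1), s = c(1, 1))
  phit <- fast_optimal_phi(c(2, 2), pt, 1)
  expect_gt(phit[1], 0)
  expect_equal(phit[2], 0)
  # single resource reduces to the closed form
  p1 <- make_pair(kappa_n = 1.2, K = 1, xi = 2, s = 1)
  expect_equal(fast_optimal_phi(1, p1, 1),
               single_resource_phi(p1$Phi[1], p1$gamma[1, 1], 0.5))
  expect_warning(fast_optimal_phi(c(0, 0, 0), p, 1), "zero")
})

test_that("adaptive flow at fixed concentrations reaches the optimal vertex", {
  p <- three_res(tau = 0.05)
  cc <- c(0.6, 1.2, 0.3)
  target <- fast_optimal_phi(cc, p, 1)
  st0 <- random_state(p, seed = 8)
  rhs <- function(t, y, parms) {
    st <- st0
    st$phi <- matrix(pmax(y, 0), 1)
    st$c <- cc
    d <- phi_drift_adaptive(st, c(0, 0, 0), p, drift_options())
    list(as.numeric(apply_positivity(d, st, p, zero_tol = 1e-10)))
  }
  st0$c <- cc
  phi_start <- phi_initial_on_constraint(matrix(1 / 3, 1, 3), cc, p)
  sol <- deSolve::ode(as.numeric(phi_start), seq(0, 20, 0.5), rhs, NULL,
                      rtol = 1e-9, atol = 1e-11)
  final <- pmax(sol[nrow(sol), -1], 0)
  expect_equal(unname(final), target, tolerance = 1e-6)
  # growth never decreases along the flow
  r <- monod(cc, p$K)
  gvals <- apply(sol[, -1, drop = FALSE], 1, function(ph)
    sum(p$eta[1, ] * r * ph))
  expect_true(all(diff(gvals) > -1e-9))
})

test_that("a two-resource depletion sequence produces a diauxic support switch", {
  # resource 1 is depleted while resource 2 stays rich: a fast adapter
  # reallocates from the exhausted to the remaining resource
  p <- make_pair(kappa_n = c(1.2, 1.0), K = c(0.1, 0.1), xi = c(2, 2),
                 s = c(0, 0), tau = 0.05, q = 0.01)
  c0 <- c(1, 6)
  phi0 <- phi_initial_on_constraint(matrix(c(0.95, 0.05), 1), c0, p)
  init <- community_state(0.2, c0, phi0, params = p)
  traj <- simulate_cpr(p, init, 30, drift_options(), n_out = 301)
  # initially the species prefers resource 1; as it is drawn down the
  # payoff ranking flips and the allocation switches support to resource 2
  # while plenty of it remains
  phi_before <- traj$phi[2, 1, ]
  expect_gt(phi_before[1], phi_before[2])
  k_switch <- which(traj$phi[, 1, 2] > traj$phi[, 1, 1] & traj$c[, 2] > 1)
  expect_gt(length(k_switch), 0)
  # and resource 1 is the first to be (mostly) consumed
  expect_lt(traj$c[k_switch[1], 1] / traj$c[1, 1], 0.5)
})
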