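pack_state <- function(state) c(state$m, state$c, as.vector(state$phi))

unpack_state <- function(y, params) {
  ns <- params$n_species; nr <- params$n_resources
  list(m = y[seq_len(ns)],
       c = y[ns + seq_len(nr)],
       phi = matrix(y[ns + nr + seq_len(ns * nr)], ns, nr))
}

# Project each phi row back onto its constraint hyperplane F = 0 along the
# normal (1 + gamma r), clipping negative components and re-projecting on the
# reduced support. Repairs accumulated floating-point drift.
project_phi <- function(phi, c, params) {
  r <- resource_response(params, pmax(c, 0))
  bracket <- 1 + sweep(params$gamma, 2, r, "*")
  for (s in seq_len(params$n_species)) {
    b <- bracket[s, ]
    row <- phi[s, ]
    free <- rep(TRUE, length(row))
    repeat {
      resid <- sum(row[free] * b[free]) - params$Phi[s]
      row[free] <- row[free] - b[free] * resid / sum(b[free]^2)
      neg <- free & row < 0
      if (!any(neg)) break
      row[neg] <- 0
      free <- free & !neg
      if (!any(free)) break
    }
    phi[s, ] <- row
  }
  phi
}

# Smooth counterpart of apply_positivity() for use inside the ODE
# right-hand side: outward drift is shrunk by the continuous factor
# phi/(phi + eps) instead of being switched off, and the shrunken
# contribution is redistributed along the constraint normal with weights
# proportional to phi (so boundary components absorb nothing). This keeps
# F_dot = 0 exactly while making the right-hand side continuous in the
# state, which the discontinuous active-set correction is not -- a
# discontinuity at the phi = 0 boundary makes adaptive step-size control
# chatter. As eps -> 0 this reduces to the exact active-set correction.
smooth_positivity <- function(phi_dot, phi, grad_phi, eps = 1e-6) {
  shrink <- ifelse(phi_dot < 0, phi / (phi + eps), 1)
  d <- phi_dot * shrink
  deficit <- rowSums((phi_dot - d) * grad_phi)
  wt <- phi * grad_phi^2
  alpha <- deficit / pmax(rowSums(wt), .Machine$double.xmin)
  d + (phi * grad_phi) * alpha
}

# The right-hand side is evaluated tens of thousands of times per run, so
# it is written allocation-lean: column-index expansion instead of sweep(),
# and the drift laws inlined rather than dispatched through the exported
# (shape-checking) API. The algebra is identical to phi_drift_slow() /
# phi_drift_adaptive() + smooth_positivity(), which the tests cross-check.
cpr_derivative <- function(params, options) {
  ns <- params$n_species; nr <- params$n_resources
  i_m <- seq_len(ns); i_c <- ns + seq_len(nr); i_phi <- ns + nr + seq_len(ns * nr)
  colidx <- as.vector(col(params$eta))
  eta <- params$eta; gamma <- params$gamma
  q <- params$q; s_in <- params$s; xi <- params$xi; K <- params$K
  inv_tau <- ifelse(params$tau < options$tau_infinite_threshold,
                    1 / params$tau, 0)
  adaptive <- options$mode == "adaptive"
  positivity <- options$positivity
  r_fn <- params$r_fn; r_deriv_fn <- params$r_deriv_fn
  function(t, y, parms) {
    m <- y[i_m]
    cc <- pmax(y[i_c], 0)
    phi <- matrix(pmax(y[i_phi], 0), ns, nr)
    r <- r_fn(cc, K)
    rcol <- r[colidx]
    err <- eta * rcol              # d(growth)/d(phi)
    gross <- rowSums(err * phi)
    mdot <- m * (gross - q)
    cdot <- s_in - xi * r * as.numeric(crossprod(phi, m))
    gp <- 1 + gamma * rcol         # d(F)/d(phi)
    gc_dot <- (phi * gamma * r_deriv_fn(cc, K)[colidx]) %*% cdot
    norm2 <- rowSums(gp * gp)
    if (adaptive) {
      gg <- err * inv_tau
      lambda <- (rowSums(gg * gp) + gc_dot) / norm2
      phidot <- gg - gp * as.numeric(lambda)
    } else {
      phidot <- -gp * as.numeric(gc_dot / norm2)
    }
    if (positivity)
      phidot <- smooth_positivity(phidot, phi, gp)
    list(c(mdot, cdot, phidot))
  }
}

#' Simulate the CPR community dynamics
#'
#' Integrates the full consumer-proteome-resource system: biomass growth
#' minus maintenance, resource supply minus consumption, and the slow or
#' adaptive proteome-allocation drift, using an adaptive-step stiff-capable
#' solver (deSolve's `lsoda`). After every `project_every`-th output time
#' each allocation row is projected back onto its constraint hyperplane to
#' repair floating-point drift.
#'
#' @param params A [community_params()].
#' @param init A [community_state()] satisfying the proteome constraint to
#'   1e-8 (violating states are rejected).
#' @param t_end Integration horizon (hours).
#' @param options A [drift_options()].
#' @param n_out Number of equally spaced output times (ignored when `times`
#'   is given).
#' @param times Optional explicit output-time vector starting at 0.
#' @param rtol,atol Solver tolerances (defaults 1e-8, 1e-10).
#' @param project_every Project the allocation onto the constraint at every
#'   `project_every`-th output time (default 1; 0 disables projection).
#' @param method deSolve integration method (default `"lsoda"`).
#' @param maxsteps Maximum internal solver steps per output interval;
#'   resource depletion can make the system stiff, so the default is
#'   generous (1e5).
#' @return A `cpr_trajectory`: list with `times`, biomass matrix `m`
#'   (time x species), concentration matrix `c` (time x resources),
#'   allocation array `phi` (time x species x resources), a `diagnostics`
#'   data frame (per-time max constraint residual and gross growth rates),
#'   an event log, and the `params`/`options` used.
#' @export
simulate_cpr <- function(params, init, t_end, options = drift_options(),
                         n_out = 201, times = NULL, rtol = 1e-8, atol = 1e-10,
                         project_every = 1, method = "lsoda",
                         maxsteps = 1e5) {
  check_shapes(init, params)
  if (t_end <= 0) stop("`t_end` must be positive")
  res0 <- constraint_residual(init, params)
  if (max(abs(res0)) > 1e-8)
    stop(sprintf("initial state violates the proteome constraint (max residual %.3g)",
                 max(abs(res0))))
  if (is.null(times)) times <- seq(0, t_end, length.out = n_out)
  if (times[1] != 0) stop("`times` must start at 0")

  events <- NULL
  if (project_every > 0) {
    idx <- seq_along(times)[-1]
    etimes <- times[idx[idx %% project_every == 0]]
    if (length(etimes)) {
      efun <- function(t, y, parms) {
        st <- unpack_state(y, params)
        phi <- project_phi(pmax(st$phi, 0), st$c, params)
        c(st$m, pmax(st$c, 0), as.vector(phi))
      }
      events <- list(func = efun, time = etimes)
    }
  }

  sol <- deSolve::ode(y = pack_state(init), times = times,
                      func = cpr_derivative(params, options), parms = NULL,
                      method = method, rtol = rtol, atol = atol,
                      maxsteps = maxsteps, events = events)
  sol <- unname(as.matrix(sol))
  if (nrow(sol) < length(times)) {
    last <- unpack_state(sol[nrow(sol), -1], params)
    err <- simpleError(sprintf(
      "integration stopped early at t = %.6g (step-size control failed)", sol[nrow(sol), 1]))
    err$last_valid_state <- last
    stop(err)
  }
  if (any(!is.finite(sol))) {
    ok <- which(apply(is.finite(sol), 1, all))
    last <- if (length(ok)) unpack_state(sol[max(ok), -1], params) else init
    err <- simpleError("integration failed: non-finite state encountered")
    err$last_valid_state <- last
    stop(err)
  }
  as_trajectory(sol, params, options, events_log = list())
}

as_trajectory <- function(sol, params, options, events_log = list()) {
  ns <- params$n_species; nr <- params$n_resources
  times <- sol[, 1]
  m <- sol[, 1 + seq_len(ns), drop = FALSE]
  cc <- sol[, 1 + ns + seq_len(nr), drop = FALSE]
  phi <- array(sol[, -(1:(1 + ns + nr)), drop = FALSE],
               dim = c(length(times), ns, nr))
  # sub-atol negative excursions are solver noise on non-negative quantities
  m[m < 0] <- 0
  cc[cc < 0] <- 0
  phi[phi < 0] <- 0
  diag <- data.frame(time = times, max_residual = NA_real_,
                     max_gross_growth = NA_real_)
  for (k in seq_along(times)) {
    st <- list(m = m[k, ], c = cc[k, ], phi = matrix(phi[k, , ], ns, nr))
    class(st) <- "community_state"
    diag$max_residual[k] <- max(abs(constraint_residual(st, params)))
    diag$max_gross_growth[k] <- max(growth_rates(st, params)$gross)
  }
  structure(list(times = times, m = m, c = cc, phi = phi,
                 diagnostics = diag, events = events_log,
                 params = params, options = options),
            class = "cpr_trajectory")
}

#' @export
print.cpr_trajectory <- function(x, ...) {
  cat(sprintf("CPR trajectory: %d species, %d resources, t in [%.3g, %.3g] h, %d output points\n",
              x$params$n_species, x$params$n_resources,
              min(x$times), max(x$times), length(x$times)))
  cat(sprintf("  max constraint residual: %.3g\n", max(x$diagnostics$max_residual)))
  invisible(x)
}

#' Extract a community state from a trajectory
#'
#' @param traj A `cpr_trajectory`.
#' @param index Time index (default: the last output point).
#' @return A [community_state()].
#' @export
state_at <- function(traj, index = length(traj$times)) {
  ns <- traj$params$n_species; nr <- traj$params$n_resources
  st <- list(m = traj$m[index, ], c = traj$c[index, ],
             phi = matrix(traj$phi[index, , ], ns, nr))
  class(st) <- "community_state"
  st
}

#' Serial-dilution (batch-transfer) protocol
#'
#' @param D Dilution factor (> 1), e.g. 100 for a daily 1:100 transfer.
#' @param cycle_hours Interval between transfers (hours).
#' @param n_cycles Number of growth cycles.
#' @param fresh_c Resource concentrations of the fresh medium (length `N_R`).
#' @param carryover Carry over spent medium at fraction `1/D` instead of
#'   resetting resources to `fresh_c` alone (default `FALSE`).
#' @param T_growth Effective growth-window length (hours) used by the
#'   Heaviside fast mode; defaults to `cycle_hours`.
#' @return A list of class `dilution_protocol`.
#' @export
dilution_protocol <- function(D, cycle_hours, n_cycles, fresh_c,
                              carryover = FALSE, T_growth = NULL) {
  if (D <= 1) stop("`D` must exceed 1")
  if (cycle_hours <= 0) stop("`cycle_hours` must be positive")
  if (n_cycles < 1) stop("`n_cycles` must be at least 1")
  if (any(fresh_c < 0)) stop("`fresh_c` must be non-negative")
  structure(list(D = D, cycle_hours = cycle_hours, n_cycles = n_cycles,
                 fresh_c = fresh_c, carryover = carryover,
                 T_growth = if (is.null(T_growth)) cycle_hours else T_growth),
            class = "dilution_protocol")
}

#' Simulate serial-dilution growth cycles
#'
#' Repeated batch growth with periodic transfer into fresh medium. In
#' `"ode"` mode each cycle integrates the full CPR system; at every transfer
#' biomasses are divided by `D` and resource concentrations are reset to the
#' fresh-medium values (optionally plus a `1/D` carry-over of spent medium),
#' after which each allocation row is re-projected onto its constraint
#' hyperplane at the new concentrations. In `"heaviside"` mode the uptake
#' response is approximated by a step function of time (growth at `r = 1`
#' for `T_growth` hours, then arrest), giving the closed-form biomass
#' `m^(N) = m^(0) D^-(N-1) exp(N eta Phi T / (1 + gamma))` at the `N`-th
#' transfer; this mode uses the first resource's capacities and requires no
#' integration.
#'
#' @param params A [community_params()].
#' @param init A [community_state()].
#' @param protocol A [dilution_protocol()].
#' @param options A [drift_options()] (ode mode only).
#' @param mode `"ode"` or `"heaviside"`.
#' @param n_out_per_cycle Output points per cycle in ode mode.
#' @param ... Further arguments passed to [simulate_cpr()].
#' @return A `cpr_trajectory` (ode mode: concatenated cycles with transfer
#'   events logged; heaviside mode: states at the transfer times).
#' @export
simulate_serial_dilution <- function(params, init, protocol,
                                     options = drift_options(),
                                     mode = c("ode", "heaviside"),
                                     n_out_per_cycle = 21, ...) {
  mode <- match.arg(mode)
  if (mode == "heaviside") return(heaviside_dilution(params, init, protocol))
  check_shapes(init, params)
  state <- init
  sols <- list()
  events_log <- list()
  t0 <- 0
  for (n in seq_len(protocol$n_cycles)) {
    traj <- simulate_cpr(params, state, protocol$cycle_hours,
                         options = options, n_out = n_out_per_cycle, ...)
    sol <- cbind(traj$times + t0,
                 traj$m, traj$c,
                 matrix(traj$phi, nrow = length(traj$times)))
    sols[[n]] <- if (n == 1) sol else sol[-1, , drop = FALSE]
    t0 <- t0 + protocol$cycle_hours
    st <- state_at(traj)
    m_new <- st$m / protocol$D
    c_new <- protocol$fresh_c + if (protocol$carryover) st$c / protocol$D else 0
    phi_new <- project_phi(st$phi, c_new, params)
    state <- community_state(m_new, c_new, phi_new)
    events_log[[n]] <- list(type = "dilution", time = t0, cycle = n,
                            D = protocol$D)
  }
  as_trajectory(do.call(rbind, sols), params, options, events_log = events_log)
}

heaviside_dilution <- function(params, init, protocol) {
  g <- params$eta[, 1] * params$Phi / (1 + params$gamma[, 1])
  Tg <- protocol$T_growth
  N <- 0:protocol$n_cycles
  m <- t(vapply(N, function(n) {
    if (n == 0) init$m
    else init$m * protocol$D^(-(n - 1)) * exp(n * g * Tg)
  }, numeric(params$n_species)))
  phi_row <- params$Phi / (1 + params$gamma[, 1])   # allocation at r = 1
  phi1 <- matrix(0, params$n_species, params$n_resources)
  phi1[, 1] <- phi_row
  times <- N * protocol$cycle_hours
  sol <- cbind(times, m,
               matrix(rep(protocol$fresh_c, each = length(N)), length(N)),
               matrix(rep(as.vector(phi1), each = length(N)), length(N)))
  traj <- as_trajectory(sol, params, drift_options(), events_log = list())
  traj$diagnostics$max_residual <- 0   # closed form, constraint not tracked
  traj$mode <- "heaviside"
  traj
}

#' Detect stationarity of a trajectory
#'
#' A trajectory is stationary if, over the trailing `window`, the relative
#' rate of change `|x_dot| / (|x| + eps)` of every state component stays
#' below `tol`, where biomasses below the extinction threshold are excluded
#' (an extinct species decays forever without ever being exactly constant).
#' Rates are estimated by finite differences between stored output times.
#'
#' @param traj A `cpr_trajectory`.
#' @param window Trailing window length in hours (default: 10% of the
#'   horizon).
#' @param tol Relative-rate tolerance (1/h, default 1e-6).
#' @param eps Regularizer in the denominator (default 1e-30).
#' @param extinction_threshold Relative biomass below which a species is
#'   ignored (default 1e-8 of the initial total biomass).
#' @return List with `stationary` (logical), the final `state`, and the
#'   maximum observed relative rate `max_rate`.
#' @export
detect_stationarity <- function(traj, window = NULL, tol = 1e-6,
                                eps = 1e-30, extinction_threshold = 1e-8) {
  tmax <- max(traj$times)
  if (is.null(window)) window <- 0.1 * tmax
  if (window >= tmax) stop("`window` must be shorter than the trajectory")
  keep <- traj$times >= tmax - window
  if (sum(keep) < 2) stop("too few output points inside `window`")
  m0_total <- sum(traj$m[1, ])
  alive <- traj$m[nrow(traj$m), ] > extinction_threshold * m0_total
  x <- cbind(traj$m[keep, alive, drop = FALSE], traj$c[keep, , drop = FALSE],
             matrix(traj$phi[keep, , ], nrow = sum(keep)))
  dt <- diff(traj$times[keep])
  rates <- abs(diff(x)) / dt / (abs(x[-1, , drop = FALSE]) + eps)
  max_rate <- max(rates)
  list(stationary = max_rate < tol, state = state_at(traj),
       max_rate = max_rate)
}

#' Classify surviving species
#'
#' A species survives if its (stationary) biomass exceeds `threshold` times
#' the total initial biomass.
#'
#' @param stationary_state A [community_state()] (or `cpr_trajectory`, in
#'   which case its final state is used).
#' @param init The initial [community_state()].
#' @param threshold Relative biomass threshold (default 1e-8).
#' @return Logical survivor mask (length `N_S`).
#' @export
classify_survivors <- function(stationary_state, init, threshold = 1e-8) {
  if (inherits(stationary_state, "cpr_trajectory"))
    stationary_state <- state_at(stationary_state)
  stationary_state$m > threshold * sum(init$m)
}
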