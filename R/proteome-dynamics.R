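#' Options for the proteome-allocation drift
#'
#' @param mode `"adaptive"` (growth-maximizing relaxation on the constraint
#'   hyperplane, the default) or `"slow"` (the minimal law in which the
#'   allocation is only dragged along by the moving constraint).
#' @param positivity Apply the active-set correction that keeps all proteome
#'   fractions non-negative (default `TRUE`).
#' @param tau_infinite_threshold Adaptation timescales above this value (in
#'   hours) are treated as infinite: the adaptive term is dropped
#'   analytically instead of being evaluated, avoiding underflow.
#' @param zero_tol Fractions below this value count as sitting on the zero
#'   boundary for the positivity correction.
#' @return A list of class `drift_options`.
#' @export
drift_options <- function(mode = c("adaptive", "slow"), positivity = TRUE,
                          tau_infinite_threshold = 1e6, zero_tol = 1e-12) {
  mode <- match.arg(mode)
  if (tau_infinite_threshold <= 0) stop("`tau_infinite_threshold` must be positive")
  structure(list(mode = mode, positivity = positivity,
                 tau_infinite_threshold = tau_infinite_threshold,
                 zero_tol = zero_tol),
            class = "drift_options")
}

#' Gradients of the proteome-finiteness constraint
#'
#' For each species `s`, the constraint function
#' `F_s = sum_i phi[s,i] (1 + gamma[s,i] r_i(c_i)) - Phi[s]` has gradients
#' `dF/dphi[s,i] = 1 + gamma[s,i] r_i(c_i)` (always >= 1) and
#' `dF/dc[s,i] = phi[s,i] gamma[s,i] r_i'(c_i)` (non-negative, zero wherever
#' `gamma` vanishes).
#'
#' @inheritParams uptake_rates
#' @return List with matrices `grad_phi` and `grad_c`, both `N_S x N_R`.
#' @export
grad_constraint <- function(state, params) {
  check_shapes(state, params)
  r <- resource_response(params, state$c)
  rp <- resource_response_deriv(params, state$c)
  grad_phi <- 1 + sweep(params$gamma, 2, r, "*")
  grad_c <- state$phi * sweep(params$gamma, 2, rp, "*")
  list(grad_phi = grad_phi, grad_c = grad_c)
}

# growth-rate gradient dg_s/dphi[s,i] = eta[s,i] r_i(c_i)
grad_growth <- function(state, params) {
  r <- resource_response(params, state$c)
  sweep(params$eta, 2, r, "*")
}

#' Constraint-dragged ("slow") allocation drift
#'
#' The minimal time derivative of each species' allocation row that keeps
#' the proteome-finiteness constraint satisfied as resource concentrations
#' change: the row is dragged along the constraint normal,
#' `phi_dot = -(grad_phi F / |grad_phi F|^2) (c_dot . grad_c F)`.
#' When all `gamma` are ~0 the constraint hyperplane barely moves and the
#' allocation is effectively frozen.
#'
#' @inheritParams uptake_rates
#' @param cdot Time derivative of the resource concentrations (length `N_R`).
#' @return `N_S x N_R` drift matrix.
#' @export
phi_drift_slow <- function(state, cdot, params) {
  check_shapes(state, params)
  g <- grad_constraint(state, params)
  drag <- as.numeric(g$grad_c %*% cdot)        # c_dot . grad_c F, per species
  -g$grad_phi * (drag / rowSums(g$grad_phi^2))
}

#' Adaptive (growth-maximizing) allocation drift
#'
#' Each species' allocation row relaxes towards higher instantaneous growth
#' at rate `1/tau` while staying on its (moving) constraint hyperplane:
#' the growth gradient is projected onto the hyperplane's tangent space and
#' the constraint-dragging term of [phi_drift_slow()] is added. In the
#' `tau -> Inf` limit the law reduces exactly to the slow drift; rows whose
#' `tau` exceeds `options$tau_infinite_threshold` take that limit
#' analytically.
#'
#' @inheritParams phi_drift_slow
#' @param options A [drift_options()] object.
#' @return `N_S x N_R` drift matrix.
#' @export
phi_drift_adaptive <- function(state, cdot, params,
                               options = drift_options()) {
  check_shapes(state, params)
  g <- grad_constraint(state, params)
  gp <- g$grad_phi
  norm2 <- rowSums(gp^2)
  drag <- as.numeric(g$grad_c %*% cdot)
  gg <- grad_growth(state, params) / params$tau
  finite <- params$tau < options$tau_infinite_threshold
  gg[!finite, ] <- 0                            # analytic tau -> Inf limit
  lambda <- (rowSums(gg * gp) + drag) / norm2
  gg - gp * lambda
}

#' Positivity-preserving active-set correction
#'
#' The raw slow/adaptive drift can push a proteome fraction that sits at
#' zero further negative. This correction freezes such components (those at
#' the boundary with outward drift) and redistributes the frozen
#' contribution along the constraint normal restricted to the remaining
#' components, so the corrected drift still conserves the constraint
#' (`F_dot = 0`) exactly. Components at zero whose raw drift points inward
#' are left untouched and may re-enter the support. The clamping is
#' iterated until the active set is stable.
#'
#' @param phi_dot Raw drift matrix from [phi_drift_slow()] or
#'   [phi_drift_adaptive()].
#' @inheritParams uptake_rates
#' @param zero_tol Boundary tolerance on `phi` (default 1e-12).
#' @return Corrected `N_S x N_R` drift matrix.
#' @export
apply_positivity <- function(phi_dot, state, params, zero_tol = 1e-12) {
  check_shapes(state, params)
  gp <- grad_constraint(state, params)$grad_phi
  out <- phi_dot
  for (s in seq_len(params$n_species)) {
    d <- out[s, ]
    phi <- state$phi[s, ]
    gps <- gp[s, ]
    clamped <- rep(FALSE, length(d))
    repeat {
      newly <- !clamped & phi <= zero_tol & d < 0
      if (!any(newly)) break
      clamped <- clamped | newly
      excess <- sum(phi_dot[s, clamped] * gps[clamped])
      free <- !clamped
      if (!any(free)) {
        if (abs(excess) > 1e-12)
          stop(sprintf("species %d: all proteome fractions clamped at zero; constraint cannot be maintained", s))
        d <- rep(0, length(d))
        break
      }
      d <- phi_dot[s, ]
      d[clamped] <- 0
      d[free] <- d[free] + gps[free] * excess / sum(gps[free]^2)
    }
    out[s, ] <- d
  }
  out
}

#' Growth-optimal allocation at fixed resource levels
#'
#' The `tau -> 0` limit of the adaptive dynamics: the allocation row of one
#' species that maximizes its gross growth rate
#' `sum_i eta[s,i] r_i phi[s,i]` subject to the proteome-finiteness
#' constraint and `phi >= 0`. The objective and constraint are both linear
#' in `phi`, so the optimum is a vertex of the feasible simplex: all weight
#' goes to the resource(s) with the largest per-unit-budget payoff
#' `eta r / (1 + gamma r)`; exact ties break deterministically to the lowest
#' resource index.
#'
#' @param c Resource concentration vector (length `N_R`).
#' @param params A [community_params()].
#' @param species_index Which species' row to optimize.
#' @return Allocation row (length `N_R`) satisfying the constraint exactly.
#' @export
fast_optimal_phi <- function(c, params, species_index = 1) {
  s <- species_index
  r <- resource_response(params, c)
  bracket <- 1 + params$gamma[s, ] * r
  payoff <- params$eta[s, ] * r / bracket
  if (all(payoff == 0)) {
    warning("all uptake responses are zero; returning an arbitrary feasible vertex")
    j <- 1L
  } else {
    j <- which.max(payoff)          # ties break to the lowest index
  }
  phi <- rep(0, params$n_resources)
  phi[j] <- params$Phi[s] / bracket[j]
  phi
}
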