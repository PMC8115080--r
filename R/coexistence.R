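#' Species coexistence constant Theta
#'
#' `Theta = Phi / (rho q) - 1 / kappa_t`. At a stationary state in which
#' every species retains a full allocation support and species outnumber
#' resources, all species must share the same value of `Theta`; this is
#' equivalent to the maintenance cost being proportional to the metabolic
#' proteome budget, `q proportional to Phi`, with a species-dependent
#' constant.
#'
#' @param species A [species_params()] with `q` set.
#' @return The species' Theta value (`Inf` with a warning when `q = 0`).
#' @export
theta_of_species <- function(species) {
  stopifnot(inherits(species, "species_params"))
  if (is.na(species$q)) stop("species has no maintenance cost `q`")
  if (species$q == 0) {
    warning("q = 0: Theta is infinite")
    return(Inf)
  }
  species$Phi / (species$rho * species$q) - 1 / species$kappa_t
}

#' Maintenance cost from a target Theta
#'
#' Inverts [theta_of_species()]: `q = Phi / (rho (Theta + 1/kappa_t))`.
#' Building every species of a community this way enforces the shared-Theta
#' coexistence condition exactly, with `q` proportional to `Phi` at fixed
#' `rho`, `kappa_t` and `Theta`.
#'
#' @param species A [species_params()] (its `q` is replaced).
#' @param Theta Target constant, positive.
#' @return The species with `q` set.
#' @export
maintenance_from_theta <- function(species, Theta) {
  stopifnot(inherits(species, "species_params"))
  if (Theta <= 0) stop("`Theta` must be positive")
  species$q <- species$Phi / (species$rho * (Theta + 1 / species$kappa_t))
  species
}

#' Stationary resource levels implied by Theta
#'
#' At a coexistence stationary state the uptake response of every resource
#' settles at `r* = 1 / (kappa_n Theta)`, giving the concentration
#' `c* = K / (kappa_n Theta - 1)` under the Monod response. Feasibility
#' requires `r* < 1`, i.e. `Theta > 1 / kappa_n` for every resource.
#'
#' @param Theta The shared coexistence constant, positive.
#' @param resources List of [resource_params()] (or a [community_params()],
#'   whose resources are used).
#' @return List with `r_star`, `c_star`, `feasible` and the indices of any
#'   `infeasible_resources`.
#' @export
stationary_concentrations <- function(Theta, resources) {
  if (Theta <= 0) stop("`Theta` must be positive")
  if (inherits(resources, "community_params")) {
    kappa_n <- resources$kappa_n; K <- resources$K
  } else {
    if (inherits(resources, "resource_params")) resources <- list(resources)
    kappa_n <- vapply(resources, `[[`, numeric(1), "kappa_n")
    K <- vapply(resources, `[[`, numeric(1), "K")
  }
  r_star <- 1 / (kappa_n * Theta)
  bad <- which(r_star >= 1)
  c_star <- ifelse(r_star < 1, K / (kappa_n * Theta - 1), Inf)
  list(r_star = r_star, c_star = c_star,
       feasible = length(bad) == 0, infeasible_resources = bad)
}

#' Stationary levels for non-overlapping specialists
#'
#' When each species consumes exactly one resource and no two species share
#' a resource (non-overlapping niches, possible when `N_S <= N_R`), species
#' coexist without the shared-Theta requirement: each assigned resource
#' settles at `r* = 1 / (kappa_n_i (Phi/(rho q) - 1/kappa_t))` computed from
#' its sole consumer. Resources with no consumer accumulate without bound
#' (`c_dot = s`).
#'
#' @param params A [community_params()].
#' @param assignment Integer vector mapping each species to the resource it
#'   consumes; must be injective.
#' @return List with `r_star` (per resource, `NA` when unassigned) and the
#'   logical vector `unbounded` marking unconsumed resources.
#' @export
nonoverlapping_stationary <- function(params, assignment) {
  stopifnot(length(assignment) == params$n_species)
  if (anyDuplicated(assignment))
    stop("`assignment` must be injective (non-overlapping niches); overlapping species require the shared-Theta condition")
  if (any(assignment < 1 | assignment > params$n_resources))
    stop("`assignment` indexes a non-existent resource")
  r_star <- rep(NA_real_, params$n_resources)
  for (s in seq_len(params$n_species)) {
    i <- assignment[s]
    theta_s <- params$Phi[s] / (params$rho[s] * params$q[s]) - 1 / params$kappa_t[s]
    r_star[i] <- 1 / (params$kappa_n[i] * theta_s)
  }
  list(r_star = r_star, unbounded = is.na(r_star))
}

#' Rescaled simplex coordinates
#'
#' Maps supply rates and allocation rows onto the `(N_R - 1)`-simplex used
#' by the convex-hull coexistence condition:
#' `s_hat_i = (s_i kappa_n_i / xi_i) / sum_j (s_j kappa_n_j / xi_j)`,
#' `phi_hat[s, i] = phi[s, i] / sum_j phi[s, j]`, and, when stationary
#' biomasses are given, the hull weights
#' `z_s = m*_s rho_s q_s / sum_l m*_l rho_l q_l`. `s_hat` is invariant under
#' a global rescaling `s -> x s` of the supply.
#'
#' @param params A [community_params()].
#' @param phi Allocation matrix (`N_S x N_R`); no row may be all zero.
#' @param m_star Optional stationary biomass vector for the weights `z`.
#' @return List of class `simplex_coords` with `s_hat`, `phi_hat` and
#'   (optionally) `z`.
#' @export
rescale_to_simplex <- function(params, phi, m_star = NULL) {
  phi <- as.matrix(phi)
  w <- params$s * params$kappa_n / params$xi
  if (sum(w) <= 0) stop("supply rates are all zero; `s_hat` is undefined")
  s_hat <- w / sum(w)
  row_sums <- rowSums(phi)
  zero <- which(row_sums <= 0)
  if (length(zero))
    stop(sprintf("allocation row(s) %s are all zero and cannot be rescaled",
                 paste(zero, collapse = ", ")))
  phi_hat <- phi / row_sums
  z <- NULL
  if (!is.null(m_star)) {
    if (any(m_star < 0)) stop("`m_star` must be non-negative")
    zw <- m_star * params$rho * params$q
    if (sum(zw) <= 0) stop("all hull weights are zero")
    z <- zw / sum(zw)
  }
  structure(list(s_hat = s_hat, phi_hat = phi_hat, z = z),
            class = "simplex_coords")
}

# Least squares over the probability simplex: min ||t(W) z - b||^2 subject
# to sum(z) = 1, z >= 0. Active-set method in the Lawson-Hanson style with
# the equality constraint carried through the KKT system; dimensions here
# are tiny (tens of species, a handful of resources), so dense solves are
# fine. Deterministic and robust in degenerate (collinear) configurations.
simplex_lsq <- function(W, b) {
  A <- t(W)                       # nr x ns
  ns <- ncol(A)
  if (ns == 1) return(1)
  z <- rep(1 / ns, ns)
  free <- rep(TRUE, ns)
  obj_prev <- Inf
  solve_free <- function(free) {
    k <- sum(free)
    Af <- A[, free, drop = FALSE]
    H <- crossprod(Af) + diag(1e-12, k)
    K <- rbind(cbind(H, rep(1, k)), c(rep(1, k), 0))
    sol <- solve(K, c(crossprod(Af, b), 1))
    list(z = sol[seq_len(k)], lambda = sol[k + 1])
  }
  for (iter in seq_len(20 * ns + 20)) {
    s <- solve_free(free)
    if (all(s$z >= -1e-12)) {
      z[free] <- pmax(s$z, 0)
      z[!free] <- 0
      resid_vec <- A %*% z - b
      obj <- sum(resid_vec^2)
      grad <- as.numeric(crossprod(A, resid_vec))
      mu <- grad - s$lambda       # multipliers of the clamped bounds
      cand <- which(!free & mu < -1e-9 * max(1, max(abs(grad))))
      # anti-cycling: on ties between optimal supports the objective stops
      # decreasing; accept the current vertex weights then
      if (!length(cand) || obj_prev - obj < 1e-15) return(z / sum(z))
      obj_prev <- obj
      free[cand[which.min(mu[cand])]] <- TRUE
    } else {
      zcur <- z[free]
      d <- s$z - zcur
      neg <- which(s$z < 0 & d < 0)
      alpha <- min(zcur[neg] / (zcur[neg] - s$z[neg]))
      znew <- zcur + alpha * d
      idx <- which(free)
      z[idx] <- pmax(znew, 0)
      free[idx[znew <= 1e-14]] <- FALSE
      if (!any(free)) free[idx[1]] <- TRUE
    }
  }
  warning("simplex least squares reached the iteration cap")
  z / sum(z)
}

#' Convex-hull coexistence condition
#'
#' Tests whether the rescaled supply vector lies in the convex hull of the
#' rescaled allocation rows, i.e. whether weights `z >= 0`, `sum z = 1`
#' exist with `s_hat = sum_s z_s phi_hat[s, ]`. All species can only
#' coexist at stationarity when this holds for the stationary allocations.
#' Membership is decided by exact projection onto the hull (active-set
#' least squares over the weight simplex, robust in degenerate, collinear
#' configurations); points on the hull boundary count as inside.
#'
#' @param s_hat Rescaled supply vector (sums to 1).
#' @param phi_hat_rows Matrix of rescaled allocation rows (rows sum to 1).
#' @param tol Slack tolerance (default 1e-9).
#' @return List with `inside` (logical), the recovered weights `z`, the
#'   reconstruction `residual` (max-norm), and, when outside, a separating
#'   `certificate` direction `w` with `w . s_hat > max_s w . phi_hat[s, ]`
#'   (the projection residual, separating by the projection theorem).
#' @export
hull_condition <- function(s_hat, phi_hat_rows, tol = 1e-9) {
  phi_hat_rows <- as.matrix(phi_hat_rows)
  if (nrow(phi_hat_rows) < 1) stop("need at least one allocation row")
  if (length(s_hat) != ncol(phi_hat_rows))
    stop("`s_hat` and `phi_hat_rows` disagree on the number of resources")
  z <- simplex_lsq(phi_hat_rows, s_hat)
  recon <- as.numeric(crossprod(phi_hat_rows, z))
  resid <- max(abs(s_hat - recon))
  inside <- resid <= max(tol, 1e-12)
  list(inside = inside, z = z, residual = resid,
       certificate = if (!inside) s_hat - recon else NULL)
}

#' Ternary plot of the coexistence simplex
#'
#' Draws the 2-simplex for a three-resource system with the rescaled supply
#' point, the initial and (optionally) stationary rescaled allocations, and
#' their convex hulls, in the style used to visualize the hull condition.
#'
#' @param coords_init A `simplex_coords` for the initial allocations.
#' @param coords_star Optional `simplex_coords` for the stationary
#'   allocations.
#' @param file Optional path to an SVG file; when `NULL` the current device
#'   is used.
#' @param main Plot title.
#' @return Invisibly, the 2D coordinates used.
#' @export
plot_simplex <- function(coords_init, coords_star = NULL, file = NULL,
                         main = "Coexistence simplex") {
  if (length(coords_init$s_hat) != 3)
    stop("ternary plot requires exactly 3 resources")
  to2d <- function(p) cbind(p[, 2] + 0.5 * p[, 3], sqrt(3) / 2 * p[, 3])
  if (!is.null(file)) {
    grDevices::svg(file, width = 6, height = 5.5)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot(NA, xlim = c(-0.05, 1.05), ylim = c(-0.05, 0.95),
                 asp = 1, axes = FALSE, xlab = "", ylab = "", main = main)
  tri <- to2d(diag(3))
  graphics::polygon(tri[, 1], tri[, 2], border = "black")
  graphics::text(tri[, 1], tri[, 2], labels = paste0("R", 1:3), pos = c(1, 1, 3))
  draw_hull <- function(pts2, col) {
    if (nrow(pts2) >= 3) {
      h <- grDevices::chull(pts2)
      graphics::polygon(pts2[h, 1], pts2[h, 2], border = col,
                        col = grDevices::adjustcolor(col, alpha.f = 0.15))
    } else {
      graphics::lines(pts2[, 1], pts2[, 2], col = col)
    }
  }
  pi2 <- to2d(coords_init$phi_hat)
  draw_hull(pi2, "darkorange")
  graphics::points(pi2, pch = 17, col = "darkorange")
  if (!is.null(coords_star)) {
    ps2 <- to2d(coords_star$phi_hat)
    draw_hull(ps2, "purple")
    graphics::points(ps2, pch = 19, col = "purple")
  }
  s2 <- to2d(matrix(coords_init$s_hat, 1))
  graphics::points(s2, pch = 8, cex = 1.6, lwd = 2)
  invisible(list(init = pi2, supply = s2))
}
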