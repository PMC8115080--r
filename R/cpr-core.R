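#' Monod uptake response
#'
#' Saturating response `r(c) = c / (K + c)` of the per-enzyme uptake (and
#' growth) machinery to the concentration of a resource. `r` is
#' dimensionless, increases monotonically from `r(0) = 0` towards 1, and
#' equals 1/2 at the half-saturation concentration `K`.
#'
#' @param c Resource concentration (mass/volume), non-negative. Vectorized.
#' @param K Half-saturation concentration (mass/volume), positive.
#' @return Values of `r(c)` in `[0, 1)`.
#' @seealso [monod_deriv()] for the derivative used by the allocation drift.
#' @examples
#' monod(0, 1)    # 0
#' monod(2, 2)    # 0.5 at half-saturation
#' @export
monod <- function(c, K) {
  if (any(!is.finite(K)) || any(K <= 0)) stop("`K` must be positive and finite")
  if (any(!is.finite(c)) || any(c < 0)) stop("`c` must be non-negative and finite")
  c / (K + c)
}

#' Derivative of the Monod response
#'
#' @param c Resource concentration, non-negative.
#' @param K Half-saturation concentration, positive.
#' @return `dr/dc = K / (K + c)^2`.
#' @export
monod_deriv <- function(c, K) {
  if (any(!is.finite(K)) || any(K <= 0)) stop("`K` must be positive and finite")
  if (any(!is.finite(c)) || any(c < 0)) stop("`c` must be non-negative and finite")
  K / (K + c)^2
}

#' Resource parameters
#'
#' Parameters of one substitutable resource in the CPR model. Units follow
#' the growth-law literature: time in hours, concentrations and biomass in a
#' consistent mass/volume unit, capacities in ug protein / ug RNA / h.
#'
#' @param kappa_n Nutritional capacity: protein biomass produced per unit
#'   ribosomal mass per hour attributable to the resource's quality.
#' @param K Half-saturation concentration of the uptake response.
#' @param xi Maximum catalytic rate of the metabolizing enzyme (resource mass
#'   per unit protein mass per hour).
#' @param s Constant external supply rate (mass/volume per hour); zero for
#'   batch growth.
#' @return An object of class `resource_params`.
#' @export
resource_params <- function(kappa_n, K, xi, s = 0) {
  stopifnot(length(kappa_n) == 1, length(K) == 1, length(xi) == 1, length(s) == 1)
  if (kappa_n <= 0) stop("`kappa_n` must be positive")
  if (K <= 0) stop("`K` must be positive")
  if (xi <= 0) stop("`xi` must be positive")
  if (s < 0) stop("`s` must be non-negative")
  structure(list(kappa_n = kappa_n, K = K, xi = xi, s = s),
            class = "resource_params")
}

#' Species parameters
#'
#' Physiological parameters of one species (or strain). The total fraction
#' `Phi` of the proteome available for metabolism and biomass synthesis can
#' either be given directly or derived as `1 - phi_Q - phi_0` from the
#' housekeeping fraction and the incompressible ribosomal core; when all
#' three are supplied their consistency is validated.
#'
#' @param rho Conversion factor between ribosomal protein mass and total RNA
#'   mass (dimensionless, ~0.76 for E. coli).
#' @param kappa_t Translational capacity (ug protein / ug RNA / h).
#' @param q Maintenance cost (1/h): minimum energy expenditure rate; net
#'   growth is gross growth minus `q`. May be `NA` and filled in later via
#'   [maintenance_from_theta()].
#' @param Phi Total metabolic + growth proteome fraction, in (0, 1).
#' @param phi_0 Incompressible ribosomal fraction (optional).
#' @param phi_Q Housekeeping fraction (optional).
#' @param tau Characteristic timescale (hours) of the adaptive proteome
#'   reallocation; large `tau` means slow switching between resources.
#' @return An object of class `species_params`.
#' @export
species_params <- function(rho, kappa_t, q = NA_real_, Phi = NULL,
                           phi_0 = NULL, phi_Q = NULL, tau = 1) {
  if (rho <= 0) stop("`rho` must be positive")
  if (kappa_t <= 0) stop("`kappa_t` must be positive")
  if (tau <= 0) stop("`tau` must be positive")
  if (!is.na(q) && q < 0) stop("`q` must be non-negative")
  if (is.null(Phi)) {
    if (is.null(phi_0) || is.null(phi_Q))
      stop("either `Phi` or both `phi_0` and `phi_Q` must be given")
    Phi <- 1 - phi_Q - phi_0
  } else if (!is.null(phi_0) && !is.null(phi_Q)) {
    if (abs(Phi - (1 - phi_Q - phi_0)) > 1e-12)
      stop("inconsistent proteome sectors: Phi != 1 - phi_Q - phi_0")
  }
  if (Phi <= 0 || Phi >= 1) stop("`Phi` must lie in (0, 1)")
  if (!is.null(phi_0) && phi_0 <= 0) stop("`phi_0` must be positive")
  if (!is.null(phi_Q) && phi_Q <= 0) stop("`phi_Q` must be positive")
  structure(list(rho = rho, kappa_t = kappa_t, q = q, Phi = Phi,
                 phi_0 = phi_0, phi_Q = phi_Q, tau = tau),
            class = "species_params")
}

#' Community parameter set
#'
#' Bundles species and resource parameters and precomputes the derived
#' coefficient matrices of the CPR model: `eta[s, i] = kappa_n[i] / rho[s]`
#' (growth yield of allocation), `gamma[s, i] = kappa_n[i] / kappa_t[s]`
#' (nutritional over translational capacity) and
#' `chi[s, i] = kappa_n[i] / (rho[s] * xi[i])` (growth per unit uptake), so
#' that `chi * xi = eta` holds exactly.
#'
#' The uptake response is pluggable: any monotone saturating function with
#' `r(0) = 0` and unit large-`c` limit may replace the default Monod form.
#'
#' @param species List of [species_params()] objects (length `N_S >= 1`).
#' @param resources List of [resource_params()] objects (length `N_R >= 1`).
#' @param r_fn Uptake response `function(c, K)`; default [monod()].
#' @param r_deriv_fn Its derivative in `c`; default [monod_deriv()].
#' @return An object of class `community_params` with vectorized parameter
#'   fields (`rho`, `kappa_t`, `q`, `Phi`, `tau`, `kappa_n`, `K`, `xi`, `s`)
#'   and derived matrices `eta`, `gamma`, `chi`.
#' @export
community_params <- function(species, resources,
                             r_fn = monod, r_deriv_fn = monod_deriv) {
  if (inherits(species, "species_params")) species <- list(species)
  if (inherits(resources, "resource_params")) resources <- list(resources)
  stopifnot(length(species) >= 1, length(resources) >= 1)
  if (!all(vapply(species, inherits, logical(1), "species_params")))
    stop("`species` must be a list of species_params")
  if (!all(vapply(resources, inherits, logical(1), "resource_params")))
    stop("`resources` must be a list of resource_params")
  gs <- function(f) vapply(species, function(x) x[[f]], numeric(1))
  gr <- function(f) vapply(resources, function(x) x[[f]], numeric(1))
  p <- list(
    n_species = length(species), n_resources = length(resources),
    species = species, resources = resources,
    rho = gs("rho"), kappa_t = gs("kappa_t"), q = gs("q"),
    Phi = gs("Phi"), tau = gs("tau"),
    kappa_n = gr("kappa_n"), K = gr("K"), xi = gr("xi"), s = gr("s"),
    r_fn = r_fn, r_deriv_fn = r_deriv_fn)
  p$eta <- outer(1 / p$rho, p$kappa_n)
  p$gamma <- outer(1 / p$kappa_t, p$kappa_n)
  p$chi <- sweep(p$eta, 2, p$xi, "/")
  structure(p, class = "community_params")
}

#' @export
print.community_params <- function(x, ...) {
  cat(sprintf("CPR community parameters: %d species, %d resources\n",
              x$n_species, x$n_resources))
  cat(sprintf("  Phi: [%s]\n", paste(signif(x$Phi, 3), collapse = ", ")))
  cat(sprintf("  gamma range: [%.3g, %.3g]; tau range: [%.3g, %.3g]\n",
              min(x$gamma), max(x$gamma), min(x$tau), max(x$tau)))
  invisible(x)
}

# uptake response r_i(c_i) as a length-N_R vector; r_fn must be vectorized
# in both arguments (the default Monod form is)
resource_response <- function(params, c) {
  params$r_fn(c, params$K)
}

resource_response_deriv <- function(params, c) {
  params$r_deriv_fn(c, params$K)
}

#' Community state
#'
#' Instantaneous state of the community: biomass densities `m`, resource
#' concentrations `c` and the proteome-fraction matrix `phi` (`N_S x N_R`),
#' whose row for species `s` gives the fractions of its proteome allocated
#' to the uptake and metabolization of each resource.
#'
#' @param m Biomass density vector (length `N_S`), non-negative.
#' @param c Resource concentration vector (length `N_R`), non-negative.
#' @param phi Proteome-fraction matrix, non-negative.
#' @param params Optional [community_params()]; when given, shapes are
#'   checked and the per-species proteome-finiteness constraint must hold to
#'   `constraint_tol`.
#' @param constraint_tol Tolerance on the constraint residual (default 1e-8).
#' @return An object of class `community_state`.
#' @export
community_state <- function(m, c, phi, params = NULL, constraint_tol = 1e-8) {
  phi <- as.matrix(phi)
  if (any(m < 0)) stop("biomasses `m` must be non-negative")
  if (any(c < 0)) stop("concentrations `c` must be non-negative")
  if (any(phi < 0)) stop("proteome fractions `phi` must be non-negative")
  if (length(m) != nrow(phi) || length(c) != ncol(phi))
    stop("shape mismatch between `m`, `c` and `phi`")
  st <- structure(list(m = as.numeric(m), c = as.numeric(c), phi = phi),
                  class = "community_state")
  if (!is.null(params)) {
    check_shapes(st, params)
    res <- constraint_residual(st, params)
    if (max(abs(res)) > constraint_tol)
      stop(sprintf("initial state violates the proteome constraint (max residual %.3g > %.3g)",
                   max(abs(res)), constraint_tol))
  }
  st
}

check_shapes <- function(state, params) {
  if (length(state$m) != params$n_species ||
      length(state$c) != params$n_resources ||
      !all(dim(state$phi) == c(params$n_species, params$n_resources)))
    stop("state dimensions do not match the community parameters")
  invisible(TRUE)
}

#' Per-species resource uptake rates
#'
#' `J[s, i] = xi[i] * r_i(c_i) * phi[s, i]`: the rate at which species `s`
#' takes up resource `i` per unit biomass, proportional to the proteome
#' fraction it allocates to that resource.
#'
#' @param state A [community_state()].
#' @param params A [community_params()].
#' @return `N_S x N_R` matrix of uptake rates.
#' @export
uptake_rates <- function(state, params) {
  check_shapes(state, params)
  r <- resource_response(params, state$c)
  sweep(state$phi, 2, params$xi * r, "*")
}

#' Gross and net growth rates
#'
#' The gross growth rate of species `s` is the sum over resources of the
#' per-resource contributions `g^(i) = chi[s,i] * J[s,i]`, equivalently
#' `sum_i eta[s,i] * r_i(c_i) * phi[s,i]`. The net rate subtracts the
#' maintenance cost `q`.
#'
#' @inheritParams uptake_rates
#' @return List with `gross` and `net` vectors (length `N_S`) and the
#'   per-resource contribution matrix `per_resource`.
#' @export
growth_rates <- function(state, params) {
  check_shapes(state, params)
  r <- resource_response(params, state$c)
  per <- sweep(params$eta, 2, r, "*") * state$phi
  gross <- rowSums(per)
  list(gross = gross, net = gross - params$q, per_resource = per)
}

#' Proteome-finiteness constraint residual
#'
#' Signed residual `F_s = sum_i phi[s,i] * (1 + gamma[s,i] * r_i(c_i)) -
#' Phi[s]` of the per-species constraint expressing that metabolic and the
#' associated ribosomal proteome investments together exhaust the
#' non-housekeeping budget. A valid state has `F = 0` for every species.
#'
#' @inheritParams uptake_rates
#' @return Numeric vector of residuals (length `N_S`).
#' @export
constraint_residual <- function(state, params) {
  check_shapes(state, params)
  r <- resource_response(params, state$c)
  bracket <- 1 + sweep(params$gamma, 2, r, "*")
  rowSums(state$phi * bracket) - params$Phi
}

#' Single-resource proteome fraction
#'
#' With one resource the constraint fixes the metabolic fraction uniquely:
#' `phi = Phi / (1 + gamma * r)`. The fraction decreases as the resource
#' becomes more available, because less catabolic protein is needed.
#'
#' @param Phi Total metabolic + growth fraction, in (0, 1).
#' @param gamma Capacity ratio `kappa_n / kappa_t`, positive.
#' @param r Uptake response value in `[0, 1]`.
#' @return The metabolic proteome fraction, in `(0, Phi]`.
#' @export
single_resource_phi <- function(Phi, gamma, r) {
  if (any(Phi <= 0) || any(Phi >= 1)) stop("`Phi` must lie in (0, 1)")
  if (any(gamma <= 0)) stop("`gamma` must be positive")
  if (any(r < 0) || any(r > 1)) stop("`r` must lie in [0, 1]")
  Phi / (1 + gamma * r)
}

#' Capacity ratios gamma and eta
#'
#' Computes the two dimensionless ratios that govern the CPR dynamics:
#' `gamma = kappa_n / kappa_t` (resource quality relative to translation
#' speed) and `eta = kappa_n / rho` (growth-rate yield per unit of metabolic
#' proteome allocation, 1/h).
#'
#' @param kappa_n Nutritional capacity, positive.
#' @param kappa_t Translational capacity, positive.
#' @param rho Ribosomal-protein/RNA conversion factor, positive.
#' @return List with elements `gamma` and `eta`.
#' @examples
#' capacity_ratios(1.2, 3.0, 0.76)  # E. coli on glucose at 30 C
#' @export
capacity_ratios <- function(kappa_n, kappa_t, rho) {
  if (any(kappa_n <= 0) || any(kappa_t <= 0) || any(rho <= 0))
    stop("all capacities must be positive")
  list(gamma = kappa_n / kappa_t, eta = kappa_n / rho)
}
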