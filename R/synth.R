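# seeded evaluation that leaves the caller's RNG state untouched
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# independent sub-streams per component, so adding one draw type does not
# perturb the others; kept below 2^31 - 1
subseed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + stream * 104729) %% 2147483629 + 1
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

# uniform draw on the simplex (normalized exponentials)
runif_simplex <- function(n, d) {
  x <- matrix(stats::rexp(n * d), n, d)
  x / rowSums(x)
}

default_ranges <- function(regime) {
  base <- list(kappa_t = c(2, 4), Phi = c(0.3, 0.5), xi = c(1, 10),
               K = c(0.1, 1), s = c(1, 10), m0 = c(0.01, 0.1),
               c0 = c(0.1, 1), theta_factor = c(1.2, 1.8), rho = 0.76)
  extra <- switch(regime,
    slow_lowgamma  = list(kappa_n = c(0.3, 0.6), kappa_t = c(4, 8),
                          tau = c(1e6, 1e7)),
    slow_highgamma = list(kappa_n = c(4, 12), tau = c(1e3, 1e4)),
    fast           = list(kappa_n = c(0.5, 3), tau = c(0.1, 1)))
  utils::modifyList(base, extra)
}

#' Synthetic community scenario specification
#'
#' Declares a randomized community in one of the three dynamical regimes of
#' the CPR model: `"slow_lowgamma"` (adaptation far slower than the
#' ecological dynamics, `tau` in 1e6-1e7 h, and low resource quality
#' `gamma <= 0.15`: allocations effectively frozen), `"slow_highgamma"`
#' (slow but finite adaptation, `tau` in 1e3-1e4 h, with `gamma >= 1`:
#' allocations reposition during long rich-resource transients), and
#' `"fast"` (`tau <= 1` h: allocations relax quickly to the growth
#' optimum). Sampling ranges are log-uniform for capacities, catalytic
#' rates, half-saturations and supplies, uniform for `Phi`, with `rho`
#' fixed at 0.76 unless overridden.
#'
#' @param N_S,N_R Numbers of species and resources.
#' @param seed Integer seed; all generation is a pure function of
#'   `(spec, seed)`.
#' @param regime One of `"slow_lowgamma"`, `"slow_highgamma"`, `"fast"`.
#' @param shared_theta Set every species' maintenance cost from a single
#'   shared coexistence constant Theta (default `TRUE`), the necessary
#'   condition for full coexistence when `N_S > N_R`.
#' @param x Supply-rate multiplier (`s -> x s`; leaves the rescaled supply
#'   point unchanged).
#' @param y Adaptation-timescale multiplier (`tau -> y tau`).
#' @param ranges Optional named list overriding individual sampling ranges.
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(N_S = 10, N_R = 3, seed = 1,
                          regime = c("slow_lowgamma", "slow_highgamma", "fast"),
                          shared_theta = TRUE, x = 1, y = 1, ranges = NULL) {
  regime <- match.arg(regime)
  if (N_S < 1 || N_R < 1) stop("`N_S` and `N_R` must be at least 1")
  if (x <= 0 || y <= 0) stop("`x` and `y` must be positive")
  rg <- default_ranges(regime)
  if (!is.null(ranges)) {
    unknown <- setdiff(names(ranges), names(rg))
    if (length(unknown))
      stop("unknown range name(s): ", paste(unknown, collapse = ", "))
    rg[names(ranges)] <- ranges
  }
  bad <- vapply(rg, function(v) any(v <= 0) || (length(v) == 2 && v[2] < v[1]),
                logical(1))
  if (any(bad)) stop("ranges must be positive and ordered: ",
                     paste(names(rg)[bad], collapse = ", "))
  structure(list(N_S = N_S, N_R = N_R, seed = seed, regime = regime,
                 shared_theta = shared_theta, x = x, y = y, ranges = rg),
            class = "scenario_spec")
}

#' Generate a random community and constraint-consistent initial state
#'
#' Draws species and resource parameters from the spec's ranges, sets
#' maintenance costs from a shared Theta (sampled above the feasibility
#' bound `max_i 1/kappa_n_i`) when `shared_theta` is on, and builds an
#' initial state whose allocation rows sit exactly on each species'
#' constraint hyperplane at the initial concentrations (random simplex
#' directions rescaled by the unique positive factor).
#'
#' @param spec A [scenario_spec()].
#' @return List with `params` ([community_params()]) and `init`
#'   ([community_state()]).
#' @export
random_community <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  rg <- spec$ranges
  drawn <- with_seed(subseed(spec$seed, 1), {
    kappa_n <- runif_log(spec$N_R, rg$kappa_n[1], rg$kappa_n[2])
    resources <- lapply(seq_len(spec$N_R), function(i)
      resource_params(kappa_n = kappa_n[i],
                      K = runif_log(1, rg$K[1], rg$K[2]),
                      xi = runif_log(1, rg$xi[1], rg$xi[2]),
                      s = spec$x * runif_log(1, rg$s[1], rg$s[2])))
    theta_shared <- stats::runif(1, rg$theta_factor[1], rg$theta_factor[2]) *
      max(1 / kappa_n)
    species <- lapply(seq_len(spec$N_S), function(s) {
      sp <- species_params(rho = rg$rho[1],
                           kappa_t = runif_log(1, rg$kappa_t[1], rg$kappa_t[2]),
                           Phi = stats::runif(1, rg$Phi[1], rg$Phi[2]),
                           tau = spec$y * runif_log(1, rg$tau[1], rg$tau[2]))
      theta_s <- if (spec$shared_theta) theta_shared
                 else stats::runif(1, rg$theta_factor[1], rg$theta_factor[2]) *
                      max(1 / kappa_n)
      maintenance_from_theta(sp, theta_s)
    })
    list(species = species, resources = resources)
  })
  params <- community_params(drawn$species, drawn$resources)
  init <- with_seed(subseed(spec$seed, 2), {
    m0 <- runif_log(spec$N_S, rg$m0[1], rg$m0[2])
    c0 <- runif_log(spec$N_R, rg$c0[1], rg$c0[2])
    targets <- runif_simplex(spec$N_S, spec$N_R)
    phi0 <- phi_initial_on_constraint(targets, c0, params)
    community_state(m0, c0, phi0, params = params, constraint_tol = 1e-10)
  })
  list(params = params, init = init)
}

#' Place allocation rows on the constraint at chosen simplex positions
#'
#' Given target rescaled allocation directions (rows on the simplex), scales
#' each row by the unique positive factor that puts it exactly on the
#' corresponding species' proteome-constraint hyperplane at concentrations
#' `c0`. Rescaling the result back to the simplex reproduces the targets.
#'
#' @param target_hat_phi Matrix of simplex rows (`N_S x N_R`, rows sum to 1,
#'   entries non-negative, no all-zero row).
#' @param c0 Resource concentrations at which the constraint is evaluated.
#' @param params A [community_params()].
#' @return Allocation matrix `phi` satisfying the constraint exactly.
#' @export
phi_initial_on_constraint <- function(target_hat_phi, c0, params) {
  target_hat_phi <- as.matrix(target_hat_phi)
  if (any(target_hat_phi < 0)) stop("target rows must be non-negative")
  if (any(rowSums(target_hat_phi) <= 0)) stop("target rows must not be all zero")
  r <- resource_response(params, c0)
  bracket <- 1 + sweep(params$gamma, 2, r, "*")
  scale <- params$Phi / rowSums(target_hat_phi * bracket)
  target_hat_phi * scale
}

#' Re-aim the supply point relative to the initial allocation hull
#'
#' Replaces the supply rates so that the rescaled supply vector `s_hat`
#' lands at a prescribed simplex position: the centroid of the rescaled
#' initial allocations (`where = "inside"`), a point pushed beyond the hull
#' towards the simplex vertex farthest from the allocation centroid
#' (`where = "outside"`), or an explicit `target`. The total supply
#' magnitude (sum of `s`) is preserved.
#'
#' @param params A [community_params()].
#' @param phi Allocation matrix whose rescaled rows define the hull.
#' @param where `"inside"`, `"outside"`, or `"target"`.
#' @param target Explicit simplex position when `where = "target"`.
#' @return The modified [community_params()].
#' @export
place_supply <- function(params, phi, where = c("inside", "outside", "target"),
                         target = NULL) {
  where <- match.arg(where)
  coords <- rescale_to_simplex(params, phi)
  centroid <- colMeans(coords$phi_hat)
  if (where == "inside") {
    target <- centroid
  } else if (where == "outside") {
    d <- apply(diag(params$n_resources), 1, function(v)
      sum(abs(v - centroid)))
    vert <- diag(params$n_resources)[which.max(d), ]
    for (a in c(0.95, 0.98, 0.995, 0.999)) {
      target <- a * vert + (1 - a) * centroid
      if (!hull_condition(target, coords$phi_hat)$inside) break
    }
    if (hull_condition(target, coords$phi_hat)$inside)
      stop("could not place the supply point outside the allocation hull")
  } else if (is.null(target)) {
    stop("`target` must be given when where = \"target\"")
  }
  if (abs(sum(target) - 1) > 1e-8 || any(target < 0))
    stop("`target` must lie on the simplex")
  total <- sum(params$s)
  s_new <- target * params$xi / params$kappa_n
  s_new <- s_new / sum(s_new) * total
  resources <- lapply(seq_len(params$n_resources), function(i)
    resource_params(params$kappa_n[i], params$K[i], params$xi[i], s_new[i]))
  community_params(params$species, resources,
                   r_fn = params$r_fn, r_deriv_fn = params$r_deriv_fn)
}

#' Synthetic serial-dilution competition data
#'
#' Generates replicate two-strain frequency series from the closed-form
#' serial-dilution dynamics, with independent Gaussian noise of standard
#' deviation `noise_sd` added to the log-odds of each measurement
#' (emulating counting noise at the flow cytometer). At `noise_sd = 0` the
#' output equals [dilution_frequencies()] exactly.
#'
#' @inheritParams dilution_frequencies
#' @param noise_sd Log-odds measurement noise, non-negative.
#' @param n_replicates Number of replicate series.
#' @param seed Integer seed.
#' @return A [competition_series()] data frame with a `replicate` column.
#' @export
synthetic_competition_data <- function(strain1, strain2, T_growth, n_cycles,
                                       noise_sd = 0, n_replicates = 1,
                                       m0 = c(1, 1), seed = 1) {
  if (noise_sd < 0) stop("`noise_sd` must be non-negative")
  base <- dilution_frequencies(strain1, strain2, T_growth, n_cycles, m0)
  out <- with_seed(subseed(seed, 3), {
    reps <- lapply(seq_len(n_replicates), function(rep) {
      lo <- base$ln_odds + stats::rnorm(nrow(base), 0, noise_sd)
      data.frame(replicate = rep, time = base$time,
                 f = 1 / (1 + exp(-lo)), ln_odds = lo)
    })
    do.call(rbind, reps)
  })
  structure(out, class = c("competition_series", "data.frame"))
}

#' Synthetic fluorescence calibration data
#'
#' Emulates an induction-calibration experiment: per inducer condition, the
#' mean cell fluorescence at the reference time and `delta_t` hours later,
#' generated from the small-degradation induction dynamics with optional
#' multiplicative noise of coefficient of variation `noise_cv`.
#'
#' @param models List of [induction_model()] objects, one per inducer
#'   condition.
#' @param inducer_conc Inducer concentrations labelling the conditions.
#' @param delta_t Time between the two measurements (hours, default 4).
#' @param noise_cv Multiplicative measurement noise CV, non-negative.
#' @param seed Integer seed.
#' @return Data frame with columns `inducer_conc`, `I_first`, `I_second`,
#'   `g`, `delta_t`.
#' @export
synthetic_fluorescence_data <- function(models, inducer_conc = seq_along(models),
                                        delta_t = 4, noise_cv = 0, seed = 1) {
  if (noise_cv < 0) stop("`noise_cv` must be non-negative")
  stopifnot(length(models) == length(inducer_conc))
  with_seed(subseed(seed, 4), {
    rows <- lapply(seq_along(models), function(j) {
      mod <- models[[j]]
      I1 <- mod$I0
      I2 <- fluorescence_intensity(mod, delta_t, approximate = TRUE)
      if (noise_cv > 0) {
        I1 <- I1 * (1 + stats::rnorm(1, 0, noise_cv))
        I2 <- I2 * (1 + stats::rnorm(1, 0, noise_cv))
      }
      data.frame(inducer_conc = inducer_conc[j], I_first = I1, I_second = I2,
                 g = mod$g, delta_t = delta_t)
    })
    do.call(rbind, rows)
  })
}
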