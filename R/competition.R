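#' Two-strain competition series
#'
#' Relative-abundance time series of a focal strain in a pairwise
#' competition; the derived log-odds `ln(f / (1 - f))` is the quantity whose
#' slope in time defines the selection coefficient.
#'
#' @param times Measurement times (hours), strictly increasing.
#' @param f Relative abundance of the focal strain, strictly inside (0, 1).
#'   Frequencies exactly 0 or 1 are rejected (the log-odds is undefined);
#'   apply a pseudo-count explicitly beforehand if needed.
#' @param replicate Optional replicate label (scalar or vector).
#' @return A data frame of class `competition_series` with columns
#'   `replicate`, `time`, `f`, `ln_odds`.
#' @export
competition_series <- function(times, f, replicate = 1L) {
  if (length(times) != length(f)) stop("`times` and `f` differ in length")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  if (any(f <= 0 | f >= 1))
    stop("frequencies must lie strictly inside (0, 1); the log-odds is undefined at 0 or 1")
  structure(data.frame(replicate = replicate, time = times, f = f,
                       ln_odds = log(f / (1 - f))),
            class = c("competition_series", "data.frame"))
}

#' Strain physiology for competition analysis
#'
#' @param Phi_baseline Metabolic + growth proteome fraction without any
#'   induced burden.
#' @param phi_induced Proteome fraction diverted to a useless (e.g.
#'   inducible fluorescent) protein; the effective budget is
#'   `Phi = Phi_baseline - phi_induced`.
#' @param eta,gamma Capacity ratios of the shared genetic background (see
#'   [capacity_ratios()]).
#' @return A list of class `strain_physiology`.
#' @export
strain_physiology <- function(Phi_baseline, phi_induced = 0, eta, gamma) {
  if (Phi_baseline <= 0 || Phi_baseline >= 1) stop("`Phi_baseline` must lie in (0, 1)")
  if (phi_induced < 0) stop("`phi_induced` must be non-negative")
  Phi <- Phi_baseline - phi_induced
  if (Phi < 0) stop("`phi_induced` exceeds the baseline budget")
  structure(list(Phi = Phi, Phi_baseline = Phi_baseline,
                 phi_induced = phi_induced, eta = eta, gamma = gamma),
            class = "strain_physiology")
}

#' Theoretical selection coefficient of strain 1 over strain 2
#'
#' For two strains with a shared genetic background (equal `eta` and
#' `gamma`) competing for one resource at uptake response `r`, the CPR model
#' predicts `S = eta r / (1 + gamma r) * (Phi_1 - Phi_2)`: the selective
#' advantage is proportional to the difference in metabolic proteome
#' budgets, vanishing exactly at `Phi_1 = Phi_2`. `r = 1` gives the
#' rich-medium expression.
#'
#' @param strain1,strain2 [strain_physiology()] objects sharing `eta` and
#'   `gamma`.
#' @param r Uptake response in `[0, 1]` (default 1, nutrient-rich medium).
#' @return Selection coefficient `S` (1/h).
#' @export
selection_theory <- function(strain1, strain2, r = 1) {
  if (abs(strain1$eta - strain2$eta) > 1e-12 ||
      abs(strain1$gamma - strain2$gamma) > 1e-12)
    stop("strains must share `eta` and `gamma` (same genetic background)")
  if (r < 0 || r > 1) stop("`r` must lie in [0, 1]")
  strain1$eta * r / (1 + strain1$gamma * r) * (strain1$Phi - strain2$Phi)
}

#' Estimate the selection coefficient from a competition series
#'
#' Fits the slope of the log-odds `ln(f / (1 - f))` against time by ordinary
#' least squares. Multiple replicate series are pooled by fitting a common
#' slope with per-replicate intercepts.
#'
#' @param series A [competition_series()] (possibly containing several
#'   replicates) or a list of them.
#' @return List with the slope `S` (1/h), its standard error `se`, and the
#'   underlying `lm` fit.
#' @export
estimate_selection <- function(series) {
  if (is.list(series) && !is.data.frame(series))
    series <- do.call(rbind, series)
  if (nrow(series) < 2) stop("need at least two points")
  if (length(unique(series$replicate)) > 1) {
    fit <- stats::lm(ln_odds ~ 0 + factor(replicate) + time, data = series)
  } else {
    fit <- stats::lm(ln_odds ~ time, data = series)
  }
  co <- summary(fit)$coefficients
  list(S = co["time", "Estimate"], se = co["time", "Std. Error"], fit = fit)
}

#' Closed-form serial-dilution competition frequencies
#'
#' Under the step-function growth approximation (abrupt resource
#' depletion after a growth window of `T` hours per cycle), the log-odds of
#' strain 1 after `N` transfers is
#' `ln_odds(N) = ln(m1_0 / m2_0) + N T eta / (1 + gamma) (Phi_1 - Phi_2)`;
#' the dilution factor cancels from the frequencies and only shifts the
#' absolute biomasses.
#'
#' @param strain1,strain2 [strain_physiology()] objects sharing `eta`,
#'   `gamma`.
#' @param T_growth Growth-window length per cycle (hours).
#' @param n_cycles Number of transfers.
#' @param m0 Initial biomasses `c(m1, m2)` (default equal inocula).
#' @return A [competition_series()] with times `0, T, ..., N T` (hours).
#' @export
dilution_frequencies <- function(strain1, strain2, T_growth, n_cycles,
                                 m0 = c(1, 1)) {
  if (abs(strain1$eta - strain2$eta) > 1e-12 ||
      abs(strain1$gamma - strain2$gamma) > 1e-12)
    stop("strains must share `eta` and `gamma`")
  N <- 0:n_cycles
  ln_odds <- log(m0[1] / m0[2]) +
    N * T_growth * strain1$eta / (1 + strain1$gamma) * (strain1$Phi - strain2$Phi)
  f <- 1 / (1 + exp(-ln_odds))
  competition_series(times = N * T_growth, f = f)
}

#' Proteome-budget ratio from selection and growth
#'
#' `Phi_1 / Phi_2 = 1 / (1 - S / g1)`, valid for any value of the uptake
#' response: the ratio of the two strains' metabolic proteome budgets is
#' recovered from the measured selection coefficient and the focal strain's
#' growth rate alone.
#'
#' @param S Selection coefficient (1/h).
#' @param g1 Growth rate of strain 1 (1/h), positive; requires `S / g1 < 1`.
#' @return The ratio `Phi_1 / Phi_2`.
#' @export
phi_ratio <- function(S, g1) {
  if (g1 <= 0) stop("`g1` must be positive")
  if (any(S / g1 >= 1)) stop("`S / g1` must be below 1")
  1 / (1 - S / g1)
}

#' Induction model for fluorescence calibration
#'
#' Parameters of the mean-cell-fluorescence dynamics of an inducible
#' protein: production at rate `k`, degradation at rate `d_FP`, and dilution
#' by growth/division at rate `g`. `I0` is the intensity at the reference
#' (first measurement) time.
#'
#' @param k Fluorescence production rate (intensity/h), non-negative.
#' @param g Cellular growth rate (1/h), positive.
#' @param d_FP Protein degradation rate (1/h), non-negative (default 0).
#' @param I0 Intensity at the reference time, non-negative.
#' @param t_ref Reference time in hours (default 4).
#' @return A list of class `induction_model`.
#' @export
induction_model <- function(k, g, d_FP = 0, I0 = 0, t_ref = 4) {
  if (k < 0) stop("`k` must be non-negative")
  if (g <= 0) stop("`g` must be positive")
  if (d_FP < 0) stop("`d_FP` must be non-negative")
  if (I0 < 0) stop("`I0` must be non-negative")
  structure(list(k = k, g = g, d_FP = d_FP, I0 = I0, t_ref = t_ref),
            class = "induction_model")
}

#' Mean cell fluorescence under induction
#'
#' Fluorescence of a growing, dividing cell population expressing an
#' induced protein, measured from the reference time. The full expression
#' accounts for protein degradation; with `approximate = TRUE` the
#' small-degradation limit `I(t) = 2 I0 e^{-g t} + 2 ln(2) (k/g)(1 -
#' e^{-g t})` is used, which starts at `2 I0` and saturates at
#' `2 ln(2) k / g`.
#'
#' @param model An [induction_model()].
#' @param t Time since the reference measurement (hours), non-negative.
#' @param approximate Use the `d_FP << g` approximation (default `TRUE`).
#' @return Fluorescence intensity at `t`.
#' @export
fluorescence_intensity <- function(model, t, approximate = TRUE) {
  if (any(t < 0)) stop("`t` must be non-negative")
  g <- model$g; k <- model$k; I0 <- model$I0; d <- model$d_FP
  if (approximate)
    return(2 * I0 * exp(-g * t) + 2 * log(2) * (k / g) * (1 - exp(-g * t)))
  a <- 1 + d / g
  decay <- exp(-g * t * a)
  2 * I0 * decay + (k / d) * (1 - decay) * (1 - 1 / (2^a - 1))
}

#' Infer the normalized protein production rate
#'
#' Inverts the small-degradation fluorescence dynamics using two mean
#' intensities measured `delta_t` hours apart:
#' `k = g (I_second - 2 I_first e^{-g delta_t}) / (2 ln(2) (1 - e^{-g
#' delta_t}))`, then divides by `I_norm` (typically the uninduced mean
#' intensity) so that the result has dimensions 1/h and is independent of
#' the instrument's arbitrary intensity units.
#'
#' @param I_first Mean intensity at the reference time.
#' @param I_second Mean intensity `delta_t` hours later.
#' @param delta_t Time between the two measurements (hours), positive.
#' @param g Cellular growth rate (1/h), positive.
#' @param I_norm Normalization intensity (default 1), positive.
#' @return List with the normalized rate `k` and `below_dilution = TRUE`
#'   when the inferred raw rate is negative (second measurement below the
#'   pure-dilution expectation).
#' @export
infer_production_rate <- function(I_first, I_second, delta_t, g, I_norm = 1) {
  if (delta_t <= 0) stop("`delta_t` must be positive")
  if (g <= 0) stop("`g` must be positive")
  if (I_norm <= 0) stop("`I_norm` must be positive")
  decay <- exp(-g * delta_t)
  k <- g * (I_second - 2 * I_first * decay) / (2 * log(2) * (1 - decay))
  list(k = k / I_norm, below_dilution = k < 0)
}

#' Nutritional capacity from growth-rate saturation
#'
#' From the saturation law `g = g_max kappa_n / (kappa_n + kappa_t)`, the
#' nutritional capacity is `kappa_n = g kappa_t / (g_max - g)`.
#'
#' @param g Observed growth rate (1/h), with `0 < g < g_max`.
#' @param g_max Maximum growth rate on the resource (1/h).
#' @param kappa_t Translational capacity.
#' @return The nutritional capacity `kappa_n`.
#' @export
estimate_kappa_n <- function(g, g_max, kappa_t) {
  if (g <= 0) stop("`g` must be positive")
  if (g >= g_max) stop("`g` must be below `g_max`")
  g * kappa_t / (g_max - g)
}

#' Maximum induced proteome fraction from selection coefficients
#'
#' The proteome fraction diverted to the inducible protein at full
#' induction, from the drop in selection coefficient between the uninduced
#' and the fully induced condition:
#' `max_phi = (1 + gamma) / eta * (S_zero - S_max)`.
#'
#' @param S_zero Mean selection coefficient without inducer (1/h).
#' @param S_max Mean selection coefficient at full induction (1/h).
#' @param eta,gamma Capacity ratios of the background.
#' @return The induced proteome fraction (0 when `S_zero = S_max`).
#' @export
max_induced_fraction <- function(S_zero, S_max, eta, gamma) {
  if (eta <= 0) stop("`eta` must be positive")
  (1 + gamma) / eta * (S_zero - S_max)
}

#' Time to reach a fold-change in density
#'
#' Under exponential growth at rate `g`, `t = ln(fold) / g`; e.g. the time
#' for a culture to saturate at a hundredfold its inoculation density.
#'
#' @param g Growth rate (1/h), positive.
#' @param fold Density fold-change, at least 1.
#' @return Time in hours.
#' @examples
#' time_to_fold(0.3, 100)  # ~15.4 h to saturation after a 1:100 transfer
#' @export
time_to_fold <- function(g, fold) {
  if (g <= 0) stop("`g` must be positive")
  if (any(fold < 1)) stop("`fold` must be at least 1")
  log(fold) / g
}
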