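# cprmodel

Simulation and analysis of competitive microbial communities whose resource
uptake is limited by **constrained, dynamically re-allocated proteomes** —
the consumer-proteome-resource (CPR) framework.

Classical consumer-resource models treat each species' "metabolic strategy"
(how much uptake machinery it points at each resource) as a fixed
parameter. Bacterial growth laws say otherwise: the proteome fraction spent
metabolizing resources trades off against the ribosomal fraction needed to
turn them into biomass, and both must fit into a finite proteome. For
species $\sigma$ and resources $i$ the CPR equations are

$$\dot m_\sigma = m_\sigma\Big[\textstyle\sum_i \eta_{\sigma i} r_i(c_i)
\varphi_{\sigma i} - q_\sigma\Big],\qquad
\dot c_i = s_i - \xi_i r_i(c_i) \textstyle\sum_\sigma m_\sigma
\varphi_{\sigma i},$$

with every allocation row constrained by
$\sum_i \varphi_{\sigma i}[1 + \gamma_{\sigma i} r_i(c_i)] = \Phi_\sigma$
at all times ($r_i$ = Monod response, $\eta = \kappa^n/\rho$,
$\gamma = \kappa^n/\kappa^t$ capacity ratios, $q$ maintenance, $\Phi$ the
metabolic + growth proteome budget). Because the constraint moves with the
resources, the allocations $\varphi_{\sigma i}$ are dynamical variables;
the package implements the constraint-dragged ("slow") law and the
growth-maximizing adaptive law with per-species timescale $\tau_\sigma$.

The package provides:

* **Core algebra** — uptake and growth rates, the constraint residual and
  its gradients, capacity ratios (`monod()`, `growth_rates()`,
  `constraint_residual()`, `capacity_ratios()`, ...).
* **Simulation** — stiff-capable integration of the full system with
  constraint projection (`simulate_cpr()`), serial-dilution protocols with
  an exact step-function growth mode (`simulate_serial_dilution()`),
  stationarity detection and survivor classification.
* **Coexistence theory** — the shared constant
  $\Theta = \Phi/(\rho q) - 1/\kappa^t$ and the $q \propto \Phi$ condition
  (`theta_of_species()`, `maintenance_from_theta()`), closed-form
  stationary resource levels (`stationary_concentrations()`), rescaled
  simplex coordinates and the convex-hull coexistence test
  (`rescale_to_simplex()`, `hull_condition()`), plus a ternary plot
  (`plot_simplex()`).
* **Two-strain competition analysis** — selection-coefficient theory and
  OLS estimation from frequency time series, closed-form serial-dilution
  frequencies, proteome-budget ratio inference, fluorescence-induction
  modeling and production-rate inversion (`selection_theory()`,
  `estimate_selection()`, `phi_ratio()`, `infer_production_rate()`, ...).
* **Seeded synthetic scenarios** — random communities in the three
  dynamical regimes (slow/low-quality, slow/high-quality, fast), supply
  placement relative to the allocation hull, and noisy synthetic
  competition/fluorescence datasets (`scenario_spec()`,
  `random_community()`, `place_supply()`, ...).
* **A thin CLI** — `exec/cpr` with `simulate`, `dilution`, `coexistence`,
  `competition`, `induction` and `synth` subcommands driven by YAML
  configs (`cpr_cli()`).

## Worked example

Two *E. coli*-like strains with identical genetic backgrounds compete for
glucose under daily 1:100 transfers; strain 1 diverts 1% of its proteome
budget to a useless induced protein.

```r
library(cprmodel)

est <- capacity_ratios(kappa_n = 1.2, kappa_t = 3.0, rho = 0.76)
est$gamma                                   # 0.4
est$eta                                     # 1.578947

s1 <- strain_physiology(0.45, phi_induced = 0.01, eta = est$eta, gamma = est$gamma)
s2 <- strain_physiology(0.44, 0,                  eta = est$eta, gamma = est$gamma)
selection_theory(s1, s2, r = 1)             # 0 : equal budgets coexist

s1b <- strain_physiology(0.45, 0, eta = 1.57, gamma = 0.4)
s2b <- strain_physiology(0.44, 0, eta = 1.57, gamma = 0.4)
selection_theory(s1b, s2b, r = 1)           # 0.01121429 : ~1.1e-2 per 1% budget

time_to_fold(0.3, 100)                      # 15.35057 h to saturation

ser <- dilution_frequencies(s1b, s2b, T_growth = 15.4, n_cycles = 6)
est_S <- estimate_selection(ser)
est_S$S                                     # 0.01121429 (recovers the slope)
```

The printed numbers mean: resource quality is 40% of translational
capacity (`gamma`), each unit of metabolic allocation buys ~1.58/h of
growth (`eta`), a strain paying a 1% proteome tax loses log-odds at
~0.011/h of growth time, and a 1:100 transfer is regrown in ~15.4 h.

A community-scale run:

```r
com  <- random_community(scenario_spec(seed = 1, regime = "fast"))
traj <- simulate_cpr(com$params, com$init, t_end = 800)
sum(classify_survivors(state_at(traj), com$init))   # 10 : all species coexist

Theta  <- theta_of_species(com$params$species[[1]])
theory <- stationary_concentrations(Theta, com$params)
max(abs(state_at(traj)$c - theory$c_star) / theory$c_star)  # ~1e-14

co <- rescale_to_simplex(com$params, state_at(traj)$phi, m_star = state_at(traj)$m)
hull_condition(co$s_hat, co$phi_hat)$inside          # TRUE
```

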