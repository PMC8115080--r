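---
title: "Consumer-proteome-resource models: theory, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consumer-proteome-resource models: theory, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprmodel)
```

## The model

Classical consumer-resource theory describes $N_S$ species competing for
$N_R$ substitutable resources through fixed "metabolic strategies". Bacterial
physiology says strategies cannot be fixed: the proteome fraction a cell
invests in metabolizing a resource trades off against the ribosomal fraction
needed to grow, and both must fit inside a finite proteome. The
consumer-proteome-resource (CPR) model couples the two levels. Its state is
the biomass vector $m_\sigma$, the resource concentrations $c_i$, and the
allocation matrix $\varphi_{\sigma i}$ (fraction of species $\sigma$'s
proteome devoted to taking up and metabolizing resource $i$):

$$\dot m_\sigma = m_\sigma\Big[\sum_i \eta_{\sigma i}\, r_i(c_i)\,
\varphi_{\sigma i} - q_\sigma\Big], \qquad
\dot c_i = s_i - \xi_i\, r_i(c_i) \sum_\sigma m_\sigma \varphi_{\sigma i},$$

subject, for every species and at every instant, to the proteome-finiteness
constraint

$$F_\sigma \equiv \sum_i \varphi_{\sigma i}\,
\big[1 + \gamma_{\sigma i}\, r_i(c_i)\big] - \Phi_\sigma = 0 .$$

Here $r_i(c) = c/(K_i + c)$ is the Monod uptake response (pluggable: any
monotone saturating function with $r(0)=0$ and unit limit may be
substituted; none of the package's structural results depend on the exact
form), $\eta_{\sigma i} = \kappa^n_i/\rho_\sigma$ converts allocation into
growth, $\gamma_{\sigma i} = \kappa^n_i/\kappa^t_\sigma$ compares the
nutritional quality of resource $i$ with the translational capacity of
species $\sigma$, $\xi_i$ is the catalytic rate of the metabolizing enzyme,
$q_\sigma$ a maintenance cost and $\Phi_\sigma$ the total proteome budget
available for metabolism plus growth. Units follow the growth-law
literature: hours for time, consistent mass/volume units for $m$ and $c$,
capacities in ug protein per ug RNA per hour ($\rho = 0.76$,
$\kappa^t \approx 3$, $\kappa^n \approx 1.2$ for *E. coli* on glucose at
30&nbsp;°C).

Because the bracket $1 + \gamma r$ moves with the resource concentrations,
the constraint hyperplane moves, and the allocations must be dynamical
variables. The package implements two laws:

* **slow (constraint-dragged)**, `phi_drift_slow()`: the minimal motion
  that keeps $F_\sigma = 0$, directed along the constraint normal
  $\nabla_\varphi F$; when all $\gamma \approx 0$ it freezes the
  allocations;
* **adaptive**, `phi_drift_adaptive()`: in addition, the allocation climbs
  the instantaneous growth gradient projected on the constraint's tangent
  space, with per-species timescale $\tau_\sigma$. As
  $\tau \to \infty$ it reduces to the slow law (rows with
  $\tau \ge 10^6$ h take the limit analytically, avoiding underflow); as
  $\tau \to 0$ it converges to the growth-maximizing vertex computed
  independently by `fast_optimal_phi()`, which the tests use as an oracle.
  Fast adaptation produces sequential resource use (diauxie-like support
  switches) as resources deplete.

## Stationary theory and the coexistence conditions

At a stationary state with all species present, each species' gross growth
balances its maintenance. When species outnumber resources this forces a
species-independent constant

$$\Theta = \frac{\Phi_\sigma}{\rho_\sigma q_\sigma} -
\frac{1}{\kappa^t_\sigma},$$

equivalent to the maintenance cost being proportional to the metabolic
budget ($q \propto \Phi$). `maintenance_from_theta()` builds communities on
this manifold exactly; `theta_of_species()` tests it. Given $\Theta$, every
resource settles at $r^*_i = 1/(\kappa^n_i \Theta)$, i.e.
$c^*_i = K_i/(\kappa^n_i\Theta - 1)$, feasible iff
$\Theta > \max_i 1/\kappa^n_i$ (`stationary_concentrations()`). When
species occupy non-overlapping niches ($N_S \le N_R$, each resource eaten
by at most one species) the shared-$\Theta$ requirement disappears and the
per-species expression applies resource by resource
(`nonoverlapping_stationary()`).

The second condition is geometric. Rescaling supplies and allocations onto
the $(N_R-1)$-simplex,

$$\hat s_i = \frac{s_i \kappa^n_i/\xi_i}{\sum_j s_j\kappa^n_j/\xi_j},
\qquad
\hat\varphi_{\sigma i} = \frac{\varphi_{\sigma i}}{\sum_j \varphi_{\sigma j}},
\qquad
z_\sigma = \frac{m^*_\sigma\rho_\sigma q_\sigma}
{\sum_\lambda m^*_\lambda\rho_\lambda q_\lambda},$$

full coexistence requires $\hat s = \sum_\sigma z_\sigma
\hat\varphi^*_{\sigma}$ with the weights $z$ on the probability simplex:
the supply point must lie in the convex hull of the *stationary* rescaled
allocations. `hull_condition()` decides membership by exact projection onto
the hull — an active-set least-squares solve over the weight simplex.
A linear-programming formulation of the same feasibility problem was tried
first and proved numerically fragile on collinear configurations; the
projection solve is deterministic, returns reconstruction weights when the
point is inside, and returns the projection residual as a separating
certificate (projection theorem) when it is not. Boundary points count as
inside; the default slack tolerance is 1e-9.

## Numerical choices

* **Integrator.** `simulate_cpr()` uses `deSolve::lsoda` (adaptive-step,
  switches to BDF when stiff) with `rtol = 1e-8`, `atol = 1e-10`. Resource
  depletion makes the system stiff, so the per-interval step budget is
  generous (1e5).
* **Constraint repair.** $\dot F_\sigma = 0$ holds analytically for both
  drift laws, but floating-point drift accumulates; at every output time
  each allocation row is projected back onto its constraint hyperplane
  along the normal (negative components clipped, the row re-projected on
  the reduced support). Accepted trajectories keep the max residual below
  1e-6; in practice it stays near 1e-7.
* **Positivity.** The exported `apply_positivity()` implements the exact
  active-set rule: a component at zero with outward drift is frozen and its
  constraint contribution redistributed along the remaining normal
  components, preserving $\dot F = 0$ to machine precision; frozen
  components re-enter as soon as their raw drift turns inward. Inside the
  ODE right-hand side the same correction is applied in a smoothed form
  (outward drift shrunk by the continuous factor $\varphi/(\varphi +
  \varepsilon)$ with $\varepsilon = 10^{-6}$, redistribution weighted by
  $\varphi$): the exact rule is discontinuous at the boundary and makes
  adaptive step-size control chatter, while the smoothed rule is
  continuous, keeps $\dot F = 0$ exactly, and reduces to the exact rule as
  $\varepsilon \to 0$. The tests verify the equivalence of the two on
  interior states to machine precision.
* **Extinction.** Biomass is never clipped during integration (the
  equations keep $m \ge 0$); extinction is purely a classification,
  `classify_survivors()`, with a default threshold of 1e-8 of the total
  initial biomass. The mask is insensitive to the threshold over
  [1e-9, 1e-7] on converged runs.
* **Stationarity.** `detect_stationarity()` declares a trajectory
  stationary when, over the trailing 10% of the horizon, every component's
  relative rate of change stays below 1e-6 per hour; extinct species are
  excluded (their decay never stops).
* **Transfers.** `simulate_serial_dilution()` divides biomass by $D$ and
  resets resources to the fresh medium (spent-medium carry-over at $1/D$
  is an option, off by default). Since the constraint depends on $c$, the
  allocation rows are re-projected after each transfer — physically, the
  fast physiological re-equilibration to the new medium. The
  `"heaviside"` mode replaces the uptake response with a step function of
  time (growth at $r=1$ for a window $T$, then arrest) and evaluates the
  closed-form biomass recursion; it exists because the two-strain
  competition theory is formulated in that limit.
* **Tie-breaking.** `fast_optimal_phi()` resolves exact payoff ties to the
  lowest resource index, for determinism.

## The synthetic-scenario generator

`random_community()` draws communities in the three regimes that organize
the model's phenomenology. The generator is the package's definition of the
study conditions; its defaults were chosen once, as follows, and all
community-scale tests run against them.

* Sampling is log-uniform for $\kappa^n, \kappa^t, \xi, K, s$ and uniform
  for $\Phi \in [0.3, 0.5]$; $\rho$ is fixed at 0.76. Default community
  size $N_S = 10$, $N_R = 3$ — large enough that species outnumber
  resources by a factor of three, small enough for desk-scale runs.
* `slow_lowgamma`: $\kappa^n \in [0.3, 0.6]$, $\kappa^t \in [4, 8]$ (so
  all $\gamma \le 0.15$), $\tau \in [10^6, 10^7]$ h. With $\gamma$ small
  the constraint barely moves and the allocations are effectively frozen;
  $\tau$ is chosen far above any simulation horizon so that adaptive
  repositioning is negligible, which is what "slow" means operationally.
* `slow_highgamma`: $\kappa^n \in [4, 12]$ (all $\gamma \ge 1$),
  $\tau \in [10^3, 10^4]$ h — slow compared to individual growth
  ($1/g \sim 1$ h) but finite, so that allocation movement can accumulate
  during long resource-rich transients. This is the regime in which
  scaling all supplies by $x > 1$ rescues coexistence: larger supply
  prolongs the phase in which every species grows (no exclusion yet) while
  the allocations reposition; the rescaled supply point $\hat s$ is
  unchanged by $x$.
* `fast`: $\tau \in [0.1, 1]$ h, $\kappa^n \in [0.5, 3]$. Allocations
  track the growth optimum closely and coexistence is recovered regardless
  of the initial allocations; multiplying $\tau$ by $y \gg 1$ moves the
  community back toward the frozen regime and loses species.
* Maintenance costs are set from a single shared $\Theta$ (drawn between
  1.2 and 1.8 times the feasibility bound $\max_i 1/\kappa^n_i$), because
  with $N_S > N_R$ the shared-$\Theta$ condition is necessary for full
  coexistence — without it the comparison of hull geometry and survival
  would be confounded. `shared_theta = FALSE` disables this.
* Initial allocations are placed at random simplex positions and scaled
  onto each species' constraint hyperplane exactly
  (`phi_initial_on_constraint()`); `place_supply()` re-aims the supply
  point inside or outside the initial allocation hull without changing the
  total supply.
* Seeding is per-component (parameters, initial state, noise draw their
  own sub-streams), so adding replicates never perturbs earlier draws, and
  every generator is a pure function of (spec, seed).

What the generator emulates is the *structure* of the community
experiments: random physiologies within literature-scale ranges, controlled
supply geometry, controlled adaptation speed. What it does not emulate:
demographic noise, cross-feeding, spatial structure, measurement error on
biomasses, or day-to-day environmental fluctuation. Tests passing on these
scenarios show that the implementation realizes the model's phenomenology,
not that any particular natural community behaves this way.

Problem sizes used by the packaged checks: community runs use horizons of
400-2500 h at 81-301 output points (chosen so that the slowest extinction
transients in each regime have decayed well past the classification
threshold); the estimator-calibration checks use 100 seeded replicates of a
6-replicate, 6-cycle competition design.

## Two-strain competition analysis

For two strains sharing a genetic background (equal $\eta, \gamma$)
competing for one resource, the model collapses to
$S \equiv \tfrac{d}{dt}\ln\tfrac{f}{1-f} =
\frac{\eta\, r}{1+\gamma r}(\Phi_1 - \Phi_2)$: the sign of the selection
coefficient is the sign of the budget difference, and coexistence requires
exactly $\Phi_1 = \Phi_2$. `estimate_selection()` fits the log-odds slope
by ordinary least squares — with replicate series pooled through a common
slope and per-replicate intercepts, since replicate inocula differ but the
physiology does not. Frequencies exactly 0 or 1 are rejected rather than
silently pseudo-counted. The budget ratio follows from
$\Phi_1/\Phi_2 = 1/(1 - S/g_1)$ for *any* value of the uptake response,
which is what makes the inference usable outside exponential phase.

The induction analysis inverts the mean-fluorescence dynamics
$I(t) = 2I_0 e^{-gt} + 2\ln 2\, (k/g)(1 - e^{-gt})$ (production $k$,
dilution by division at growth rate $g$; the factor-2 structure reflects
the division-cycle bookkeeping of the underlying derivation and is
implemented exactly as stated) to obtain $k$ from two measurements a few
hours apart, normalized by the uninduced intensity so the result is
instrument-independent. The full expression with explicit degradation
$d_{FP}$ is also provided; the tests verify it converges to the
small-degradation form at $d_{FP}/g = 10^{-6}$ within 1e-4 relative.

Where the analysis requires a growth rate measured in the experiment (for
example the nutritional-capacity estimate $\kappa^n = g\kappa^t/(g_{max} -
g)$), the functions expose it as an input instead of assuming a value.

## Design choices that were genuinely open

* **Positivity scheme.** Only the need for one is documented for the
  adaptive law; the active-set construction (freeze, redistribute,
  re-enter) was chosen because it reduces exactly to the unconstrained
  laws in the interior and preserves $\dot F = 0$; the smoothed in-solver
  variant was added after the exact rule proved numerically hostile to
  step-size control.
* **Hull membership as projection.** Least-squares projection with an
  equality-constrained active set instead of a linear program; see above.
* **Transfer semantics.** Resources are *reset* to fresh medium rather
  than diluted, matching reinoculation into fresh medium; carry-over is
  optional.
* **Timescale separation in the generator.** "Slow" is implemented
  relative to the simulation horizon (see the generator section), since
  only the ratio of adaptation to ecological timescales is meaningful.
* **Worked-estimate chaining.** The literature worked example chains the
  rounded ratios ($\eta = 1.57$, $\gamma = 0.4$); `capacity_ratios()`
  itself always returns the exact quotient (1.2/0.76 = 1.579).

## Known limitations

* The adaptive dynamics at small $\tau$ with near-tied resource payoffs
  can produce relaxation oscillations that make integration very
  expensive; one packaged fast-regime scenario (seed 1) with the supply
  aimed outside the hull hits the step budget at $y = 1$ and is not used
  in the timescale sweep.
* Stability of the stationary states is not analyzed; stationarity is
  detected empirically from trailing rates of change.
* No cross-feeding, toxin, or spatial terms; resources are strictly
  substitutable.
* The ternary plot helper covers $N_R = 3$ only.
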