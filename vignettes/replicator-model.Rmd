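---
title: "A tripartite replicator model of overtreatment governance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A tripartite replicator model of overtreatment governance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trigame)
library(ggplot2)
```

## The model

`trigame` studies the governance of excessive medical care as an evolutionary
game between three large populations of boundedly rational agents:

* **patients**, a fraction $x$ of whom *recognize* treatment outcomes (trust
  and accept what they received) while $1-x$ contest them;
* **healthcare institutions**, a fraction $y$ of which deliver *reasonable
  treatment* while $1-y$ overtreat;
* **government regulators**, a fraction $z$ of which supervise *strictly*
  while $1-z$ are lenient.

Agents do not compute best responses; they occasionally imitate a
better-performing peer from their own population. In the large-population
limit that adjustment process is the replicator dynamic

$$\dot x = x(1-x)\,A_x(y,z),\qquad
  \dot y = y(1-y)\,A_y(x,z),\qquad
  \dot z = z(1-z)\,A_z(x,y),$$

where each *advantage function* $A_i$ is the expected-payoff difference
between the population's two actions against the current mixture of the other
two populations. Payoffs are built from 14 nonnegative constants on one
arbitrary money-like scale (`param_names()` documents all of them): treatment
incomes $W_t$ (reasonable) and $W_m$ (overtreatment), subsidy $G_s$, fine
$G_f$, reputation $E_r$, operating cost $O_c$ on the institution side;
overtreatment cost $C_m$, treatment benefit $C_t$, complaint weight $C_p$ and
compensation $C_i$ for patients; and social benefit $E_g$, supervision cost
$C_r$, remediation cost $G_g$ and credibility stake $P_g$ for the regulator.
Because only payoff *differences* matter, each $A_i$ is bilinear in the two
opposing frequencies, and scaling all constants by $\lambda > 0$ only
rescales time.

Two algebraically equivalent representations of the advantages exist: the
mixture-weighted payoff differences (`expected_payoffs()`) and the expanded
bracket polynomials (`advantage_functions()`). The package treats the
expanded polynomials as canonical and proves the equivalence in the test
suite by exact polynomial interpolation: both sides are bilinear, so
agreement on the dyadic grid $\{0, \tfrac12, 1\}^3$ with integer parameters
establishes identity, not merely approximate agreement.

## Equilibria and stability

The field vanishes on every face of the cube, so the eight vertices
(`pure_profiles()`, labelled E1 = (0,0,0) through E8 = (1,1,1)) are always
fixed points. The Jacobian is diagonal at a vertex — every off-diagonal entry
carries a factor $s_i(1-s_i)$ — so the eigenvalues are available in closed
form (`vertex_eigenvalues()`), and stability follows from their signs
(indirect Lyapunov method, `classify_equilibrium()`):

* all eigenvalues negative: asymptotically stable, an evolutionarily stable
  strategy (ESS);
* any eigenvalue within `tol` of zero: *indeterminate* — the linearization
  is inconclusive along that direction and the package deliberately does not
  attempt a center-manifold analysis. E4(0,0,1) and E6(1,0,1) always carry an
  identically zero patient-direction eigenvalue and are therefore always
  indeterminate;
* otherwise unstable.

For strictly positive parameters only two profiles can ever be stable:

* **E2(1,0,0)** — patients resigned, institutions overtreating, regulators
  lenient — stable iff $W_m > E_r + O_c + W_t$;
* **E3(0,1,0)** — reasonable treatment with lenient regulation — stable iff
  $W_m < G_s + W_t + E_r$.

The two conditions overlap when $O_c < G_s$, giving a *bistable* band
$E_r + O_c + W_t < W_m < G_s + W_t + E_r$ in which the long-run outcome
depends on the initial state. The reference parameter set
(`baseline_scenarios()$scenario1`) sits in exactly that band
($7.5 < W_m = 9 < 11$):

```{r}
sc <- baseline_scenarios()
glance(ess_conditions(sc$scenario1))
tidy(ess_conditions(sc$scenario1))
```

Interior (mixed) equilibria require all three bilinear advantages to vanish
at once. `find_interior_fixed_points()` scans a regular grid (default 21
points per axis) for cells whose corners straddle zero in every component,
Newton-polishes each candidate with the analytic advantage Jacobian, merges
duplicates within $10^{-6}$, and re-verifies every root with an independent
multi-start solver (`pracma::fsolve`). Bilinearity makes sign-change
bracketing at this density reliable. Neither reference scenario has an
interior root; the tests construct parameter families that provably do (for
example $C_i = 2C_m$, $E_g = 4(C_r+G_g)$,
$W_m = E_r+G_s+W_t+G_f/2-(G_s-O_c)/4$ puts one exactly at the cube center)
and confirm the scanner finds them.

## Trajectories

`simulate_game()` integrates the system with the Dormand–Prince 4/5
adaptive pair (`deSolve::ode`, method `"ode45"`), relative tolerance
$10^{-8}$, absolute tolerance $10^{-10}$, over a horizon of $T = 50$ time
units from the neutral start $(0.5, 0.5, 0.5)$ — by that time both reference
scenarios are deep inside the $10^{-3}$ convergence ball of their limit
vertex. A trajectory still outside every convergence ball at the end of the
window is reported unconverged rather than extrapolated (horizon extension
exists but is off by default).

```{r, fig.width = 6, fig.height = 3.5}
tr1 <- simulate_game(sc$scenario1, sc$initial)
glance(tr1)
autoplot(tr1)
```

Raising reasonable-treatment income from $W_t = 4$ to $7$ destabilises E2
(its institution eigenvalue becomes $+1.5$) and the same start instead
reaches the cooperative vertex:

```{r, fig.width = 6, fig.height = 3.5}
tr2 <- simulate_game(sc$scenario2, sc$initial)
glance(tr2)
```

Numerical choices worth stating. Exact solutions never leave the cube, but a
non-projecting Runge–Kutta step can overshoot a face by roughly its local
error, which the solver controls as $\mathrm{abs\_tol} + \mathrm{rel\_tol}\,
|y|$; near the $y = 1$ face that scale is `rel_tol`, not `abs_tol`.
Excursions up to $10(\mathrm{rel\_tol} + \mathrm{abs\_tol})$ are therefore
clamped as round-off, anything larger raises an error as a genuine
integration failure. The integrator is cross-checked in the tests against an
independent explicit-Euler path (step 0.01) and against tolerance halving.

`multi_start()` integrates from a regular interior lattice (faces are
invariant, so starts are offset inward; a 1-point "lattice" is the cube
center) and tallies basin membership. In the $W_t = 7$ regime the
institution advantage satisfies $A_y \ge 1.5$ on the whole cube, so $y \to 1$
from every interior start and all 27 starts of the default $3^3$ lattice
reach E3.

## Sensitivity sweeps

`sweep_parameter()` replaces one constant at a time and records, per value,
the limit vertex and the first entry time into the convergence ball
(linearly interpolated between saved steps, spacing 0.1). The standard
battery (`standard_sweep_suite()`) runs six sweeps against the $W_t = 7$ base
scenario: $G_s \in \{5,10,15\}$, fine level $\in \{20,150,300\}$,
$G_g \in \{50,150,200\}$, $C_r \in \{40,100,150\}$, $W_t \in \{4,8,12\}$ and
$W_m \in \{15,10,5\}$.

Two modelling notes. First, the fine sweep varies the fine $G_f$ by default;
a `fine_symbol = "Pg"` option varies the credibility stake instead. Second,
$G_f$ appears in the institutions' advantage but *not* in the regulator's
own advantage $A_z$ — within this payoff structure fines deter institutions
but cannot move the regulator's strategy, a structural fact the reports
annotate rather than patch.

```{r}
su <- standard_sweep_suite()
tidy(su)
```

Every converged sweep record lands on a vertex that `ess_conditions()`
classifies stable for that record's parameters (a cross-module invariant the
acceptance tests enforce), and on the $W_t = 7$ base the time for $y$ to
exceed 0.9 is non-increasing in the subsidy $G_s$.

## Generating parameter regimes and the imitation check

`sample_parameters()` rejection-samples seeded parameter sets (each symbol
uniform on $[0.5, 20]$ by default — a range spanning all the reference
values; sweep-scale values up to 300 are reachable by widening the ranges)
constrained to a named stability regime: `E2_stable_only`, `E3_stable_only`,
`bistable` or `neither`, each enforced with a strict $10^{-6}$ margin on the
defining inequalities. An empty region (bistability is impossible when
$O_c > G_s$) is reported as an error with advice rather than an endless
loop.

`finite_population_oracle()` is the package's independent stochastic check
on the whole pipeline: three finite populations in which each agent revises
with probability `step_scale` per generation and imitates a random
same-population peer with probability proportional to the positive part of
the payoff advantage. The expected per-generation change of a frequency $p$
is exactly `step_scale` $\cdot\, p(1-p) A$, so the mean-field limit is the
replicator flow with one generation worth `step_scale` time units —
proportional imitation was chosen over other imitation rules precisely so
the oracle converges to the object it checks. At population $10^4$ the
empirical path stays within max-norm 0.1 of the ODE solution for both
reference scenarios.

What the generator does *not* emulate: real hospitals and regulators are
heterogeneous, interact on networks, and experience shocks and mutation
(strategy exploration); the populations here are well-mixed and noiseless,
and absorbing faces stay absorbed. Passing tests therefore validate the
mathematics of the model, not its calibration to any real healthcare
system — all parameter values are on an arbitrary common scale.

## Problem sizes used by the test suite

The suite's property checks use 1,000 random draws for the algebraic
identities and inequality/eigenvalue coherence, 200 draws for vertex
diagonality, 100 random integrations for box invariance, a $3^3$ lattice for
basin exploration, 1,000 sampled sets per regime tag for the generator
audit, and population $10^4$ over 2,000 generations for the imitation
check — sizes at which every stochastic tolerance holds with a wide margin
under the fixed seeds.

## Limitations

* Stability classification is linear: indeterminate vertices (E4, E6, and
  any profile with an eigenvalue within `tol` of zero) are not resolved
  further.
* Edge and face equilibria other than the eight vertices are detected by the
  interior/face search only if strictly interior; their stability is not
  analysed.
* The sweep battery inherits the model's structural blind spot that fines
  do not feed back into the regulator's own incentives.
* No best-response or stochastically perturbed dynamics; the replicator
  flow with proportional imitation is the only adjustment process.
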