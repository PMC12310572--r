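# trigame

Evolutionary-game analysis of overtreatment governance: three large
populations — patients (recognize treatment outcomes or contest them, share
`x`), healthcare institutions (reasonable treatment or overtreatment, share
`y`) and government regulators (strict or lenient supervision, share `z`) —
adapt by imitation under bounded rationality. The package is for
health-policy modellers who want a tested, scriptable implementation of the
model rather than a one-off simulation: it provides the replicator dynamics,
closed-form stability analysis of all pure-strategy profiles, trajectory and
basin simulation, one-parameter sensitivity sweeps, seeded generation of
parameter regimes, and a finite-population imitation simulator that serves
as an independent stochastic check.

## The model

Strategy shares evolve by the three-population replicator dynamic

    dx/dt = x(1-x) A_x(y,z)
    dy/dt = y(1-y) A_y(x,z)
    dz/dt = z(1-z) A_z(x,y)

where each advantage function `A_i` is the expected-payoff difference between
the population's two actions, bilinear in the other two populations'
frequencies, built from 14 nonnegative constants (incomes `Wt`, `Wm`,
subsidy `Gs`, fine `Gf`, reputation `Er`, operating cost `Oc`, patient-side
`Cm`, `Ct`, `Cp`, `Ci`, and regulator-side `Eg`, `Cr`, `Gg`, `Pg`; see
`?param_names`). Every vertex of the unit cube is a fixed point; the
Jacobian is diagonal there, so the eigenvalues are closed-form and only two
vertices can ever be evolutionarily stable:

* `E2 = (1,0,0)` (resigned patients, overtreatment, lenient regulation),
  stable iff `Wm > Er + Oc + Wt`;
* `E3 = (0,1,0)` (reasonable treatment, lenient regulation),
  stable iff `Wm < Gs + Wt + Er`.

Both hold at once in the band `Er+Oc+Wt < Wm < Gs+Wt+Er` (bistability: the
outcome depends on where the system starts).

## Worked example

```r
library(trigame)

sc <- baseline_scenarios()      # two reference parameter sets + neutral start
glance(ess_conditions(sc$scenario1))
#> # A tibble: 1 × 4
#>   n_stable stable_set bistable n_indeterminate
#>      <int> <chr>      <lgl>              <int>
#> 1        2 E2,E3      TRUE                   2

tr <- simulate_game(sc$scenario1, sc$initial)   # horizon 50, ode45
glance(tr)
#> # A tibble: 1 × 7
#>   horizon x_final  y_final   z_final converged limit_vertex entry_time
#>     <dbl>   <dbl>    <dbl>     <dbl> <lgl>     <chr>             <dbl>
#> 1      50       1 1.46e-31 1.16e-106 TRUE      E2                 7.27
```

The reference scenario is bistable, and from the neutral start
`(0.5, 0.5, 0.5)` the system reaches `E2`: patients stop contesting
outcomes, institutions overtreat, regulators relax — the bad equilibrium.
Raising reasonable-treatment income `Wt` from 4 to 7 destabilises `E2` and
the same start reaches the cooperative vertex instead:

```r
glance(simulate_game(sc$scenario2, sc$initial))
#> # A tibble: 1 × 7
#>   horizon  x_final y_final  z_final converged limit_vertex entry_time
#>     <dbl>    <dbl>   <dbl>    <dbl> <lgl>     <chr>             <dbl>
#> 1      50 6.03e-12       1 1.04e-65 TRUE      E3                 12.1
```

`sweep_parameter()` / `standard_sweep_suite()` run the sensitivity battery
(subsidies, fines, remediation and regulatory costs, both treatment
incomes), `multi_start()` maps basins of attraction from an interior
lattice, `sample_parameters()` draws seeded parameter sets from a named
stability regime, and `autoplot()` works on trajectories, sweeps and
multi-start batches. A small command-line wrapper is included:

```sh
Rscript inst/cli/trigame.R simulate --scenario scenario2 --out-dir out/
Rscript inst/cli/trigame.R stability --params inst/extdata/scenario2.yaml --out-dir out/
```

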