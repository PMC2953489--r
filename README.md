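# normdyn

Replicator dynamics of two interacting populations with **incompatible
preferences** and **unequal power** — a quantitative framework for asking
when self-interested imitation produces a breakdown of cooperation, separate
subcultures, a shared behavioral norm, or polarization and abrupt
("revolutionary") regime shifts.

## The model

Two well-mixed populations interact within and across group boundaries.
Population 1 prefers behavior 1, population 2 prefers behavior 2, so each
population's "cooperative" behavior is the other's uncooperative one. The
state is $(p, q) \in [0,1]^2$: the fractions of each population showing its
own preferred behavior. Each pairwise game is summarized by the payoff
differences $B = S - P$ and $C = R - T$, whose signs select the prisoner's
dilemma, snowdrift, stag hunt, or harmony game; $b_a, c_a$ apply in-group and
$B_a, C_a$ out-group, and $f \in [0,1]$ is the relative power of
population 1. The coupled replicator equations are

$$\dot p = p(1-p)\,G_1, \qquad \dot q = q(1-q)\,G_2,$$

with the affine growth brackets

$$G_1 = f[c_1 p + b_1(1-p)] + (1-f)[C_1(1-q) + B_1 q],$$
$$G_2 = (1-f)[c_2 q + b_2(1-q)] + f[C_2(1-p) + B_2 p].$$

The package provides:

* game classification and the costly-punishment and group-pressure payoff
  transformations (`classify_game`, `apply_punishment`,
  `apply_group_pressure`);
* adaptive ODE integration with explicit convergence detection
  (`integrate_replicator`, `find_attractor`);
* closed-form enumeration of **all** stationary solutions — corners, edge
  points, interior points, and equilibrium continua — with Jacobian-based
  stability classification and a Nash-equilibrium check
  (`enumerate_fixed_points`, `classify_stability`, `nash_check`);
* basin-of-attraction maps, parameter sweeps, norm phase diagrams, and
  discontinuous-transition detection (`basin_map`, `sweep_attractor`,
  `phase_diagram_norms`, `detect_discontinuity`);
* a seeded finite-population proportional-imitation counterpart whose mean
  dynamics reproduce the replicator flow (`agent_state`, `abm_run`);
* the reference parameter sets as fixtures (`scenario_fixtures`), YAML/JSON
  configuration (`read_game_config`), and a thin command-line front end
  (`inst/cli/normdyn.R`).

## Worked example

The two-population snowdrift game with a stronger population 1
($B = 1$, $C = -2$, $f = 0.8$):

```r
library(normdyn)
g <- game_params(B = 1, C = -2, f = 0.8)
enumerate_fixed_points(g)
#> Equilibrium set: 6 isolated fixed point(s)
#>   (0.000000, 0.000000)  corner   saddle
#>   (0.000000, 1.000000)  corner   unstable
#>   (1.000000, 0.000000)  corner   unstable
#>   (1.000000, 1.000000)  corner   saddle
#>   (0.166667, 0.000000)  edge     stable
#>   (0.416667, 1.000000)  edge     saddle

find_attractor(g, 0.5, 0.5)$attractor
#>            p            q
#> 1.666667e-01 2.088304e-22

overall_cooperation(g, 1/6, 0)
#> [1] 0.3333333
```

The unique attractor $(1/6, 0)$ is the "tacit alliance": the weaker
population is pinned to an extreme ($q^* = 0$, everyone there shows
behavior 1) and coordinates with the *minority* of the stronger population,
which itself polarizes. The overall fraction of individuals showing
behavior 1, $f p^* + (1-f)(1-q^*) = 1/3$, equals the one-population snowdrift
expectation $|B|/(|B|+|C|)$ of the stronger population exactly. Raising $B$
past $|C|$ flips the weaker population discontinuously to $q^* = 1$ — the
revolutionary transition:

```r
sr <- sweep_attractor(seq(0.55, 1.95, by = 0.1),
                      function(B) game_params(B = B, C = -1, f = 0.8),
                      p0 = 0.5, q0 = 0.5, param_name = "B")
detect_discontinuity(sr, "q_star")
#>   value_lo value_hi before after jump
#> 1     0.95     1.05  2e-08     1    1
```

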