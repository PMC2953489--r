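---
title: "Replicator dynamics of two populations with incompatible preferences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicator dynamics of two populations with incompatible preferences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normdyn)
```

## The model

Two well-mixed populations interact among and between each other. Population 1
prefers behavior 1, population 2 prefers behavior 2, so a behavior that is
"cooperative" from one population's viewpoint is uncooperative from the
other's. The state of the system is a point $(p, q)$ in the unit square: $p$
is the fraction of population 1 showing behavior 1 and $q$ the fraction of
population 2 showing behavior 2.

Each pairwise interaction is a symmetric $2 \times 2$ game with payoffs $R$
(mutual cooperation), $S$ (unilateral cooperation), $T$ (unilateral
defection), and $P$ (mutual defection), always read in the focal individual's
own frame. Only the differences

$$B = S - P, \qquad C = R - T$$

enter the dynamics: $C$ is the gain from coordinating on one's preferred
behavior, $B$ the gain from abandoning coordinated but non-preferred
behavior. Their signs select the game: $B<0, C<0$ prisoner's dilemma (PD);
$B>0, C<0$ snowdrift (SD); $B<0, C>0$ stag hunt (SH); $B>0, C>0$ harmony
(HG). Lower-case $b_a, c_a$ parametrize in-group interactions of population
$a$, upper-case $B_a, C_a$ the out-group interactions; the frequently used
shorthand sets them all equal.

Individuals imitate more successful behaviors *in their own population*
(proportional imitation), and a power parameter $f \in [0, 1]$ weights how
much population 1's members determine expected payoffs. Writing the
expected-payoff advantage of the preferred behavior as the affine *growth
brackets*

$$G_1(p, q) = f\,[c_1 p + b_1 (1-p)] + (1-f)\,[C_1 (1-q) + B_1 q],$$
$$G_2(p, q) = (1-f)\,[c_2 q + b_2 (1-q)] + f\,[C_2 (1-p) + B_2 p],$$

the coupled replicator equations are

$$\dot p = p (1-p)\, G_1(p, q), \qquad \dot q = q (1-q)\, G_2(p, q).$$

Note the mirrored out-group terms: an out-group partner of population 1 shows
behavior 1 — cooperative in population 1's frame — with probability $1-q$.
The unit square is forward-invariant and every edge and corner is invariant.

Model assumptions worth keeping in mind: large well-mixed populations,
constant preferences and powers, no spatial or network structure, no
mutation, and payoff levels that matter only through the differences $B$ and
$C$ (the package anchors $T = P = 0$ whenever actual payoff levels are
needed, e.g. for the Nash check).

## Payoff transformations

**Costly punishment.** A unilateral cooperator — whoever receives the
sucker's payoff $S$ in its own frame — sanctions the defecting partner with a
fine $\beta_a$ at a cost $\gamma_a$ to itself. In-group this gives
$b_a' = b_a - \gamma_a$ and $c_a' = c_a + \beta_a$: an in-group PD becomes a
stag hunt exactly when $\beta_a > |c_a|$. In a discoordinated *cross*
encounter each side perceives itself as the unilateral cooperator, so under
the default rule both punish and the cross sucker's payoff drops by the own
cost plus the other population's fine: $B_a' = B_a - \gamma_a -
\beta_{\bar a}$, $C_a' = C_a$. The cross-group PD therefore stays a PD. This
two-sided rule is a modeling choice the package makes explicit: it follows
from applying the punishment trigger ("whoever receives $S$ punishes")
symmetrically in both frames, and it reproduces the three attractors $(0,0)$,
$(1,0)$, $(0,1)$ of the punished-PD portrait. The alternative one-sided rule
($B_a' = B_a - \gamma_a$) is available via `cross = "one_sided"`; all
attractor-level results in this package hold under both.

In the punished-PD reference portrait the fine is read as five times the cost
($\gamma = 2.5$, $\beta = 12.5$). A fine of $\beta = 5$ would still turn the
in-group game into a stag hunt ($c' = 3 > 0$) but leaves the growth bracket
$G_2(0, 1) = 0.2\,c' + 0.8\,C' = -1 < 0$, so the $(0,1)$ norm would not be
asymptotically stable under the stated power; the five-fold reading is the
one consistent with the portrait's three stable points, and
`scenario_fixtures()` uses it.

**Group pressure.** Subtracting $g \ge 0$ from the off-diagonal payoffs $S$
and $T$ (equivalently adding $g$ to $R$ and $P$) gives $B' = B - g$,
$C' = C + g$; a PD becomes a stag hunt exactly when $g > |C|$.

## Stationary solutions and stability

Because $G_1$ and $G_2$ are affine in $(p, q)$, every stationary solution can
be enumerated in closed form (`enumerate_fixed_points()`):

* the four corners;
* edge points, solving the affine restriction of the relevant bracket on each
  edge, e.g. $G_1(p, 0) = 0$ with $p \in (0, 1)$;
* an interior point solving the $2\times2$ linear system $G_1 = G_2 = 0$ when
  its determinant is nonzero and the solution is inside the open square;
* an *equilibrium continuum* — a whole line segment of fixed points — when
  the two zero-sets coincide. Coincidence is declared when, after normalizing
  each coefficient vector to unit sup-norm, the coefficient determinant and
  both augmented determinants are below $10^{-10}$. In the shorthand model
  with $C = -B$ one has $G_2 \equiv -G_1$ and the continuum is the line
  $f(1 - 2p) + (1 - f)(2q - 1) = 0$ for every $f \in (0, 1)$.

Stability is classified from the closed-form Jacobian (exploiting the affine
structure) by eigenvalue real parts with a hyperbolicity tolerance of
$10^{-8}$: both negative is stable, both positive unstable, mixed a saddle,
and any real part within tolerance of zero is reported `nonhyperbolic` —
points on a continuum always are, and they are excluded from basin-label
matching against isolated points. Edge points are classified with the full
2-D Jacobian, since edge equilibria of these portraits are frequently
saddles. Every stable or neutrally stable point should be a Nash equilibrium
of the underlying game; `nash_check()` verifies the no-profitable-unilateral-
deviation property directly from expected payoffs.

```{r}
g <- game_params(B = 1, C = -2, f = 0.8)   # snowdrift, stronger population 1
enumerate_fixed_points(g)
```

The single stable point has the weaker population at an extreme ($q^* \in
\{0, 1\}$) and the overall cooperation $f p^* + (1-f)(1 - q^*)$ equals the
one-population expectation $|B|/(|B|+|C|)$ of the stronger population
exactly — a structural identity of the model that the tests verify to
$10^{-6}$.

## Numerical choices

Integration uses `deSolve::lsodar` with `rtol = 1e-9`, `atol = 1e-11`, and a
root function that stops the run once the sup-norm of the vector field drops
below `eps_conv = 1e-9`. These defaults resolve attractor coordinates well
below $10^{-6}$, comfortably inside the $10^{-4}$ tolerance used for the
attractor-level checks. The state is clamped to the unit square before each
derivative evaluation and on output; the square is forward-invariant, so
clamping only removes roundoff excursions. `find_attractor()` escalates the
horizon over $10^2, 10^3, 10^4$ time units and reports non-convergence
explicitly rather than rounding to the nearest fixed point. A start placed
exactly on any fixed point — including an unstable one — is returned as
converged with zero field. Degenerate inputs ($B$ or $C$ zero within
$10^{-12}$) are classified `degenerate` and rejected by the one-population
predictor rather than silently binned.

Convergence onto a *continuum* is detected by the vector-field norm, not by
proximity to a precomputed point list: near the line the field vanishes
linearly with distance, so the stopping rule applies unchanged. The line
attracts trajectories in the snowdrift orientation ($B > 0$, $C = -B < 0$);
in the stag-hunt orientation the same line consists of unstable points and
trajectories leave it for the shared-norm corners.

## Basins, sweeps, and transitions

`basin_map()` integrates from an $n \times n$ lattice of initial conditions
(boundary points included — they are invariant and label themselves) and
labels each endpoint by outcome: `breakdown` $(0,0)$, `norm_pop1` $(1,0)$,
`norm_pop2` $(0,1)$, `subcultures` $(1,1)$, `continuum`, `mixed_edge`, with
`unresolved` reserved for cells that fail to converge within the budget
(never nearest-matched). The matching tolerance is $10^{-3}$.

`sweep_attractor()` records the attractor from a fixed start across a
parameter grid; `detect_discontinuity()` flags adjacent-value jumps of an
attractor coordinate above `jump_tol = 0.5` — the signature of the
discontinuous ("revolutionary") transition in which the weaker population's
coordinate $q^*$ flips between 0 and 1 as $|B|/|C|$ crosses 1 in the
snowdrift regime. Sweep grids should avoid sampling the degenerate point
$|B| = |C|$ itself, where the whole continuum appears and the recorded
coordinate sits wherever the start projects onto it. The movie-style sweep
(`movie_sweep()`) varies $B$ with $C = -B^3$ and offers the in-group-only and
out-group-only interaction structures alongside the full model.

The norm phase diagram (`phase_diagram_norms()`) uses the
benefit/coordination parametrization $B = b - c$, $C = b + c$ (benefit $b$ of
the preferred behavior, benefit $c$ of coordinating; both the conformity and
the disapproval payoff tables reduce to the same $(B, C)$, which is why the
parametrization is convenient). Every run starts from everyone playing their
own preference, perturbed to $(1-\varepsilon, 1-\varepsilon)$ with
$\varepsilon = 10^{-3}$ because $(1, 1)$ is itself a fixed point; the
perturbation represents an infinitesimally mixed history, and the outcome is
insensitive to $\varepsilon$ over orders of magnitude.

## The finite-population counterpart

`abm_run()` implements the standard proportional-imitation chain whose mean
field is the replicator flow. One elementary step: a population is chosen
with probability proportional to its size; a focal and a model agent are
drawn uniformly without replacement from it; the focal adopts the model's
behavior with probability $\max(0, \Delta E)/\Delta_{\max}$, where $\Delta E$
is the model-minus-focal expected payoff at the current state and
$\Delta_{\max}$ is the maximal payoff difference over the parameter set
(computed once from the bracket values at the four corners, where the affine
brackets attain their extrema). One generation is $N_1 + N_2$ elementary
steps, which makes the per-generation drift equal to the replicator field
divided by $\Delta_{\max}$ regardless of the population sizes.

Design choices made here, deliberately:

* $f$ is the payoff/influence weight and is varied independently of the
  population sizes — power may stem from resources or status, not only
  numbers. Tie $f$ to sizes yourself via `f = N1/(N1+N2)` if you want the
  size interpretation.
* The global $\Delta_{\max}$ normalization keeps imitation probabilities in
  $[0, 1]$ and yields the standard mean field.
* No mutation by default (the deterministic model has none); a `mutation`
  rate is available for robustness studies.
* A single seeded generator (R's RNG via `set.seed()`); replicates offset the
  seed deterministically, so every series is bitwise reproducible.

Monomorphic states are absorbing, so for finite $N$ the chain eventually
fixates even where the flow has interior attractors; on the time scales used
here the chain tracks the flow and concentrates near the deterministic
attractor with fluctuations of order $N^{-1/2}$.

## What the fixtures emulate, and test problem sizes

`scenario_fixtures()` transcribes the reference phase portraits: PD and HG
shorthand games ($B = C = \pm 1$, $f = 0.8$), the stag-hunt panels
($|B|, |C| \in \{1, 2\}$, $f \in \{1/2, 0.8\}$), the snowdrift panels
including the $C = -B$ continuum case, the punished PD, and the mixed
SH-vs-PD pairing. These are *parameter sets*, not data: the model has no
external inputs, so the fixtures fully determine the study conditions and
passing tests show faithfulness to the stated dynamics — they say nothing
about how well replicator dynamics describe any empirical population.

The test suite runs basin maps at $n = 11$–$21$ (labels are checked to be
refinement-stable away from basin boundaries), grid-scan oracles at
$200 \times 200$, 1000 random Jacobian draws against central differences,
and ABM checks with $N = 2000$ per population, 100 replicates, and 200–400
generations — lengths chosen as several multiples of the mean-field
convergence time implied by the per-generation drift. Full-resolution
($101 \times 101$) maps and sweeps remain a few-minute desk computation via
the same functions.

## Known limitations

* Two behaviors, two populations; the `game_params` container does not
  generalize to more.
* No bifurcation continuation: transitions are located by dense sweeps only.
* No center-manifold analysis at nonhyperbolic points; the continuum is
  reported and matched, not analyzed further.
* No interaction-rate asymmetry beyond $f$, no spatial/network structure, no
  finite-population diffusion approximations.
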