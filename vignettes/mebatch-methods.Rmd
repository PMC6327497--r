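---
title: "Simulating batch growth of metabolism-and-expression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating batch growth of metabolism-and-expression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mebatch)
```

This vignette is the package's account of its methods: the growth model
and how it is solved, the dynamic simulation loop in both modes, the
design choices that were genuinely open, and what the desk-scale tests
do and do not demonstrate.

## The growth problem

A metabolism-and-expression (ME) model couples metabolic fluxes to the
expression machinery that sustains them. Its defining feature is that
the constraint data depend on the growth rate: stoichiometric
coefficients and flux bounds are functions of $\mu$, for instance
because macromolecule dilution scales linearly with growth while
translation capacity saturates hyperbolically. Growth maximization is

$$\max_{\mu,\,v} \ \mu \quad \text{s.t.} \quad S(\mu)\,v = 0,\qquad
l(\mu) \le v \le u(\mu),$$

a linear program at any fixed $\mu$ and quasi-convex in $\mu$: if the
program is feasible at some $\mu_1$ it is feasible at every
$\mu < \mu_1$. The optimum is therefore located by bisection on
$[0, \mu_{\max}]$, shrinking the bracket until its width falls below
`tol` (default $10^{-6}$ h$^{-1}$) and returning the last feasible
$\mu$ with its flux vector.

**$\mu$-dependence.** Coefficients are restricted to three forms —
constant $a$, linear $a + b\mu$, hyperbolic $a\mu/(b+\mu)$ with $b>0$ —
which cover the dependencies that arise in ME-type models (dilution
terms, translation-rate saturation) while keeping every fixed-$\mu$
instantiation finite on the bracket and the whole model serializable to
JSON. Arbitrary callables were rejected for exactly that
serializability.

**Enzyme coupling.** In the base formulation each catalytic complex is
an ordinary network species: its formation reaction carries $+1$ on the
complex row, and each catalyzed reaction $j$ carries a dilution coupling
$-\mu/k^{\mathrm{eff}}_{ij}$, so mass balance on the complex row states
that synthesis exactly replaces growth dilution of the enzyme pool
($e_i = \sum_j v_{ij}/k^{\mathrm{eff}}_{ij}$, $v^{form}_i = \mu e_i$).
The explicit inequality $\sum_j v_{ij}/k^{\mathrm{eff}}_{ij} \le p_i$
appears only in the inertia mode, where $p$ is a variable.

**Shared proteome budget.** The model JSON supports an optional budget
$\sum_i c_i\, p_i \le e_{\max}$ over complex concentrations. When $p$ is
not an explicit variable this is encoded on formation fluxes as
$\sum_i c_i\, v^{form}_i \le \mu\, e_{\max}$ (equivalent because
$p_i = v^{form}_i/\mu$ at balance); in inertia mode it constrains the
$p$ variables directly. The budget is what makes the toy models display
substrate preference: both encodings reproduce the same closed-form
optima, which would not be true had the budget been expressed as a
fixed bound on formation fluxes alone.

**Units.** Fluxes mmol/gDW/h, extracellular concentrations mmol/L,
complex concentrations mmol/gDW, biomass gDW/L, $\mu$ 1/h, molecular
weights kDa. $\mu_{\max}$ defaults to 2 h$^{-1}$, safely above
bacterial-scale growth.

## Solving the fixed-μ programs

No dedicated LP solver is assumed; the polytope computations are
delegated to the dual active-set quadratic-programming method of
\pkg{quadprog}, used two ways:

* **Feasibility and canonical point.** Projecting the origin onto
  $\{A x = b,\ l \le x \le u\}$ (minimize $\|x\|^2$) either returns a
  feasible point or reports the constraints inconsistent — an exact
  feasibility oracle, which is all bisection needs. The minimum-norm
  point is also the deterministic canonical solution reported at the
  optimum; at the growth optimum of a budget-limited model the feasible
  set is essentially a single point, so the choice is immaterial there.
* **Linear objectives.** `solve_lp()` with an objective adds a tiny
  quadratic ridge ($\min c'x + \varepsilon\|x\|^2$,
  $\varepsilon = 10^{-8}$), which for small $\varepsilon$ returns the
  minimum-norm point of the optimal face; a solution escaping to the
  $O(1/\varepsilon)$ scale is reported as unbounded.

Double precision with a $10^{-9}$ feasibility tolerance is deliberate:
the desk-scale models here are well-scaled (coefficient range under
$10^6$). Genome-scale ME reconstructions are famously ill-conditioned
and are solved in practice with quad-precision solvers at far tighter
tolerances; that regime is outside this package's scope and is the main
known limitation for transferring it to full-size models. Inequalities
are carried as equality rows with explicit non-negative slacks so one
problem shape serves both formulations.

## Protein inertia

The inertia formulation makes the proteome a state variable. For every
complex $i$ the mass-balance row is removed and replaced by

$$v^{form}_i - \mu p_i = \delta_i, \qquad
\sum_{j \in CAT(i)} v_{ij}/k^{\mathrm{eff}}_{ij} \le p_i, \qquad
p_i = p^0_i + \delta_i H,$$

with $p \ge 0$ and $v^{form} \ge 0$: no active degradation, so
abundance falls only when dilution outpaces formation
($\delta_i < 0 \iff \mu p_i > v^{form}_i$). $H$ (default 2 h) is the
horizon over which the optimization anticipates re-allocating the
proteome; it is independent of the simulation step.

For the single-substrate toy the optimum has a closed form from
$p^0 = 0$:
$\mu^*(H) = e_{\max}(k^{\mathrm{eff}} - q/H)/(b + q\,e_{\max})$ (clipped
at 0; $b$, $q$ the biomass and enzyme synthesis costs), which the test
suite checks at several horizons; $H \to \infty$ recovers the base
optimum.

One behavior is worth flagging because it is easy to mispredict:
starting **at** the steady-state proteome with a finite horizon, the
optimum is slightly *above* the steady-state growth rate. The model may
set $v^{form} = 0$ and let the standing enzyme pool dilute over the
horizon, re-investing the saved synthesis cost into growth — transient
"coasting". The gain vanishes as $H$ grows. This is a genuine property
of the formulation, not a solver artifact; the suite asserts it
explicitly.

## Batch dynamics

The extracellular state is concentrations $c$ (mmol/L) and biomass $X$
(gDW/L). The literature this loop descends from does not pin down an
integration rule, so the package declares one: biomass updates
exponentially, $X' = X e^{\mu\,\Delta t}$ (exact while $\mu$ is
constant), and concentrations by forward Euler with start-of-step
biomass, $c_i' = c_i + v_i X \Delta t$ plus any feed. The scheme's
$O(\Delta t)$ carbon-balance defect is testable and halves when the
step halves, which the suite verifies on a two-substrate batch.

**Event-driven mode.** Uptake bounds do not depend on concentration;
an available substrate's exchange lower bound is the effectively
unconstrained $-1000$ mmol/gDW/h and a depleted one's is 0, so the
growth solution only changes when the *availability set* changes.
One optimization runs at $t=0$ and afterwards only on depletion,
feed-window boundaries, or a secreted product crossing the availability
threshold ($10^{-9}$ mmol/L, then clamped to zero — floating-point
hygiene for the set). Fixed overrides (e.g. an oxygen-style global cap
of $-20$ mmol/gDW/h) can be pinned per reaction in the configuration.
Every solve is logged with its trigger, which makes "how many solves and
why" a first-class, testable output. Michaelis–Menten uptake kinetics
and product inhibition are deliberately out of scope; with them one
would re-solve every step and the event machinery would be moot.

**Variable step.** Before each step,
$\Delta t = \min\{\Delta t_0,\ \min_i c_i/(-r_i),\ \min_i p_i/(-\delta_i)\}$
over the species that would otherwise be driven negative ($r_i$ the net
volumetric rate including feed), so trajectories land exactly on
depletion events; rates below $10^{-12}$ and pools below $10^{-12}$ are
ignored as solver noise (the updater clamps sub-tolerance negatives to
zero). Subsequent steps continue with $\Delta t_0$ without re-aligning
to the original grid; downstream comparisons interpolate, so nothing
depends on grid phase.

**Inertia mode** re-solves at every step (the proteome can change even
in a constant environment), advances $p \leftarrow p_0 + \delta\,
\Delta t$ with the *realized* step — the horizon only shapes the
optimization — and includes the protein term in the step rule.

## Toy fixtures

The fixtures exist so that every algorithm in the package can be tested
against pencil-and-paper results. All share one architecture: substrate
→ common precursor M → biomass and enzymes, one uptake enzyme per
substrate, one shared budget. `TOY1` (one substrate, $k^{\mathrm{eff}}
= 10$/h, costs 10 and 100, $e_{\max} = 0.01$) has
$\mu^* = 1/110$; doubling the budget gives $1/60$. `TOY2` adds a
five-fold less efficient substrate: the budget makes preference strict,
and the batch shows a clean diauxic switch with exactly two solve
events. `TOY5` has five substrates with staggered efficiencies, an
uptake cap on the second (which forces a genuinely mixed phase), and an
overflow by-product secreted during the first phase and re-consumed at
the end — the single → mixed → re-consumption phase ordering appears in
one 20 h batch. Initial concentrations were chosen once so that the
full cascade completes within that batch at the fixtures' slow growth
rates. Synthetic "measurements" are simulations shifted by a planted
lag with i.i.d. Gaussian noise added (clamped at zero for
concentrations) — a deliberately simple error model chosen for
testability, with no claim to microarray error structure.

What the toys do *not* emulate: genome-scale stoichiometry, coefficient
ill-conditioning, realistic uptake kinetics, or quantitative growth
physiology. Passing tests demonstrate algorithmic correctness, not
biological accuracy on real data.

## keff ensembles and archetypes

Effective rate constants are the dominant uncertain parameters, so
predictions are stress-tested by sampling them: each targeted coupling
is multiplied by an independent factor, log-uniform on $[0.1, 10]$ —
the stated range, with the distribution a package choice: symmetric in
log space, median 1, halves above and below. Factors are i.i.d. across
couplings (nothing known argues for a correlation structure). Fit
against measured concentrations is scored by the sum of squared errors
on a common grid; the "consistent ensemble" keeps samples under a
user-set SSE threshold, defaulting to $1.5\times$ the best sample since
no canonical cutoff exists.

Ensembles of time courses are summarized by archetypal analysis: flatten
each run to a feature vector (time-major, species lexicographic within
each timepoint), then factor $X \approx ZA$ with $Z = XB$, columns of
$A$ and $B$ on the probability simplex. Fitting alternates exact block
updates — each column of $A$ given $Z$, then each column of $B$ with the
others fixed — each a small quadratic program, so the residual is
non-increasing by construction; iteration stops at a $10^{-6}$ relative
change or 500 sweeps, with a $10^{-10}$-scaled ridge guarding
rank-deficient blocks. Initialization takes $p$ mutually far data
columns (FurthestSum), reproducible under a seed. Columns are not
standardized by default (the profiles share units); a `scale` flag
exists. Since "pick the elbow of the scree" is a visual rule, the
package makes it explicit: the interior point with the largest
perpendicular distance to the chord joining the scree's endpoints, ties
to the smallest $p$. Companion views (proteome, exchange fluxes) map
through $B$, i.e. each archetype's companion profile is the same convex
combination of sample profiles that defines the archetype.

## Calibration by list-based threshold accepting

The calibration objective — multipliers on targeted couplings →
simulate → SSE against measured concentrations — is noisy-free but
non-smooth, so a threshold-accepting local search is used. The specific
variant: a warm-up random walk of $5L$ moves builds a list of the $L$
largest *relative* worsenings $(Z_k - Z_0)/|Z_0|$; afterwards a move is
accepted iff its relative worsening is below the list maximum
$T_{\max}$, and every accepted worsening overwrites $T_{\max}$ with the
(smaller) realized value, so the threshold anneals monotonically.
Proposals perturb one coordinate multiplicatively (log-space, reflecting
at the bounds, span up to the `neighborhood` factor, default 2) —
natural for rate-constant multipliers bounded in $[0.1, 10]$. The
hyperparameters ($L = 8$, 300 iterations, warm-up $5L$) are declared
defaults, all exposed in `lta_config()`; evaluations are memoized on
rounded log-multipliers.

The multi-walker mode is a *contract*, not a threading implementation:
walker 1 is purely local; at synchronization points every
`restart_period` iterations the others jump to the global best if it
beats their current point. Chains run serially in round-robin order with
per-walker RNG substreams, so a concurrent implementation that exchanges
the best only at sync points would produce identical output — and
single-walker runs are bitwise reproducible under a seed.

## Validation against expression time courses

Predicted proteome composition is summarized as mass fractions, defined
from translation fluxes ($f_j = v^{trsl}_j w_j / \sum_k v^{trsl}_k w_k$)
in the base mode and from complex concentrations in the inertia mode.
After growth stops all synthesis fluxes are zero and the fractions are
formally undefined; the trajectory helper carries the last defined
composition forward, since zero synthesis leaves the standing proteome
unchanged. Fractions can be exactly zero, so the log2 transform clamps
at $10^{-6}$ first.

Cross-correlation conventions differ enough between implementations
that the package pins one: for lag $\ell$, the Pearson correlation of
the overlapping pairs $(x_t, y_{t+\ell})$, with mean and variance
computed on the overlap; a zero-variance overlap yields a missing
value, never 0, and missing proteins are excluded from the per-lag
median. Profiles are first linearly interpolated onto a common regular
grid (the smaller of the two native intervals, 0.1 h in the intended
use); the lag scan covers $[-1.7, 1.7]$ h by default and reports the
single lag maximizing the median per-protein correlation, ties to the
smallest absolute lag. With this orientation a positive lag means the
predictions run ahead of the measurements. The property suite checks the
convention against a reference implementation and recovers planted
shifts exactly on the grid (and within one grid step at
signal-to-noise 10).

## Problem sizes and runtimes

The shipped tests and the acceptance script run the complete pipeline at
fixture scale: models with 4–19 reactions, batches of 100–200 steps,
ensembles of 4–200 samples, archetype problems of 40 samples × 10
features, and calibration budgets of ≤ 500 simulation evaluations —
sizes chosen so that each analysis answers its question in seconds while
still exercising every code path. Scaling beyond that (thousands of
reactions, quad-precision tolerances, MPI-distributed walkers) is
explicitly out of scope.
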