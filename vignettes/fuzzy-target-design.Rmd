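---
title: "Fuzzy multiobjective target design on power-law kinetic models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy multiobjective target design on power-law kinetic models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fmdd)
```

## The problem

Enzymopathies such as the dopamine deficiencies behind Parkinsonian motor
symptoms can, in a kinetic model of the affected pathway, be phrased as a
target-design question: which enzyme activities or external inputs should a
drug regulate, and by how much, so that the therapeutic species returns to
its healthy level, toxic by-products stay low, the intervention itself stays
small (the low-dose principle), and as few targets as possible are touched?
These goals conflict, and `fmdd` treats them as a single fuzzy
multiobjective decision problem rather than a two-stage screen-then-choose
procedure.

## The kinetic model

Networks are represented in generalized mass action (GMA) form. Species
concentrations $x \in \mathbb{R}^n_{>0}$ evolve as

$$\frac{dx}{dt} = N\,v(x,\alpha) + B\,u,$$

with stoichiometric matrix $N$, external controls $u$ entering through a
connectivity matrix $B$, and each reaction rate a power law

$$v_k = \alpha_k \prod_l x_l^{g_{kl}},$$

where $\alpha_k$ is the rate constant (the drug-regulable enzyme activity)
and $g_{kl}$ are real-valued kinetic orders. We adopt the standard
convention $0^0 = 1$, so zero-order reactions remain well-defined constant
fluxes. A disease is a *restriction*: a deficient enzyme's activity is fixed
at $\alpha^{DS} = (1-\delta/100)\,\alpha^{basal}$ for deficiency percentage
$\delta$, and that reaction is excluded from the regulable set.

Steady states solve $N v + B u = 0$. The primary solver is a damped Newton
iteration on log-concentrations $y = \log x$: in log space the power law
becomes affine, iterates stay positive, and the Jacobian
$N\,\mathrm{diag}(v)\,G$ is available in closed form. Steps are halved until
the residual decreases, with a trust region of 5 log units. If Newton
stalls, the balance ODE is integrated (`deSolve::lsoda`) over expanding
horizons from the initial guess and the result polished by Newton. The
default tolerance is a max-norm residual below $10^{-10}$ times the basal
flux scale.

Log space cannot represent a concentration of exactly zero, yet severe
deficiencies genuinely empty some pools (an extracellular dopamine pool
with a saturated, effectively zero-order clearance collapses once its
influx falls below the clearance rate). We therefore floor concentrations
at $\varepsilon = 10^{-9}$ relative units; a species pinned at the floor
whose net balance still drains it is treated as balanced-at-zero, excluded
from the convergence norm, and flagged *effectively zero* in the result.
This keeps the log transform intact while reporting the collapse regime
honestly.

## Fuzzy objectives and the decision problem

Each design goal is graded by a membership function mapping the relevant
quantity to a satisfaction grade in $[0,1]$:

* **fuzzy-equal** (therapeutic species, variation of regulated activities):
  grade 1 on a plateau around the basal value, falling monotonically to 0
  at outer bounds $x^{LB}, x^{UB}$;
* **fuzzy-minimize** (toxic species, dosing controls): grade 1 at or below
  basal, falling monotonically to 0 at $x^{UB}$.

Five monotone branch shapes are available (linear, exponential, hyperbolic,
inverse, piecewise-linear); the default is linear, which is also the shape
that self-consistently reproduces the published grade/fold pairs we use as
a calibration oracle in the test suite (e.g. $(10-f)/9$ for adverse folds
$f$). Default breakpoints are expressed as folds of basal: therapeutic
species rise from 0 at $0.1\times$ basal to a degenerate plateau at basal
and fall to 0 at $10\times$ basal; adverse species are zero-graded at
$10\times$ basal. These folds are a calibration choice consistent with the
published tables, not a universal constant, and every spec can be
overridden per objective.

Variation-effect grades are computed on the *fold change* of each regulable
activity (plateau at fold 1, zero at folds 0.1 and 10 by default). The
published sources never state their variation-effect breakpoints, so these
defaults are explicitly package choices — absolute satisfaction grades of
optimal designs are therefore not comparable across tools, and we treat
published optimal grades as qualitative ordering information only.
Controls are split by a simple rule the user can override: controls with a
positive basal value (ordinary inputs such as tyrosine intake) are graded
fuzzy-equal on their fold, while zero-basal controls (dosing inputs absent
in health, such as exogenous L-DOPA or a dopamine agonist) are graded
fuzzy-minimize on their absolute value.

The overall satisfaction grade is $\lambda = \min_i \eta_i$, and the design
objective multiplies it by the target-count factor
$(Z^{UB} - \sum_j z_j)/(Z^{UB} - 1)$, which equals 1 for a single target
and decreases linearly as targets are added ($Z^{UB}$ defaults to 10). The
max–min problem is solved with $\lambda$ as the implicit objective: for a
fixed binary selection $z$, the selected activities (log-fold scale,
bounds $\pm\ln 10$ by default) and controls are the only free variables,
every other activity is pinned to basal exactly (the switched-bound
collapse), and we maximize the minimum grade of the resulting steady
state.

## The nested search

`solve_fixed_targets()` handles the continuous inner problem. With one
decision variable it evaluates a 41-point grid and refines the best
bracket by golden-section search; with several it runs multistart
Nelder–Mead from the basal point plus Latin-hypercube starts
(`lhs::randomLHS`, seed-controlled, 8 starts by default). The min-grade
objective is piecewise smooth; Nelder–Mead is robust to its kinks, and on
synthetic problems the solver matches dense grid-search oracles to within
0.01 (this is asserted in the test suite). Ties in $\lambda$ are broken
toward the smallest deviation from basal — implemented as a $10^{-6}$
deviation penalty, aligning with the variation-effect intent. A candidate
whose steady state fails to converge grades to $\lambda = 0$ and is
flagged infeasible rather than propagating NaNs.

`nhde_search()` handles the outer combinatorial problem with a nested
hybrid differential evolution: individuals are fixed-length integer codes
naming the selected targets (0 marks an empty slot in free-cardinality
mode), mutated by rounded difference vectors reflected into range,
recombined binomially (defaults $F = 0.5$, $CR = 0.8$, population 20, 200
generations — all configurable), and repaired by redrawing duplicate
indices. Selection is two-step: a one-to-one parent/trial competition,
then an incumbent update; ties prefer fewer targets, then the
lexicographically smaller code, so the best fitness is non-decreasing by
construction. Two hybrid operators complete the algorithm: *acceleration*
(a small one-swap hill climb on the incumbent each generation) and
*migration* (when the fraction of distinct codes falls below 0.1, all but
the incumbent are re-seeded). Every evaluated subset is memoized, and each
subset's inner solve derives its seed from the run seed and an
order-independent subset hash, so results are independent of evaluation
order — the contract a parallel evaluator would need, and the reason a
fixed seed reproduces byte-identical results. Fixed-cardinality sweeps and
combination searches (a drug class's known targets forced into every
candidate, with the search free over the complement) are thin wrappers.

## The synthetic data generator and the packaged dopamine network

`generate_random_gma()` builds test networks by construction rather than
rejection: it draws a layered pathway (main chain, a downstream toxic
byproduct branch so therapeutic and adverse objectives are both
exercisable, random extra forward edges), routes a unit influx through
per-species Dirichlet-like splits (every species keeps at least ~20% of
its throughput as terminal efflux), draws substrate kinetic orders from
[0.3, 1] (sub-linear to linear, the range typical of biochemical systems
models, and comfortably conditioned for Newton), and then back-solves each
rate constant as assigned flux over the power-law product. The designated
state is therefore a steady state to machine precision, which the tests
verify at $10^{-10}$.

The packaged dopamine network (`load_dopamine_model()`) is built the same
way from a hand-specified pathway map: tyrosine hydroxylase, AADC, VMAT2
packaging, vesicular release, DAT reuptake, intracellular/extracellular
MAO and COMT, quinone formation and thiol conjugation, the glutathione
cycle, and superoxide/peroxide/hydroxyl-radical and NO-derived branches,
with 34 dependent metabolites, 68 reactions, 3 external controls
(tyrosine intake `u_t`, exogenous L-DOPA `u_l`, dopamine dosing `u_d`)
and 18 independent variables recorded as metadata (constant cofactors and
enzyme amounts absorbed into the rate constants). Basal concentrations of
the reported metabolites are matched exactly by construction (extracellular
dopamine 400 relative units in health). It is, deliberately and
prominently, a **synthetic stand-in**: the original model's parameter
listing was published only as supporting material we do not redistribute,
and inventing "the" parameters would misrepresent them. The stand-in
reproduces the qualitative disease regimes — extracellular dopamine falls
monotonically with VMAT2 deficiency, collapses to the effectively-zero
flag for deficiencies above 90% (a zero-order clearance component sets the
collapse threshold), and stays nonzero under complete TH deficiency
because exogenous L-DOPA feeds DOPA decarboxylase — but its quantitative
fold changes are illustrative only. The acceptance-level tests that
compare against the original model's printed fold changes are kept in the
suite and fail on the stand-in by design, documenting exactly which
numbers depend on the unpublished parameters.

What passing tests do and do not show about real data follows directly:
the engine, memberships, inner solver and outer search are verified
against closed forms, independent oracles and printed calibration values;
conclusions about the real dopamine network require the real parameters.

## Numerical choices and degenerate inputs

* Residual tolerances are relative to the basal flux scale; consistency of
  a loaded model requires a basal residual below $10^{-8}$ on that scale.
* Exponent clipping at $\pm 500$ guards the log-space rate evaluation and
  is reported via a flag rather than silently.
* A zero rate constant is allowed only as a disease knockout; negative
  concentrations or activities are domain errors.
* Fold changes against a zero reference are reported as `NA` with status
  `"undefined"`, never as infinity.
* Empty target selections are valid (they grade the scenario itself) and
  take a count factor of 1.
* Problem sizes in the tests are deliberately small (toy network, 5–9
  species synthetic networks, single- and two-target searches, population
  6 × 8 generations over 20 seeds), chosen so the full suite exercises
  every oracle comparison in about two minutes.

## Known limitations

Only GMA/power-law kinetics are supported (no Michaelis–Menten or
convenience kinetics), there is no parameter estimation and no stochastic
simulation, the inner solver carries no global-optimality certificate, and
the outer search is a heuristic — on small instances it provably matches
exhaustive enumeration in the suite, on large ones it inherits the usual
evolutionary-search caveats. Doses are activity folds and control levels
in relative units; no pharmacokinetics is implied.
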