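# fmdd — fuzzy multiobjective drug-target discovery on power-law kinetic models

`fmdd` identifies candidate enzyme drug targets in generalized mass action
(GMA) kinetic models of metabolism. It is aimed at computational systems
biologists who have (or can generate) a power-law model of a diseased
pathway and want a principled, reproducible answer to: *which activities
should be regulated, by how much, to restore the therapeutic species while
keeping toxic by-products, dose size and target count low?*

## The model and the decision problem

A network follows $dx/dt = N\,v(x,\alpha) + B\,u$ with power-law rates
$v_k = \alpha_k \prod_l x_l^{g_{kl}}$ (rate constants $\alpha$, kinetic
orders $g$, external controls $u$). A disease fixes a deficient enzyme at
$\alpha^{DS} = (1-\delta/100)\,\alpha^{basal}$ and removes it from the
regulable set.

Every design goal is graded by a fuzzy membership $\eta \in [0,1]$:
therapeutic species are *fuzzy-equal* to their healthy level, toxic
species and dosing inputs are *fuzzy-minimized*, and regulated activities
are graded on how little they deviate from basal. The design maximizes

$$\frac{Z^{UB} - \sum_j z_j}{Z^{UB} - 1}\;\lambda,
\qquad \lambda = \min_i \eta_i,$$

over the binary target selection $z$, the selected activity folds and the
control levels, subject to the steady-state constraints — a mixed-integer
problem solved by a nested hybrid differential evolution (NHDE): an
integer-coded evolutionary outer search over target subsets, each
evaluated by a continuous inner solve (multistart Nelder–Mead /
golden-section in log space), with memoization, migration and
acceleration operators, deterministic for a fixed seed.

The package ships a clearly labelled **synthetic stand-in** of the
presynaptic dopamine network (34 metabolites, 68 reactions, controls for
tyrosine intake, exogenous L-DOPA and dopamine dosing) with VMAT2/TH
deficiency scenarios and current Parkinson's-disease drug-class presets,
plus generators for random consistent GMA networks. See the vignette
(`vignettes/fuzzy-target-design.Rmd`) for what the stand-in does and does
not reproduce.

## Worked example

```r
library(fmdd)

net <- load_dopamine_model()
tab <- run_scenario_table(net, c("HS", "VM50", "VM90"))
tab$summary
#>   scenario status     T     A V lambda overall targets
#> 1       HS     ok 1.000 1.000 1  1.000   1.000
#> 2     VM50     ok 0.316 0.967 1  0.316   0.316
#> 3     VM90     ok 0.000 0.926 1  0.000   0.000

subset(tab$folds, scenario == "VM50" &
                  metabolite %in% c("DA-e", "DOPA-Q", "DA-Q", "HO"))
#>  scenario metabolite basal  fold grade      status effectively_zero
#>      VM50     DOPA-Q     5 1.000 1.000       Toxic            FALSE
#>      VM50       DA-e   400 0.384 0.316 Therapeutic            FALSE
#>      VM50       DA-Q    10 1.220 0.976       Toxic            FALSE
#>      VM50         HO     2 1.101 0.989         ROS            FALSE
```

Reading: a 50% VMAT2 deficiency drops extracellular dopamine to 0.384 of
its healthy level (therapeutic grade 0.316 under the default linear
membership rising from 0 at fold 0.1 to 1 at fold 1), while the quinone
and radical species rise mildly (adverse grades near 1). A target search
then looks for regulations that lift the minimum grade:

```r
sets <- dopamine_objective_sets(net, Z_UB = 10)
prob <- decision_problem(net, sets, scenario = dopamine_scenario(net, "VM50"))
res  <- nhde_search(prob, nhde_config(pop_size = 10, generations = 10, seed = 1,
                                      inner = list(n_starts = 3, maxit = 80)))
res$best
#> design point: {a68, u_l, a25} lambda=0.843 overall=0.655
#>   values: a68=2.329, a25=0.8769, u_l=5.171
```

The best three-target design reaches a minimum satisfaction grade of
0.843; the overall objective 0.655 discounts it for using three targets
(factor $(10-3)/9$). Values are activity folds of basal (`a68`, `a25`)
and an absolute control level (`u_l`). This run takes a couple of minutes
on one CPU; `fixed_cardinality_sweep()` and `combination_search()` explore
target-count trade-offs and drug-class combinations the same way.

A thin command-line launcher is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "fmdd.R", package = "fmdd"))')" \
  simulate --model dopamine --scenario VM50 --out results/
```

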