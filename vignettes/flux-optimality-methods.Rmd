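---
title: "Testing evolutionary optimality of central metabolism with ratio-constrained FBA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing evolutionary optimality of central metabolism with ratio-constrained FBA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evoflux)
```

## The question

Flux balance analysis (FBA) is an evolutionary optimality model: it assumes
selection has pushed a cell's internal fluxes toward the distribution that
maximizes some criterion — biomass yield per substrate (BM/S), ATP yield per
substrate (ATP/S), or those yields per unit of total enzymatic flux (BM/Σv,
ATP/Σv). Experimental evolution lets this assumption be tested directly:
measure branch-point flux ratios (from ^13^C labeling) in an ancestor and in
its evolved descendants, and ask whether the descendants moved *toward* or
*away from* the criterion-optimal flux distribution.

`evoflux` implements that test as a pipeline: stoichiometric model in, per-
strain physiology and replicate-structured flux-ratio observations in;
percent optimality, distance to the nearest optimal flux distribution,
Pareto-surface distance, sensitivity scans, and ancestor-versus-evolved
statistics out.

## The model and its machinery

### Ratio-constrained linear programming

A flux ratio is a linear-fractional function of the flux vector,
$R = \mathrm{num}(v)/\mathrm{den}(v)$, e.g. the fraction of oxaloacetate made
from PEP among all oxaloacetate producers. An observed ratio $R$ is embedded
by appending the homogeneous row

$$\mathrm{num}(v) - R\,\mathrm{den}(v) = 0$$

to the stoichiometric constraint system (`embed_ratio_constraint()`). This
is exact whenever $\mathrm{den}(v) > 0$, which the package enforces by
requiring denominator reactions to be irreversible (or split). Bound-mode
observations use the corresponding one-sided inequality; interval modes
(used for the lactate-style ±5 % relative bounds and the knockout-style
± SE bounds) use a pair of inequalities. The base model object is never
mutated — ratio rows live in a separate `flux_problem`.

**Percent optimality** for a criterion is
$100 \times \text{(constrained optimum)} / \text{(unconstrained optimum)}$
(`percent_optimality()`). Because only criterion *values* are compared, the
measure is insensitive to alternate optima.

### The four criteria

With substrate uptake fixed to the observed rate, maximizing yield per
substrate is the same LP as maximizing the biomass (or maintenance-ATP)
flux. For the ATP criteria, the maintenance flux is maximized subject to a
biomass floor representing the ancestral growth rate. The per-flux criteria
maximize $f(v)/\sum_i |v_i|$, a linear-fractional program solved by
Dinkelbach iteration: repeatedly solve the LP
$\max f(v) - \lambda \sum |v_i|$ and update
$\lambda \leftarrow f(v^*)/\sum|v^*_i|$ until the LP value is ~0
(tolerance 1e-9 on the certificate, cap 50 iterations; convergence is
finite because each iterate is a vertex). $\sum|v|$ is linearized by
splitting reversible reactions into forward/backward parts; by default it
runs over internal (non-exchange) reactions so the fixed uptake does not
dominate the enzymatic-burden proxy (`include_exchanges` switches this).

All LPs are solved by an internal dense two-phase primal simplex with
Bland's anti-cycling rule (`solve_lp()`). The problems here are small
(tens of variables), where a termination-guaranteed dense method is more
robust than a tuned sparse solver; the test suite cross-checks it against
exhaustive vertex enumeration and an independent simplex implementation.

### Distance to the nearest optimal flux distribution

Per-substrate criteria usually have many equally optimal flux
distributions, so each strain is compared against the *closest* one
(`closest_optimal_ratios()`): the criterion is pinned at its optimum, each
ratio residual $\mathrm{num}(v) - R_{obs}\mathrm{den}(v)$ is absorbed into
a pair of nonnegative deviation columns, and the LP minimizes their sum.
This L1 construction selects the solution; the reported distance
$D$ is the Euclidean norm over the predicted-vs-observed *ratios* of that
solution, and both numbers are exposed (plus an optional exact quadratic
minimization via `quadprog` for cross-checking). Note the deliberate,
documented discrepancy: the LP measures deviations in denominator-weighted
flux units, the headline distance in ratio units. For the scale-invariant
per-flux criteria the optimum is pinned by the linear certificate
$f(v) - \lambda^*\sum|v| \ge -\varepsilon$ together with a flux-sum scale
pin, since otherwise a scaled-down vector could hide inside the tolerance.

The evolved-versus-ancestor summary is
$\log_{10}(D_{AO}/D_{EO})$ (`distance_metric()`): positive when the evolved
strain sits nearer its optimum than the ancestor did, negative when it
moved away, with both distances floored at $10^{-6}$. The mirrored
convention is available via `sign_convention` because figure labellings of
this quantity are ambiguous in the literature.

### Pareto surface

`build_pareto_surface()` runs the nested grid search at fixed uptake: an
outer grid over feasible biomass, an inner grid over feasible maintenance-
ATP at each biomass, minimizing $\sum|v|$ at every node, then discarding
dominated nodes. Coordinates are standardized by their unconstrained maxima
and the flux-sum axis is mapped to $1 - \Sigma v/\Sigma v_{max}$ so all
three axes point "better-ward" — a Euclidean distance over mixed-orientation
axes would be meaningless. $\Sigma v_{max}$ is the largest minimal flux sum
on the surface (the standardization constant is not uniquely pinned by
convention; this choice keeps all standardized coordinates in [0, 1]).
`pareto_distance()` then finds, for each surface point, the achievable flux
distribution under the observed ratio constraints closest in L1
(standardized units) and reports the minimal Euclidean distance over the
grid — a conservative "closest possible position".

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| maintenance lower bound | 8.9 | mmol ATP/gCDW/hr | the standard non-growth ATP drain for the *E. coli* genome-scale model; 8.39 appears in parts of the literature and is settable, not silently reconciled |
| substrate/excretion bounds | observed ± 1 SE | mmol/gCDW/hr | observations constrain as equalities within measurement error; exact equality when no SE is given |
| oxygen bound (evolved) | ancestor O₂ × scaled uptake ratio | mmol/gCDW/hr | evolved oxygen uptake is unmeasured in two of the three designs; the ancestral oxygen/substrate ratio is preserved (slope 1), scanned 0.5–1.5 |
| ancestral oxygen uptake | 14.75 | mmol/gCDW/hr | top of the literature range 11.5–14.75, the default reporting point |
| biomass floor (ATP criteria) | 0.9 × ancestor's ratio-constrained biomass optimum | 1/hr | stands in for the measured ancestral growth rate, which sits below the model optimum; a floor at exactly the optimum is infeasible for noisy replicate data |
| Dinkelbach tolerance | 1e-9 | – | certificate tolerance on $f - \lambda \Sigma|v|$ |
| LP pivot tolerance | 1e-9 | – | dense simplex at these problem sizes is accurate well past this |
| Pareto grid | 20 × 20 (12 × 12 in the pipeline) | nodes | grid approximation of the continuous frontier |
| metric floor $\varepsilon$ | 1e-6 | ratio units | keeps the log metric finite when a strain sits on its optimum |

## The synthetic-data generator

`make_toy_network()` provides three templates with analytically known
optima: the two-path yield toy (`T1_two_path`), its ATP-drain extension
(`T1_plus_atp`), and a ~17-reaction carbon-lumped cartoon of *E. coli*
central metabolism with glycolysis, Entner–Doudoroff, an oxidative
pentose-phosphate branch feeding a biomass-required pentose pool (so the
glycolysis/PPP split is interior at the optimum, as observed in the
organism), anaplerosis in both directions, malic enzyme, the glyoxylate
shunt and acetate overflow. All five branch-point ratios of the long-term-
evolution design have non-degenerate denominators at the biomass optimum.

`simulate_dataset()` emulates the three study designs — ten replicated
populations with a replicated ancestor (`ltee_like`, 3 biological × 3
technical replicates), seven populations against a single-valued ancestor
(`lactate_like`), and paired populations per knockout ancestor (`ko_like`,
deleting the glycolysis, lower-glycolysis or anaplerosis analogue). The
ancestor's true ratios are placed at a prescribed percent optimality by
bisection along the feasible path
$v(t) = (1-t)\,v_{opt} + t\,v_{far}$ between the biomass-optimal flux
distribution and a wasteful anchor (pentose-cycle + futile-cycle +
malic-enzyme flux). Evolved strains shift the path coordinate $t$ — not the
individual ratios — because the set of jointly achievable ratio vectors is
not convex and independent per-ratio shifts can be infeasible to embed; the
truth record carries the realized per-ratio values. Observations add
independent Gaussian noise (SD in ratio units, default 0.02, the scale of
replicate scatter in ^13^C datasets) per technical replicate, truncated to
[0, 1]; ratios whose numerator reactions are deleted are reported as
structural zeros. A single global seed drives per-strain substreams hashed
from the strain id, so adding a strain never perturbs the others.

What the generator does *not* emulate: correlated measurement errors across
ratios (real ^13^C ratio estimates share spectra), model mismatch between
the flux-ratio equations and the true network, non-Gaussian error tails,
and strain-to-strain variation in directions off the optimal-to-wasteful
path. Passing recovery tests therefore demonstrate the pipeline's internal
consistency and statistical calibration, not the biological fidelity of any
particular dataset. One consequence of independent noise is worth knowing:
ratio sets coupled by a structural constraint (e.g. two producer fractions
that must sum to 1 after a knockout) can be *jointly* infeasible; the
pipeline records such replicates as per-strain failures and continues,
which is also how infeasible populations are handled in real analyses.

## Statistics

Ancestor-versus-evolved comparisons (`compare_strains()`) gate a pooled-
variance two-sample t-test (or one-sample against a single ancestral value)
on a Shapiro–Wilk normality check of the residuals at α = 0.05, falling
back to the Mann–Whitney–Wilcoxon test; zero-variance degenerate data go
straight to the rank test. Per-ratio change is assessed with one-way ANOVA
across strains, Tukey HSD contrasts against the ancestor, and Benjamini–
Hochberg FDR over the regression contrasts; multivariate change with MANOVA
(Pillai's trace) on the ratios (`flux_change_tests()`). All of these call
base R's implementations. Uncertainty propagates by computing every
quantity per biological replicate (each the mean of its technical
replicates) and summarizing per strain as mean ± SE.

Note a structural property of Pillai's trace relevant to interpretation:
each separating dimension contributes at most 1, so parallel evolution
(all populations shifted along one direction) yields a modest trace even
when separation is enormous.

## Design choices that were genuinely open

- **LP engine.** No dedicated LP package is assumed; the dense two-phase
  simplex is authored here and oracle-checked. At ≤ a few hundred variables
  this is fast and, with Bland's rule, immune to cycling.
- **Fractional programs** use Dinkelbach iteration rather than a
  Charnes–Cooper transform because fixed nonzero bounds (uptake,
  maintenance) break the homogeneity Charnes–Cooper requires.
- **CV definition.** Cross-population parallelism is the mean over ratios
  of (SD across evolved strains / mean), using sample (n−1) SDs; ratios
  with zero mean are excluded with a note.
- **Knockouts** are reaction-level (`apply_knockout()`), matching how gene
  deletions are simulated by zeroing the corresponding flux; no
  gene–protein–reaction logic.
- **Sensitivity axes** re-run the whole analysis: ancestral oxygen uptake
  (11.5–14.75), oxygen slope (0.5–1.5), evolved maintenance (50–150 % of
  default; a no-op for ATP criteria since the maintenance flux is the
  objective) and evolved biomass lipid content (80–120 %), with infeasible
  settings reported rather than fatal.

## Problem sizes used in the shipped checks

The shipped tests and the acceptance script run entirely on the toy
networks: oracle comparisons enumerate vertices of ≤ 8-reaction fixtures;
recovery, calibration and sign-direction checks use 100–200 seeded
replicates of the two-path toy (a few LP solves per strain); the
genome-scale reproduction path requires a local copy of the published
*E. coli* model and strain tables and is exercised by the same functions.

## Known limitations

- The L1-selected closest-optimal solution is a proxy for the true L2
  minimizer on degenerate optimal faces (both are reported; the QP
  cross-check is available).
- The Pareto distance is a grid approximation, conservative by
  construction; no continuous frontier is computed.
- The simplex is dense: genome-scale models load and solve, but slowly;
  the package's analysis surface is aimed at the branch-point-ratio scale.
- SBML support covers Level 3 core + FBC bounds/objectives, not the full
  standard (annotations, gene products, units are ignored).

## A worked run

```{r worked}
net <- make_toy_network("central_metabolism")
defs <- toy_ratio_definitions("central_metabolism")
sim <- simulate_dataset(net, scenario_spec(
  "ltee_like", n_populations = 4, noise_sd = 0.02, evolved_shift = 0.05,
  ancestor_percent_optimality = 95, seed = 42))
res <- run_analysis(net, sim$datasets, defs,
                    criteria = c("BM_per_S", "ATP_per_S"))
subset(res$strains, criterion == "BM_per_S",
       select = c(strain, role, percent_mean, percent_se, D_mean,
                  dist_metric))
res$tests
res$cv
```
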