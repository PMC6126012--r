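---
title: "Constraint-based redox analysis with redoxsid: models, methods, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based redox analysis with redoxsid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(redoxsid)
```

## The problem

Xylose-fermenting yeasts such as *Scheffersomyces stipitis* face a built-in
redox imbalance: xylose reductase (XR) reduces xylose to xylitol using NADPH
or NADH, while xylitol dehydrogenase (XDH) reoxidises xylitol strictly with
NAD^+^. Under oxygen limitation the cell cannot dispose of the resulting
NADH surplus through respiration, and carbon spills over into xylitol and
ethanol. Understanding how the whole metabolic network re-routes reducing
equivalents when oxygen is scarce — which shuttles carry cytosolic NADH into
the mitochondria, how NADPH supply contracts, where ATP production moves —
is a systems-level question that a genome-scale metabolic model (GEM) can
answer through constraint-based simulation.

`redoxsid` implements that analysis as a reusable pipeline: flux balance
analysis (FBA) and parsimonious FBA on models read from tabular tables or
SBML, phenotype phase planes (PhPP) with line-of-optimality (LO) extraction,
a system-identification (SID) workflow that decomposes designed condition
sweeps by PCA, compartment-aware cofactor ledgers, fitting of culture
parameters to measured ethanol yields, and GPR-based comparison of predicted
flux changes with transcriptome changes. A small synthetic network with
hand-derivable optima makes every stage testable without external data.

## Flux balance analysis

A model is a stoichiometric matrix $S \in \mathbb{R}^{m \times n}$ over
metabolites tagged by compartment (`nadh[c]`, `q6h2[m]`, ...), flux bounds
$l \le v \le u$ in mmol gCDW$^{-1}$ h$^{-1}$, and a biomass objective. FBA
solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \; l \le v \le u,$$

optionally with coupling rows $v_A - r\,v_B = 0$ expressing an enzyme's
cofactor preference as an exact linear constraint. Exchange reactions are
written export-positive; an uptake of 5 is imposed as $l = u = -5$, and all
user-facing helpers speak the positive-uptake convention.

FBA optima are massively degenerate. Wherever a single representative flux
vector is needed (phase-plane observables, sweep rows, ledgers) the package
uses parsimonious FBA: the objective is fixed at its optimum and the total
absolute flux $\sum_i |v_i|$ is minimised via the standard split into
non-negative forward/backward parts. This picks the stoichiometrically
cheapest of the alternative optima — e.g. the one-reaction external NADH
dehydrogenase shuttle over the two-reaction glycerol-3-phosphate shuttle —
and makes all downstream tables deterministic.

### The LP solver

No dedicated linear-programming package is assumed; the engine is a dense
two-phase bounded-variable primal simplex written for this package, with
Bland's anti-cycling rule, artificial-variable phase 1, and the basis
re-factorised at every pivot. That design trades speed for exactness and
determinism, which is the right trade at the problem sizes involved (tens
of reactions; a genome-scale model of ~1400 reactions remains comfortably
solvable, just not at production-solver speed). Feasibility tolerance is
$10^{-9}$; a flux below $10^{-6}$ is reported "inactive" — the same
threshold everywhere (phase signatures, ledger listings, response classes)
so that "carries no flux" means one thing across the package.

## Phenotype phase planes and the line of optimality

`compute_phpp()` fixes the substrate and oxygen uptake in every grid cell,
maximises growth, and records observable secretions from the parsimonious
representative. Cells whose constraints are contradictory (e.g. forced
oxygen uptake with no carbon to reduce the quinone pool, or carbon uptake
whose ATP cost cannot be paid anaerobically) are recorded infeasible and
stay `NA` — they are phenotypes that do not exist, not zeros. The default
grid is 50 × 50 over 0–10 substrate × 0–20 oxygen; tests and examples use
coarser grids because the surfaces of the toy network are piecewise linear
and carry no extra information at high resolution.

Phase segmentation tags each cell with the sign pattern (−/0/+) of every
recorded surface and merges 4-neighbour runs of one signature into a phase.
This reproduces the visual phase structure of a phase-plane plot without
committing to any shadow-price convention. The phase count is checked to be
stable under 2× grid refinement on the toy model.

The LO is computed directly from its definition: fix a series of substrate
uptakes, leave oxygen free ($l = -1000, u = 0$), maximise growth, and read
the oxygen uptake actually used. The slope is the least-squares line
through the origin — within one phase all points are exactly proportional,
so the regression only averages solver round-off.

## The SID workflow

A designed experiment is a pair of endpoint conditions with every varied
scalar (bounds, coupling ratios) interpolated linearly over $n$ steps
(default 10). The resulting condition × reaction flux matrix is column
centered (never variance-scaled — loadings must stay in flux units so their
magnitudes read as flux changes) and decomposed by SVD. PC signs are fixed
by orienting the growth loading non-negative.

Two facts shape how results should be read:

* When only **right-hand-side data** (bounds) vary, LP sensitivity theory
  makes the optimal flux vector affine in the varied scalars inside one
  phase, so PC1 carries 100% of the variance and the loadings are exact
  per-reaction flux-change rates. The suite asserts PC1 $\ge 0.999$ and
  per-column affine residuals $\le 10^{-6}$ on such sweeps.
* A **coupling ratio** multiplies a variable, so a ratio sweep is not an
  RHS perturbation and the response is only approximately affine. On the
  toy network's oxygen-downshift sweep (oxygen uptake 2.33 → 1.42, XR
  ratio 0.94 → 0.11) PC1 still carries ~99.2% of the variance — "one
  component" to printing precision, but not exactly 1.

Responses are classified from the endpoint change in carried flux
magnitude: `up` (blue on a network map), `down` (red), `inactive`/no change
(black). Using $|v|$ rather than signed flux classifies reversible
reactions by the duty they carry. Non-monotone columns are classified by
their endpoints and flagged.

Forced-behavior probes pin a reaction to a flux profile ($l = u$ per step)
and rerun the sweep; the reactions with the largest PC1 loadings are the
candidates that had to adjust. On the toy network, forcing oxidative-PPP
flux well above its optimum saturates the NADPH-consuming XR route and
surfaces the glutamate-shuttle lump — a "distant" compensator of exactly
the kind such probes exist to find.

## Cofactor ledgers and electron accounting

For a cofactor in a compartment, reaction $j$ contributes
$S_{\text{cof},j}\, v_j$: positive produces, negative consumes. At steady
state production equals consumption for every internal metabolite, which
the suite verifies to $10^{-6}$ for every optimal solution — the ledger is
bookkeeping, not a new model. Ledger deltas between two conditions mirror
the condition-to-condition comparison tables of chemostat studies, and
named shuttle definitions (NADHDH, GLYC3P, GLU) aggregate the defining
reactions' fluxes.

Electron accounting converts a quinol-pool production change into a
fraction of the removed oxygen capacity: each O$_2$ accepts electrons from
two quinol equivalents, so
$\text{pct} = 100\,|\Delta Q_6H_2| / (2\,|\Delta \text{OUR}|)$. With a
quinol drop of 1.79 against an oxygen downshift from 2.33 to 1.42
mmol gCDW$^{-1}$ h$^{-1}$ this evaluates to 98.35% — the analytic
"essentially all of the lost oxygen capacity" result, reproducible with no
model at all. On the toy network the same computation returns exactly 100%
because its only oxygen sink is the lumped quinol oxidase.

## Fitting culture conditions to an ethanol yield

When a study reports an ethanol yield but not the oxygen supply, the
operating point can be recovered by tuning the oxygen uptake rate (OUR) and
the XR cofactor-preference ratio $r$ until the model's molar yield
$Y_{E/S} = v_{\text{EtOH}} / v_{\text{xylose}}$ matches. `fit_condition()`
scans a coarse grid (default 41 × 41) and refines the best axis-aligned
neighbourhood by golden-section search until $|\Delta Y| \le 10^{-4}$.

One yield does not pin down two parameters: an isoline of $(\text{OUR}, r)$
pairs achieves the same yield. The reported representative is the
deterministic, biologically conservative one — smallest OUR, ties broken by
smaller $r$ — and the suite checks that refitting a fitted point returns it
unchanged. The companion `linearity_check()` regresses ratio and yield
against OUR across several fitted conditions; near-unity $R^2$ places them
in one phenotype phase and justifies linear interpolation between them.
The substrate uptake behind a fit defaults to 5 mmol gCDW$^{-1}$ h$^{-1}$;
since the yield is a flux ratio, this choice only sets the scale of the
fitted OUR.

## Transcriptome comparison

Reaction expression follows the standard GPR rules: isozymes (OR) sum,
complex subunits (AND) take the minimum, genes missing from a sample count
zero, and genes absent from the table entirely are skipped inside AND
minima so annotation gaps cannot zero out a complex. Duplicate chemostat
samples (collected minutes apart) are averaged before change calling — the
minimal aggregation; the sample columns are explicit arguments, so any
other scheme is one call away.

A change call is `+`/`-` when the relative change against the aerobic level
exceeds 10%, else `o`. The agreement score is the fraction of scoped
reactions whose flux symbol matches the expression symbol, with `o`
agreeing only with a below-threshold flux change. The scope must exclude
zero-flux reactions, exchange/transport reactions, and reactions whose
routes transcripts cannot separate (the two cofactor routes of one XR
enzyme).

## The toy network

`make_toy_model()` builds a 29-reaction, 28-metabolite, three-compartment
network carrying the motifs that matter: the NADH/NADPH-split XR pair,
NAD^+^-strict XDH, xylulokinase, lumped oxidative PPP
(g6p + 2 NADP$^+$ → x5p + CO$_2$ + 2 NADPH), lumped non-oxidative PPP
(6 x5p ⟷ 5 g6p), lumped glycolysis (g6p → 2 pyr + 2 ATP + 2 NADH), an
ethanol branch, lumped TCA (pyr → 3 CO$_2$ + 4 NADH$_m$ + quinol), the ETC
(quinol + ½ O$_2$ + 1.5 ADP → ATP), the NADHDH and two-step GLYC3P
shuttles, a glutamate-shuttle lump with the net transhydrogenase
stoichiometry 1 NADH$_c$ + 1 NADPH$_c$ → 2 NADH$_m$, ATP-coupled xylose
uptake, and a biomass sink (10 g6p + 100 ATP + 40 NADPH per unit growth).
Each reaction carries a one-gene GPR except two isozyme (OR) and two
complex (AND) lumps, so the GPR rules are exercised end to end.

Coefficients were chosen once for hand-verifiable optima, not biological
fidelity. Carbon is conserved in C-mol terms through every lump, and the
aerobic optimum closes in closed form. With xylose uptake $U$, XR ratio
coupling $r$ ($\rho = r/(1+r)$ the NADPH-route share), ETC yield $P = 1.5$
ATP/quinol, uptake cost $a = 1$ ATP, and biomass demands
$(b_G, b_A, b_N) = (10, 100, 40)$, balancing NADPH, pentose, hexose,
pyruvate, cytosolic NADH, quinol and ATP at zero secretion gives

$$\mu/U = \frac{(2 + 12P)\left(\tfrac{5}{6} - \tfrac{\rho}{12}\right) - (a+1) + P\rho}
               {(2 + 12P)\left(\tfrac{b_N}{12} + b_G\right) + b_A},
\qquad
\text{OUR}/U = 6\,G/U + \tfrac{\rho}{2},$$

with glycolytic flux
$G/U = \tfrac{5}{6} - \tfrac{\rho}{12} - (\mu/U)(\tfrac{b_N}{12} + b_G)$.
At the defaults this yields $\mu = 0.04\,U$ (0.2 h$^{-1}$ at $U = 5$) and
an LO slope of exactly 1.8 mol O$_2$/mol xylose ($\rho = 0$), shifting to
≈1.8176 under the 0.94 cofactor coupling. The test suite holds `find_lo()`
to this closed form at $10^{-8}$ — an oracle fully independent of the LP
path.

The toy reproduces the qualitative oxygen-limitation phenotype: with the
XR preference coupled, xylitol secretion peaks at an interior oxygen level
(the anaerobic edge is infeasible because ATP-coupled uptake cannot be paid
without respiration), ethanol rises as oxygen falls, and above the LO both
vanish. What passing these tests does **not** show: behaviour of real
genome-scale networks with thousands of alternate routes, realistic P/O
ratios, maintenance ATP, or biomass equations — the toy is an oracle, not
an organism. Quantities like its ethanol yields (order 1.5 mol/mol) are
deliberately simple stoichiometric consequences, not predictions.

The synthetic expression generator plants a per-reaction agreement with the
flux-change call at probability $p$ (default 0.75, two duplicate samples
per condition, baseline TPMs log-uniform on [1, 1000], 1% log-normal
duplicate noise, fold changes kept clear of the 10% calling threshold).
Because every scored toy reaction owns its genes, scaling a reaction's
genes together commutes with the OR-sum and AND-min rules and the planted
symbol is realised exactly; recovery of $p$ is then a pure binomial
experiment, which the suite verifies to well within sampling error.

## Numerical choices and degenerate inputs

* Feasibility tolerance $10^{-9}$; zero-flux/no-change threshold $10^{-6}$;
  coupling residuals verified $\le 10^{-8}$.
* `run_pca()` on a zero-variance matrix returns one PC with fraction
  defined as 1, zero loadings, and a `degenerate` flag rather than an
  error; `linearity_check()` on a constant response reports slope 0,
  $R^2 = 1$, flagged degenerate.
* Loading ranks break ties lexicographically by reaction id, so reported
  candidate lists are reproducible.
* `err_percent()` switches to absolute error (flagged) when the
  experimental value is zero.
* Null reactions (identical sides) are detected at parse time and flagged
  rather than silently dropped.

## Problem sizes

The shipped tests and the acceptance script run the toy network with
sweeps of 4–10 conditions, phase grids up to 16 × 26 cells, a 21 × 21 fit
grid, and a few hundred synthetic-expression replicates; everything
completes in about a minute on one CPU. These sizes were chosen because the
toy's piecewise-linear surfaces are fully characterised at that resolution;
the same code paths accept genome-scale inputs through `load_model()`.

## Known limitations

* SBML support is read-only and limited to Level 3 FBC bounds, gene
  associations and objectives; the tabular dialect is canonical.
* Per-reaction fluxes inside degenerate optima are meaningful only as the
  pFBA representative; comparisons of individual shuttle fluxes between
  solvers can differ even when every total matches.
* The yield fit reports an isoline representative, not a unique operating
  point; with richer data (measured OUR or xylitol) the ambiguity
  disappears.
* The SID machinery assumes sweeps stay within one phenotype phase;
  `segment_phases()` is the tool to check that assumption before trusting
  one-component summaries.
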