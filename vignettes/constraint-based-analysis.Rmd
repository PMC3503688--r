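---
title: "Constraint-based analysis with FluxBalanceR: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based analysis with FluxBalanceR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(FluxBalanceR)
```

# The model and its assumptions

A `MetabolicModel` is a compartmentalized stoichiometric network: metabolites
with compartment labels (`c` cytosol, `m` mitochondrion, `e` extracellular),
reactions with flux bounds in mmol/gDCW/h, Boolean gene-protein-reaction
(GPR) trees, one biomass reaction whose flux is the growth rate (1/h), and
exchange reactions — boundary pseudo-reactions touching exactly one
extracellular metabolite, with uptake as negative flux. Reversibility is
encoded purely by the bounds (default -1000/1000 reversible, 0/1000
irreversible); there is no separate flag, so the two cannot disagree.

Flux balance analysis assumes steady state (`S v = 0`) and optimality of a
linear objective, usually biomass. These are the standard assumptions of the
field and inherit its caveats: no kinetics, no regulation, no
thermodynamic constraints, and — important for interpreting any per-reaction
output — **degenerate optima**. Only the optimal objective value is unique.
Wherever the package reports a flux vector (`conditionFluxReport`,
`solveFBA(pfba = TRUE)`) it returns a parsimonious representative: total
absolute flux is minimized at the fixed optimal objective via a second LP
with split variables. Tests and contracts therefore only bind objective
values, never individual fluxes of degenerate alternatives.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| carbon uptake | 3 | mmol/gDCW/h | the standard limited-carbon minimal-medium condition for this yeast |
| aerobic oxygen bound | -1000 | mmol/gDCW/h | effectively unconstrained within default bounds |
| semiaerobic oxygen bound | -5 | mmol/gDCW/h | the conventional oxygen-limited condition |
| amino-acid uptake cap | 0.1 | mmol/gDCW/h | supplements are trace additions, not carbon sources |
| essentiality threshold | 1e-6 | growth ratio | mutant/wild-type ratio below which a gene counts as essential |
| robustness fixed growth | 0.01 | 1/h | a minimal viability demand during product-maximization scans |
| OptKnock `min_growth_fraction` | 0.1 | fraction of wild type | keeps designs viable; the bilevel literature gives no canonical value |
| solver feasibility tolerance | 1e-9 | — | requested of the simplex |
| contract tolerance | 1e-6 | — | what results are checked against (`max|S v|`, duality gaps) |

The minimal medium opens the inorganic components — ammonia, sulphate,
phosphate, sodium, potassium, iron(II), water, protons — at (-1000, 1000),
closes every other exchange's uptake, and opens exactly one carbon source.
Water and protons are included although some published component lists omit
them; an exchange already unbounded in the model file is simply re-opened to
the same bounds, so the choice is inert for models that track neither.

Boundary semantics of the annotation filter follow the reconstruction
thresholds as worded: e-value *less than* 1e-30 (strict), identity *above*
40% (strict), coverage *at least* 70% (inclusive), with coverage defined as
alignment length over each direction's own query length. Whether
bidirectionality is required is a flag (`require_bidirectional`, default
TRUE) because published pipelines differ on applying it per template.

# The linear-programming layer

No LP or MILP library is a dependency: the package carries its own
bounded-variable primal simplex (phase 1 with artificial variables, Dantzig
pricing with a Bland fallback after degenerate stalls, the basis inverse
recomputed by dense factorization at every pivot). For the problem sizes
this package targets — tens to a few hundred rows — the O(m^3)-per-pivot
cost is irrelevant and full refactorization is the most numerically
self-correcting choice. The test suite validates it against an independently
coded dense Big-M tableau simplex (a different formulation: variables
shifted/split to be nonnegative, bounds as explicit rows) on random LPs and
random metabolic networks; agreement is required to 1e-6 on objectives and
on feasibility verdicts.

Mixed-binary programs (OptKnock, gap filling) are solved by depth-first
branch-and-bound on the binary variables over LP relaxations, with
most-fractional branching and incumbent pruning. Problem sizes are kept
small by construction (knockout candidates, pool reactions), not by
heuristics.

# OptKnock: bilevel design by strong duality

The outer problem chooses gene knockouts (binary `y_g`, 1 = present, budget
`sum(1 - y_g) <= K`) to maximize secretion of a target; the inner problem is
the cell's growth-optimal response. Inner optimality is certified inside a
single MILP by strong duality: primal feasibility, dual feasibility, and
equality of the primal and dual inner objectives. Knockouts enter through
reaction-activity indicators `z_j` with bound rows `lb_j z_j <= v_j <= ub_j
z_j`; the products of `z_j` with the dual multipliers of those rows are
linearized with big-M terms.

Three design choices deserve emphasis:

* **Gene-level binaries, exact GPR linearization.** `z_j` is pinned to the
  GPR's value by prime-implicant cuts ("keeping these genes keeps the
  reaction": `z_j >= sum(y_I) - |I| + 1`) and prime-implicate cuts
  ("knocking this minimal set kills it": `z_j <= sum(y_C)`). For monotone
  AND/OR trees these two families are exact, and when all `y` are integral
  they force `z` integral, so branching is restricted to `y`.
* **Inner tie-breaking is lexicographic and optimistic.** "Production at
  maximum growth" is ambiguous when the growth optimum is degenerate. The
  reported rate maximizes growth first, then production at the fixed growth
  optimum — consistent with what the duality MILP itself selects. A
  pessimistic variant (minimize production at the growth optimum) is
  available via `pessimistic = TRUE` in the evaluation functions for
  worst-case screening.
* **Big-M on duals is guarded by certification.** Dual variables are boxed
  at `dual_bound` (default 100, chosen from the model's bound magnitude of
  1000 scaled by the unit biomass objective with a safety margin). An
  undersized box could silently truncate the dual space, so every returned
  design is re-solved by direct FBA and the growth values must agree within
  1e-6; a discrepancy is reported in the result's diagnostic attribute
  rather than hidden. The test suite additionally requires equality with
  exhaustive enumeration (`enumerateKnockouts`) for small candidate sets.

# Gap analysis

Production and consumption tests attach a temporary drain or supply to each
metabolite and maximize its flux; an optimum at or below 1e-9 flags the
metabolite. By default all exchange lower bounds are opened to -1000 first,
so the report reflects network topology rather than starvation under a
particular medium; passing a `MediumSpec` tests a specific condition
instead. Blocked reactions are those whose flux variability range is
identically zero.

Gap filling minimizes the number of pool reactions added to make a target
producible (at `min_production`, default 1 mmol/gDCW/h, comfortably above
solver tolerance and below any pathway capacity used here), as a MILP with
one inclusion binary per pool reaction. Ties among minimum-cardinality
solutions are broken deterministically toward lexicographically early pool
reaction ids by adding vanishing rank weights (1e-7 per rank) to the
cardinality objective — cheap, deterministic, and indistinguishable from
pure lexicographic choice at the pool sizes the MILP is intended for.

# The synthetic-network generator

`generateNetwork()` composes substrate uptakes, linear conversion pathways,
and one biomass reaction draining every pathway's terminal precursor with
unit coefficients. Because yields are 1 and each pathway's only bottleneck
is its uptake bound, the maximal growth is known analytically (the minimum
uptake bound), and the generator records it together with the planted
essential genes (sole catalysts and complex subunits on required paths;
isoenzyme pairs are nonessential by construction) and planted dead-end
metabolites (produced, never consumed). An optional growth-coupled module
adds a substrate split into a biomass precursor plus a redox-like byproduct
that must leave through either a gene-guarded waste route or a
product-forming route — knocking the waste gene couples product secretion to
growth, giving OptKnock a planted optimum to find.

What the generator emulates: stoichiometric consistency, compartment
structure, GPR logic (isoenzymes and complexes), bounded uptakes, dead ends.
What it does not: realistic cofactor cycling, branched topology with
alternative optima, mass-balanced formulas, or realistic pathway lengths.
Passing the planted-truth tests therefore demonstrates correctness of the
*algorithms* (GPR evaluation, LP solves, essentiality classification,
dead-end detection), not predictive accuracy on real reconstructions.

# The bundled toy model

`toyStipitisModel()` is a ~110-reaction qualitative fixture of *S. stipitis*
central carbon metabolism: seven fermentable sugars, the xylulokinase route
(XYL1 -> XYL2 -> XKS1) and the D-arabinitol bypass (ARD2/AAD1/RKS1) into the
pentose phosphate pathway, the four-step L-arabinose route via L-arabitol,
L-xylulose and xylitol, cellobiose hydrolysis (eight-gene OR), a lumped
four-gene rhamnose route, simplified glycolysis with gluconeogenesis (PEP
carboxykinase, FBPase), lumped oxidative PPP, a partially lumped TCA cycle,
cytosolic (ADH1/2/4/5) and mitochondrial (ADH3) ethanol formation, a
glycerol shunt as the anaerobic NADH sink, a lumped respiratory chain at
P/O = 2, NADP- and NAD-dependent glutamate dehydrogenases, and exchanges for
minimal-medium components and all 20 amino acids (only glutamate has uptake
machinery; the other 19 are deliberately inert supplements).

Cofactor couplings are fixed from standard yeast biochemistry — the xylose
reductase is NADPH-specific, the xylitol dehydrogenase NAD-specific, which
is precisely the imbalance that makes xylose fermentation oxygen-sensitive.
Stoichiometric coefficients of lumped segments are the implementer's
choices; the fixture is built for topological behaviour (route redundancy,
medium-dependent essentiality, an interior ethanol/oxygen optimum), and no
quantitative rate printed for the full genome-scale model is expected from
it.

Two emergent properties are worth knowing when reading scan output. First,
strictly anaerobic xylose catabolism is infeasible in this network: the
xylulokinase ATP cost plus the glycerol diversion forced by the XYL1/XYL2
cofactor imbalance make the pathway ATP-negative at zero oxygen, so the
first point of an oxygen scan is flagged infeasible rather than zero —
consistent with this yeast's requirement for some aeration on xylose.
Second, the feasible oxygen range is capped near 14 mmol/gDCW/h at xylose
uptake 3: beyond complete oxidation there is no NADH left to satisfy a
larger forced oxygen flux, and ethanol reaches zero just before that cap.

# Problem sizes and runtime choices

The shipped tests and the acceptance script use 50 random networks for the
LP cross-check, 20 seeds for planted-truth recovery, 10 models (about 15
reactions, up to 6 candidate genes, k <= 2) for OptKnock-vs-enumeration, and
oxygen grids of step 0.25-0.5 over 0-15 mmol/gDCW/h for the toy scans. These
sizes were chosen so the whole battery solves a few thousand small LPs in
about a minute on one CPU while still exercising every code path; the
functions themselves accept arbitrary sizes, and `reproduceSupplementary()`
defaults to a 0.05-step oxygen grid (0.01 resolves a genome-scale optimum
more finely at proportional cost).

# Known limitations

* The simplex is dense; models beyond a few thousand reactions would need a
  sparse factorized implementation.
* SBML support is Level 3 core with bounds as parameters and GPRs in notes —
  enough to round-trip this package's models and exchange with tools that
  accept plain L3, but not the fbc extension.
* The OptKnock MILP's dual box is heuristic; it is certified per design, not
  proven globally, and `n_designs > 1` enumerates alternatives by no-good
  cuts rather than a true solution pool.
* No thermodynamic or regulatory constraints; futile cycles are avoided only
  where irreversibilities happen to forbid them.
* KO-to-reaction expansion is table-driven; the package performs no online
  database queries.
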