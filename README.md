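# FluxBalanceR

Constraint-based analysis of compartmentalized genome-scale metabolic models
in R, built for studying xylose-to-ethanol fermentation in the yeast
*Scheffersomyces stipitis* and for anyone who needs a self-contained,
solver-included FBA toolbox: model curators checking draft reconstructions,
and metabolic engineers screening knockout and supplementation strategies
in silico.

## What it computes

The core object is a stoichiometric model: a matrix **S** (metabolites x
reactions), flux bounds, and Boolean gene-protein-reaction (GPR)
associations (OR = isoenzymes, AND = enzyme complex subunits). Flux balance
analysis solves the linear program

```
max  c'v    subject to   S v = 0,   lb <= v <= ub
```

where `v` are reaction fluxes in mmol/gDCW/h, uptake through an exchange
reaction is a negative flux, and the biomass flux is the growth rate (1/h).
On top of this the package implements:

* **Media construction** — minimal medium with a single limited carbon
  source (default uptake 3 mmol/gDCW/h), aerobic (oxygen lower bound -1000)
  or semiaerobic (-5) conditions, optional amino-acid supplements capped at
  0.1 mmol/gDCW/h.
* **Single-gene deletion** — a gene is essential when mutant growth falls
  below 1e-6 of wild type; knockouts act through the GPRs.
* **Robustness analysis** — the objective re-maximized while one exchange
  flux (e.g. oxygen uptake) is fixed across a grid, optionally at fixed
  growth.
* **OptKnock-style strain design** — the bilevel program (outer: choose at
  most K gene knockouts maximizing product secretion; inner: the cell
  maximizes growth) collapsed to a single-level MILP via strong duality,
  with an exhaustive-enumeration oracle for verification.
* **Gap analysis** — dead-end (no-production / no-consumption) metabolites
  and blocked reactions; minimal reaction additions from a universal pool
  via a MILP.
* **Annotation filtering** — bidirectional homology hits kept at e-value
  < 1e-30, identity > 40%, coverage >= 70%, merged with KO assignments into
  draft gene-reaction associations.
* **Synthetic networks** — generators with planted ground truth (essential
  genes, dead ends, analytic maximal growth) used throughout the test suite.

All linear and mixed-binary programs are solved by the package's own
bounded-variable simplex and branch-and-bound, so no external solver is
needed.

## Worked example

The bundled toy model covers *S. stipitis* central carbon metabolism: the
seven sugars it ferments, the xylulokinase route (XYL1 -> XYL2 -> XKS1) and
its D-arabinitol bypass, cytosolic and mitochondrial ethanol formation, and
a glycerol shunt.

```r
library(FluxBalanceR)

model <- toyStipitisModel()
model
#> MetabolicModel: 95 metabolites, 109 reactions, 72 genes
#>   compartments: c, e, m
#>   exchange reactions: 40
#>   biomass reaction: BIOMASS

glc <- buildMedium(model, "glucose")   # 3 mmol/gDCW/h, aerobic
xyl <- buildMedium(model, "xylose")
solveFBA(model, xyl)
#> FluxSolution: optimal
#>   objective (BIOMASS): 0.153409

# genes essential on xylose but not on glucose
compareMediaEssentiality(model, glc, xyl)$only_b
#> [1] "GND1" "PGI1" "SOL3" "TAL1" "TKL1" "XYL1" "XYL2" "ZWF1"

# ethanol vs fixed oxygen uptake at growth pinned to 0.01 1/h
robustnessScan(model, xyl, "o2", seq(0, 15, by = 0.5),
               objective = "EX_etoh", fixedGrowth = 0.01)
#> RobustnessCurve over EX_o2 : 31 points, 3 infeasible
#>   maximum response 4.07167 at uptake 2
```

The growth rates are in 1/h (0.15 on xylose vs 0.20 on glucose: the extra
oxidoreductase steps of pentose assimilation cost carbon). The xylose-only
essential set contains the two xylose-entry genes (XYL1, XYL2) plus the
enzymes that connect the pentose phosphate pathway back to glycolysis
(PGI1, TAL1, TKL1) and the NADPH supply for the xylose reductase (oxidative
PPP). The robustness curve peaks at an intermediate oxygen uptake — ethanol
formation needs enough respiration to balance redox and ATP, but excess
oxygen burns the carbon — and the flagged infeasible points at the extremes
are real: fully anaerobic xylose catabolism is ATP-negative in this network,
and beyond ~14 mmol/gDCW/h there is not enough substrate to satisfy the
forced oxygen consumption.

A command-line wrapper over the same functions ships in
`inst/scripts/fluxbalancer`:

```sh
Rscript inst/scripts/fluxbalancer robustness --model toy --medium XA \
    --controlled o2 --grid 0:15:0.5 --objective EX_etoh --fix-growth 0.01 \
    --out curve.tsv
```

Every run writes a JSON manifest (parameters, model checksum, solver,
tolerances, seed) next to its output.

## Reading full models

`readModel()` accepts the package's native JSON dialect, a three-table TSV
twin, SBML Level 3 core (bounds as parameters), and CSV exports of published
model workbooks through a user-supplied column mapping
(`supplementaryMappingTemplate()`). `reproduceSupplementary()` runs the full
analysis battery (statistics, glucose/xylose essentiality, the oxygen
robustness scan, knockout and glutamate-supplementation designs) on such an
export; the published *S. stipitis* workbook itself is not redistributable
here, so the corresponding checks run only when the user supplies the export
under `inst/extdata/itl885/`.

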