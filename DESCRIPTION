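Package: FluxBalanceR
Title: Constraint-Based Analysis of Compartmentalized Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based analysis of compartmentalized
    genome-scale metabolic models, motivated by the study of xylose-to-ethanol
    fermentation in the yeast Scheffersomyces stipitis. Provides an S4 model
    container with Boolean gene-protein-reaction (GPR) logic, readers and
    writers for a native JSON/TSV model dialect, tabular supplementary-model
    exports and SBML Level 3, flux balance analysis on a built-in
    bounded-variable simplex solver, minimal-medium construction, robustness
    scans, parsimonious flux reporting, single-gene deletion essentiality,
    OptKnock-style bilevel strain design via a strong-duality MILP
    reformulation with an exhaustive-enumeration oracle, amino-acid
    supplementation scans, dead-end metabolite detection and minimal gap
    filling, a generator of synthetic stoichiometric networks with planted
    ground truth, a bundled toy model of S. stipitis central carbon
    metabolism, and a homology/KO annotation filter for draft reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
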