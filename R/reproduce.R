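## End-to-end reproduction pipeline for a full published model supplied as a
## supplementary CSV export (reactions/metabolites sheets plus a
## column-mapping config). Runs the complete analysis battery on it: model
## statistics, glucose/xylose essentiality comparison, the oxygen robustness
## scan of ethanol production, and the knockout / glutamate-supplementation
## predictions.

#' Reproduce the published analysis battery on a supplementary model export
#'
#' @param dir directory holding the CSV export of the model workbook.
#' @param mapping column-mapping config (path or list), see
#'   \code{\link{supplementaryMappingTemplate}}.
#' @param oxygen_grid grid of oxygen uptake rates for the robustness scan
#'   (default 0 to 30 step 0.05; step 0.01 resolves the optimum more finely
#'   at proportional cost).
#' @param fixed_growth growth rate fixed during the robustness scan (default
#'   0.01 1/h).
#' @param knockouts list of gene sets to evaluate directly (default: the
#'   GDH3, ALA2 and GLY1+GLY2 strategies via the shipped alias table).
#' @return list with \code{statistics}, \code{essentiality} (glucose count,
#'   xylose-only genes), \code{robustness} (curve, optimum), and
#'   \code{designs} (knockout and glutamate-supplementation table).
#' @export
reproduceSupplementary <- function(dir, mapping,
                                   oxygen_grid = seq(0, 30, by = 0.05),
                                   fixed_growth = 0.01,
                                   knockouts = NULL) {
  model <- readModel(dir, dialect = "supplementary-csv", mapping = mapping)
  stats <- modelStatistics(model)

  glcMed <- buildMedium(model, "glucose", 3, "aerobic")
  xylMed <- buildMedium(model, "xylose", 3, "aerobic")
  cmp <- compareMediaEssentiality(model, glcMed, xylMed)

  etoh <- findExchange(model, "etoh")
  curve <- robustnessScan(model, xylMed, "o2", oxygen_grid, etoh,
                          fixedGrowth = fixed_growth)
  iopt <- which.max(curve@responses)

  if (is.null(knockouts)) {
    al <- geneAliases()
    sym <- function(s) {
      tag <- al$locus_tag[match(s, al$symbol)]
      ifelse(tag %in% model@genes, tag, s)
    }
    knockouts <- list(GDH3 = sym("GDH3"), ALA2 = sym("ALA2"),
                      GLY1_GLY2 = sym(c("GLY1", "GLY2")))
  }
  designRows <- lapply(names(knockouts), function(nm) {
    pt <- productionEnvelopePoint(model, xylMed, etoh, knockouts[[nm]])
    data.frame(strategy = nm, growth_rate = pt$growth,
               production_rate = pt$production, stringsAsFactors = FALSE)
  })
  wt <- productionEnvelopePoint(model, xylMed, etoh)
  gluMed <- buildMedium(model, "xylose", 3, "aerobic",
                        amino_acid = "glutamate", amino_acid_uptake = 0.1)
  glu <- productionEnvelopePoint(model, gluMed, etoh)
  comb <- productionEnvelopePoint(model, gluMed, etoh,
                                  knockouts[["ALA2"]] %||% character(0))
  designs <- rbind(
    data.frame(strategy = "wild-type", growth_rate = wt$growth,
               production_rate = wt$production, stringsAsFactors = FALSE),
    do.call(rbind, designRows),
    data.frame(strategy = "glutamate", growth_rate = glu$growth,
               production_rate = glu$production, stringsAsFactors = FALSE),
    data.frame(strategy = "glutamate+ALA2", growth_rate = comb$growth,
               production_rate = comb$production, stringsAsFactors = FALSE))
  designs$production_vs_wildtype <- designs$production_rate / wt$production

  list(
    statistics = stats,
    essentiality = list(
      glucose_essential = length(cmp$essential_a),
      xylose_only = cmp$only_b),
    robustness = list(
      curve = data.frame(oxygen_uptake = curve@grid, ethanol = curve@responses),
      optimum_oxygen = curve@grid[iopt],
      optimum_ethanol = curve@responses[iopt]),
    designs = designs
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
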