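## Hand-built toy model of S. stipitis central carbon metabolism.
##
## A qualitative ~90-reaction fixture covering the seven sugars this yeast
## ferments (glucose, mannose, galactose, xylose, L- and D-arabinose,
## cellobiose, rhamnose), the xylulokinase route (XYL1 -> XYL2 -> XKS1) and
## the D-arabinitol bypass (ARD2/AAD1/RKS1) into the pentose phosphate
## pathway, the four-step L-arabinose route via L-arabitol, L-xylulose and
## xylitol, simplified glycolysis / PPP / TCA, cytosolic and mitochondrial
## (ADH3) ethanol formation, a glycerol shunt as the anaerobic NADH sink,
## lumped respiration, nitrogen assimilation through an NADPH- and an
## NADH-dependent glutamate dehydrogenase, a simple biomass reaction, and
## exchanges for all sugars, oxygen, fermentation products, minimal-medium
## components and the 20 proteinogenic amino acids.
##
## Stoichiometric coefficients and cofactor couplings (e.g. NADPH use by the
## xylose reductase, NAD use by the xylitol dehydrogenase) are fixed here
## from standard yeast biochemistry; several multi-enzyme segments are lumped
## (their GPRs join the member genes with AND). The fixture is for
## topological behaviour - route redundancy, medium-dependent essentiality,
## an interior ethanol/oxygen optimum - not for quantitative rates.

AMINO_ACID_TOKENS <- c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly",
                       "his", "ile", "leu", "lys", "met", "phe", "pro", "ser",
                       "thr", "trp", "tyr", "val")

#' The bundled toy model of S. stipitis central carbon metabolism
#'
#' @return a validated \linkS4class{MetabolicModel} with compartments
#'   \code{c} (cytosol), \code{m} (mitochondrion), \code{e} (extracellular),
#'   biomass reaction \code{BIOMASS}. Exchange bounds in the returned object
#'   leave all carbon uptake closed; use \code{\link{buildMedium}} to define
#'   a growth condition.
#' @examples
#' m <- toyStipitisModel()
#' modelStatistics(m)[c("genes", "metabolites", "reactions")]
#' @export
toyStipitisModel <- function() {
  r <- function(id, eq, lb = 0, ub = 1000, gpr = "", sub = NA_character_, name = id) {
    data.frame(id = id, eq = eq, lb = lb, ub = ub, gpr = gpr, sub = sub,
               name = name, stringsAsFactors = FALSE)
  }
  EXC <- "Exchange"; TRA <- "Transport"; GLY <- "Glycolysis"
  PPP <- "Pentose phosphate pathway"; XYL <- "Xylose metabolism"
  ARA <- "Arabinose metabolism"; SUG <- "Other sugar metabolism"
  TCA <- "Citrate cycle"; ETH <- "Ethanol synthesis"
  AAM <- "Amino acid metabolism"; OXP <- "Oxidative phosphorylation"

  defs <- rbind(
    ## exchanges (uptake = negative flux; carbon closed by default)
    r("EX_glc",  "glc[e] ->", 0, 1000, sub = EXC),
    r("EX_man",  "man[e] ->", 0, 1000, sub = EXC),
    r("EX_gal",  "gal[e] ->", 0, 1000, sub = EXC),
    r("EX_xyl",  "xyl[e] ->", 0, 1000, sub = EXC),
    r("EX_larab", "larab[e] ->", 0, 1000, sub = EXC),
    r("EX_darab", "darab[e] ->", 0, 1000, sub = EXC),
    r("EX_cellb", "cellb[e] ->", 0, 1000, sub = EXC),
    r("EX_rha",  "rha[e] ->", 0, 1000, sub = EXC),
    r("EX_o2",   "o2[e] ->", -1000, 1000, sub = EXC),
    r("EX_co2",  "co2[e] ->", 0, 1000, sub = EXC),
    r("EX_etoh", "etoh[e] ->", 0, 1000, sub = EXC),
    r("EX_glyc", "glyc[e] ->", 0, 1000, sub = EXC),
    r("EX_nh4",  "nh4[e] ->", -1000, 1000, sub = EXC),
    r("EX_so4",  "so4[e] ->", -1000, 1000, sub = EXC),
    r("EX_pi",   "pi[e] ->", -1000, 1000, sub = EXC),
    r("EX_na1",  "na1[e] ->", -1000, 1000, sub = EXC),
    r("EX_k",    "k[e] ->", -1000, 1000, sub = EXC),
    r("EX_fe2",  "fe2[e] ->", -1000, 1000, sub = EXC),
    r("EX_h2o",  "h2o[e] ->", -1000, 1000, sub = EXC),
    r("EX_h",    "h[e] ->", -1000, 1000, sub = EXC),

    ## sugar and nutrient transport
    r("GLCt",  "glc[e] -> glc[c]", 0, 1000, "SUT1 or SUT2 or SUT3", TRA),
    r("MANt",  "man[e] -> man[c]", 0, 1000, "SUT1 or SUT2", TRA),
    r("GALt",  "gal[e] -> gal[c]", 0, 1000, "SUT1", TRA),
    r("XYLt",  "xyl[e] -> xyl[c]", 0, 1000, "XUT1 or XUT3 or SUT1", TRA),
    r("LARABt", "larab[e] -> larab[c]", 0, 1000, "AUT1", TRA),
    r("DARABt", "darab[e] -> darab[c]", 0, 1000, "AUT1", TRA),
    r("CELLBt", "cellb[e] -> cellb[c]", 0, 1000, "HGT1", TRA),
    r("RHAt",  "rha[e] -> rha[c]", 0, 1000, sub = TRA),
    r("O2t",   "o2[e] -> o2[c]", 0, 1000, sub = TRA),
    r("O2tm",  "o2[c] -> o2[m]", 0, 1000, sub = TRA),
    r("CO2t",  "co2[c] <=> co2[e]", -1000, 1000, sub = TRA),
    r("CO2tm", "co2[m] <=> co2[c]", -1000, 1000, sub = TRA),
    r("ETOHt", "etoh[c] <=> etoh[e]", -1000, 1000, sub = TRA),
    r("ETOHtm", "etoh[m] <=> etoh[c]", -1000, 1000, sub = TRA),
    r("ACALDtm", "acald[c] <=> acald[m]", -1000, 1000, sub = TRA),
    r("GLYCt", "glyc[c] -> glyc[e]", 0, 1000, sub = TRA),
    r("NH4t",  "nh4[e] -> nh4[c]", 0, 1000, sub = TRA),
    r("H2Ot",  "h2o[e] <=> h2o[c]", -1000, 1000, sub = TRA),
    r("GLUt",  "glu[e] -> glu[c]", 0, 1000, "DIP5", TRA),
    r("PYRtm", "pyr[c] -> pyr[m]", 0, 1000, sub = TRA),

    ## hexose and disaccharide entry
    r("HXK",   "glc[c] + atp[c] -> g6p[c] + adp[c]", 0, 1000, "HXK1 or HXK2", GLY),
    r("MANK",  "man[c] + atp[c] -> man6p[c] + adp[c]", 0, 1000, "HXK1", SUG),
    r("PMI",   "man6p[c] <=> f6p[c]", -1000, 1000, "PMI1", SUG),
    r("GALK_L", "gal[c] + atp[c] -> g6p[c] + adp[c]", 0, 1000,
      "GAL1 and GAL7 and GAL10", SUG, name = "Leloir pathway (lumped)"),
    r("BGL",   "cellb[c] + h2o[c] -> 2 glc[c]", 0, 1000,
      "BGL1 or BGL2 or BGL3 or BGL4 or BGL5 or BGL6 or BGL7 or SUN4", SUG),

    ## xylose: xylulokinase route and D-arabinitol bypass
    r("XYLR",  "xyl[c] + nadph[c] -> xylt[c] + nadp[c]", 0, 1000, "XYL1", XYL,
      name = "xylose reductase"),
    r("XYLDH", "xylt[c] + nad[c] -> xlu[c] + nadh[c]", 0, 1000, "XYL2", XYL,
      name = "xylitol dehydrogenase"),
    r("XKS",   "xlu[c] + atp[c] -> x5p[c] + adp[c]", 0, 1000, "XKS1", XYL,
      name = "D-xylulokinase"),
    r("RBUR",  "xlu[c] + nadh[c] <=> dartol[c] + nad[c]", -1000, 1000, "ARD2", XYL,
      name = "D-ribulose reductase (xylulose/arabinitol)"),
    r("DARTD", "dartol[c] + nad[c] <=> drbu[c] + nadh[c]", -1000, 1000, "AAD1", XYL,
      name = "D-arabinitol dehydrogenase"),
    r("RBK",   "drbu[c] + atp[c] -> ru5p[c] + adp[c]", 0, 1000, "RKS1", XYL,
      name = "D-ribulokinase"),
    r("DARABR", "darab[c] + nadph[c] -> dartol[c] + nadp[c]", 0, 1000, "ARD2", ARA,
      name = "D-arabinose reductase"),

    ## L-arabinose: four oxidoreductase steps via L-arabitol, L-xylulose, xylitol
    r("LARABR", "larab[c] + nadph[c] -> larabtol[c] + nadp[c]", 0, 1000, "XYL1", ARA,
      name = "L-arabinose reductase (aldose reductase)"),
    r("LAD",   "larabtol[c] + nad[c] -> lxlu[c] + nadh[c]", 0, 1000, "LAD1", ARA,
      name = "L-arabitol 4-dehydrogenase"),
    r("LXR",   "lxlu[c] + nadph[c] -> xylt[c] + nadp[c]", 0, 1000, "LXR1", ARA,
      name = "L-xylulose reductase"),

    ## rhamnose (lumped four-step route) and lactaldehyde disposal
    r("RHA_L", "rha[c] + nad[c] -> pyr[c] + lald[c] + nadh[c]", 0, 1000,
      "LRA1 and LRA2 and LRA3 and LRA4", SUG, name = "rhamnose catabolism (lumped)"),
    r("LALDO", "lald[c] + nad[c] -> lac[c] + nadh[c]", 0, 1000, "ALD5", SUG),
    r("LACD",  "lac[c] + nad[c] -> pyr[c] + nadh[c]", 0, 1000, "DLD1", SUG),

    ## glycolysis
    r("PGI",   "g6p[c] <=> f6p[c]", -1000, 1000, "PGI1", GLY),
    r("PFK",   "f6p[c] + atp[c] -> fdp[c] + adp[c]", 0, 1000, "PFK1", GLY),
    r("FBA",   "fdp[c] <=> dhap[c] + g3p[c]", -1000, 1000, "FBA1", GLY),
    r("TPI",   "dhap[c] <=> g3p[c]", -1000, 1000, "TPI1", GLY),
    r("GAPD_L", "g3p[c] + nad[c] + adp[c] <=> pg3[c] + nadh[c] + atp[c]",
      -1000, 1000, "TDH1 and PGK1", GLY, name = "GAPDH + PGK (lumped)"),
    r("ENO_L", "pg3[c] <=> pep[c]", -1000, 1000, "GPM1 and ENO1", GLY,
      name = "phosphoglycerate mutase + enolase (lumped)"),
    r("PYK",   "pep[c] + adp[c] -> pyr[c] + atp[c]", 0, 1000, "PYK1", GLY),
    ## gluconeogenesis (lets rhamnose-derived pyruvate rebuild sugar phosphates)
    r("PEPCK", "oaa[m] + atp[c] -> pep[c] + co2[m] + adp[c]", 0, 1000, "PCK1", GLY,
      name = "PEP carboxykinase"),
    r("FBP",   "fdp[c] -> f6p[c]", 0, 1000, "FBP1", GLY,
      name = "fructose-1,6-bisphosphatase"),

    ## pentose phosphate pathway
    r("ZWF_L", "g6p[c] + 2 nadp[c] -> ru5p[c] + co2[c] + 2 nadph[c]", 0, 1000,
      "ZWF1 and SOL3 and GND1", PPP, name = "oxidative PPP (lumped)"),
    r("RPE",   "ru5p[c] <=> x5p[c]", -1000, 1000, "RPE1", PPP),
    r("RKI",   "ru5p[c] <=> r5p[c]", -1000, 1000, "RKI1", PPP),
    r("TKL1",  "x5p[c] + r5p[c] <=> s7p[c] + g3p[c]", -1000, 1000, "TKL1", PPP),
    r("TAL",   "s7p[c] + g3p[c] <=> e4p[c] + f6p[c]", -1000, 1000, "TAL1", PPP),
    r("TKL2",  "x5p[c] + e4p[c] <=> f6p[c] + g3p[c]", -1000, 1000, "TKL1", PPP),

    ## fermentation and glycerol shunt
    r("PDC",   "pyr[c] -> acald[c] + co2[c]", 0, 1000, "PDC1", ETH),
    r("ADHc",  "acald[c] + nadh[c] -> etoh[c] + nad[c]", 0, 1000,
      "ADH1 or ADH2 or ADH4 or ADH5", ETH, name = "cytosolic alcohol dehydrogenase"),
    r("ADHm",  "acald[m] + nadh[m] -> etoh[m] + nad[m]", 0, 1000, "ADH3", ETH,
      name = "mitochondrial alcohol dehydrogenase"),
    r("GPD_L", "dhap[c] + nadh[c] -> glyc[c] + nad[c]", 0, 1000, "GPD1",
      "Glycerol metabolism", name = "glycerol formation (lumped)"),

    ## TCA cycle (mitochondrial, partially lumped) and respiration
    r("PDHm",  "pyr[m] + nad[m] -> accoa[m] + co2[m] + nadh[m]", 0, 1000,
      "PDA1 and PDB1 and LAT1", TCA, name = "pyruvate dehydrogenase complex"),
    r("CS",    "accoa[m] + oaa[m] -> cit[m]", 0, 1000, "CIT1", TCA),
    r("IDH_L", "cit[m] + nad[m] -> akg[m] + co2[m] + nadh[m]", 0, 1000,
      "IDH1 and IDH2", TCA, name = "aconitase + isocitrate dehydrogenase (lumped)"),
    r("TCA_L", "akg[m] + 2 nad[m] + adp[c] -> oaa[m] + 2 co2[m] + 2 nadh[m] + atp[c]",
      0, 1000, "KGD1", TCA, name = "KGD-SDH-FUM-MDH segment (lumped)"),
    r("PYC",   "pyr[m] + co2[m] + atp[c] -> oaa[m] + adp[c]", 0, 1000, "PYC1", TCA),
    r("NADHSm", "nadh[c] + nad[m] -> nad[c] + nadh[m]", 0, 1000, sub = OXP,
      name = "cytosolic-to-mitochondrial NADH shuttle (lumped)"),
    r("RESP",  "nadh[m] + 0.5 o2[m] + 2 adp[c] -> nad[m] + 2 atp[c]", 0, 1000,
      sub = OXP, name = "respiratory chain (lumped, P/O = 2)"),
    r("ATPM",  "atp[c] -> adp[c]", 0, 1000, sub = OXP, name = "ATP dissipation"),

    ## nitrogen assimilation / glutamate node
    r("GDH3",  "akg[m] + nh4[c] + nadph[c] -> glu[c] + nadp[c]", 0, 1000,
      "GDH3", AAM, name = "NADP-dependent glutamate dehydrogenase"),
    r("GDH1",  "akg[m] + nh4[c] + nadh[c] -> glu[c] + nad[c]", 0, 1000,
      "GDH1", AAM, name = "NAD-dependent glutamate dehydrogenase"),
    r("GDH2",  "glu[c] + nad[c] -> akg[m] + nh4[c] + nadh[c]", 0, 1000,
      "GDH2", AAM, name = "catabolic glutamate dehydrogenase"),

    ## biomass
    r("BIOMASS", paste("5 g6p[c] + 10 pyr[c] + 3 glu[c] + 2 r5p[c] + 20 atp[c]",
                       "-> 20 adp[c]"),
      0, 1000, sub = "Biomass", name = "biomass formation")
  )

  ## amino-acid exchanges (uptake closed; only glutamate has cellular routes)
  for (aa in AMINO_ACID_TOKENS) {
    defs <- rbind(defs, r(paste0("EX_", aa), paste0(aa, "[e] ->"), 0, 1000, sub = EXC))
  }

  stoich <- list()
  for (i in seq_len(nrow(defs))) {
    stoich[[defs$id[i]]] <- parseEquation(defs$eq[i], context = defs$id[i])$stoich
  }
  mets <- sort(unique(unlist(lapply(stoich, names))))
  MetabolicModel(
    metabolites = data.frame(id = mets, stringsAsFactors = FALSE),
    reactions = data.frame(id = defs$id, name = defs$name,
                           lower_bound = defs$lb, upper_bound = defs$ub,
                           subsystem = defs$sub, gpr = defs$gpr,
                           stringsAsFactors = FALSE),
    stoichiometry = stoich,
    biomass = "BIOMASS",
    compartments = c("c", "e", "m"))
}

#' Gene symbol to locus-tag aliases for the toy model
#'
#' Reads the alias table shipped with the package (symbolic names such as
#' XYL1 against PICST locus tags) so that results computed on symbolic ids
#' can be reported in either naming scheme.
#' @return data.frame with columns \code{symbol} and \code{locus_tag}.
#' @export
geneAliases <- function() {
  utils::read.delim(system.file("extdata", "gene_aliases.tsv",
                                package = "FluxBalanceR"),
                    stringsAsFactors = FALSE)
}
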