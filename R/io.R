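## Model readers and writers.
##
## Native dialects:
##   native-json  - one JSON file, top-level keys metabolites / reactions /
##                  genes / biomass_reaction_id / compartments. Reaction
##                  stoichiometry is a {metabolite id: coefficient} object.
##   tsv-tables   - a path PREFIX expands to three files:
##                  <prefix>_metabolites.tsv, <prefix>_reactions.tsv (with an
##                  equation column), <prefix>_model.tsv (key/value rows).
##   supplementary-csv - CSV exports of a published model workbook (sheets of
##                  reactions and metabolites); the exact column layout is
##                  supplied by a small column-mapping config, not hard-coded.
##   sbml         - SBML Level 3 core, best-effort: flux bounds are carried
##                  as constant parameters <rid>_lb / <rid>_ub, GPRs in
##                  reaction notes.
##
## Metabolite ids carry the compartment as a bracket suffix (met[c], met[m],
## met[e]); equations are written "2 a[c] + b[c] -> c[e]".

#' Parse a reaction equation string
#' @param eq e.g. \code{"2 a[c] + b[c] -> c[e]"}; arrows \code{->}, \code{=>},
#'   \code{<=>}, \code{<->} are recognized, the double-headed forms marking
#'   reversibility (used only when no explicit bounds are available).
#' @return list with \code{stoich} (named numeric) and \code{reversible}.
#' @keywords internal
parseEquation <- function(eq, context = eq) {
  arrow <- regmatches(eq, regexpr("<=>|<->|=>|->", eq))
  if (length(arrow) == 0L) {
    stop("malformed stoichiometry (no reaction arrow) in: ", context)
  }
  reversible <- arrow %in% c("<=>", "<->")
  sides <- strsplit(eq, "<=>|<->|=>|->")[[1]]
  if (length(sides) > 2L) stop("malformed stoichiometry (multiple arrows) in: ", context)
  parseSide <- function(side, sign) {
    side <- trimws(side)
    if (!nzchar(side)) return(numeric(0))
    terms <- trimws(strsplit(side, "\\s\\+\\s|^\\+\\s|\\s\\+$")[[1]])
    terms <- terms[nzchar(terms)]
    out <- numeric(0)
    for (tm in terms) {
      mm <- regmatches(tm, regexec("^\\(?([0-9.eE+-]+)\\)?\\s+(\\S+)$", tm))[[1]]
      if (length(mm) == 3L) {
        coef <- suppressWarnings(as.numeric(mm[2]))
        met <- mm[3]
        if (is.na(coef)) stop("malformed stoichiometry (bad coefficient ",
                              sQuote(mm[2]), ") in: ", context)
      } else if (grepl("^\\S+$", tm)) {
        coef <- 1
        met <- tm
      } else {
        stop("malformed stoichiometry (bad term ", sQuote(tm), ") in: ", context)
      }
      out[met] <- (if (is.na(out[met])) 0 else out[met]) + sign * coef
      if (!met %in% names(out)) out <- c(out, stats::setNames(sign * coef, met))
    }
    out
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- if (length(sides) == 2L) parseSide(sides[2], +1) else numeric(0)
  st <- lhs
  for (met in names(rhs)) {
    st[met] <- (if (met %in% names(st)) st[met] else 0) + rhs[met]
  }
  st <- st[st != 0]
  if (length(st) == 0L) stop("malformed stoichiometry (empty net equation) in: ", context)
  list(stoich = st, reversible = reversible)
}

#' @keywords internal
writeEquation <- function(stoich, reversible = FALSE) {
  fmt <- function(v, names) {
    paste(vapply(seq_along(v), function(i) {
      if (abs(v[i] - 1) < 1e-12) names[i] else paste(format(v[i], digits = 10), names[i])
    }, character(1)), collapse = " + ")
  }
  lhs <- stoich[stoich < 0]
  rhs <- stoich[stoich > 0]
  paste(fmt(-as.numeric(lhs), names(lhs)),
        if (reversible) "<=>" else "->",
        fmt(as.numeric(rhs), names(rhs)))
}

#' Read a metabolic model
#'
#' @param path file path (native-json, sbml), path prefix (tsv-tables) or
#'   directory (supplementary-csv).
#' @param dialect one of \code{"native-json"}, \code{"tsv-tables"},
#'   \code{"supplementary-csv"}, \code{"sbml"}.
#' @param mapping for \code{supplementary-csv}: a column-mapping config,
#'   either a named list or the path of a JSON file (see
#'   \code{\link{supplementaryMappingTemplate}}).
#' @return a validated \linkS4class{MetabolicModel}.
#' @examples
#' toy <- readModel(system.file("extdata", "toy_stipitis.json",
#'                              package = "FluxBalanceR"))
#' @export
readModel <- function(path, dialect = c("native-json", "tsv-tables",
                                        "supplementary-csv", "sbml"),
                      mapping = NULL) {
  dialect <- match.arg(dialect)
  switch(dialect,
    "native-json" = readModelJSON(path),
    "tsv-tables" = readModelTSV(path),
    "supplementary-csv" = readModelSupplementary(path, mapping),
    "sbml" = readModelSBML(path)
  )
}

#' Write a metabolic model
#'
#' The emitted file re-reads to an equivalent model (same ids, bounds,
#' stoichiometry and GPR truth tables); SBML additionally round-trips through
#' the package's own conventions but drops dialect-specific metadata.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param path output path (or prefix for \code{tsv-tables}).
#' @param dialect one of \code{"native-json"}, \code{"tsv-tables"}, \code{"sbml"}.
#' @return invisibly, \code{path}.
#' @export
writeModel <- function(model, path, dialect = c("native-json", "tsv-tables", "sbml")) {
  dialect <- match.arg(dialect)
  stopifnot(methods::is(model, "MetabolicModel"))
  methods::validObject(model)
  switch(dialect,
    "native-json" = writeModelJSON(model, path),
    "tsv-tables" = writeModelTSV(model, path),
    "sbml" = writeModelSBML(model, path)
  )
  invisible(path)
}

## ---- native-json ----

readModelJSON <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  mets <- do.call(rbind, lapply(doc$metabolites, function(m) {
    data.frame(id = m$id,
               name = if (!is.null(m$name)) m$name else m$id,
               compartment = if (!is.null(m$compartment)) m$compartment else compartmentOf(m$id),
               formula = if (!is.null(m$formula)) m$formula else NA_character_,
               stringsAsFactors = FALSE)
  }))
  stoich <- list()
  rxns <- do.call(rbind, lapply(doc$reactions, function(r) {
    st <- unlist(r$stoichiometry)
    if (is.null(st) || length(st) == 0L) {
      stop("malformed stoichiometry (empty) in reaction: ", r$id)
    }
    stoich[[r$id]] <<- st
    data.frame(id = r$id,
               name = if (!is.null(r$name)) r$name else r$id,
               lower_bound = if (!is.null(r$lower_bound)) r$lower_bound else DEFAULT_LB_REV,
               upper_bound = if (!is.null(r$upper_bound)) r$upper_bound else DEFAULT_UB,
               subsystem = if (!is.null(r$subsystem)) r$subsystem else NA_character_,
               gpr = if (!is.null(r$gpr)) r$gpr else "",
               stringsAsFactors = FALSE)
  }))
  MetabolicModel(mets, rxns, stoich,
                 biomass = if (!is.null(doc$biomass_reaction_id)) doc$biomass_reaction_id else "",
                 genes = if (!is.null(doc$genes)) unlist(doc$genes) else NULL,
                 compartments = if (!is.null(doc$compartments)) unlist(doc$compartments) else NULL)
}

writeModelJSON <- function(model, path) {
  met <- model@metabolites
  rxn <- model@reactions
  doc <- list(
    biomass_reaction_id = model@biomassReactionId,
    compartments = model@compartments,
    genes = model@genes,
    metabolites = lapply(seq_len(nrow(met)), function(i) {
      out <- list(id = met$id[i], name = met$name[i], compartment = met$compartment[i])
      if (!is.na(met$formula[i])) out$formula <- met$formula[i]
      out
    }),
    reactions = lapply(seq_len(nrow(rxn)), function(j) {
      st <- model@S[, j]
      st <- st[st != 0]
      list(id = rxn$id[j], name = rxn$name[j],
           stoichiometry = as.list(st),
           lower_bound = rxn$lower_bound[j], upper_bound = rxn$upper_bound[j],
           subsystem = rxn$subsystem[j], gpr = rxn$gpr[j])
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
}

## ---- tsv-tables ----

tsvPaths <- function(prefix) {
  list(metabolites = paste0(prefix, "_metabolites.tsv"),
       reactions = paste0(prefix, "_reactions.tsv"),
       model = paste0(prefix, "_model.tsv"))
}

readModelTSV <- function(prefix) {
  p <- tsvPaths(prefix)
  for (f in unlist(p)) if (!file.exists(f)) stop("no such file: ", f)
  mets <- utils::read.delim(p$metabolites, stringsAsFactors = FALSE)
  rxns <- utils::read.delim(p$reactions, stringsAsFactors = FALSE)
  meta <- utils::read.delim(p$model, stringsAsFactors = FALSE, header = TRUE)
  kv <- stats::setNames(meta$value, meta$key)
  stoich <- list()
  for (i in seq_len(nrow(rxns))) {
    pe <- parseEquation(rxns$equation[i], context = paste0("row ", i, " (", rxns$id[i], ")"))
    stoich[[rxns$id[i]]] <- pe$stoich
  }
  rxns$equation <- NULL
  MetabolicModel(mets, rxns, stoich,
                 biomass = if ("biomass_reaction_id" %in% names(kv)) unname(kv["biomass_reaction_id"]) else "",
                 genes = if ("genes" %in% names(kv) && nzchar(kv["genes"]))
                   strsplit(unname(kv["genes"]), ",", fixed = TRUE)[[1]] else NULL,
                 compartments = if ("compartments" %in% names(kv))
                   strsplit(unname(kv["compartments"]), ",", fixed = TRUE)[[1]] else NULL)
}

writeModelTSV <- function(model, prefix) {
  p <- tsvPaths(prefix)
  utils::write.table(model@metabolites, p$metabolites, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  rxn <- model@reactions
  rxn$equation <- vapply(seq_len(ncol(model@S)), function(j) {
    st <- model@S[, j]
    writeEquation(st[st != 0])
  }, character(1))
  rxn <- rxn[, c("id", "name", "equation", "lower_bound", "upper_bound", "subsystem", "gpr")]
  utils::write.table(rxn, p$reactions, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- data.frame(key = c("biomass_reaction_id", "compartments", "genes"),
                     value = c(model@biomassReactionId,
                               paste(model@compartments, collapse = ","),
                               paste(model@genes, collapse = ",")))
  utils::write.table(meta, p$model, sep = "\t", row.names = FALSE, quote = FALSE)
}

## ---- supplementary-csv ----

#' Template column mapping for supplementary CSV exports
#'
#' Published model workbooks differ in their column headers, so the
#' supplementary reader takes a mapping config instead of hard-coding a
#' layout. This returns a template to adapt: file names relative to the
#' export directory and the header names holding each field. \code{lower_bound}
#' / \code{upper_bound} may be omitted, in which case reversibility is taken
#' from the equation arrow (\code{<=>} reversible).
#'
#' @return a named list; serialize with \code{jsonlite::write_json} if a file
#'   is preferred.
#' @export
supplementaryMappingTemplate <- function() {
  list(
    reactions_file = "reactions.csv",
    metabolites_file = "metabolites.csv",
    reaction_columns = list(id = "Abbreviation", name = "Description",
                            equation = "Equation", gpr = "GPR",
                            subsystem = "Subsystem",
                            lower_bound = "LB", upper_bound = "UB"),
    metabolite_columns = list(id = "Abbreviation", name = "Description",
                              compartment = "Compartment", formula = "Formula"),
    biomass_reaction_id = "biomass"
  )
}

readModelSupplementary <- function(dir, mapping) {
  if (is.null(mapping)) stop("supplementary-csv requires a column mapping config")
  if (is.character(mapping)) mapping <- jsonlite::fromJSON(mapping, simplifyVector = FALSE)
  rf <- file.path(dir, mapping$reactions_file)
  if (!file.exists(rf)) stop("no such file: ", rf)
  rtab <- utils::read.csv(rf, stringsAsFactors = FALSE, check.names = FALSE)
  rc <- mapping$reaction_columns
  need <- c("id", "equation")
  if (!all(need %in% names(rc))) stop("reaction_columns must map at least 'id' and 'equation'")
  getcol <- function(tab, col) if (!is.null(col) && col %in% names(tab)) tab[[col]] else NULL
  rid <- getcol(rtab, rc$id)
  req <- getcol(rtab, rc$equation)
  if (is.null(rid) || is.null(req)) stop("mapped reaction columns missing from ", rf)
  stoich <- list()
  reversible <- logical(nrow(rtab))
  for (i in seq_len(nrow(rtab))) {
    pe <- parseEquation(req[i], context = paste0("row ", i, " (", rid[i], ") of ", rf))
    stoich[[rid[i]]] <- pe$stoich
    reversible[i] <- pe$reversible
  }
  rxns <- data.frame(id = rid, stringsAsFactors = FALSE)
  nm <- getcol(rtab, rc$name); if (!is.null(nm)) rxns$name <- nm
  gp <- getcol(rtab, rc$gpr); if (!is.null(gp)) rxns$gpr <- gp
  ss <- getcol(rtab, rc$subsystem); if (!is.null(ss)) rxns$subsystem <- ss
  lbc <- getcol(rtab, rc$lower_bound); ubc <- getcol(rtab, rc$upper_bound)
  if (!is.null(lbc) && !is.null(ubc)) {
    rxns$lower_bound <- as.numeric(lbc)
    rxns$upper_bound <- as.numeric(ubc)
  } else {
    rxns$lower_bound <- ifelse(reversible, DEFAULT_LB_REV, 0)
    rxns$upper_bound <- DEFAULT_UB
  }

  mf <- if (!is.null(mapping$metabolites_file)) file.path(dir, mapping$metabolites_file) else NULL
  if (!is.null(mf) && file.exists(mf)) {
    mtab <- utils::read.csv(mf, stringsAsFactors = FALSE, check.names = FALSE)
    mc <- mapping$metabolite_columns
    mets <- data.frame(id = getcol(mtab, mc$id), stringsAsFactors = FALSE)
    v <- getcol(mtab, mc$name); if (!is.null(v)) mets$name <- v
    v <- getcol(mtab, mc$compartment); if (!is.null(v)) mets$compartment <- v
    v <- getcol(mtab, mc$formula); if (!is.null(v)) mets$formula <- v
  } else {
    mets <- data.frame(id = sort(unique(unlist(lapply(stoich, names)))),
                       stringsAsFactors = FALSE)
  }
  MetabolicModel(mets, rxns, stoich,
                 biomass = if (!is.null(mapping$biomass_reaction_id)) mapping$biomass_reaction_id else "")
}

## ---- SBML Level 3 core (best-effort) ----

sbmlSafeId <- function(id) {
  # SBML SIds cannot contain brackets; encode the compartment suffix
  gsub("[^A-Za-z0-9_]", "_", sub("\\[([^][]+)\\]$", "__\\1", id))
}

writeModelSBML <- function(model, path) {
  met <- model@metabolites
  rxn <- model@reactions
  sid <- stats::setNames(sbmlSafeId(met$id), met$id)
  doc <- xml2::xml_new_root("sbml",
    xmlns = "http://www.sbml.org/sbml/level3/version1/core",
    level = "3", version = "1")
  mdl <- xml2::xml_add_child(doc, "model", id = "model",
                             name = if (nzchar(model@biomassReactionId))
                               paste0("biomass:", model@biomassReactionId) else "model")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in model@compartments) {
    xml2::xml_add_child(lc, "compartment", id = cp, constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(met))) {
    sp <- xml2::xml_add_child(ls, "species", id = sid[[met$id[i]]], name = met$name[i],
                              compartment = met$compartment[i],
                              hasOnlySubstanceUnits = "false",
                              boundaryCondition = "false", constant = "false")
    if (!is.na(met$formula[i])) xml2::xml_set_attr(sp, "metaid", met$formula[i])
  }
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (j in seq_len(nrow(rxn))) {
    rid <- sbmlSafeId(rxn$id[j])
    xml2::xml_add_child(lp, "parameter", id = paste0(rid, "_lb"),
                        value = format(rxn$lower_bound[j], digits = 12), constant = "true")
    xml2::xml_add_child(lp, "parameter", id = paste0(rid, "_ub"),
                        value = format(rxn$upper_bound[j], digits = 12), constant = "true")
    rx <- xml2::xml_add_child(lr, "reaction", id = rid, name = rxn$name[j],
                              reversible = tolower(rxn$lower_bound[j] < 0),
                              fast = "false")
    if (nzchar(rxn$gpr[j]) || !is.na(rxn$subsystem[j])) {
      notes <- xml2::xml_add_child(rx, "notes")
      body <- xml2::xml_add_child(notes, "body", xmlns = "http://www.w3.org/1999/xhtml")
      if (nzchar(rxn$gpr[j])) {
        xml2::xml_add_child(body, "p", paste0("GENE_ASSOCIATION: ", rxn$gpr[j]))
      }
      if (!is.na(rxn$subsystem[j])) {
        xml2::xml_add_child(body, "p", paste0("SUBSYSTEM: ", rxn$subsystem[j]))
      }
    }
    st <- model@S[, j]
    sub <- st[st < 0]; prod <- st[st > 0]
    if (length(sub)) {
      lre <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_along(sub)) {
        xml2::xml_add_child(lre, "speciesReference", species = sid[[names(sub)[k]]],
                            stoichiometry = format(-as.numeric(sub[k]), digits = 12),
                            constant = "true")
      }
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_along(prod)) {
        xml2::xml_add_child(lpr, "speciesReference", species = sid[[names(prod)[k]]],
                            stoichiometry = format(as.numeric(prod[k]), digits = 12),
                            constant = "true")
      }
    }
  }
  # original bracketed ids preserved in an annotation map
  ann <- xml2::xml_add_child(mdl, "annotation")
  idmap <- xml2::xml_add_child(ann, "idMap")
  for (i in seq_len(nrow(met))) {
    xml2::xml_add_child(idmap, "m", sbml = sid[[met$id[i]]], orig = met$id[i])
  }
  for (j in seq_len(nrow(rxn))) {
    xml2::xml_add_child(idmap, "r", sbml = sbmlSafeId(rxn$id[j]), orig = rxn$id[j])
  }
  xml2::write_xml(doc, path)
}

readModelSBML <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mdl <- xml2::xml_find_first(doc, ".//model")
  idmapM <- xml2::xml_find_all(doc, ".//annotation/idMap/m")
  idmapR <- xml2::xml_find_all(doc, ".//annotation/idMap/r")
  mapM <- stats::setNames(xml2::xml_attr(idmapM, "orig"), xml2::xml_attr(idmapM, "sbml"))
  mapR <- stats::setNames(xml2::xml_attr(idmapR, "orig"), xml2::xml_attr(idmapR, "sbml"))
  origM <- function(x) ifelse(x %in% names(mapM), unname(mapM[x]), x)
  origR <- function(x) ifelse(x %in% names(mapR), unname(mapR[x]), x)

  sp <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  mets <- data.frame(
    id = origM(xml2::xml_attr(sp, "id")),
    name = xml2::xml_attr(sp, "name"),
    compartment = xml2::xml_attr(sp, "compartment"),
    formula = xml2::xml_attr(sp, "metaid"),
    stringsAsFactors = FALSE)
  mets$name[is.na(mets$name)] <- mets$id[is.na(mets$name)]

  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))

  rxnodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  stoich <- list()
  rows <- lapply(rxnodes, function(rx) {
    sbid <- xml2::xml_attr(rx, "id")
    rid <- origR(sbid)
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rx, "./listOfReactants/speciesReference")) {
      met <- origM(xml2::xml_attr(sr, "species"))
      st[met] <- (if (met %in% names(st)) st[met] else 0) -
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rx, "./listOfProducts/speciesReference")) {
      met <- origM(xml2::xml_attr(sr, "species"))
      st[met] <- (if (met %in% names(st)) st[met] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    stoich[[rid]] <<- st
    ps <- xml2::xml_text(xml2::xml_find_all(rx, "./notes/body/p"))
    gpr <- sub("^GENE_ASSOCIATION:\\s*", "", ps[grepl("^GENE_ASSOCIATION:", ps)])
    sub <- sub("^SUBSYSTEM:\\s*", "", ps[grepl("^SUBSYSTEM:", ps)])
    lbName <- paste0(sbid, "_lb"); ubName <- paste0(sbid, "_ub")
    rev <- identical(xml2::xml_attr(rx, "reversible"), "true")
    data.frame(
      id = rid,
      name = ifelse(is.na(xml2::xml_attr(rx, "name")), rid, xml2::xml_attr(rx, "name")),
      lower_bound = if (lbName %in% names(pval)) pval[[lbName]] else if (rev) DEFAULT_LB_REV else 0,
      upper_bound = if (ubName %in% names(pval)) pval[[ubName]] else DEFAULT_UB,
      subsystem = if (length(sub)) sub[1] else NA_character_,
      gpr = if (length(gpr)) gpr[1] else "",
      stringsAsFactors = FALSE)
  })
  rxns <- do.call(rbind, rows)
  mname <- xml2::xml_attr(mdl, "name")
  biomass <- if (!is.na(mname) && grepl("^biomass:", mname)) sub("^biomass:", "", mname) else ""
  comps <- xml2::xml_attr(xml2::xml_find_all(doc, ".//listOfCompartments/compartment"), "id")
  MetabolicModel(mets, rxns, stoich, biomass = biomass,
                 compartments = if (length(comps)) comps else NULL)
}
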