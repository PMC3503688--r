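## Minimal-medium construction.
##
## A MediumSpec is a complete set of bound overrides for a model's exchange
## reactions. buildMedium() encodes the study's minimal medium: the inorganic
## components (ammonia, sulphate, phosphate, sodium, potassium, iron(II),
## water, protons) unconstrained at (-1000, 1000), a single limited carbon
## source, oxygen per condition, and optionally one amino acid at a capped
## uptake. Uptake is a negative exchange flux.

MINIMAL_MEDIUM_TOKENS <- c("nh4", "so4", "pi", "na1", "k", "fe2", "h2o", "h")

CARBON_ALIASES <- c(glucose = "glc", xylose = "xyl", mannose = "man",
                    galactose = "gal", arabinose = "arab", cellobiose = "cellb",
                    rhamnose = "rha", glutamate = "glu")

#' Find the exchange reaction for a metabolite token
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param what a reaction id, a metabolite token (\code{"xyl"}), or a common
#'   name (\code{"xylose"}).
#' @return the exchange reaction id.
#' @export
findExchange <- function(model, what) {
  rxn <- model@reactions
  if (what %in% rxn$id) {
    if (!rxn$is_exchange[match(what, rxn$id)]) {
      stop(what, " is not an exchange reaction")
    }
    return(what)
  }
  token <- if (what %in% names(CARBON_ALIASES)) CARBON_ALIASES[[what]] else what
  exch <- which(rxn$is_exchange)
  for (j in exch) {
    met <- rownames(model@S)[which(model@S[, j] != 0)]
    if (sub("\\[[^][]+\\]$", "", met) == token) return(rxn$id[j])
  }
  stop("no exchange reaction found for ", sQuote(what))
}

#' Build a minimal-medium growth condition
#'
#' Closes every exchange reaction's uptake, then opens: the minimal-medium
#' inorganic components at (-1000, 1000); the sole carbon source at a lower
#' bound of \code{-carbon_uptake}; oxygen according to \code{oxygen_mode};
#' and optionally one amino acid at \code{-amino_acid_uptake}. Secretion
#' (upper bounds) is left as in the model.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param carbon_source \code{"glucose"}, \code{"xylose"}, another sugar name,
#'   a metabolite token, or an exchange reaction id.
#' @param carbon_uptake maximal uptake rate of the carbon source,
#'   mmol/gDCW/h (default 3).
#' @param oxygen_mode \code{"aerobic"} (lower bound -1000), \code{"semiaerobic"}
#'   (lower bound -5), or a number \code{v} fixing oxygen uptake exactly at
#'   \code{v} mmol/gDCW/h (bounds \code{-v, -v}).
#' @param amino_acid optional amino-acid exchange (id or token) to supplement.
#' @param amino_acid_uptake maximal amino-acid uptake, mmol/gDCW/h (default 0.1).
#' @return a \linkS4class{MediumSpec}.
#' @examples
#' m <- toyStipitisModel()
#' xa <- buildMedium(m, "xylose", oxygen_mode = "aerobic")
#' @export
buildMedium <- function(model, carbon_source, carbon_uptake = 3,
                        oxygen_mode = c("aerobic", "semiaerobic"),
                        amino_acid = NULL, amino_acid_uptake = 0.1) {
  stopifnot(methods::is(model, "MetabolicModel"), carbon_uptake >= 0)
  rxn <- model@reactions
  exch <- rxn$id[rxn$is_exchange]
  if (!length(exch)) stop("model has no exchange reactions")
  b <- cbind(lower = rep(0, length(exch)),
             upper = rxn$upper_bound[rxn$is_exchange])
  rownames(b) <- exch

  for (token in MINIMAL_MEDIUM_TOKENS) {
    id <- tryCatch(findExchange(model, token), error = function(e) NULL)
    if (!is.null(id)) b[id, ] <- c(-1000, 1000)
  }
  carbon <- findExchange(model, carbon_source)
  b[carbon, "lower"] <- -carbon_uptake

  o2 <- tryCatch(findExchange(model, "o2"), error = function(e) NULL)
  oxyLabel <- "no-oxygen-exchange"
  if (!is.null(o2)) {
    if (is.numeric(oxygen_mode)) {
      b[o2, ] <- c(-oxygen_mode, -oxygen_mode)
      oxyLabel <- paste0("o2-fixed-", oxygen_mode)
    } else {
      oxygen_mode <- match.arg(oxygen_mode)
      b[o2, "lower"] <- if (oxygen_mode == "aerobic") -1000 else -5
      oxyLabel <- oxygen_mode
    }
  }
  aaLabel <- NULL
  if (!is.null(amino_acid)) {
    aa <- findExchange(model, amino_acid)   # errors if absent from the model
    b[aa, "lower"] <- -amino_acid_uptake
    aaLabel <- paste0("+", amino_acid)
  }
  methods::new("MediumSpec",
               name = paste(c(carbon_source, oxyLabel, aaLabel), collapse = "-"),
               bounds = b)
}

#' Apply a medium to a model
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium a \linkS4class{MediumSpec}; every referenced id must be an
#'   exchange reaction of the model.
#' @return the model with overridden exchange bounds.
#' @export
applyMedium <- function(model, medium) {
  if (is.null(medium)) return(model)
  stopifnot(methods::is(medium, "MediumSpec"))
  ids <- rownames(medium@bounds)
  j <- match(ids, model@reactions$id)
  if (anyNA(j)) stop("medium references unknown reaction(s): ",
                     paste(ids[is.na(j)], collapse = ", "))
  if (!all(model@reactions$is_exchange[j])) {
    stop("medium references non-exchange reaction(s): ",
         paste(ids[!model@reactions$is_exchange[j]], collapse = ", "))
  }
  setReactionBounds(model, ids, medium@bounds[, "lower"], medium@bounds[, "upper"])
}

#' Named medium presets for the four study conditions
#'
#' GA/GSA/XA/XSA: glucose or xylose at 3 mmol/gDCW/h, aerobic or semiaerobic
#' oxygen.
#' @param model a \linkS4class{MetabolicModel}.
#' @param name one of \code{"GA"}, \code{"GSA"}, \code{"XA"}, \code{"XSA"},
#'   or the long forms \code{"glucose-minimal"} / \code{"xylose-minimal"}
#'   (aerobic).
#' @return a \linkS4class{MediumSpec}.
#' @export
mediumPreset <- function(model, name) {
  switch(name,
    GA = buildMedium(model, "glucose", 3, "aerobic"),
    GSA = buildMedium(model, "glucose", 3, "semiaerobic"),
    XA = buildMedium(model, "xylose", 3, "aerobic"),
    XSA = buildMedium(model, "xylose", 3, "semiaerobic"),
    `glucose-minimal` = buildMedium(model, "glucose", 3, "aerobic"),
    `xylose-minimal` = buildMedium(model, "xylose", 3, "aerobic"),
    stop("unknown medium preset: ", name)
  )
}
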