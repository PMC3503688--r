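## Single-gene deletion and essentiality classification.
##
## A knockout sets a gene's state FALSE; every reaction whose (non-empty)
## GPR then evaluates FALSE is constrained to zero flux. A gene is essential
## when the mutant's maximal growth falls below a threshold fraction
## (default 1e-6) of wild type; infeasible mutant LPs are treated as zero
## growth and hence essential (logged distinctly in the result table).

#' Reactions disabled by a gene knockout set
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param knockedGenes character vector of gene ids (must exist in the model).
#' @return reaction ids whose GPR is non-empty and evaluates FALSE with the
#'   knocked genes off and all other genes on. Reactions without a gene
#'   association are never disabled.
#' @examples
#' m <- toyStipitisModel()
#' disabledReactions(m, "XKS1")
#' @export
disabledReactions <- function(model, knockedGenes) {
  unknown <- setdiff(knockedGenes, model@genes)
  if (length(unknown)) stop("unknown gene(s): ", paste(unknown, collapse = ", "))
  if (!length(knockedGenes)) return(character(0))
  states <- stats::setNames(rep(FALSE, length(knockedGenes)), knockedGenes)
  off <- vapply(model@gprTrees, function(tree) {
    !is.null(tree) && !gprEval(tree, states)
  }, logical(1))
  model@reactions$id[off]
}

#' Apply a gene knockout to a model
#'
#' @inheritParams disabledReactions
#' @return the model with the disabled reactions' bounds set to (0, 0).
#' @export
knockoutGenes <- function(model, knockedGenes) {
  dis <- disabledReactions(model, knockedGenes)
  if (!length(dis)) return(model)
  setReactionBounds(model, dis, 0, 0)
}

#' Single-gene deletion scan
#'
#' Solves the wild type once, then for each gene disables its reactions and
#' re-maximizes growth.
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param medium a \linkS4class{MediumSpec}; wild-type growth on it must be
#'   positive.
#' @param geneIds optional subset of genes (default: all model genes).
#' @param threshold essentiality threshold on the growth ratio (default 1e-6).
#' @return data.frame with columns \code{gene}, \code{mutant_growth},
#'   \code{growth_ratio}, \code{essential}, \code{infeasible},
#'   \code{disabled_reactions} (comma-separated).
#' @examples
#' m <- toyStipitisModel()
#' del <- singleGeneDeletion(m, buildMedium(m, "glucose"))
#' head(del[del$essential, "gene"])
#' @export
singleGeneDeletion <- function(model, medium, geneIds = NULL, threshold = 1e-6) {
  stopifnot(threshold > 0)
  if (is.null(geneIds)) geneIds <- model@genes
  model <- applyMedium(model, medium)
  wt <- solveFBA(model)
  if (solutionStatus(wt) != "optimal" || objectiveValue(wt) <= 0) {
    stop("wild-type growth on this medium is not positive; check the medium ",
         "(carbon source, oxygen) before running deletions")
  }
  wtGrowth <- objectiveValue(wt)
  rows <- lapply(geneIds, function(g) {
    dis <- disabledReactions(model, g)
    if (!length(dis)) {
      mut <- wtGrowth   # no reaction touched: growth unchanged exactly
      feas <- TRUE
    } else {
      m2 <- setReactionBounds(model, dis, 0, 0)
      sol <- solveFBA(m2)
      feas <- solutionStatus(sol) == "optimal"
      mut <- if (feas) objectiveValue(sol) else 0
    }
    data.frame(gene = g, mutant_growth = mut, growth_ratio = mut / wtGrowth,
               essential = (mut / wtGrowth) < threshold, infeasible = !feas,
               disabled_reactions = paste(dis, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "wild_type_growth") <- wtGrowth
  out
}

#' Essential genes on a medium
#' @inheritParams singleGeneDeletion
#' @return sorted character vector of essential gene ids.
#' @export
essentialGenes <- function(model, medium, threshold = 1e-6) {
  del <- singleGeneDeletion(model, medium, threshold = threshold)
  sort(del$gene[del$essential])
}

#' Compare gene essentiality between two media
#'
#' @param model a \linkS4class{MetabolicModel}.
#' @param mediumA,mediumB two \linkS4class{MediumSpec} conditions; both must
#'   support wild-type growth.
#' @param threshold essentiality threshold (default 1e-6).
#' @return list with sorted character vectors \code{only_a} (essential on A
#'   but not B) and \code{only_b}, plus \code{essential_a}, \code{essential_b}.
#' @examples
#' m <- toyStipitisModel()
#' cmp <- compareMediaEssentiality(m, buildMedium(m, "glucose"),
#'                                 buildMedium(m, "xylose"))
#' cmp$only_b   # xylose-only essentials
#' @export
compareMediaEssentiality <- function(model, mediumA, mediumB, threshold = 1e-6) {
  ea <- essentialGenes(model, mediumA, threshold)
  eb <- essentialGenes(model, mediumB, threshold)
  list(only_a = sort(setdiff(ea, eb)),
       only_b = sort(setdiff(eb, ea)),
       essential_a = ea, essential_b = eb)
}
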