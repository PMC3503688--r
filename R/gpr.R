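## Boolean gene-protein-reaction (GPR) expressions.
##
## A GPR is a Boolean tree over gene identifiers: OR joins isoenzymes (any
## one suffices), AND joins subunits of a complex (all required).  AND binds
## tighter than OR, parentheses override; this is the COBRA community
## convention.  An empty GPR means "no gene association" and always
## evaluates TRUE (the reaction cannot be disabled by a gene knockout).
##
## Trees are nested lists: a leaf is a length-1 character vector (the gene
## id); an internal node is list(op = "and"|"or", args = list(...)).

gprTokenize <- function(s) {
  s <- gsub("&&|&", " and ", s)
  s <- gsub("\\|\\||\\|", " or ", s)
  s <- gsub("\\(", " ( ", s)
  s <- gsub("\\)", " ) ", s)
  toks <- strsplit(trimws(s), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a GPR string into a Boolean expression tree
#'
#' @param s a GPR string such as \code{"(A and B) or C"}; \code{NA} or an
#'   empty/whitespace string yields \code{NULL} (no gene association).
#' @return a GPR tree (nested list) or \code{NULL}.
#' @examples
#' g <- gprParse("(A and B) or C")
#' gprEval(g, c(A = FALSE, B = TRUE, C = TRUE))
#' @export
gprParse <- function(s) {
  if (is.null(s) || length(s) == 0L || is.na(s) || !nzchar(trimws(s))) return(NULL)
  toks <- gprTokenize(s)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parseExpr <- function() {
    args <- list(parseTerm())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args[[length(args) + 1L]] <- parseTerm()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parseTerm <- function() {
    args <- list(parseFactor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args[[length(args) + 1L]] <- parseFactor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parseFactor <- function() {
    t <- peek()
    if (is.na(t)) stop("GPR parse error: unexpected end of expression in ", sQuote(s))
    if (t == "(") {
      advance()
      e <- parseExpr()
      if (is.na(peek()) || peek() != ")") {
        stop("GPR parse error: missing closing parenthesis in ", sQuote(s))
      }
      advance()
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      stop("GPR parse error: unexpected token ", sQuote(t), " in ", sQuote(s))
    }
    advance()
    t
  }
  tree <- parseExpr()
  if (pos <= length(toks)) {
    stop("GPR parse error: trailing tokens after position ", pos - 1L, " in ", sQuote(s))
  }
  tree
}

#' Evaluate a GPR tree over gene states
#'
#' @param tree a GPR tree from \code{\link{gprParse}}, or \code{NULL}.
#' @param states named logical vector of gene states; genes missing from
#'   \code{states} are taken as present (\code{TRUE}).
#' @return logical: is the reaction enabled?
#' @export
gprEval <- function(tree, states = logical(0)) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) {
    if (tree %in% names(states)) return(unname(states[[tree]]))
    return(TRUE)
  }
  vals <- vapply(tree$args, gprEval, logical(1), states = states)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR tree
#' @param tree a GPR tree or \code{NULL}.
#' @return character vector of unique gene identifiers (possibly empty).
#' @export
gprGenes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gprGenes)))
}

#' Render a GPR tree back to a string
#' @param tree a GPR tree or \code{NULL} (rendered as \code{""}).
#' @return character GPR string with explicit parentheses around OR groups
#'   nested under AND.
#' @export
gprDeparse <- function(tree) {
  if (is.null(tree)) return("")
  rec <- function(t, parentOp) {
    if (is.character(t)) return(t)
    parts <- vapply(t$args, rec, character(1), parentOp = t$op)
    joined <- paste(parts, collapse = paste0(" ", t$op, " "))
    if (!is.na(parentOp) && t$op == "or" && parentOp == "and") {
      joined <- paste0("(", joined, ")")
    }
    joined
  }
  rec(tree, NA_character_)
}

#' Truth table of a GPR tree
#'
#' Enumerates all assignments of the referenced genes; used for round-trip
#' equivalence of serialized GPRs.
#' @param tree a GPR tree.
#' @param genes gene universe (defaults to the genes in the tree).
#' @return data.frame of gene columns plus a logical \code{value} column.
#' @export
gprTruthTable <- function(tree, genes = gprGenes(tree)) {
  if (length(genes) == 0L) {
    return(data.frame(value = gprEval(tree)))
  }
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(genes)))
  names(grid) <- genes
  grid$value <- apply(grid, 1L, function(row) gprEval(tree, stats::setNames(as.logical(row), genes)))
  grid
}
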