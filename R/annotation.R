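## Draft-reconstruction annotation filter.
##
## Bidirectional protein-homology hits against template organisms are kept
## when e-value < 1e-30, amino-acid identity > 40% and alignment coverage
## (match length over the query length, each direction using its own query)
## >= 70%; boundary semantics follow the wording exactly ("less than" and
## "above" strict, "at least" inclusive). Surviving hits, mapped to
## reactions through template models, are merged with KO/EC-derived
## gene-reaction pairs into a draft association table.

#' Filter homology hit records by reconstruction thresholds
#'
#' @param hits data.frame with columns \code{query_gene}, \code{subject_gene},
#'   \code{template}, \code{e_value}, \code{identity_pct}, \code{coverage_pct},
#'   \code{bidirectional} (logical).
#' @param e_max keep \code{e_value < e_max} (strict; default 1e-30).
#' @param identity_min_pct keep \code{identity_pct > identity_min_pct}
#'   (strict; default 40).
#' @param coverage_min_pct keep \code{coverage_pct >= coverage_min_pct}
#'   (inclusive; default 70).
#' @param require_bidirectional drop unidirectional hits (default TRUE).
#' @return the surviving rows, input order preserved.
#' @examples
#' h <- data.frame(query_gene = "q", subject_gene = "s", template = "t",
#'                 e_value = 1e-40, identity_pct = 55, coverage_pct = 80,
#'                 bidirectional = TRUE)
#' nrow(filterHits(h))
#' @export
filterHits <- function(hits, e_max = 1e-30, identity_min_pct = 40,
                       coverage_min_pct = 70, require_bidirectional = TRUE) {
  if (!is.finite(e_max) || e_max < 0 || identity_min_pct < 0 || coverage_min_pct < 0) {
    stop("thresholds must be finite and non-negative")
  }
  need <- c("query_gene", "subject_gene", "template", "e_value",
            "identity_pct", "coverage_pct", "bidirectional")
  miss <- setdiff(need, names(hits))
  if (length(miss)) stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
  if (any(hits$e_value < 0) ||
      any(hits$identity_pct < 0 | hits$identity_pct > 100) ||
      any(hits$coverage_pct < 0 | hits$coverage_pct > 100)) {
    stop("malformed hit record: percentages must lie in [0,100], e-values >= 0")
  }
  keep <- hits$e_value < e_max &
    hits$identity_pct > identity_min_pct &
    hits$coverage_pct >= coverage_min_pct &
    (hits$bidirectional | !require_bidirectional)
  hits[keep, , drop = FALSE]
}

#' Merge template-homology and KO-derived gene-reaction pairs
#'
#' @param template_pairs data.frame with columns \code{gene},
#'   \code{reaction_id} (from filtered hits mapped through template models).
#' @param ko_pairs data.frame with the same columns (from KO/EC lookup).
#' @return data.frame \code{gene}, \code{reaction_id}, \code{evidence}
#'   (\code{"template-homology"}, \code{"ko"}, or \code{"both"}), ordered by
#'   (gene, reaction_id); the union of the de-duplicated inputs.
#' @export
mergeAssociations <- function(template_pairs, ko_pairs) {
  canon <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(character(0))
    unique(paste(df$gene, df$reaction_id, sep = "\r"))
  }
  a <- canon(template_pairs)
  b <- canon(ko_pairs)
  all <- sort(union(a, b))
  parts <- strsplit(all, "\r", fixed = TRUE)
  data.frame(
    gene = vapply(parts, `[`, character(1), 1),
    reaction_id = vapply(parts, `[`, character(1), 2),
    evidence = ifelse(all %in% a & all %in% b, "both",
                      ifelse(all %in% a, "template-homology", "ko")),
    stringsAsFactors = FALSE)
}

#' Read a BLAST outfmt-6-like hit table
#'
#' Expects a TSV with header columns \code{qseqid}, \code{sseqid},
#' \code{pident}, \code{length}, \code{evalue}, \code{qlen}, \code{template}
#' and optionally \code{bidirectional} (0/1; default 1). Coverage is computed
#' as \code{100 * length / qlen}.
#' @param path TSV file.
#' @return data.frame in \code{\link{filterHits}} layout.
#' @export
readHitTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("qseqid", "sseqid", "pident", "length", "evalue", "qlen", "template")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("hit table lacks column(s): ", paste(miss, collapse = ", "))
  data.frame(
    query_gene = tab$qseqid, subject_gene = tab$sseqid, template = tab$template,
    e_value = tab$evalue, identity_pct = tab$pident,
    coverage_pct = 100 * tab$length / tab$qlen,
    bidirectional = if ("bidirectional" %in% names(tab)) tab$bidirectional > 0 else TRUE,
    stringsAsFactors = FALSE)
}

#' Read a two-column KO assignment table
#' @param path TSV with header columns \code{gene}, \code{ko_id}.
#' @return data.frame with those columns.
#' @export
readKOTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "ko_id") %in% names(tab))) {
    stop("KO table must have columns 'gene' and 'ko_id'")
  }
  if (any(!nzchar(tab$gene))) stop("KO table contains empty gene ids")
  tab[, c("gene", "ko_id")]
}

#' Expand KO assignments to gene-reaction pairs through a lookup table
#' @param ko data.frame from \code{\link{readKOTable}}.
#' @param ko_to_reaction data.frame with columns \code{ko_id}, \code{reaction_id}
#'   (user-supplied; this package performs no online KEGG queries).
#' @return data.frame \code{gene}, \code{reaction_id}, de-duplicated.
#' @export
expandKOPairs <- function(ko, ko_to_reaction) {
  mg <- merge(ko, ko_to_reaction, by = "ko_id")
  unique(mg[order(mg$gene, mg$reaction_id), c("gene", "reaction_id")])
}
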