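# Functional-annotation layer: GO-slim mapping, pred2GOA consensus,
# annotation summaries and two-species term enrichment.

#' Map GO annotations to a slim subset
#'
#' Each annotation is replaced by its *minimal* slim ancestors: slim terms
#' reachable via is_a/part_of that are not themselves ancestors of another
#' matched slim term.  A term already in the slim maps to itself.  Terms
#' with no slim ancestor are dropped (default) or mapped to the aspect
#' root; obsolete terms are dropped with a warning.
#'
#' @param goa annotation data.frame (as from [readGAF()]).
#' @param ontology a \code{GOOntology}.
#' @param slimTerms character vector of slim term ids.
#' @param noSlim \code{"drop"} or \code{"root"}.
#' @param aspectRoots named character vector BP/MF/CC -> root term id
#'   (used when \code{noSlim = "root"}).
#' @return annotation data.frame at slim level (duplicates collapsed).
#' @export
mapToSlim <- function(goa, ontology, slimTerms,
                      noSlim = c("drop", "root"), aspectRoots = NULL) {
  noSlim <- match.arg(noSlim)
  obs <- ontology$terms$id[ontology$terms$obsolete]
  if (any(goa$term %in% obs)) {
    warning(sum(goa$term %in% obs), " annotation(s) to obsolete terms dropped")
    goa <- goa[!goa$term %in% obs, , drop = FALSE]
  }
  slimOf <- function(term) {
    if (term %in% slimTerms) return(term)
    anc <- intersect(termAncestors(ontology, term), slimTerms)
    if (!length(anc)) return(character(0))
    # minimal: drop slim terms that are ancestors of another matched one
    isAbove <- vapply(anc, function(s)
      any(vapply(setdiff(anc, s), function(t)
        s %in% termAncestors(ontology, t), logical(1))), logical(1))
    anc[!isAbove]
  }
  uniq <- unique(goa$term)
  mapped <- lapply(uniq, slimOf)
  names(mapped) <- uniq
  rows <- lapply(seq_len(nrow(goa)), function(i) {
    s <- mapped[[goa$term[i]]]
    if (!length(s)) {
      if (noSlim == "drop") return(NULL)
      s <- aspectRoots[[goa$aspect[i]]]
      if (is.null(s)) return(NULL)
    }
    out <- goa[rep(i, length(s)), , drop = FALSE]
    out$term <- s
    out
  })
  out <- unique(do.call(rbind, rows))
  if (is.null(out)) out <- goa[0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Weighted majority-rule consensus of subcellular predictions (pred2GOA)
#'
#' Pools per-protein subcellular localization calls from multiple
#' predictors at the GO cellular-component slim level and assigns a term
#' when its supporting weight strictly exceeds \code{majorityFraction}
#' times the total weight of the tools voting on that protein.  For
#' proteins flagged incomplete (no annotated UTR or no start codon) the
#' assignment additionally requires at least one supporting tool whose
#' prediction is based on more than the N-terminal region.  Assignments
#' carry the ISS evidence code and are merged into the existing annotation
#' without deleting anything.
#'
#' @param calls data.frame: \code{tool}, \code{protein}, \code{compartment}
#'   (tool vocabulary), optional \code{score}.
#' @param tools data.frame: \code{tool}, \code{weight} (> 0),
#'   \code{n_terminal_only} (logical).
#' @param compartmentMap named character vector: compartment label -> GO
#'   CC term; an unmappable label is an error naming tool and label.
#' @param completeness data.frame \code{protein}/\code{complete}; proteins
#'   absent from it are treated as complete.
#' @param existingGoa annotation data.frame to merge into (may be NULL).
#' @param majorityFraction strict-majority threshold (default 0.5).
#' @return list: \code{assignments} (protein/term/weight_fraction/
#'   evidence/tools), \code{goa} (merged annotation data.frame).
#' @export
pred2goa <- function(calls, tools, compartmentMap, completeness = NULL,
                     existingGoa = NULL, majorityFraction = 0.5) {
  if (any(tools$weight <= 0)) stop("tool weights must be positive")
  unmapped <- !(calls$compartment %in% names(compartmentMap))
  if (any(unmapped)) {
    k <- which(unmapped)[1L]
    stop(sprintf("unmappable compartment label '%s' from tool '%s'",
                 calls$compartment[k], calls$tool[k]))
  }
  calls$term <- unname(compartmentMap[calls$compartment])
  w <- setNames(tools$weight, tools$tool)
  nterm <- setNames(as.logical(tools$n_terminal_only), tools$tool)
  if (anyNA(w[calls$tool])) stop("call from unconfigured tool")
  completeOf <- function(p) {
    if (is.null(completeness)) return(TRUE)
    hit <- completeness$complete[completeness$protein == p]
    if (!length(hit)) TRUE else as.logical(hit[1L])
  }
  assignments <- do.call(rbind, lapply(split(calls, calls$protein), function(d) {
    total <- sum(w[d$tool])
    byTerm <- split(d, d$term)
    rows <- lapply(byTerm, function(t) {
      support <- sum(w[t$tool])
      if (support <= majorityFraction * total) return(NULL)
      if (!completeOf(d$protein[1L]) && all(nterm[t$tool])) return(NULL)
      data.frame(protein = d$protein[1L], term = t$term[1L],
                 weight_fraction = support / total, evidence = "ISS",
                 tools = paste(sort(t$tool), collapse = ","),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }))
  if (is.null(assignments))
    assignments <- data.frame(protein = character(0), term = character(0),
                              weight_fraction = numeric(0),
                              evidence = character(0), tools = character(0),
                              stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  newRows <- if (nrow(assignments))
    data.frame(gene = assignments$protein, term = assignments$term,
               aspect = "CC", evidence = "ISS",
               ref = "structome:pred2goa", negated = FALSE,
               stringsAsFactors = FALSE)
  else NULL
  goa <- if (is.null(existingGoa)) newRows
         else unique(rbind(existingGoa[, c("gene", "term", "aspect",
                                           "evidence", "ref", "negated")],
                           newRows))
  list(assignments = assignments, goa = goa)
}

#' Summarize a GO annotation set
#'
#' Counts non-redundant (gene, term) pairs per aspect, genes with at least
#' one term (overall and per aspect), and the coverage fraction of the
#' gene complement.  \code{NOT}-qualified annotations are excluded.
#'
#' @param goa annotation data.frame.
#' @param totalGenes number of protein-coding genes (denominator).
#' @return list: \code{term_counts}, \code{genes_with_term} (both named by
#'   aspect plus \code{total}), \code{coverage}.
#' @export
goaSummary <- function(goa, totalGenes) {
  if (!is.null(goa) && "negated" %in% names(goa))
    goa <- goa[!goa$negated, , drop = FALSE]
  if (is.null(goa) || !nrow(goa)) {
    z <- c(total = 0, BP = 0, MF = 0, CC = 0)
    return(list(term_counts = z, genes_with_term = z, coverage = 0))
  }
  goa <- unique(goa[, c("gene", "term", "aspect")])
  tc <- c(total = nrow(goa), table(factor(goa$aspect, c("BP", "MF", "CC"))))
  gw <- c(total = length(unique(goa$gene)),
          vapply(c("BP", "MF", "CC"), function(a)
            length(unique(goa$gene[goa$aspect == a])), numeric(1)))
  list(term_counts = tc, genes_with_term = gw,
       coverage = gw[["total"]] / totalGenes)
}

#' Two-species GO term enrichment
#'
#' For every term present in either annotation set, builds the 2x2 table
#' of annotated genes against the per-species universes and computes the
#' one-sided exact hypergeometric p-value in each direction (log-space
#' safe), the odds ratio, and Benjamini-Hochberg q-values per aspect over
#' the focal-enrichment p-values.  \code{NOT}-qualified annotations are
#' excluded.
#'
#' @param goaFocal,goaOther annotation data.frames.
#' @param universes numeric vector \code{c(focal = A, other = B)}: genes
#'   in each species' universe (e.g. genes with >= 1 annotation in the
#'   aspect, or all genes).
#' @param alpha significance cutoff on q (default 0.05).
#' @return data.frame sorted by q: \code{term}, \code{aspect}, \code{a},
#'   \code{A}, \code{b}, \code{B}, \code{odds_ratio}, \code{p_focal},
#'   \code{p_other}, \code{log10_p_focal}, \code{q}, \code{significant}.
#' @export
termEnrichment <- function(goaFocal, goaOther, universes, alpha = 0.05) {
  drop_not <- function(g) if ("negated" %in% names(g))
    g[!g$negated, , drop = FALSE] else g
  gf <- unique(drop_not(goaFocal)[, c("gene", "term", "aspect")])
  go <- unique(drop_not(goaOther)[, c("gene", "term", "aspect")])
  A <- universes[["focal"]]; B <- universes[["other"]]
  terms <- unique(rbind(gf[, c("term", "aspect")], go[, c("term", "aspect")]))
  res <- do.call(rbind, lapply(seq_len(nrow(terms)), function(i) {
    tm <- terms$term[i]
    a <- length(unique(gf$gene[gf$term == tm]))
    b <- length(unique(go$gene[go$term == tm]))
    t2 <- twoProportionExactTest(a, A, b, B)
    orr <- (a / max(A - a, .Machine$double.eps)) /
           max(b / max(B - b, .Machine$double.eps), .Machine$double.eps)
    data.frame(term = tm, aspect = terms$aspect[i], a = a, A = A, b = b,
               B = B, odds_ratio = orr, p_focal = t2$p_greater,
               p_other = t2$p_less, log10_p_focal = t2$log10_p_greater,
               stringsAsFactors = FALSE)
  }))
  res$q <- NA_real_
  for (asp in unique(res$aspect))
    res$q[res$aspect == asp] <- adjustFdr(res$p_focal[res$aspect == asp])
  res$significant <- res$q < alpha
  res <- res[order(res$q, res$p_focal), , drop = FALSE]
  rownames(res) <- NULL
  res
}
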