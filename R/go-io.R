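# GAF 2.x and OBO 1.2 input/output plus ancestor queries.
#
# No GAF/OBO reader ships with the installed stack, so these are minimal
# purpose-built parsers for the subsets of both formats this package uses.

GAF_NCOL <- 17L

#' Read a GAF 2.x annotation file
#'
#' Comment lines (\code{!}) are skipped.  Rows with fewer than 15 columns
#' are collected as row-level errors (attribute \code{"errors"}) and the
#' parse continues; columns beyond 17 are ignored.  \code{NOT}-qualified
#' annotations are kept but flagged (\code{negated}); all counting
#' functions in this package exclude them.
#'
#' @param path GAF file.
#' @return data.frame with columns \code{gene}, \code{term}, \code{aspect}
#'   (\code{BP}/\code{MF}/\code{CC}), \code{evidence}, \code{ref},
#'   \code{negated}; attribute \code{"errors"} holds skipped line numbers.
#' @export
readGAF <- function(path) {
  lines <- readLines(path)
  keep <- !startsWith(lines, "!") & nzchar(lines)
  lineNo <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ok <- lengths(fields) >= 15L
  errors <- lineNo[!ok]
  if (length(errors))
    warning(sprintf("%d malformed GAF row(s) skipped (lines %s)",
                    length(errors), paste(errors, collapse = ",")))
  fields <- fields[ok]
  getcol <- function(i) vapply(fields, function(f) f[[i]], character(1))
  aspect <- c(P = "BP", F = "MF", C = "CC")[getcol(9L)]
  out <- data.frame(gene = getcol(2L), term = getcol(5L),
                    aspect = unname(aspect), evidence = getcol(7L),
                    ref = getcol(6L),
                    negated = grepl("(^|\\|)NOT($|\\|)", getcol(4L)),
                    stringsAsFactors = FALSE)
  attr(out, "errors") <- errors
  out
}

#' Write annotations in GAF 2.1 format
#'
#' @param goa data.frame as from [readGAF()] (or with the same columns);
#'   an optional \code{db} column fills column 1.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGAF <- function(goa, path) {
  aspect <- c(BP = "P", MF = "F", CC = "C")[goa$aspect]
  qual <- ifelse(isTRUE(goa$negated) | (is.logical(goa$negated) & goa$negated),
                 "NOT", "")
  db <- if ("db" %in% names(goa)) goa$db else "structome"
  rows <- paste(db, goa$gene, goa$gene, qual, goa$term,
                if ("ref" %in% names(goa)) goa$ref else "structome:consensus",
                goa$evidence, "", aspect, "", "", "protein", "taxon:0",
                format(Sys.Date(), "%Y%m%d"), "structome", "", "",
                sep = "\t")
  writeLines(c("!gaf-version: 2.1", rows), path)
  invisible(path)
}

#' Read an OBO 1.2 ontology
#'
#' Parses \code{[Term]} stanzas, collecting \code{is_a} and
#' \code{relationship: part_of} parents.  Obsolete terms are flagged.
#' A cycle in the parent graph is an error.
#'
#' @param path OBO file.
#' @return an object of class \code{GOOntology}: list with \code{terms}
#'   (data.frame id/name/namespace/obsolete) and \code{parents} (named list
#'   of parent term ids, the union of is_a and part_of).
#' @export
readOBO <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas in ", path)
  bounds <- c(starts, length(lines) + 1L)
  ids <- character(0); nm <- character(0); ns <- character(0)
  obs <- logical(0); parents <- list()
  for (k in seq_along(starts)) {
    chunk <- lines[seq(bounds[k] + 1L, bounds[k + 1L] - 1L)]
    chunk <- chunk[nzchar(chunk) & !startsWith(chunk, "[")]
    val <- function(key) {
      hit <- chunk[startsWith(chunk, paste0(key, ":"))]
      trimws(sub("!.*$", "", sub(paste0("^", key, ":"), "", hit)))
    }
    id <- val("id")[1L]
    if (is.na(id)) next
    isa <- val("is_a")
    rel <- val("relationship")
    po <- sub("^part_of\\s+", "", rel[startsWith(rel, "part_of")])
    ids <- c(ids, id)
    nm <- c(nm, if (length(val("name"))) val("name")[1L] else id)
    ns <- c(ns, if (length(val("namespace"))) val("namespace")[1L] else NA_character_)
    obs <- c(obs, identical(val("is_obsolete")[1L], "true"))
    parents[[id]] <- unique(c(isa, po))
  }
  edges <- do.call(rbind, lapply(ids, function(i) {
    p <- parents[[i]]
    if (length(p)) cbind(i, p) else NULL
  }))
  if (!is.null(edges) && nrow(edges)) {
    g <- igraph::graph_from_edgelist(edges, directed = TRUE)
    if (!igraph::is_dag(g)) stop("cycle detected in ontology ", path)
  }
  structure(list(terms = data.frame(id = ids, name = nm, namespace = ns,
                                    obsolete = obs, stringsAsFactors = FALSE),
                 parents = parents),
            class = "GOOntology")
}

#' @export
print.GOOntology <- function(x, ...) {
  cat(sprintf("GOOntology: %d terms (%d obsolete), namespaces: %s\n",
              nrow(x$terms), sum(x$terms$obsolete),
              paste(unique(stats::na.omit(x$terms$namespace)), collapse = ", ")))
  invisible(x)
}

#' Ancestors of an ontology term
#'
#' Transitive closure over the union of is_a and part_of relations.  The
#' term itself is not included.
#'
#' @param ontology a \code{GOOntology}.
#' @param term term identifier.
#' @return character vector of ancestor term ids (possibly empty).
#' @export
termAncestors <- function(ontology, term) {
  seen <- character(0)
  frontier <- ontology$parents[[term]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
  }
  seen
}
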