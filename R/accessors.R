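# Accessor generics and methods for the gene-model classes.

#' @rdname accessors
#' @param object a TranscriptModel, GeneModel or GenomeAnnotation.
#' @export
setGeneric("speciesLabel", function(object) standardGeneric("speciesLabel"))
#' @rdname accessors
#' @export
setGeneric("genomeSize", function(object) standardGeneric("genomeSize"))
#' @rdname accessors
#' @export
setGeneric("geneModels", function(object) standardGeneric("geneModels"))
#' @rdname accessors
#' @export
setGeneric("transcriptModels", function(object) standardGeneric("transcriptModels"))
#' @rdname accessors
#' @export
setGeneric("exonRanges", function(object) standardGeneric("exonRanges"))
#' @rdname accessors
#' @export
setGeneric("cdsRanges", function(object) standardGeneric("cdsRanges"))
#' @rdname accessors
#' @export
setGeneric("utr5Ranges", function(object) standardGeneric("utr5Ranges"))
#' @rdname accessors
#' @export
setGeneric("utr3Ranges", function(object) standardGeneric("utr3Ranges"))
#' @rdname accessors
#' @export
setGeneric("intronTable", function(object) standardGeneric("intronTable"))

#' Accessors for gene-model objects
#'
#' \code{speciesLabel}, \code{genomeSize}: annotation-level metadata.
#' \code{geneModels}: named list of \linkS4class{GeneModel}.
#' \code{transcriptModels}: flat named list of all
#' \linkS4class{TranscriptModel} objects (annotation or gene level).
#' \code{exonRanges}, \code{cdsRanges}, \code{utr5Ranges}, \code{utr3Ranges}:
#' the corresponding \code{IRanges} of a transcript. \code{intronTable}: the
#' derived intron data.frame (one row per intron with genomic interval,
#' length, region class and spliced offsets).
#'
#' @name accessors
NULL

setMethod("speciesLabel", "GenomeAnnotation", function(object) object@species)
setMethod("genomeSize", "GenomeAnnotation", function(object) object@genomeSize)
setMethod("geneModels", "GenomeAnnotation", function(object) object@genes)

setMethod("transcriptModels", "GeneModel", function(object) {
  txs <- object@transcripts
  names(txs) <- vapply(txs, function(t) t@id, character(1))
  txs
})
setMethod("transcriptModels", "GenomeAnnotation", function(object) {
  txs <- unlist(lapply(object@genes, function(g) g@transcripts),
                recursive = FALSE, use.names = FALSE)
  names(txs) <- vapply(txs, function(t) t@id, character(1))
  txs
})

setMethod("exonRanges", "TranscriptModel", function(object) object@exons)
setMethod("cdsRanges", "TranscriptModel", function(object) object@cds)
setMethod("utr5Ranges", "TranscriptModel", function(object) object@utr5)
setMethod("utr3Ranges", "TranscriptModel", function(object) object@utr3)
setMethod("intronTable", "TranscriptModel", function(object) object@introns)
setMethod("intronTable", "GenomeAnnotation", function(object) {
  txs <- transcriptModels(object)
  out <- lapply(names(txs), function(id) {
    it <- txs[[id]]@introns
    if (nrow(it)) cbind(transcript = id, it, stringsAsFactors = FALSE) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) cbind(transcript = character(0), emptyIntronFrame())
  else out
})

#' Is a transcript coding?
#'
#' Transcripts without CDS are retained in the annotation but excluded from
#' CDS/UTR statistics.
#' @param tx a TranscriptModel.
#' @return logical.
#' @export
isCoding <- function(tx) length(tx@cds) > 0L

#' Spliced (mRNA) length of a transcript
#' @param tx a TranscriptModel.
#' @return total exonic length in nt.
#' @export
splicedLength <- function(tx) sum(width(tx@exons))
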