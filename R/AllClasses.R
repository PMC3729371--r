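#' @import methods
#' @importFrom IRanges IRanges start end width reduce findOverlaps
#' @importFrom S4Vectors queryHits subjectHits mcols elementNROWS
NULL

#' TranscriptModel: one transcript of a gene model
#'
#' A transcript is an ordered set of exons on one scaffold and strand,
#' optionally with CDS intervals.  UTRs and introns are *derived* slots,
#' filled by [deriveTranscriptRegions()]: 5'/3'-UTRs from the exon/CDS
#' geometry, and one record per intron carrying its genomic interval,
#' length, region class (\code{UTR5}/\code{CDS}/\code{UTR3}) and its
#' donor/acceptor offsets in spliced (mRNA) coordinates.
#'
#' All genomic coordinates are 1-based inclusive, as in GFF3.
#'
#' @slot id transcript identifier (opaque text).
#' @slot geneId identifier of the parent gene.
#' @slot scaffold scaffold/chromosome name.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons \linkS4class{IRanges} of exons, sorted genomically, non-overlapping.
#' @slot cds \linkS4class{IRanges} of CDS segments (may be empty).
#' @slot utr5,utr3 derived exonic UTR intervals (genomic).
#' @slot introns derived data.frame: start, end, width, region_class,
#'   donor_offset, acceptor_offset (spliced nt 5' of the intron).
#' @slot estSupported logical flag: transcript-evidence support.
#' @slot hasStartCodon logical flag: start codon annotated.
#' @exportClass TranscriptModel
setClass("TranscriptModel", representation(
  id = "character",
  geneId = "character",
  scaffold = "character",
  strand = "character",
  exons = "IRanges",
  cds = "IRanges",
  utr5 = "IRanges",
  utr3 = "IRanges",
  introns = "data.frame",
  estSupported = "logical",
  hasStartCodon = "logical"
))

emptyIntronFrame <- function() {
  data.frame(start = integer(0), end = integer(0), width = integer(0),
             region_class = character(0), donor_offset = integer(0),
             acceptor_offset = integer(0), stringsAsFactors = FALSE)
}

setValidity("TranscriptModel", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L) msg <- c(msg, "id must be a single string")
  if (!object@strand %in% c("+", "-"))
    msg <- c(msg, "strand must be '+' or '-'")
  ex <- object@exons
  if (length(ex) == 0L) msg <- c(msg, "transcript must have >= 1 exon")
  if (length(ex) > 1L) {
    if (is.unsorted(start(ex)))
      msg <- c(msg, "exons must be sorted genomically")
    if (any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      msg <- c(msg, "exons must be non-overlapping and separated")
  }
  if (length(object@cds)) {
    hit <- findOverlaps(object@cds, ex, type = "within")
    if (length(unique(queryHits(hit))) < length(object@cds))
      msg <- c(msg, sprintf("CDS interval outside any exon in transcript '%s'",
                            object@id))
  }
  if (length(msg)) msg else TRUE
})

#' GeneModel: a locus with one or more transcripts
#'
#' @slot id gene (locus) identifier.
#' @slot scaffold,strand location; all transcripts must agree.
#' @slot transcripts list of \linkS4class{TranscriptModel}.
#' @exportClass GeneModel
setClass("GeneModel", representation(
  id = "character",
  scaffold = "character",
  strand = "character",
  transcripts = "list"
))

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (!length(object@transcripts))
    msg <- c(msg, "gene must have >= 1 transcript")
  for (tx in object@transcripts) {
    if (!is(tx, "TranscriptModel"))
      msg <- c(msg, "transcripts must be TranscriptModel objects")
    else if (!identical(tx@scaffold, object@scaffold) ||
             !identical(tx@strand, object@strand))
      msg <- c(msg, sprintf("transcript '%s' disagrees with gene '%s' on scaffold/strand",
                            tx@id, object@id))
  }
  if (length(msg)) msg else TRUE
})

#' GenomeAnnotation: a genome's protein-coding gene complement
#'
#' The central container of the package: a collection of
#' \linkS4class{GeneModel} objects with a species label and (optionally)
#' the genome size, which enables gene-density statistics.
#'
#' @slot species species label, e.g. \code{"Ppatens"}.
#' @slot genomeSize genome size in base pairs (\code{NA} if unknown).
#' @slot genes named list of \linkS4class{GeneModel}; names are gene ids.
#' @exportClass GenomeAnnotation
setClass("GenomeAnnotation", representation(
  species = "character",
  genomeSize = "numeric",
  genes = "list"
))

setValidity("GenomeAnnotation", function(object) {
  msg <- character(0)
  ids <- vapply(object@genes, function(g) g@id, character(1))
  if (anyDuplicated(ids)) msg <- c(msg, "gene identifiers must be unique")
  if (length(ids) && !identical(unname(names(object@genes)), unname(ids)))
    msg <- c(msg, "genes list names must equal gene ids")
  if (length(msg)) msg else TRUE
})

#' Construct a TranscriptModel
#'
#' Exons (and CDS) may be given in any order; they are sorted genomically.
#' Derived slots (UTRs, introns) are filled immediately via
#' [deriveTranscriptRegions()].
#'
#' @param id,geneId,scaffold,strand identity and location.
#' @param exonStarts,exonEnds integer vectors of exon bounds (1-based inclusive).
#' @param cdsStarts,cdsEnds CDS segment bounds (may be empty).
#' @param estSupported,hasStartCodon evidence flags.
#' @return a validated \linkS4class{TranscriptModel} with derived regions.
#' @export
#' @examples
#' tx <- Transcript("t1", "g1", "chr1", "+", c(1, 201), c(100, 300),
#'                  cdsStarts = 51, cdsEnds = 250)
#' intronTable(tx)
Transcript <- function(id, geneId = id, scaffold = "chr1", strand = "+",
                       exonStarts, exonEnds,
                       cdsStarts = integer(0), cdsEnds = integer(0),
                       estSupported = NA, hasStartCodon = NA) {
  o <- order(as.integer(exonStarts))
  ex <- IRanges(start = as.integer(exonStarts)[o], end = as.integer(exonEnds)[o])
  if (length(cdsStarts)) {
    oc <- order(as.integer(cdsStarts))
    cds <- IRanges(start = as.integer(cdsStarts)[oc], end = as.integer(cdsEnds)[oc])
    # a CDS span may cross introns (it is clipped to the exons), but a CDS
    # interval with no exonic overlap is a structural error
    hit <- findOverlaps(cds, ex)
    if (length(unique(queryHits(hit))) < length(cds))
      stop(sprintf("CDS interval outside any exon in transcript '%s'", id))
    cds <- IRanges::intersect(cds, ex)
  } else cds <- IRanges()
  tx <- new("TranscriptModel", id = as.character(id), geneId = as.character(geneId),
            scaffold = as.character(scaffold), strand = strand,
            exons = ex, cds = cds, utr5 = IRanges(), utr3 = IRanges(),
            introns = emptyIntronFrame(),
            estSupported = as.logical(estSupported),
            hasStartCodon = as.logical(hasStartCodon))
  deriveTranscriptRegions(tx)
}

#' Construct a GeneModel
#' @param id gene identifier.
#' @param transcripts list of \linkS4class{TranscriptModel}.
#' @return a validated \linkS4class{GeneModel}.
#' @export
Gene <- function(id, transcripts) {
  if (is(transcripts, "TranscriptModel")) transcripts <- list(transcripts)
  new("GeneModel", id = as.character(id),
      scaffold = transcripts[[1L]]@scaffold, strand = transcripts[[1L]]@strand,
      transcripts = transcripts)
}

#' Construct a GenomeAnnotation
#' @param genes list of \linkS4class{GeneModel}.
#' @param species species label.
#' @param genomeSize genome size in bp (optional; enables gene density).
#' @return a validated \linkS4class{GenomeAnnotation}.
#' @export
Annotation <- function(genes, species = "unknown", genomeSize = NA_real_) {
  if (is(genes, "GeneModel")) genes <- list(genes)
  names(genes) <- vapply(genes, function(g) g@id, character(1))
  new("GenomeAnnotation", species = as.character(species),
      genomeSize = as.numeric(genomeSize), genes = genes)
}

setMethod("show", "TranscriptModel", function(object) {
  cat(sprintf("TranscriptModel '%s' (gene '%s') %s:%s  %d exon(s), %d CDS segment(s)\n",
              object@id, object@geneId, object@scaffold, object@strand,
              length(object@exons), length(object@cds)))
  if (nrow(object@introns))
    cat(sprintf("  introns: %s\n",
                paste(sprintf("%d-%d[%s]", object@introns$start,
                              object@introns$end, object@introns$region_class),
                      collapse = " ")))
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel '%s' %s:%s with %d transcript(s)\n",
              object@id, object@scaffold, object@strand,
              length(object@transcripts)))
})

setMethod("show", "GenomeAnnotation", function(object) {
  ntx <- sum(vapply(object@genes, function(g) length(g@transcripts), integer(1)))
  cat(sprintf("GenomeAnnotation '%s': %d gene(s), %d transcript(s), genome size %s\n",
              object@species, length(object@genes), ntx,
              ifelse(is.na(object@genomeSize), "unknown",
                     sprintf("%.1f Mb", object@genomeSize / 1e6))))
})
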