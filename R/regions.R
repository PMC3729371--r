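# Derivation of UTRs, introns and spliced-coordinate geometry.
#
# Convention (the single authority in this package): all region
# classification happens in spliced (mRNA) coordinates.  An intron sits
# between spliced positions b and b+1, where b is the number of exonic
# nucleotides 5' of it in transcript orientation; with u5 = 5'-UTR spliced
# length and c = CDS spliced length, the intron is classed UTR5 if b <= u5,
# UTR3 if b >= u5 + c, and CDS otherwise.  An intron whose acceptor abuts
# the ATG (b == u5) is therefore a 5'-UTR intron with distance-to-ATG 0.

#' Map a genomic position to its spliced (mRNA) coordinate
#'
#' @param tx a TranscriptModel.
#' @param pos genomic position (must be exonic).
#' @return 1-based position along the spliced transcript, counted from the
#'   transcript 5' end (strand-aware).
#' @export
genomicToSpliced <- function(tx, pos) {
  ex <- tx@exons
  w <- width(ex)
  idx <- which(pos >= start(ex) & pos <= end(ex))
  if (!length(idx))
    stop(sprintf("position %d is not exonic in transcript '%s'", pos, tx@id))
  if (tx@strand == "+") {
    before <- if (idx > 1L) sum(w[seq_len(idx - 1L)]) else 0L
    before + (pos - start(ex)[idx] + 1L)
  } else {
    after <- if (idx < length(ex)) sum(w[seq(idx + 1L, length(ex))]) else 0L
    after + (end(ex)[idx] - pos + 1L)
  }
}

#' Derive UTRs and region-classified introns of a transcript
#'
#' Fills the \code{utr5}, \code{utr3} and \code{introns} slots from the
#' exon/CDS geometry.  The 5'-UTR is the exonic sequence 5' of the first
#' CDS base in transcript orientation, the 3'-UTR the exonic sequence 3'
#' of the last CDS base.  Each intron is classified \code{UTR5}/\code{CDS}/
#' \code{UTR3} purely by its spliced offset relative to the CDS start/stop
#' offsets (see the convention above).  Transcripts without CDS get empty
#' UTRs and all introns classed \code{CDS}.
#'
#' Any UTR features a source file may have carried are ignored; the
#' exon/CDS geometry is the single authority.
#'
#' @param tx a TranscriptModel.
#' @return the transcript with derived slots filled.
#' @export
deriveTranscriptRegions <- function(tx) {
  validObject(tx)
  ex <- tx@exons
  n <- length(ex)
  w <- width(ex)
  total <- sum(w)

  # introns: gaps between consecutive genomic exons
  if (n > 1L) {
    istart <- end(ex)[-n] + 1L
    iend <- start(ex)[-1L] - 1L
    # spliced nt 5' of intron i (transcript orientation)
    if (tx@strand == "+") b <- cumsum(w)[-n]
    else b <- rev(cumsum(rev(w))[-n])
  } else {
    istart <- iend <- integer(0)
    b <- integer(0)
  }

  if (length(tx@cds)) {
    cdsLen <- sum(width(tx@cds))
    if (tx@strand == "+") {
      firstCdsPos <- min(start(tx@cds)); lastCdsPos <- max(end(tx@cds))
    } else {
      firstCdsPos <- max(end(tx@cds)); lastCdsPos <- min(start(tx@cds))
    }
    u5 <- genomicToSpliced(tx, firstCdsPos) - 1L
    u3 <- total - u5 - cdsLen
    stopifnot(u3 == total - genomicToSpliced(tx, lastCdsPos))
    span <- range(c(start(ex), end(ex)))
    if (tx@strand == "+") {
      up <- if (firstCdsPos > span[1L])
        IRanges(span[1L], firstCdsPos - 1L) else IRanges()
      down <- if (lastCdsPos < span[2L])
        IRanges(lastCdsPos + 1L, span[2L]) else IRanges()
    } else {
      up <- if (firstCdsPos < span[2L])
        IRanges(firstCdsPos + 1L, span[2L]) else IRanges()
      down <- if (lastCdsPos > span[1L])
        IRanges(span[1L], lastCdsPos - 1L) else IRanges()
    }
    tx@utr5 <- IRanges::intersect(ex, up)
    tx@utr3 <- IRanges::intersect(ex, down)
    cls <- rep("CDS", length(b))
    cls[b <= u5] <- "UTR5"
    cls[b >= u5 + cdsLen] <- "UTR3"
  } else {
    tx@utr5 <- IRanges()
    tx@utr3 <- IRanges()
    cls <- rep("CDS", length(b))
  }

  tx@introns <- data.frame(start = as.integer(istart), end = as.integer(iend),
                           width = as.integer(iend - istart + 1L),
                           region_class = cls,
                           donor_offset = as.integer(b),
                           acceptor_offset = as.integer(b),
                           stringsAsFactors = FALSE)
  tx
}

#' Spliced CDS offsets of a coding transcript
#'
#' @param tx a coding TranscriptModel.
#' @return named numeric: \code{utr5_len}, \code{cds_len}, \code{utr3_len}
#'   (spliced lengths; the CDS start offset is \code{utr5_len}).
#' @export
splicedCdsOffsets <- function(tx) {
  if (!isCoding(tx)) stop(sprintf("transcript '%s' has no CDS", tx@id))
  c(utr5_len = sum(width(tx@utr5)), cds_len = sum(width(tx@cds)),
    utr3_len = sum(width(tx@utr3)))
}

# intron chain of a transcript as a two-column matrix (used by the splice
# classifier); empty matrix if single-exon
intronBounds <- function(tx) {
  it <- tx@introns
  cbind(start = it$start, end = it$end)
}
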