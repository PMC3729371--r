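# Per-genome gene-structure statistics and 5'-UTR intron profiling.

txHasUtr5Intron <- function(tx) any(tx@introns$region_class == "UTR5")
txHasUtr3Intron <- function(tx) any(tx@introns$region_class == "UTR3")

# representative transcript of a gene for scope = "representative_only":
# an explicit map wins; otherwise the longest transcript, ties broken by
# lexicographically smallest id
pickRepresentative <- function(gene, representatives = NULL) {
  txs <- transcriptModels(gene)
  if (!is.null(representatives) && gene@id %in% names(representatives)) {
    id <- representatives[[gene@id]]
    if (!id %in% names(txs))
      stop(sprintf("representative '%s' is not a transcript of gene '%s'",
                   id, gene@id))
    return(txs[[id]])
  }
  len <- vapply(txs, splicedLength, numeric(1))
  cand <- names(txs)[len == max(len)]
  txs[[sort(cand)[1L]]]
}

statRow <- function(statistic, measure, value)
  data.frame(statistic = statistic, measure = measure, value = value,
             stringsAsFactors = FALSE)

meanMedianRows <- function(statistic, x) {
  if (!length(x)) return(NULL)
  rbind(statRow(statistic, "mean", mean(x)),
        statRow(statistic, "median", stats::median(x)))
}

#' Per-genome gene structure summary
#'
#' Computes the standard per-genome structure statistics: counts of genes
#' and transcripts, mean and (interpolated) median of gene, transcript,
#' CDS, exon and intron lengths, exons/introns per gene, per-region UTR
#' exon/intron lengths and total UTR lengths, single- vs multi-exon
#' transcript fractions, UTR-presence counts, multi-exon 5'/3'-UTR
#' fractions (denominator: transcripts with that UTR), and -- when the
#' genome size is known -- gene density in kb per gene.
#'
#' With \code{scope = "representative_only"} all per-transcript statistics
#' are computed on one representative isoform per locus (an explicit
#' gene-to-transcript map, or the longest transcript); the default pools
#' over all transcripts.
#'
#' @param annotation a \linkS4class{GenomeAnnotation} with derived regions.
#' @param scope \code{"all_transcripts"} or \code{"representative_only"}.
#' @param representatives optional named character vector gene id ->
#'   transcript id, used when \code{scope = "representative_only"}.
#' @return long-format data.frame: \code{statistic}, \code{measure}
#'   (\code{mean}/\code{median}/\code{count}/\code{fraction}), \code{value}.
#' @export
genomeStructureSummary <- function(annotation,
                                   scope = c("all_transcripts",
                                             "representative_only"),
                                   representatives = NULL) {
  scope <- match.arg(scope)
  genes <- annotation@genes
  if (!length(genes)) stop("no genes in annotation")
  txs <- if (scope == "all_transcripts") transcriptModels(annotation)
         else lapply(genes, pickRepresentative, representatives = representatives)

  geneLen <- vapply(genes, function(g) {
    spans <- vapply(g@transcripts, function(tx)
      c(min(start(tx@exons)), max(end(tx@exons))), numeric(2))
    max(spans[2, ]) - min(spans[1, ]) + 1
  }, numeric(1))

  txLen <- vapply(txs, splicedLength, numeric(1))
  coding <- vapply(txs, isCoding, logical(1))
  cdsLen <- vapply(txs[coding], function(tx) sum(width(tx@cds)), numeric(1))
  exonLen <- unlist(lapply(txs, function(tx) width(tx@exons)), use.names = FALSE)
  intronLen <- unlist(lapply(txs, function(tx) tx@introns$width), use.names = FALSE)
  exPerTx <- vapply(txs, function(tx) length(tx@exons), numeric(1))

  u5ExonLen <- unlist(lapply(txs[coding], function(tx) width(tx@utr5)), use.names = FALSE)
  u3ExonLen <- unlist(lapply(txs[coding], function(tx) width(tx@utr3)), use.names = FALSE)
  u5IntronLen <- unlist(lapply(txs, function(tx)
    tx@introns$width[tx@introns$region_class == "UTR5"]), use.names = FALSE)
  u3IntronLen <- unlist(lapply(txs, function(tx)
    tx@introns$width[tx@introns$region_class == "UTR3"]), use.names = FALSE)
  u5Tot <- vapply(txs[coding], function(tx) sum(width(tx@utr5)), numeric(1))
  u3Tot <- vapply(txs[coding], function(tx) sum(width(tx@utr3)), numeric(1))
  hasU5 <- coding & vapply(txs, function(tx) sum(width(tx@utr5)) > 0, logical(1))
  hasU3 <- coding & vapply(txs, function(tx) sum(width(tx@utr3)) > 0, logical(1))

  nTx <- length(txs)
  multi <- sum(exPerTx > 1)
  multiU5 <- sum(hasU5 & vapply(txs, txHasUtr5Intron, logical(1)))
  multiU3 <- sum(hasU3 & vapply(txs, txHasUtr3Intron, logical(1)))

  out <- rbind(
    statRow("genes", "count", length(genes)),
    statRow("transcripts", "count", nTx),
    meanMedianRows("gene_length", geneLen),
    meanMedianRows("transcript_length", txLen),
    meanMedianRows("cds_length", cdsLen),
    meanMedianRows("exon_length", exonLen),
    meanMedianRows("intron_length", intronLen),
    meanMedianRows("exons_per_gene", exPerTx),
    meanMedianRows("introns_per_gene", exPerTx - 1),
    meanMedianRows("utr5_exon_length", u5ExonLen),
    meanMedianRows("utr5_intron_length", u5IntronLen),
    meanMedianRows("utr3_exon_length", u3ExonLen),
    meanMedianRows("utr3_intron_length", u3IntronLen),
    meanMedianRows("utr5_length", u5Tot[u5Tot > 0]),
    meanMedianRows("utr3_length", u3Tot[u3Tot > 0]),
    statRow("multi_exon_transcripts", "count", multi),
    statRow("multi_exon_transcripts", "fraction", multi / nTx),
    statRow("single_exon_transcripts", "count", nTx - multi),
    statRow("single_exon_transcripts", "fraction", (nTx - multi) / nTx),
    statRow("transcripts_with_both_utr", "count", sum(hasU5 & hasU3)),
    statRow("transcripts_with_utr5", "count", sum(hasU5)),
    statRow("transcripts_with_utr3", "count", sum(hasU3)),
    statRow("transcripts_without_utr", "count", sum(!hasU5 & !hasU3)),
    statRow("multi_exon_utr5", "count", multiU5),
    statRow("single_exon_utr5", "count", sum(hasU5) - multiU5),
    statRow("multi_exon_utr3", "count", multiU3),
    statRow("single_exon_utr3", "count", sum(hasU3) - multiU3)
  )
  if (sum(hasU5) > 0)
    out <- rbind(out,
      statRow("multi_exon_utr5", "fraction", multiU5 / sum(hasU5)),
      statRow("single_exon_utr5", "fraction", 1 - multiU5 / sum(hasU5)))
  if (sum(hasU3) > 0)
    out <- rbind(out,
      statRow("multi_exon_utr3", "fraction", multiU3 / sum(hasU3)),
      statRow("single_exon_utr3", "fraction", 1 - multiU3 / sum(hasU3)))
  if (!is.na(annotation@genomeSize))
    out <- rbind(out, statRow("gene_density_kb_per_gene", "value",
                              annotation@genomeSize / 1000 / length(genes)))
  rownames(out) <- NULL
  out
}

#' Gene density in kb per gene
#' @param genomeSizeBp genome size in base pairs.
#' @param nGenes number of protein-coding genes.
#' @return kb of genome per gene.
#' @export
geneDensity <- function(genomeSizeBp, nGenes) {
  if (nGenes <= 0) stop("no genes")
  genomeSizeBp / 1000 / nGenes
}

#' Fetch one value from a structure summary
#' @param stats result of [genomeStructureSummary()].
#' @param statistic,measure row selector.
#' @return the value (numeric scalar); error if absent.
#' @export
statValue <- function(stats, statistic, measure) {
  hit <- stats$statistic == statistic & stats$measure == measure
  if (sum(hit) != 1L)
    stop(sprintf("no unique row for (%s, %s)", statistic, measure))
  stats$value[hit]
}

#' Intron length profile by region class
#'
#' Pools intron lengths by region class (\code{UTR5}/\code{CDS}/\code{UTR3})
#' and reports, per class, the count, mean, median, and the fraction of
#' introns *strictly* longer than \code{threshold} (default 500 bp).
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param threshold length threshold in bp (strictly-greater convention).
#' @return list with \code{lengths} (list of numeric vectors per class) and
#'   \code{summary} (data.frame class/n/mean/median/frac_gt_threshold).
#' @export
intronLengthProfile <- function(annotation, threshold = 500) {
  it <- intronTable(annotation)
  classes <- c("UTR5", "CDS", "UTR3")
  lengths <- lapply(classes, function(cl) it$width[it$region_class == cl])
  names(lengths) <- classes
  summary <- do.call(rbind, lapply(classes, function(cl) {
    x <- lengths[[cl]]
    data.frame(class = cl, n = length(x),
               mean = if (length(x)) mean(x) else NA_real_,
               median = if (length(x)) stats::median(x) else NA_real_,
               frac_gt_threshold = if (length(x)) mean(x > threshold) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(lengths = lengths, summary = summary, threshold = threshold)
}

#' 5'-UTR intron number frequencies
#'
#' Distribution of the number of 5'-UTR introns per transcript, over the
#' transcripts that have a 5'-UTR (the denominator convention of the
#' multi-exon 5'-UTR fraction).
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @return data.frame \code{n_introns}/\code{count}/\code{fraction};
#'   attribute \code{"denominator"} holds the number of transcripts with a
#'   5'-UTR, and \code{"empty"} flags the no-5'-UTR case.
#' @export
utr5IntronCountFrequencies <- function(annotation) {
  txs <- transcriptModels(annotation)
  hasU5 <- vapply(txs, function(tx) sum(width(tx@utr5)) > 0, logical(1))
  if (!any(hasU5)) {
    out <- data.frame(n_introns = integer(0), count = integer(0),
                      fraction = numeric(0))
    attr(out, "denominator") <- 0L
    attr(out, "empty") <- TRUE
    return(out)
  }
  counts <- vapply(txs[hasU5], function(tx)
    sum(tx@introns$region_class == "UTR5"), integer(1))
  tab <- table(counts)
  out <- data.frame(n_introns = as.integer(names(tab)),
                    count = as.integer(tab),
                    fraction = as.integer(tab) / sum(hasU5))
  attr(out, "denominator") <- sum(hasU5)
  attr(out, "empty") <- FALSE
  out
}

#' Proximal 5'-UTR intron distances to ATG and TSS
#'
#' For every transcript with at least one 5'-UTR intron, selects the
#' intron with the smallest spliced distance to the first CDS base (the
#' proximal intron) and reports that distance (\code{distance_to_atg},
#' acceptor end to ATG) and the spliced distance from the transcript 5'
#' end to its donor end (\code{distance_to_tss}).  Distances are measured
#' in spliced coordinates: the functional 5'-UTR length is the spliced one.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param atgThreshold distances strictly below this value are counted in
#'   the \code{frac_atg_below} attribute (default 65 nt).
#' @return data.frame \code{transcript}/\code{distance_to_atg}/
#'   \code{distance_to_tss}; attribute \code{"frac_atg_below"}.
#' @export
proximalUtr5IntronDistances <- function(annotation, atgThreshold = 65) {
  txs <- transcriptModels(annotation)
  rows <- lapply(txs, function(tx) {
    if (!isCoding(tx)) return(NULL)
    it <- tx@introns[tx@introns$region_class == "UTR5", , drop = FALSE]
    if (!nrow(it)) return(NULL)
    u5 <- sum(width(tx@utr5))
    dAtg <- u5 - it$acceptor_offset
    k <- which.min(dAtg)
    data.frame(transcript = tx@id, distance_to_atg = dAtg[k],
               distance_to_tss = it$donor_offset[k], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript = character(0), distance_to_atg = numeric(0),
                      distance_to_tss = numeric(0))
  rownames(out) <- NULL
  attr(out, "frac_atg_below") <-
    if (nrow(out)) mean(out$distance_to_atg < atgThreshold) else NA_real_
  attr(out, "atg_threshold") <- atgThreshold
  out
}
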