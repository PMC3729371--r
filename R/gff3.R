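# GFF3 reading (via rtracklayer) and writing.

#' Read a GFF3 genome annotation
#'
#' Builds a \linkS4class{GenomeAnnotation} from the gene/mRNA/exon/CDS
#' features of a GFF3 file (1-based inclusive coordinates).  Features of
#' other types -- including any five_prime_UTR/three_prime_UTR lines --
#' are ignored; UTRs are re-derived from the exon/CDS geometry so that a
#' single convention governs all downstream statistics.
#'
#' @param path GFF3 file.
#' @param species species label stored in the annotation.
#' @param genomeSize genome size in bp (optional).
#' @param synthesizeGenes if TRUE, an mRNA without a gene parent gets a
#'   single-transcript gene synthesized around it; otherwise this is an
#'   error.
#' @param transcriptTypes feature types treated as transcripts.
#' @return a \linkS4class{GenomeAnnotation} with derived regions.
#' @export
readGFF3 <- function(path, species = "unknown", genomeSize = NA_real_,
                     synthesizeGenes = FALSE,
                     transcriptTypes = c("mRNA", "transcript")) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(mcols(gr)$type)
  id <- as.character(mcols(gr)$ID)
  parent <- mcols(gr)$Parent
  firstParent <- ifelse(elementNROWS(parent) > 0L,
                        vapply(parent, function(p)
                          if (length(p)) p[[1L]] else NA_character_,
                          character(1)), NA_character_)

  isGene <- type == "gene"
  isTx <- type %in% transcriptTypes
  geneStrand <- setNames(as.character(GenomicRanges::strand(gr))[isGene],
                         id[isGene])
  geneScaffold <- setNames(as.character(GenomicRanges::seqnames(gr))[isGene],
                           id[isGene])

  txIdx <- which(isTx)
  if (!length(txIdx)) stop("no transcript features found in ", path)
  txId <- id[txIdx]
  if (anyDuplicated(txId)) stop("duplicated transcript identifiers in ", path)
  txGene <- firstParent[txIdx]
  orphan <- is.na(txGene) | !(txGene %in% names(geneStrand))
  if (any(orphan)) {
    if (!synthesizeGenes)
      stop("mRNA without gene parent: ",
           paste(txId[orphan], collapse = ", "),
           " (set synthesizeGenes = TRUE to accept)")
    txGene[orphan] <- txId[orphan]
  }

  # collect exon/CDS children per transcript (a child may list several parents)
  childRows <- function(what) {
    idx <- which(type == what)
    if (!length(idx)) return(NULL)
    pl <- parent[idx]
    reps <- elementNROWS(pl)
    data.frame(parent = unlist(pl, use.names = FALSE),
               start = rep(GenomicRanges::start(gr)[idx], reps),
               end = rep(GenomicRanges::end(gr)[idx], reps),
               stringsAsFactors = FALSE)
  }
  exdf <- childRows("exon")
  cddf <- childRows("CDS")
  if (is.null(exdf)) stop("no exon features found in ", path)
  exByTx <- split(exdf[c("start", "end")], exdf$parent)
  cdByTx <- if (is.null(cddf)) list() else split(cddf[c("start", "end")], cddf$parent)

  txStrand <- as.character(GenomicRanges::strand(gr))[txIdx]
  txScaffold <- as.character(GenomicRanges::seqnames(gr))[txIdx]
  txs <- vector("list", length(txIdx))
  for (i in seq_along(txIdx)) {
    ex <- exByTx[[txId[i]]]
    if (is.null(ex))
      stop(sprintf("transcript '%s' has no exon features", txId[i]))
    cd <- cdByTx[[txId[i]]]
    txs[[i]] <- Transcript(txId[i], geneId = txGene[i],
                           scaffold = txScaffold[i], strand = txStrand[i],
                           exonStarts = ex$start, exonEnds = ex$end,
                           cdsStarts = if (is.null(cd)) integer(0) else cd$start,
                           cdsEnds = if (is.null(cd)) integer(0) else cd$end)
  }
  genes <- lapply(split(txs, txGene), function(ts) Gene(ts[[1L]]@geneId, ts))
  # keep file order of genes
  genes <- genes[unique(txGene)]
  Annotation(genes, species = species, genomeSize = genomeSize)
}

#' Write a GenomeAnnotation as GFF3
#'
#' Emits gene/mRNA/exon/CDS features only (the modeled feature set); UTRs
#' are derived on reading, so the read-write-read round trip is lossless.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeGFF3 <- function(annotation, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in annotation@genes) {
    spans <- vapply(g@transcripts, function(tx)
      c(min(start(tx@exons)), max(end(tx@exons))), numeric(2))
    writeLines(sprintf("%s\tstructome\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g@scaffold, min(spans[1, ]), max(spans[2, ]),
                       g@strand, g@id), con)
    for (tx in g@transcripts) {
      writeLines(sprintf("%s\tstructome\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                         tx@scaffold, min(start(tx@exons)), max(end(tx@exons)),
                         tx@strand, tx@id, g@id), con)
      writeLines(sprintf("%s\tstructome\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         tx@scaffold, start(tx@exons), end(tx@exons),
                         tx@strand, tx@id), con)
      if (length(tx@cds)) {
        cds <- tx@cds
        ord <- if (tx@strand == "+") order(start(cds)) else order(-start(cds))
        cum <- c(0L, cumsum(width(cds)[ord]))[seq_along(ord)]
        phase <- (3L - (cum %% 3L)) %% 3L
        writeLines(sprintf("%s\tstructome\tCDS\t%d\t%d\t.\t%s\t%d\tParent=%s",
                           tx@scaffold, start(cds)[ord], end(cds)[ord],
                           tx@strand, phase, tx@id), con)
      }
    }
  }
  invisible(path)
}
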