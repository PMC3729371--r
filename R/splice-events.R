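# Pairwise classification of alternative-splicing events and locus/genome
# summaries.
#
# Events are detected only inside the genomic overlap of the two
# transcripts, so plain TSS/poly-A variation produces no event.  Rule
# precedence (each intron/exon participates in one rule):
#   1. cassette exons: an exon of one transcript strictly inside an intron
#      of the other whose flanking introns share that intron's outer splice
#      sites -> retained_exon (exon carrier) + skipped_exon (partner);
#   2. retention: an intron of one strictly inside an exon of the other ->
#      retained_intron (exon carrier) + spliced_intron (intron carrier);
#   3. alternative donor/acceptor: two introns sharing exactly one splice
#      site (donor = transcript-5' end of the intron, strand-aware).  A
#      pair is skipped when either intron wholly contains a complete exon
#      of the partner -- that configuration is an exon-level event;
#   4. a transcript terminus strictly inside a partner intron ->
#      starts_in_intron / ends_in_intron;
#   5. residual: exons (clipped to the overlap window) matching no partner
#      exon and not adjacent to any event above -> alternate_exon.  A
#      mutually-exclusive exon pair therefore yields one alternate_exon
#      per unmatched exon.
# Containment is strict throughout: shared single-nucleotide boundaries do
# not count as "inside".

AS_EVENT_TYPES <- c("alt_acceptor", "alt_donor", "alternate_exon",
                    "ends_in_intron", "retained_exon", "retained_intron",
                    "skipped_exon", "spliced_intron", "starts_in_intron")

emptyEventFrame <- function()
  data.frame(type = character(0), carrier = character(0),
             partner = character(0), start = integer(0), end = integer(0),
             stringsAsFactors = FALSE)

eventRow <- function(type, carrier, partner, start, end)
  data.frame(type = type, carrier = carrier, partner = partner,
             start = as.integer(start), end = as.integer(end),
             stringsAsFactors = FALSE)

#' Classify alternative-splicing events between two isoforms
#'
#' Compares two transcripts of the same locus and returns the set of
#' events in the standard PASA-style taxonomy: \code{alt_acceptor},
#' \code{alt_donor}, \code{alternate_exon}, \code{ends_in_intron},
#' \code{retained_exon}, \code{retained_intron}, \code{skipped_exon},
#' \code{spliced_intron}, \code{starts_in_intron}.  Retention and cassette
#' events come in complementary pairs across the two transcripts.  Two
#' isoforms with identical intron chains inside their overlap yield no
#' events.
#'
#' @param a,b TranscriptModel objects on the same scaffold and strand.
#' @return data.frame with columns \code{type}, \code{carrier},
#'   \code{partner} (transcript ids) and the genomic \code{start},
#'   \code{end} of the affected feature.
#' @export
classifyPairwiseEvents <- function(a, b) {
  if (!identical(a@strand, b@strand))
    stop("transcripts are on different strands")
  if (!identical(a@scaffold, b@scaffold))
    stop("transcripts are on different scaffolds")
  strand <- a@strand
  exA <- cbind(start(a@exons), end(a@exons))
  exB <- cbind(start(b@exons), end(b@exons))
  inA <- intronBounds(a)
  inB <- intronBounds(b)
  w1 <- max(exA[1, 1], exB[1, 1])
  w2 <- min(exA[nrow(exA), 2], exB[nrow(exB), 2])
  if (w1 > w2) return(emptyEventFrame())

  within <- function(m) m[m[, 1] >= w1 & m[, 2] <= w2, , drop = FALSE]
  inAw <- within(inA); inBw <- within(inB)

  events <- list()
  consumedA <- rep(FALSE, nrow(inAw))
  consumedB <- rep(FALSE, nrow(inBw))
  usedExon <- list()   # exons already explained by an exon-level rule

  hasIntron <- function(m, s, e) any(m[, 1] == s & m[, 2] == e)
  strictlyInside <- function(s, e, S, E) S < s && e < E

  # -- rule 1: cassette exons ------------------------------------------------
  cassette <- function(exCar, inCar, carId, inPartner, partnerId) {
    out <- list()
    for (j in seq_len(nrow(inPartner))) {
      S <- inPartner[j, 1]; E <- inPartner[j, 2]
      for (i in seq_len(nrow(exCar))) {
        s <- exCar[i, 1]; e <- exCar[i, 2]
        if (strictlyInside(s, e, S, E) &&
            hasIntron(inCar, S, s - 1L) && hasIntron(inCar, e + 1L, E)) {
          out[[length(out) + 1L]] <- rbind(
            eventRow("retained_exon", carId, partnerId, s, e),
            eventRow("skipped_exon", partnerId, carId, s, e))
        }
      }
    }
    out
  }
  casA <- cassette(exA, inA, a@id, inB, b@id)
  casB <- cassette(exB, inB, b@id, inA, a@id)
  events <- c(events, casA, casB)
  # the containing intron and its flanks overlap/abut the cassette exon, so
  # an interval test is enough to consume them for rule 3
  cassetteIv <- do.call(rbind, lapply(c(casA, casB), function(ev)
    c(ev$start[1L], ev$end[1L])))

  intronTouchesCassette <- function(s, e) {
    if (is.null(cassetteIv)) return(FALSE)
    any(s <= cassetteIv[, 2] + 1L & e >= cassetteIv[, 1] - 1L)
  }

  # -- rule 2: intron retention ---------------------------------------------
  retention <- function(inCarW, carId, exPartner, partnerId) {
    out <- list(); cons <- rep(FALSE, nrow(inCarW))
    for (i in seq_len(nrow(inCarW))) {
      s <- inCarW[i, 1]; e <- inCarW[i, 2]
      for (j in seq_len(nrow(exPartner))) {
        if (strictlyInside(s, e, exPartner[j, 1], exPartner[j, 2])) {
          out[[length(out) + 1L]] <- rbind(
            eventRow("retained_intron", partnerId, carId, s, e),
            eventRow("spliced_intron", carId, partnerId, s, e))
          cons[i] <- TRUE
        }
      }
    }
    list(events = out, consumed = cons)
  }
  retA <- retention(inAw, a@id, exB, b@id)
  retB <- retention(inBw, b@id, exA, a@id)
  events <- c(events, retA$events, retB$events)
  consumedA <- consumedA | retA$consumed
  consumedB <- consumedB | retB$consumed

  # -- rule 3: alternative donor / acceptor ---------------------------------
  containsCompleteExon <- function(s, e, exons) {
    any(exons[, 1] > s & exons[, 2] < e)
  }
  donorEnd <- if (strand == "+") 1L else 2L
  acceptorEnd <- if (strand == "+") 2L else 1L
  for (i in seq_len(nrow(inAw))) {
    if (consumedA[i] || intronTouchesCassette(inAw[i, 1], inAw[i, 2])) next
    for (j in seq_len(nrow(inBw))) {
      if (consumedB[j] || intronTouchesCassette(inBw[j, 1], inBw[j, 2])) next
      sA <- inAw[i, ]; sB <- inBw[j, ]
      if (sA[1] == sB[1] && sA[2] == sB[2]) next
      sharedDonor <- sA[donorEnd] == sB[donorEnd]
      sharedAcceptor <- sA[acceptorEnd] == sB[acceptorEnd]
      if (xor(sharedDonor, sharedAcceptor)) {
        if (containsCompleteExon(sA[1], sA[2], exB) ||
            containsCompleteExon(sB[1], sB[2], exA)) next
        carrier <- if ((sA[2] - sA[1]) >= (sB[2] - sB[1])) a@id else b@id
        partner <- if (carrier == a@id) b@id else a@id
        events[[length(events) + 1L]] <- eventRow(
          if (sharedDonor) "alt_acceptor" else "alt_donor",
          carrier, partner, min(sA[1], sB[1]), max(sA[2], sB[2]))
      }
    }
  }

  # -- rule 4: termini inside partner introns -------------------------------
  termini <- function(exSelf, selfId, inPartner, partnerId) {
    out <- list()
    span <- c(exSelf[1, 1], exSelf[nrow(exSelf), 2])
    p5 <- if (strand == "+") span[1] else span[2]
    p3 <- if (strand == "+") span[2] else span[1]
    for (j in seq_len(nrow(inPartner))) {
      S <- inPartner[j, 1]; E <- inPartner[j, 2]
      if (S < p5 && p5 < E)
        out[[length(out) + 1L]] <- eventRow("starts_in_intron", selfId,
                                            partnerId, S, E)
      if (S < p3 && p3 < E)
        out[[length(out) + 1L]] <- eventRow("ends_in_intron", selfId,
                                            partnerId, S, E)
    }
    out
  }
  events <- c(events, termini(exA, a@id, inB, b@id), termini(exB, b@id, inA, a@id))

  # -- rule 5: residual alternate exons -------------------------------------
  evFrame <- if (length(events)) do.call(rbind, events) else emptyEventFrame()
  clip <- function(m) {
    s <- pmax(m[, 1], w1); e <- pmin(m[, 2], w2)
    keep <- s <= e
    cbind(s[keep], e[keep])
  }
  cA <- clip(exA); cB <- clip(exB)
  explained <- function(s, e) {
    nrow(evFrame) > 0L && any(s <= evFrame$end + 1L & e >= evFrame$start - 1L)
  }
  residual <- function(cSelf, cOther, selfId, otherId) {
    out <- list()
    for (i in seq_len(nrow(cSelf))) {
      s <- cSelf[i, 1]; e <- cSelf[i, 2]
      if (any(cOther[, 1] == s & cOther[, 2] == e)) next
      if (explained(s, e)) next
      out[[length(out) + 1L]] <- eventRow("alternate_exon", selfId, otherId, s, e)
    }
    out
  }
  alt <- c(residual(cA, cB, a@id, b@id), residual(cB, cA, b@id, a@id))
  out <- rbind(evFrame, if (length(alt)) do.call(rbind, alt) else NULL)
  rownames(out) <- NULL
  unique(out)
}

exonChainKey <- function(tx)
  paste(start(tx@exons), end(tx@exons), sep = "-", collapse = ";")

cdsChainKey <- function(tx)
  paste(start(tx@cds), end(tx@cds), sep = "-", collapse = ";")

#' Locus-level splicing report
#'
#' Classifies every unordered pair of isoforms of a gene and summarizes:
#' whether the locus is alternatively spliced (>= 2 structurally distinct
#' isoforms), per-type locus-level presence, transcript-level event counts,
#' the number of distinct proteins (distinct CDS interval chains), and the
#' splicing effect: \code{CDS_altering}, \code{UTR_only}, \code{both} or
#' \code{none}.  An event is UTR-located when its interval overlaps a UTR
#' of the pair but none of their CDS segments.
#'
#' @param gene a \linkS4class{GeneModel}.
#' @return list: \code{locus}, \code{is_AS}, \code{effect},
#'   \code{distinct_proteins}, \code{events} (data.frame),
#'   \code{type_present} (named logical), \code{transcript_event_counts}.
#' @export
locusSplicingReport <- function(gene) {
  txs <- gene@transcripts
  chains <- vapply(txs, exonChainKey, character(1))
  isAS <- length(unique(chains)) >= 2L
  events <- emptyEventFrame()
  utrEvent <- FALSE
  if (isAS && length(txs) >= 2L) {
    for (i in seq_len(length(txs) - 1L)) for (j in seq(i + 1L, length(txs))) {
      ev <- classifyPairwiseEvents(txs[[i]], txs[[j]])
      if (nrow(ev)) {
        events <- rbind(events, ev)
        cds <- rbind(cbind(start(txs[[i]]@cds), end(txs[[i]]@cds)),
                     cbind(start(txs[[j]]@cds), end(txs[[j]]@cds)))
        utrs <- rbind(cbind(start(txs[[i]]@utr5), end(txs[[i]]@utr5)),
                      cbind(start(txs[[i]]@utr3), end(txs[[i]]@utr3)),
                      cbind(start(txs[[j]]@utr5), end(txs[[j]]@utr5)),
                      cbind(start(txs[[j]]@utr3), end(txs[[j]]@utr3)))
        ovl <- function(m, s, e)
          !is.null(m) && nrow(m) > 0L && any(s <= m[, 2] & e >= m[, 1])
        for (k in seq_len(nrow(ev)))
          if (ovl(utrs, ev$start[k], ev$end[k]) &&
              !ovl(cds, ev$start[k], ev$end[k])) utrEvent <- TRUE
      }
    }
    events <- unique(events)
  }
  coding <- vapply(txs, isCoding, logical(1))
  nProteins <- length(unique(vapply(txs[coding], cdsChainKey, character(1))))
  cdsAltering <- nProteins > 1L
  effect <- if (!isAS) "none"
    else if (cdsAltering && utrEvent) "both"
    else if (cdsAltering) "CDS_altering"
    else "UTR_only"
  present <- vapply(AS_EVENT_TYPES, function(t) t %in% events$type, logical(1))
  txCounts <- if (nrow(events))
    table(factor(events$type, levels = AS_EVENT_TYPES),
          factor(events$carrier, levels = vapply(txs, function(t) t@id,
                                                 character(1))))
  else NULL
  list(locus = gene@id, is_AS = isAS, effect = effect,
       distinct_proteins = nProteins, events = events,
       type_present = present, transcript_event_counts = txCounts)
}

#' Genome-wide alternative-splicing summary
#'
#' Aggregates [locusSplicingReport()] over all loci: per-type counts at
#' transcript granularity (carrier transcripts of at least one event of
#' the type) and locus granularity, the AS fraction (AS loci / all loci),
#' and the CDS-altering / UTR-only breakdown.
#'
#' @param annotation a \linkS4class{GenomeAnnotation}.
#' @return list: \code{per_type} (data.frame type / n_transcripts /
#'   n_loci), \code{n_loci}, \code{n_as_loci}, \code{as_fraction},
#'   \code{effects} (table), \code{reports} (list of locus reports).
#' @export
genomeASSummary <- function(annotation) {
  reports <- lapply(annotation@genes, locusSplicingReport)
  nLoci <- length(reports)
  asLoci <- vapply(reports, function(r) r$is_AS, logical(1))
  perType <- do.call(rbind, lapply(AS_EVENT_TYPES, function(t) {
    nL <- sum(vapply(reports, function(r) r$type_present[[t]], logical(1)))
    nT <- sum(vapply(reports, function(r)
      length(unique(r$events$carrier[r$events$type == t])), integer(1)))
    data.frame(type = t, n_transcripts = nT, n_loci = nL,
               stringsAsFactors = FALSE)
  }))
  effects <- table(factor(vapply(reports, function(r) r$effect, character(1)),
                          levels = c("none", "UTR_only", "CDS_altering", "both")))
  list(per_type = perType, n_loci = nLoci, n_as_loci = sum(asLoci),
       as_fraction = sum(asLoci) / nLoci, effects = effects,
       reports = reports)
}
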