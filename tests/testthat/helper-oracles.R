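# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the package's code paths: region geometry is
# computed from explicit position sets, the splice classifier enumerates
# every containment relation with plain loops, and Wright's formula is
# evaluated directly from codon counts.

# region lengths and intron classes from explicit exonic position sets
oracleRegions <- function(exS, exE, cdS = integer(0), cdE = integer(0),
                          strand = "+") {
  ord <- order(exS)
  exS <- exS[ord]; exE <- exE[ord]
  pos <- unlist(mapply(seq, exS, exE, SIMPLIFY = FALSE))
  if (strand == "-") pos <- rev(pos)      # transcript orientation
  cdsPos <- if (length(cdS))
    intersect(pos, unlist(mapply(seq, cdS, cdE, SIMPLIFY = FALSE)))
  else integer(0)
  if (length(cdsPos)) {
    u5 <- min(match(cdsPos, pos)) - 1L
    cdsLen <- length(cdsPos)
    u3 <- length(pos) - u5 - cdsLen
  } else {
    u5 <- 0L; cdsLen <- 0L; u3 <- 0L
  }
  n <- length(exS)
  introns <- if (n > 1L)
    data.frame(start = exE[-n] + 1L, end = exS[-1L] - 1L)
  else data.frame(start = integer(0), end = integer(0))
  if (nrow(introns)) {
    # transcript positions 5' of each intron, counted from the raw
    # exonic position set
    b <- vapply(seq_len(nrow(introns)), function(i) {
      if (strand == "+") sum(unlist(mapply(seq, exS, exE, SIMPLIFY = FALSE)) <
                               introns$start[i])
      else sum(unlist(mapply(seq, exS, exE, SIMPLIFY = FALSE)) >
                 introns$end[i])
    }, integer(1))
    cls <- rep("CDS", length(b))
    if (length(cdsPos)) {
      cls[b <= u5] <- "UTR5"
      cls[b >= u5 + cdsLen] <- "UTR3"
    }
    introns$b <- b
    introns$class <- cls
    introns$width <- introns$end - introns$start + 1L
  }
  list(utr5 = u5, cds = cdsLen, utr3 = u3, spliced = length(pos),
       introns = introns)
}

# naive re-computation of the key structure-summary fields by full
# enumeration over a small annotation
naiveStructStats <- function(ann) {
  txLen <- c(); cdsLen <- c(); exonLen <- c(); intronLen <- c()
  exPerTx <- c(); u5i <- c(); u3i <- c(); hasU5 <- c(); hasU3 <- c()
  multiU5 <- 0L
  for (g in geneModels(ann)) for (tx in transcriptModels(g)) {
    exS <- IRanges::start(exonRanges(tx)); exE <- IRanges::end(exonRanges(tx))
    cdS <- IRanges::start(cdsRanges(tx)); cdE <- IRanges::end(cdsRanges(tx))
    r <- oracleRegions(exS, exE, cdS, cdE, tx@strand)
    txLen <- c(txLen, r$spliced)
    exonLen <- c(exonLen, exE - exS + 1)
    exPerTx <- c(exPerTx, length(exS))
    if (nrow(r$introns)) {
      intronLen <- c(intronLen, r$introns$width)
      u5i <- c(u5i, r$introns$width[r$introns$class == "UTR5"])
      u3i <- c(u3i, r$introns$width[r$introns$class == "UTR3"])
    }
    if (length(cdS)) {
      cdsLen <- c(cdsLen, r$cds)
      hasU5 <- c(hasU5, r$utr5 > 0); hasU3 <- c(hasU3, r$utr3 > 0)
      if (r$utr5 > 0 && any(r$introns$class == "UTR5")) multiU5 <- multiU5 + 1L
    } else {
      hasU5 <- c(hasU5, FALSE); hasU3 <- c(hasU3, FALSE)
    }
  }
  list(n_tx = length(txLen), mean_tx_len = mean(txLen),
       median_tx_len = stats::median(txLen),
       mean_cds_len = mean(cdsLen), mean_exon_len = mean(exonLen),
       mean_intron_len = if (length(intronLen)) mean(intronLen) else NA,
       mean_exons = mean(exPerTx),
       n_single_exon = sum(exPerTx == 1),
       n_with_u5 = sum(hasU5), n_with_u3 = sum(hasU3),
       n_multi_u5 = multiU5,
       mean_u5_intron = if (length(u5i)) mean(u5i) else NA,
       mean_u3_intron = if (length(u3i)) mean(u3i) else NA)
}

# independent splice-event classifier: enumerates every splice-site /
# containment relation with plain loops over raw coordinate matrices
bruteClassify <- function(exA, exB, strand = "+", idA = "A", idB = "B") {
  intronsOf <- function(m) {
    n <- nrow(m)
    if (n < 2L) matrix(integer(0), ncol = 2)
    else cbind(m[-n, 2] + 1L, m[-1L, 1] - 1L)
  }
  inA <- intronsOf(exA); inB <- intronsOf(exB)
  w1 <- max(exA[1, 1], exB[1, 1])
  w2 <- min(exA[nrow(exA), 2], exB[nrow(exB), 2])
  ev <- list()
  add <- function(type, car, par, s, e)
    ev[[length(ev) + 1L]] <<- data.frame(type = type, carrier = car,
                                         partner = par, start = s, end = e,
                                         stringsAsFactors = FALSE)
  if (w1 > w2) return(do.call(rbind, ev))
  inW <- function(m) m[m[, 1] >= w1 & m[, 2] <= w2, , drop = FALSE]
  iAw <- inW(inA); iBw <- inW(inB)
  has <- function(m, s, e) nrow(m) > 0 && any(m[, 1] == s & m[, 2] == e)

  # cassettes
  cassIv <- NULL
  for (side in 1:2) {
    exX <- if (side == 1) exA else exB; inX <- if (side == 1) inA else inB
    inY <- if (side == 1) inB else inA
    idX <- if (side == 1) idA else idB; idY <- if (side == 1) idB else idA
    for (i in seq_len(nrow(exX))) for (j in seq_len(nrow(inY))) {
      s <- exX[i, 1]; e <- exX[i, 2]; S <- inY[j, 1]; E <- inY[j, 2]
      if (S < s && e < E && has(inX, S, s - 1L) && has(inX, e + 1L, E)) {
        add("retained_exon", idX, idY, s, e)
        add("skipped_exon", idY, idX, s, e)
        cassIv <- rbind(cassIv, c(s, e))
      }
    }
  }
  touchesCass <- function(s, e)
    !is.null(cassIv) && any(s <= cassIv[, 2] + 1L & e >= cassIv[, 1] - 1L)

  # retention
  retA <- rep(FALSE, nrow(iAw)); retB <- rep(FALSE, nrow(iBw))
  for (side in 1:2) {
    iX <- if (side == 1) iAw else iBw; exY <- if (side == 1) exB else exA
    idX <- if (side == 1) idA else idB; idY <- if (side == 1) idB else idA
    for (i in seq_len(nrow(iX))) for (j in seq_len(nrow(exY)))
      if (exY[j, 1] < iX[i, 1] && iX[i, 2] < exY[j, 2]) {
        add("retained_intron", idY, idX, iX[i, 1], iX[i, 2])
        add("spliced_intron", idX, idY, iX[i, 1], iX[i, 2])
        if (side == 1) retA[i] <- TRUE else retB[i] <- TRUE
      }
  }

  # alternative donor / acceptor
  dEnd <- if (strand == "+") 1L else 2L
  aEnd <- if (strand == "+") 2L else 1L
  containsExon <- function(s, e, m) any(m[, 1] > s & m[, 2] < e)
  for (i in seq_len(nrow(iAw))) for (j in seq_len(nrow(iBw))) {
    if (retA[i] || retB[j]) next
    if (touchesCass(iAw[i, 1], iAw[i, 2]) ||
        touchesCass(iBw[j, 1], iBw[j, 2])) next
    if (iAw[i, 1] == iBw[j, 1] && iAw[i, 2] == iBw[j, 2]) next
    sd <- iAw[i, dEnd] == iBw[j, dEnd]; sa <- iAw[i, aEnd] == iBw[j, aEnd]
    if (sd == sa) next
    if (containsExon(iAw[i, 1], iAw[i, 2], exB) ||
        containsExon(iBw[j, 1], iBw[j, 2], exA)) next
    lenA <- iAw[i, 2] - iAw[i, 1]; lenB <- iBw[j, 2] - iBw[j, 1]
    car <- if (lenA >= lenB) idA else idB
    add(if (sd) "alt_acceptor" else "alt_donor", car,
        if (car == idA) idB else idA,
        min(iAw[i, 1], iBw[j, 1]), max(iAw[i, 2], iBw[j, 2]))
  }

  # termini inside partner introns
  for (side in 1:2) {
    exX <- if (side == 1) exA else exB; inY <- if (side == 1) inB else inA
    idX <- if (side == 1) idA else idB; idY <- if (side == 1) idB else idA
    lo <- exX[1, 1]; hi <- exX[nrow(exX), 2]
    p5 <- if (strand == "+") lo else hi
    p3 <- if (strand == "+") hi else lo
    for (j in seq_len(nrow(inY))) {
      if (inY[j, 1] < p5 && p5 < inY[j, 2])
        add("starts_in_intron", idX, idY, inY[j, 1], inY[j, 2])
      if (inY[j, 1] < p3 && p3 < inY[j, 2])
        add("ends_in_intron", idX, idY, inY[j, 1], inY[j, 2])
    }
  }

  # residual alternate exons within the overlap window
  evf <- do.call(rbind, ev)
  clip <- function(m) {
    s <- pmax(m[, 1], w1); e <- pmin(m[, 2], w2)
    cbind(s, e)[s <= e, , drop = FALSE]
  }
  cA <- clip(exA); cB <- clip(exB)
  expl <- function(s, e)
    !is.null(evf) && any(s <= evf$end + 1L & e >= evf$start - 1L)
  for (side in 1:2) {
    cX <- if (side == 1) cA else cB; cY <- if (side == 1) cB else cA
    idX <- if (side == 1) idA else idB; idY <- if (side == 1) idB else idA
    for (i in seq_len(nrow(cX))) {
      s <- cX[i, 1]; e <- cX[i, 2]
      if (any(cY[, 1] == s & cY[, 2] == e)) next
      if (expl(s, e)) next
      add("alternate_exon", idX, idY, s, e)
    }
  }
  out <- unique(do.call(rbind, ev))
  if (is.null(out)) return(NULL)
  out[order(out$type, out$carrier, out$start), ]
}

# random exon chain on a 10-bp grid (shared grid provokes shared splice
# sites between the two isoforms of a locus)
randomExonChain <- function(maxExons = 6L) {
  k <- sample.int(maxExons, 1L)
  p <- sort(sample(seq(10L, 600L, by = 10L), 2L * k))
  cbind(p[seq(1L, 2L * k, by = 2L)], p[seq(2L, 2L * k, by = 2L)] - 1L)
}

# direct evaluation of Wright's estimator from a codon vector
bruteENC <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  keep <- !is.na(aa) & !(aa %in% c("*", "M", "W"))
  codons <- codons[keep]; aa <- aa[keep]
  deg <- table(gc[gc != "*"])
  deg <- deg[!names(deg) %in% c("M", "W")]
  Fbar <- sapply(c(2, 3, 4, 6), function(k) {
    fs <- c()
    for (a in names(deg)[deg == k]) {
      cnt <- table(codons[aa == a]); n <- sum(cnt)
      if (n >= 2) {
        f <- (n * sum((as.numeric(cnt) / n)^2) - 1) / (n - 1)
        if (f > 0) fs <- c(fs, f)
      }
    }
    if (length(fs)) mean(fs) else NA_real_
  })
  if (is.na(Fbar[2]) && !is.na(Fbar[1]) && !is.na(Fbar[3]))
    Fbar[2] <- (Fbar[1] + Fbar[3]) / 2
  if (anyNA(Fbar[c(1, 3, 4)]) || is.na(Fbar[2])) return(NA_real_)
  min(61, 2 + 9 / Fbar[1] + 1 / Fbar[2] + 5 / Fbar[3] + 3 / Fbar[4])
}

sortedEvents <- function(ev) {
  if (is.null(ev) || !nrow(ev))
    return(data.frame(type = character(0), carrier = character(0),
                      start = integer(0), end = integer(0)))
  out <- ev[order(ev$type, ev$carrier, ev$start, ev$end),
            c("type", "carrier", "start", "end")]
  rownames(out) <- NULL
  out
}
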