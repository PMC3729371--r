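# Seeded synthetic-data generators with planted ground truth.
#
# Planted quantities that downstream tests assert exactly (AS locus
# counts, intron-loss calls, expansions, enriched terms) are constructed,
# not sampled; sampled quantities (lengths, exon counts) converge to their
# targets and are asserted with CLT tolerances.  Genomic sequence is never
# emitted; coordinates are self-consistent without it.

# random composition of total into m parts, each >= minPart
randomComposition <- function(total, m, minPart = 1L) {
  total <- as.integer(total); m <- as.integer(m)
  if (total < m * minPart) total <- m * minPart
  extra <- as.integer(stats::rmultinom(1L, total - m * minPart, rep(1, m)))
  minPart + extra
}

rlnormMean <- function(n, meanTarget, sdlog = 0.6)
  pmax(1L, as.integer(round(stats::rlnorm(n, log(meanTarget) - sdlog^2 / 2,
                                          sdlog))))

#' Simulate a genome annotation with planted ground truth
#'
#' Generates a structurally valid \linkS4class{GenomeAnnotation} (and
#' optionally its GFF3 file) whose realized distributions converge to the
#' configured targets.  Defaults emulate a moss-like gene complement:
#' exon-count mean 5, region-specific lognormal intron lengths with means
#' 520 (5'-UTR) / 264 (CDS) / 268 (3'-UTR) bp, 5'-/3'-UTR presence
#' probabilities 0.47 / 0.50, and mean 5'-UTR intron count such that
#' ~39\% of transcripts with a 5'-UTR carry an intron there.  A planted
#' fraction of loci (constructed exactly, not sampled) carries a second
#' isoform exhibiting one alternative-splicing event type.
#'
#' @param nGenes number of loci.
#' @param seed RNG seed (set for byte-identical reruns).
#' @param exonMean target mean exons per transcript.
#' @param intronMeanBp named numeric: target mean intron length per region
#'   class (\code{UTR5}, \code{CDS}, \code{UTR3}).
#' @param intronSdLog lognormal sdlog of intron lengths.
#' @param utr5Prob,utr3Prob probability a transcript has that UTR.
#' @param utr5IntronMean,utr3IntronMean Poisson mean of UTR intron counts
#'   (given the UTR is present).
#' @param utr5MeanBp,cdsMeanBp,utr3MeanBp target spliced region lengths.
#' @param asFraction fraction of loci planted with an AS isoform (exact
#'   count \code{round(asFraction * nGenes)}).
#' @param asEventMix event types cycled over the planted AS loci.
#' @param genomeSize genome size in bp stored in the annotation.
#' @param genesPerScaffold layout parameter.
#' @param gff3Path if non-NULL, the annotation is also written there.
#' @return list: \code{annotation}, \code{truth} (per-gene data.frame with
#'   planted attributes), \code{path} (or NULL).
#' @export
simulateGenome <- function(nGenes = 2000, seed = NULL, exonMean = 5,
                           intronMeanBp = c(UTR5 = 520, CDS = 264, UTR3 = 268),
                           intronSdLog = 0.6,
                           utr5Prob = 0.47, utr3Prob = 0.50,
                           utr5IntronMean = 0.5, utr3IntronMean = 0.076,
                           utr5MeanBp = 307, cdsMeanBp = 1062,
                           utr3MeanBp = 367,
                           asFraction = 0, asEventMix = AS_EVENT_TYPES,
                           genomeSize = NA_real_, genesPerScaffold = 50,
                           gff3Path = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cdsIntronMean <- exonMean - 1 - utr5Prob * utr5IntronMean -
    utr3Prob * utr3IntronMean
  if (cdsIntronMean < 0) stop("infeasible config: exonMean too small")
  nAS <- round(asFraction * nGenes)
  if (nAS > nGenes) stop("asFraction > 1")
  asTypes <- if (nAS) rep_len(asEventMix, nAS) else character(0)
  if (nAS && !all(asTypes %in% AS_EVENT_TYPES))
    stop("unknown AS event type in asEventMix")

  genes <- vector("list", nGenes)
  truth <- vector("list", nGenes)
  offset <- 0L; scaffoldNo <- 1L; onScaffold <- 0L
  for (i in seq_len(nGenes)) {
    id <- sprintf("g%05d", i)
    scaffold <- sprintf("scaffold_%04d", scaffoldNo)
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    if (i <= nAS) {
      g <- generateASLocus(asTypes[i], id = id, scaffold = scaffold,
                           offset = offset, strand = strand)
      spanLen <- max(vapply(g@transcripts, function(tx) max(end(tx@exons)),
                            numeric(1))) - offset
      truth[[i]] <- data.frame(gene = id, as_type = asTypes[i],
                               n_exons = NA_integer_,
                               n_utr5_introns = NA_integer_,
                               n_cds_introns = NA_integer_,
                               n_utr3_introns = NA_integer_,
                               utr5_len = NA_integer_, cds_len = NA_integer_,
                               utr3_len = NA_integer_,
                               stringsAsFactors = FALSE)
    } else {
      has5 <- stats::runif(1) < utr5Prob
      has3 <- stats::runif(1) < utr3Prob
      j5 <- if (has5) stats::rpois(1, utr5IntronMean) else 0L
      j3 <- if (has3) stats::rpois(1, utr3IntronMean) else 0L
      jc <- stats::rpois(1, cdsIntronMean)
      u5 <- if (has5) max(rlnormMean(1, utr5MeanBp, 0.5), (j5 + 1L) * 10L) else 0L
      u3 <- if (has3) max(rlnormMean(1, utr3MeanBp, 0.5), (j3 + 1L) * 10L) else 0L
      Lc <- 3L * max(rlnormMean(1, cdsMeanBp, 0.5) %/% 3L, jc + 1L, 30L)
      # spliced intron offsets: partitions keep every intron strictly
      # inside its region
      b5 <- if (j5) cumsum(randomComposition(u5, j5 + 1L, 5L))[seq_len(j5)]
            else integer(0)
      bc <- if (jc) u5 + cumsum(randomComposition(Lc, jc + 1L, 3L))[seq_len(jc)]
            else integer(0)
      b3 <- if (j3) u5 + Lc +
              cumsum(randomComposition(u3, j3 + 1L, 5L))[seq_len(j3)]
            else integer(0)
      bounds <- c(0L, b5, bc, b3, u5 + Lc + u3)
      exonW <- diff(bounds)
      cls <- c(rep("UTR5", j5), rep("CDS", jc), rep("UTR3", j3))
      intronW <- if (length(cls))
        pmax(20L, rlnormMean(length(cls), unname(intronMeanBp[cls]),
                             intronSdLog))
      else integer(0)
      # plus-orientation layout, then mirror for minus strand
      exStart <- offset + 1L +
        c(0L, cumsum(exonW[-length(exonW)] + intronW))
      exEnd <- exStart + exonW - 1L
      cdsStart <- exonicShift(exStart, exEnd, u5 + 1L)
      cdsEnd <- exonicShift(exStart, exEnd, u5 + Lc)
      cdsIv <- clipToExons(exStart, exEnd, cdsStart, cdsEnd)
      if (strand == "-") {
        L <- max(exEnd) + min(exStart)  # mirror within the span
        mir <- function(s, e) list(start = L - e, end = L - s)
        ex <- mir(exStart, exEnd)
        cd <- mir(cdsIv$start, cdsIv$end)
        exStart <- rev(ex$start); exEnd <- rev(ex$end)
        cdsIv <- list(start = rev(cd$start), end = rev(cd$end))
      }
      tx <- Transcript(paste0(id, ".1"), geneId = id, scaffold = scaffold,
                       strand = strand, exonStarts = exStart,
                       exonEnds = exEnd, cdsStarts = cdsIv$start,
                       cdsEnds = cdsIv$end)
      g <- Gene(id, tx)
      spanLen <- max(exEnd) - offset
      truth[[i]] <- data.frame(gene = id, as_type = NA_character_,
                               n_exons = length(exonW),
                               n_utr5_introns = j5, n_cds_introns = jc,
                               n_utr3_introns = j3,
                               utr5_len = u5, cds_len = Lc, utr3_len = u3,
                               stringsAsFactors = FALSE)
    }
    genes[[i]] <- g
    offset <- offset + spanLen + 500L
    onScaffold <- onScaffold + 1L
    if (onScaffold >= genesPerScaffold) {
      onScaffold <- 0L; scaffoldNo <- scaffoldNo + 1L; offset <- 0L
    }
  }
  ann <- Annotation(genes, species = "synthetic", genomeSize = genomeSize)
  truth <- do.call(rbind, truth)
  path <- NULL
  if (!is.null(gff3Path)) path <- writeGFF3(ann, gff3Path)
  list(annotation = ann, truth = truth, path = path)
}

# spliced offset k (1-based) -> genomic position, given plus-orientation
# exon layout
exonicShift <- function(exStart, exEnd, k) {
  w <- exEnd - exStart + 1L
  cum <- cumsum(w)
  idx <- which(cum >= k)[1L]
  before <- if (idx > 1L) cum[idx - 1L] else 0L
  exStart[idx] + (k - before) - 1L
}

clipToExons <- function(exStart, exEnd, s, e) {
  cs <- pmax(exStart, s); ce <- pmin(exEnd, e)
  keep <- cs <= ce
  list(start = cs[keep], end = ce[keep])
}

# fixed two-isoform templates, one per event type, in plus-orientation
# relative coordinates; verified closed-loop against the classifier
asTemplates <- list(
  alt_acceptor    = list(a = rbind(c(1, 100), c(201, 400)),
                         b = rbind(c(1, 100), c(231, 400))),
  alt_donor       = list(a = rbind(c(1, 100), c(201, 400)),
                         b = rbind(c(1, 130), c(201, 400))),
  retained_intron = list(a = rbind(c(1, 400)),
                         b = rbind(c(1, 100), c(201, 400))),
  spliced_intron  = list(a = rbind(c(1, 100), c(201, 400)),
                         b = rbind(c(1, 400))),
  skipped_exon    = list(a = rbind(c(1, 100), c(401, 500)),
                         b = rbind(c(1, 100), c(201, 300), c(401, 500))),
  retained_exon   = list(a = rbind(c(1, 100), c(201, 300), c(401, 500)),
                         b = rbind(c(1, 100), c(401, 500))),
  alternate_exon  = list(a = rbind(c(1, 100), c(201, 260), c(401, 500)),
                         b = rbind(c(1, 100), c(301, 360), c(401, 500))),
  starts_in_intron = list(a = rbind(c(130, 300)),
                          b = rbind(c(1, 100), c(201, 300))),
  ends_in_intron  = list(a = rbind(c(1, 150)),
                         b = rbind(c(1, 100), c(201, 300)))
)

#' Generate a two-isoform locus exhibiting exactly one AS event type
#'
#' The pair is built from a fixed template per type; complementary-pair
#' types (\code{retained_intron}/\code{spliced_intron},
#' \code{retained_exon}/\code{skipped_exon}) yield their complementary
#' label on the partner isoform, as the classification rules require.
#'
#' @param eventType one of the nine event types.
#' @param id locus id; isoforms get \code{.1}/\code{.2} suffixes.
#' @param scaffold,offset,strand placement; minus-strand loci are built by
#'   mirroring the template, which preserves the planted type.
#' @return a \linkS4class{GeneModel} with two transcripts.
#' @export
generateASLocus <- function(eventType, id = "as_locus", scaffold = "chr1",
                            offset = 0L, strand = "+") {
  tpl <- asTemplates[[eventType]]
  if (is.null(tpl))
    stop("unknown AS event type '", eventType, "' (expected one of: ",
         paste(AS_EVENT_TYPES, collapse = ", "), ")")
  place <- function(m) {
    s <- m[, 1] + offset; e <- m[, 2] + offset
    if (strand == "-") {
      L <- 2L * offset + 501L  # mirror inside a fixed 500-bp frame
      tmp <- L - e; e <- L - s; s <- tmp
    }
    list(start = sort(s), end = sort(e))
  }
  pa <- place(tpl$a); pb <- place(tpl$b)
  Gene(id, list(
    Transcript(paste0(id, ".1"), geneId = id, scaffold = scaffold,
               strand = strand, exonStarts = pa$start, exonEnds = pa$end),
    Transcript(paste0(id, ".2"), geneId = id, scaffold = scaffold,
               strand = strand, exonStarts = pb$start, exonEnds = pb$end)))
}

#' Simulate gene-family clusters with planted intron losses and expansions
#'
#' Builds a cluster set over one focal and several other species together
#' with matching per-species annotations.  Planted counts are exact:
#' \code{round(lossFraction * nClusters)} focal genes are constructed with
#' fewer introns than the cross-species median (of which
#' \code{round(fullLossFraction * nClusters)} with zero introns while the
#' median is >= 1), \code{nFragmentary} decoy focal genes are intron-less
#' *and* shorter than half the non-focal median transcript length (so the
#' fragmentary filter must exclude them), and \code{nExpanded} /
#' \code{nStronglyExpanded} clusters carry focal-member excesses of >1x /
#' >2x the largest other-species count.
#'
#' @param nClusters number of clusters (one focal gene each, plus planted
#'   extras in expanded clusters).
#' @param seed RNG seed.
#' @param focalSpecies,otherSpecies species labels.
#' @param lossFraction,fullLossFraction planted call fractions.
#' @param nFragmentary planted fragmentary decoys.
#' @param nExpanded,nStronglyExpanded planted expansion counts
#'   (strong expansions are a subset of expansions).
#' @param clusterPath if non-NULL, the cluster file is written there.
#' @return list: \code{clusters}, \code{annotations} (named list),
#'   \code{truth} (per focal gene: planted call), \code{path}.
#' @export
simulateClusterSet <- function(nClusters = 100, seed = NULL,
                               focalSpecies = "Pp",
                               otherSpecies = c("At", "Os"),
                               lossFraction = 0.14,
                               fullLossFraction = 0.03,
                               nFragmentary = 0,
                               nExpanded = 0, nStronglyExpanded = 0,
                               clusterPath = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nLoss <- round(lossFraction * nClusters)
  nFull <- round(fullLossFraction * nClusters)
  if (nFull > nLoss) stop("fullLossFraction cannot exceed lossFraction")
  if (nLoss + nFragmentary > nClusters)
    stop("infeasible config: more planted calls than clusters")
  if (nStronglyExpanded > nExpanded)
    stop("strong expansions are a subset of expansions")

  # non-focal reference per cluster: intron counts 4 and 6 -> median 5,
  # transcript length 1200 nt
  mkGene <- function(id, scaffold, nIntrons, txLen) {
    exW <- randomComposition(txLen, nIntrons + 1L, 30L)
    inW <- if (nIntrons) pmax(20L, rlnormMean(nIntrons, 264, 0.4))
           else integer(0)
    s <- 1L + c(0L, cumsum(exW[-length(exW)] + inW))
    Gene(id, Transcript(paste0(id, ".1"), geneId = id, scaffold = scaffold,
                        strand = "+", exonStarts = s, exonEnds = s + exW - 1L))
  }
  call <- c(rep("full_loss", nFull), rep("reduced_introns", nLoss - nFull),
            rep("fragmentary", nFragmentary),
            rep("none", nClusters - nLoss - nFragmentary))
  focalGenes <- vector("list", 0L)
  otherGenes <- stats::setNames(vector("list", length(otherSpecies)),
                                otherSpecies)
  rows <- list()
  truth <- list()
  for (i in seq_len(nClusters)) {
    cid <- sprintf("C%04d", i)
    gid <- sprintf("pg%04d", i)
    nIntrons <- switch(call[i],
                       full_loss = 0L, fragmentary = 0L,
                       reduced_introns = sample(1:4, 1L),
                       none = sample(5:7, 1L))
    txLen <- if (call[i] == "fragmentary") 300L else 1200L
    focalGenes[[gid]] <- mkGene(gid, sprintf("pscf%04d", i), nIntrons, txLen)
    members <- paste(focalSpecies, gid, sep = "|")
    extra <- if (i <= nStronglyExpanded) 2L
             else if (i <= nExpanded) 1L else 0L
    if (extra) for (k in seq_len(extra)) {
      xid <- sprintf("pg%04d_x%d", i, k)
      focalGenes[[xid]] <- mkGene(xid, sprintf("pscf%04d", i), 5L, 1200L)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cid, species = focalSpecies, gene = xid,
                   stringsAsFactors = FALSE)
    }
    rows[[length(rows) + 1L]] <-
      data.frame(cluster = cid, species = focalSpecies, gene = gid,
                 stringsAsFactors = FALSE)
    for (k in seq_along(otherSpecies)) {
      oid <- sprintf("%sg%04d", tolower(otherSpecies[k]), i)
      otherGenes[[otherSpecies[k]]][[oid]] <-
        mkGene(oid, sprintf("oscf%04d", i), if (k %% 2L) 4L else 6L, 1200L)
      rows[[length(rows) + 1L]] <-
        data.frame(cluster = cid, species = otherSpecies[k], gene = oid,
                   stringsAsFactors = FALSE)
    }
    truth[[i]] <- data.frame(gene = gid, cluster = cid, planted = call[i],
                             stringsAsFactors = FALSE)
  }
  clusters <- do.call(rbind, rows)
  annotations <- c(stats::setNames(list(Annotation(unname(focalGenes),
                                                   species = focalSpecies)),
                                   focalSpecies),
                   stats::setNames(lapply(names(otherGenes), function(sp)
                     Annotation(unname(otherGenes[[sp]]), species = sp)),
                     names(otherGenes)))
  path <- if (!is.null(clusterPath)) writeClusters(clusters, clusterPath)
          else NULL
  list(clusters = clusters, annotations = annotations,
       truth = do.call(rbind, truth), path = path)
}

#' Simulate a two-species GO annotation pair with planted enrichment
#'
#' Null terms are annotated in both species at the same base frequency;
#' planted terms are annotated \code{fold} times more frequently in the
#' focal species.
#'
#' @param nTerms total number of terms.
#' @param nPlanted number of planted enriched terms (the first ones).
#' @param fold focal/other frequency ratio of planted terms.
#' @param universeSize genes per species.
#' @param baseProb per-gene annotation probability of a null term.
#' @param aspect GO aspect of all generated terms.
#' @param seed RNG seed.
#' @return list: \code{goaFocal}, \code{goaOther}, \code{universes},
#'   \code{plantedTerms}.
#' @export
simulateGoaPair <- function(nTerms = 200, nPlanted = 1, fold = 4,
                            universeSize = 2000, baseProb = 0.05,
                            aspect = "BP", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  terms <- sprintf("GO:%07d", seq_len(nTerms))
  planted <- terms[seq_len(nPlanted)]
  mk <- function(probs, prefix) {
    rows <- lapply(seq_along(terms), function(i) {
      hit <- which(stats::runif(universeSize) < probs[i])
      if (!length(hit)) return(NULL)
      data.frame(gene = sprintf("%s%05d", prefix, hit), term = terms[i],
                 aspect = aspect, evidence = "IEA", ref = "synthetic",
                 negated = FALSE, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  pf <- rep(baseProb, nTerms)
  pf[seq_len(nPlanted)] <- pmin(1, fold * baseProb)
  list(goaFocal = mk(pf, "fg"), goaOther = mk(rep(baseProb, nTerms), "og"),
       universes = c(focal = universeSize, other = universeSize),
       plantedTerms = planted)
}

#' Default compartment -> GO cellular component slim mapping
#' @return named character vector.
#' @export
defaultCompartmentMap <- function() c(
  chloroplast   = "GO:0009507",
  mitochondrion = "GO:0005739",
  secreted      = "GO:0005576",
  cytosol       = "GO:0005829",
  nucleus       = "GO:0005634",
  membrane      = "GO:0016020"
)

#' Simulate subcellular-predictor call tables with planted localizations
#'
#' @param nProteins number of proteins.
#' @param tools data.frame \code{tool}/\code{weight}/\code{n_terminal_only}
#'   (default: three unit-weight full-length tools).
#' @param accuracy probability a tool reports the true compartment.
#' @param compartments compartment vocabulary (must map via
#'   [defaultCompartmentMap()]).
#' @param seed RNG seed.
#' @return list: \code{calls}, \code{tools}, \code{truth}
#'   (protein/compartment), \code{compartmentMap}.
#' @export
simulatePredictorCalls <- function(nProteins = 50,
                                   tools = data.frame(
                                     tool = c("toolA", "toolB", "toolC"),
                                     weight = 1,
                                     n_terminal_only = FALSE),
                                   accuracy = 1,
                                   compartments = c("chloroplast",
                                                    "mitochondrion",
                                                    "secreted", "cytosol"),
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  prot <- sprintf("prot%04d", seq_len(nProteins))
  truthComp <- sample(compartments, nProteins, replace = TRUE)
  calls <- do.call(rbind, lapply(seq_len(nrow(tools)), function(t) {
    correct <- stats::runif(nProteins) < accuracy
    comp <- ifelse(correct, truthComp,
                   vapply(truthComp, function(x)
                     sample(setdiff(compartments, x), 1L), character(1)))
    data.frame(tool = tools$tool[t], protein = prot, compartment = comp,
               score = NA_real_, stringsAsFactors = FALSE)
  }))
  list(calls = calls, tools = tools,
       truth = data.frame(protein = prot, compartment = truthComp,
                          stringsAsFactors = FALSE),
       compartmentMap = defaultCompartmentMap())
}

#' Simulate a codon-usage-biased coding sequence
#'
#' Within every synonymous family the codon probabilities are proportional
#' to \code{exp(-bias * rank)}; \code{bias = 0} gives uniform usage (Nc
#' approaches 61 for long sequences), large \code{bias} approaches one
#' codon per amino acid (Nc = 20).
#'
#' @param nCodons sequence length in codons.
#' @param bias non-negative bias parameter.
#' @param seed RNG seed.
#' @return list: \code{sequence} (nucleotide string), \code{codons}.
#' @export
simulateBiasedCds <- function(nCodons = 300, bias = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  fams <- split(names(gc), gc)
  fams <- fams[!names(fams) %in% c("*", "M", "W")]
  aa <- sample(names(fams), nCodons, replace = TRUE)
  codons <- vapply(aa, function(x) {
    syn <- fams[[x]]
    p <- exp(-bias * (seq_along(syn) - 1L))
    sample(syn, 1L, prob = p / sum(p))
  }, character(1))
  list(sequence = paste(codons, collapse = ""), codons = unname(codons))
}
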