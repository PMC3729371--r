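# Gene-family analyses: representative-isoform selection, family size /
# orphan / expansion profiling, and cluster-based secondary intron-loss
# inference.

#' Uncorrected pairwise distance (p-distance)
#'
#' Proportion of mismatching positions between two equal-length aligned
#' sequences; positions where either sequence carries a gap (\code{-} or
#' \code{.}) are excluded from the comparison.
#'
#' @param a,b aligned sequences (single strings or character vectors of
#'   residues) of equal length.
#' @return proportion in [0, 1]; \code{NA_real_} when no position is
#'   comparable.
#' @export
pairwiseUncorrectedDistance <- function(a, b) {
  toChars <- function(x) if (length(x) == 1L) strsplit(x, "")[[1L]] else x
  a <- toupper(toChars(a)); b <- toupper(toChars(b))
  if (length(a) != length(b)) stop("aligned sequences must have equal length")
  gap <- a %in% c("-", ".") | b %in% c("-", ".")
  n <- sum(!gap)
  if (!n) return(NA_real_)
  sum(a[!gap] != b[!gap]) / n
}

#' Select the representative isoform per focal locus in a cluster
#'
#' Three-tier rule: (1) \emph{min_distance} -- when the cluster has at
#' least one non-focal member and a distance matrix is supplied, the focal
#' isoform with the smallest distance to any non-focal member; (2)
#' \emph{best_hit_coverage} -- for focal-only clusters with homology hits,
#' the isoform best covering its closest hit; (3) \emph{longest_transcript}
#' otherwise.  Ties break to the lexicographically smallest transcript id.
#'
#' @param cluster data.frame (rows of one cluster: \code{species},
#'   \code{gene}); focal rows are transcript/isoform ids.
#' @param focalSpecies focal species label.
#' @param distMatrix symmetric matrix of pairwise distances over member
#'   ids (needed for tier 1; an isoform absent from it is an error).
#' @param hitTable data.frame \code{query}/\code{query_coverage} (tier 2).
#' @param annotation \linkS4class{GenomeAnnotation} of the focal species;
#'   used to resolve isoforms to loci and transcript lengths.
#' @return data.frame: \code{locus}, \code{transcript}, \code{tier},
#'   \code{supporting_value}.
#' @export
selectRepresentative <- function(cluster, focalSpecies, distMatrix = NULL,
                                 hitTable = NULL, annotation) {
  txs <- transcriptModels(annotation)
  focal <- cluster$gene[cluster$species == focalSpecies]
  other <- cluster$gene[cluster$species != focalSpecies]
  missing <- setdiff(focal, names(txs))
  if (length(missing))
    stop("focal isoform(s) not resolvable to a locus: ",
         paste(missing, collapse = ", "))
  locus <- vapply(focal, function(id) txs[[id]]@geneId, character(1))

  out <- lapply(split(focal, locus), function(iso) {
    iso <- sort(iso)
    if (length(other) && !is.null(distMatrix)) {
      absent <- setdiff(iso, rownames(distMatrix))
      if (length(absent))
        stop("isoform(s) absent from distance matrix: ",
             paste(absent, collapse = ", "))
      d <- vapply(iso, function(i)
        min(distMatrix[i, intersect(other, colnames(distMatrix))]), numeric(1))
      k <- which.min(d)  # first minimum = smallest id (iso sorted)
      data.frame(locus = txs[[iso[k]]]@geneId, transcript = iso[k],
                 tier = "min_distance", supporting_value = d[k],
                 stringsAsFactors = FALSE)
    } else if (!is.null(hitTable) && any(iso %in% hitTable$query)) {
      cov <- vapply(iso, function(i) {
        h <- hitTable$query_coverage[hitTable$query == i]
        if (length(h)) max(h) else -Inf
      }, numeric(1))
      k <- which.max(cov)
      data.frame(locus = txs[[iso[k]]]@geneId, transcript = iso[k],
                 tier = "best_hit_coverage", supporting_value = cov[k],
                 stringsAsFactors = FALSE)
    } else {
      len <- vapply(iso, function(i) splicedLength(txs[[i]]), numeric(1))
      k <- which.max(len)
      data.frame(locus = txs[[iso[k]]]@geneId, transcript = iso[k],
                 tier = "longest_transcript", supporting_value = len[k],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Gene-family size profile and expansion calls
#'
#' Per cluster: member counts per species, the focal-only flag, and
#' expansion calls -- \code{expanded} when the focal count strictly
#' exceeds the largest other-species count, \code{strongly_expanded} when
#' it exceeds twice that count.  The genome summary reports the fraction
#' of focal loci in focal-only clusters, and size-frequency distributions
#' per species restricted to clusters shared by the focal species and at
#' least one other.
#'
#' @param clusters data.frame from [readClusters()].
#' @param focalSpecies focal species label.
#' @return list: \code{profiles} (per-cluster data.frame with
#'   \code{cluster}, \code{focal_n}, \code{max_other_n}, \code{n_species},
#'   \code{focal_only}, \code{expanded}, \code{strongly_expanded}),
#'   \code{focal_only_fraction} (of focal loci), \code{shared_clusters},
#'   \code{size_frequency} (species x family-size table over shared
#'   clusters).
#' @export
familyProfile <- function(clusters, focalSpecies) {
  if (!nrow(clusters)) stop("no clusters")
  byc <- split(clusters, clusters$cluster)
  profiles <- do.call(rbind, lapply(byc, function(d) {
    counts <- table(d$species)
    fn <- if (focalSpecies %in% names(counts)) counts[[focalSpecies]] else 0L
    others <- counts[names(counts) != focalSpecies]
    mo <- if (length(others)) max(others) else 0L
    data.frame(cluster = d$cluster[1L], focal_n = fn, max_other_n = mo,
               n_species = length(counts),
               focal_only = fn > 0L && length(others) == 0L,
               expanded = length(others) > 0L && fn > mo,
               strongly_expanded = length(others) > 0L && fn > 2L * mo,
               stringsAsFactors = FALSE)
  }))
  rownames(profiles) <- NULL
  focalRows <- clusters$species == focalSpecies
  focalOnlyClusters <- profiles$cluster[profiles$focal_only]
  focalOnlyFraction <- if (any(focalRows))
    sum(clusters$cluster[focalRows] %in% focalOnlyClusters) / sum(focalRows)
  else NA_real_
  shared <- profiles$cluster[profiles$focal_n > 0L & profiles$n_species > 1L]
  sz <- clusters[clusters$cluster %in% shared, , drop = FALSE]
  sizeFreq <- if (nrow(sz)) {
    cnt <- stats::aggregate(gene ~ cluster + species, data = sz, FUN = length)
    table(cnt$species, cnt$gene, dnn = c("species", "family_size"))
  } else NULL
  list(profiles = profiles, focal_only_fraction = focalOnlyFraction,
       shared_clusters = shared, size_frequency = sizeFreq)
}

#' Classify focal loci as family members or orphans
#'
#' Rule table: locus in a multi-species cluster -> \code{has_plant_family};
#' focal-only locus with a homology hit -> \code{focal_only_with_homolog};
#' no hit and no transcript evidence -> \code{orphan_no_homolog}; no hit
#' but transcript evidence -> \code{orphan_with_est}.
#'
#' @param clusters data.frame from [readClusters()].
#' @param focalSpecies focal species label.
#' @param hitTable data.frame with a \code{query} column of genes with
#'   homology hits (may be NULL = no hits).
#' @param estFlags data.frame \code{gene}/\code{est_supported}.
#' @return data.frame \code{gene}/\code{class}.
#' @export
classifyOrphans <- function(clusters, focalSpecies, hitTable = NULL,
                            estFlags = NULL) {
  prof <- familyProfile(clusters, focalSpecies)$profiles
  focalOnly <- prof$cluster[prof$focal_only]
  rows <- clusters[clusters$species == focalSpecies, , drop = FALSE]
  hits <- if (is.null(hitTable)) character(0) else unique(hitTable$query)
  est <- if (is.null(estFlags)) character(0)
         else estFlags$gene[as.logical(estFlags$est_supported)]
  cls <- ifelse(!(rows$cluster %in% focalOnly), "has_plant_family",
         ifelse(rows$gene %in% hits, "focal_only_with_homolog",
         ifelse(rows$gene %in% est, "orphan_with_est", "orphan_no_homolog")))
  out <- unique(data.frame(gene = rows$gene, class = cls,
                           stringsAsFactors = FALSE))
  # a gene in several clusters: any non-orphan evidence wins
  rank <- c(has_plant_family = 1L, focal_only_with_homolog = 2L,
            orphan_with_est = 3L, orphan_no_homolog = 4L)
  out <- out[order(out$gene, rank[out$class]), , drop = FALSE]
  out <- out[!duplicated(out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Infer secondary intron loss from gene-family clusters
#'
#' For every cluster with at least one non-focal member, the cross-species
#' reference is the (interpolated) median intron count of the non-focal
#' members.  Focal genes whose transcript is shorter than
#' \code{lengthRatioThreshold} times the median non-focal transcript
#' length are flagged \code{excluded_fragmentary} and receive no call.
#' Otherwise a focal gene with strictly fewer introns than the reference
#' median is called \code{reduced_introns}; if in addition it has zero
#' introns while the median is >= 1, the call is \code{full_loss}
#' (putative retrocopy).  A locus appearing in several clusters is
#' evaluated per cluster and reported with its most severe call.
#'
#' @param clusters data.frame from [readClusters()].
#' @param annotations named list of \linkS4class{GenomeAnnotation}, one
#'   per species label used in the clusters.
#' @param focalSpecies focal species label.
#' @param lengthRatioThreshold fragmentary-model cutoff on the transcript
#'   length ratio (default 0.5).
#' @param representatives optional named vector gene -> transcript id.
#' @return list: \code{calls} (per gene x cluster data.frame),
#'   \code{per_gene} (most severe call per gene), \code{summary} with the
#'   genome-level fractions (denominator: all focal genes in the
#'   annotation).
#' @export
inferIntronLoss <- function(clusters, annotations, focalSpecies,
                            lengthRatioThreshold = 0.5,
                            representatives = NULL) {
  txOf <- function(species, gene) {
    ann <- annotations[[species]]
    if (is.null(ann)) stop("no annotation for species ", species)
    g <- ann@genes[[gene]]
    if (is.null(g)) return(NULL)
    pickRepresentative(g, representatives)
  }
  unknown <- !vapply(seq_len(nrow(clusters)), function(i) {
    ann <- annotations[[clusters$species[i]]]
    !is.null(ann) && clusters$gene[i] %in% names(ann@genes)
  }, logical(1))
  if (any(unknown))
    stop("cluster member(s) not found in annotations: ",
         paste(paste(clusters$species[unknown], clusters$gene[unknown],
                     sep = "|"), collapse = ", "))

  byc <- split(clusters, clusters$cluster)
  calls <- do.call(rbind, lapply(byc, function(d) {
    focal <- d[d$species == focalSpecies, , drop = FALSE]
    other <- d[d$species != focalSpecies, , drop = FALSE]
    if (!nrow(focal) || !nrow(other)) return(NULL)
    otherTx <- lapply(seq_len(nrow(other)), function(i)
      txOf(other$species[i], other$gene[i]))
    m <- stats::median(vapply(otherTx, function(tx) length(tx@exons) - 1L,
                              integer(1)))
    medLen <- stats::median(vapply(otherTx, splicedLength, numeric(1)))
    do.call(rbind, lapply(focal$gene, function(g) {
      tx <- txOf(focalSpecies, g)
      nIntrons <- length(tx@exons) - 1L
      frag <- splicedLength(tx) < lengthRatioThreshold * medLen
      call <- if (frag) NA_character_
        else if (nIntrons == 0L && m >= 1) "full_loss"
        else if (nIntrons < m) "reduced_introns"
        else "none"
      data.frame(gene = g, cluster = d$cluster[1L],
                 focal_introns = nIntrons, median_other_introns = m,
                 excluded_fragmentary = frag, call = call,
                 stringsAsFactors = FALSE)
    }))
  }))
  if (is.null(calls))
    calls <- data.frame(gene = character(0), cluster = character(0),
                        focal_introns = integer(0),
                        median_other_introns = numeric(0),
                        excluded_fragmentary = logical(0),
                        call = character(0), stringsAsFactors = FALSE)
  rownames(calls) <- NULL

  sev <- c(full_loss = 1L, reduced_introns = 2L, none = 3L)
  scored <- calls[!calls$excluded_fragmentary, , drop = FALSE]
  perGene <- scored[order(scored$gene, sev[scored$call]), , drop = FALSE]
  perGene <- perGene[!duplicated(perGene$gene), , drop = FALSE]
  rownames(perGene) <- NULL

  nFocal <- length(annotations[[focalSpecies]]@genes)
  nReduced <- sum(perGene$call %in% c("reduced_introns", "full_loss"))
  nFull <- sum(perGene$call == "full_loss")
  list(calls = calls, per_gene = perGene,
       summary = list(total_focal_genes = nFocal,
                      n_reduced = nReduced, n_full_loss = nFull,
                      fraction_reduced = nReduced / nFocal,
                      fraction_full_loss = nFull / nFocal,
                      n_excluded_fragmentary =
                        sum(calls$excluded_fragmentary)))
}
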