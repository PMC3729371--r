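# Pipeline driver: wires the analysis stages and writes tabular + JSON
# results.

SUMMARY_SCHEMA_VERSION <- "1.0"

#' Run the analysis pipeline
#'
#' Executes the selected stages in dependency order (annotation input ->
#' structure stats / splice classification -> families & intron loss ->
#' functional annotation) and writes TSV tables plus a versioned JSON
#' summary aggregating the headline numbers (AS fraction, intron-loss
#' fraction, GO coverage, focal-only fraction) with all thresholds echoed
#' for provenance.  Missing inputs for a selected stage fail pre-flight,
#' before any stage runs.
#'
#' @param config a named list or the path of a YAML file with entries:
#'   \code{gff} (path), \code{species}, \code{genome_size} (bp, optional),
#'   \code{stages} (subset of \code{c("stats","splice","families",
#'   "functional")}), \code{clusters} + \code{focal_species} (+ optional
#'   \code{gff_by_species}: named list of non-focal GFF3 paths) for the
#'   families stage, \code{gaf_focal}/\code{gaf_other} +
#'   \code{universe_focal}/\code{universe_other} for the functional stage,
#'   \code{out_dir}, \code{seed}, and thresholds
#'   \code{length_ratio_threshold} (0.5), \code{intron_length_threshold}
#'   (500), \code{atg_distance_threshold} (65), \code{alpha} (0.05),
#'   \code{majority_fraction} (0.5).
#' @return invisibly, the summary list (also written as
#'   \code{summary.json}).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- function(key, default = NULL)
    if (!is.null(config[[key]])) config[[key]] else default
  stages <- cfg("stages", c("stats", "splice"))
  outDir <- cfg("out_dir", ".")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(cfg("seed"))) set.seed(as.integer(cfg("seed")))

  thresholds <- list(
    length_ratio_threshold = cfg("length_ratio_threshold", 0.5),
    intron_length_threshold = cfg("intron_length_threshold", 500),
    atg_distance_threshold = cfg("atg_distance_threshold", 65),
    alpha = cfg("alpha", 0.05),
    majority_fraction = cfg("majority_fraction", 0.5))

  # pre-flight: every selected stage must have its inputs
  need <- c(if (any(c("stats", "splice", "families") %in% stages)) "gff",
            if ("families" %in% stages) c("clusters", "focal_species"),
            if ("functional" %in% stages) c("gaf_focal", "gaf_other"))
  missingKeys <- setdiff(need, names(config))
  if (length(missingKeys))
    stop("missing required config entries: ",
         paste(missingKeys, collapse = ", "))
  paths <- unlist(config[intersect(names(config),
                                   c("gff", "clusters", "gaf_focal",
                                     "gaf_other", "obo"))], use.names = FALSE)
  absent <- paths[!file.exists(paths)]
  if (length(absent))
    stop("missing input file(s): ", paste(absent, collapse = ", "))

  log <- function(...) message(format(Sys.time(), "[%H:%M:%S] "),
                               sprintf(...))
  summary <- list(schema_version = SUMMARY_SCHEMA_VERSION,
                  thresholds = thresholds, stages = stages)
  tsv <- function(d, name) utils::write.table(
    d, file.path(outDir, name), sep = "\t", quote = FALSE, row.names = FALSE)

  ann <- NULL
  if (!is.null(cfg("gff"))) {
    log("reading annotation %s", cfg("gff"))
    ann <- readGFF3(cfg("gff"), species = cfg("species", "unknown"),
                    genomeSize = cfg("genome_size", NA_real_))
  }
  if ("stats" %in% stages) {
    log("stage stats")
    st <- genomeStructureSummary(ann)
    tsv(st, "stats.tsv")
    prof <- intronLengthProfile(ann, thresholds$intron_length_threshold)
    tsv(prof$summary, "intron_profile.tsv")
    dist <- proximalUtr5IntronDistances(ann, thresholds$atg_distance_threshold)
    tsv(dist, "utr5_intron_distances.tsv")
    summary$stats <- list(
      genes = statValue(st, "genes", "count"),
      transcripts = statValue(st, "transcripts", "count"),
      frac_utr5_intron_gt_threshold =
        prof$summary$frac_gt_threshold[prof$summary$class == "UTR5"],
      frac_atg_below_threshold = attr(dist, "frac_atg_below"))
  }
  if ("splice" %in% stages) {
    log("stage splice")
    as <- genomeASSummary(ann)
    ev <- do.call(rbind, lapply(as$reports, function(r)
      if (nrow(r$events)) cbind(locus = r$locus, r$events) else NULL))
    if (is.null(ev)) ev <- cbind(locus = character(0), emptyEventFrame())
    tsv(ev, "splice_events.tsv")
    tsv(as$per_type, "splice_summary.tsv")
    summary$splice <- list(n_loci = as$n_loci, n_as_loci = as$n_as_loci,
                           as_fraction = as$as_fraction,
                           effects = as.list(as$effects))
  }
  if ("families" %in% stages) {
    log("stage families")
    clusters <- readClusters(cfg("clusters"))
    focal <- cfg("focal_species")
    fam <- familyProfile(clusters, focal)
    tsv(fam$profiles, "families.tsv")
    summary$families <- list(
      n_clusters = nrow(fam$profiles),
      focal_only_fraction = fam$focal_only_fraction,
      n_expanded = sum(fam$profiles$expanded),
      n_strongly_expanded = sum(fam$profiles$strongly_expanded))
    gffBySpecies <- cfg("gff_by_species")
    if (!is.null(gffBySpecies)) {
      anns <- c(stats::setNames(list(ann), focal),
                lapply(gffBySpecies, readGFF3))
      loss <- inferIntronLoss(clusters, anns, focal,
                              thresholds$length_ratio_threshold)
      tsv(loss$per_gene, "intron_loss.tsv")
      summary$intron_loss <- loss$summary
    }
  }
  if ("functional" %in% stages) {
    log("stage functional")
    gf <- readGAF(cfg("gaf_focal"))
    go <- readGAF(cfg("gaf_other"))
    universes <- c(focal = cfg("universe_focal",
                               length(unique(gf$gene[!gf$negated]))),
                   other = cfg("universe_other",
                               length(unique(go$gene[!go$negated]))))
    enr <- termEnrichment(gf, go, universes, thresholds$alpha)
    tsv(enr, "enrichment.tsv")
    gs <- goaSummary(gf, cfg("total_genes",
                             if (!is.null(ann)) length(ann@genes)
                             else universes[["focal"]]))
    summary$functional <- list(
      coverage = gs$coverage,
      n_significant = sum(enr$significant),
      top_terms = utils::head(enr$term[enr$significant], 10))
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log("done: %s", file.path(outDir, "summary.json"))
  invisible(summary)
}
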