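test_that("single-gene geometry flows into the summary", {
  # CDS span 51-250 crosses the intron: spliced CDS = 50 + 50 = 100 nt,
  # leaving a 50-nt 5'-UTR and a 50-nt 3'-UTR (verified against the
  # position-set oracle)
  ann <- Annotation(Gene("g1", Transcript("g1.1", "g1",
                                          exonStarts = c(1, 201),
                                          exonEnds = c(100, 300),
                                          cdsStarts = 51, cdsEnds = 250)))
  o <- oracleRegions(c(1, 201), c(100, 300), 51, 250)
  expect_equal(o$cds, 100)
  st <- genomeStructureSummary(ann)
  expect_equal(statValue(st, "transcript_length", "mean"), 200)
  expect_equal(statValue(st, "cds_length", "mean"), o$cds)
  expect_equal(statValue(st, "utr5_length", "mean"), o$utr5)
  expect_equal(statValue(st, "exons_per_gene", "mean"), 2)
  expect_equal(statValue(st, "introns_per_gene", "mean"), 1)
  expect_equal(statValue(st, "single_exon_transcripts", "fraction"), 0)
  expect_equal(statValue(st, "transcripts_with_utr3", "count"), 1)
  expect_equal(statValue(st, "utr3_length", "mean"), 50)
})

test_that("empty annotations are rejected", {
  expect_error(genomeStructureSummary(Annotation(list())), "no genes")
})

test_that("gene density reproduces the published arithmetic", {
  # 480 Mb genome over 32,275 genes prints as 14.9 kb per gene
  expect_equal(round(geneDensity(480e6, 32275), 1), 14.9)
  ann <- Annotation(lapply(1:10, function(i)
    Gene(paste0("g", i), Transcript(paste0("g", i, ".1"), paste0("g", i),
                                    exonStarts = 1, exonEnds = 100))),
    genomeSize = 1e6)
  st <- genomeStructureSummary(ann)
  expect_equal(statValue(st, "gene_density_kb_per_gene", "value"), 100)
})

test_that("intron length profile uses a strictly-greater threshold", {
  mk <- function(id, intronW, utr5Intron) {
    # two exons of 600 bp separated by an intron of the requested width;
    # the CDS starts downstream of the intron when it should be in the UTR
    Transcript(id, exonStarts = c(1, 601 + intronW),
               exonEnds = c(600, 1200 + intronW),
               cdsStarts = if (utr5Intron) 651 + intronW else 1,
               cdsEnds = 1200 + intronW)
  }
  # UTR5 introns 600 and 700 bp; CDS introns 100 and 200 bp
  ann <- Annotation(list(
    Gene("a", mk("a.1", 600, TRUE)), Gene("b", mk("b.1", 700, TRUE)),
    Gene("c", mk("c.1", 100, FALSE)), Gene("d", mk("d.1", 200, FALSE))))
  prof <- intronLengthProfile(ann)$summary
  expect_equal(prof$frac_gt_threshold[prof$class == "UTR5"], 1.0)
  expect_equal(prof$frac_gt_threshold[prof$class == "CDS"], 0.0)
  ann500 <- Annotation(Gene("e", mk("e.1", 500, FALSE)))
  prof500 <- intronLengthProfile(ann500)$summary
  expect_equal(prof500$frac_gt_threshold[prof500$class == "CDS"], 0)
})

test_that("5'-UTR intron frequencies use transcripts-with-5'-UTR as denominator", {
  mk <- function(id, withIntron) {
    if (withIntron)
      Transcript(id, exonStarts = c(1, 201), exonEnds = c(100, 400),
                 cdsStarts = 251, cdsEnds = 400)
    else
      Transcript(id, exonStarts = 1, exonEnds = 400,
                 cdsStarts = 101, cdsEnds = 400)
  }
  genes <- lapply(1:10, function(i)
    Gene(paste0("g", i), mk(paste0("g", i, ".1"), i <= 4)))
  freq <- utr5IntronCountFrequencies(Annotation(genes))
  expect_equal(attr(freq, "denominator"), 10L)
  expect_equal(freq$fraction[freq$n_introns == 1], 0.4)
  expect_equal(sum(freq$fraction), 1)
  st <- genomeStructureSummary(Annotation(genes))
  expect_equal(statValue(st, "multi_exon_utr5", "fraction"), 0.4)

  # no 5'-UTR at all -> empty table with explicit flag
  noUtr <- Annotation(Gene("g", Transcript("g.1", exonStarts = 1,
                                           exonEnds = 300, cdsStarts = 1,
                                           cdsEnds = 300)))
  f2 <- utr5IntronCountFrequencies(noUtr)
  expect_true(attr(f2, "empty"))

  # all single-exon 5'-UTRs -> frequency(0) = 1
  allSingle <- Annotation(lapply(1:3, function(i)
    Gene(paste0("s", i), mk(paste0("s", i, ".1"), FALSE))))
  f3 <- utr5IntronCountFrequencies(allSingle)
  expect_equal(f3$fraction[f3$n_introns == 0], 1)
})

test_that("proximal 5'-UTR intron distances follow the min-to-ATG rule", {
  # one UTR5 intron: 50 exonic UTR nt remain downstream of it
  ann <- Annotation(Gene("g", Transcript("g.1", exonStarts = c(1, 201),
                                         exonEnds = c(100, 300),
                                         cdsStarts = 251, cdsEnds = 300)))
  d <- proximalUtr5IntronDistances(ann)
  expect_equal(d$distance_to_atg, 50)
  expect_equal(d$distance_to_tss, 100)

  # two UTR5 introns at acceptor offsets 30 and 120, CDS start offset 150:
  # the proximal one ends at 120 -> distance 30
  tx <- Transcript("h.1", exonStarts = c(1, 131, 321),
                   exonEnds = c(30, 220, 500),
                   cdsStarts = 351, cdsEnds = 500)
  expect_equal(sum(IRanges::width(utr5Ranges(tx))), 150)
  d2 <- proximalUtr5IntronDistances(Annotation(Gene("h", tx)))
  expect_equal(d2$distance_to_atg, 30)
  expect_equal(d2$distance_to_tss, 120)

  # intron acceptor immediately adjacent to the ATG -> distance 0
  tx0 <- Transcript("k.1", exonStarts = c(1, 201), exonEnds = c(100, 300),
                    cdsStarts = 201, cdsEnds = 300)
  d0 <- proximalUtr5IntronDistances(Annotation(Gene("k", tx0)))
  expect_equal(d0$distance_to_atg, 0)
})

test_that("summary counts are internally consistent and match the naive oracle", {
  sim <- simulateGenome(nGenes = 50, seed = 3, asFraction = 0.1)
  st <- genomeStructureSummary(sim$annotation)
  nTx <- statValue(st, "transcripts", "count")
  expect_equal(statValue(st, "multi_exon_transcripts", "count") +
               statValue(st, "single_exon_transcripts", "count"), nTx)
  expect_lte(statValue(st, "multi_exon_utr5", "count"),
             statValue(st, "transcripts_with_utr5", "count"))

  o <- naiveStructStats(sim$annotation)
  expect_equal(nTx, o$n_tx)
  expect_equal(statValue(st, "transcript_length", "mean"), o$mean_tx_len)
  expect_equal(statValue(st, "transcript_length", "median"), o$median_tx_len)
  expect_equal(statValue(st, "cds_length", "mean"), o$mean_cds_len)
  expect_equal(statValue(st, "exon_length", "mean"), o$mean_exon_len)
  expect_equal(statValue(st, "intron_length", "mean"), o$mean_intron_len)
  expect_equal(statValue(st, "exons_per_gene", "mean"), o$mean_exons)
  expect_equal(statValue(st, "single_exon_transcripts", "count"),
               o$n_single_exon)
  expect_equal(statValue(st, "transcripts_with_utr5", "count"), o$n_with_u5)
  expect_equal(statValue(st, "multi_exon_utr5", "count"), o$n_multi_u5)
  expect_equal(statValue(st, "utr5_intron_length", "mean"), o$mean_u5_intron)
})

test_that("adding an intron-free gene cannot raise mean introns per gene", {
  sim <- simulateGenome(nGenes = 30, seed = 9)
  st1 <- genomeStructureSummary(sim$annotation)
  extra <- Gene("zz", Transcript("zz.1", "zz", exonStarts = 1, exonEnds = 500,
                                 cdsStarts = 1, cdsEnds = 500))
  st2 <- genomeStructureSummary(Annotation(c(geneModels(sim$annotation),
                                             list(extra))))
  expect_lte(statValue(st2, "introns_per_gene", "mean"),
             statValue(st1, "introns_per_gene", "mean"))
})

test_that("representative scope uses the longest isoform by default", {
  g <- Gene("g", list(
    Transcript("g.1", "g", exonStarts = 1, exonEnds = 300,
               cdsStarts = 1, cdsEnds = 300),
    Transcript("g.2", "g", exonStarts = 1, exonEnds = 900,
               cdsStarts = 1, cdsEnds = 900)))
  st <- genomeStructureSummary(Annotation(g), scope = "representative_only")
  expect_equal(statValue(st, "transcript_length", "mean"), 900)
  st2 <- genomeStructureSummary(Annotation(g),
                                scope = "representative_only",
                                representatives = c(g = "g.1"))
  expect_equal(statValue(st2, "transcript_length", "mean"), 300)
})
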