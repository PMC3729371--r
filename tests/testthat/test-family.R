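test_that("p-distance excludes gap columns", {
  expect_equal(pairwiseUncorrectedDistance("ACGT", "ACGT"), 0.0)
  expect_equal(pairwiseUncorrectedDistance("ACGT", "ACGA"), 0.25)
  expect_equal(pairwiseUncorrectedDistance("AC-T", "ACGT"), 0.0)
  expect_true(is.na(pairwiseUncorrectedDistance("---", "AAA")))
  expect_error(pairwiseUncorrectedDistance("AC", "ACG"), "equal length")
})

repFixture <- function() {
  g1 <- Gene("L1", list(
    Transcript("L1.1", "L1", exonStarts = 1, exonEnds = 900,
               cdsStarts = 1, cdsEnds = 900),
    Transcript("L1.2", "L1", exonStarts = 1, exonEnds = 1400,
               cdsStarts = 1, cdsEnds = 1400)))
  Annotation(g1, species = "Pp")
}

test_that("representative selection walks the three tiers with deterministic ties", {
  ann <- repFixture()
  clMulti <- data.frame(cluster = "C1", species = c("Pp", "Pp", "At"),
                        gene = c("L1.1", "L1.2", "AT1"))
  d <- matrix(1, 3, 3, dimnames = list(c("L1.1", "L1.2", "AT1"),
                                       c("L1.1", "L1.2", "AT1")))
  d["L1.1", "AT1"] <- d["AT1", "L1.1"] <- 0.10
  d["L1.2", "AT1"] <- d["AT1", "L1.2"] <- 0.25
  r <- selectRepresentative(clMulti, "Pp", distMatrix = d, annotation = ann)
  expect_equal(r$transcript, "L1.1")
  expect_equal(r$tier, "min_distance")
  expect_equal(r$supporting_value, 0.10)

  clOnly <- data.frame(cluster = "C2", species = c("Pp", "Pp"),
                       gene = c("L1.1", "L1.2"))
  hits <- data.frame(query = c("L1.1", "L1.2"), query_coverage = c(0.9, 0.5))
  r2 <- selectRepresentative(clOnly, "Pp", hitTable = hits, annotation = ann)
  expect_equal(r2$transcript, "L1.1")
  expect_equal(r2$tier, "best_hit_coverage")

  r3 <- selectRepresentative(clOnly, "Pp", annotation = ann)
  expect_equal(r3$transcript, "L1.2")   # 1,400 nt beats 900 nt
  expect_equal(r3$tier, "longest_transcript")

  # tier-1 with an isoform missing from the matrix is an error naming it
  dBad <- d[-2, -2]
  expect_error(selectRepresentative(clMulti, "Pp", distMatrix = dBad,
                                    annotation = ann), "L1.2")

  # equal distances tie-break to the lexicographically smallest id
  dTie <- d; dTie["L1.2", "AT1"] <- dTie["AT1", "L1.2"] <- 0.10
  rT <- selectRepresentative(clMulti, "Pp", distMatrix = dTie,
                             annotation = ann)
  expect_equal(rT$transcript, "L1.1")

  # determinism: identical inputs, identical choices
  expect_identical(r, selectRepresentative(clMulti, "Pp", distMatrix = d,
                                           annotation = ann))
})

test_that("family profiles count focal-only loci and flag expansions", {
  cl <- rbind(
    data.frame(cluster = "C1", species = c("Pp", "Pp", "Pp", "At"),
               gene = c("p1", "p2", "p3", "a1")),
    data.frame(cluster = "C2", species = c("Pp", "Pp"), gene = c("p4", "p5")),
    data.frame(cluster = "C3", species = c("Pp", "Os", "Os", "Os", "Os"),
               gene = c("p6", "o1", "o2", "o3", "o4")))
  f <- familyProfile(cl, "Pp")
  expect_equal(f$focal_only_fraction, 2 / 6)
  p <- f$profiles
  expect_true(p$expanded[p$cluster == "C1"])
  expect_true(p$strongly_expanded[p$cluster == "C1"])   # 3 > 2 x 1
  expect_false(p$expanded[p$cluster == "C3"])
  expect_true(p$focal_only[p$cluster == "C2"])
  expect_setequal(f$shared_clusters, c("C1", "C3"))

  # 5 focal vs max other 2 -> strongly expanded (5 > 4)
  cl5 <- data.frame(cluster = "C9", species = c(rep("Pp", 5), "At", "At"),
                    gene = c(paste0("p", 1:5), "a1", "a2"))
  expect_true(familyProfile(cl5, "Pp")$profiles$strongly_expanded)

  # single-member single-species cluster
  c1 <- familyProfile(data.frame(cluster = "S", species = "Pp", gene = "p"),
                      "Pp")
  expect_true(c1$profiles$focal_only)
  expect_equal(c1$focal_only_fraction, 1)
})

test_that("size-frequency distributions count clusters, not members", {
  cl <- rbind(
    data.frame(cluster = "C1", species = c("Pp", "Pp", "At"),
               gene = c("p1", "p2", "a1")),
    data.frame(cluster = "C2", species = c("Pp", "Pp", "At"),
               gene = c("p3", "p4", "a2")))
  sf <- familyProfile(cl, "Pp")$size_frequency
  expect_equal(unname(sf["Pp", "2"]), 2L)  # two clusters of focal size 2
  expect_equal(unname(sf["At", "1"]), 2L)
})

test_that("orphan classification follows the rule table", {
  cl <- rbind(
    data.frame(cluster = "M", species = c("Pp", "At"), gene = c("p1", "a1")),
    data.frame(cluster = "O1", species = "Pp", gene = "p2"),
    data.frame(cluster = "O2", species = "Pp", gene = "p3"),
    data.frame(cluster = "O3", species = "Pp", gene = "p4"))
  hits <- data.frame(query = c("p1", "p3"))
  est <- data.frame(gene = c("p4"), est_supported = TRUE)
  oc <- classifyOrphans(cl, "Pp", hits, est)
  cls <- setNames(oc$class, oc$gene)
  expect_equal(unname(cls["p1"]), "has_plant_family")  # hits irrelevant
  expect_equal(unname(cls["p2"]), "orphan_no_homolog")
  expect_equal(unname(cls["p3"]), "focal_only_with_homolog")
  expect_equal(unname(cls["p4"]), "orphan_with_est")
})

lossFixture <- function(focalIntrons, otherIntrons = c(4, 6, 8),
                        focalLen = 1200, otherLen = 1200) {
  mk <- function(id, sp, n, len) {
    w <- rep(len %/% (n + 1), n + 1)
    w[1] <- w[1] + len - sum(w)
    s <- 1 + c(0, cumsum(w[-length(w)] + 100))
    Gene(id, Transcript(paste0(id, ".1"), id, scaffold = id, strand = "+",
                        exonStarts = s, exonEnds = s + w - 1))
  }
  focal <- Annotation(mk("pg1", "Pp", focalIntrons, focalLen), species = "Pp")
  others <- lapply(seq_along(otherIntrons), function(i)
    mk(paste0("og", i), "At", otherIntrons[i], otherLen))
  names(others) <- paste0("og", seq_along(otherIntrons))
  cl <- data.frame(cluster = "C1",
                   species = c("Pp", rep("At", length(otherIntrons))),
                   gene = c("pg1", names(others)))
  list(clusters = cl,
       annotations = list(Pp = focal,
                          At = Annotation(unname(others), species = "At")))
}

test_that("intron-loss calls follow the strict-median rule", {
  f <- lossFixture(0)           # median other introns = 6
  r <- inferIntronLoss(f$clusters, f$annotations, "Pp")
  expect_equal(r$per_gene$call, "full_loss")

  f4 <- lossFixture(4, otherIntrons = c(4, 4, 4))  # m = 4, strict less
  expect_equal(inferIntronLoss(f4$clusters, f4$annotations,
                               "Pp")$per_gene$call, "none")

  f3 <- lossFixture(3, otherIntrons = c(4, 4, 4))
  expect_equal(inferIntronLoss(f3$clusters, f3$annotations,
                               "Pp")$per_gene$call, "reduced_introns")

  # 300 nt focal vs 1,200 nt median at threshold 0.5 -> excluded
  ff <- lossFixture(0, focalLen = 300)
  rf <- inferIntronLoss(ff$clusters, ff$annotations, "Pp")
  expect_true(rf$calls$excluded_fragmentary)
  expect_equal(nrow(rf$per_gene), 0L)
  # a permissive threshold keeps it
  rf2 <- inferIntronLoss(ff$clusters, ff$annotations, "Pp",
                         lengthRatioThreshold = 0.1)
  expect_equal(rf2$per_gene$call, "full_loss")

  # unknown cluster member errors with its id
  bad <- f$clusters; bad$gene[1] <- "ghost"
  expect_error(inferIntronLoss(bad, f$annotations, "Pp"), "ghost")
})

test_that("removing introns never flips a call from reduced to none", {
  for (n in 5:0) {
    f <- lossFixture(n)
    call <- inferIntronLoss(f$clusters, f$annotations, "Pp")$per_gene$call
    if (n >= 6) expect_equal(call, "none")
    else if (n >= 1) expect_equal(call, "reduced_introns")
    else expect_equal(call, "full_loss")
  }
})

test_that("planted loss fractions are recovered exactly from simulated clusters", {
  sim <- simulateClusterSet(nClusters = 100, seed = 31, lossFraction = 0.14,
                            fullLossFraction = 0.03)
  r <- inferIntronLoss(sim$clusters, sim$annotations, "Pp")
  expect_equal(r$summary$fraction_reduced, 0.14)
  expect_equal(r$summary$fraction_full_loss, 0.03)
  planted <- sim$truth$gene[sim$truth$planted == "full_loss"]
  called <- r$per_gene$gene[r$per_gene$call == "full_loss"]
  expect_setequal(called, planted)   # precision and recall 1

  # no planted losses -> no calls
  sim0 <- simulateClusterSet(nClusters = 40, seed = 33, lossFraction = 0,
                             fullLossFraction = 0)
  r0 <- inferIntronLoss(sim0$clusters, sim0$annotations, "Pp")
  expect_equal(r0$summary$n_reduced, 0L)
})

test_that("fragmentary decoys are excluded, keeping planted recovery exact", {
  sim <- simulateClusterSet(nClusters = 50, seed = 35, lossFraction = 0.2,
                            fullLossFraction = 0.1, nFragmentary = 5)
  r <- inferIntronLoss(sim$clusters, sim$annotations, "Pp")
  expect_equal(r$summary$n_excluded_fragmentary, 5L)
  expect_equal(r$summary$n_reduced, 10L)
})

test_that("planted expansions are flagged exactly", {
  sim <- simulateClusterSet(nClusters = 30, seed = 37, lossFraction = 0,
                            fullLossFraction = 0, nExpanded = 5,
                            nStronglyExpanded = 2)
  f <- familyProfile(sim$clusters, "Pp")
  expect_equal(sum(f$profiles$expanded), 5L)
  expect_equal(sum(f$profiles$strongly_expanded), 2L)
})

test_that("family counts match a naive per-cluster recomputation", {
  sim <- simulateClusterSet(nClusters = 15, seed = 39, lossFraction = 0.2,
                            nExpanded = 3, nStronglyExpanded = 1)
  f <- familyProfile(sim$clusters, "Pp")
  for (cid in unique(sim$clusters$cluster)) {
    d <- sim$clusters[sim$clusters$cluster == cid, ]
    fn <- sum(d$species == "Pp")
    mo <- if (any(d$species != "Pp"))
      max(table(d$species[d$species != "Pp"])) else 0
    row <- f$profiles[f$profiles$cluster == cid, ]
    expect_equal(row$focal_n, fn)
    expect_equal(row$max_other_n, as.integer(mo))
    expect_equal(row$expanded, mo > 0 && fn > mo)
  }
})
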