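mkGoa <- function(gene, term, aspect = "BP", evidence = "IEA")
  data.frame(gene = gene, term = term, aspect = aspect, evidence = evidence,
             ref = "t", negated = FALSE, stringsAsFactors = FALSE)

test_that("slim mapping keeps minimal ancestors and is idempotent", {
  ont <- toyOntology()   # GO:1 is_a GO:2 is_a GO:3; GO:4 part_of GO:3
  # a slim term maps to itself
  m1 <- mapToSlim(mkGoa("g", "GO:0000002"), ont, "GO:0000002")
  expect_equal(m1$term, "GO:0000002")
  # both ancestors in the slim: only the nearer one is kept
  m2 <- mapToSlim(mkGoa("g", "GO:0000001"), ont,
                  c("GO:0000002", "GO:0000003"))
  expect_equal(m2$term, "GO:0000002")
  # part_of edges count as ancestry
  m3 <- mapToSlim(mkGoa("g", "GO:0000004", aspect = "CC"), ont, "GO:0000003")
  expect_equal(m3$term, "GO:0000003")
  # no slim ancestor, drop mode -> absent
  m4 <- mapToSlim(mkGoa("g", "GO:0000003"), ont, "GO:0000001")
  expect_equal(nrow(m4), 0L)
  # obsolete terms are dropped with a warning
  expect_warning(m5 <- mapToSlim(mkGoa("g", "GO:0000005"), ont,
                                 "GO:0000003"), "obsolete")
  expect_equal(nrow(m5), 0L)
  # idempotence
  goa <- rbind(mkGoa("g1", "GO:0000001"), mkGoa("g2", "GO:0000002"))
  once <- mapToSlim(goa, ont, c("GO:0000002", "GO:0000003"))
  twice <- mapToSlim(once, ont, c("GO:0000002", "GO:0000003"))
  expect_equal(once, twice)
})

p2gFixture <- function(compartments, tools = c("toolA", "toolB", "toolC"),
                       weights = 1, ntOnly = FALSE) {
  list(calls = data.frame(tool = tools, protein = "p1",
                          compartment = compartments,
                          stringsAsFactors = FALSE),
       tools = data.frame(tool = tools, weight = weights,
                          n_terminal_only = ntOnly,
                          stringsAsFactors = FALSE))
}

test_that("pred2goa assigns on strict weighted majority only", {
  map <- defaultCompartmentMap()
  # unanimous equal-weight vote on a complete protein
  f <- p2gFixture(rep("chloroplast", 3))
  r <- pred2goa(f$calls, f$tools, map)
  expect_equal(r$assignments$term, unname(map["chloroplast"]))
  expect_equal(r$assignments$weight_fraction, 1.0)
  expect_equal(r$assignments$evidence, "ISS")

  # 0.4 / 0.4 / 0.2 split over three compartments: no strict majority
  f2 <- p2gFixture(c("chloroplast", "mitochondrion", "secreted"),
                   weights = c(0.4, 0.4, 0.2))
  expect_equal(nrow(pred2goa(f2$calls, f2$tools, map)$assignments), 0L)

  # exactly half the weight is not a majority
  f3 <- p2gFixture(c("chloroplast", "mitochondrion"),
                   tools = c("toolA", "toolB"))
  expect_equal(nrow(pred2goa(f3$calls, f3$tools, map)$assignments), 0L)
})

test_that("incomplete proteins need a non-N-terminal supporter", {
  map <- defaultCompartmentMap()
  incomplete <- data.frame(protein = "p1", complete = FALSE)
  fNt <- p2gFixture(rep("chloroplast", 3), ntOnly = TRUE)
  r <- pred2goa(fNt$calls, fNt$tools, map, completeness = incomplete)
  expect_equal(nrow(r$assignments), 0L)

  fMix <- p2gFixture(rep("chloroplast", 3), ntOnly = c(TRUE, TRUE, FALSE))
  r2 <- pred2goa(fMix$calls, fMix$tools, map, completeness = incomplete)
  expect_equal(nrow(r2$assignments), 1L)
  # the same calls on a complete protein are never gated
  r3 <- pred2goa(fNt$calls, fNt$tools, map)
  expect_equal(nrow(r3$assignments), 1L)
})

test_that("pred2goa merges with existing annotations and validates labels", {
  map <- defaultCompartmentMap()
  f <- p2gFixture(rep("nucleus", 3))
  existing <- mkGoa("p1", "GO:0000001")
  r <- pred2goa(f$calls, f$tools, map, existingGoa = existing)
  expect_setequal(r$goa$term, c("GO:0000001", unname(map["nucleus"])))

  bad <- f$calls; bad$compartment[2] <- "spaceship"
  expect_error(pred2goa(bad, f$tools, map), "spaceship")
  badW <- f$tools; badW$weight[1] <- 0
  expect_error(pred2goa(f$calls, badW, map), "positive")
})

test_that("unanimous accurate predictors recover all planted localizations", {
  sim <- simulatePredictorCalls(nProteins = 40, accuracy = 1, seed = 51)
  r <- pred2goa(sim$calls, sim$tools, sim$compartmentMap)
  expect_equal(nrow(r$assignments), 40L)
  expected <- unname(sim$compartmentMap[sim$truth$compartment])
  got <- r$assignments$term[match(sim$truth$protein, r$assignments$protein)]
  expect_equal(got, expected)
})

test_that("GOA summaries count non-redundantly and compute coverage", {
  goa <- rbind(mkGoa("g1", "GO:1"), mkGoa("g1", "GO:1"),   # duplicate row
               mkGoa("g1", "GO:2", aspect = "MF"),
               mkGoa("g2", "GO:3", aspect = "CC"))
  s <- goaSummary(goa, totalGenes = 4)
  expect_equal(unname(s$term_counts[["total"]]), 3)
  expect_equal(unname(s$genes_with_term[["total"]]), 2)
  expect_equal(s$coverage, 0.5)
  # the published coverage arithmetic: 18,786 of 32,275 loci ~ 58%
  expect_equal(round(18786 / 32275 * 100), 58)
  expect_equal(goaSummary(NULL, 10)$coverage, 0)
  # NOT-qualified annotations never count
  notg <- mkGoa("g9", "GO:9"); notg$negated <- TRUE
  expect_equal(goaSummary(notg, 10)$coverage, 0)
})

test_that("enrichment handles equal frequencies and one-sided extremes", {
  gf <- mkGoa(sprintf("f%03d", 1:10), "GO:X")
  go <- mkGoa(sprintf("o%03d", 1:20), "GO:X")
  r <- termEnrichment(gf, go, c(focal = 100, other = 200))
  expect_equal(r$odds_ratio, 1, tolerance = 1e-9)
  expect_gte(r$p_focal, 0.5)

  # focal-only term: finite one-sided p in the focal direction
  gf2 <- mkGoa(sprintf("f%03d", 1:50), "GO:Y")
  go2 <- mkGoa("o001", "GO:Z")
  r2 <- termEnrichment(gf2, go2, c(focal = 2000, other = 2000))
  ry <- r2[r2$term == "GO:Y", ]
  expect_true(is.finite(ry$log10_p_focal))
  expect_lt(ry$p_focal, 0.05)
  expect_gt(ry$odds_ratio, 1)
})

test_that("focal-enrichment p never increases with the focal count", {
  p <- vapply(5:30, function(a)
    twoProportionExactTest(a, 100, 10, 200)$p_greater, numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("planted enrichment is recovered with controlled null discoveries", {
  sim <- simulateGoaPair(nTerms = 100, nPlanted = 1, fold = 4,
                         universeSize = 1000, seed = 53)
  r <- termEnrichment(sim$goaFocal, sim$goaOther, sim$universes)
  expect_lt(r$q[r$term == sim$plantedTerms], 0.05)
  nullQ <- r$q[!(r$term %in% sim$plantedTerms)]
  expect_lte(mean(nullQ < 0.05), 0.05)
  expect_true(all(r$q >= r$p_focal - 1e-12))
})
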