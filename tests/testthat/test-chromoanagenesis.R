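transloc <- function(id, chA, pA, chB, pB) data.frame(
  id = id, chromA = chA, posA = pA, strandA = "+",
  chromB = chB, posB = pB, strandB = "-", svType = "inter_translocation",
  stringsAsFactors = FALSE)

test_that("adjacency edges require proximity or a deletion bridge", {
  svs <- SVCallSet(rbind(transloc("a", "1", 1e6, "2", 5e6),
                         transloc("b", "1", 1e6 + 1e4, "3", 7e6)))
  g <- breakendAdjacencyGraph(svs, maxGap = 33000)
  adj <- igraph::E(g)[igraph::edge_attr(g, "type") == "adjacency"]
  expect_equal(length(adj), 1)   # 10 kb apart on chr1
  expect_false(any(igraph::edge_attr(g, "bridge",
                                     igraph::E(g))[igraph::edge_attr(g, "type") == "adjacency"]))

  far <- SVCallSet(rbind(transloc("a", "1", 1e6, "2", 5e6),
                         transloc("b", "1", 1.1e6, "3", 7e6)))
  g2 <- breakendAdjacencyGraph(far, maxGap = 33000)
  expect_equal(sum(igraph::edge_attr(g2, "type") == "adjacency"), 0)

  # the same 100 kb gap becomes linkable when a deletion spans it
  del <- CNVSegmentSet(data.frame(chrom = "1", start = 0.99e6, end = 1.11e6, cn = 1))
  g3 <- breakendAdjacencyGraph(far, maxGap = 33000, deletions = del)
  adjIdx <- which(igraph::edge_attr(g3, "type") == "adjacency")
  expect_equal(length(adjIdx), 1)
  expect_true(all(igraph::edge_attr(g3, "bridge", igraph::E(g3)[adjIdx])))
})

test_that("chromoplexy chains need three chromosomes and honor bridges", {
  # closed loop t(1;2) + t(2;3) + t(3;1) with tight same-chromosome gaps
  loop <- SVCallSet(rbind(
    transloc("j12", "1", 1.000e6, "2", 2.000e6),
    transloc("j23", "2", 2.010e6, "3", 3.000e6),
    transloc("j31", "3", 3.012e6, "1", 1.008e6)))
  ch <- detectChromoplexy(loop)
  expect_equal(length(ch), 1)
  expect_equal(ch[[1]]$svIds, c("j12", "j23", "j31"))
  expect_equal(ch[[1]]$chromosomes, c("1", "2", "3"))
  expect_true(ch[[1]]$closed)

  # a reciprocal two-chromosome pair is not chromoplexy
  recip <- SVCallSet(rbind(transloc("f", "1", 1e6, "2", 2e6),
                           transloc("r", "1", 1.005e6, "2", 2.004e6)))
  expect_equal(length(detectChromoplexy(recip)), 0)

  # 4-chromosome open chain, one long gap rescued by a deletion bridge
  open4 <- SVCallSet(rbind(
    transloc("a", "1", 1.000e6, "2", 2.000e6),
    transloc("b", "2", 2.015e6, "3", 3.000e6),
    transloc("c", "3", 3.200e6, "5", 4.000e6)))   # 200 kb gap on chr3
  del <- CNVSegmentSet(data.frame(chrom = "3", start = 2.99e6, end = 3.21e6, cn = 1))
  ch4 <- detectChromoplexy(open4, deletions = del)
  expect_equal(length(ch4), 1)
  expect_equal(ch4[[1]]$svIds, c("a", "b", "c"))
  expect_equal(length(ch4[[1]]$chromosomes), 4)
  expect_equal(ch4[[1]]$deletionBridges, 1)
  expect_false(ch4[[1]]$closed)
  # without the bridge the chain breaks at the chr3 gap: the remaining
  # linked pair t(1;2)+t(2;3) still spans three chromosomes on its own
  noBridge <- detectChromoplexy(open4)
  expect_equal(length(noBridge), 1)
  expect_equal(noBridge[[1]]$svIds, c("a", "b"))
})

test_that("chain detection equals exhaustive enumeration on random instances", {
  for (seed in 1:60) {
    svs <- randomSVInstance(seed)
    impl <- detectChromoplexy(svs, maxGap = 33000)
    implSets <- lapply(impl, `[[`, "svIds")
    implSets <- implSets[order(vapply(implSets, paste, "", collapse = "|"))]
    oracle <- oracleChains(svCalls(svs), maxGap = 33000)
    expect_identical(implSets, oracle, label = paste("seed", seed))
  }
})

test_that("chromothripsis calls require count, CN coexistence, interspersion and uniformity", {
  g <- makeToyGenome(1)
  sizes <- toyChromSizes()
  pos <- simulateCase(g, simScenario("MDM2_AMPLICON_CT", nBackgroundSVs = 0), 5)
  rg <- detectChromothripsis(pos$svs, pos$cnvs, chromSizes = sizes)
  expect_equal(length(rg), 1)
  expect_equal(rg[[1]]$chrom, "12")
  expect_gt(rg[[1]]$nRearrangements, 7)
  expect_gte(length(rg[[1]]$cnStates), 2)
  expect_true(rg[[1]]$interspersionPass)
  # truth span contains the detected region
  expect_gte(rg[[1]]$start, pos$truth$region$start - 1)
  expect_lte(rg[[1]]$end, pos$truth$region$end + 1e6 + 1)

  # same junctions without copy-number change: nothing
  expect_equal(length(detectChromothripsis(pos$svs, CNVSegmentSet(),
                                           chromSizes = sizes)), 0)

  # exactly seven junctions: "more than seven" is strict
  seven <- simulateCase(g, simScenario("MDM2_AMPLICON_CT", nBackgroundSVs = 0,
                                       ctRearrangements = 7), 5)
  expect_equal(length(detectChromothripsis(seven$svs, seven$cnvs,
                                           chromSizes = sizes)), 0)

  # junctions piled into 1% of the copy-number-affected span: interspersion fails
  set.seed(2)
  p1 <- runif(20, 40e6, 40.3e6)
  clustered <- SVCallSet(data.frame(
    id = sprintf("c%02d", 1:20), chromA = "12", posA = round(p1),
    strandA = "+", chromB = "12", posB = round(p1 + runif(20, 1e3, 2e5)),
    strandB = "+", svType = "inversion"))
  osc <- CNVSegmentSet(data.frame(chrom = "12", start = seq(26e6, 53e6, 3e6),
                                  end = seq(29e6, 56e6, 3e6), cn = rep(c(2, 8), 5)))
  expect_equal(length(detectChromothripsis(clustered, osc, chromSizes = sizes)), 0)
})

test_that("region detection is threshold-monotone and stable under reruns", {
  g <- makeToyGenome(1)
  sizes <- toyChromSizes()
  for (seed in c(3, 9, 21)) {
    cs <- simulateCase(g, simScenario("MDM2_AMPLICON_CT"), seed)
    last <- Inf
    for (mr in c(5, 8, 15, 25)) {
      n <- length(detectChromothripsis(cs$svs, cs$cnvs, minRearr = mr,
                                       chromSizes = sizes))
      expect_lte(n, last)
      last <- n
    }
    a <- detectChromothripsis(cs$svs, cs$cnvs, chromSizes = sizes)
    b <- detectChromothripsis(cs$svs, cs$cnvs, chromSizes = sizes)
    expect_identical(a, b)
  }
})

test_that("case classification follows the chain/region combination", {
  chain <- list(list(svIds = "x"))
  region <- list(list(chrom = "12"))
  expect_equal(classifyChromoanagenesis(chain, list()), "CHROMOPLEXY")
  expect_equal(classifyChromoanagenesis(list(), region), "CHROMOTHRIPSIS")
  expect_equal(classifyChromoanagenesis(chain, region), "BOTH")
  expect_equal(classifyChromoanagenesis(list(), list()), "NONE")
})
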