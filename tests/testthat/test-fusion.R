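# orientation logic is checked against a brute-force enumeration of
# derivative-chromosome readings (helper-oracles.R)

test_that("orientation compatibility matches derivative-reading enumeration (inter)", {
  chromLens <- c("1" = 10000, "2" = 10000)
  for (gsA in c("+", "-")) for (gsB in c("+", "-")) {
    genes <- miniFusionGenes(gsA, gsB)
    panel <- GenePanel(cbind(genes, role = "fusion_partner"))
    for (sA in c("+", "-")) for (sB in c("+", "-")) {
      sv <- list(chromA = "1", posA = 4500, strandA = sA,
                 chromB = "2", posB = 5500, strandB = sB)
      oracle <- oracleFusionPairs(sv, genes, chromLens)
      f <- inferFusions(SVCallSet(data.frame(
        id = "s", chromA = "1", posA = 4500, strandA = sA,
        chromB = "2", posB = 5500, strandB = sB,
        svType = "inter_translocation")), panel)
      impl <- if (nrow(f)) sort(paste(f$fivePrime, f$threePrime, sep = ">"))
              else character()
      expect_identical(impl, oracle,
                       label = paste("genes", gsA, gsB, "breakends", sA, sB))
    }
  }
})

test_that("adjacent opposite-strand pair fuses through inversion, not deletion", {
  # same-chromosome configuration of the NAB2/STAT6 kind
  genes <- data.frame(symbol = c("GA", "GB"), chrom = "1",
                      start = c(3000, 5000), end = c(4500, 6500),
                      strand = c("+", "-"), stringsAsFactors = FALSE)
  panel <- GenePanel(cbind(genes, role = "fusion_partner"))
  chromLens <- c("1" = 10000)
  res <- list()
  for (sA in c("+", "-")) for (sB in c("+", "-")) {
    sv <- list(chromA = "1", posA = 3700, strandA = sA,
               chromB = "1", posB = 5700, strandB = sB)
    f <- inferFusions(SVCallSet(data.frame(
      id = "s", chromA = "1", posA = 3700, strandA = sA, chromB = "1",
      posB = 5700, strandB = sB,
      svType = if (sA == sB) "inversion" else "deletion")), panel)
    impl <- if (nrow(f)) sort(paste(f$fivePrime, f$threePrime, sep = ">"))
            else character()
    expect_identical(impl, oracleFusionPairs(sv, genes, chromLens))
    res[[paste0(sA, sB)]] <- impl
  }
  # deletion-type orientations produce nothing; inversions fuse, and
  # flipping both orientations swaps the partner order
  expect_identical(res[["+-"]], character())
  expect_identical(res[["-+"]], character())
  expect_identical(res[["++"]], "GA>GB")
  expect_identical(res[["--"]], "GB>GA")
})

test_that("simulated fusion scenarios reproduce the orientation requirement", {
  g <- makeToyGenome(1)
  panel <- sarcomaGenePanel()
  inv <- simulateCase(g, simScenario("SIMPLE_FUSION", nBackgroundSVs = 0), 7)
  f <- inferFusions(inv$svs, panel, bands = toyCytobands())
  expect_equal(f$fivePrime, "NAB2")
  expect_equal(f$threePrime, "STAT6")
  expect_equal(f$mechanism, "inversion")
  expect_match(f$iscn, "^inv\\(12\\)")

  del <- simulateCase(g, simScenario("SIMPLE_FUSION", nBackgroundSVs = 0,
                                     fusionMechanism = "deletion"), 7)
  expect_equal(nrow(inferFusions(del$svs, panel)), 0)
  expect_null(inferFusion(svCalls(del$svs), panel))

  mn1 <- simulateCase(g, simScenario("SIMPLE_FUSION", nBackgroundSVs = 0,
                                     fusionPair = c("MN1", "CXXC5")), 3)
  f2 <- inferFusions(mn1$svs, panel, bands = toyCytobands())
  expect_equal(f2$fivePrime, "MN1")
  expect_equal(f2$iscn, "t(5;22)(q31.2;q12.1)")
})

test_that("compatibility is invariant under flipping all strands", {
  chromLens <- c("1" = 10000, "2" = 10000)
  set.seed(5)
  for (i in 1:20) {
    gsA <- sample(c("+", "-"), 1); gsB <- sample(c("+", "-"), 1)
    sA <- sample(c("+", "-"), 1); sB <- sample(c("+", "-"), 1)
    mk <- function(gsA, gsB, sA, sB) {
      genes <- miniFusionGenes(gsA, gsB)
      f <- inferFusions(SVCallSet(data.frame(
        id = "s", chromA = "1", posA = 4500, strandA = sA, chromB = "2",
        posB = 5500, strandB = sB, svType = "inter_translocation")),
        GenePanel(cbind(genes, role = "fusion_partner")))
      nrow(f) > 0
    }
    flip <- function(s) if (s == "+") "-" else "+"
    expect_equal(mk(gsA, gsB, sA, sB),
                 mk(flip(gsA), flip(gsB), flip(sA), flip(sB)))
  }
})

test_that("intergenic breakends yield no fusion; gene hits yield rearrangements", {
  panel <- sarcomaGenePanel()
  inter <- SVCallSet(data.frame(id = "s", chromA = "1", posA = 100,
                                strandA = "+", chromB = "2", posB = 100,
                                strandB = "-", svType = "inter_translocation"))
  expect_equal(nrow(inferFusions(inter, panel)), 0)
  expect_equal(nrow(geneRearrangements(inter, panel)), 0)

  g <- panelGenes(panel)
  phf1 <- g[g$symbol == "PHF1", ]
  hit <- SVCallSet(data.frame(id = "r1", chromA = phf1$chrom,
                              posA = (phf1$start + phf1$end) / 2, strandA = "+",
                              chromB = phf1$chrom, posB = phf1$end + 5e6,
                              strandB = "+", svType = "inversion"))
  rr <- geneRearrangements(hit, panel)
  expect_equal(rr$gene, "PHF1")
  expect_equal(rr$svId, "r1")
})
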