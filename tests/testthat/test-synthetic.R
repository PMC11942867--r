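test_that("toy genomes are deterministic with label density in the motif band", {
  g1 <- makeToyGenome(seed = 1)
  g2 <- makeToyGenome(seed = 1)
  expect_identical(g1@labels, g2@labels)
  expect_false(identical(g1@labels, makeToyGenome(seed = 2)@labels))

  dens <- labelDensity(g1)
  expect_true(all(dens >= 14 & dens <= 17))

  # expectation check on a single chromosome: ~15 labels / 100 kbp
  n12 <- length(g1@labels[["12"]])
  expect_lt(abs(n12 - 15 * 600), 3 * sqrt(15 * 600) + 0.04 * 15 * 600)

  # genes live inside chromosome bounds and the panel covers the rule genes
  p <- panelGenes(g1@genes)
  expect_true(all(p$end <= toyChromSizes()[p$chrom]))
  expect_true(all(c("MDM2", "CDK4", "HMGA2", "NAB2", "STAT6", "MN1", "CXXC5",
                    "SRSF3", "USP6", "OGA", "TGFBR3", "VGLL3", "TP53", "RB1",
                    "CDKN2A", "CDKN2B", "PHF1", "COL6A3", "CSF1")
                  %in% p$symbol))
  # NAB2/STAT6 analogs: adjacent, opposite strands
  nab2 <- p[p$symbol == "NAB2", ]; stat6 <- p[p$symbol == "STAT6", ]
  expect_equal(nab2$chrom, stat6$chrom)
  expect_true(nab2$strand != stat6$strand)
  expect_lt(abs(stat6$start - nab2$end), 5e4)
})

test_that("simulated cases are seed-deterministic with coherent truth labels", {
  g <- makeToyGenome(1)
  for (kind in c("QUIET", "SIMPLE_FUSION", "MDM2_AMPLICON_CT",
                 "CHROMOPLEXY_CHAIN", "MIXED")) {
    sc <- simScenario(kind)
    a <- simulateCase(g, sc, 42)
    b <- simulateCase(g, sc, 42)
    expect_identical(svCalls(a$svs), svCalls(b$svs))
    expect_identical(cnvSegments(a$cnvs), cnvSegments(b$cnvs))
    expect_identical(a$qc, b$qc)
    expect_identical(a$truth, b$truth)
    expect_equal(a$truth$kind, kind)
  }
  expect_error(simScenario("CHROMOPLEXY_CHAIN", chainChromosomes = 2),
               "at least 3")
})

test_that("injected events satisfy their detectors at default thresholds", {
  g <- makeToyGenome(1)
  sizes <- toyChromSizes()
  # chromoplexy chains are recovered, including the injected sv ids
  for (seed in c(7, 19, 33)) {
    cs <- simulateCase(g, simScenario("CHROMOPLEXY_CHAIN", chainChromosomes = 3,
                                      nBackgroundSVs = 0), seed)
    ch <- detectChromoplexy(cs$svs, deletions = cs$cnvs)
    expect_equal(length(ch), 1)
    expect_identical(ch[[1]]$svIds, sort(cs$truth$chain$svIds))
    expect_setequal(ch[[1]]$chromosomes, cs$truth$chain$chromosomes)
  }
  # the amplicon scenario yields exactly one region on the 12-like chromosome
  cs <- simulateCase(g, simScenario("MDM2_AMPLICON_CT", nBackgroundSVs = 0), 3)
  rg <- detectChromothripsis(cs$svs, cs$cnvs, chromSizes = sizes)
  expect_equal(length(rg), 1)
  expect_equal(rg[[1]]$chrom, "12")
  # and its amplicon drives an MDM2-analog amplification call
  ev <- callGeneCNV(cs$cnvs, g@genes)
  expect_true(any(ev$gene == "MDM2" & ev$event == "amplification"))
})

test_that("per-tissue QC draws are deterministic and respect the mixture", {
  a <- simulateQC("bone", seed = 5, n = 10)
  b <- simulateQC("bone", seed = 5, n = 10)
  expect_identical(a, b)
  expect_true(all(a$map_rate_pct >= 0 & a$map_rate_pct <= 100))
  # small-n sanity on rates (full-n calibration is exercised in acceptance)
  ad <- simulateQC("adipocytic", seed = 11, n = 200)
  expect_gt(mean(ad$evaluable), 0.40)
  expect_lt(mean(ad$evaluable), 0.75)
  expect_error(simulateQC("liver", seed = 1), "arg")
})

test_that("the bundled cohort fixture is internally consistent", {
  fx <- cohortFixture()
  expect_equal(nrow(fx), 33)
  expect_equal(fx$total_dna_gbp[fx$case_id == "8"], 640.20)
  expect_equal(fx$effective_coverage[fx$case_id == "8"], 107.44)
  expect_false(fx$detected[fx$case_id == "33"])
  expect_equal(fx$detection_tier[fx$case_id == "36"], "DENOVO")
  # every rule text parses under the closed grammar
  for (r in fx$expected_rule) expect_silent(parseAlterationRule(r))
  # refined cases cross-reference the reclassification worked examples
  rc <- reclassifiedCasesFixture()
  expect_setequal(rc$case_id, fx$case_id[fx$refined])
  ev <- evaluabilityFixture()
  expect_equal(sum(ev$n_total), 53)
  expect_equal(sum(ev$n_evaluable), 33)
})
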