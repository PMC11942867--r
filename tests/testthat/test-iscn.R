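test_that("cytoband assignment is half-open containment", {
  bands <- CytobandTable(data.frame(
    chrom = "6", start = c(0, 10e6, 12e6), end = c(10e6, 12e6, 20e6),
    band = c("p22", "p21.31", "p11")))
  expect_equal(assignCytoband("6", 11e6, bands), "p21.31")
  expect_equal(assignCytoband("chr6", 10e6, bands), "p21.31")  # boundary
  expect_equal(assignCytoband("6", 12e6, bands), "p11")
  expect_error(assignCytoband("6", 25e6, bands), "not covered")

  # bundled synthetic table: the MDM2-analog locus sits on 12q15
  g <- panelGenes(sarcomaGenePanel())
  mdm2 <- g[g$symbol == "MDM2", ]
  expect_equal(assignCytoband("12", mdm2$start, toyCytobands()), "q15")
})

test_that("ISCN strings follow the emitted grammar with karyotypic ordering", {
  expect_equal(formatISCN(list(kind = "translocation", chromA = "17",
                               bandA = "p13.2", chromB = "6", bandB = "p21.31")),
               "t(6;17)(p21.31;p13.2)")
  expect_equal(formatISCN(list(kind = "translocation", chromA = "5",
                               bandA = "q31.2", chromB = "22", bandB = "q12.1")),
               "t(5;22)(q31.2;q12.1)")
  expect_equal(formatISCN(list(kind = "translocation", chromA = "1",
                               bandA = "p22", chromB = "10", bandB = "q24")),
               "t(1;10)(p22;q24)")
  expect_equal(formatISCN(list(kind = "monosomy", chrom = "13")), "-13")
  expect_equal(formatISCN(list(kind = "inversion", chrom = "12",
                               bandStart = "q13.3", bandEnd = "q13.3")),
               "inv(12)(q13.3q13.3)")
  expect_equal(formatISCN(list(kind = "amplification", gene = "MDM2",
                               chrom = "12", band = "q15")),
               "amp(MDM2)(12q15)")
  expect_error(formatISCN(list(kind = "ring")), "unknown event kind")
})

test_that("the emitted grammar round-trips through its parser", {
  evs <- list(
    list(kind = "translocation", chromA = "6", bandA = "p21.31",
         chromB = "17", bandB = "p13.2"),
    list(kind = "translocation", chromA = "5", bandA = "q31.2",
         chromB = "22", bandB = "q12.1"),
    list(kind = "inversion", chrom = "12", bandStart = "q13.3",
         bandEnd = "q14.1"),
    list(kind = "monosomy", chrom = "13"),
    list(kind = "amplification", gene = "MDM2", chrom = "12", band = "q15"))
  for (ev in evs) {
    back <- parseISCN(formatISCN(ev))
    expect_equal(back[sort(names(back))], ev[sort(names(ev))])
  }
})

test_that("expected-alteration matching follows the rule grammar and tiers", {
  events <- list(
    fusions = data.frame(fivePrime = "STAT6", threePrime = "NAB2",
                         svId = "s1", compatible = TRUE,
                         mechanism = "inversion", tier = "DENOVO",
                         iscn = NA, stringsAsFactors = FALSE),
    geneCNV = data.frame(gene = "MDM2", event = "amplification", cn = 12,
                         homozygous = FALSE, chrom = "12", segStart = 0,
                         segEnd = 1, overlapBp = 1, tier = "RVA",
                         stringsAsFactors = FALSE),
    rearrangements = data.frame(gene = "PHF1", svId = "s2",
                                svType = "inversion", tier = "RVA",
                                stringsAsFactors = FALSE),
    svs = SVCallSet(), cnvs = CNVSegmentSet())

  # fusion match is order-insensitive and keeps the De Novo tier
  m <- matchExpected(alterationRule("fusion", "NAB2", "STAT6"), events)
  expect_true(m$detected)
  expect_equal(m$tier, "DENOVO")
  expect_true(matchExpected(alterationRule("amplification", "MDM2"), events)$detected)
  expect_equal(matchExpected(alterationRule("amplification", "MDM2"), events)$tier, "RVA")
  expect_true(matchExpected(alterationRule("gene_rearrangement", "PHF1"), events)$detected)
  miss <- matchExpected(alterationRule("fusion", "COL6A3", "CSF1"), events)
  expect_false(miss$detected)
  expect_equal(miss$tier, "NONE")
  # cnv_sv_any needs at least one surviving prioritized variant
  expect_false(matchExpected(alterationRule("cnv_sv_any"), events)$detected)
  events$svs <- SVCallSet(data.frame(id = "d", chromA = "1", posA = 1e6,
                                     strandA = "+", chromB = "1", posB = 2e6,
                                     strandB = "-", svType = "deletion"))
  expect_true(matchExpected(alterationRule("cnv_sv_any"), events)$detected)

  # an incompatible fusion call never satisfies a fusion rule
  events$fusions$compatible <- FALSE
  expect_false(matchExpected(alterationRule("fusion", "NAB2", "STAT6"),
                             events)$detected)
})

test_that("matching is monotone in events", {
  base <- list(fusions = NULL, geneCNV = NULL, rearrangements = NULL,
               svs = SVCallSet(), cnvs = CNVSegmentSet())
  rules <- list(alterationRule("fusion", "NAB2", "STAT6"),
                alterationRule("amplification", "MDM2"),
                alterationRule("cnv_sv_any"))
  richer <- base
  richer$fusions <- data.frame(fivePrime = "NAB2", threePrime = "STAT6",
                               svId = "s", compatible = TRUE,
                               mechanism = "inversion", tier = "RVA",
                               iscn = NA, stringsAsFactors = FALSE)
  richer$geneCNV <- data.frame(gene = "MDM2", event = "amplification", cn = 8,
                               homozygous = FALSE, chrom = "12", segStart = 0,
                               segEnd = 1, overlapBp = 1, tier = "RVA",
                               stringsAsFactors = FALSE)
  richer$svs <- SVCallSet(data.frame(id = "d", chromA = "1", posA = 1e6,
                                     strandA = "+", chromB = "1", posB = 2e6,
                                     strandB = "-", svType = "deletion"))
  for (rule in rules) {
    before <- matchExpected(rule, base)$detected
    after <- matchExpected(rule, richer)$detected
    expect_true(!before || after)   # adding events never un-detects
    expect_true(after)
  }
  expect_error(matchExpected(list(form = "weird"), base), "unknown rule form")
})

test_that("rule text parses back to the constructor form", {
  for (txt in c("fusion(FUS,DDIT3)", "amplification(MDM2)",
                "gene_rearrangement(PHF1)", "cnv_sv_any")) {
    expect_equal(formatAlterationRule(parseAlterationRule(txt)), txt)
  }
  expect_error(parseAlterationRule("fusion(ONLYONE)"), "2 gene argument")
  expect_error(alterationRule("fusion", "A"), "2 gene argument")
})
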