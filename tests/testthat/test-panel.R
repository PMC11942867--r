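mkSVs <- function(sizes, inter = 0) {
  rows <- lapply(seq_along(sizes), function(i) data.frame(
    id = paste0("s", i), chromA = "1", posA = 1e6 * i, strandA = "+",
    chromB = "1", posB = 1e6 * i + sizes[i], strandB = "-",
    svType = "deletion", vaf = 0.3, stringsAsFactors = FALSE))
  if (inter > 0) for (k in seq_len(inter)) rows[[length(rows) + 1]] <-
    data.frame(id = paste0("t", k), chromA = "1", posA = 5e6 + k, strandA = "+",
               chromB = "2", posB = 5e6, strandB = "-",
               svType = "inter_translocation", vaf = 0.3,
               stringsAsFactors = FALSE)
  SVCallSet(do.call(rbind, rows))
}

test_that("size prioritization keeps junctions above 500 bp plus all inter events", {
  svs <- mkSVs(c(100, 499, 501, 10000), inter = 1)
  out <- filterVariants(svs, CNVSegmentSet())
  expect_equal(length(out$svs), 3)
  kept <- svCalls(out$svs)$id
  expect_setequal(kept, c("s3", "s4", "t1"))
  # a 300 bp deletion is removed; an inter junction with size 0 is retained
  expect_false("s1" %in% kept)
  cnv <- CNVSegmentSet(data.frame(chrom = "1", start = c(0, 1e4),
                                  end = c(400, 1e4 + 5e5), cn = c(1, 6)))
  out2 <- filterVariants(svs, cnv)
  expect_equal(nrow(cnvSegments(out2$cnvs)), 1)
})

test_that("VAF floors drop only records with a known low VAF", {
  df <- svCalls(mkSVs(c(1000, 2000, 3000)))
  df$vaf <- c(0.02, NA, 0.3)
  out <- filterVariants(SVCallSet(df), CNVSegmentSet(), minVAF = 0.05)
  expect_setequal(svCalls(out$svs)$id, c("s2", "s3"))
})

test_that("raising size thresholds never increases retained counts", {
  set.seed(7)
  svs <- mkSVs(round(exp(runif(30, log(100), log(1e6)))), inter = 3)
  cnv <- CNVSegmentSet(data.frame(chrom = "1", start = seq(0, 29e6, 1e6),
                                  end = seq(0, 29e6, 1e6) + round(exp(runif(30, 5, 13))),
                                  cn = rep(c(1, 6), 15)))
  last <- Inf
  for (th in c(0, 500, 5000, 50000, 5e5)) {
    out <- filterVariants(svs, cnv, minSVSize = th, minCNVSize = th)
    n <- length(out$svs) + nrow(cnvSegments(out$cnvs))
    expect_lte(n, last)
    last <- n
  }
})

test_that("gene-level CNV calls pick one event per gene with the extreme segment", {
  panel <- sarcomaGenePanel()
  mdm2 <- panelGenes(panel)[panelGenes(panel)$symbol == "MDM2", ]
  amp <- CNVSegmentSet(data.frame(chrom = "12", start = mdm2$start - 1e6,
                                  end = mdm2$end + 1e6, cn = 12))
  ev <- callGeneCNV(amp, panel)
  expect_equal(ev$gene, "MDM2")
  expect_equal(ev$event, "amplification")
  expect_equal(ev$cn, 12)
  expect_gte(ev$overlapBp, 1)

  # neutral segment: no event
  expect_equal(nrow(callGeneCNV(CNVSegmentSet(
    data.frame(chrom = "12", start = 0, end = 6e7, cn = 2)), panel)), 0)

  # two qualifying segments over one gene: the larger |cn - ploidy| wins
  rb1 <- panelGenes(panel)[panelGenes(panel)$symbol == "RB1", ]
  two <- CNVSegmentSet(data.frame(
    chrom = "13", start = c(rb1$start - 10, rb1$start + 1000),
    end = c(rb1$start + 500, rb1$end + 10), cn = c(1, 0)))
  ev2 <- callGeneCNV(two, panel)
  expect_equal(ev2$gene, "RB1")
  expect_equal(ev2$cn, 0)
  expect_true(ev2$homozygous)
})

test_that("gene-event output is independent of segment order and panel-restricted", {
  panel <- sarcomaGenePanel()
  set.seed(11)
  segs <- data.frame(chrom = sample(c("12", "13", "17", "9"), 40, TRUE),
                     start = round(runif(40, 0, 3e7)), cn = sample(0:12, 40, TRUE))
  segs$end <- segs$start + round(runif(40, 1e4, 5e6))
  a <- callGeneCNV(CNVSegmentSet(segs), panel)
  b <- callGeneCNV(CNVSegmentSet(segs[sample(nrow(segs)), ]), panel)
  expect_equal(a, b)
  expect_true(all(a$gene %in% panelGenes(panel)$symbol))
})

test_that("monosomy calls require near-complete loss coverage", {
  sz <- toyChromSizes()
  full <- CNVSegmentSet(data.frame(chrom = "13", start = 0, end = sz[["13"]], cn = 1))
  expect_equal(callMonosomy(full, sz)$chrom, "13")
  half <- CNVSegmentSet(data.frame(chrom = "13", start = 0, end = 0.5 * sz[["13"]], cn = 1))
  expect_equal(nrow(callMonosomy(half, sz)), 0)
  # two segments jointly covering 95% (union, overlap not double-counted)
  two <- CNVSegmentSet(data.frame(chrom = "13", start = c(0, 0.4 * sz[["13"]]),
                                  end = c(0.5 * sz[["13"]], 0.95 * sz[["13"]]),
                                  cn = c(1, 0)))
  out <- callMonosomy(two, sz)
  expect_equal(out$chrom, "13")
  expect_equal(out$coveredFraction, 0.95, tolerance = 1e-6)
  expect_equal(out$minCN, 0)
})
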