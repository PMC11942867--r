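## Synthetic toy genome and scenario-structured cohort simulator.
##
## The toy genome is a scaled-down karyotype (16 chromosomes, 25-60 Mb each)
## carrying analogs of the sarcoma genes the interpretation modules care
## about: an adjacent opposite-strand NAB2/STAT6 pair, an MDM2/CDK4/HMGA2
## cluster on the 12q-like arm, fusion partners on distinct chromosomes, and
## tumor suppressors. Label positions emulate CTTAAG-motif labeling at
## 14-17 labels per 100 kbp. Everything is deterministic given a seed.

## evaluate expr under a seed, restoring the caller's RNG state afterwards
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

.TOY_SIZES_MB <- c("1" = 60, "2" = 55, "3" = 50, "5" = 50, "6" = 45,
                   "9" = 40, "10" = 45, "11" = 40, "12" = 60, "13" = 35,
                   "16" = 30, "17" = 30, "18" = 30, "21" = 25, "22" = 25,
                   "X" = 40)

## band layout per chromosome: name + breakpoints in Mb from pter
.TOY_BANDS_MB <- list(
  "1" = list(bands = c("p36", "p22", "p13.3", "p11", "q11", "q23.1", "q32"),
             breaks = c(0, 8, 16, 20, 24, 30, 40, 60)),
  "2" = list(bands = c("p25", "p11", "q11", "q14.2", "q37"),
             breaks = c(0, 10, 22, 28, 36, 55)),
  "3" = list(bands = c("p26", "p12.1", "p11", "q11", "q26"),
             breaks = c(0, 8, 16, 20, 26, 50)),
  "5" = list(bands = c("p15", "p11", "q11", "q31.2", "q35"),
             breaks = c(0, 10, 20, 28, 36, 50)),
  "6" = list(bands = c("p25", "p21.32", "p21.31", "p21.1", "p11", "q11", "q25"),
             breaks = c(0, 6, 10, 14, 17, 18, 24, 45)),
  "9" = list(bands = c("p24", "p21.3", "p11", "q11", "q34"),
             breaks = c(0, 6, 12, 16, 22, 40)),
  "10" = list(bands = c("p15", "p11", "q11", "q24", "q26"),
              breaks = c(0, 9, 18, 24, 32, 45)),
  "11" = list(bands = c("p15", "p11", "q11", "q24.3"),
              breaks = c(0, 8, 16, 22, 40)),
  "12" = list(bands = c("p13", "p11", "q11", "q13.3", "q14.1", "q14.3",
                        "q15", "q21", "q24"),
              breaks = c(0, 12, 24, 26, 30, 33, 36, 40, 50, 60)),
  "13" = list(bands = c("p11", "q11", "q14.2", "q34"),
              breaks = c(0, 5, 10, 18, 35)),
  "16" = list(bands = c("p13", "p11.2", "p11", "q11", "q24"),
              breaks = c(0, 6, 10, 12, 18, 30)),
  "17" = list(bands = c("p13.2", "p13.1", "p11", "q11", "q25"),
              breaks = c(0, 5, 9, 12, 18, 30)),
  "18" = list(bands = c("p11", "q11.2", "q23"),
              breaks = c(0, 6, 14, 30)),
  "21" = list(bands = c("p11", "q11", "q22.2", "q22.3"),
              breaks = c(0, 5, 10, 16, 25)),
  "22" = list(bands = c("p11", "q11", "q12.1", "q12.2", "q13"),
              breaks = c(0, 5, 9, 14, 18, 25)),
  "X" = list(bands = c("p22", "p11.23", "p11", "q11", "q28"),
             breaks = c(0, 8, 14, 16, 22, 40)))

## gene analogs: symbol, chrom, start/end in Mb, strand, role, cytoband
.TOY_GENES <- data.frame(
  symbol = c("TGFBR3", "CSF1", "NTRK1", "GLI2", "COL6A3", "VGLL3", "CXXC5",
             "PHF1", "SRSF3", "RUNX2", "CDKN2A", "CDKN2B", "OGA", "FLI1",
             "NAB2", "STAT6", "DDIT3", "CDK4", "HMGA2", "MDM2", "RB1", "FUS",
             "USP6", "TP53", "SS18", "ERG", "MN1", "EWSR1", "SSX1"),
  chrom = c("1", "1", "1", "2", "2", "3", "5",
            "6", "6", "6", "9", "9", "10", "11",
            "12", "12", "12", "12", "12", "12", "13", "16",
            "17", "17", "18", "21", "22", "22", "X"),
  startMb = c(10, 17, 34, 30, 50, 12, 31,
              8, 11, 15, 8, 8.1, 27, 30,
              27, 27.06, 28.5, 31, 34, 37, 13, 7,
              2, 6, 8, 12, 10, 15, 10),
  endMb = c(10.2, 17.05, 34.05, 30.2, 50.1, 12.1, 31.05,
            8.05, 11.02, 15.2, 8.03, 8.13, 27.03, 30.1,
            27.05, 27.12, 28.52, 31.05, 34.15, 37.1, 13.2, 7.05,
            2.1, 6.03, 8.1, 12.3, 10.05, 15.1, 10.02),
  strand = c("-", "+", "+", "+", "-", "+", "+",
             "+", "+", "+", "-", "-", "-", "+",
             "+", "-", "-", "-", "+", "+", "+", "+",
             "+", "-", "-", "-", "-", "+", "-"),
  role = c("fusion_partner", "fusion_partner", "oncogene", "oncogene",
           "fusion_partner", "oncogene", "fusion_partner",
           "fusion_partner", "fusion_partner", "oncogene",
           "tumor_suppressor", "tumor_suppressor", "fusion_partner",
           "fusion_partner", "fusion_partner", "fusion_partner",
           "fusion_partner", "oncogene", "oncogene", "oncogene",
           "tumor_suppressor", "fusion_partner", "fusion_partner",
           "tumor_suppressor", "fusion_partner", "fusion_partner",
           "fusion_partner", "fusion_partner", "fusion_partner"),
  stringsAsFactors = FALSE)

.toyCytobandFrame <- function() {
  out <- lapply(names(.TOY_BANDS_MB), function(ch) {
    b <- .TOY_BANDS_MB[[ch]]
    data.frame(chrom = ch, start = b$breaks[-length(b$breaks)] * 1e6,
               end = b$breaks[-1] * 1e6, band = b$bands,
               stain = rep_len(c("gneg", "gpos50"), length(b$bands)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.toyGeneFrame <- function() {
  g <- .TOY_GENES
  df <- data.frame(symbol = g$symbol, chrom = g$chrom,
                   start = g$startMb * 1e6, end = g$endMb * 1e6,
                   strand = g$strand, role = g$role, stringsAsFactors = FALSE)
  bands <- .toyCytobandFrame()
  df$cytoband <- vapply(seq_len(nrow(df)), function(i) {
    b <- bands[bands$chrom == df$chrom[i] & bands$start <= df$start[i] &
                 df$start[i] < bands$end, "band"]
    if (length(b)) b[1] else NA_character_
  }, "")
  df
}

#' The bundled synthetic sarcoma gene panel
#'
#' A stand-in panel on the toy genome containing an analog of every gene the
#' interpretation rules reference (MDM2, CDK4, HMGA2, GLI2, NTRK1, RUNX2,
#' VGLL3, CDKN2A/B, TP53, RB1, FUS, DDIT3, EWSR1, FLI1, ERG, SS18, SSX1,
#' NAB2, STAT6, MN1, CXXC5, SRSF3, USP6, OGA, TGFBR3, COL6A3, CSF1, PHF1),
#' with strands and cytobands. Coordinates are synthetic: this is not a
#' reference annotation.
#'
#' @return a \linkS4class{GenePanel}.
#' @export
sarcomaGenePanel <- function() GenePanel(.toyGeneFrame())

#' The bundled synthetic cytoband table
#' @return a \linkS4class{CytobandTable} for the toy genome.
#' @export
toyCytobands <- function() CytobandTable(.toyCytobandFrame())

#' Toy chromosome sizes
#' @return named numeric vector of toy chromosome lengths in bp.
#' @export
toyChromSizes <- function() .TOY_SIZES_MB * 1e6

#' Generate a labeled toy genome
#'
#' Chromosome sizes, genes and cytobands are fixed; label positions are drawn
#' per seed as a uniform point process whose per-chromosome density is kept
#' inside the 14-17 per 100 kbp band characteristic of CTTAAG-motif labeling.
#'
#' @param seed integer seed; fully determines the label positions.
#' @param labelDensity target labels per 100 kbp (default 15).
#' @return a \linkS4class{ToyGenome}.
#' @examples
#' g <- makeToyGenome(seed = 1)
#' @export
makeToyGenome <- function(seed = 1L, labelDensity = 15) {
  sizes <- toyChromSizes()
  labels <- .withSeed(seed, {
    lapply(sizes, function(L) {
      n <- stats::rpois(1, labelDensity * L / 1e5)
      n <- min(max(n, ceiling(14 * L / 1e5)), floor(17 * L / 1e5))
      sort(stats::runif(n, 0, L))
    })
  })
  new("ToyGenome", chromSizes = sizes, labels = labels,
      genes = sarcomaGenePanel(), cytobands = toyCytobands(),
      seed = as.integer(seed))
}

#' @describeIn makeToyGenome per-chromosome label density (labels/100 kbp).
#' @param genome a \linkS4class{ToyGenome}.
#' @export
labelDensity <- function(genome) {
  stopifnot(is(genome, "ToyGenome"))
  1e5 * lengths(genome@labels) / genome@chromSizes[names(genome@labels)]
}

## ---------------------------------------------------------------------------
## Scenarios
## ---------------------------------------------------------------------------

.SCENARIO_KINDS <- c("QUIET", "SIMPLE_FUSION", "MDM2_AMPLICON_CT",
                     "CHROMOPLEXY_CHAIN", "MIXED")

#' Define a simulation scenario
#'
#' @param kind one of QUIET, SIMPLE_FUSION, MDM2_AMPLICON_CT,
#'   CHROMOPLEXY_CHAIN, MIXED.
#' @param nBackgroundSVs background junction count (default 20).
#' @param chainChromosomes chromosomes in an injected chromoplexy chain
#'   (default 3; must be >= 3).
#' @param chainDeletionBridges how many chain adjacencies are realized as
#'   long gaps spanned by a deletion instead of short gaps (default 0).
#' @param ctRearrangements junctions in the chromothripsis region (default 20).
#' @param ctSpanMb chromothripsis span in Mb (default 30, within one 50 Mb
#'   window).
#' @param cnStates the two oscillating copy-number states (default c(2, 8)).
#' @param vafRange VAF range for background SVs (default c(0.05, 0.5),
#'   respecting the 5-10% detection floor of the platform).
#' @param fusionPair 5' and 3' partner of the injected fusion
#'   (default c("NAB2", "STAT6")).
#' @param fusionMechanism "inversion", "deletion" (orientation-incompatible
#'   for an opposite-strand pair) or "translocation" (default "inversion").
#' @param tissue tissue type driving QC simulation (default "non_adipocytic").
#' @return scenario list.
#' @export
simScenario <- function(kind = c("QUIET", "SIMPLE_FUSION", "MDM2_AMPLICON_CT",
                                 "CHROMOPLEXY_CHAIN", "MIXED"),
                        nBackgroundSVs = 20L, chainChromosomes = 3L,
                        chainDeletionBridges = 0L, ctRearrangements = 20L,
                        ctSpanMb = 30, cnStates = c(2L, 8L),
                        vafRange = c(0.05, 0.5),
                        fusionPair = c("NAB2", "STAT6"),
                        fusionMechanism = c("inversion", "deletion",
                                            "translocation"),
                        tissue = "non_adipocytic") {
  kind <- match.arg(kind)
  fusionMechanism <- match.arg(fusionMechanism)
  if (kind %in% c("CHROMOPLEXY_CHAIN", "MIXED") && chainChromosomes < 3)
    stop("a chromoplexy chain requires at least 3 chromosomes")
  list(kind = kind, nBackgroundSVs = as.integer(nBackgroundSVs),
       chainChromosomes = as.integer(chainChromosomes),
       chainDeletionBridges = as.integer(chainDeletionBridges),
       ctRearrangements = as.integer(ctRearrangements), ctSpanMb = ctSpanMb,
       cnStates = as.integer(cnStates), vafRange = vafRange,
       fusionPair = fusionPair, fusionMechanism = fusionMechanism,
       tissue = tissue)
}

.bgSVs <- function(genome, n, vafRange, idPrefix = "bg") {
  if (n == 0) return(NULL)
  sizes <- genome@chromSizes
  ch <- sample(names(sizes), n, replace = TRUE, prob = sizes / sum(sizes))
  sz <- exp(stats::runif(n, log(500), log(1e6)))
  type <- sample(c("deletion", "duplication", "inversion"), n, replace = TRUE)
  posA <- vapply(seq_len(n), function(i)
    stats::runif(1, 0, sizes[[ch[i]]] - sz[i]), 0)
  strands <- t(vapply(type, function(tt) .SMAP_STRANDS[[tt]], c("", "")))
  data.frame(id = sprintf("%s%03d", idPrefix, seq_len(n)),
             chromA = ch, posA = round(posA), strandA = strands[, 1],
             chromB = ch, posB = round(posA + sz), strandB = strands[, 2],
             svType = type, sizeBp = round(sz),
             vaf = stats::runif(n, vafRange[1], vafRange[2]),
             confidence = stats::runif(n, 0.5, 1),
             stringsAsFactors = FALSE)
}

.fusionSV <- function(genome, five, three, mechanism) {
  g <- panelGenes(genome@genes)
  gf <- g[g$symbol == five, ]; gt <- g[g$symbol == three, ]
  if (!nrow(gf) || !nrow(gt)) stop("unknown fusion partner gene")
  posF <- round((gf$start + gf$end) / 2)
  posT <- round((gt$start + gt$end) / 2)
  if (mechanism == "deletion" && gf$chrom == gt$chrom) {
    strands <- c("+", "-")   # canonical deletion junction
  } else {
    ## compatible orientation: gene strand at the 5' breakend, flipped gene
    ## strand at the 3' breakend
    strands <- c(gf$strand, .flipStrand(gt$strand))
  }
  type <- if (gf$chrom != gt$chrom) "inter_translocation"
          else .inferSVType(gf$chrom, gt$chrom, strands[1], strands[2])
  data.frame(id = paste0("fus_", five, "_", three),
             chromA = gf$chrom, posA = posF, strandA = strands[1],
             chromB = gt$chrom, posB = posT, strandB = strands[2],
             svType = type, sizeBp = NA_real_, vaf = 0.4, confidence = 0.9,
             stringsAsFactors = FALSE)
}

.ctEvents <- function(genome, scenario) {
  span <- scenario$ctSpanMb * 1e6
  start <- 26e6                       # 12q-like arm, covers the oncogene cluster
  end <- start + span
  n <- scenario$ctRearrangements
  pos <- sort(round(stats::runif(2 * n, start, end)))
  pos <- matrix(sample(pos), ncol = 2)
  svs <- data.frame(
    id = sprintf("ct%03d", seq_len(n)),
    chromA = "12", posA = pmin(pos[, 1], pos[, 2]),
    chromB = "12", posB = pmax(pos[, 1], pos[, 2]),
    svType = sample(c("deletion", "duplication", "inversion"), n, replace = TRUE),
    vaf = stats::runif(n, 0.2, 0.5), confidence = stats::runif(n, 0.5, 1),
    stringsAsFactors = FALSE)
  st <- t(vapply(svs$svType, function(tt) .SMAP_STRANDS[[tt]], c("", "")))
  svs$strandA <- st[, 1]; svs$strandB <- st[, 2]
  svs$sizeBp <- svs$posB - svs$posA
  ## oscillating copy number over the span + a high-level amplicon on the
  ## MDM2-analog
  nseg <- 10
  bk <- seq(start, end, length.out = nseg + 1)
  cn <- rep(scenario$cnStates, length.out = nseg)
  cnv <- data.frame(chrom = "12", start = round(bk[-length(bk)]),
                    end = round(bk[-1]), cn = cn, stringsAsFactors = FALSE)
  g <- panelGenes(genome@genes)
  mdm2 <- g[g$symbol == "MDM2", ]
  cnv <- rbind(cnv, data.frame(chrom = "12", start = mdm2$start - 5e5,
                               end = mdm2$end + 5e5, cn = 12L))
  list(svs = svs, cnvs = cnv, region = c(start = start, end = end))
}

.chainEvents <- function(genome, scenario, maxGap = defaultMaxGap()) {
  k <- scenario$chainChromosomes
  chroms <- sample(names(genome@chromSizes), k)
  anchor <- vapply(chroms, function(ch)
    stats::runif(1, 5e6, genome@chromSizes[[ch]] - 5e6), 0)
  nBridge <- min(scenario$chainDeletionBridges, k)
  bridged <- rep(FALSE, k)
  if (nBridge > 0) bridged[sample(k, nBridge)] <- TRUE
  ## on each chromosome the incoming and outgoing breakends sit `gap` apart;
  ## bridged transitions use a long gap spanned by a deletion segment
  gap <- ifelse(bridged, stats::runif(k, 1e5, 5e5),
                stats::runif(k, 1e3, 0.75 * maxGap))
  outPos <- anchor + gap
  svs <- lapply(seq_len(k), function(i) {
    j <- if (i == k) 1L else i + 1L
    data.frame(id = sprintf("chain%02d", i),
               chromA = chroms[i], posA = round(outPos[i]),
               strandA = sample(c("+", "-"), 1),
               chromB = chroms[j], posB = round(anchor[j]),
               strandB = sample(c("+", "-"), 1),
               svType = "inter_translocation", sizeBp = 0,
               vaf = stats::runif(1, 0.2, 0.5), confidence = 0.9,
               stringsAsFactors = FALSE)
  })
  cnv <- NULL
  if (any(bridged)) {
    cnv <- data.frame(chrom = chroms[bridged],
                      start = round(anchor[bridged]) - 100,
                      end = round(outPos[bridged]) + 100,
                      cn = 1L, stringsAsFactors = FALSE)
  }
  list(svs = do.call(rbind, svs), cnvs = cnv, chromosomes = chroms,
       svIds = sprintf("chain%02d", seq_len(k)))
}

#' Simulate one case from a scenario
#'
#' Deterministic per (genome, scenario, seed). Injected events are emitted
#' together with a ground-truth record naming them, so detectors can be
#' scored against the simulation truth.
#'
#' @param genome a \linkS4class{ToyGenome}.
#' @param scenario from \code{\link{simScenario}}.
#' @param seed integer seed.
#' @return list with \code{svs} (\linkS4class{SVCallSet}), \code{cnvs}
#'   (\linkS4class{CNVSegmentSet}), \code{qc} (one-row QC data.frame) and
#'   \code{truth} (scenario kind plus injected chain/region/fusion
#'   descriptors).
#' @export
simulateCase <- function(genome, scenario, seed) {
  stopifnot(is(genome, "ToyGenome"))
  .withSeed(seed, {
    svs <- list(); cnvs <- list()
    truth <- list(kind = scenario$kind)
    if (scenario$kind %in% c("SIMPLE_FUSION", "MIXED")) {
      f <- .fusionSV(genome, scenario$fusionPair[1], scenario$fusionPair[2],
                     scenario$fusionMechanism)
      svs <- c(svs, list(f))
      truth$fusion <- list(fivePrime = scenario$fusionPair[1],
                           threePrime = scenario$fusionPair[2],
                           svId = f$id,
                           mechanism = scenario$fusionMechanism)
    }
    if (scenario$kind %in% c("MDM2_AMPLICON_CT", "MIXED")) {
      ct <- .ctEvents(genome, scenario)
      svs <- c(svs, list(ct$svs)); cnvs <- c(cnvs, list(ct$cnvs))
      truth$region <- list(chrom = "12", start = ct$region[["start"]],
                           end = ct$region[["end"]], svIds = ct$svs$id)
    }
    if (scenario$kind %in% c("CHROMOPLEXY_CHAIN", "MIXED")) {
      chain <- .chainEvents(genome, scenario)
      svs <- c(svs, list(chain$svs))
      if (!is.null(chain$cnvs)) cnvs <- c(cnvs, list(chain$cnvs))
      truth$chain <- list(chromosomes = chain$chromosomes, svIds = chain$svIds)
    }
    bg <- .bgSVs(genome, scenario$nBackgroundSVs, scenario$vafRange)
    if (!is.null(bg)) svs <- c(svs, list(bg))
    qc <- simulateQC(scenario$tissue, seed = floor(stats::runif(1, 1, 2^30)))
    svdf <- do.call(rbind, lapply(svs, function(x)
      x[, c("id", "chromA", "posA", "strandA", "chromB", "posB", "strandB",
            "svType", "sizeBp", "vaf", "confidence")]))
    list(svs = SVCallSet(if (is.null(svdf)) data.frame() else svdf),
         cnvs = CNVSegmentSet(if (length(cnvs)) do.call(rbind, cnvs) else data.frame()),
         qc = qc, truth = truth)
  })
}

## ---------------------------------------------------------------------------
## QC simulation
## ---------------------------------------------------------------------------

.TISSUE_EVAL_RATES <- c(adipocytic = 12 / 21, non_adipocytic = 11 / 15,
                        bone = 2 / 6, uncertain = 5 / 7, srcs = 3 / 4)

.rtnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  pmin(pmax(x, lo), hi)
}

#' Simulate per-sample QC metrics for a tissue type
#'
#' A two-component mixture: with the tissue's evaluability probability the
#' sample draws metrics from truncated normals around the typical values of
#' an assessable run (and is re-drawn until it classifies GOOD or EVALUABLE);
#' otherwise it draws from a degraded-run component (re-drawn until
#' NOT_EVALUABLE). Expected evaluability therefore matches the tissue rates
#' by construction: adipocytic 12/21, non-adipocytic 11/15, bone 2/6,
#' uncertain differentiation 5/7, small round cell sarcomas 3/4.
#'
#' @param tissue one of \code{"adipocytic"}, \code{"non_adipocytic"},
#'   \code{"bone"}, \code{"uncertain"}, \code{"srcs"}.
#' @param seed integer seed.
#' @param n number of samples to draw (default 1).
#' @return data.frame with columns \code{tissue, total_dna_gbp, map_rate_pct,
#'   effective_coverage, tier, evaluable}.
#' @export
simulateQC <- function(tissue, seed, n = 1L) {
  tissue <- match.arg(tissue, names(.TISSUE_EVAL_RATES))
  p <- .TISSUE_EVAL_RATES[[tissue]]
  .withSeed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      ok <- stats::runif(1) < p
      repeat {
        if (ok) {
          m <- c(.rtnorm(1, 1450, 250, 300, 2200),
                 .rtnorm(1, 72, 14.2, 30, 95),
                 .rtnorm(1, 328, 130.8, 20, 600))
        } else {
          m <- c(.rtnorm(1, 900, 400, 50, 1600),
                 .rtnorm(1, 38, 8, 5, 60),
                 .rtnorm(1, 90, 40, 5, 200))
        }
        tier <- classifyQuality(m[1], m[2], m[3])$tier
        if (ok == (tier != "NOT_EVALUABLE")) break
      }
      data.frame(tissue = tissue, total_dna_gbp = round(m[1], 2),
                 map_rate_pct = round(m[2], 1),
                 effective_coverage = round(m[3], 2),
                 tier = tier, evaluable = tier != "NOT_EVALUABLE",
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}
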