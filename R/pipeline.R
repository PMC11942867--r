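## End-to-end per-sample and cohort orchestration: QC gate -> size/VAF
## prioritization -> gene-level annotation -> fusion inference ->
## chromoanagenesis detection -> expected-alteration matching -> report.

#' Pipeline configuration with paper-derived defaults
#'
#' Every threshold used anywhere in the pipeline, with its default:
#' QC gate (1500 Gbp / 70\% / 300x recommended; 40-50\%+150x or >=50\%+100x
#' evaluable bands), prioritization floors (SVs and CNVs > 500 bp), gene
#' copy-number thresholds (amplification >= 5, deletion <= 1, ploidy 2,
#' monosomy coverage 0.9), chromoplexy gap (five labels at 15/100 kbp,
#' ~33 kb), and chromothripsis window rules (> 7 junctions per 50 Mb window,
#' >= 2 CN states, interspersion 0.8, KS uniformity alpha 0.01).
#'
#' @param ... named overrides of any default.
#' @return named list of settings.
#' @export
runConfig <- function(...) {
  cfg <- list(
    qc = qcThresholds(),
    minSVSize = 500, minCNVSize = 500, minVAF = NULL,
    ampCN = 5L, gainCN = 3L, delCN = 1L, ploidy = 2L, padBp = 0,
    monosomyFraction = 0.9,
    maxGap = defaultMaxGap(), minChainChromosomes = 3L,
    windowMb = 50, minRearr = 8L, minCNStates = 2L,
    interspersionMax = 0.8, uniformityAlpha = 0.01, strideMb = 1)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config setting(s): ", paste(bad, collapse = ", "))
  utils::modifyList(cfg, over)
}

#' Run the full interpretation pipeline on one sample
#'
#' Applies the QC gate (NOT_EVALUABLE samples short-circuit to a QC-only
#' report), prioritizes variants, annotates gene-level copy-number events,
#' infers fusions and single-gene rearrangements, detects chromoplexy chains
#' and chromothripsis regions, matches the case's expected alteration, and
#' returns a \linkS4class{CaseReport}.
#'
#' @param svs an \linkS4class{SVCallSet} or path to a BEDPE file.
#' @param cnvs a \linkS4class{CNVSegmentSet} or path to a CNV TSV.
#' @param qc one-row data.frame with \code{total_dna_gbp, map_rate_pct,
#'   effective_coverage} (or a list with those names).
#' @param panel a \linkS4class{GenePanel}.
#' @param bands a \linkS4class{CytobandTable}.
#' @param chromSizes named chromosome lengths in bp (for monosomy calls).
#' @param expectedRule an \code{\link{alterationRule}}; default
#'   \code{cnv_sv_any}.
#' @param caseId,subtype identifiers recorded in the report.
#' @param config from \code{\link{runConfig}}.
#' @return a \linkS4class{CaseReport}.
#' @export
runSample <- function(svs, cnvs, qc, panel, bands, chromSizes,
                      expectedRule = alterationRule("cnv_sv_any"),
                      caseId = "sample", subtype = "unspecified",
                      config = runConfig()) {
  if (is.character(svs)) svs <- readSVTable(svs, "bedpe")
  if (is.character(cnvs)) cnvs <- readCNVTable(cnvs, ploidy = config$ploidy,
                                               ampCN = config$ampCN)
  qcRes <- classifyQuality(qc$total_dna_gbp, qc$map_rate_pct,
                           qc$effective_coverage, config$qc)
  if (qcRes$tier == "NOT_EVALUABLE") {
    return(new("CaseReport", caseId = as.character(caseId),
               subtype = subtype, qcTier = qcRes$tier,
               expectedRule = expectedRule, detected = FALSE,
               detectionTier = "NONE", events = list(), chromoClass = "NONE",
               iscn = character()))
  }
  filt <- filterVariants(svs, cnvs, minSVSize = config$minSVSize,
                         minCNVSize = config$minCNVSize, minVAF = config$minVAF)
  geneCNV <- callGeneCNV(filt$cnvs, panel, ampCN = config$ampCN,
                         gainCN = config$gainCN, delCN = config$delCN,
                         padBp = config$padBp)
  fusions <- inferFusions(filt$svs, panel, bands = bands)
  rearr <- geneRearrangements(filt$svs, panel)
  mono <- callMonosomy(filt$cnvs, chromSizes,
                       covFraction = config$monosomyFraction,
                       delCN = config$delCN)
  chains <- detectChromoplexy(filt$svs, maxGap = config$maxGap,
                              deletions = filt$cnvs,
                              minChromosomes = config$minChainChromosomes)
  regions <- detectChromothripsis(filt$svs, filt$cnvs,
                                  windowMb = config$windowMb,
                                  minRearr = config$minRearr,
                                  minCNStates = config$minCNStates,
                                  interspersionMax = config$interspersionMax,
                                  uniformityAlpha = config$uniformityAlpha,
                                  strideMb = config$strideMb,
                                  chromSizes = chromSizes)
  events <- list(fusions = fusions, geneCNV = geneCNV, rearrangements = rearr,
                 monosomies = mono, chains = chains, regions = regions,
                 svs = filt$svs, cnvs = filt$cnvs)
  m <- matchExpected(expectedRule, events)
  iscn <- .reportISCN(fusions, geneCNV, mono, panel, bands)
  new("CaseReport", caseId = as.character(caseId), subtype = subtype,
      qcTier = qcRes$tier, expectedRule = expectedRule,
      detected = m$detected, detectionTier = m$tier, events = events,
      chromoClass = classifyChromoanagenesis(chains, regions), iscn = iscn)
}

.reportISCN <- function(fusions, geneCNV, mono, panel, bands) {
  out <- character()
  if (nrow(fusions)) out <- c(out, stats::na.omit(fusions$iscn))
  g <- panelGenes(panel)
  amps <- geneCNV[geneCNV$event == "amplification", , drop = FALSE]
  for (i in seq_len(nrow(amps))) {
    gene <- g[g$symbol == amps$gene[i], ]
    band <- tryCatch(assignCytoband(gene$chrom, gene$start, bands),
                     error = function(e) NA_character_)
    if (!is.na(band))
      out <- c(out, formatISCN(list(kind = "amplification", gene = gene$symbol,
                                    chrom = gene$chrom, band = band)))
  }
  for (ch in mono$chrom)
    out <- c(out, formatISCN(list(kind = "monosomy", chrom = ch)))
  unique(out)
}

#' Write a CaseReport as JSON
#'
#' Serializes the report (identifiers, QC tier, rule, detection outcome,
#' event tables, chromoanagenesis evidence, ISCN strings) for downstream
#' consumption or audit.
#'
#' @param report a \linkS4class{CaseReport}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeCaseReportJSON <- function(report, path) {
  ev <- report@events
  ser <- list(
    case_id = report@caseId, subtype = report@subtype,
    qc_tier = report@qcTier,
    expected_rule = formatAlterationRule(report@expectedRule),
    detected = report@detected, detection_tier = report@detectionTier,
    chromoanagenesis = report@chromoClass, iscn = report@iscn,
    fusions = ev$fusions, gene_cnv = ev$geneCNV,
    rearrangements = ev$rearrangements, monosomies = ev$monosomies,
    chains = ev$chains, regions = ev$regions)
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the pipeline over a cohort
#'
#' @param cases list of per-case input lists, each with elements \code{svs,
#'   cnvs, qc} and optional \code{expectedRule, caseId, subtype} (the layout
#'   produced by \code{\link{simulateCase}}).
#' @param panel,bands,chromSizes,config shared assets, as in
#'   \code{\link{runSample}}.
#' @return list with \code{reports} (per-case \linkS4class{CaseReport}s, in
#'   input order) and \code{summary} (from \code{\link{cohortReport}}). The
#'   summary is invariant under reordering of \code{cases}.
#' @export
runCohort <- function(cases, panel, bands, chromSizes, config = runConfig()) {
  if (!length(cases)) stop("empty cohort manifest")
  reports <- lapply(seq_along(cases), function(i) {
    cs <- cases[[i]]
    runSample(cs$svs, cs$cnvs, cs$qc, panel, bands, chromSizes,
              expectedRule = if (is.null(cs$expectedRule))
                alterationRule("cnv_sv_any") else cs$expectedRule,
              caseId = if (is.null(cs$caseId)) as.character(i) else cs$caseId,
              subtype = if (is.null(cs$subtype)) "unspecified" else cs$subtype,
              config = config)
  })
  list(reports = reports, summary = cohortReport(reports))
}
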