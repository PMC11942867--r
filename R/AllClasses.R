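#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.SV_TYPES <- c("deletion", "insertion", "duplication", "inversion",
               "intra_translocation", "inter_translocation")
.CNV_KINDS <- c("gain", "loss", "amplification", "neutral")
.GENE_ROLES <- c("oncogene", "tumor_suppressor", "fusion_partner", "other")
.QC_TIERS <- c("GOOD", "EVALUABLE", "NOT_EVALUABLE")
.CHROMO_CLASSES <- c("NONE", "CHROMOPLEXY", "CHROMOTHRIPSIS", "BOTH")

## ---------------------------------------------------------------------------
## SVCallSet: a set of rearrangement junctions (two oriented breakends each)
## ---------------------------------------------------------------------------

#' SVCallSet: structural variant junctions
#'
#' Container for rearrangement junctions called from optical genome mapping
#' (or any SV caller). Each record is one junction with two breakends
#' (chromosome, position, orientation), an SV type, a size, and optional
#' variant allele frequency (VAF) and confidence. Records are stored
#' normalized: coordinates are 0-based, intra-chromosomal junctions have
#' \code{posA <= posB}, inter-chromosomal junctions have breakend A karyotypically
#' before breakend B, and the type is consistent with chromosome equality.
#'
#' Breakend orientation follows the BEDPE strand convention: \code{"+"} means
#' the reference segment with coordinates below the breakpoint is retained and
#' enters the junction reading left-to-right; \code{"-"} means the segment above
#' the breakpoint enters the junction (reverse-complemented).
#'
#' @slot calls data.frame with columns \code{id, chromA, posA, strandA,
#'   chromB, posB, strandB, svType, sizeBp, vaf, confidence, tier}.
#' @export
setClass("SVCallSet", representation(calls = "data.frame"))

setValidity("SVCallSet", function(object) {
  df <- object@calls
  need <- c("id", "chromA", "posA", "strandA", "chromB", "posB", "strandB",
            "svType", "sizeBp", "vaf", "confidence", "tier")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  if (any(df$posA < 0) || any(df$posB < 0)) return("negative breakend position")
  if (!all(df$strandA %in% c("+", "-")) || !all(df$strandB %in% c("+", "-")))
    return("breakend orientations must be '+' or '-'")
  if (!all(df$svType %in% .SV_TYPES))
    return("unknown svType")
  intra <- df$chromA == df$chromB
  if (any(intra & df$posA > df$posB))
    return("intra-chromosomal junction with posA > posB")
  if (any(df$svType[intra] == "inter_translocation"))
    return("inter_translocation on a single chromosome")
  if (any(df$svType[!intra] != "inter_translocation"))
    return("two-chromosome junction must be inter_translocation")
  if (any(!.breakendLE(df$chromA[!intra], df$posA[!intra],
                       df$chromB[!intra], df$posB[!intra])))
    return("inter-chromosomal breakends not in karyotypic order")
  if (any(df$sizeBp < 0)) return("negative sizeBp")
  bad <- !is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1)
  if (any(bad)) return("vaf outside [0,1]")
  TRUE
})

## ---------------------------------------------------------------------------
## CNVSegmentSet: copy-number intervals with integer CN state
## ---------------------------------------------------------------------------

#' CNVSegmentSet: copy-number segments
#'
#' Copy-number intervals with an integer copy-number state. Each segment
#' carries a derived \code{kind}: \code{amplification} (cn at or above the
#' amplification threshold), \code{gain}, \code{loss} or \code{neutral},
#' relative to the assumed ploidy.
#'
#' @slot segments data.frame with columns \code{chrom, start, end, cn, kind, tier}.
#' @slot ploidy integer assumed baseline copy number (default 2).
#' @export
setClass("CNVSegmentSet",
         representation(segments = "data.frame", ploidy = "integer"))

setValidity("CNVSegmentSet", function(object) {
  df <- object@segments
  need <- c("chrom", "start", "end", "cn", "kind", "tier")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  if (any(df$start >= df$end)) return("segment with start >= end")
  if (any(df$cn < 0)) return("negative copy number")
  if (!all(df$kind %in% .CNV_KINDS)) return("unknown CNV kind")
  p <- object@ploidy
  if (any(df$cn > p & !df$kind %in% c("gain", "amplification")))
    return("cn above ploidy must be gain/amplification")
  if (any(df$cn < p & df$kind != "loss"))
    return("cn below ploidy must be loss")
  if (any(df$cn == p & df$kind != "neutral"))
    return("cn equal to ploidy must be neutral")
  TRUE
})

## ---------------------------------------------------------------------------
## GenePanel: gene models used for prioritization and fusion inference
## ---------------------------------------------------------------------------

#' GenePanel: sarcoma gene models
#'
#' A panel of gene bodies with strand (transcription direction), a functional
#' role (oncogene, tumor suppressor, fusion partner, other) and the cytoband
#' the gene lies in. Symbols are unique within a panel.
#'
#' @slot genes data.frame with columns \code{symbol, chrom, start, end,
#'   strand, role, cytoband}.
#' @export
setClass("GenePanel", representation(genes = "data.frame"))

setValidity("GenePanel", function(object) {
  df <- object@genes
  need <- c("symbol", "chrom", "start", "end", "strand", "role", "cytoband")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  if (anyDuplicated(df$symbol)) return("duplicate gene symbol in panel")
  if (any(df$start >= df$end)) return("gene with start >= end")
  if (!all(df$strand %in% c("+", "-"))) return("gene strand must be '+' or '-'")
  if (!all(df$role %in% .GENE_ROLES)) return("unknown gene role")
  TRUE
})

## ---------------------------------------------------------------------------
## CytobandTable: ordered, contiguous band intervals per chromosome
## ---------------------------------------------------------------------------

#' CytobandTable: cytogenetic band table
#'
#' Ordered cytoband records (UCSC cytoBand layout). Within each chromosome
#' bands are sorted, non-overlapping and contiguous; coordinates are 0-based
#' half-open.
#'
#' @slot bands data.frame with columns \code{chrom, start, end, band, stain}.
#' @export
setClass("CytobandTable", representation(bands = "data.frame"))

setValidity("CytobandTable", function(object) {
  df <- object@bands
  need <- c("chrom", "start", "end", "band", "stain")
  if (!all(need %in% names(df)))
    return(paste("missing columns:", paste(setdiff(need, names(df)), collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  if (any(df$start >= df$end)) return("band with start >= end")
  for (ch in unique(df$chrom)) {
    b <- df[df$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE)) return("bands not sorted within chromosome")
    if (nrow(b) > 1 && any(b$start[-1] != b$end[-nrow(b)]))
      return("bands not contiguous within chromosome")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## ToyGenome: synthetic reference for simulation and tests
## ---------------------------------------------------------------------------

#' ToyGenome: synthetic labeled reference genome
#'
#' A scaled-down synthetic genome used by the cohort simulator: chromosome
#' sizes, fluorescent label positions (emulating CTTAAG-motif labels at
#' 14-17 per 100 kbp), a gene panel and cytoband table. Fully determined by
#' its seed.
#'
#' @slot chromSizes named numeric vector of chromosome lengths (bp).
#' @slot labels named list of sorted label positions per chromosome.
#' @slot genes a \linkS4class{GenePanel}.
#' @slot cytobands a \linkS4class{CytobandTable}.
#' @slot seed integer seed used to generate label positions.
#' @export
setClass("ToyGenome",
         representation(chromSizes = "numeric", labels = "list",
                        genes = "GenePanel", cytobands = "CytobandTable",
                        seed = "integer"))

setValidity("ToyGenome", function(object) {
  if (is.null(names(object@chromSizes))) return("chromSizes must be named")
  if (any(object@chromSizes <= 0)) return("chromosome sizes must be positive")
  if (!all(names(object@labels) %in% names(object@chromSizes)))
    return("labels for unknown chromosome")
  g <- panelGenes(object@genes)
  if (nrow(g)) {
    sz <- object@chromSizes[g$chrom]
    if (any(is.na(sz)) || any(g$end > sz)) return("gene outside chromosome bounds")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## CaseReport: per-case interpretation result
## ---------------------------------------------------------------------------

#' CaseReport: per-case interpretation summary
#'
#' The end product of the per-sample pipeline: QC tier, expected-alteration
#' rule, whether it was detected and by which pipeline tier, the prioritized
#' events, the chromoanagenesis class, and ISCN-style strings for reportable
#' events.
#'
#' @slot caseId character case identifier.
#' @slot subtype character sarcoma subtype / diagnosis label.
#' @slot qcTier character one of GOOD, EVALUABLE, NOT_EVALUABLE.
#' @slot expectedRule list expected-alteration rule (see \code{\link{alterationRule}}).
#' @slot detected logical whether the expected alteration was found.
#' @slot detectionTier character one of RVA, DENOVO, NONE.
#' @slot events list of event tables (fusions, gene CNV events, rearrangements,
#'   chains, regions, monosomies).
#' @slot chromoClass character chromoanagenesis class.
#' @slot iscn character vector of ISCN-style strings.
#' @export
setClass("CaseReport",
         representation(caseId = "character", subtype = "character",
                        qcTier = "character", expectedRule = "list",
                        detected = "logical", detectionTier = "character",
                        events = "list", chromoClass = "character",
                        iscn = "character"))

setValidity("CaseReport", function(object) {
  if (!object@qcTier %in% .QC_TIERS) return("unknown QC tier")
  if (!object@detectionTier %in% c("RVA", "DENOVO", "NONE"))
    return("unknown detection tier")
  if (!object@chromoClass %in% .CHROMO_CLASSES) return("unknown chromoanagenesis class")
  if (object@detected && object@detectionTier == "NONE")
    return("detected case must carry a detection tier")
  TRUE
})
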