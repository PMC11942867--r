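## Variant prioritization against the sarcoma gene panel and gene-level
## copy-number calling.

#' @importFrom GenomicRanges GRanges findOverlaps reduce
#' @importFrom IRanges IRanges pintersect
#' @importFrom S4Vectors queryHits subjectHits
NULL

#' Filter SV and CNV calls by size and VAF
#'
#' Size prioritization: retained intra-chromosomal SVs must span more than
#' \code{minSVSize} bp; inter-chromosomal junctions have no defined span and
#' are always retained. CNV segments must span more than \code{minCNVSize} bp.
#' When \code{minVAF} is given, records whose VAF is present and below it are
#' dropped; records without a VAF pass (the caller filters VAF at calling
#' time, not post hoc).
#'
#' @param svs an \linkS4class{SVCallSet}.
#' @param cnvs a \linkS4class{CNVSegmentSet}.
#' @param minSVSize minimum intra-chromosomal SV span in bp (default 500,
#'   strict).
#' @param minCNVSize minimum CNV span in bp (default 500, strict).
#' @param minVAF optional VAF floor in [0,1]; \code{NULL} disables.
#' @return list with elements \code{svs} and \code{cnvs}, filtered.
#' @export
filterVariants <- function(svs, cnvs, minSVSize = 500, minCNVSize = 500,
                           minVAF = NULL) {
  sdf <- svCalls(svs)
  keep <- rep(TRUE, nrow(sdf))
  intra <- sdf$chromA == sdf$chromB
  keep[intra] <- sdf$sizeBp[intra] > minSVSize
  if (!is.null(minVAF))
    keep <- keep & (is.na(sdf$vaf) | sdf$vaf >= minVAF)
  cdf <- cnvSegments(cnvs)
  ckeep <- (cdf$end - cdf$start) > minCNVSize
  list(svs = SVCallSet(sdf[keep, , drop = FALSE]),
       cnvs = CNVSegmentSet(cdf[ckeep, , drop = FALSE], ploidy = ploidy(cnvs)))
}

#' Call gene-level amplifications and deletions
#'
#' A panel gene is called amplified when any overlapping segment has
#' \code{cn >= ampCN}, and deleted when any overlapping segment has
#' \code{cn <= delCN} (cn = 0 is flagged homozygous). Overlap requires at
#' least 1 bp intersection with the gene body plus \code{pad}. One event is
#' emitted per gene: among qualifying segments the one with the largest
#' \code{|cn - ploidy|} wins; ties go to the more extreme copy number, then to
#' the leftmost segment.
#'
#' @param cnvs a \linkS4class{CNVSegmentSet}.
#' @param panel a \linkS4class{GenePanel}.
#' @param ampCN amplification threshold (default 5).
#' @param gainCN simple-gain threshold, recorded for context only (default 3);
#'   gains below \code{ampCN} are not emitted as events.
#' @param delCN deletion threshold (default 1).
#' @param padBp symmetric padding added to gene bodies before intersection
#'   (default 0).
#' @return data.frame with columns \code{gene, event, cn, homozygous, chrom,
#'   segStart, segEnd, overlapBp, tier}, ordered by gene position.
#' @export
callGeneCNV <- function(cnvs, panel, ampCN = 5L, gainCN = 3L, delCN = 1L,
                        padBp = 0) {
  g <- panelGenes(panel)
  if (nrow(g) == 0) stop("empty gene panel")
  cdf <- cnvSegments(cnvs)
  empty <- data.frame(gene = character(), event = character(), cn = integer(),
                      homozygous = logical(), chrom = character(),
                      segStart = numeric(), segEnd = numeric(),
                      overlapBp = numeric(), tier = character(),
                      stringsAsFactors = FALSE)
  if (nrow(cdf) == 0) return(empty)
  p <- ploidy(cnvs)
  qualifies <- cdf$cn >= ampCN | cdf$cn <= delCN
  cdf <- cdf[qualifies, , drop = FALSE]
  if (nrow(cdf) == 0) return(empty)

  geneGR <- GRanges(g$chrom, IRanges(pmax(0, g$start - padBp) + 1, g$end + padBp))
  segGR <- GRanges(cdf$chrom, IRanges(cdf$start + 1, cdf$end))
  hits <- findOverlaps(geneGR, segGR)
  if (!length(hits)) return(empty)
  ov <- pintersect(geneGR[queryHits(hits)], segGR[subjectHits(hits)])
  cand <- data.frame(
    gene = g$symbol[queryHits(hits)],
    geneIdx = queryHits(hits),
    cn = cdf$cn[subjectHits(hits)],
    chrom = cdf$chrom[subjectHits(hits)],
    segStart = cdf$start[subjectHits(hits)],
    segEnd = cdf$end[subjectHits(hits)],
    overlapBp = BiocGenerics::width(ov),
    tier = cdf$tier[subjectHits(hits)],
    stringsAsFactors = FALSE)
  cand$event <- ifelse(cand$cn >= ampCN, "amplification", "deletion")
  cand$dev <- abs(cand$cn - p)
  ## per-gene winner: largest |cn - ploidy|, then extreme cn, then leftmost
  cand <- cand[order(cand$geneIdx, -cand$dev,
                     ifelse(cand$event == "deletion", cand$cn, -cand$cn),
                     cand$segStart), , drop = FALSE]
  cand <- cand[!duplicated(cand$geneIdx), , drop = FALSE]
  cand$homozygous <- cand$event == "deletion" & cand$cn == 0
  out <- cand[order(cand$geneIdx),
              c("gene", "event", "cn", "homozygous", "chrom",
                "segStart", "segEnd", "overlapBp", "tier")]
  rownames(out) <- NULL
  out
}

#' Call whole-chromosome losses (monosomies)
#'
#' A chromosome is reported lost when loss segments with \code{cn <= delCN}
#' jointly cover at least \code{covFraction} of its length.
#'
#' @param cnvs a \linkS4class{CNVSegmentSet}.
#' @param chromSizes named numeric vector of chromosome lengths in bp.
#' @param covFraction fraction of the chromosome that must be covered
#'   (default 0.9).
#' @param delCN copy-number ceiling for a loss segment (default 1).
#' @return data.frame with columns \code{chrom, coveredFraction, minCN}.
#' @export
callMonosomy <- function(cnvs, chromSizes, covFraction = 0.9, delCN = 1L) {
  if (is.null(names(chromSizes))) stop("chromSizes must be named")
  names(chromSizes) <- normChrom(names(chromSizes))
  cdf <- cnvSegments(cnvs)
  cdf <- cdf[cdf$cn <= delCN, , drop = FALSE]
  out <- data.frame(chrom = character(), coveredFraction = numeric(),
                    minCN = integer(), stringsAsFactors = FALSE)
  if (nrow(cdf) == 0) return(out)
  for (ch in sortChrom(unique(cdf$chrom))) {
    if (!ch %in% names(chromSizes)) next
    seg <- cdf[cdf$chrom == ch, , drop = FALSE]
    merged <- reduce(GRanges(ch, IRanges(seg$start + 1, pmin(seg$end, chromSizes[[ch]]))))
    frac <- sum(BiocGenerics::width(merged)) / chromSizes[[ch]]
    if (frac >= covFraction)
      out <- rbind(out, data.frame(chrom = ch, coveredFraction = frac,
                                   minCN = min(seg$cn)))
  }
  rownames(out) <- NULL
  out
}
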