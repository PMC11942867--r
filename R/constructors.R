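## Constructors, accessors and show() methods for the core containers.

.normalizeSVFrame <- function(df) {
  df$chromA <- normChrom(df$chromA)
  df$chromB <- normChrom(df$chromB)
  df$posA <- as.numeric(df$posA)
  df$posB <- as.numeric(df$posB)
  intra <- df$chromA == df$chromB

  ## order breakends: intra by position, inter karyotypically; orientations
  ## travel with their breakend
  swap <- (intra & df$posA > df$posB) |
    (!intra & !.breakendLE(df$chromA, df$posA, df$chromB, df$posB))
  if (any(swap)) {
    tmp <- df[swap, c("chromA", "posA", "strandA")]
    df[swap, c("chromA", "posA", "strandA")] <-
      df[swap, c("chromB", "posB", "strandB")]
    df[swap, c("chromB", "posB", "strandB")] <- tmp
  }

  ## type consistency with chromosome equality
  df$svType[!intra] <- "inter_translocation"
  fix <- intra & df$svType == "inter_translocation"
  df$svType[fix] <- "intra_translocation"

  ## size: canonically the breakend span for intra junctions (except
  ## insertions, whose inserted length is not a reference span), 0 for inter
  span <- intra & df$svType != "insertion"
  df$sizeBp[span] <- (df$posB - df$posA)[span]
  df$sizeBp[is.na(df$sizeBp)] <- 0
  df$sizeBp[!intra] <- 0
  rownames(df) <- NULL
  df
}

#' Construct an SVCallSet
#'
#' Builds a normalized \linkS4class{SVCallSet} from a data.frame of junction
#' records. Chromosome names are normalized, breakends ordered (intra: by
#' position; inter: karyotypically), the SV type reconciled with chromosome
#' equality, and sizes filled in for intra-chromosomal junctions.
#'
#' @param calls data.frame with at least \code{id, chromA, posA, strandA,
#'   chromB, posB, strandB, svType}; optional \code{sizeBp, vaf, confidence,
#'   tier} (tier defaults to "RVA").
#' @return an \linkS4class{SVCallSet}.
#' @examples
#' SVCallSet(data.frame(id = "sv1", chromA = "chr2", posA = 500, strandA = "-",
#'                      chromB = "chr1", posB = 100, strandB = "+",
#'                      svType = "inter_translocation"))
#' @export
SVCallSet <- function(calls = data.frame()) {
  df <- as.data.frame(calls, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(id = character(), chromA = character(), posA = numeric(),
                     strandA = character(), chromB = character(), posB = numeric(),
                     strandB = character(), svType = character(), sizeBp = numeric(),
                     vaf = numeric(), confidence = numeric(), tier = character(),
                     stringsAsFactors = FALSE)
    return(new("SVCallSet", calls = df))
  }
  for (col in c("sizeBp", "vaf", "confidence")) if (is.null(df[[col]])) df[[col]] <- NA_real_
  if (is.null(df$tier)) df$tier <- "RVA"
  df$id <- as.character(df$id)
  df <- .normalizeSVFrame(df)
  ord <- order(chromRank(df$chromA), df$posA, chromRank(df$chromB), df$posB, df$id)
  cols <- c("id", "chromA", "posA", "strandA", "chromB", "posB", "strandB",
            "svType", "sizeBp", "vaf", "confidence", "tier")
  new("SVCallSet", calls = df[ord, cols, drop = FALSE])
}

#' @describeIn SVCallSet accessor for the normalized call table.
#' @param x an SVCallSet.
#' @export
svCalls <- function(x) {
  stopifnot(is(x, "SVCallSet"))
  df <- x@calls
  rownames(df) <- NULL
  df
}

#' @export
setMethod("length", "SVCallSet", function(x) nrow(x@calls))

setMethod("show", "SVCallSet", function(object) {
  df <- object@calls
  cat("SVCallSet with", nrow(df), "junction(s)\n")
  if (nrow(df)) {
    tab <- table(df$svType)
    cat("  types:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
    cat("  chromosomes:", paste(sortChrom(unique(c(df$chromA, df$chromB))),
                                collapse = " "), "\n")
  }
})

.cnvKind <- function(cn, ploidy, ampCN) {
  ifelse(cn >= ampCN & cn > ploidy, "amplification",
         ifelse(cn > ploidy, "gain", ifelse(cn < ploidy, "loss", "neutral")))
}

#' Construct a CNVSegmentSet
#'
#' @param segments data.frame with \code{chrom, start, end, cn}; optional
#'   \code{tier}.
#' @param ploidy assumed baseline copy number (default 2).
#' @param ampCN copy number at or above which a gain is classed as an
#'   amplification (default 5).
#' @return a \linkS4class{CNVSegmentSet} with the derived \code{kind} column.
#' @examples
#' CNVSegmentSet(data.frame(chrom = "12", start = 6e7, end = 7e7, cn = 12))
#' @export
CNVSegmentSet <- function(segments = data.frame(), ploidy = 2L, ampCN = 5L) {
  df <- as.data.frame(segments, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                     cn = integer(), kind = character(), tier = character(),
                     stringsAsFactors = FALSE)
    return(new("CNVSegmentSet", segments = df, ploidy = as.integer(ploidy)))
  }
  if (any(df$start >= df$end))
    stop("CNV segment with start >= end")
  df$chrom <- normChrom(df$chrom)
  df$cn <- as.integer(df$cn)
  df$kind <- .cnvKind(df$cn, ploidy, ampCN)
  if (is.null(df$tier)) df$tier <- "RVA"
  df <- df[order(chromRank(df$chrom), df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  new("CNVSegmentSet", segments = df, ploidy = as.integer(ploidy))
}

#' @describeIn CNVSegmentSet accessor for the segment table.
#' @param x a CNVSegmentSet.
#' @export
cnvSegments <- function(x) {
  stopifnot(is(x, "CNVSegmentSet"))
  df <- x@segments
  rownames(df) <- NULL
  df
}

#' @describeIn CNVSegmentSet assumed baseline ploidy.
#' @export
ploidy <- function(x) {
  stopifnot(is(x, "CNVSegmentSet"))
  x@ploidy
}

#' @export
setMethod("length", "CNVSegmentSet", function(x) nrow(x@segments))

setMethod("show", "CNVSegmentSet", function(object) {
  df <- object@segments
  cat("CNVSegmentSet with", nrow(df), "segment(s), ploidy", object@ploidy, "\n")
  if (nrow(df)) {
    tab <- table(df$kind)
    cat("  kinds:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})

#' Construct a GenePanel
#'
#' @param genes data.frame with \code{symbol, chrom, start, end, strand};
#'   optional \code{role} (default "other") and \code{cytoband}.
#' @return a \linkS4class{GenePanel}.
#' @export
GenePanel <- function(genes) {
  df <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (nrow(df)) {
    df$chrom <- normChrom(df$chrom)
    if (is.null(df$role)) df$role <- "other"
    if (is.null(df$cytoband)) df$cytoband <- NA_character_
    if (anyDuplicated(df$symbol))
      stop("duplicate gene symbol in panel: ",
           paste(unique(df$symbol[duplicated(df$symbol)]), collapse = ", "))
    df <- df[order(chromRank(df$chrom), df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  new("GenePanel", genes = df)
}

#' @describeIn GenePanel accessor for the gene table.
#' @param x a GenePanel.
#' @export
panelGenes <- function(x) {
  stopifnot(is(x, "GenePanel"))
  df <- x@genes
  rownames(df) <- NULL
  df
}

#' @export
setMethod("length", "GenePanel", function(x) nrow(x@genes))

setMethod("show", "GenePanel", function(object) {
  df <- object@genes
  cat("GenePanel with", nrow(df), "gene(s)\n")
  if (nrow(df)) {
    tab <- table(df$role)
    cat("  roles:", paste(names(tab), tab, sep = ":", collapse = " "), "\n")
  }
})

#' Construct a CytobandTable
#'
#' Bands are sorted on construction; within each chromosome they must be
#' non-overlapping and contiguous.
#'
#' @param bands data.frame with \code{chrom, start, end, band}; optional
#'   \code{stain}.
#' @return a \linkS4class{CytobandTable}.
#' @export
CytobandTable <- function(bands) {
  df <- as.data.frame(bands, stringsAsFactors = FALSE)
  if (nrow(df)) {
    df$chrom <- normChrom(df$chrom)
    if (is.null(df$stain)) df$stain <- "gneg"
    df <- df[order(chromRank(df$chrom), df$start), , drop = FALSE]
    rownames(df) <- NULL
  }
  new("CytobandTable", bands = df)
}

#' @describeIn CytobandTable accessor for the band table.
#' @param x a CytobandTable.
#' @export
cytobands <- function(x) {
  stopifnot(is(x, "CytobandTable"))
  df <- x@bands
  rownames(df) <- NULL
  df
}

setMethod("show", "CytobandTable", function(object) {
  df <- object@bands
  cat("CytobandTable with", nrow(df), "band(s) on",
      length(unique(df$chrom)), "chromosome(s)\n")
})

setMethod("show", "ToyGenome", function(object) {
  cat("ToyGenome:", length(object@chromSizes), "chromosomes,",
      round(sum(object@chromSizes) / 1e6), "Mb total,",
      sum(lengths(object@labels)), "labels, seed", object@seed, "\n")
})

setMethod("show", "CaseReport", function(object) {
  cat("CaseReport", object@caseId, "(", object@subtype, ")\n")
  cat("  QC tier:        ", object@qcTier, "\n")
  cat("  expected rule:  ", formatAlterationRule(object@expectedRule), "\n")
  cat("  detected:       ", object@detected,
      if (object@detected) paste0(" [", object@detectionTier, "]") else "", "\n", sep = "")
  cat("  chromoanagenesis:", object@chromoClass, "\n")
  if (length(object@iscn))
    cat("  ISCN:           ", paste(object@iscn, collapse = ", "), "\n")
})

## Accessors for CaseReport ---------------------------------------------------

#' @describeIn CaseReport QC tier of the case.
#' @param x a CaseReport.
#' @export
qcTier <- function(x) { stopifnot(is(x, "CaseReport")); x@qcTier }

#' @describeIn CaseReport whether the expected alteration was detected.
#' @export
isDetected <- function(x) { stopifnot(is(x, "CaseReport")); x@detected }

#' @describeIn CaseReport pipeline tier that detected the expected alteration.
#' @export
detectionTier <- function(x) { stopifnot(is(x, "CaseReport")); x@detectionTier }

#' @describeIn CaseReport chromoanagenesis class of the case.
#' @export
chromoClass <- function(x) { stopifnot(is(x, "CaseReport")); x@chromoClass }

#' @describeIn CaseReport event tables (fusions, gene CNV events, chains, regions).
#' @export
caseEvents <- function(x) { stopifnot(is(x, "CaseReport")); x@events }
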