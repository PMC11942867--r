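## Gene-fusion inference from junction breakend orientations.
##
## A junction produces a candidate fusion when both breakends fall inside
## distinct panel gene bodies and the reconstructed derivative reads 5'->3'
## from one gene's promoter-side portion through the junction into the other
## gene's 3'-side portion.
##
## With the BEDPE orientation convention ("+" = the reference segment below
## the breakpoint enters the junction left-to-right; "-" = the segment above
## enters reverse-complemented), traversal of the derivative enters the
## junction along breakend A moving in the direction given by strandA, and
## leaves through breakend B moving opposite to strandB. Gene A can donate
## its 5' (promoter-side) portion exactly when the entry direction equals its
## transcription strand; gene B can accept as 3' partner exactly when the
## exit direction equals its transcription strand. Hence:
##   A 5' -> B 3'  iff  strandA == strand(geneA)  and  strandB != strand(geneB)
##   B 5' -> A 3'  iff  strandB == strand(geneB)  and  strandA != strand(geneA)
## The two conditions are mutually exclusive, so a junction yields at most one
## orientation per gene pair. A canonical deletion junction (+/-) between an
## adjacent opposite-strand pair (the NAB2/STAT6 configuration) is therefore
## incompatible, while an inversion junction (+/+ or -/-) is compatible.

.flipStrand <- function(s) ifelse(s == "+", "-", "+")

.genesAtPoint <- function(chrom, pos, genes) {
  hit <- genes$chrom == chrom & genes$start <= pos & pos < genes$end
  g <- genes[hit, , drop = FALSE]
  ## when a breakend lies in overlapping genes, rank the smaller (more
  ## specific) gene first
  g[order(g$end - g$start), , drop = FALSE]
}

.mechanismFromType <- function(svType) {
  switch(svType,
         inversion = "inversion", deletion = "deletion",
         duplication = "duplication", insertion = "insertion",
         "translocation")
}

#' Infer candidate gene fusions from SV junctions
#'
#' For every junction whose two breakends fall within gene bodies of distinct
#' panel genes, evaluates breakend-orientation compatibility with a 5'->3'
#' read-through on a derivative chromosome and emits the fusion with its 5'
#' and 3' partners. Incompatible gene-pair junctions can be retained for
#' auditing with \code{keepIncompatible = TRUE}.
#'
#' @param svs an \linkS4class{SVCallSet}.
#' @param panel a \linkS4class{GenePanel} (strands required).
#' @param bands optional \linkS4class{CytobandTable} used to attach ISCN
#'   strings.
#' @param keepIncompatible also return orientation-incompatible gene-pair
#'   junctions, flagged \code{compatible = FALSE} (default FALSE).
#' @return data.frame with columns \code{fivePrime, threePrime, svId,
#'   compatible, mechanism, tier, iscn}.
#' @examples
#' panel <- GenePanel(data.frame(
#'   symbol = c("NAB2", "STAT6"), chrom = "12",
#'   start = c(1e6, 1.12e6), end = c(1.1e6, 1.2e6), strand = c("+", "-")))
#' inv <- SVCallSet(data.frame(id = "sv1", chromA = "12", posA = 1.05e6,
#'                             strandA = "+", chromB = "12", posB = 1.15e6,
#'                             strandB = "+", svType = "inversion"))
#' inferFusions(inv, panel)
#' @export
inferFusions <- function(svs, panel, bands = NULL, keepIncompatible = FALSE) {
  genes <- panelGenes(panel)
  sdf <- svCalls(svs)
  out <- list()
  for (i in seq_len(nrow(sdf))) {
    sv <- sdf[i, ]
    gA <- .genesAtPoint(sv$chromA, sv$posA, genes)
    gB <- .genesAtPoint(sv$chromB, sv$posB, genes)
    if (nrow(gA) == 0 || nrow(gB) == 0) next
    for (a in seq_len(nrow(gA))) for (b in seq_len(nrow(gB))) {
      geneA <- gA[a, ]; geneB <- gB[b, ]
      if (geneA$symbol == geneB$symbol) next
      aFive <- sv$strandA == geneA$strand && sv$strandB != geneB$strand
      bFive <- sv$strandB == geneB$strand && sv$strandA != geneA$strand
      compatible <- aFive || bFive
      if (!compatible && !keepIncompatible) next
      five <- if (aFive) geneA else if (bFive) geneB else geneA
      three <- if (aFive) geneB else if (bFive) geneA else geneB
      iscn <- NA_character_
      if (!is.null(bands) && compatible) {
        iscn <- tryCatch(.fusionISCN(sv, bands), error = function(e) NA_character_)
      }
      out[[length(out) + 1]] <- data.frame(
        fivePrime = five$symbol, threePrime = three$symbol, svId = sv$id,
        compatible = compatible, mechanism = .mechanismFromType(sv$svType),
        tier = sv$tier, iscn = iscn, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(fivePrime = character(), threePrime = character(),
                      svId = character(), compatible = logical(),
                      mechanism = character(), tier = character(),
                      iscn = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.fusionISCN <- function(sv, bands) {
  bandA <- assignCytoband(sv$chromA, sv$posA, bands)
  bandB <- assignCytoband(sv$chromB, sv$posB, bands)
  if (sv$chromA == sv$chromB && sv$svType == "inversion") {
    formatISCN(list(kind = "inversion", chrom = sv$chromA,
                    bandStart = bandA, bandEnd = bandB))
  } else {
    formatISCN(list(kind = "translocation", chromA = sv$chromA, bandA = bandA,
                    chromB = sv$chromB, bandB = bandB))
  }
}

#' Single-junction fusion inference
#'
#' Convenience wrapper over \code{\link{inferFusions}} for one junction;
#' mirrors the one-call-at-a-time interface.
#'
#' @param sv a one-row \linkS4class{SVCallSet} (or coercible data.frame).
#' @param panel a \linkS4class{GenePanel}.
#' @param bands optional \linkS4class{CytobandTable}.
#' @return a one-row fusion data.frame, or \code{NULL} when the junction does
#'   not produce a compatible fusion.
#' @export
inferFusion <- function(sv, panel, bands = NULL) {
  if (!is(sv, "SVCallSet")) sv <- SVCallSet(sv)
  res <- inferFusions(sv, panel, bands = bands)
  if (nrow(res) == 0) return(NULL)
  res[1, , drop = FALSE]
}

#' Report single-gene rearrangements
#'
#' SVs with at least one breakend inside a panel gene body, reported as
#' (gene, svId) records — the grammar used for expected alterations such as a
#' PHF1 rearrangement.
#'
#' @param svs an \linkS4class{SVCallSet}.
#' @param panel a \linkS4class{GenePanel}.
#' @return data.frame with columns \code{gene, svId, svType, tier}.
#' @export
geneRearrangements <- function(svs, panel) {
  genes <- panelGenes(panel)
  sdf <- svCalls(svs)
  out <- list()
  for (i in seq_len(nrow(sdf))) {
    sv <- sdf[i, ]
    hit <- rbind(.genesAtPoint(sv$chromA, sv$posA, genes),
                 .genesAtPoint(sv$chromB, sv$posB, genes))
    for (sym in unique(hit$symbol))
      out[[length(out) + 1]] <- data.frame(
        gene = sym, svId = sv$id, svType = sv$svType, tier = sv$tier,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene = character(), svId = character(),
                      svType = character(), tier = character(),
                      stringsAsFactors = FALSE))
  res <- unique(do.call(rbind, out))
  rownames(res) <- NULL
  res
}
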