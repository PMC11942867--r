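## Cytoband assignment, ISCN-style nomenclature, expected-alteration matching
## and cohort reporting.
##
## The ISCN surface is deliberately a small grammar subset: t(A;B)(bA;bB),
## inv(A)(b1b2), -N (whole-chromosome loss) and amp(GENE)(chrom+band).

#' Assign the cytoband containing a position
#'
#' Bands are half-open [start, end); a position on a band start belongs to
#' that band.
#'
#' @param chrom chromosome name.
#' @param pos 0-based base-pair position.
#' @param bands a \linkS4class{CytobandTable}.
#' @return the band name, e.g. \code{"q15"}.
#' @export
assignCytoband <- function(chrom, pos, bands) {
  chrom <- normChrom(chrom)
  df <- cytobands(bands)
  b <- df[df$chrom == chrom & df$start <= pos & pos < df$end, , drop = FALSE]
  if (nrow(b) == 0)
    stop("position ", chrom, ":", pos, " not covered by the cytoband table")
  b$band[1]
}

#' Format an event as an ISCN-style string
#'
#' Supported kinds: \code{translocation} (fields chromA, bandA, chromB,
#' bandB; partners emitted in karyotypic order), \code{inversion} (chrom,
#' bandStart, bandEnd), \code{monosomy} (chrom), \code{amplification} (gene,
#' chrom, band).
#'
#' @param event a list with a \code{kind} field and kind-specific fields.
#' @return character ISCN-style string, e.g. \code{"t(6;17)(p21.31;p13.2)"}.
#' @examples
#' formatISCN(list(kind = "translocation", chromA = "17", bandA = "p13.2",
#'                 chromB = "6", bandB = "p21.31"))
#' formatISCN(list(kind = "monosomy", chrom = "13"))
#' @export
formatISCN <- function(event) {
  if (is.null(event$kind)) stop("event must carry a 'kind' field")
  switch(event$kind,
    translocation = {
      a <- list(chrom = normChrom(event$chromA), band = event$bandA)
      b <- list(chrom = normChrom(event$chromB), band = event$bandB)
      if (chromRank(b$chrom) < chromRank(a$chrom)) { tmp <- a; a <- b; b <- tmp }
      sprintf("t(%s;%s)(%s;%s)", a$chrom, b$chrom, a$band, b$band)
    },
    inversion = sprintf("inv(%s)(%s%s)", normChrom(event$chrom),
                        event$bandStart, event$bandEnd),
    monosomy = sprintf("-%s", normChrom(event$chrom)),
    amplification = sprintf("amp(%s)(%s%s)", event$gene,
                            normChrom(event$chrom), event$band),
    stop("unknown event kind: ", event$kind)
  )
}

#' Parse an ISCN-style string emitted by formatISCN
#'
#' Inverse of \code{\link{formatISCN}} over the emitted grammar subset;
#' recovers chromosome and band fields exactly.
#'
#' @param x character ISCN-style string.
#' @return list with a \code{kind} field and the same fields formatISCN
#'   consumes.
#' @export
parseISCN <- function(x) {
  if (grepl("^t\\(", x)) {
    m <- regmatches(x, regexec("^t\\(([^;]+);([^)]+)\\)\\(([^;]+);([^)]+)\\)$", x))[[1]]
    if (length(m) != 5) stop("unparsable translocation string: ", x)
    return(list(kind = "translocation", chromA = m[2], bandA = m[4],
                chromB = m[3], bandB = m[5]))
  }
  if (grepl("^inv\\(", x)) {
    m <- regmatches(x, regexec("^inv\\(([^)]+)\\)\\(([pq][0-9.]+)([pq][0-9.]+)\\)$", x))[[1]]
    if (length(m) != 4) stop("unparsable inversion string: ", x)
    return(list(kind = "inversion", chrom = m[2], bandStart = m[3], bandEnd = m[4]))
  }
  if (grepl("^-", x)) return(list(kind = "monosomy", chrom = sub("^-", "", x)))
  if (grepl("^amp\\(", x)) {
    m <- regmatches(x, regexec("^amp\\(([^)]+)\\)\\(([0-9XY]+)([pq][0-9.]+)\\)$", x))[[1]]
    if (length(m) != 4) stop("unparsable amplification string: ", x)
    return(list(kind = "amplification", gene = m[2], chrom = m[3], band = m[4]))
  }
  stop("unrecognized ISCN-style string: ", x)
}

#' Build an expected-alteration rule
#'
#' The closed rule grammar for expected alterations per sarcoma subtype:
#' \code{fusion(geneA, geneB)}, \code{gene_rearrangement(gene)},
#' \code{amplification(gene)}, or \code{cnv_sv_any} (any prioritized SV or
#' CNV).
#'
#' @param form one of \code{"fusion"}, \code{"gene_rearrangement"},
#'   \code{"amplification"}, \code{"cnv_sv_any"}.
#' @param ... rule arguments (gene symbols).
#' @return a rule list with fields \code{form} and \code{genes}.
#' @export
alterationRule <- function(form = c("fusion", "gene_rearrangement",
                                    "amplification", "cnv_sv_any"), ...) {
  form <- match.arg(form)
  genes <- as.character(unlist(list(...)))
  n <- c(fusion = 2L, gene_rearrangement = 1L, amplification = 1L,
         cnv_sv_any = 0L)[[form]]
  if (length(genes) != n)
    stop("rule form '", form, "' takes ", n, " gene argument(s)")
  list(form = form, genes = genes)
}

#' @describeIn alterationRule render a rule as text, e.g. "fusion(NAB2,STAT6)".
#' @param rule a rule list.
#' @export
formatAlterationRule <- function(rule) {
  if (rule$form == "cnv_sv_any") return("cnv_sv_any")
  sprintf("%s(%s)", rule$form, paste(rule$genes, collapse = ","))
}

#' @describeIn alterationRule parse the textual rule form.
#' @param x character rule text.
#' @export
parseAlterationRule <- function(x) {
  x <- trimws(x)
  if (x == "cnv_sv_any") return(alterationRule("cnv_sv_any"))
  m <- regmatches(x, regexec("^([a-z_]+)\\(([^)]*)\\)$", x))[[1]]
  if (length(m) != 3) stop("unparsable rule: ", x)
  genes <- trimws(strsplit(m[3], ",")[[1]])
  do.call(alterationRule, c(list(form = m[2]), as.list(genes)))
}

#' Match an expected-alteration rule against detected events
#'
#' \itemize{
#'   \item \code{fusion(a,b)}: any compatible fusion call with that
#'     (order-insensitive) gene pair;
#'   \item \code{amplification(g)}: a gene-level amplification event for g;
#'   \item \code{gene_rearrangement(g)}: any SV with a breakend in g;
#'   \item \code{cnv_sv_any}: any surviving prioritized SV or CNV.
#' }
#' The detection tier is RVA when at least one matching event carries the
#' RVA flag, DENOVO when matches exist only from the assembly tier, NONE
#' otherwise.
#'
#' @param rule a rule from \code{\link{alterationRule}}.
#' @param events event list with components \code{fusions},
#'   \code{geneCNV}, \code{rearrangements} (data.frames as produced by
#'   \code{\link{inferFusions}}, \code{\link{callGeneCNV}},
#'   \code{\link{geneRearrangements}}), and \code{svs}/\code{cnvs}
#'   (\linkS4class{SVCallSet}/\linkS4class{CNVSegmentSet}).
#' @return list with \code{detected} (logical) and \code{tier} ("RVA",
#'   "DENOVO" or "NONE").
#' @export
matchExpected <- function(rule, events) {
  tiers <- switch(rule$form,
    fusion = {
      f <- events$fusions
      if (is.null(f) || nrow(f) == 0) character() else {
        hit <- f$compatible &
          (f$fivePrime == rule$genes[1] & f$threePrime == rule$genes[2] |
           f$fivePrime == rule$genes[2] & f$threePrime == rule$genes[1])
        f$tier[hit]
      }
    },
    amplification = {
      g <- events$geneCNV
      if (is.null(g) || nrow(g) == 0) character()
      else g$tier[g$event == "amplification" & g$gene == rule$genes[1]]
    },
    gene_rearrangement = {
      r <- events$rearrangements
      if (is.null(r) || nrow(r) == 0) character()
      else r$tier[r$gene == rule$genes[1]]
    },
    cnv_sv_any = {
      sv <- if (is.null(events$svs)) character() else svCalls(events$svs)$tier
      cnv <- if (is.null(events$cnvs)) character() else {
        seg <- cnvSegments(events$cnvs)
        seg$tier[seg$kind != "neutral"]
      }
      c(sv, cnv)
    },
    stop("unknown rule form: ", rule$form)
  )
  if (!length(tiers)) return(list(detected = FALSE, tier = "NONE"))
  list(detected = TRUE, tier = if (any(tiers == "RVA")) "RVA" else "DENOVO")
}

#' Summarize a cohort of case reports
#'
#' @param reports list of \linkS4class{CaseReport} objects.
#' @return list with components \code{nCases}, \code{detected} (n, fraction),
#'   \code{byTier} (RVA / DENOVO counts among detected),
#'   \code{byCategory} (detected counts per expected-alteration category),
#'   \code{chromoanagenesis} (class counts), and \code{table}
#'   (per-case data.frame).
#' @export
cohortReport <- function(reports) {
  if (!length(reports)) stop("empty cohort")
  tab <- do.call(rbind, lapply(reports, function(r) data.frame(
    caseId = r@caseId, subtype = r@subtype, qcTier = r@qcTier,
    expected = formatAlterationRule(r@expectedRule),
    category = .ruleCategory(r@expectedRule, r@events),
    detected = r@detected, tier = r@detectionTier,
    chromoClass = r@chromoClass, stringsAsFactors = FALSE)))
  rownames(tab) <- NULL
  n <- nrow(tab)
  det <- sum(tab$detected)
  list(
    nCases = n,
    detected = list(n = det, fraction = det / n,
                    pct = round(100 * det / n, 1)),
    byTier = list(RVA = sum(tab$detected & tab$tier == "RVA"),
                  DENOVO = sum(tab$detected & tab$tier == "DENOVO")),
    byCategory = tapply(tab$detected, tab$category, sum),
    chromoanagenesis = table(factor(tab$chromoClass, levels = .CHROMO_CLASSES)),
    table = tab)
}

## expected-alteration category used in cohort summaries: fusion-type
## (fusion or single-gene rearrangement, including cases whose defining
## fusion emerged on review), MDM2-amplification, or non-specific CNV+SV
.ruleCategory <- function(rule, events) {
  if (!is.null(events$category)) return(events$category)
  switch(rule$form,
         fusion = "fusion",
         gene_rearrangement = "fusion",
         amplification = if (identical(rule$genes, "MDM2")) "mdm2_amplification"
                         else "amplification",
         cnv_sv_any = "cnv_sv")
}
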