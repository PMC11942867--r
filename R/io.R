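## Readers and writers for SV/CNV call sets, gene panels, cytoband tables and
## QC metric tables. Internal coordinates are 0-based half-open; BEDPE/BED are
## native, VCF is converted on read. All readers accept gzip-compressed input.

.readLinesAny <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .openConn(path)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

.dropComments <- function(lines) {
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

## splits TSV lines, enforcing a minimum column count; errors name the line
.splitRows <- function(lines, lineno, minCols, what) {
  rows <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(rows)
  if (any(nc < minCols))
    stop(what, ": malformed row at line ", lineno[which(nc < minCols)[1]],
         " (expected >= ", minCols, " columns, found ", nc[nc < minCols][1], ")")
  rows
}

.asNum <- function(x, lineno, what, field) {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v) & !x %in% c(".", "", "NA")))
    stop(what, ": malformed row at line ", lineno[which(is.na(v))[1]],
         " (non-numeric ", field, ")")
  v
}

## drops records on unrecognized chromosomes with one summary warning
.filterKnownChrom <- function(df, chromCols, what) {
  known <- rep(TRUE, nrow(df))
  for (cc in chromCols) known <- known & .isKnownChrom(df[[cc]])
  if (any(!known))
    warning(what, ": skipped ", sum(!known),
            " record(s) on unrecognized chromosomes", call. = FALSE)
  df[known, , drop = FALSE]
}

## inferred junction type from chromosomes and BEDPE breakend orientations
.inferSVType <- function(chromA, chromB, strandA, strandB) {
  ifelse(chromA != chromB, "inter_translocation",
         ifelse(strandA == "+" & strandB == "-", "deletion",
                ifelse(strandA == "-" & strandB == "+", "duplication", "inversion")))
}

#' Read a structural variant call table
#'
#' Reads SV junction calls in one of three dialects and returns a normalized
#' \linkS4class{SVCallSet}.
#'
#' \describe{
#'   \item{\code{bedpe}}{10+ column BEDPE: chrom1 start1 end1 chrom2 start2
#'     end2 name score strand1 strand2, with optional extra columns
#'     \code{sv_type}, \code{vaf}, \code{confidence}, \code{tier}. Breakend
#'     positions are the \code{start} fields (0-based). Without a type column
#'     the type is inferred from chromosomes and orientations.}
#'   \item{\code{smap_like}}{TSV with a header naming at least
#'     \code{SmapId, RefcontigId1, RefcontigId2, RefStartPos, RefEndPos, Type};
#'     optional \code{VAF}, \code{Confidence}. Only these columns are consumed.
#'     Numeric contig ids 23/24 map to X/Y. Breakend orientations are assigned
#'     canonically from the type (deletion +/-, duplication -/+,
#'     inversion +/+, translocation +/-).}
#'   \item{\code{vcf_bnd}}{VCF with BND breakend notation for junctions
#'     (both mates or single records) and optionally symbolic
#'     \code{<DEL>/<DUP>/<INV>} records with an INFO END. Requires the
#'     VariantAnnotation package. 1-based positions are converted to 0-based.}
#' }
#'
#' Malformed rows raise an error naming the line; records on unrecognized
#' chromosomes are skipped with a warning giving the count.
#'
#' @param path input file (may be gzip-compressed).
#' @param dialect one of \code{"bedpe"}, \code{"smap_like"}, \code{"vcf_bnd"}.
#' @return an \linkS4class{SVCallSet}.
#' @export
readSVTable <- function(path, dialect = c("bedpe", "smap_like", "vcf_bnd")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         bedpe = .readBEDPE(path),
         smap_like = .readSMAPLike(path),
         vcf_bnd = .readVCFBnd(path))
}

.readBEDPE <- function(path) {
  x <- .dropComments(.readLinesAny(path))
  if (!length(x$lines)) return(SVCallSet())
  rows <- .splitRows(x$lines, x$lineno, 10, "BEDPE")
  get <- function(i) vapply(rows, function(r) if (length(r) >= i) r[i] else NA_character_, "")
  df <- data.frame(
    chromA = get(1),
    posA = .asNum(get(2), x$lineno, "BEDPE", "start1"),
    chromB = get(4),
    posB = .asNum(get(5), x$lineno, "BEDPE", "start2"),
    id = get(7), strandA = get(9), strandB = get(10),
    stringsAsFactors = FALSE)
  df$svType <- get(11)
  df$vaf <- suppressWarnings(as.numeric(get(12)))
  df$confidence <- suppressWarnings(as.numeric(get(13)))
  tier <- get(14)
  df$tier <- ifelse(is.na(tier) | tier %in% c(".", ""), "RVA", tier)
  if (any(!df$strandA %in% c("+", "-")) || any(!df$strandB %in% c("+", "-")))
    stop("BEDPE: malformed row at line ",
         x$lineno[which(!df$strandA %in% c("+", "-") | !df$strandB %in% c("+", "-"))[1]],
         " (bad strand)")
  df <- .filterKnownChrom(df, c("chromA", "chromB"), "BEDPE")
  miss <- is.na(df$svType) | df$svType %in% c(".", "")
  df$svType[miss] <- .inferSVType(normChrom(df$chromA[miss]), normChrom(df$chromB[miss]),
                                  df$strandA[miss], df$strandB[miss])
  SVCallSet(df)
}

.SMAP_STRANDS <- list(deletion = c("+", "-"), insertion = c("+", "-"),
                      duplication = c("-", "+"), inversion = c("+", "+"),
                      intra_translocation = c("+", "-"),
                      inter_translocation = c("+", "-"))

.smapType <- function(x) {
  x <- tolower(x)
  ifelse(grepl("^trans", x) & grepl("interchr", x), "inter_translocation",
  ifelse(grepl("^trans", x), "intra_translocation",
  ifelse(grepl("^del", x), "deletion",
  ifelse(grepl("^ins", x), "insertion",
  ifelse(grepl("^dup", x), "duplication",
  ifelse(grepl("^inv", x), "inversion", NA_character_))))))
}

.contigToChrom <- function(x) {
  n <- suppressWarnings(as.integer(x))
  out <- as.character(x)
  out[!is.na(n) & n == 23] <- "X"
  out[!is.na(n) & n == 24] <- "Y"
  out
}

.readSMAPLike <- function(path) {
  x <- .readLinesAny(path)
  hdrIdx <- grep("SmapId", x)[1]
  if (is.na(hdrIdx)) stop("SMAP-like: no header row naming SmapId found")
  header <- strsplit(sub("^#h?\\s*", "", x[hdrIdx]), "\t", fixed = TRUE)[[1]]
  header <- trimws(header)
  body <- x[-seq_len(hdrIdx)]
  keep <- nzchar(trimws(body)) & !grepl("^#", body)
  lineno <- (hdrIdx + seq_along(body))[keep]
  body <- body[keep]
  if (!length(body)) return(SVCallSet())
  rows <- .splitRows(body, lineno, length(header), "SMAP-like")
  col <- function(nm) {
    i <- match(nm, header)
    if (is.na(i)) return(NULL)
    vapply(rows, `[`, "", i)
  }
  need <- c("SmapId", "RefcontigId1", "RefcontigId2", "RefStartPos", "RefEndPos", "Type")
  if (!all(need %in% header))
    stop("SMAP-like: missing required column(s): ",
         paste(setdiff(need, header), collapse = ", "))
  type <- .smapType(col("Type"))
  if (any(is.na(type)))
    stop("SMAP-like: malformed row at line ", lineno[which(is.na(type))[1]],
         " (unknown Type)")
  strands <- t(vapply(type, function(tt) .SMAP_STRANDS[[tt]], c("", "")))
  vafCol <- col("VAF"); confCol <- col("Confidence")
  df <- data.frame(
    id = paste0("smap", col("SmapId")),
    chromA = .contigToChrom(col("RefcontigId1")),
    posA = .asNum(col("RefStartPos"), lineno, "SMAP-like", "RefStartPos"),
    strandA = strands[, 1],
    chromB = .contigToChrom(col("RefcontigId2")),
    posB = .asNum(col("RefEndPos"), lineno, "SMAP-like", "RefEndPos"),
    strandB = strands[, 2],
    svType = type,
    vaf = if (is.null(vafCol)) NA_real_ else suppressWarnings(as.numeric(vafCol)),
    confidence = if (is.null(confCol)) NA_real_ else suppressWarnings(as.numeric(confCol)),
    stringsAsFactors = FALSE)
  df <- .filterKnownChrom(df, c("chromA", "chromB"), "SMAP-like")
  SVCallSet(df)
}

## VCF BND bracket notation -> BEDPE-style breakend orientations:
##   t[p[ -> +/-   t]p] -> +/+   ]p]t -> -/+   [p[t -> -/-
.parseBndAlt <- function(alt) {
  m <- regmatches(alt, regexec("([\\[\\]])([^:\\[\\]]+):([0-9]+)([\\[\\]])",
                               alt, perl = TRUE))[[1]]
  if (length(m) != 5) return(NULL)
  bracket <- m[2]
  before <- regexpr("[][]", alt) > 1  # replacement sequence precedes bracket
  if (before && bracket == "[") s <- c("+", "-")
  else if (before && bracket == "]") s <- c("+", "+")
  else if (!before && bracket == "]") s <- c("-", "+")
  else s <- c("-", "-")
  list(chrom = m[3], pos = as.numeric(m[4]), strandA = s[1], strandB = s[2])
}

.readVCFBnd <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("the 'vcf_bnd' dialect requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gr <- SummarizedExperiment::rowRanges(vcf)
  if (!length(gr)) return(SVCallSet())
  chrom <- as.character(GenomicRanges::seqnames(gr))
  pos <- GenomicRanges::start(gr)          # 1-based
  ids <- names(gr)
  alts <- vapply(as.list(VariantAnnotation::fixed(vcf)$ALT),
                 function(a) as.character(a)[1], "")
  info <- VariantAnnotation::info(vcf)
  svtype <- if ("SVTYPE" %in% names(info)) as.character(info$SVTYPE) else rep(NA, length(gr))
  endpos <- if ("END" %in% names(info)) suppressWarnings(as.numeric(unlist(info$END))) else rep(NA, length(gr))
  vaf <- if ("VAF" %in% names(info)) suppressWarnings(as.numeric(unlist(info$VAF))) else rep(NA, length(gr))

  out <- list()
  seen <- character()
  for (i in seq_along(gr)) {
    bnd <- .parseBndAlt(alts[i])
    if (!is.null(bnd)) {
      ## emit each mate pair once: keep the record whose breakend sorts first
      if (!.breakendLE(chrom[i], pos[i], bnd$chrom, bnd$pos) ||
          paste(bnd$chrom, bnd$pos, chrom[i], pos[i]) %in% seen) next
      seen <- c(seen, paste(chrom[i], pos[i], bnd$chrom, bnd$pos))
      out[[length(out) + 1]] <- data.frame(
        id = ids[i], chromA = chrom[i], posA = pos[i] - 1, strandA = bnd$strandA,
        chromB = bnd$chrom, posB = bnd$pos - 1, strandB = bnd$strandB,
        svType = if (normChrom(chrom[i]) == normChrom(bnd$chrom))
          .inferSVType(chrom[i], chrom[i], bnd$strandA, bnd$strandB)
        else "inter_translocation",
        vaf = vaf[i], stringsAsFactors = FALSE)
    } else if (!is.na(svtype[i]) && svtype[i] %in% c("DEL", "DUP", "INV", "INS") &&
               !is.na(endpos[i])) {
      tt <- c(DEL = "deletion", DUP = "duplication",
              INV = "inversion", INS = "insertion")[[svtype[i]]]
      ss <- .SMAP_STRANDS[[tt]]
      out[[length(out) + 1]] <- data.frame(
        id = ids[i], chromA = chrom[i], posA = pos[i] - 1, strandA = ss[1],
        chromB = chrom[i], posB = endpos[i] - 1, strandB = ss[2],
        svType = tt, vaf = vaf[i], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(SVCallSet())
  df <- do.call(rbind, out)
  df <- .filterKnownChrom(df, c("chromA", "chromB"), "VCF")
  SVCallSet(df)
}

#' Write an SVCallSet as BEDPE
#'
#' Writes the normalized call set in the extended BEDPE layout accepted by
#' \code{\link{readSVTable}} (columns 11-14: sv_type, vaf, confidence, tier),
#' so that write-then-read round-trips exactly.
#'
#' @param x an \linkS4class{SVCallSet}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeSVTable <- function(x, path) {
  df <- svCalls(x)
  dot <- function(v) ifelse(is.na(v), ".", as.character(v))
  out <- data.frame(df$chromA, format(df$posA, scientific = FALSE, trim = TRUE),
                    format(df$posA + 1, scientific = FALSE, trim = TRUE),
                    df$chromB, format(df$posB, scientific = FALSE, trim = TRUE),
                    format(df$posB + 1, scientific = FALSE, trim = TRUE),
                    df$id, ".", df$strandA, df$strandB,
                    df$svType, dot(df$vaf), dot(df$confidence), df$tier)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CNV segment table
#'
#' Accepts either a headered TSV (\code{chrom start end cn [tier]}) or a
#' BED-like 4-column file whose fourth field is \code{cn=<int>} or a bare
#' integer. Segments with \code{start >= end} are rejected; unrecognized
#' chromosomes are skipped with a warning.
#'
#' @param path input file (may be gzip-compressed).
#' @param ploidy,ampCN passed to \code{\link{CNVSegmentSet}}.
#' @return a \linkS4class{CNVSegmentSet}.
#' @export
readCNVTable <- function(path, ploidy = 2L, ampCN = 5L) {
  x <- .dropComments(.readLinesAny(path))
  if (!length(x$lines)) return(CNVSegmentSet(ploidy = ploidy, ampCN = ampCN))
  first <- strsplit(x$lines[1], "\t", fixed = TRUE)[[1]]
  hasHeader <- any(tolower(first) %in% c("chrom", "chr", "chromosome"))
  lines <- x$lines; lineno <- x$lineno
  if (hasHeader) { lines <- lines[-1]; lineno <- lineno[-1] }
  if (!length(lines)) return(CNVSegmentSet(ploidy = ploidy, ampCN = ampCN))
  rows <- .splitRows(lines, lineno, 4, "CNV table")
  get <- function(i) vapply(rows, function(r) if (length(r) >= i) r[i] else NA_character_, "")
  cnRaw <- sub("^cn=", "", get(4))
  df <- data.frame(
    chrom = get(1),
    start = .asNum(get(2), lineno, "CNV table", "start"),
    end = .asNum(get(3), lineno, "CNV table", "end"),
    cn = .asNum(cnRaw, lineno, "CNV table", "cn"),
    stringsAsFactors = FALSE)
  tier <- get(5)
  df$tier <- ifelse(is.na(tier) | tier %in% c(".", ""), "RVA", tier)
  if (any(df$start >= df$end))
    stop("CNV table: segment with start >= end at line ",
         lineno[which(df$start >= df$end)[1]])
  df <- .filterKnownChrom(df, "chrom", "CNV table")
  CNVSegmentSet(df, ploidy = ploidy, ampCN = ampCN)
}

#' Write a CNVSegmentSet as a headered TSV
#' @param x a \linkS4class{CNVSegmentSet}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeCNVTable <- function(x, path) {
  df <- cnvSegments(x)[, c("chrom", "start", "end", "cn", "tier")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene panel from a BED6 file
#'
#' BED6 columns chrom/start/end/name/score/strand, with optional columns 7
#' (role) and 8 (cytoband). Duplicate symbols are an error.
#'
#' @param path input BED file (may be gzip-compressed).
#' @return a \linkS4class{GenePanel}.
#' @export
readGeneBed <- function(path) {
  x <- .dropComments(.readLinesAny(path))
  if (!length(x$lines)) return(GenePanel(data.frame()))
  rows <- .splitRows(x$lines, x$lineno, 6, "gene BED")
  get <- function(i) vapply(rows, function(r) if (length(r) >= i) r[i] else NA_character_, "")
  df <- data.frame(
    chrom = get(1),
    start = .asNum(get(2), x$lineno, "gene BED", "start"),
    end = .asNum(get(3), x$lineno, "gene BED", "end"),
    symbol = get(4), strand = get(6),
    stringsAsFactors = FALSE)
  role <- get(7); band <- get(8)
  df$role <- ifelse(is.na(role) | role %in% c(".", ""), "other", role)
  df$cytoband <- ifelse(is.na(band) | band %in% c(".", ""), NA_character_, band)
  if (any(df$start >= df$end))
    stop("gene BED: start >= end at line ", x$lineno[which(df$start >= df$end)[1]])
  df <- .filterKnownChrom(df, "chrom", "gene BED")
  GenePanel(df)
}

#' Write a gene panel as BED6(+2)
#' @param x a \linkS4class{GenePanel}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeGeneBed <- function(x, path) {
  df <- panelGenes(x)
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    df$symbol, 0, df$strand, df$role,
                    ifelse(is.na(df$cytoband), ".", df$cytoband))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a cytoband table (UCSC cytoBand layout)
#'
#' Five tab-separated columns: chrom, start, end, band name, Giemsa stain.
#' Rows are sorted on load.
#'
#' @param path input file (may be gzip-compressed).
#' @return a \linkS4class{CytobandTable}.
#' @export
readCytobands <- function(path) {
  x <- .dropComments(.readLinesAny(path))
  if (!length(x$lines)) return(CytobandTable(data.frame()))
  rows <- .splitRows(x$lines, x$lineno, 4, "cytoband table")
  get <- function(i) vapply(rows, function(r) if (length(r) >= i) r[i] else NA_character_, "")
  df <- data.frame(
    chrom = get(1),
    start = .asNum(get(2), x$lineno, "cytoband table", "start"),
    end = .asNum(get(3), x$lineno, "cytoband table", "end"),
    band = get(4),
    stain = { s <- get(5); ifelse(is.na(s), "gneg", s) },
    stringsAsFactors = FALSE)
  df <- .filterKnownChrom(df, "chrom", "cytoband table")
  CytobandTable(df)
}

#' Read a per-sample QC metric table
#'
#' Headered TSV with columns \code{sample_id, total_dna_gbp, map_rate_pct,
#' effective_coverage} and optional \code{label_density, plv, nlv}.
#'
#' @param path input file (may be gzip-compressed).
#' @return data.frame of QC metrics, one row per sample.
#' @export
readQCTable <- function(path) {
  con <- .openConn(path)
  on.exit(close(con))
  df <- utils::read.delim(con, stringsAsFactors = FALSE)
  need <- c("sample_id", "total_dna_gbp", "map_rate_pct", "effective_coverage")
  if (!all(need %in% names(df)))
    stop("QC table: missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  bad <- df$map_rate_pct < 0 | df$map_rate_pct > 100 |
    df$total_dna_gbp < 0 | df$effective_coverage < 0
  if (any(bad, na.rm = TRUE))
    stop("QC table: metric out of range for sample ",
         df$sample_id[which(bad)[1]])
  df
}
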