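## Chromosome naming and ordering helpers shared across modules.

#' Normalize chromosome names
#'
#' Strips a leading \code{"chr"} prefix and upper-cases the sex chromosomes so
#' that call sets, panels and cytoband tables from different sources agree on
#' naming.
#'
#' @param x character vector of chromosome names.
#' @return character vector of normalized names ("1".."22", "X", "Y", "M").
#' @examples
#' normChrom(c("chr1", "12", "chrX"))
#' @export
normChrom <- function(x) {
  x <- sub("^chr", "", as.character(x))
  up <- toupper(x)
  ifelse(up %in% c("X", "Y", "M", "MT"), up, x)
}

## karyotypic order 1..22, X, Y, M; anything else sorts after, alphabetically
.karyotypeLevels <- c(as.character(1:22), "X", "Y", "M", "MT")

#' Karyotypic rank of chromosome names
#'
#' @param x character vector of (normalized) chromosome names.
#' @return integer rank; 1..22 then X, Y, M; unknown names rank last.
#' @export
chromRank <- function(x) {
  x <- normChrom(x)
  r <- match(x, .karyotypeLevels)
  extra <- is.na(r)
  if (any(extra)) {
    r[extra] <- length(.karyotypeLevels) + match(x[extra], sort(unique(x[extra])))
  }
  r
}

#' Sort chromosome names karyotypically
#' @param x character vector of chromosome names.
#' @return \code{x} sorted as 1..22, X, Y.
#' @export
sortChrom <- function(x) x[order(chromRank(x))]

.isKnownChrom <- function(x) normChrom(x) %in% .karyotypeLevels

## TRUE when (chromA,posA) <= (chromB,posB) in karyotypic order
.breakendLE <- function(chromA, posA, chromB, posB) {
  ra <- chromRank(chromA); rb <- chromRank(chromB)
  ra < rb | (ra == rb & posA <= posB)
}

.openConn <- function(path) {
  ## read.* on a file() connection transparently handles gzip
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}
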