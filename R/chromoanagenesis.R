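## Chromoplexy chain and chromothripsis region detection.
##
## Chromoplexy: chained rearrangements across >= 3 chromosomes. Breakends of
## different junctions on the same chromosome are "adjacent" when they are
## less than a configurable gap apart (default: five labels' worth of
## sequence, ~33 kb at 15 labels per 100 kbp), or when a deletion spans the
## interval between them (a deletion bridge, any size). Chains are the
## connected clusters of the breakend graph whose junctions span at least
## three chromosomes.
##
## Chromothripsis: a region where copy-number variation coexists with more
## than seven rearrangements in a 50 Mb window, with breakpoints interspersed
## and near-uniform over the affected span.

## default gap: five labels at the CTTAAG-motif density of ~15 per 100 kbp
#' Default chromoplexy adjacency gap in base pairs
#'
#' Five labels at the canonical label density of 15 per 100 kbp, i.e.
#' \code{5 * 100000 / 15} (about 33 kb). When an actual label map is
#' available, use \code{\link{labelGap}} to convert a label count into base
#' pairs locally.
#' @param nLabels gap expressed in labels (default 5).
#' @param labelsPer100kbp assumed label density (default 15).
#' @return gap in base pairs.
#' @export
defaultMaxGap <- function(nLabels = 5, labelsPer100kbp = 15) {
  nLabels * 1e5 / labelsPer100kbp
}

#' Convert a label-count gap to base pairs at a genomic position
#'
#' With a label map, the distance "n labels apart" at a position is the
#' base-pair span of the n-th label away from that position.
#'
#' @param chrom chromosome name.
#' @param pos base-pair position.
#' @param labels named list of sorted label positions per chromosome.
#' @param nLabels label count (default 5).
#' @return gap in base pairs at that position.
#' @export
labelGap <- function(chrom, pos, labels, nLabels = 5) {
  chrom <- normChrom(chrom)
  lp <- labels[[chrom]]
  if (is.null(lp) || length(lp) < nLabels + 1) return(defaultMaxGap(nLabels))
  i <- findInterval(pos, lp)
  hi <- min(length(lp), i + nLabels)
  abs(lp[hi] - pos)
}

## breakend table: one row per breakend, junction id and side
.breakendTable <- function(sdf) {
  if (nrow(sdf) == 0)
    return(data.frame(svId = character(), side = integer(), chrom = character(),
                      pos = numeric(), stringsAsFactors = FALSE))
  data.frame(svId = rep(sdf$id, 2),
             side = rep(1:2, each = nrow(sdf)),
             chrom = c(sdf$chromA, sdf$chromB),
             pos = c(sdf$posA, sdf$posB),
             stringsAsFactors = FALSE)
}

#' Build the breakend adjacency graph
#'
#' Nodes are breakends; each junction contributes an edge between its two
#' breakends, and adjacency edges link breakends of different junctions on
#' the same chromosome when they are less than \code{maxGap} bp apart or when
#' a deletion spans the interval between them (deletion bridge, any gap
#' size). Deletions are taken from deletion-type SVs in \code{svs} and from
#' loss segments in \code{deletions}.
#'
#' @param svs an \linkS4class{SVCallSet} (already prioritized).
#' @param maxGap adjacency gap in bp (default \code{defaultMaxGap()}).
#' @param deletions optional \linkS4class{CNVSegmentSet} whose loss segments
#'   may act as deletion bridges.
#' @return an \pkg{igraph} graph with vertex attributes \code{svId, chrom,
#'   pos} and edge attributes \code{type} ("junction"/"adjacency"),
#'   \code{gap}, \code{bridge}.
#' @export
breakendAdjacencyGraph <- function(svs, maxGap = defaultMaxGap(),
                                   deletions = NULL) {
  sdf <- svCalls(svs)
  if (nrow(sdf) == 0) return(igraph::make_empty_graph(directed = FALSE))
  be <- .breakendTable(sdf)
  be$name <- paste0(be$svId, ":", be$side)

  delIv <- .deletionIntervals(sdf, deletions)

  edges <- data.frame(from = paste0(sdf$id, ":1"), to = paste0(sdf$id, ":2"),
                      type = "junction", gap = NA_real_, bridge = FALSE,
                      stringsAsFactors = FALSE)
  if (nrow(be) > 1) {
    for (ch in unique(be$chrom)) {
      sub <- be[be$chrom == ch, , drop = FALSE]
      if (nrow(sub) < 2) next
      cmb <- utils::combn(nrow(sub), 2)
      for (k in seq_len(ncol(cmb))) {
        i <- cmb[1, k]; j <- cmb[2, k]
        if (sub$svId[i] == sub$svId[j]) next
        gap <- abs(sub$pos[i] - sub$pos[j])
        bridged <- gap >= maxGap &&
          .spannedByDeletion(ch, min(sub$pos[i], sub$pos[j]),
                             max(sub$pos[i], sub$pos[j]), delIv)
        if (gap < maxGap || bridged) {
          edges <- rbind(edges, data.frame(
            from = sub$name[i], to = sub$name[j], type = "adjacency",
            gap = gap, bridge = bridged, stringsAsFactors = FALSE))
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(
                                       name = be$name, svId = be$svId,
                                       chrom = be$chrom, pos = be$pos,
                                       stringsAsFactors = FALSE))
  g
}

.deletionIntervals <- function(sdf, deletions) {
  iv <- data.frame(chrom = character(), start = numeric(), end = numeric())
  svDel <- sdf[sdf$svType == "deletion", , drop = FALSE]
  if (nrow(svDel))
    iv <- rbind(iv, data.frame(chrom = svDel$chromA, start = svDel$posA,
                               end = svDel$posB))
  if (!is.null(deletions)) {
    cdf <- cnvSegments(deletions)
    cdf <- cdf[cdf$kind == "loss", , drop = FALSE]
    if (nrow(cdf))
      iv <- rbind(iv, data.frame(chrom = cdf$chrom, start = cdf$start,
                                 end = cdf$end))
  }
  iv
}

.spannedByDeletion <- function(chrom, lo, hi, delIv) {
  if (nrow(delIv) == 0) return(FALSE)
  any(delIv$chrom == chrom & delIv$start <= lo & delIv$end >= hi)
}

#' Detect chromoplexy chains
#'
#' Connected clusters of the breakend adjacency graph whose junctions span at
#' least three distinct chromosomes. Chains are breakend-disjoint by
#' construction and returned sorted by decreasing size, then by first
#' breakend coordinate.
#'
#' @param svs an \linkS4class{SVCallSet}, or a graph from
#'   \code{\link{breakendAdjacencyGraph}}.
#' @param maxGap,deletions passed to \code{\link{breakendAdjacencyGraph}} when
#'   \code{svs} is a call set.
#' @param minChromosomes minimum distinct chromosomes per chain (default 3).
#' @return list of chains; each chain is a list with \code{svIds},
#'   \code{chromosomes}, \code{gaps} (adjacency distances in bp),
#'   \code{deletionBridges} (count of bridged adjacencies), \code{closed}
#'   (TRUE when the chain is a cycle).
#' @export
detectChromoplexy <- function(svs, maxGap = defaultMaxGap(), deletions = NULL,
                              minChromosomes = 3L) {
  g <- if (inherits(svs, "igraph")) svs
       else breakendAdjacencyGraph(svs, maxGap = maxGap, deletions = deletions)
  if (igraph::vcount(g) == 0) return(list())
  comp <- igraph::components(g)
  chains <- list()
  for (ci in seq_len(comp$no)) {
    v <- which(comp$membership == ci)
    svIds <- unique(igraph::vertex_attr(g, "svId", v))
    chroms <- unique(igraph::vertex_attr(g, "chrom", v))
    if (length(svIds) < 2 || length(chroms) < minChromosomes) next
    sub <- igraph::induced_subgraph(g, v)
    adjE <- which(igraph::edge_attr(sub, "type") == "adjacency")
    gaps <- igraph::edge_attr(sub, "gap", adjE)
    bridges <- sum(igraph::edge_attr(sub, "bridge", adjE))
    ## a closed chain (cycle) has as many adjacency edges as junctions and
    ## every breakend participates in one adjacency
    closed <- length(adjE) == length(svIds) &&
      all(igraph::degree(sub) == 2)
    chains[[length(chains) + 1]] <- list(
      svIds = sort(svIds), chromosomes = sortChrom(chroms),
      gaps = sort(gaps[!igraph::edge_attr(sub, "bridge", adjE)]),
      deletionBridges = bridges, closed = closed,
      firstPos = min(igraph::vertex_attr(sub, "pos")))
  }
  if (!length(chains)) return(list())
  ord <- order(-vapply(chains, function(ch) length(ch$svIds), 0L),
               vapply(chains, function(ch) ch$firstPos, 0))
  chains <- chains[ord]
  lapply(chains, function(ch) ch[setdiff(names(ch), "firstPos")])
}

#' Detect chromothripsis regions
#'
#' Slides a window (default 50 Mb, stride 1 Mb) along each chromosome and
#' flags windows where, over the affected span — the extent of copy-number
#' segmentation intersecting the window, since chromothripsis requires CNVs
#' coexisting with the rearrangements — (a) more than \code{minRearr - 1}
#' junctions have at least one breakend inside (each junction counted once;
#' in-span ends of inter-chromosomal junctions count), (b) the CNV segments
#' carry at least \code{minCNStates} distinct copy-number states,
#' (c) breakpoints are interspersed — neither half of the affected span holds
#' more than \code{interspersionMax} of them — and (d) breakpoint positions
#' are compatible with a uniform distribution over the affected span
#' (one-sample Kolmogorov-Smirnov test at \code{uniformityAlpha}).
#' Overlapping flagged windows are merged into maximal regions and region
#' statistics recomputed over the merged affected span.
#'
#' @param svs an \linkS4class{SVCallSet} (prioritized).
#' @param cnvs a \linkS4class{CNVSegmentSet}.
#' @param windowMb window size in Mb (default 50).
#' @param minRearr minimum junction count per window; the default 8 encodes
#'   the strict "more than seven" rule.
#' @param minCNStates minimum distinct CN states (default 2).
#' @param interspersionMax maximal breakpoint share of either half-span
#'   (default 0.8).
#' @param uniformityAlpha KS significance floor; the window fails uniformity
#'   when the KS p-value drops below it (default 0.01).
#' @param strideMb window stride in Mb (default 1).
#' @param chromSizes optional named chromosome lengths; inferred from the
#'   data when absent.
#' @return list of regions; each region is a list with \code{chrom, start,
#'   end, nRearrangements, cnStates, uniformityStat, interspersionPass}.
#' @export
detectChromothripsis <- function(svs, cnvs, windowMb = 50, minRearr = 8L,
                                 minCNStates = 2L, interspersionMax = 0.8,
                                 uniformityAlpha = 0.01, strideMb = 1,
                                 chromSizes = NULL) {
  sdf <- svCalls(svs)
  cdf <- cnvSegments(cnvs)
  if (nrow(sdf) == 0) return(list())
  be <- .breakendTable(sdf)
  W <- windowMb * 1e6
  stride <- strideMb * 1e6
  regions <- list()
  for (ch in sortChrom(unique(be$chrom))) {
    bp <- be[be$chrom == ch, , drop = FALSE]
    L <- if (!is.null(chromSizes) && ch %in% normChrom(names(chromSizes)))
      chromSizes[[which(normChrom(names(chromSizes)) == ch)[1]]]
    else max(bp$pos, cdf$end[cdf$chrom == ch], 0)
    starts <- unique(c(seq(0, max(0, L - W), by = stride), max(0, L - W)))
    flagged <- logical(length(starts))
    for (k in seq_along(starts)) {
      s <- starts[k]; e <- s + W
      flagged[k] <- .windowIsChromothriptic(bp, cdf, ch, s, e, minRearr,
                                            minCNStates, interspersionMax,
                                            uniformityAlpha)
    }
    if (!any(flagged)) next
    ## merge overlapping flagged windows into maximal runs and recompute
    ## region statistics over each merged affected span
    runs <- .mergeWindows(starts[flagged], W)
    for (r in seq_len(nrow(runs))) {
      span <- .affectedSpan(cdf, ch, runs$start[r], runs$end[r])
      inSpan <- bp$pos >= span$lo & bp$pos <= span$hi
      pos <- bp$pos[inSpan]
      ks <- .uniformityKS(pos, span$lo, span$hi)
      regions[[length(regions) + 1]] <- list(
        chrom = ch, start = span$lo, end = span$hi,
        nRearrangements = length(unique(bp$svId[inSpan])),
        cnStates = sort(unique(span$segs$cn)),
        uniformityStat = ks$statistic,
        interspersionPass = .interspersed(pos, c(span$lo, span$hi),
                                          interspersionMax))
    }
  }
  regions
}

## the affected region inside a window: the span over which the caller
## emitted copy-number segmentation (clipped to the window). Chromothripsis
## is defined by CNVs *coexisting* with the rearrangements, so breakpoint
## interspersion and uniformity are judged over the copy-number-affected
## span; sporadic breakpoints elsewhere in the window are unrelated activity
.affectedSpan <- function(cdf, ch, s, e) {
  segs <- cdf[cdf$chrom == ch & cdf$start < e & cdf$end > s, , drop = FALSE]
  if (nrow(segs) == 0) return(NULL)
  list(lo = max(min(segs$start), s), hi = min(max(segs$end), e), segs = segs)
}

.windowIsChromothriptic <- function(bp, cdf, ch, s, e, minRearr, minCNStates,
                                    interspersionMax, uniformityAlpha) {
  span <- .affectedSpan(cdf, ch, s, e)
  if (is.null(span)) return(FALSE)
  if (length(unique(span$segs$cn)) < minCNStates) return(FALSE)
  inSpan <- bp$pos >= span$lo & bp$pos <= span$hi
  if (length(unique(bp$svId[inSpan])) < minRearr) return(FALSE)
  pos <- bp$pos[inSpan]
  if (!.interspersed(pos, c(span$lo, span$hi), interspersionMax)) return(FALSE)
  ks <- .uniformityKS(pos, span$lo, span$hi)
  ks$p.value >= uniformityAlpha
}

.interspersed <- function(pos, span, interspersionMax) {
  if (diff(span) <= 0) return(FALSE)
  mid <- mean(span)
  fracLeft <- mean(pos <= mid)
  max(fracLeft, 1 - fracLeft) <= interspersionMax
}

.uniformityKS <- function(pos, lo, hi) {
  if (hi <= lo || length(pos) < 2)
    return(list(statistic = 1, p.value = 0))
  ## jitter-free KS on the open span; ties from duplicated breakpoints only
  ## affect the conservative warning, not the decision
  res <- suppressWarnings(stats::ks.test(pos, "punif", min = lo, max = hi))
  list(statistic = unname(res$statistic), p.value = res$p.value)
}

.mergeWindows <- function(starts, W) {
  starts <- sort(starts)
  ends <- starts + W
  out <- data.frame(start = starts[1], end = ends[1])
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      if (starts[i] <= out$end[nrow(out)]) {
        out$end[nrow(out)] <- max(out$end[nrow(out)], ends[i])
      } else {
        out <- rbind(out, data.frame(start = starts[i], end = ends[i]))
      }
    }
  }
  out
}

#' Classify a case's chromoanagenesis status
#'
#' @param chains list from \code{\link{detectChromoplexy}}.
#' @param regions list from \code{\link{detectChromothripsis}}.
#' @return one of \code{"NONE"}, \code{"CHROMOPLEXY"}, \code{"CHROMOTHRIPSIS"},
#'   \code{"BOTH"}.
#' @export
classifyChromoanagenesis <- function(chains, regions) {
  hasChain <- length(chains) > 0
  hasRegion <- length(regions) > 0
  if (hasChain && hasRegion) "BOTH"
  else if (hasChain) "CHROMOPLEXY"
  else if (hasRegion) "CHROMOTHRIPSIS"
  else "NONE"
}
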