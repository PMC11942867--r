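# Independent oracles used to cross-check the package's detectors.
# They share no code with the implementation: the fusion oracle walks an
# explicitly constructed derivative chromosome block by block; the chain
# oracle computes pairwise linkage and a transitive closure by fixpoint
# iteration (no graph library).

# ---------------------------------------------------------------------------
# Fusion oracle: brute-force derivative-chromosome reading on a mini genome.
# Genes are data.frame rows (symbol, chrom, start, end, strand); chromLens a
# named vector. The derivative is built from the two retained pieces implied
# by the BEDPE orientations and discretized into blocks; a fusion (F, T)
# exists when some reading direction of the derivative runs from F's
# promoter block through the junction into T and reaches T's 3' terminus.
# ---------------------------------------------------------------------------

derivativeBlocks <- function(chromA, posA, strandA, chromB, posB, strandB,
                             chromLens, block = 100) {
  centers <- function(lo, hi) if (hi - lo < block) numeric() else
    seq(lo + block / 2, hi - block / 2, by = block)
  p1 <- if (strandA == "+") {
    data.frame(chrom = chromA, center = centers(0, posA), dir = 1)
  } else {
    cc <- centers(posA, chromLens[[chromA]])
    data.frame(chrom = chromA, center = rev(cc), dir = -1)
  }
  p2 <- if (strandB == "+") {
    cc <- centers(0, posB)
    data.frame(chrom = chromB, center = rev(cc), dir = -1)
  } else {
    data.frame(chrom = chromB, center = centers(posB, chromLens[[chromB]]), dir = 1)
  }
  p1$piece <- 1L
  p2$piece <- 2L
  rbind(p1, p2)
}

# walk the block sequence looking for promoter(F) -> junction -> 3'(T)
.readsAsFusion <- function(blocks, F, T) {
  inGene <- function(b, g) b$chrom == g$chrom & b$center >= g$start & b$center < g$end
  fDir <- if (F$strand == "+") 1 else -1
  tDir <- if (T$strand == "+") 1 else -1
  fBlocks <- which(inGene(blocks, F) & blocks$dir == fDir)
  if (!length(fBlocks)) return(FALSE)
  # candidate promoter blocks: F blocks at the transcription start
  promPos <- if (F$strand == "+") F$start else F$end
  starts <- fBlocks[abs(blocks$center[fBlocks] - promPos) <= 100]
  termPos <- if (T$strand == "+") T$end else T$start
  for (start in starts) {
    i <- start
    while (i < nrow(blocks) && (i + 1) %in% fBlocks &&
           blocks$piece[i + 1] == blocks$piece[i]) i <- i + 1
    # must leave F by crossing the junction, not by running out of gene body
    if (i == nrow(blocks) || blocks$piece[i + 1] == blocks$piece[i]) next
    j <- i + 1
    if (!(inGene(blocks[j, ], T) && blocks$dir[j] == tDir)) next
    while (j < nrow(blocks) && inGene(blocks[j + 1, ], T) &&
           blocks$dir[j + 1] == tDir && blocks$piece[j + 1] == blocks$piece[j]) j <- j + 1
    if (abs(blocks$center[j] - termPos) <= 100) return(TRUE)
  }
  FALSE
}

# set of compatible ordered fusion pairs by exhaustive derivative reading
oracleFusionPairs <- function(sv, genes, chromLens, block = 100) {
  fwd <- derivativeBlocks(sv$chromA, sv$posA, sv$strandA,
                          sv$chromB, sv$posB, sv$strandB, chromLens, block)
  rev_ <- fwd[rev(seq_len(nrow(fwd))), ]
  rev_$dir <- -rev_$dir
  out <- character()
  for (f in seq_len(nrow(genes))) for (t in seq_len(nrow(genes))) {
    if (f == t) next
    hit <- .readsAsFusion(fwd, genes[f, ], genes[t, ]) ||
      .readsAsFusion(rev_, genes[f, ], genes[t, ])
    if (hit) out <- c(out, paste(genes$symbol[f], genes$symbol[t], sep = ">"))
  }
  sort(out)
}

# ---------------------------------------------------------------------------
# Chromoplexy oracle: pairwise linkage + fixpoint transitive closure.
# svdf is the normalized call frame from svCalls(); delIv a data.frame of
# deletion intervals (chrom, start, end) or NULL.
# ---------------------------------------------------------------------------

oracleChains <- function(svdf, maxGap, delIv = NULL) {
  n <- nrow(svdf)
  if (n < 2) return(list())
  ends <- function(i) list(
    list(chrom = svdf$chromA[i], pos = svdf$posA[i]),
    list(chrom = svdf$chromB[i], pos = svdf$posB[i]))
  spanned <- function(chrom, lo, hi) {
    if (is.null(delIv) || nrow(delIv) == 0) return(FALSE)
    any(delIv$chrom == chrom & delIv$start <= lo & delIv$end >= hi)
  }
  linked <- diag(TRUE, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    for (ei in ends(i)) for (ej in ends(j)) {
      if (ei$chrom != ej$chrom) next
      d <- abs(ei$pos - ej$pos)
      if (d < maxGap || spanned(ei$chrom, min(ei$pos, ej$pos),
                                max(ei$pos, ej$pos)))
        linked[i, j] <- linked[j, i] <- TRUE
    }
  }
  repeat {
    nxt <- (linked %*% linked) > 0
    if (identical(nxt, linked)) break
    linked <- nxt
  }
  comps <- unique(apply(linked, 1, function(r) paste(which(r), collapse = ",")))
  out <- list()
  for (cp in comps) {
    idx <- as.integer(strsplit(cp, ",")[[1]])
    chroms <- unique(c(svdf$chromA[idx], svdf$chromB[idx]))
    if (length(idx) >= 2 && length(chroms) >= 3)
      out[[length(out) + 1]] <- sort(svdf$id[idx])
  }
  out[order(vapply(out, paste, "", collapse = "|"))]
}

# random small SV instance on a 5-chromosome mini genome, built to produce a
# mix of linked and unlinked junctions
randomSVInstance <- function(seed, maxGap = 33000) {
  set.seed(seed)
  chroms <- as.character(1:5)
  sizes <- stats::setNames(rep(10e6, 5), chroms)
  n <- sample(3:10, 1)
  nAnchor <- sample(3:6, 1)
  anchors <- data.frame(chrom = sample(chroms, nAnchor, replace = TRUE),
                        pos = runif(nAnchor, 1e6, 9e6))
  rndEnd <- function() {
    if (runif(1) < 0.7) {
      a <- anchors[sample(nAnchor, 1), ]
      list(chrom = a$chrom, pos = max(0, a$pos + runif(1, -1.5, 1.5) * maxGap))
    } else {
      list(chrom = sample(chroms, 1), pos = runif(1, 0, 10e6))
    }
  }
  rows <- lapply(seq_len(n), function(i) {
    e1 <- rndEnd(); e2 <- rndEnd()
    data.frame(id = sprintf("sv%02d", i),
               chromA = e1$chrom, posA = round(e1$pos),
               strandA = sample(c("+", "-"), 1),
               chromB = e2$chrom, posB = round(e2$pos),
               strandB = sample(c("+", "-"), 1),
               svType = if (e1$chrom == e2$chrom) "inversion"
                        else "inter_translocation",
               stringsAsFactors = FALSE)
  })
  SVCallSet(do.call(rbind, rows))
}

# expand group count pairs into per-case flags
expandGroupFlags <- function(fx) {
  list(group = rep(fx$group, fx$n_total),
       evaluable = unlist(mapply(function(e, t) c(rep(TRUE, e), rep(FALSE, t - e)),
                                 fx$n_evaluable, fx$n_total, SIMPLIFY = FALSE)))
}

# mini two-gene configuration used by the fusion enumeration tests
miniFusionGenes <- function(strandA = "+", strandB = "-") {
  data.frame(symbol = c("GA", "GB"), chrom = c("1", "2"),
             start = c(3000, 4000), end = c(6000, 7000),
             strand = c(strandA, strandB), stringsAsFactors = FALSE)
}
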