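# Shared fixtures and independent brute-force oracles.
#
# The oracles deliberately materialize the explicit genome-length occupancy
# vector and compute on it directly — the thing the package avoids doing —
# so they share no code path with the implementation under test.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(GenomeInfoDb)
})

toyGenome <- function(lens = c(chr1 = 100L, chr2 = 80L)) {
  Seqinfo(seqnames = names(lens), seqlengths = unname(lens))
}

# build a track from 0-based half-open records without going through a file
makeTrack <- function(name, genome, chrom, start0, end0) {
  GenomeTrack(name, GRanges(chrom, IRanges(start0 + 1L, end0),
                            seqinfo = genome))
}

writeBedFile <- function(path, chrom, start0, end0) {
  writeLines(paste(chrom, start0, end0, sep = "\t"), path)
  path
}

writeChromSizes <- function(path, genome) {
  writeLines(paste(seqnames(genome), seqlengths(genome), sep = "\t"), path)
  path
}

# random merged track on a toy genome; nRecords pre-merge records
randomTrack <- function(genome, nRecords = 8L, maxLen = 15L,
                        name = "random") {
  sl <- seqlengths(genome)
  chrom <- sample(names(sl), nRecords, replace = TRUE)
  len <- sample.int(maxLen, nRecords, replace = TRUE)
  start0 <- vapply(seq_len(nRecords), function(i)
    sample.int(sl[[chrom[i]]] - len[i] + 1L, 1L) - 1L, 0L)
  makeTrack(name, genome, chrom, start0, start0 + len)
}

# ---- per-bp oracle ---------------------------------------------------------

.chromOffsets <- function(genome) {
  sl <- seqlengths(genome)
  stats::setNames(c(0L, cumsum(as.numeric(sl)))[seq_along(sl)], names(sl))
}

# explicit 0/1 occupancy vector of length N for a GRanges
bpVector <- function(gr, genome) {
  off <- .chromOffsets(genome)
  v <- logical(sum(as.numeric(seqlengths(genome))))
  for (i in seq_along(gr)) {
    pos <- off[[as.character(seqnames(gr)[i])]] + (start(gr)[i]:end(gr)[i])
    v[pos] <- TRUE
  }
  v
}

# explicit per-bp value vector of a ValuedTrack (0 where uncovered)
bpValues <- function(track, genome) {
  off <- .chromOffsets(genome)
  v <- numeric(sum(as.numeric(seqlengths(genome))))
  steps <- trackSteps(track)
  for (i in seq_along(steps)) {
    pos <- off[[as.character(seqnames(steps)[i])]] +
      (start(steps)[i]:end(steps)[i])
    v[pos] <- mcols(steps)$value[i]
  }
  v
}

oracleJaccard <- function(a, b, genome) {
  va <- bpVector(trackRanges(a), genome)
  vb <- bpVector(trackRanges(b), genome)
  sum(va & vb) / sum(va | vb)
}

# ---- naive UPGMA-family agglomerator ---------------------------------------
# Recomputes the linkage distance between clusters from the original matrix
# at every step (no Lance-Williams update); same tie-break contract as the
# implementation: minimal distance, then lexicographically smallest
# (smaller id, larger id); children ordered by smallest leaf index.
naiveAgglomerate <- function(d, linkage = "average") {
  n <- nrow(d)
  clusters <- as.list(seq_len(n) - 1L)   # leaf sets, keyed by cluster id
  ids <- 0:(n - 1L)
  merges <- data.frame(left = integer(0), right = integer(0),
                       height = numeric(0), size = integer(0))
  linkDist <- function(A, B) {
    vals <- d[A + 1L, B + 1L, drop = FALSE]
    switch(linkage, average = mean(vals), single = min(vals),
           complete = max(vals))
  }
  for (step in seq_len(n - 1L)) {
    best <- NULL; bestD <- Inf
    for (ii in seq_along(ids)[-length(ids)]) {
      for (jj in (ii + 1L):length(ids)) {
        dd <- linkDist(clusters[[ii]], clusters[[jj]])
        pair <- sort(c(ids[ii], ids[jj]))
        if (dd < bestD || (dd == bestD &&
            (pair[1L] < best[1L] ||
             (pair[1L] == best[1L] && pair[2L] < best[2L])))) {
          bestD <- dd; best <- pair
        }
      }
    }
    ii <- which(ids == best[1L]); jj <- which(ids == best[2L])
    newId <- n + step - 1L
    ordered <- if (min(clusters[[ii]]) <= min(clusters[[jj]]))
      c(best[1L], best[2L]) else c(best[2L], best[1L])
    merged <- c(clusters[[ii]], clusters[[jj]])
    merges[step, ] <- list(ordered[1L], ordered[2L], bestD, length(merged))
    clusters <- c(clusters[-c(ii, jj)], list(merged))
    ids <- c(ids[-c(ii, jj)], newId)
  }
  merges
}

randomDistanceMatrix <- function(n, names = paste0("t", seq_len(n))) {
  d <- matrix(0, n, n, dimnames = list(names, names))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- runif(1L, 0.05, 1)
  d
}

asDistanceMatrix <- function(d, method = "test") {
  new("TrackDistanceMatrix", values = d, method = method)
}

# canonical topology signature: sorted list of sorted leaf-name sets, one
# per internal node
mergeLeafSets <- function(dg) {
  n <- length(dg@leaves)
  sets <- lapply(seq_len(n - 1L), function(i) {
    ids <- trackdist:::.leavesUnder(dg, n + i - 1L)
    sort(dg@leaves[ids + 1L])
  })
  sets[order(vapply(sets, paste, "", collapse = "|"))]
}

# standard 12-track benchmark: 3 groups x 4 tracks on a 2 Mb toy genome
benchmarkGenome <- function() toyGenome(c(chr1 = 1000000L, chr2 = 1000000L))

benchmarkData <- function(seed = 42L) {
  generateGroupTracks(benchmarkGenome(), GroupSpec(seed = seed))
}
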