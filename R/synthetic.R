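# Synthetic group-structured tracks. Each group has an archetype segment set
# drawn uniformly over the genome without overlap (across all groups);
# member tracks keep each archetype segment with probability keepProb,
# displace its start by a rounded Normal(0, jitterSd) offset (clipped to the
# chromosome), and add uniformly placed noise segments. This emulates the
# situation the clustering method targets — replicate occupancy tracks from
# the same tissue sharing most peaks up to small positional shifts — with a
# known ground-truth partition for recovery benchmarks.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# draw one segment start uniformly over the genome (chromosome weighted by
# placeable length), avoiding overlap with `occupied`; bounded retries
.placeSegment <- function(genome, segLen, occupied, retries = 1000L) {
  sl <- seqlengths(genome)
  ok <- sl >= segLen
  if (!any(ok))
    .tdStop("trackdist_packing_failure",
            "no chromosome can hold a segment of this length")
  w <- ifelse(ok, sl - segLen + 1L, 0L)
  for (r in seq_len(retries)) {
    chrom <- sample(names(sl), 1L, prob = w)
    start <- sample.int(sl[[chrom]] - segLen + 1L, 1L)
    cand <- GRanges(chrom, IRanges(start, width = segLen), seqinfo = genome)
    if (is.null(occupied) || !any(overlapsAny(cand, occupied)))
      return(cand)
  }
  .tdStop("trackdist_packing_failure",
          "could not place a non-overlapping segment; genome too crowded")
}

#' Generate groups of tracks with planted cluster structure
#'
#' See [GroupSpec-class] for the generative model. Given the same genome and
#' spec (including its seed), output is fully deterministic: all random
#' draws consume one stream in a fixed order (archetypes by group, then per
#' track: keep decisions, jitters, noise placements).
#'
#' @param genome a [GenomeInfoDb::Seqinfo]. Total demanded archetype bp must
#'   be below half the genome so uniform non-overlapping placement succeeds.
#' @param spec a [GroupSpec-class].
#' @return A list with `tracks` (list of [GenomeTrack-class], named
#'   "g<group>_t<member>"), `labels` (integer group of each track),
#'   `archetypes` (list of per-group GRanges).
#' @export
generateGroupTracks <- function(genome, spec) {
  validObject(spec)
  segLen <- spec@segmentLength
  demanded <- as.numeric(spec@nGroups) * spec@segmentsPerArchetype * segLen
  if (demanded >= 0.5 * genomeLength(genome))
    .tdStop("trackdist_packing_failure",
            "archetypes would demand >= 50% of the genome; enlarge the genome")
  .withSeed(spec@seed, {
    occupied <- NULL
    archetypes <- vector("list", spec@nGroups)
    for (g in seq_len(spec@nGroups)) {
      segs <- .emptyGRanges(genome)
      for (s in seq_len(spec@segmentsPerArchetype)) {
        seg <- .placeSegment(genome, segLen, occupied)
        occupied <- if (is.null(occupied)) seg else c(occupied, seg)
        segs <- c(segs, seg)
      }
      archetypes[[g]] <- sort(segs)
    }
    tracks <- list()
    labels <- integer(0)
    sl <- seqlengths(genome)
    for (g in seq_len(spec@nGroups)) {
      arch <- archetypes[[g]]
      for (t in seq_len(spec@tracksPerGroup)) {
        keep <- stats::runif(length(arch)) <= spec@keepProb
        kept <- arch[keep]
        if (length(kept)) {
          shift <- round(stats::rnorm(length(kept), 0, spec@jitterSd))
          newStart <- pmin(pmax(GenomicRanges::start(kept) + shift, 1L),
                           sl[as.character(seqnames(kept))] - segLen + 1L)
          kept <- GRanges(seqnames(kept), IRanges(newStart, width = segLen),
                          seqinfo = genome)
        }
        noise <- .emptyGRanges(genome)
        for (s in seq_len(spec@noiseSegments)) {
          chrom <- sample(names(sl), 1L, prob = pmax(sl - segLen + 1L, 0L))
          start <- sample.int(sl[[chrom]] - segLen + 1L, 1L)
          noise <- c(noise, GRanges(chrom, IRanges(start, width = segLen),
                                    seqinfo = genome))
        }
        name <- sprintf("g%d_t%d", g, t)
        tracks[[name]] <- GenomeTrack(name, c(kept, noise))
        labels <- c(labels, g)
      }
    }
    names(labels) <- names(tracks)
    list(tracks = tracks, labels = labels, archetypes = archetypes)
  })
}

#' Write generated tracks and truth labels to a directory
#'
#' One BED file per track plus `truth_labels.tsv` (track, group); byte
#' deterministic for a fixed spec.
#'
#' @param generated result of [generateGroupTracks()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeGroupTracks <- function(generated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tr in generated$tracks)
    writeBed(tr, file.path(dir, paste0(trackName(tr), ".bed")))
  con <- file(file.path(dir, "truth_labels.tsv"), "w")
  on.exit(close(con))
  writeLines("track\tgroup", con)
  writeLines(paste(names(generated$labels), generated$labels, sep = "\t"),
             con)
  invisible(dir)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions (up
#' to relabelling), about 0 for independent ones; can be negative.
#'
#' @param labelsA,labelsB equal-length label vectors over the same elements.
#' @return The ARI (<= 1).
#' @export
adjustedRandIndex <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    .tdStop("trackdist_invalid_input", "partitions differ in size")
  tab <- table(labelsA, labelsB)
  choose2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(choose2(tab))
  sumI <- sum(choose2(rowSums(tab)))
  sumJ <- sum(choose2(colSums(tab)))
  nPairs <- choose2(length(labelsA))
  expected <- sumI * sumJ / nPairs
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)  # both partitions trivial
  (sumIJ - expected) / (maxIdx - expected)
}
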