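# Interval algebra on tracks. Every operation is defined in terms of the
# implicit genome-length occupancy vector V (V[i] = 1 iff position i is
# covered) but computed on sorted merged intervals via GenomicRanges, so the
# cost scales with the number of intervals, never with genome length.

.seqinfoOf <- function(x) if (is(x, "Seqinfo")) x else seqinfo(x)

.checkSameGenome <- function(a, b) {
  if (!identical(.seqinfoOf(a), .seqinfoOf(b)))
    .tdStop("trackdist_genome_mismatch",
            "operands are defined on different genomes")
  invisible(TRUE)
}

# overlap coverage between two merged GRanges via a single findOverlaps();
# far cheaper than materializing GenomicRanges::intersect()
.overlapBp <- function(a, b) {
  h <- findOverlaps(a, b)
  if (length(h) == 0L) return(0L)
  sum(pmin(GenomicRanges::end(a)[queryHits(h)],
           GenomicRanges::end(b)[subjectHits(h)]) -
      pmax(GenomicRanges::start(a)[queryHits(h)],
           GenomicRanges::start(b)[subjectHits(h)]) + 1L)
}

#' Total base-pair coverage of a track
#'
#' The number of genome positions covered, i.e. the number of ones in the
#' track's binary occupancy vector. This is also the denominator of relative
#' coverage normalization.
#'
#' @param track a [GenomeTrack-class].
#' @return Integer number of covered base pairs.
#' @export
totalCoverage <- function(track) {
  sum(GenomicRanges::width(trackRanges(track)))
}

#' Base pairs covered by both of two tracks
#'
#' @param a,b [GenomeTrack-class] objects on the same genome.
#' @return Integer count of positions covered by both tracks.
#' @export
intersectCoverage <- function(a, b) {
  .checkSameGenome(trackRanges(a), trackRanges(b))
  .overlapBp(trackRanges(a), trackRanges(b))
}

#' Base pairs covered by either of two tracks
#'
#' @inheritParams intersectCoverage
#' @return Integer count of positions covered by at least one track.
#' @export
unionCoverage <- function(a, b) {
  # inclusion-exclusion on merged tracks; avoids building the union set
  .checkSameGenome(trackRanges(a), trackRanges(b))
  totalCoverage(a) + totalCoverage(b) - intersectCoverage(a, b)
}

#' Covered base pairs of a track falling inside a region set
#'
#' The coverage aggregation g: the number of covered positions of the track
#' that lie in the region set (a bin or a reference track's positions).
#'
#' @param track a [GenomeTrack-class].
#' @param regions a [RegionSet-class] on the same genome.
#' @return Integer base-pair count.
#' @export
coverageInRegions <- function(track, regions) {
  .checkSameGenome(trackRanges(track), regionRanges(regions))
  .overlapBp(trackRanges(track), regionRanges(regions))
}

#' Elements of a track falling inside a region set
#'
#' The count aggregation g: the number of original (pre-merge) elements whose
#' start coordinate lies inside the region set. Assignment by start position
#' is unique even for elements spanning a region boundary, so counts over a
#' genome partition sum to the track's element count.
#'
#' @inheritParams coverageInRegions
#' @return Integer element count.
#' @export
countInRegions <- function(track, regions) {
  .checkSameGenome(trackRanges(track), regionRanges(regions))
  sum(overlapsAny(elementStarts(track), regionRanges(regions)))
}

# Pieces of a ValuedTrack's steps falling inside a region set, as a GRanges
# with the step value attached.
.valuedPieces <- function(track, regions) {
  steps <- trackSteps(track)
  hits <- findOverlaps(steps, regionRanges(regions))
  pieces <- pintersect(granges(steps)[queryHits(hits)],
                       regionRanges(regions)[subjectHits(hits)])
  mcols(pieces)$value <- mcols(steps)$value[queryHits(hits)]
  pieces
}

#' Mean per-base-pair value of a valued track over a region set
#'
#' The mean-value aggregation g for Function-type tracks: the average of the
#' per-position values over every position of the region set, with positions
#' not covered by any step contributing 0.
#'
#' @param track a [ValuedTrack-class].
#' @param regions a non-empty [RegionSet-class] on the same genome.
#' @return The mean value (double).
#' @export
meanValueInRegions <- function(track, regions) {
  .checkSameGenome(trackSteps(track), regionRanges(regions))
  n <- sum(as.numeric(GenomicRanges::width(regionRanges(regions))))
  if (n == 0)
    .tdStop("trackdist_empty_regions",
            "mean value over an empty region set is undefined")
  pieces <- .valuedPieces(track, regions)
  sum(mcols(pieces)$value * GenomicRanges::width(pieces)) / n
}

#' Per-base-pair Pearson correlation of two valued tracks over a region set
#'
#' Pearson correlation of the two per-position value vectors restricted to
#' the region set (uncovered positions valued 0), computed from sums over
#' step pieces in a single sweep — the position vectors are never
#' materialized.
#'
#' @param a,b [ValuedTrack-class] objects on the same genome.
#' @param regions a [RegionSet-class] covering at least 2 bp.
#' @return Correlation in \[-1, 1\].
#' @export
pearsonBp <- function(a, b, regions) {
  .checkSameGenome(trackSteps(a), trackSteps(b))
  .checkSameGenome(trackSteps(a), regionRanges(regions))
  n <- sum(as.numeric(GenomicRanges::width(regionRanges(regions))))
  if (n < 2)
    .tdStop("trackdist_empty_regions",
            "Pearson correlation needs a region set covering >= 2 bp")
  pa <- .valuedPieces(a, regions)
  pb <- .valuedPieces(b, regions)
  wa <- GenomicRanges::width(pa); va <- mcols(pa)$value
  wb <- GenomicRanges::width(pb); vb <- mcols(pb)$value
  sumA <- sum(va * wa); sumA2 <- sum(va^2 * wa)
  sumB <- sum(vb * wb); sumB2 <- sum(vb^2 * wb)
  # cross term: disjoin the union of piece boundaries; each fragment has one
  # a-value and one b-value (0 where absent)
  frags <- GenomicRanges::disjoin(c(granges(pa), granges(pb)))
  ha <- findOverlaps(frags, pa)
  hb <- findOverlaps(frags, pb)
  fa <- numeric(length(frags)); fa[queryHits(ha)] <- va[subjectHits(ha)]
  fb <- numeric(length(frags)); fb[queryHits(hb)] <- vb[subjectHits(hb)]
  sumAB <- sum(fa * fb * GenomicRanges::width(frags))
  covAB <- sumAB - sumA * sumB / n
  varA <- sumA2 - sumA^2 / n
  varB <- sumB2 - sumB^2 / n
  tol <- 1e-12 * max(1, sumA2, sumB2)
  if (varA <= tol || varB <= tol)
    .tdStop("trackdist_constant_track",
            "Pearson correlation undefined: a track is constant over the regions")
  covAB / sqrt(varA * varB)
}
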