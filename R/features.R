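# Feature extraction: turn each track into a feature vector F, either by
# tiling the genome into fixed-width bins (positional distribution) or by
# aggregating over the position sets of reference tracks (relations to other
# genomic features). F[j] = g(V restricted to the positions of feature j),
# with g = bp coverage, element count, or mean value; "relative"
# normalization divides each row by the track's genome-wide total so tracks
# of very different overall coverage become comparable.

.AGGREGATIONS <- c("coverage", "count", "mean_value")
.NORMALIZATIONS <- c("relative", "raw")

#' Tile a genomic extent into fixed-width bins
#'
#' Bins tile each region left to right; the last bin of a region is shorter
#' when the region length is not a multiple of `binSize`, and is kept (so
#' bins exactly cover the extent and coverage mass is conserved). Bins never
#' span chromosomes. Ordering is deterministic: genome chromosome order, then
#' coordinate.
#'
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param binSize bin width in bp (>= 1).
#' @param regions optional [RegionSet-class] extent to bin; default is the
#'   whole genome.
#' @return A [GenomicRanges::GRanges] of bins, named "chrom:start-end" in
#'   BED-style 0-based half-open coordinates.
#' @examples
#' g <- Seqinfo("chr1", 120)
#' names(makeBins(g, 50))  # "chr1:0-50" "chr1:50-100" "chr1:100-120"
#' @export
makeBins <- function(genome, binSize, regions = NULL) {
  binSize <- as.integer(binSize)
  if (is.na(binSize) || binSize < 1L)
    .tdStop("trackdist_invalid_binsize", "binSize must be a positive integer")
  extent <- if (is.null(regions)) {
    GRanges(seqnames(genome), IRanges(1L, seqlengths(genome)),
            seqinfo = genome)
  } else {
    .checkSameGenome(regionRanges(regions), genome)
    regionRanges(regions)
  }
  if (length(extent) == 0L)
    .tdStop("trackdist_empty_regions", "cannot bin an empty extent")
  bins <- sort(unlist(slidingWindows(extent, width = binSize, step = binSize)))
  names(bins) <- paste0(seqnames(bins), ":", GenomicRanges::start(bins) - 1L,
                        "-", GenomicRanges::end(bins))
  bins
}

# Per-bin aggregation against a non-overlapping bin GRanges, vectorized.
.binAggregate <- function(track, bins, aggregation) {
  agg <- numeric(length(bins))
  if (aggregation == "coverage") {
    hits <- findOverlaps(trackRanges(track), bins)
    if (length(hits)) {
      w <- GenomicRanges::width(pintersect(
        trackRanges(track)[queryHits(hits)], bins[subjectHits(hits)]))
      sums <- rowsum(as.numeric(w), subjectHits(hits))
      agg[as.integer(rownames(sums))] <- sums[, 1L]
    }
  } else {  # count: each width-1 start hits at most one bin
    cnt <- countOverlaps(bins, elementStarts(track))
    agg <- as.numeric(cnt)
  }
  agg
}

.relativeDenominator <- function(track, aggregation) {
  total <- if (aggregation == "coverage") totalCoverage(track)
           else elementCount(track)
  if (total == 0)
    .tdStop("trackdist_zero_total",
            sprintf("track '%s' has zero genome-wide total %s; its relative feature vector is undefined",
                    trackName(track), aggregation))
  total
}

.newFeatureMatrix <- function(values, trackNames, labels, aggregation,
                              normalization) {
  dimnames(values) <- list(trackNames, labels)
  new("FeatureMatrix", values = values, aggregation = aggregation,
      normalization = normalization)
}

#' Extract bin-based feature vectors (positional distribution)
#'
#' Each track becomes a vector of per-bin aggregates over a fixed-width
#' tiling of the genome (or of a restricted extent). With coverage
#' aggregation and relative normalization, entry (t, j) is the fraction of
#' track t's covered base pairs that fall in bin j — the track's smoothed
#' positional distribution — and rows over a genome-tiling bin set sum to 1.
#'
#' @param tracks list of [GenomeTrack-class] on a common genome.
#' @param genome the common [GenomeInfoDb::Seqinfo].
#' @param binSize bin width, bp.
#' @param regions optional [RegionSet-class] extent to bin.
#' @param aggregation "coverage" (bp) or "count" (elements, assigned by start
#'   position).
#' @param normalization "relative" (divide by the track's genome-wide total)
#'   or "raw".
#' @return A [FeatureMatrix-class].
#' @export
extractBinFeatures <- function(tracks, genome, binSize, regions = NULL,
                               aggregation = c("coverage", "count"),
                               normalization = c("relative", "raw")) {
  aggregation <- match.arg(aggregation)
  normalization <- match.arg(normalization)
  .checkTrackList(tracks, genome)
  bins <- makeBins(genome, binSize, regions)
  raw <- vapply(tracks, .binAggregate, numeric(length(bins)),
                bins = bins, aggregation = aggregation)
  values <- if (length(bins) == 1L) matrix(raw, ncol = 1L) else t(raw)
  if (normalization == "relative") {
    den <- vapply(tracks, .relativeDenominator, numeric(1L), aggregation)
    values <- values / den
  }
  .newFeatureMatrix(values, vapply(tracks, trackName, ""), names(bins),
                    aggregation, normalization)
}

.asRegionSet <- function(x) {
  if (is(x, "RegionSet")) return(x)
  if (is(x, "GenomeTrack")) return(RegionSet(trackRanges(x), trackName(x)))
  .tdStop("trackdist_invalid_reference",
          "references must be GenomeTrack or RegionSet objects")
}

#' Extract reference-track feature vectors (relations to other features)
#'
#' Generalizes binning to arbitrary position sets: feature j is the
#' aggregate of the track over the (possibly non-contiguous) positions
#' covered by reference track j, e.g. the gene regions of one functional
#' category. Reference tracks may overlap each other. Relative normalization
#' divides by the track's genome-wide total, exactly as in the bin case.
#'
#' @param tracks list of [GenomeTrack-class] (or [ValuedTrack-class] for
#'   mean-value aggregation) on a common genome.
#' @param references list of [GenomeTrack-class] or [RegionSet-class]; their
#'   labels become the feature labels. At least 2, all non-empty.
#' @param genome the common [GenomeInfoDb::Seqinfo].
#' @param aggregation "coverage", "count", or "mean_value" (valued tracks
#'   only).
#' @param normalization "relative" or "raw"; relative is defined only for
#'   coverage and count.
#' @return A [FeatureMatrix-class].
#' @export
extractReferenceFeatures <- function(tracks, references, genome,
                                     aggregation = c("coverage", "count",
                                                     "mean_value"),
                                     normalization = c("relative", "raw")) {
  aggregation <- match.arg(aggregation)
  normalization <- match.arg(normalization)
  if (length(references) < 2L)
    .tdStop("trackdist_invalid_reference", "need at least 2 reference tracks")
  refs <- lapply(references, .asRegionSet)
  empty <- vapply(refs, function(r) length(regionRanges(r)) == 0L, NA)
  if (any(empty))
    .tdStop("trackdist_invalid_reference",
            sprintf("reference '%s' covers no positions",
                    regionLabel(refs[[which(empty)[1L]]])))
  if (aggregation == "mean_value") {
    if (normalization == "relative")
      .tdStop("trackdist_invalid_normalization",
              "relative normalization is not defined for mean_value aggregation")
    if (!all(vapply(tracks, is, NA, "ValuedTrack")))
      .tdStop("trackdist_invalid_reference",
              "mean_value aggregation needs ValuedTrack inputs")
    values <- t(vapply(tracks, function(tr)
      vapply(refs, function(r) meanValueInRegions(tr, r), numeric(1L)),
      numeric(length(refs))))
  } else {
    .checkTrackList(tracks, genome)
    aggFun <- if (aggregation == "coverage") coverageInRegions else countInRegions
    values <- t(vapply(tracks, function(tr)
      vapply(refs, function(r) as.numeric(aggFun(tr, r)), numeric(1L)),
      numeric(length(refs))))
    if (normalization == "relative") {
      den <- vapply(tracks, .relativeDenominator, numeric(1L), aggregation)
      values <- values / den
    }
  }
  .newFeatureMatrix(values, vapply(tracks, trackName, ""),
                    vapply(refs, regionLabel, ""), aggregation, normalization)
}

.checkTrackList <- function(tracks, genome) {
  if (length(tracks) < 1L)
    .tdStop("trackdist_invalid_input", "need at least one track")
  nm <- vapply(tracks, trackName, "")
  if (anyDuplicated(nm))
    .tdStop("trackdist_invalid_input",
            sprintf("duplicate track name '%s'", nm[anyDuplicated(nm)]))
  ok <- vapply(tracks, function(t)
    identical(seqinfo(trackRanges(t)), genome), NA)
  if (!all(ok))
    .tdStop("trackdist_genome_mismatch",
            sprintf("track '%s' is not defined on the given genome", nm[which(!ok)[1L]]))
  invisible(TRUE)
}

.formatNum <- function(x) {
  # shortest representation that round-trips doubles
  vapply(x, function(v) {
    s <- format(v, digits = 15)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, "")
}

#' Write a FeatureMatrix as TSV
#'
#' One comment line records aggregation and normalization; then a header row
#' of feature labels (first field `track`) and one row per track, values at
#' full double precision so a read-back reproduces them exactly.
#'
#' @param fm a [FeatureMatrix-class].
#' @param path output file.
#' @export
writeFeatureMatrix <- function(fm, path) {
  v <- featureValues(fm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#aggregation=%s\tnormalization=%s",
                     fm@aggregation, fm@normalization), con)
  writeLines(paste(c("track", colnames(v)), collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], .formatNum(v[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' Read back a TSV written by [writeFeatureMatrix()]
#'
#' @param path the TSV file.
#' @return A [FeatureMatrix-class].
#' @export
readFeatureMatrix <- function(path) {
  lines <- readLines(path)
  meta <- c(aggregation = "coverage", normalization = "raw")
  if (length(lines) && startsWith(lines[1L], "#")) {
    kv <- strsplit(strsplit(sub("^#", "", lines[1L]), "\t")[[1L]], "=")
    for (p in kv) meta[p[1L]] <- p[2L]
    lines <- lines[-1L]
  }
  header <- strsplit(lines[1L], "\t")[[1L]]
  rows <- strsplit(lines[-1L], "\t")
  values <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                     numeric(length(header) - 1L)))
  if (length(header) == 2L) values <- matrix(values, ncol = 1L)
  .newFeatureMatrix(values, vapply(rows, `[`, "", 1L), header[-1L],
                    meta[["aggregation"]], meta[["normalization"]])
}
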