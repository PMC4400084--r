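# Pairwise track distances. Direct base-pair-level similarity is the Jaccard
# index of covered positions (intersection over union of the two occupancy
# sets); feature-vector distances are the standard euclidean, manhattan and
# maximum metrics. All distances are assembled once into a full symmetric
# matrix that is then handed to clustering — the clusterer never sees
# genome-length vectors.

.METRICS <- c("euclidean", "manhattan", "maximum")

.checkNonEmptyTrack <- function(track) {
  if (totalCoverage(track) == 0)
    .tdStop("trackdist_empty_track",
            sprintf("track '%s' covers no positions; base-pair similarity against it is degenerate",
                    trackName(track)))
  invisible(TRUE)
}

#' Jaccard similarity of two tracks at base-pair resolution
#'
#' Intersection of the base pairs covered by the two tracks divided by the
#' union: 1 when the tracks cover exactly the same positions, 0 when they
#' share none. This is the direct sequence-level similarity between two
#' binary occupancy vectors, with normalization built into the measure.
#'
#' @param a,b non-empty [GenomeTrack-class] objects on the same genome.
#' @return Similarity in \[0, 1\].
#' @export
jaccardSimilarity <- function(a, b) {
  ra <- a@ranges; rb <- b@ranges
  .checkSameGenome(ra, rb)
  .checkNonEmptyTrack(a)
  .checkNonEmptyTrack(b)
  inter <- .overlapBp(ra, rb)
  inter / (sum(GenomicRanges::width(ra)) + sum(GenomicRanges::width(rb)) - inter)
}

#' Jaccard distance: 1 - Jaccard similarity
#'
#' The dissimilarity form handed to clustering; a metric on merged tracks.
#'
#' @inheritParams jaccardSimilarity
#' @return Distance in \[0, 1\].
#' @export
jaccardDistance <- function(a, b) 1 - jaccardSimilarity(a, b)

#' Distance between two feature vectors
#'
#' @param x,y equal-length finite numeric vectors.
#' @param metric "euclidean" (root sum of squared differences), "manhattan"
#'   (sum of absolute differences) or "maximum" (largest absolute
#'   difference).
#' @return Non-negative distance.
#' @export
vectorDistance <- function(x, y, metric = c("euclidean", "manhattan",
                                            "maximum")) {
  metric <- match.arg(metric)
  if (length(x) != length(y))
    .tdStop("trackdist_invalid_input", "feature vectors differ in length")
  if (length(x) == 0L)
    .tdStop("trackdist_invalid_input", "feature vectors must be non-empty")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    .tdStop("trackdist_invalid_input", "feature vectors must be finite")
  as.numeric(stats::dist(rbind(x, y), method = metric))
}

.newDistanceMatrix <- function(values, trackNames, method) {
  dimnames(values) <- list(trackNames, trackNames)
  new("TrackDistanceMatrix", values = values, method = method)
}

#' Pairwise Jaccard distance matrix (direct sequence-level similarity)
#'
#' Computes all pairwise Jaccard distances between tracks, optionally after
#' clipping every track to a region extent (e.g. autosomes only).
#'
#' @param tracks list of >= 2 non-empty [GenomeTrack-class] on one genome.
#' @param regions optional [RegionSet-class]; tracks are clipped to it first.
#'   A track left empty by clipping is an error.
#' @return A [TrackDistanceMatrix-class] with method "jaccard-distance".
#' @export
distanceMatrixDirect <- function(tracks, regions = NULL) {
  if (length(tracks) < 2L)
    .tdStop("trackdist_invalid_input", "need at least 2 tracks to compare")
  if (!is.null(regions))
    tracks <- lapply(tracks, clipTrack, regions = regions)
  nm <- vapply(tracks, trackName, "")
  if (anyDuplicated(nm))
    .tdStop("trackdist_invalid_input",
            sprintf("duplicate track name '%s'", nm[anyDuplicated(nm)]))
  lapply(tracks, .checkNonEmptyTrack)
  n <- length(tracks)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      d[i, j] <- d[j, i] <- jaccardDistance(tracks[[i]], tracks[[j]])
  .newDistanceMatrix(d, nm, "jaccard-distance")
}

#' Pairwise distance matrix between feature-matrix rows
#'
#' @param fm a [FeatureMatrix-class] with >= 2 tracks.
#' @param metric see [vectorDistance()].
#' @return A [TrackDistanceMatrix-class]; the method descriptor records the
#'   metric, normalization and aggregation (e.g.
#'   "euclidean-on-relative-coverage").
#' @export
distanceMatrixFeatures <- function(fm, metric = c("euclidean", "manhattan",
                                                  "maximum")) {
  metric <- match.arg(metric)
  v <- featureValues(fm)
  if (nrow(v) < 2L)
    .tdStop("trackdist_invalid_input", "need at least 2 tracks to compare")
  if (!all(is.finite(v)))
    .tdStop("trackdist_invalid_input", "feature matrix contains non-finite values")
  d <- as.matrix(stats::dist(v, method = metric))
  diag(d) <- 0
  .newDistanceMatrix(unname(d), rownames(v),
                     sprintf("%s-on-%s-%s", metric, fm@normalization,
                             fm@aggregation))
}

#' Write a TrackDistanceMatrix as TSV
#'
#' A `#method` comment line records provenance, then a square matrix with a
#' header row and first column of track names, at full double precision.
#'
#' @param dm a [TrackDistanceMatrix-class].
#' @param path output file.
#' @export
writeDistanceMatrix <- function(dm, path) {
  v <- distValues(dm)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#method=%s", distMethod(dm)), con)
  writeLines(paste(c("track", colnames(v)), collapse = "\t"), con)
  for (i in seq_len(nrow(v)))
    writeLines(paste(c(rownames(v)[i], .formatNum(v[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' Read back a TSV written by [writeDistanceMatrix()]
#'
#' @param path the TSV file.
#' @return A [TrackDistanceMatrix-class].
#' @export
readDistanceMatrix <- function(path) {
  lines <- readLines(path)
  method <- "unknown"
  if (length(lines) && startsWith(lines[1L], "#")) {
    method <- sub("^#method=", "", lines[1L])
    lines <- lines[-1L]
  }
  header <- strsplit(lines[1L], "\t")[[1L]]
  rows <- strsplit(lines[-1L], "\t")
  values <- t(vapply(rows, function(r) as.numeric(r[-1L]),
                     numeric(length(header) - 1L)))
  .newDistanceMatrix(values, header[-1L], method)
}
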