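#' @import methods
#' @importFrom GenomicRanges GRanges granges reduce intersect union setdiff
#'   findOverlaps pintersect countOverlaps slidingWindows tileGenome
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqnames seqlengths seqlevels
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<- new2
NULL

.emptyGRanges <- function(genome) {
  GRanges(seqinfo = genome)
}

#' GenomeTrack: a merged point/segment track on a fixed genome
#'
#' A genomic track is a set of points or segments on the coordinate line of a
#' reference genome. Conceptually it is the binary occupancy vector V over all
#' N genome positions (V[i] = 1 iff position i is covered); `GenomeTrack`
#' realizes that vector compactly as a sorted, merged set of intervals, so no
#' genome-length array is ever materialized.
#'
#' Overlapping and abutting input records are coalesced at load time (the
#' binary vector is unchanged by within-track multiplicity), but the original
#' element starts are retained so that count-based aggregation can still count
#' pre-merge elements.
#'
#' @slot name single track name.
#' @slot ranges [GenomicRanges::GRanges] of merged, sorted intervals carrying
#'   the full genome [GenomeInfoDb::Seqinfo].
#' @slot elementStarts [GenomicRanges::GRanges] of width-1 ranges at the start
#'   position of each original (pre-merge) record.
#'
#' @seealso [readBed()], [readGff()], [totalCoverage()]
#' @export
setClass("GenomeTrack", representation(
  name = "character",
  ranges = "GRanges",
  elementStarts = "GRanges"
))

setValidity("GenomeTrack", function(object) {
  msg <- character()
  if (length(object@name) != 1L || is.na(object@name) || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  sl <- seqlengths(object@ranges)
  if (length(sl) == 0L || anyNA(sl))
    msg <- c(msg, "track genome must have defined chromosome lengths")
  r <- granges(object@ranges)
  if (!identical(r, reduce(r)))
    msg <- c(msg, "intervals must be sorted, merged and non-adjacent")
  if (length(r) && (any(GenomicRanges::start(r) < 1L) ||
                    any(GenomicRanges::end(r) > sl[as.character(seqnames(r))])))
    msg <- c(msg, "intervals must lie within chromosome bounds")
  if (!identical(seqinfo(object@elementStarts), seqinfo(object@ranges)))
    msg <- c(msg, "elementStarts must share the track's genome")
  if (length(msg)) msg else TRUE
})

#' ValuedTrack: a step function assigning a numeric value per base pair
#'
#' Extension of the point/segment model to tracks that carry a numeric value
#' at every base pair (e.g. a signal or propensity track). Stored sparsely as
#' non-overlapping steps; every position not covered by a step has value 0, so
#' the track is a total function over the genome.
#'
#' @slot name single track name.
#' @slot steps [GenomicRanges::GRanges] of sorted non-overlapping intervals
#'   with a numeric `value` metadata column.
#' @export
setClass("ValuedTrack", representation(
  name = "character",
  steps = "GRanges"
))

setValidity("ValuedTrack", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@steps) == 0L)
    msg <- c(msg, "a ValuedTrack needs at least one step")
  if (!"value" %in% names(mcols(object@steps)) ||
      !is.numeric(mcols(object@steps)$value))
    msg <- c(msg, "steps need a numeric 'value' column")
  if (!GenomicRanges::isDisjoint(object@steps))
    msg <- c(msg, "steps must be non-overlapping")
  if (!identical(object@steps, sort(object@steps)))
    msg <- c(msg, "steps must be sorted")
  if (length(msg)) msg else TRUE
})

#' RegionSet: a labelled set of (possibly non-contiguous) genome positions
#'
#' The aggregation target of feature extraction: either a contiguous bin of
#' consecutive positions, or an arbitrary set of positions covered by a
#' reference track (e.g. all genes of a functional category). Regions are
#' merged and sorted, so the set is a plain subset of genome positions.
#'
#' @slot label feature label carried into feature matrices.
#' @slot regions merged, sorted [GenomicRanges::GRanges].
#' @export
setClass("RegionSet", representation(
  label = "character",
  regions = "GRanges"
))

setValidity("RegionSet", function(object) {
  msg <- character()
  if (length(object@label) != 1L || !nzchar(object@label))
    msg <- c(msg, "'label' must be a single non-empty string")
  r <- granges(object@regions)
  if (!identical(r, reduce(r)))
    msg <- c(msg, "regions must be sorted, merged and non-adjacent")
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: tracks-by-features aggregation table
#'
#' Rows are tracks, columns are features (genome bins labelled
#' "chrom:start-end" in BED-style half-open coordinates, or reference-track
#' names). Cell (t, j) holds g(V^t restricted to feature j's positions) for
#' the chosen aggregation g: base-pair coverage, element count, or mean value.
#' Under relative normalization each row is divided by the track's
#' genome-wide total, making rows comparable between tracks of very different
#' overall coverage.
#'
#' @slot values numeric matrix with track rownames and feature colnames.
#' @slot aggregation one of "coverage", "count", "mean_value".
#' @slot normalization one of "raw", "relative".
#' @export
setClass("FeatureMatrix", representation(
  values = "matrix",
  aggregation = "character",
  normalization = "character"
))

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (!is.numeric(v)) msg <- c(msg, "'values' must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' needs track rownames and feature colnames")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate track names")
  if (!object@aggregation %in% c("coverage", "count", "mean_value"))
    msg <- c(msg, "unknown aggregation")
  if (!object@normalization %in% c("raw", "relative"))
    msg <- c(msg, "unknown normalization")
  if (length(msg)) msg else TRUE
})

#' TrackDistanceMatrix: symmetric pairwise track distances
#'
#' The precomputed distance matrix that is handed to the clustering step, so
#' that clustering never touches genome-length vectors. Symmetric,
#' non-negative, zero diagonal, finite.
#'
#' @slot values symmetric numeric matrix with identical row/col track names.
#' @slot method descriptor of how distances were computed, e.g.
#'   "jaccard-distance" or "euclidean-on-coverage-relative".
#' @export
setClass("TrackDistanceMatrix", representation(
  values = "matrix",
  method = "character"
))

setValidity("TrackDistanceMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "row and column track names must be identical")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate track names")
  if (!all(is.finite(v))) msg <- c(msg, "distances must be finite")
  else {
    if (any(v < 0)) msg <- c(msg, "distances must be non-negative")
    if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
    if (!isSymmetric(unname(v), tol = 0)) msg <- c(msg, "matrix must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' TrackDendrogram: binary merge tree from agglomerative clustering
#'
#' Leaves are tracks (ids 0..n-1 in input order); each of the n-1 merges
#' creates internal node n..2n-2 and records its two children, the merge
#' height, and the size of the merged cluster. Supports height- and k-based
#' subcluster cutting, Newick export, and leaf ordering for heat maps.
#'
#' @slot leaves track names in input order.
#' @slot merges data.frame with integer columns `left`, `right`, numeric
#'   `height`, integer `size`; row i creates node `length(leaves) + i - 1`.
#' @slot method distance-method descriptor inherited from the matrix.
#' @slot linkage one of "average", "single", "complete".
#' @export
setClass("TrackDendrogram", representation(
  leaves = "character",
  merges = "data.frame",
  method = "character",
  linkage = "character"
))

setValidity("TrackDendrogram", function(object) {
  n <- length(object@leaves)
  m <- object@merges
  msg <- character()
  if (!all(c("left", "right", "height", "size") %in% names(m)))
    msg <- c(msg, "merges needs columns left, right, height, size")
  else {
    if (nrow(m) != n - 1L) msg <- c(msg, "need exactly n-1 merges")
    kids <- c(m$left, m$right)
    if (anyDuplicated(kids) || !all(kids %in% 0:(2L * n - 3L)))
      msg <- c(msg, "every node id must be used exactly once as a child")
    if (any(m$height < 0)) msg <- c(msg, "merge heights must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' GroupSpec: parameters of the synthetic group-structured track generator
#'
#' Describes families of tracks with planted group structure: each group has
#' an archetype segment set; members keep each archetype segment with
#' probability `keepProb`, jitter its start by a rounded Normal(0, jitterSd)
#' displacement, and add `noiseSegments` uniformly placed extra segments.
#'
#' @slot nGroups number of groups (>= 2).
#' @slot tracksPerGroup tracks per group (>= 2).
#' @slot segmentsPerArchetype segments in each group archetype.
#' @slot segmentLength segment length, bp.
#' @slot jitterSd SD of the per-segment start displacement, bp.
#' @slot keepProb probability a member keeps an archetype segment.
#' @slot noiseSegments random extra segments per member track.
#' @slot seed integer seed driving the single pseudo-random stream.
#' @export
setClass("GroupSpec", representation(
  nGroups = "integer",
  tracksPerGroup = "integer",
  segmentsPerArchetype = "integer",
  segmentLength = "integer",
  jitterSd = "numeric",
  keepProb = "numeric",
  noiseSegments = "integer",
  seed = "integer"
))

setValidity("GroupSpec", function(object) {
  msg <- character()
  if (object@nGroups < 2L) msg <- c(msg, "need >= 2 groups")
  if (object@tracksPerGroup < 2L) msg <- c(msg, "need >= 2 tracks per group")
  if (object@segmentsPerArchetype < 1L) msg <- c(msg, "need >= 1 archetype segment")
  if (object@segmentLength < 1L) msg <- c(msg, "segment length must be >= 1 bp")
  if (object@jitterSd < 0) msg <- c(msg, "jitterSd must be >= 0")
  if (object@keepProb <= 0 || object@keepProb > 1)
    msg <- c(msg, "keepProb must be in (0, 1]")
  if (object@noiseSegments < 0L) msg <- c(msg, "noiseSegments must be >= 0")
  if (length(msg)) msg else TRUE
})
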