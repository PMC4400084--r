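#' Construct a GenomeTrack from a GRanges
#'
#' Input ranges are merged (overlapping/abutting intervals coalesced) and
#' sorted; the start of every input range is retained as an element start so
#' count aggregation can count pre-merge elements.
#'
#' @param name track name.
#' @param gr a [GenomicRanges::GRanges] whose seqinfo carries chromosome
#'   lengths (see [readChromSizes()]).
#' @return A [GenomeTrack-class] object.
#' @examples
#' g <- Seqinfo("chr1", 1000)
#' tr <- GenomeTrack("t", GRanges("chr1", IRanges(c(1, 6), c(10, 15)),
#'                               seqinfo = g))
#' totalCoverage(tr)  # 15: records merged into chr1:1-15
#' @export
GenomeTrack <- function(name, gr) {
  gr <- granges(gr)
  starts <- GRanges(seqnames(gr), IRanges(GenomicRanges::start(gr), width = 1L),
                    seqinfo = seqinfo(gr))
  merged <- sort(reduce(gr))
  if (length(merged) && (length(seqlengths(merged)) == 0L ||
                         anyNA(seqlengths(merged)) ||
                         any(GenomicRanges::end(merged) >
                             seqlengths(merged)[as.character(seqnames(merged))])))
    .tdStop("trackdist_invalid_interval",
            "track intervals must lie within a genome with defined lengths")
  # invariants hold by construction; skip the (costly) validity re-check
  S4Vectors::new2("GenomeTrack", name = as.character(name),
                  ranges = merged, elementStarts = starts, check = FALSE)
}

#' @describeIn GenomeTrack Track name.
#' @param x,object a `GenomeTrack`.
#' @export
setGeneric("trackName", function(x) standardGeneric("trackName"))

#' @rdname GenomeTrack
#' @export
setMethod("trackName", "GenomeTrack", function(x) x@name)

#' @rdname GenomeTrack
#' @export
setMethod("trackName", "ValuedTrack", function(x) x@name)

#' @describeIn GenomeTrack Merged intervals as a GRanges.
#' @export
setGeneric("trackRanges", function(x) standardGeneric("trackRanges"))

#' @rdname GenomeTrack
#' @export
setMethod("trackRanges", "GenomeTrack", function(x) x@ranges)

#' @describeIn GenomeTrack Number of original (pre-merge) elements.
#' @export
setGeneric("elementCount", function(x) standardGeneric("elementCount"))

#' @rdname GenomeTrack
#' @export
setMethod("elementCount", "GenomeTrack", function(x) length(x@elementStarts))

#' @describeIn GenomeTrack Width-1 GRanges at original element starts.
#' @export
setGeneric("elementStarts", function(x) standardGeneric("elementStarts"))

#' @rdname GenomeTrack
#' @export
setMethod("elementStarts", "GenomeTrack", function(x) x@elementStarts)

setMethod("show", "GenomeTrack", function(object) {
  cat("GenomeTrack '", object@name, "': ", length(object@ranges),
      " merged intervals, ", elementCount(object), " elements, ",
      totalCoverage(object), " bp covered on ",
      length(seqlevels(object@ranges)), " chromosome(s)\n", sep = "")
})

#' Construct a ValuedTrack
#'
#' @param name track name.
#' @param steps GRanges with a numeric `value` metadata column; positions not
#'   covered by any step implicitly have value 0.
#' @return A [ValuedTrack-class] object.
#' @export
ValuedTrack <- function(name, steps) {
  steps <- sort(steps)
  new("ValuedTrack", name = as.character(name), steps = steps)
}

#' @describeIn ValuedTrack Step intervals with values.
#' @param x,object a `ValuedTrack`.
#' @export
setGeneric("trackSteps", function(x) standardGeneric("trackSteps"))

#' @rdname ValuedTrack
#' @export
setMethod("trackSteps", "ValuedTrack", function(x) x@steps)

setMethod("show", "ValuedTrack", function(object) {
  cat("ValuedTrack '", object@name, "': ", length(object@steps),
      " steps, value range [", min(mcols(object@steps)$value), ", ",
      max(mcols(object@steps)$value), "]\n", sep = "")
})

#' Construct a RegionSet
#'
#' @param regions a GRanges; merged and sorted on construction.
#' @param label feature label (defaults to "regions").
#' @return A [RegionSet-class] object.
#' @export
RegionSet <- function(regions, label = "regions") {
  S4Vectors::new2("RegionSet", label = as.character(label),
                  regions = sort(reduce(granges(regions))), check = FALSE)
}

#' @describeIn RegionSet The merged regions as a GRanges.
#' @param x,object a `RegionSet`.
#' @export
setGeneric("regionRanges", function(x) standardGeneric("regionRanges"))

#' @rdname RegionSet
#' @export
setMethod("regionRanges", "RegionSet", function(x) x@regions)

#' @describeIn RegionSet The feature label.
#' @export
setGeneric("regionLabel", function(x) standardGeneric("regionLabel"))

#' @rdname RegionSet
#' @export
setMethod("regionLabel", "RegionSet", function(x) x@label)

setMethod("show", "RegionSet", function(object) {
  cat("RegionSet '", object@label, "': ", length(object@regions),
      " regions, ", sum(GenomicRanges::width(object@regions)), " bp\n",
      sep = "")
})

#' @describeIn FeatureMatrix The numeric values matrix.
#' @param x,object a `FeatureMatrix`.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @describeIn FeatureMatrix Feature (column) labels.
#' @export
setGeneric("featureLabels", function(x) standardGeneric("featureLabels"))

#' @rdname FeatureMatrix
#' @export
setMethod("featureLabels", "FeatureMatrix", function(x) colnames(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix: ", nrow(object@values), " tracks x ",
      ncol(object@values), " features (", object@aggregation, ", ",
      object@normalization, ")\n", sep = "")
})

#' @describeIn TrackDistanceMatrix The numeric distance matrix.
#' @param x,object a `TrackDistanceMatrix`.
#' @export
setGeneric("distValues", function(x) standardGeneric("distValues"))

#' @rdname TrackDistanceMatrix
#' @export
setMethod("distValues", "TrackDistanceMatrix", function(x) x@values)

#' @describeIn TrackDistanceMatrix Descriptor of the distance computation.
#' @export
setGeneric("distMethod", function(x) standardGeneric("distMethod"))

#' @rdname TrackDistanceMatrix
#' @export
setMethod("distMethod", "TrackDistanceMatrix", function(x) x@method)

setMethod("show", "TrackDistanceMatrix", function(object) {
  cat("TrackDistanceMatrix: ", nrow(object@values), " tracks, method '",
      object@method, "'\n", sep = "")
})

setMethod("show", "TrackDendrogram", function(object) {
  cat("TrackDendrogram: ", length(object@leaves), " leaves, ",
      object@linkage, " linkage, max height ",
      format(max(object@merges$height)), "\n", sep = "")
})

#' Construct a GroupSpec
#'
#' Defaults describe the package's standard synthetic benchmark: 3 groups of
#' 4 tracks, 20 archetype segments of 1 kb per group, start jitter with SD of
#' 1/20 of the segment length, 95% segment retention, and 1 noise segment per
#' track (5% of the archetype count).
#'
#' @param nGroups,tracksPerGroup,segmentsPerArchetype,segmentLength,jitterSd,keepProb,noiseSegments,seed
#'   see [GroupSpec-class].
#' @return A [GroupSpec-class] object.
#' @export
GroupSpec <- function(nGroups = 3L, tracksPerGroup = 4L,
                      segmentsPerArchetype = 20L, segmentLength = 1000L,
                      jitterSd = segmentLength / 20, keepProb = 0.95,
                      noiseSegments = 1L, seed = 1L) {
  new("GroupSpec", nGroups = as.integer(nGroups),
      tracksPerGroup = as.integer(tracksPerGroup),
      segmentsPerArchetype = as.integer(segmentsPerArchetype),
      segmentLength = as.integer(segmentLength),
      jitterSd = as.numeric(jitterSd), keepProb = as.numeric(keepProb),
      noiseSegments = as.integer(noiseSegments), seed = as.integer(seed))
}

setMethod("show", "GroupSpec", function(object) {
  cat("GroupSpec: ", object@nGroups, " groups x ", object@tracksPerGroup,
      " tracks; ", object@segmentsPerArchetype, " segments of ",
      object@segmentLength, " bp; jitter SD ", object@jitterSd,
      " bp; keepProb ", object@keepProb, "; ", object@noiseSegments,
      " noise segment(s); seed ", object@seed, "\n", sep = "")
})
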