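# Track input/output: chrom.sizes, BED (0-based half-open), GFF (1-based
# inclusive), bedGraph. Internally everything is a GRanges (1-based
# inclusive); conversion happens only at the file boundary.
#
# Validation is strict by design: unknown chromosomes, records past
# chromosome ends and zero-length records are errors, not silently fixed —
# they almost always indicate a genome-build mismatch.

.tdStop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "trackdist_error")))
}

#' Read a UCSC chrom.sizes file as the genome coordinate system
#'
#' The genome is an ordered list of chromosomes with lengths; every track,
#' bin and reference set is validated against it. Chromosome order in the
#' file defines the canonical output order everywhere downstream.
#'
#' @param path two-column whitespace-separated file: chromosome name, length.
#' @return A [GenomeInfoDb::Seqinfo] with chromosomes in file order.
#' @examples
#' f <- tempfile(); writeLines(c("chr1\t1000", "chr2\t500"), f)
#' g <- readChromSizes(f)
#' sum(seqlengths(g))  # genome length N = 1500
#' @export
readChromSizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    .tdStop("trackdist_parse_error", "empty chrom.sizes file")
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    .tdStop("trackdist_parse_error",
            sprintf("malformed chrom.sizes line %d: need 'name length'", bad[1L]))
  nm <- vapply(fields, `[`, "", 1L)
  len <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(len) || any(len != floor(len)))
    .tdStop("trackdist_parse_error", "chromosome lengths must be integers")
  if (any(len <= 0))
    .tdStop("trackdist_invalid_genome",
            sprintf("non-positive length for chromosome '%s'", nm[which(len <= 0)[1L]]))
  if (anyDuplicated(nm))
    .tdStop("trackdist_invalid_genome",
            sprintf("duplicate chromosome '%s'", nm[anyDuplicated(nm)]))
  Seqinfo(seqnames = nm, seqlengths = as.integer(len))
}

#' Total genome length
#'
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @return Total number of positions N (sum of chromosome lengths).
#' @export
genomeLength <- function(genome) sum(as.numeric(seqlengths(genome)))

# Shared record validation; start0/end0 are 0-based half-open.
.validateRecords <- function(chrom, start0, end0, genome, what) {
  sl <- seqlengths(genome)
  unknown <- !(chrom %in% names(sl))
  if (any(unknown))
    .tdStop("trackdist_unknown_chromosome",
            sprintf("%s: unknown chromosome '%s' (not in genome)",
                    what, chrom[which(unknown)[1L]]))
  if (anyNA(start0) || anyNA(end0))
    .tdStop("trackdist_parse_error", sprintf("%s: non-numeric coordinates", what))
  if (any(start0 < 0))
    .tdStop("trackdist_invalid_interval", sprintf("%s: negative start", what))
  if (any(end0 <= start0))
    .tdStop("trackdist_invalid_interval",
            sprintf("%s: end <= start (zero-length and reversed records are rejected)", what))
  over <- end0 > sl[chrom]
  if (any(over))
    .tdStop("trackdist_invalid_interval",
            sprintf("%s: record ends at %d, past end of %s (%d bp)", what,
                    end0[which(over)[1L]], chrom[which(over)[1L]],
                    sl[chrom[which(over)[1L]]]))
  invisible(TRUE)
}

.readTabular <- function(path, minCols, what) {
  lines <- readLines(path)
  keep <- nzchar(trimws(lines)) & !grepl("^(#|track\\b|browser\\b)", lines)
  lines <- lines[keep]
  if (length(lines) == 0L) return(NULL)
  fields <- strsplit(lines, "\t")
  ws <- lengths(fields) < minCols
  if (any(ws))  # tolerate space-separated files
    fields[ws] <- strsplit(lines[ws], "[ \t]+")
  if (any(lengths(fields) < minCols))
    .tdStop("trackdist_parse_error",
            sprintf("%s: line with fewer than %d fields", what, minCols))
  fields
}

.trackFromRecords <- function(name, chrom, start1, end1, genome) {
  gr <- GRanges(chrom, IRanges(start1, end1), seqinfo = genome)
  GenomeTrack(name, gr)
}

#' Read a BED file as a GenomeTrack
#'
#' BED coordinates are 0-based half-open. Records are validated against the
#' genome, then merged (overlapping/abutting records coalesced); the number
#' and start positions of the original records are retained for count
#' aggregation.
#'
#' @param path BED3+ file.
#' @param genome a [GenomeInfoDb::Seqinfo] from [readChromSizes()].
#' @param name track name; defaults to the file name without extension.
#' @return A [GenomeTrack-class].
#' @export
readBed <- function(path, genome, name = sub("\\.[^.]*$", "", basename(path))) {
  fields <- .readTabular(path, 3L, basename(path))
  if (is.null(fields))
    return(GenomeTrack(name, .emptyGRanges(genome)))
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  .validateRecords(chrom, start0, end0, genome, basename(path))
  .trackFromRecords(name, chrom, start0 + 1, end0, genome)
}

#' Read a GFF file as a GenomeTrack
#'
#' GFF coordinates (columns 4-5) are 1-based inclusive; they are converted to
#' the internal convention on read, so a record with start == end is a valid
#' 1-bp point. Everything else behaves as [readBed()].
#'
#' @inheritParams readBed
#' @return A [GenomeTrack-class].
#' @export
readGff <- function(path, genome, name = sub("\\.[^.]*$", "", basename(path))) {
  fields <- .readTabular(path, 5L, basename(path))
  if (is.null(fields))
    return(GenomeTrack(name, .emptyGRanges(genome)))
  chrom <- vapply(fields, `[`, "", 1L)
  start1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  end1 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 5L)))
  # 1-based inclusive -> 0-based half-open, then shared validation
  .validateRecords(chrom, start1 - 1, end1, genome, basename(path))
  .trackFromRecords(name, chrom, start1, end1, genome)
}

#' Write a GenomeTrack as BED3
#'
#' Records are the merged intervals, in genome chromosome order then
#' coordinate order; re-reading the file reproduces the track's intervals
#' exactly.
#'
#' @param track a [GenomeTrack-class].
#' @param path output file.
#' @export
writeBed <- function(track, path) {
  gr <- sort(trackRanges(track))
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  # write.table on a 0-row frame still emits nothing, giving an empty file
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file as a ValuedTrack
#'
#' Four columns, 0-based half-open, one numeric value per step. Steps must
#' not overlap; positions without a step have value 0 (the track is a total
#' function over the genome). Values may be negative.
#'
#' @inheritParams readBed
#' @return A [ValuedTrack-class].
#' @export
readBedGraph <- function(path, genome,
                         name = sub("\\.[^.]*$", "", basename(path))) {
  fields <- .readTabular(path, 4L, basename(path))
  if (is.null(fields))
    .tdStop("trackdist_parse_error",
            sprintf("%s: a bedGraph needs at least one step", basename(path)))
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  value <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4L)))
  if (anyNA(value))
    .tdStop("trackdist_parse_error",
            sprintf("%s: non-numeric step value", basename(path)))
  .validateRecords(chrom, start0, end0, genome, basename(path))
  steps <- GRanges(chrom, IRanges(start0 + 1, end0), seqinfo = genome,
                   value = value)
  if (!GenomicRanges::isDisjoint(steps))
    .tdStop("trackdist_invalid_interval",
            sprintf("%s: overlapping bedGraph steps", basename(path)))
  ValuedTrack(name, steps)
}

#' Clip a track to a region set
#'
#' Restricts the track to the positions of `regions`: intervals are
#' intersected with the regions, and only elements whose start position lies
#' inside the regions are retained for count aggregation. This implements the
#' "region" restriction of a clustering run (e.g. autosomes only).
#'
#' @param track a [GenomeTrack-class].
#' @param regions a [RegionSet-class].
#' @return A clipped [GenomeTrack-class].
#' @export
clipTrack <- function(track, regions) {
  .checkSameGenome(trackRanges(track), regionRanges(regions))
  clipped <- GenomicRanges::intersect(trackRanges(track),
                                      regionRanges(regions))
  keep <- overlapsAny(elementStarts(track), regionRanges(regions))
  S4Vectors::new2("GenomeTrack", name = trackName(track),
                  ranges = sort(reduce(clipped)),
                  elementStarts = elementStarts(track)[keep], check = FALSE)
}
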