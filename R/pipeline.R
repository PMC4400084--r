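# End-to-end runs of the three canonical clustering cases, driven by a
# declarative run configuration (a flat key-value list, serialized as YAML).
# Every run writes, alongside its results, an echo of its own configuration;
# replaying the echo reproduces the output files byte for byte. The echo
# deliberately omits the output directory, so a replay into a fresh
# directory yields identical files.

.CASES <- c("direct", "positional", "reference")

#' Assemble a run configuration
#'
#' @param case "direct" (base-pair Jaccard), "positional" (genome bins) or
#'   "reference" (reference-track features).
#' @param genome path to a chrom.sizes file.
#' @param tracks named character vector/list: track name -> BED or GFF path
#'   (GFF recognized by .gff/.gff3/.gtf extension).
#' @param regions optional extent: character vector of chromosome names, or
#'   a BED file path.
#' @param binSize bin width, bp (positional case).
#' @param references named vector/list of reference BED paths (reference
#'   case).
#' @param aggregation,normalization,metric,linkage see the respective
#'   computation functions.
#' @param cutHeight,k optional subcluster cut; at most one of the two.
#' @return A validated run-configuration list.
#' @export
runConfig <- function(case, genome, tracks, regions = NULL, binSize = NULL,
                      references = NULL, aggregation = "coverage",
                      normalization = "relative", metric = "euclidean",
                      linkage = "average", cutHeight = NULL, k = NULL) {
  config <- list(case = case, genome = genome,
                 tracks = as.list(unlist(tracks)),
                 regions = regions, bin_size = binSize,
                 references = if (!is.null(references)) as.list(unlist(references)),
                 aggregation = aggregation, normalization = normalization,
                 metric = metric, linkage = linkage,
                 cut_height = cutHeight, k = k)
  .validateConfig(config)
}

.validateConfig <- function(config) {
  if (is.null(config$case) || !config$case %in% .CASES)
    .tdStop("trackdist_invalid_config",
            sprintf("case must be one of %s", paste(.CASES, collapse = "/")))
  if (is.null(config$genome))
    .tdStop("trackdist_invalid_config", "missing genome (chrom.sizes path)")
  if (length(config$tracks) < 2L || is.null(names(config$tracks)) ||
      any(!nzchar(names(config$tracks))))
    .tdStop("trackdist_invalid_config", "need >= 2 named track paths")
  if (config$case == "positional" && is.null(config$bin_size))
    .tdStop("trackdist_invalid_config", "positional case needs bin_size")
  if (config$case == "reference" && length(config$references) < 2L)
    .tdStop("trackdist_invalid_config", "reference case needs >= 2 references")
  if (!is.null(config$cut_height) && !is.null(config$k))
    .tdStop("trackdist_invalid_config", "give cut_height or k, not both")
  for (p in c(config$genome, unlist(config$tracks), unlist(config$references)))
    if (!file.exists(p))
      .tdStop("trackdist_invalid_config", sprintf("missing input file: %s", p))
  # canonical key order so the YAML echo is byte-stable
  keys <- c("case", "genome", "tracks", "regions", "bin_size", "references",
            "aggregation", "normalization", "metric", "linkage",
            "cut_height", "k")
  config <- config[keys]
  names(config) <- keys
  config[!vapply(config, is.null, NA)]
}

#' Read a run configuration from YAML
#'
#' @param path YAML file written by hand or echoed by a previous run.
#' @return A validated configuration list.
#' @export
readRunConfig <- function(path) {
  .validateConfig(yaml::read_yaml(path))
}

#' Write a run configuration as YAML
#'
#' @param config a configuration list.
#' @param path output file.
#' @export
writeRunConfig <- function(config, path) {
  writeLines(yaml::as.yaml(config), path)
  invisible(path)
}

.readTrackFile <- function(path, genome, name) {
  if (grepl("\\.(gff3?|gtf)$", path, ignore.case = TRUE))
    readGff(path, genome, name)
  else readBed(path, genome, name)
}

.loadRegions <- function(regions, genome) {
  if (is.null(regions)) return(NULL)
  regions <- unlist(regions)
  if (length(regions) == 1L && file.exists(regions))
    return(RegionSet(trackRanges(readBed(regions, genome)), "regions"))
  unknown <- setdiff(regions, seqnames(genome))
  if (length(unknown))
    .tdStop("trackdist_invalid_config",
            sprintf("region chromosome '%s' not in genome", unknown[1L]))
  sel <- seqnames(genome) %in% regions
  RegionSet(GRanges(seqnames(genome)[sel],
                    IRanges(1L, seqlengths(genome)[sel]), seqinfo = genome),
            "regions")
}

.loadRun <- function(config) {
  genome <- readChromSizes(config$genome)
  tracks <- mapply(function(p, nm) .readTrackFile(p, genome, nm),
                   config$tracks, names(config$tracks), SIMPLIFY = FALSE)
  list(genome = genome, tracks = unname(tracks),
       regions = .loadRegions(config$regions, genome))
}

.cutLabels <- function(dg, config) {
  if (!is.null(config$cut_height)) cutByHeight(dg, config$cut_height)
  else if (!is.null(config$k)) cutByK(dg, config$k)
  else NULL
}

.writeBundle <- function(config, outDir, dm, dg, fm = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeDistanceMatrix(dm, file.path(outDir, "distances.tsv"))
  writeLines(toNewick(dg), file.path(outDir, "dendrogram.newick"))
  ord <- leafOrder(dg)
  writeLines(ord, file.path(outDir, "leaf_order.txt"))
  labels <- .cutLabels(dg, config)
  if (!is.null(labels))
    writeSubclusters(labels, file.path(outDir, "subclusters.tsv"))
  if (!is.null(fm)) {
    writeFeatureMatrix(fm, file.path(outDir, "features.tsv"))
    reord <- new("FeatureMatrix",
                 values = featureValues(fm)[ord, , drop = FALSE],
                 aggregation = fm@aggregation,
                 normalization = fm@normalization)
    writeFeatureMatrix(reord, file.path(outDir, "features_leaf_ordered.tsv"))
  }
  writeRunConfig(config, file.path(outDir, "run_config.echo"))
  log <- c(sprintf("case: %s", config$case),
           sprintf("tracks: %d", nrow(distValues(dm))),
           sprintf("distance matrix: %dx%d (%s)", nrow(distValues(dm)),
                   ncol(distValues(dm)), distMethod(dm)),
           if (!is.null(fm)) sprintf("features: %d", ncol(featureValues(fm))),
           sprintf("linkage: %s", dg@linkage),
           if (!is.null(labels)) sprintf("subclusters: %d", max(labels)))
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(list(distances = dm, dendrogram = dg, features = fm,
                 subclusters = labels, leafOrder = ord, config = config,
                 outDir = outDir))
}

#' Run the direct sequence-level similarity case end to end
#'
#' Reads genome and tracks, clips to the region extent, computes the pairwise
#' Jaccard distance matrix, clusters, and writes `distances.tsv`,
#' `dendrogram.newick`, `leaf_order.txt`, `subclusters.tsv` (when a cut is
#' requested), `run_log.txt` and the replayable `run_config.echo` into
#' `outDir`.
#'
#' @param config configuration from [runConfig()] or [readRunConfig()], with
#'   `case = "direct"`.
#' @param outDir output directory.
#' @return Invisibly, a list with the computed objects (`distances`,
#'   `dendrogram`, `subclusters`, `leafOrder`) and the output paths.
#' @export
runDirect <- function(config, outDir) {
  config <- .validateConfig(config)
  if (config$case != "direct")
    .tdStop("trackdist_invalid_config", "runDirect needs case = 'direct'")
  inputs <- .loadRun(config)
  log <- sprintf("track %s: %d elements, %d bp",
                 vapply(inputs$tracks, trackName, ""),
                 vapply(inputs$tracks, elementCount, 0L),
                 vapply(inputs$tracks, totalCoverage, 0))
  dm <- distanceMatrixDirect(inputs$tracks, inputs$regions)
  dg <- hierarchicalCluster(dm, config$linkage)
  res <- .writeBundle(config, outDir, dm, dg)
  cat(log, sep = "\n", file = file.path(outDir, "run_log.txt"), append = TRUE)
  invisible(res)
}

.runFeatureCase <- function(config, outDir, fm) {
  dm <- distanceMatrixFeatures(fm, config$metric)
  dg <- hierarchicalCluster(dm, config$linkage)
  .writeBundle(config, outDir, dm, dg, fm)
}

#' Run the positional-distribution case (genome bins) end to end
#'
#' As [runDirect()], but features are per-bin aggregates
#' ([extractBinFeatures()]); additionally writes `features.tsv` and the
#' leaf-ordered `features_leaf_ordered.tsv` for heat-map rendering.
#'
#' @param config configuration with `case = "positional"` and `bin_size`.
#' @param outDir output directory.
#' @return Invisibly, the result bundle (see [runDirect()]), plus
#'   `features`.
#' @export
runPositional <- function(config, outDir) {
  config <- .validateConfig(config)
  if (config$case != "positional")
    .tdStop("trackdist_invalid_config", "runPositional needs case = 'positional'")
  inputs <- .loadRun(config)
  fm <- extractBinFeatures(inputs$tracks, inputs$genome, config$bin_size,
                           regions = inputs$regions,
                           aggregation = config$aggregation,
                           normalization = config$normalization)
  .runFeatureCase(config, outDir, fm)
}

#' Run the reference-track case end to end
#'
#' As [runPositional()], but features are aggregates over the position sets
#' of the configured reference tracks ([extractReferenceFeatures()]);
#' feature labels are the reference names.
#'
#' @param config configuration with `case = "reference"` and `references`.
#' @param outDir output directory.
#' @return Invisibly, the result bundle.
#' @export
runReference <- function(config, outDir) {
  config <- .validateConfig(config)
  if (config$case != "reference")
    .tdStop("trackdist_invalid_config", "runReference needs case = 'reference'")
  inputs <- .loadRun(config)
  refs <- mapply(function(p, nm) .readTrackFile(p, inputs$genome, nm),
                 config$references, names(config$references),
                 SIMPLIFY = FALSE)
  fm <- extractReferenceFeatures(inputs$tracks, unname(refs), inputs$genome,
                                 aggregation = config$aggregation,
                                 normalization = config$normalization)
  .runFeatureCase(config, outDir, fm)
}

#' Dispatch a run configuration to the matching case
#'
#' @param config a configuration list.
#' @param outDir output directory.
#' @return Invisibly, the result bundle.
#' @export
executeRun <- function(config, outDir) {
  config <- .validateConfig(config)
  switch(config$case,
         direct = runDirect(config, outDir),
         positional = runPositional(config, outDir),
         reference = runReference(config, outDir))
}

#' Replay a run from an echoed configuration
#'
#' Re-executes the analysis described by a `run_config.echo` (or any config
#' YAML); output files are byte-identical to the original run's.
#'
#' @param configPath path to the YAML configuration.
#' @param outDir output directory.
#' @return Invisibly, the result bundle.
#' @export
replayRun <- function(configPath, outDir) {
  executeRun(readRunConfig(configPath), outDir)
}

#' Generate a synthetic benchmark data set on disk
#'
#' Writes a chrom.sizes file, one BED per generated track, and
#' `truth_labels.tsv` into `outDir`; byte-deterministic for a fixed spec.
#'
#' @param genome a [GenomeInfoDb::Seqinfo].
#' @param spec a [GroupSpec-class].
#' @param outDir output directory.
#' @return Invisibly, the [generateGroupTracks()] result with an added
#'   `dir` element.
#' @export
runSimulate <- function(genome, spec, outDir) {
  generated <- generateGroupTracks(genome, spec)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste(seqnames(genome), seqlengths(genome), sep = "\t"),
             file.path(outDir, "genome.chrom.sizes"))
  writeGroupTracks(generated, outDir)
  generated$dir <- outDir
  invisible(generated)
}
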