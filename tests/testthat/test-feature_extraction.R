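test_that("bins tile the extent with a short last bin, never across chromosomes", {
  g1 <- toyGenome(c(chr1 = 100L))
  expect_equal(names(makeBins(g1, 50)), c("chr1:0-50", "chr1:50-100"))

  g2 <- toyGenome(c(chr1 = 120L))
  bins <- makeBins(g2, 50)
  expect_equal(names(bins), c("chr1:0-50", "chr1:50-100", "chr1:100-120"))
  expect_equal(sum(width(bins)), 120)

  g3 <- toyGenome(c(chr1 = 100L, chr2 = 50L))
  bins <- makeBins(g3, 50)
  expect_length(bins, 3L)
  expect_equal(as.character(seqnames(bins)), c("chr1", "chr1", "chr2"))
  expect_error(makeBins(g3, 0), class = "trackdist_invalid_binsize")
})

test_that("bin features give per-bin mass, relative rows normalized by track total", {
  g <- toyGenome(c(chr1 = 100L))
  tr <- makeTrack("t", g, c("chr1", "chr1"), c(0, 60), c(10, 90))
  fm <- extractBinFeatures(list(tr), g, 50, normalization = "relative")
  expect_equal(unname(featureValues(fm)[1, ]), c(0.25, 0.75))
  raw <- extractBinFeatures(list(tr), g, 50, normalization = "raw")
  expect_equal(unname(featureValues(raw)[1, ]), c(10, 30))

  single <- makeTrack("s", g, "chr1", 0, 10)
  fm <- extractBinFeatures(list(single), g, 50)
  expect_equal(unname(featureValues(fm)[1, ]), c(1, 0))

  empty <- GenomeTrack("e", GRanges(seqinfo = g))
  expect_error(extractBinFeatures(list(empty), g, 50),
               class = "trackdist_zero_total")
  expect_error(extractBinFeatures(list(empty), g, 50),
               regexp = "'e'")  # the offending track is named
})

test_that("bin features equal brute-force aggregation of the binary vector", {
  set.seed(31)
  g <- toyGenome(c(chr1 = 150L, chr2 = 90L))
  bins <- makeBins(g, 40)
  for (rep in 1:20) {
    tr <- randomTrack(g)
    v <- bpVector(trackRanges(tr), g)
    expected <- vapply(seq_along(bins), function(j)
      sum(v & bpVector(bins[j], g)), 0L)
    fm <- extractBinFeatures(list(tr), g, 40, normalization = "raw")
    expect_equal(unname(featureValues(fm)[1, ]), as.numeric(expected))
  }
})

test_that("row sums are conserved over genome-tiling bins", {
  set.seed(41)
  g <- toyGenome(c(chr1 = 137L, chr2 = 91L))
  for (rep in 1:20) {
    tr <- randomTrack(g)
    rel <- extractBinFeatures(list(tr), g, 30)
    expect_equal(sum(featureValues(rel)), 1, tolerance = 1e-9)
    raw <- extractBinFeatures(list(tr), g, 30, normalization = "raw")
    expect_equal(sum(featureValues(raw)), totalCoverage(tr))
    cnt <- extractBinFeatures(list(tr), g, 30, aggregation = "count")
    expect_equal(sum(featureValues(cnt)), 1, tolerance = 1e-9)
  }
})

test_that("reference features aggregate over arbitrary position sets", {
  g <- toyGenome(c(chr1 = 100L))
  r1 <- makeTrack("R1", g, "chr1", 0, 10)
  r2 <- makeTrack("R2", g, "chr1", 20, 40)
  tr <- makeTrack("t", g, "chr1", 5, 25)
  fm <- extractReferenceFeatures(list(tr), list(r1, r2), g)
  expect_equal(unname(featureValues(fm)[1, ]), c(0.25, 0.25))  # 5/20 each
  expect_equal(featureLabels(fm), c("R1", "R2"))

  far <- makeTrack("far", g, "chr1", 60, 80)
  fm <- extractReferenceFeatures(list(far), list(r1, r2), g)
  expect_equal(unname(featureValues(fm)[1, ]), c(0, 0))

  same <- makeTrack("same", g, "chr1", 0, 10)
  fm <- extractReferenceFeatures(list(same), list(r1, r2), g)
  expect_equal(unname(featureValues(fm)[1, ]),
               c(1, intersectCoverage(same, r2) / totalCoverage(same)))

  emptyRef <- GenomeTrack("er", GRanges(seqinfo = g))
  expect_error(extractReferenceFeatures(list(tr), list(r1, emptyRef), g),
               class = "trackdist_invalid_reference")
  expect_error(extractReferenceFeatures(list(tr), list(r1), g),
               class = "trackdist_invalid_reference")
})

test_that("single-bin references reproduce bin features exactly", {
  set.seed(51)
  g <- toyGenome(c(chr1 = 150L, chr2 = 90L))
  bins <- makeBins(g, 40)
  refs <- lapply(seq_along(bins), function(j)
    RegionSet(bins[j], names(bins)[j]))
  for (rep in 1:5) {
    tracks <- list(randomTrack(g, name = "a"), randomTrack(g, name = "b"))
    viaBins <- extractBinFeatures(tracks, g, 40)
    viaRefs <- extractReferenceFeatures(tracks, refs, g)
    expect_identical(featureValues(viaBins), featureValues(viaRefs))
  }
})

test_that("feature extraction is equivariant under track reordering", {
  set.seed(61)
  g <- toyGenome()
  tracks <- lapply(c("a", "b", "c"), function(nm) randomTrack(g, name = nm))
  fm1 <- extractBinFeatures(tracks, g, 25)
  fm2 <- extractBinFeatures(tracks[c(3, 1, 2)], g, 25)
  expect_identical(featureValues(fm1)[c("c", "a", "b"), ],
                   featureValues(fm2))
})

test_that("feature matrix TSV round-trips values and labels exactly", {
  set.seed(71)
  g <- toyGenome()
  tracks <- list(randomTrack(g, name = "a"), randomTrack(g, name = "b"))
  fm <- extractBinFeatures(tracks, g, 33)
  f <- withr::local_tempfile()
  writeFeatureMatrix(fm, f)
  back <- readFeatureMatrix(f)
  expect_identical(featureValues(back), featureValues(fm))
  expect_identical(back@aggregation, fm@aggregation)
  expect_identical(back@normalization, fm@normalization)

  # labels containing spaces survive verbatim (tab-separated format)
  rs <- list(RegionSet(GRanges("chr1", IRanges(1, 40), seqinfo = g),
                       "GO axon growth"),
             RegionSet(GRanges("chr2", IRanges(1, 40), seqinfo = g),
                       "GO caspase activation"))
  fm <- extractReferenceFeatures(tracks, rs, g)
  writeFeatureMatrix(fm, f)
  expect_identical(featureLabels(readFeatureMatrix(f)),
                   c("GO axon growth", "GO caspase activation"))
})

test_that("mean-value reference features work for valued tracks", {
  g <- toyGenome(c(chr1 = 100L))
  vt <- ValuedTrack("v", GRanges("chr1", IRanges(1, 10), value = 2,
                                 seqinfo = g))
  refs <- list(RegionSet(GRanges("chr1", IRanges(1, 20), seqinfo = g), "A"),
               RegionSet(GRanges("chr1", IRanges(41, 60), seqinfo = g), "B"))
  fm <- extractReferenceFeatures(list(vt), refs, g,
                                 aggregation = "mean_value",
                                 normalization = "raw")
  expect_equal(unname(featureValues(fm)[1, ]), c(1, 0))
  expect_error(
    extractReferenceFeatures(list(vt), refs, g, aggregation = "mean_value",
                             normalization = "relative"),
    class = "trackdist_invalid_normalization")
})
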