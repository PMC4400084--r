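test_that("coverage and overlap operations match the worked examples", {
  g <- toyGenome(c(chr1 = 100L))
  a <- makeTrack("a", g, c("chr1", "chr1"), c(0, 60), c(10, 90))
  expect_equal(totalCoverage(a), 40)
  expect_equal(totalCoverage(GenomeTrack("e", GRanges(seqinfo = g))), 0)
  full <- makeTrack("f", g, "chr1", 0, 100)
  expect_equal(totalCoverage(full), 100)

  b <- makeTrack("b", g, "chr1", 5, 15)
  a1 <- makeTrack("a1", g, "chr1", 0, 10)
  expect_equal(intersectCoverage(a1, b), 5)
  expect_equal(unionCoverage(a1, b), 15)
  expect_equal(intersectCoverage(a, a), totalCoverage(a))
  expect_equal(unionCoverage(a, a), totalCoverage(a))
  disj <- makeTrack("d", g, "chr1", 10, 15)
  expect_equal(intersectCoverage(a1, disj), 0)

  tr <- makeTrack("t", g, "chr1", 5, 25)
  rs <- RegionSet(GRanges("chr1", IRanges(1, 10), seqinfo = g))
  expect_equal(coverageInRegions(tr, rs), 5)
  inside <- RegionSet(GRanges("chr1", IRanges(1, 50), seqinfo = g))
  expect_equal(coverageInRegions(tr, inside), totalCoverage(tr))
})

test_that("operations on different genomes are rejected", {
  a <- makeTrack("a", toyGenome(), "chr1", 0, 10)
  b <- makeTrack("b", toyGenome(c(chr1 = 50L)), "chr1", 0, 10)
  expect_error(intersectCoverage(a, b), class = "trackdist_genome_mismatch")
})

test_that("element counts assign boundary-spanning segments by start", {
  g <- toyGenome(c(chr1 = 100L))
  tr <- makeTrack("t", g, c("chr1", "chr1"), c(3, 45), c(8, 50))
  rs <- RegionSet(GRanges("chr1", IRanges(1, 10), seqinfo = g))
  expect_equal(countInRegions(tr, rs), 1L)

  spanning <- makeTrack("s", g, "chr1", 5, 30)  # starts inside, ends outside
  expect_equal(countInRegions(spanning, rs), 1L)
  expect_equal(countInRegions(GenomeTrack("e", GRanges(seqinfo = g)), rs), 0L)
})

test_that("sweep operations equal brute-force binary-vector computation", {
  set.seed(101)
  for (rep in 1:40) {
    g <- toyGenome(c(chr1 = 150L, chr2 = 90L))
    a <- randomTrack(g, name = "a")
    b <- randomTrack(g, name = "b")
    va <- bpVector(trackRanges(a), g)
    vb <- bpVector(trackRanges(b), g)
    expect_identical(totalCoverage(a), sum(va))
    expect_identical(intersectCoverage(a, b), sum(va & vb))
    expect_identical(unionCoverage(a, b), sum(va | vb))
    # inclusion-exclusion and symmetry
    expect_identical(unionCoverage(a, b),
                     totalCoverage(a) + totalCoverage(b) -
                       intersectCoverage(a, b))
    expect_identical(intersectCoverage(a, b), intersectCoverage(b, a))

    rs <- RegionSet(trackRanges(randomTrack(g, 4L, 30L)))
    vr <- bpVector(regionRanges(rs), g)
    expect_identical(coverageInRegions(a, rs), sum(va & vr))
  }
})

test_that("coverage in regions grows monotonically with the region set", {
  set.seed(7)
  g <- toyGenome()
  tr <- randomTrack(g)
  small <- RegionSet(GRanges("chr1", IRanges(1, 40), seqinfo = g))
  big <- RegionSet(GRanges(c("chr1", "chr2"), IRanges(c(1, 1), c(80, 50)),
                           seqinfo = g))
  expect_gte(coverageInRegions(tr, big), coverageInRegions(tr, small))
})

test_that("mean value aggregation zero-fills uncovered positions", {
  g <- toyGenome(c(chr1 = 100L))
  vt <- ValuedTrack("v", GRanges("chr1", IRanges(1, 5), value = 2,
                                 seqinfo = g))
  rs <- RegionSet(GRanges("chr1", IRanges(1, 10), seqinfo = g))
  expect_equal(meanValueInRegions(vt, rs), 1.0)  # (5*2 + 5*0) / 10

  const <- ValuedTrack("c", GRanges("chr1", IRanges(1, 10), value = 3.5,
                                    seqinfo = g))
  expect_equal(meanValueInRegions(const, rs), 3.5)

  far <- RegionSet(GRanges("chr1", IRanges(50, 60), seqinfo = g))
  expect_equal(meanValueInRegions(vt, far), 0)

  empty <- RegionSet(GRanges(seqinfo = g))
  expect_error(meanValueInRegions(vt, empty),
               class = "trackdist_empty_regions")
})

test_that("per-bp Pearson correlation matches explicit vectors", {
  g <- toyGenome(c(chr1 = 10L))
  rs <- RegionSet(GRanges("chr1", IRanges(1, 10), seqinfo = g))
  a <- ValuedTrack("a", GRanges("chr1", IRanges(c(1, 6), c(3, 8)),
                                value = c(1, 4), seqinfo = g))
  b2 <- ValuedTrack("b2", GRanges("chr1", IRanges(c(1, 6), c(3, 8)),
                                  value = c(2, 8), seqinfo = g))
  expect_equal(pearsonBp(a, b2, rs), 1.0)
  bneg <- ValuedTrack("bn", GRanges("chr1", IRanges(c(1, 6), c(3, 8)),
                                    value = c(-1, -4), seqinfo = g))
  expect_equal(pearsonBp(a, bneg, rs), -1.0)

  set.seed(21)
  for (rep in 1:15) {
    mkValued <- function(nm) {
      starts <- sort(sample(seq(1, 9, by = 2), 3))
      ValuedTrack(nm, GRanges("chr1", IRanges(starts, width = 1),
                              value = round(runif(3, -2, 2), 2),
                              seqinfo = g))
    }
    x <- mkValued("x"); y <- mkValued("y")
    expect_equal(pearsonBp(x, y, rs),
                 cor(bpValues(x, g), bpValues(y, g)), tolerance = 1e-12)
  }

  const <- ValuedTrack("c", GRanges("chr1", IRanges(1, 10), value = 1,
                                    seqinfo = g))
  expect_error(pearsonBp(const, const, rs),
               class = "trackdist_constant_track")
})
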