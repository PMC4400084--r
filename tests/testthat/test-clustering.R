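fixtureMatrix <- function() {
  asDistanceMatrix(matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
                          dimnames = list(c("A", "B", "C"),
                                          c("A", "B", "C"))))
}

test_that("the three linkages agree with hand-computed merge heights", {
  dm <- fixtureMatrix()
  avg <- hierarchicalCluster(dm, "average")
  expect_equal(avg@merges$height, c(1, 4.5))       # (4 + 5) / 2
  expect_equal(avg@merges[1, c("left", "right")],
               data.frame(left = 0L, right = 1L), ignore_attr = TRUE)
  expect_equal(hierarchicalCluster(dm, "single")@merges$height, c(1, 4))
  expect_equal(hierarchicalCluster(dm, "complete")@merges$height, c(1, 5))
})

test_that("average linkage matches a naive all-pairs-recomputing agglomerator", {
  set.seed(121)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    d <- randomDistanceMatrix(n)
    dg <- hierarchicalCluster(asDistanceMatrix(d), "average")
    naive <- naiveAgglomerate(d, "average")
    expect_equal(dg@merges$height, naive$height, tolerance = 1e-12)
    expect_equal(dg@merges$left, naive$left)
    expect_equal(dg@merges$right, naive$right)
    # UPGMA merge heights are non-decreasing
    expect_true(all(diff(dg@merges$height) >= -1e-12))
  }
})

test_that("single and complete linkage also match the naive oracle", {
  set.seed(131)
  for (linkage in c("single", "complete")) {
    for (rep in 1:10) {
      d <- randomDistanceMatrix(6)
      dg <- hierarchicalCluster(asDistanceMatrix(d), linkage)
      naive <- naiveAgglomerate(d, linkage)
      expect_equal(dg@merges$height, naive$height, tolerance = 1e-12)
      expect_equal(dg@merges$left, naive$left)
    }
  }
})

test_that("merge heights agree with stats::hclust on tie-free matrices", {
  set.seed(141)
  for (rep in 1:10) {
    d <- randomDistanceMatrix(7)
    dg <- hierarchicalCluster(asDistanceMatrix(d), "average")
    h <- hclust(as.dist(d), method = "average")
    expect_equal(dg@merges$height, h$height, tolerance = 1e-12)
  }
})

test_that("height cuts sever merges at or above the threshold", {
  dg <- hierarchicalCluster(fixtureMatrix())
  expect_equal(unname(cutByHeight(dg, 2)), c(1, 1, 2), ignore_attr = TRUE)
  expect_equal(unname(cutByHeight(dg, 0)), 1:3, ignore_attr = TRUE)  # everything severed
  expect_equal(unname(cutByHeight(dg, 100)), c(1, 1, 1), ignore_attr = TRUE)
  # boundary: a merge exactly at the cut height does not survive
  expect_equal(unname(cutByHeight(dg, 4.5)), c(1, 1, 2), ignore_attr = TRUE)
})

test_that("k cuts undo the last merges and agree with height cuts", {
  dg <- hierarchicalCluster(fixtureMatrix())
  expect_equal(unname(cutByK(dg, 3)), 1:3, ignore_attr = TRUE)
  expect_equal(unname(cutByK(dg, 1)), c(1, 1, 1), ignore_attr = TRUE)
  expect_equal(cutByK(dg, 2), cutByHeight(dg, 2), ignore_attr = TRUE)
  expect_error(cutByK(dg, 0), class = "trackdist_invalid_input")
  expect_error(cutByK(dg, 4), class = "trackdist_invalid_input")

  set.seed(151)
  for (rep in 1:10) {
    n <- 7
    dg <- hierarchicalCluster(asDistanceMatrix(randomDistanceMatrix(n)))
    hts <- dg@merges$height
    for (k in 1:n) {
      mid <- if (k == n) hts[1] / 2
             else if (k == 1) hts[n - 1] + 1
             else (hts[n - k] + hts[n - k + 1]) / 2
      expect_equal(cutByK(dg, k), cutByHeight(dg, mid), ignore_attr = TRUE)
    }
  }
})

test_that("Newick export carries heights as branch lengths and round-trips", {
  skip_if_not_installed("ape")
  dg <- hierarchicalCluster(fixtureMatrix())
  nwk <- toNewick(dg)
  expect_equal(nwk, "((A:1,B:1):3.5,C:4.5);")
  tree <- ape::read.tree(text = nwk)
  expect_setequal(tree$tip.label, c("A", "B", "C"))
  # root-to-leaf path length equals the root merge height for every leaf
  depths <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  expect_equal(unname(depths), rep(4.5, 3))

  two <- hierarchicalCluster(asDistanceMatrix(
    matrix(c(0, 3, 3, 0), 2, dimnames = list(c("X", "Y"), c("X", "Y")))))
  expect_equal(toNewick(two), "(X:3,Y:3);")

  # names with Newick metacharacters get single-quoted and stay parseable
  sp <- asDistanceMatrix(matrix(c(0, 1, 1, 0), 2,
                                dimnames = list(c("a b", "c(d)"),
                                                c("a b", "c(d)"))))
  nwk <- toNewick(hierarchicalCluster(sp))
  expect_equal(nwk, "('a b':1,'c(d)':1);")
  expect_s3_class(ape::read.tree(text = nwk), "phylo")
})

test_that("leaf order follows construction order and permutes with input", {
  dg <- hierarchicalCluster(fixtureMatrix())
  expect_equal(leafOrder(dg), c("A", "B", "C"))

  set.seed(161)
  d <- randomDistanceMatrix(6)
  dg1 <- hierarchicalCluster(asDistanceMatrix(d))
  perm <- sample(6)
  dp <- d[perm, perm]
  dg2 <- hierarchicalCluster(asDistanceMatrix(dp))
  # same topology under row/column permutation with names
  expect_identical(mergeLeafSets(dg1), mergeLeafSets(dg2))
  expect_equal(sort(dg1@merges$height), sort(dg2@merges$height))
})

test_that("ties break deterministically", {
  nm <- paste0("t", 1:4)
  d <- matrix(1, 4, 4, dimnames = list(nm, nm)); diag(d) <- 0
  dg <- hierarchicalCluster(asDistanceMatrix(d))
  # identical distances: (0,1) merge first, then (2,3), then the pair roots
  expect_equal(dg@merges$left, c(0L, 2L, 4L))
  expect_equal(dg@merges$right, c(1L, 3L, 5L))
  expect_equal(leafOrder(dg), nm)
})

test_that("hclust conversion preserves heights and supports plotting math", {
  dg <- hierarchicalCluster(fixtureMatrix())
  h <- asHclust(dg)
  expect_s3_class(h, "hclust")
  expect_equal(h$height, c(1, 4.5))
  expect_equal(h$labels[h$order], leafOrder(dg))
  expect_equal(sort(stats::cutree(h, 2)), sort(c(A = 1L, B = 1L, C = 2L)))
})

test_that("swapping euclidean for manhattan preserves the group partition", {
  gen <- benchmarkData(seed = 42L)
  fm <- extractBinFeatures(gen$tracks, benchmarkGenome(), 100000L)
  parts <- lapply(c("euclidean", "manhattan"), function(metric)
    cutByK(hierarchicalCluster(distanceMatrixFeatures(fm, metric)), 3L))
  expect_equal(adjustedRandIndex(parts[[1]], parts[[2]]), 1)
  expect_equal(adjustedRandIndex(parts[[1]], gen$labels), 1)
})

test_that("invalid distance matrices are rejected", {
  bad <- matrix(c(0, 1, 2, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(new("TrackDistanceMatrix", values = bad, method = "x"),
               "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(new("TrackDistanceMatrix", values = neg, method = "x"),
               "non-negative")
})
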