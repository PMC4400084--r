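# Agglomerative hierarchical clustering from a precomputed distance matrix.
#
# Implemented with Lance-Williams updates: average linkage (UPGMA) keeps the
# inter-cluster distance equal to the size-weighted mean of all pairwise
# object distances between the two clusters; single/complete use min/max.
# Determinism is pinned down explicitly: among pairs at the minimal distance
# the pair with the lexicographically smallest (smaller id, larger id) is
# merged, and the two children of a merge are ordered by their smallest leaf
# index — so the same matrix always yields the same tree, bit for bit.

#' Agglomerative hierarchical clustering of tracks
#'
#' @param dm a [TrackDistanceMatrix-class] with n >= 2 tracks.
#' @param linkage "average" (UPGMA: size-weighted mean of all pairwise
#'   object distances, robust to outliers), "single" (nearest neighbour) or
#'   "complete" (farthest neighbour).
#' @return A [TrackDendrogram-class]. Leaf ids are 0..n-1 in the matrix's
#'   track order; merge i creates internal node n+i-1.
#' @examples
#' d <- matrix(c(0, 1, 4, 1, 0, 5, 4, 5, 0), 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' dg <- hierarchicalCluster(new("TrackDistanceMatrix", values = d,
#'                               method = "example"))
#' dg@merges$height  # 1.0, then (4 + 5) / 2 = 4.5
#' @export
hierarchicalCluster <- function(dm, linkage = c("average", "single",
                                                "complete")) {
  linkage <- match.arg(linkage)
  v <- distValues(dm)
  n <- nrow(v)
  if (n < 2L)
    .tdStop("trackdist_invalid_input", "need at least 2 tracks to cluster")
  nTotal <- 2L * n - 1L
  # distance between active clusters, indexed by node id + 1
  D <- matrix(NA_real_, nTotal, nTotal)
  D[1:n, 1:n] <- v
  active <- 0:(n - 1L)
  size <- c(rep(1L, n), rep(NA_integer_, n - 1L))
  minLeaf <- c(0:(n - 1L), rep(NA_integer_, n - 1L))
  merges <- data.frame(left = integer(n - 1L), right = integer(n - 1L),
                       height = numeric(n - 1L), size = integer(n - 1L))
  for (step in seq_len(n - 1L)) {
    # locate the minimal active pair; ties broken on (smaller id, larger id)
    best <- c(NA_integer_, NA_integer_); bestD <- Inf
    for (ii in seq_along(active)[-length(active)]) {
      i <- active[ii]
      for (j in active[(ii + 1L):length(active)]) {
        dij <- D[i + 1L, j + 1L]
        lo <- min(i, j); hi <- max(i, j)
        if (dij < bestD ||
            (dij == bestD && (lo < min(best) ||
                              (lo == min(best) && hi < max(best))))) {
          bestD <- dij; best <- c(lo, hi)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    newId <- n + step - 1L
    size[newId + 1L] <- size[i + 1L] + size[j + 1L]
    minLeaf[newId + 1L] <- min(minLeaf[i + 1L], minLeaf[j + 1L])
    ordered <- if (minLeaf[i + 1L] <= minLeaf[j + 1L]) c(i, j) else c(j, i)
    merges[step, ] <- list(ordered[1L], ordered[2L], bestD, size[newId + 1L])
    active <- setdiff(active, c(i, j))
    for (k in active) {
      dik <- D[i + 1L, k + 1L]; djk <- D[j + 1L, k + 1L]
      dNew <- switch(linkage,
        average = (size[i + 1L] * dik + size[j + 1L] * djk) /
                  (size[i + 1L] + size[j + 1L]),
        single = min(dik, djk),
        complete = max(dik, djk))
      D[newId + 1L, k + 1L] <- D[k + 1L, newId + 1L] <- dNew
    }
    active <- c(active, newId)
  }
  new("TrackDendrogram", leaves = rownames(v), merges = merges,
      method = distMethod(dm), linkage = linkage)
}

# children of each internal node, by id
.childMap <- function(dg) {
  n <- length(dg@leaves)
  m <- dg@merges
  lapply(seq_len(n - 1L), function(i) c(m$left[i], m$right[i]))
}

# leaf ids (0-based) under each node, left to right
.leavesUnder <- function(dg, node) {
  n <- length(dg@leaves)
  if (node < n) return(node)
  kids <- .childMap(dg)[[node - n + 1L]]
  c(.leavesUnder(dg, kids[1L]), .leavesUnder(dg, kids[2L]))
}

#' Left-to-right leaf ordering of a dendrogram
#'
#' The order in which leaves appear when the tree is drawn; used to sort
#' feature-matrix rows for heat-map output so similar tracks are adjacent.
#'
#' @param dg a [TrackDendrogram-class].
#' @return Character vector of track names.
#' @export
leafOrder <- function(dg) {
  n <- length(dg@leaves)
  dg@leaves[.leavesUnder(dg, 2L * n - 2L) + 1L]
}

.labelPartition <- function(dg, apply) {
  # apply: logical over merges, TRUE = merge survives
  n <- length(dg@leaves)
  parent <- 0:(2L * n - 2L)
  find <- function(x) { while (parent[x + 1L] != x) x <- parent[x + 1L]; x }
  for (i in which(apply)) {
    parent[dg@merges$left[i] + 1L] <- n + i - 1L
    parent[dg@merges$right[i] + 1L] <- n + i - 1L
  }
  roots <- vapply(0:(n - 1L), find, 0L)
  # number clusters 1..k by first appearance along the drawn leaf order
  ord <- .leavesUnder(dg, 2L * n - 2L)
  labelOf <- integer(0)
  nextLab <- 1L
  labels <- integer(n)
  for (leaf in ord) {
    r <- as.character(roots[leaf + 1L])
    if (is.null(labelOf[r]) || is.na(labelOf[r])) {
      labelOf[r] <- nextLab; nextLab <- nextLab + 1L
    }
    labels[leaf + 1L] <- labelOf[r]
  }
  names(labels) <- dg@leaves
  labels
}

#' Cut a dendrogram at a height
#'
#' Merges at height greater than or equal to the cut height are severed; the
#' resulting connected components are the subclusters. Labels are numbered
#' 1..k in leaf order.
#'
#' @param dg a [TrackDendrogram-class].
#' @param height cut height (>= 0). A cut at 0 gives all singletons; a cut
#'   above the root height gives one cluster.
#' @return Named integer vector of cluster labels, one per track (in input
#'   order), with attribute `cutHeight`.
#' @export
cutByHeight <- function(dg, height) {
  if (height < 0)
    .tdStop("trackdist_invalid_input", "cut height must be >= 0")
  labels <- .labelPartition(dg, dg@merges$height < height)
  attr(labels, "cutHeight") <- height
  labels
}

#' Cut a dendrogram into k subclusters
#'
#' Undoes the last k-1 merges; equivalent to [cutByHeight()] at any height
#' between the (n-k)th and (n-k+1)th merge heights.
#'
#' @param dg a [TrackDendrogram-class].
#' @param k number of clusters, 1 <= k <= n.
#' @return Named integer vector of cluster labels with attribute `k`.
#' @export
cutByK <- function(dg, k) {
  n <- length(dg@leaves)
  if (k < 1L || k > n)
    .tdStop("trackdist_invalid_input", sprintf("k must be in 1..%d", n))
  labels <- .labelPartition(dg, seq_len(n - 1L) <= n - k)
  attr(labels, "k") <- k
  labels
}

.escapeNewick <- function(x) {
  needs <- grepl("[][ \t(),:;']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Serialize a dendrogram as a Newick string
#'
#' Branch lengths are parent merge height minus child merge height (leaves
#' have height 0), so root-to-leaf path lengths equal the root merge height.
#' Names containing Newick metacharacters are single-quoted.
#'
#' @param dg a [TrackDendrogram-class].
#' @return A single Newick string terminated by ";".
#' @export
toNewick <- function(dg) {
  n <- length(dg@leaves)
  nodeHeight <- function(id) if (id < n) 0 else dg@merges$height[id - n + 1L]
  emit <- function(id, parentH) {
    bl <- sprintf("%.10g", parentH - nodeHeight(id))
    if (id < n)
      return(paste0(.escapeNewick(dg@leaves[id + 1L]), ":", bl))
    kids <- .childMap(dg)[[id - n + 1L]]
    h <- nodeHeight(id)
    paste0("(", emit(kids[1L], h), ",", emit(kids[2L], h), "):", bl)
  }
  root <- 2L * n - 2L
  h <- nodeHeight(root)
  kids <- .childMap(dg)[[root - n + 1L]]
  paste0("(", emit(kids[1L], h), ",", emit(kids[2L], h), ");")
}

#' Convert a TrackDendrogram to a stats::hclust object
#'
#' Enables base-R plotting (`plot()`) and interoperability with the wider
#' clustering ecosystem.
#'
#' @param dg a [TrackDendrogram-class].
#' @return An object of class `hclust`.
#' @export
asHclust <- function(dg) {
  n <- length(dg@leaves)
  toH <- function(id) if (id < n) -(id + 1L) else id - n + 1L
  merge <- cbind(vapply(dg@merges$left, toH, 0L),
                 vapply(dg@merges$right, toH, 0L))
  structure(list(merge = merge, height = dg@merges$height,
                 order = .leavesUnder(dg, 2L * n - 2L) + 1L,
                 labels = dg@leaves,
                 method = dg@linkage, dist.method = dg@method,
                 call = match.call()),
            class = "hclust")
}

#' Write a subcluster assignment as TSV
#'
#' Two columns, `track` and `cluster`, in track input order.
#'
#' @param labels result of [cutByHeight()] or [cutByK()].
#' @param path output file.
#' @export
writeSubclusters <- function(labels, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track\tcluster", con)
  writeLines(paste(names(labels), labels, sep = "\t"), con)
  invisible(path)
}
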