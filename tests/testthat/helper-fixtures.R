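# Shared fixture builders; everything is generated in code under fixed seeds.

# Random cloud of n points in a box, reproducible.
randomStructure <- function(n, seed = 1L, scale = 10) {
  set.seed(seed)
  Structure3D(matrix(stats::runif(3 * n, -scale, scale), ncol = 3))
}

# Random symmetric contact map with given pair density and integer counts.
randomContactMap <- function(n, density = 0.3, seed = 1L) {
  set.seed(seed)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pr)) < density
  pr <- pr[keep, , drop = FALSE]
  ContactMap(i = pr[, 1], j = pr[, 2],
             f = stats::rpois(nrow(pr), 4) + 1, nLoci = n)
}

# Random connected distance graph: a ring backbone plus random chords.
randomGraph <- function(n, extraEdges = 2L * n, seed = 1L) {
  set.seed(seed)
  i <- c(seq_len(n - 1L), sample.int(n, extraEdges, replace = TRUE))
  j <- c(seq_len(n - 1L) + 1L, sample.int(n, extraEdges, replace = TRUE))
  keep <- i != j
  edges <- data.frame(i = i[keep], j = j[keep],
                      d = stats::runif(sum(keep), 0.1, 2))
  buildDistanceGraph(edges, n)
}

# Exact-distance oracle for a structure: complete graph on true pairwise
# distances with every vertex a pivot, so queries return true distances.
exactOracle <- function(structure) {
  X <- coords(structure)
  n <- nrow(X)
  d <- as.matrix(stats::dist(X))
  ut <- which(upper.tri(d), arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2], d = d[ut])
  g <- buildDistanceGraph(edges, n)
  buildPivotOracle(g, seq_len(n))
}

# igraph reference shortest-path distances (independent oracle).
igraphDistances <- function(graph, sources = NULL) {
  n <- nLoci(graph)
  j <- rep.int(seq_len(n), diff(graph@ptr))
  i <- graph@nbr + 1L
  keep <- i < j
  ig <- igraph::graph_from_data_frame(
    data.frame(from = i[keep], to = j[keep]),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n))
  )
  igraph::E(ig)$weight <- graph@wt[keep]
  if (is.null(sources)) sources <- seq_len(n)
  igraph::distances(ig, v = as.character(sources), algorithm = "dijkstra")
}

expect_structuresEquivalent <- function(A, B, tol = 1e-6) {
  expect_lt(normalizedRMSD(A, B), tol)
}
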