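test_that("graph construction handles paths, components and self-loops", {
  g <- buildDistanceGraph(data.frame(i = c(1, 2), j = c(2, 3),
                                     d = c(0.5, 0.5)), n = 3)
  expect_equal(nLoci(g), 3L)
  expect_equal(shortestPathsFrom(g, 1), c(0, 0.5, 1))

  # disconnected: largest component kept, the rest reported
  g2 <- buildDistanceGraph(data.frame(i = 1, j = 2, d = 1), n = 4)
  expect_equal(nLoci(g2), 2L)
  expect_equal(sort(attr(g2, "dropped")), c(3L, 4L))
  expect_equal(loci(g2), c(1L, 2L))

  # self-loops dropped silently with a count
  g3 <- buildDistanceGraph(data.frame(i = c(1, 2, 2), j = c(2, 2, 3),
                                      d = c(1, 1, 1)), n = 3)
  expect_equal(attr(g3, "selfLoops"), 1L)
  expect_equal(length(g3@wt), 4L) # two undirected edges, both directions

  # adjacency symmetric: degree sums equal 2e on a random graph
  g4 <- randomGraph(200, seed = 5)
  deg <- diff(g4@ptr)
  expect_equal(sum(deg), length(g4@wt))
  ii <- rep.int(seq_len(nLoci(g4)), deg)
  jj <- g4@nbr + 1L
  key <- paste(pmin(ii, jj), pmax(ii, jj))
  expect_true(all(table(key) == 2L))

  expect_error(buildDistanceGraph(data.frame(i = 1, j = 2, d = -1), n = 2),
               "positive")
})

test_that("backbone edges connect consecutive loci with the median weight", {
  edges <- data.frame(i = c(1, 3), j = c(2, 4), d = c(1, 3))
  g <- buildDistanceGraph(edges, n = 4, backbone = TRUE)
  expect_equal(nLoci(g), 4L)
  d <- shortestPathsFrom(g, 1)
  expect_equal(d[3], 1 + 2) # backbone edge (2,3) with median weight 2
})

test_that("pivot selection is uniform, distinct, and seed-deterministic", {
  expect_setequal(selectPivots(5, 5, seed = 1), 1:5)
  expect_equal(selectPivots(1000, 1, seed = 9), selectPivots(1000, 1, seed = 9))
  a <- selectPivots(10000, 100, seed = 1)
  b <- selectPivots(10000, 100, seed = 2)
  expect_false(identical(sort(a), sort(b)))
  expect_equal(anyDuplicated(a), 0L)
  expect_error(selectPivots(10, 11), "count")
})

test_that("Dijkstra distances match hand cases and the igraph reference", {
  # triangle where the two-hop route beats the direct edge
  tri <- buildDistanceGraph(data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                                       d = c(5, 1, 1)), n = 3)
  expect_equal(shortestPathsFrom(tri, 1), c(0, 2, 1))

  skip_if_not_installed("igraph")
  g <- randomGraph(300, seed = 13)
  ref <- igraphDistances(g, sources = c(1, 57, 200))
  for (k in seq_along(c(1, 57, 200))) {
    src <- c(1, 57, 200)[k]
    expect_equal(shortestPathsFrom(g, src), unname(ref[k, ]),
                 tolerance = 1e-12)
  }
})

test_that("oracle queries are exact for pivots, zero on the diagonal, and upper bounds", {
  g <- randomGraph(100, seed = 3)
  piv <- selectPivots(100, 10, seed = 4)
  o <- buildPivotOracle(g, piv)

  # pivot rows are served exactly
  expect_equal(oracleDistance(o, piv[1], seq_len(100)),
               shortestPathsFrom(g, piv[1]), tolerance = 1e-12)
  expect_equal(oracleDistance(o, 5, 5), 0)
  expect_equal(oracleDistance(o, 7, 42), oracleDistance(o, 42, 7))

  # upper-bound property against exhaustive shortest paths, with equality
  # whenever a pivot lies on a shortest path
  pairs <- which(upper.tri(matrix(0, 100, 100)), arr.ind = TRUE)
  exact <- t(vapply(seq_len(100), function(s) shortestPathsFrom(g, s),
                    numeric(100)))
  q <- oracleDistance(o, pairs[, 1], pairs[, 2])
  ex <- exact[pairs]
  expect_true(all(q >= ex - 1e-9))

  # oracle distance matrix agrees with elementwise queries
  idx <- c(3, 20, 77, 50)
  sub <- oracleSubmatrix(o, idx)
  expect_equal(sub[2, 4], oracleDistance(o, 20, 50))
  expect_equal(diag(sub), rep(0, 4))
})

test_that("AR and EMR behave as bounded, pivot-monotone quality measures", {
  g <- randomGraph(120, seed = 8)
  piv <- selectPivots(120, 120, seed = 2)
  oAll <- buildPivotOracle(g, piv)

  # all pivots: approximation is exact
  expect_equal(approximationRatio(oAll, g), 1, tolerance = 1e-12)
  expect_equal(exactMatchingRate(oAll, g), 1)

  # nested subsets: AR and EMR never decrease as pivots are added
  counts <- c(5, 15, 40, 120)
  pairs <- .allPairs(120)
  exact <- .exactPairDistances(g, pairs)
  ar <- vapply(counts, function(l) {
    approximationRatio(oAll, g, pairs, nPivots = l, exact = exact)
  }, numeric(1))
  emr <- vapply(counts, function(l) {
    exactMatchingRate(oAll, g, pairs, nPivots = l, exact = exact)
  }, numeric(1))
  expect_true(all(diff(ar) >= -1e-12))
  expect_true(all(diff(emr) >= -1e-12))
  expect_true(all(ar > 0 & ar <= 1 + 1e-12))

  # star graph centred on the single pivot: every shortest path crosses it
  nStar <- 30
  star <- buildDistanceGraph(
    data.frame(i = rep(1, nStar - 1), j = 2:nStar,
               d = stats::runif(nStar - 1, 0.5, 2)), n = nStar)
  oStar <- buildPivotOracle(star, 1L)
  expect_equal(exactMatchingRate(oStar, star), 1)

  # single endpoint pivot on a 3-node path: AR computable by hand
  path3 <- buildDistanceGraph(data.frame(i = c(1, 2), j = c(2, 3),
                                         d = c(1, 1)), n = 3)
  oPath <- buildPivotOracle(path3, 1L)
  # pairs (1,2)=1, (1,3)=2 exact; (2,3) approximated via pivot 1: 1+2=3 vs 1
  expect_equal(approximationRatio(oPath, path3), (1 + 2 + 1) / (1 + 2 + 3))
})

test_that("oracle agrees with exhaustive shortest paths when every vertex is a pivot", {
  skip_if_not_installed("igraph")
  g <- randomGraph(150, seed = 31)
  o <- buildPivotOracle(g, seq_len(150))
  ref <- igraphDistances(g)
  pairs <- .allPairs(150)
  q <- oracleDistance(o, pairs[, 1], pairs[, 2])
  expect_equal(q, ref[pairs], tolerance = 1e-12)
})
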