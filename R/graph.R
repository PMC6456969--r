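## Contact graph construction and the pivot-based shortest-path oracle.

#' Build a distance graph from a weighted edge list
#'
#' Assembles the undirected contact graph (adjacency-list storage) from
#' power-law-converted distances. Self-loops are dropped. If the graph is
#' disconnected, only the largest connected component is retained and the
#' dropped loci are reported; alternatively, `backbone = TRUE` first inserts
#' an edge between consecutive loci of the same chain that lack one, with
#' weight equal to the median observed edge weight.
#'
#' @param edges data frame with columns `i`, `j` (1-based) and `d`
#'   (positive weights), as produced by [contactsToDistances()].
#' @param n number of loci.
#' @param backbone insert chain-backbone edges for missing consecutive pairs.
#' @param chainLabels optional chain label per locus (consecutive loci in
#'   different chains never get a backbone edge).
#' @return a [DistanceGraph-class] whose `loci` slot maps vertices back to
#'   input indices; `attr(, "dropped")` lists loci outside the largest
#'   component, `attr(, "selfLoops")` counts removed self-loops.
#' @export
buildDistanceGraph <- function(edges, n, backbone = FALSE,
                               chainLabels = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop("graph needs at least one vertex")
  i <- as.integer(edges$i); j <- as.integer(edges$j); w <- as.numeric(edges$d)
  if (any(w <= 0)) stop("edge weights must be strictly positive")
  self <- i == j
  nSelf <- sum(self)
  if (nSelf) {
    i <- i[!self]; j <- j[!self]; w <- w[!self]
  }
  if (backbone && n > 1L) {
    have <- rep(FALSE, n - 1L)
    consec <- abs(i - j) == 1L
    have[pmin(i, j)[consec]] <- TRUE
    need <- which(!have)
    if (!is.null(chainLabels)) {
      sameChain <- chainLabels[need] == chainLabels[need + 1L]
      need <- need[sameChain]
    }
    if (length(need)) {
      mw <- if (length(w)) stats::median(w) else 1
      i <- c(i, need); j <- c(j, need + 1L); w <- c(w, rep(mw, length(need)))
    }
  }
  m <- Matrix::sparseMatrix(i = pmin(i, j), j = pmax(i, j), x = w,
                            dims = c(n, n), symmetric = TRUE)
  g <- as(m, "generalMatrix") # CSC == CSR for a symmetric matrix
  comp <- cpp_components(g@p, g@i)
  sizes <- tabulate(comp + 1L)
  keepComp <- which.max(sizes) - 1L
  kept <- which(comp == keepComp)
  dropped <- which(comp != keepComp)
  if (length(dropped)) {
    m <- m[kept, kept, drop = FALSE]
    g <- as(as(Matrix::forceSymmetric(m, uplo = "U"), "CsparseMatrix"),
            "generalMatrix")
  }
  out <- new("DistanceGraph",
             ptr = g@p, nbr = g@i, wt = g@x,
             loci = as.integer(kept),
             chains = if (!is.null(chainLabels)) {
               as.character(chainLabels[kept])
             } else {
               character()
             })
  attr(out, "dropped") <- dropped
  attr(out, "selfLoops") <- nSelf
  out
}

#' Select random pivot loci
#'
#' Uniform sampling without replacement; deterministic under a fixed seed.
#' At least 10\% of the loci is the recommended pivot count for
#' reconstruction.
#'
#' @param n number of vertices.
#' @param count number of pivots, `1 <= count <= n`.
#' @param seed RNG seed.
#' @return integer vector of `count` distinct 1-based vertex ids.
#' @export
selectPivots <- function(n, count, seed = 1L) {
  n <- as.integer(n); count <- as.integer(count)
  if (count < 1L || count > n) stop("pivot count must be in [1, n]")
  .withSeed(seed, sample.int(n, count))
}

#' Single-source shortest-path distances
#'
#' Dijkstra distances from one vertex to all vertices of the graph
#' (`Inf` for unreachable vertices).
#'
#' @param graph a [DistanceGraph-class].
#' @param source 1-based source vertex.
#' @return numeric vector of length `nLoci(graph)`.
#' @export
shortestPathsFrom <- function(graph, source) {
  stopifnot(is(graph, "DistanceGraph"))
  source <- as.integer(source)
  n <- nLoci(graph)
  if (source < 1L || source > n) stop("source not in graph")
  cpp_sssp(graph@ptr, graph@nbr, graph@wt, source - 1L)
}

#' Build a pivot distance oracle
#'
#' Runs Dijkstra from each pivot and stores the `l x n` distance table; no
#' `n x n` structure is ever materialized, so memory stays `O(l n + e)`.
#'
#' @param graph a [DistanceGraph-class].
#' @param pivotIds 1-based vertex ids (e.g. from [selectPivots()]).
#' @return a [PivotOracle-class].
#' @export
buildPivotOracle <- function(graph, pivotIds) {
  stopifnot(is(graph, "DistanceGraph"))
  pivotIds <- as.integer(pivotIds)
  n <- nLoci(graph)
  if (!length(pivotIds) || any(pivotIds < 1L | pivotIds > n)) {
    stop("pivot ids must be in [1, n]")
  }
  tab <- .ssspTable(graph, pivotIds)
  new("PivotOracle", pivots = pivotIds, distTable = tab, loci = graph@loci)
}

#' Approximate pairwise shortest-path distance
#'
#' Returns the stored exact distance when `i` or `j` is a pivot, and
#' \eqn{\min_{p \in P} d_p(i) + d_p(j)} otherwise (the minimum naturally
#' reduces to the stored row when an endpoint is a pivot). The result is
#' always an upper bound on the true shortest-path distance, symmetric in
#' its arguments, and `0` for `i == j`.
#'
#' @param oracle a [PivotOracle-class].
#' @param i,j 1-based vertex ids (vectorized; recycled to common length).
#' @param nPivots optionally use only the first `nPivots` pivots (nested
#'   pivot subsets; useful for approximation-quality curves).
#' @return numeric vector of approximate distances.
#' @export
oracleDistance <- function(oracle, i, j, nPivots = NULL) {
  stopifnot(is(oracle, "PivotOracle"))
  l <- length(oracle@pivots)
  lUse <- if (is.null(nPivots)) l else as.integer(nPivots)
  if (lUse < 1L || lUse > l) stop("nPivots must be in [1, ", l, "]")
  n <- ncol(oracle@distTable)
  k <- max(length(i), length(j))
  i <- rep_len(as.integer(i), k); j <- rep_len(as.integer(j), k)
  if (any(i < 1L | i > n | j < 1L | j > n)) stop("vertex id out of range")
  cpp_query_pairs(oracle@distTable, i - 1L, j - 1L, lUse)
}

#' Approximate distance matrix for a vertex subset
#'
#' @param oracle a [PivotOracle-class].
#' @param idx 1-based vertex ids.
#' @param nPivots optional nested pivot count (see [oracleDistance()]).
#' @return symmetric `length(idx) x length(idx)` matrix with zero diagonal.
#' @export
oracleSubmatrix <- function(oracle, idx, nPivots = NULL) {
  stopifnot(is(oracle, "PivotOracle"))
  l <- length(oracle@pivots)
  lUse <- if (is.null(nPivots)) l else as.integer(nPivots)
  if (lUse < 1L || lUse > l) stop("nPivots must be in [1, ", l, "]")
  idx <- as.integer(idx)
  n <- ncol(oracle@distTable)
  if (any(idx < 1L | idx > n)) stop("vertex id out of range")
  cpp_query_submatrix(oracle@distTable, idx - 1L, lUse)
}

# Uniformly sample pairs as (source, target) with a limited number of
# distinct sources, so the exact side needs only `nSources` Dijkstra runs.
.samplePairs <- function(n, nPairs, nSources, seed) {
  .withSeed(seed, {
    nSources <- min(nSources, n)
    src <- sample.int(n, nSources)
    per <- ceiling(nPairs / nSources)
    i <- rep(src, each = per)
    j <- sample.int(n, length(i), replace = TRUE)
    keep <- i != j
    cbind(i = i[keep], j = j[keep])[seq_len(min(nPairs, sum(keep))), ,
                                    drop = FALSE]
  })
}

# Exact shortest-path distances for given pairs (one Dijkstra per distinct
# first-column vertex).
.exactPairDistances <- function(graph, pairs) {
  us <- sort(unique(pairs[, 1L]))
  tab <- .ssspTable(graph, us)
  tab[cbind(match(pairs[, 1L], us), pairs[, 2L])]
}

# Multi-source shortest-path table; uniform-weight graphs (e.g. from binary
# contact maps) take the BFS fast path: hop counts times the common weight.
.ssspTable <- function(graph, sources) {
  w <- graph@wt
  if (length(w) && all(w == w[1L])) {
    cpp_bfs_multi(graph@ptr, graph@nbr, sources - 1L) * w[1L]
  } else {
    cpp_sssp_multi(graph@ptr, graph@nbr, graph@wt, sources - 1L)
  }
}

.allPairs <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  cbind(i = ut[, 1L], j = ut[, 2L])
}

#' Approximation ratio of a pivot oracle
#'
#' The ratio between the summed exact all-pairs shortest-path distances and
#' the summed pivot-approximated distances, over all pairs (`pairs = NULL`;
#' intended for small graphs) or over a supplied pair sample. Because the
#' approximation is an upper bound, the ratio always lies in `(0, 1]`, and it
#' is non-decreasing in the number of pivots.
#'
#' @param oracle a [PivotOracle-class].
#' @param graph the [DistanceGraph-class] the oracle was built from.
#' @param pairs optional two-column matrix of 1-based vertex pairs.
#' @param nPivots optional nested pivot count.
#' @param exact optional precomputed exact distances for `pairs` (saves the
#'   Dijkstra runs when evaluating several pivot counts on the same sample).
#' @return scalar approximation ratio in `(0, 1]`.
#' @export
approximationRatio <- function(oracle, graph, pairs = NULL, nPivots = NULL,
                               exact = NULL) {
  if (is.null(pairs)) pairs <- .allPairs(nLoci(graph))
  if (is.null(exact)) exact <- .exactPairDistances(graph, pairs)
  approx <- oracleDistance(oracle, pairs[, 1L], pairs[, 2L], nPivots = nPivots)
  sum(exact) / sum(approx)
}

#' Exact matching rate of a pivot oracle
#'
#' Fraction of pairs whose approximated shortest-path distance equals the
#' exact one to relative tolerance `relTol` (default 1e-9; exact equality is
#' ill-posed in floating point).
#'
#' @inheritParams approximationRatio
#' @param relTol relative tolerance defining a match.
#' @return scalar in `[0, 1]`.
#' @export
exactMatchingRate <- function(oracle, graph, pairs = NULL, relTol = 1e-9,
                              nPivots = NULL, exact = NULL) {
  if (is.null(pairs)) pairs <- .allPairs(nLoci(graph))
  if (is.null(exact)) exact <- .exactPairDistances(graph, pairs)
  approx <- oracleDistance(oracle, pairs[, 1L], pairs[, 2L], nPivots = nPivots)
  mean(abs(approx - exact) <= relTol * pmax(exact, .Machine$double.xmin))
}

#' Sampled oracle-quality summary
#'
#' Convenience wrapper computing the approximation ratio and exact matching
#' rate on one uniformly sampled set of pairs (exact side via Dijkstra from
#' the sampled sources), optionally for several nested pivot counts at once.
#'
#' @param oracle a [PivotOracle-class].
#' @param graph the underlying [DistanceGraph-class].
#' @param nPairs number of sampled pairs (default 1e5).
#' @param nSources number of distinct exact-Dijkstra sources (default 100).
#' @param pivotCounts integer vector of nested pivot counts to evaluate
#'   (default: all pivots).
#' @param relTol matching tolerance for the exact matching rate.
#' @param seed RNG seed for the pair sample.
#' @return data frame with columns `nPivots`, `ar`, `emr`.
#' @export
oracleAccuracy <- function(oracle, graph, nPairs = 1e5, nSources = 100L,
                           pivotCounts = NULL, relTol = 1e-9, seed = 1L) {
  stopifnot(is(oracle, "PivotOracle"), is(graph, "DistanceGraph"))
  if (is.null(pivotCounts)) pivotCounts <- length(oracle@pivots)
  pairs <- .samplePairs(nLoci(graph), nPairs, nSources, seed)
  exact <- .exactPairDistances(graph, pairs)
  res <- lapply(pivotCounts, function(l) {
    data.frame(
      nPivots = l,
      ar = approximationRatio(oracle, graph, pairs, nPivots = l,
                              exact = exact),
      emr = exactMatchingRate(oracle, graph, pairs, relTol = relTol,
                              nPivots = l, exact = exact)
    )
  })
  do.call(rbind, res)
}
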