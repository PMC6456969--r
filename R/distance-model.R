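## Power-law frequency-to-distance conversion and exponent estimation.

#' Convert contact frequencies to distances
#'
#' Applies the power-law model \eqn{d_{ij} = 1 / f_{ij}^{\alpha}} to every
#' stored (positive-frequency) contact. Pairs without an observed contact get
#' no edge at all — their distances are later recovered as shortest paths in
#' the contact graph, which avoids having to pick an arbitrary cap for the
#' otherwise infinite converted distance. The case `alpha = 1` is the
#' classical inverse-frequency conversion.
#'
#' @param map a [ContactMap-class].
#' @param alpha positive power-law exponent.
#' @return a data frame with columns `i`, `j` (1-based, `i < j`) and `d`
#'   (strictly positive finite distances); self-contacts are omitted.
#' @seealso [buildDistanceGraph()], [estimateAlpha()]
#' @export
contactsToDistances <- function(map, alpha) {
  stopifnot(is(map, "ContactMap"), alpha > 0)
  tr <- .mapTriplets(map)
  off <- tr$i != tr$j
  d <- tr$f[off]^(-alpha)
  if (any(!is.finite(d))) stop("non-finite converted distance")
  data.frame(i = tr$i[off], j = tr$j[off], d = d)
}

#' Goodness of fit of a structure to a contact map
#'
#' For a candidate exponent `alpha` and structure `X`, back-converts the
#' structure's pairwise distances to predicted frequencies
#' \eqn{f'_{ij} = 1 / d(X)_{ij}^{1/\alpha}} and returns
#' \eqn{\sum_{f_{ij} > 0} (f'_{ij} - f_{ij})^2}, summed only over observed
#' contacts.
#'
#' @param map a [ContactMap-class].
#' @param structure a [Structure3D-class] with `nLoci(map)` points.
#' @param alpha positive exponent.
#' @return non-negative scalar; 0 iff the structure's distances exactly
#'   invert the power law on all observed pairs.
#' @export
goodnessOfFit <- function(map, structure, alpha) {
  stopifnot(is(map, "ContactMap"), is(structure, "Structure3D"), alpha > 0)
  if (nLoci(structure) != nLoci(map)) {
    stop("structure has ", nLoci(structure), " loci but map has ", nLoci(map))
  }
  tr <- .mapTriplets(map)
  off <- tr$i != tr$j
  i <- tr$i[off]; j <- tr$j[off]; f <- tr$f[off]
  if (!length(f)) return(0)
  d <- .pairDistances(structure@coords, i, j)
  zero <- which(d == 0)
  if (length(zero)) {
    stop(sprintf("coincident loci (%d, %d) have zero distance",
                 i[zero[1L]], j[zero[1L]]))
  }
  fhat <- d^(-1 / alpha)
  sum((fhat - f)^2)
}

# Coarse grid scan followed by golden-section refinement in the best
# bracket. The goodness landscape can be locally jagged (embedding
# degeneracies at extreme exponents produce spikes), so a pure
# golden-section from the full interval can lock onto the wrong basin; the
# grid stage restores robustness at a constant number of extra evaluations.
.gridGolden <- function(f, lo, hi, tol, gridPoints = 15L) {
  if (hi - lo <= tol) {
    x <- (lo + hi) / 2
    return(list(x = x, value = f(x), evals = 1L))
  }
  xs <- seq(lo, hi, length.out = gridPoints)
  vals <- vapply(xs, f, numeric(1))
  k <- which.min(vals)
  inner <- .goldenSection(f, xs[max(1L, k - 1L)],
                          xs[min(gridPoints, k + 1L)], tol)
  if (vals[k] < inner$value) {
    inner$x <- xs[k]
    inner$value <- vals[k]
  }
  inner$evals <- inner$evals + gridPoints
  inner
}

# Golden-section search for the minimum of a unimodal function on [lo, hi].
# Returns list(x, value, evals); bracket shrinks by (sqrt(5)-1)/2 per step.
.goldenSection <- function(f, lo, hi, tol) {
  if (hi < lo) stop("invalid bracket")
  if (hi - lo <= tol) {
    x <- (lo + hi) / 2
    return(list(x = x, value = f(x), evals = 1L))
  }
  ratio <- (sqrt(5) - 1) / 2
  x1 <- hi - ratio * (hi - lo)
  x2 <- lo + ratio * (hi - lo)
  f1 <- f(x1)
  f2 <- f(x2)
  evals <- 2L
  while (hi - lo > tol) {
    if (f1 <= f2) {
      hi <- x2
      x2 <- x1; f2 <- f1
      x1 <- hi - ratio * (hi - lo)
      f1 <- f(x1)
    } else {
      lo <- x1
      x1 <- x2; f1 <- f2
      x2 <- lo + ratio * (hi - lo)
      f2 <- f(x2)
    }
    evals <- evals + 1L
  }
  if (f1 <= f2) {
    list(x = x1, value = f1, evals = evals)
  } else {
    list(x = x2, value = f2, evals = evals)
  }
}

# Cheap reconstruction callback used by estimateAlpha: classical MDS on the
# shortest-path distances of the induced subgraph of a fixed locus
# subsample. Every subsample locus serves as a pivot (exact shortest paths):
# at m <= 500 this costs little and removes the systematic upward bias that
# pivot-approximated (inflated) distances otherwise impose on the exponent.
.alphaProbeRecon <- function(map, subsample, pivotFrac = 1) {
  subMap <- .induceMap(map, subsample)
  m <- length(subsample)
  function(alpha) {
    edges <- contactsToDistances(subMap, alpha)
    g <- buildDistanceGraph(edges, n = m)
    kept <- g@loci
    piv <- seq_len(max(1L, ceiling(pivotFrac * length(kept))))
    oracle <- buildPivotOracle(g, piv)
    D <- oracleSubmatrix(oracle, seq_along(kept))
    X <- classicalMDS(D, dim = 3L)
    Structure3D(X, loci = kept)
  }
}

# Induced sub-map on a locus subset (1-based indices of map).
.induceMap <- function(map, idx) {
  m <- map@contacts[idx, idx, drop = FALSE]
  m <- as(Matrix::forceSymmetric(m, uplo = "U"), "CsparseMatrix")
  new("ContactMap", contacts = m, resolution = map@resolution)
}

#' Estimate the power-law exponent by golden-section search
#'
#' Minimizes the goodness-of-fit function over `alpha` in `bounds`
#' (default `[0.1, 3]`, the range covering exponents reported across Hi-C
#' studies) by a coarse grid scan followed by golden-section refinement in
#' the best grid bracket (the grid stage guards against locally jagged
#' goodness landscapes). Each probe reconstructs a structure for
#' the candidate `alpha` via the `recon` callback and scores it with
#' [goodnessOfFit()]. The default callback embeds a fixed uniformly sampled
#' subset of at most `subsampleSize` loci: the induced sub-map is converted,
#' its contact graph's pivot-oracle shortest-path distances are embedded by
#' classical MDS, and the fit is evaluated on the sub-map. The subsample is
#' drawn once so all probes score the same objective.
#'
#' @param map a [ContactMap-class].
#' @param bounds numeric length-2 search interval inside `[0.1, 3]`.
#' @param tol bracket width at which the search stops (default 0.01).
#' @param recon optional callback `function(alpha) -> Structure3D` over the
#'   loci of `subsampleMap` (advanced use; the default is recommended).
#' @param subsampleSize subsample cap for the default callback (default 500).
#' @param seed seed for the subsample draw.
#' @return the estimated `alpha`, with attributes `value` (objective at the
#'   optimum) and `evals` (number of objective evaluations).
#' @export
estimateAlpha <- function(map, bounds = c(0.1, 3), tol = 0.01, recon = NULL,
                          subsampleSize = 500L, seed = 1L) {
  stopifnot(is(map, "ContactMap"), length(bounds) == 2L, tol > 0)
  lo <- bounds[1L]; hi <- bounds[2L]
  if (lo > hi) stop("invalid alpha bounds")
  if (hi == lo) {
    out <- lo
    attr(out, "evals") <- 0L
    return(out)
  }
  n <- nLoci(map)
  if (is.null(recon)) {
    subsample <- .withSeed(seed, sort(sample.int(n, min(n, subsampleSize))))
    scoreMap <- .induceMap(map, subsample)
    recon <- .alphaProbeRecon(map, subsample)
  } else {
    scoreMap <- map
  }
  objective <- function(alpha) {
    s <- tryCatch(recon(alpha), error = function(e) {
      stop("reconstruction failed at alpha = ", signif(alpha, 4), ": ",
           conditionMessage(e))
    })
    sm <- scoreMap
    if (nLoci(s) != nLoci(sm)) {
      # callback embedded only the graph's retained loci
      sm <- .induceMap(sm, s@loci)
      s <- Structure3D(s@coords)
    }
    # a probe whose embedding collapses observed pairs is an arbitrarily bad
    # fit, not a search-stopping failure (typical near the alpha = 0.1 edge,
    # where all converted distances approach 1)
    tryCatch(goodnessOfFit(sm, s, alpha),
             error = function(e) {
               if (grepl("coincident", conditionMessage(e))) {
                 return(.Machine$double.xmax)
               }
               stop(e)
             })
  }
  res <- .gridGolden(objective, lo, hi, tol)
  out <- res$x
  attr(out, "value") <- res$value
  attr(out, "evals") <- res$evals
  out
}
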