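#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib chromrec, .registration = TRUE
NULL

#' ContactMap: a symmetric sparse map of contact frequencies
#'
#' Stores normalized Hi-C contact frequencies \eqn{f_{ij}} between `n` genomic
#' loci as a symmetric sparse matrix (only the upper triangle is kept in
#' memory, via [Matrix::dsCMatrix-class]). Entries with zero frequency are not
#' stored. Locus indices are 1-based in the R API; on-disk interchange formats
#' use 0-based bin indices (see [readContacts()]).
#'
#' @slot contacts a symmetric sparse [Matrix::dsCMatrix-class] of non-negative
#'   frequencies.
#' @slot resolution bin size in base pairs (`NA` when unknown/abstract loci).
#' @slot chains optional character vector of chain (chromosome) labels, one
#'   per locus, or length zero.
#'
#' @seealso [readContacts()], [balanceContacts()], [contactsToDistances()]
#' @export
setClass("ContactMap",
  representation(
    contacts = "dsCMatrix",
    resolution = "integer",
    chains = "character"
  ),
  prototype(resolution = NA_integer_, chains = character())
)

setValidity("ContactMap", function(object) {
  m <- object@contacts
  msg <- character()
  if (nrow(m) != ncol(m)) msg <- c(msg, "contact matrix must be square")
  if (length(m@x) && any(!is.finite(m@x))) {
    msg <- c(msg, "contact frequencies must be finite")
  }
  if (length(m@x) && any(m@x < 0)) {
    msg <- c(msg, "contact frequencies must be non-negative")
  }
  if (length(object@chains) && length(object@chains) != nrow(m)) {
    msg <- c(msg, "chains must have one label per locus")
  }
  if (length(msg)) msg else TRUE
})

#' Structure3D: a reconstructed or simulated 3D chromatin structure
#'
#' The 3D positions of `n` loci (one point per genomic bin, taken as the bin
#' centroid), with the original locus indices and optional chain labels.
#'
#' @slot coords numeric `n x 3` matrix of coordinates.
#' @slot loci integer vector of 1-based original locus indices (bookkeeping
#'   for loci dropped during balancing or component filtering).
#' @slot chains optional chain labels (length `n` or zero).
#' @slot metadata list of run information (pipeline reports and the like).
#'
#' @export
setClass("Structure3D",
  representation(
    coords = "matrix",
    loci = "integer",
    chains = "character",
    metadata = "list"
  ),
  prototype(chains = character(), metadata = list())
)

setValidity("Structure3D", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must have 3 columns")
  if (nrow(object@coords) < 1L) msg <- c(msg, "structure needs at least one locus")
  if (!all(is.finite(object@coords))) msg <- c(msg, "coordinates must be finite")
  if (length(object@loci) != nrow(object@coords)) {
    msg <- c(msg, "loci must have one index per point")
  }
  if (anyDuplicated(object@loci)) msg <- c(msg, "duplicate locus indices")
  if (length(object@chains) && length(object@chains) != nrow(object@coords)) {
    msg <- c(msg, "chains must have one label per locus")
  }
  if (length(msg)) msg else TRUE
})

#' DistanceGraph: weighted contact graph in adjacency-list (CSR) form
#'
#' An undirected graph whose vertices are loci and whose edge weights are
#' power-law-converted distances. Stored as compressed sparse rows so that
#' single-source shortest paths run without ever materializing an `n x n`
#' matrix.
#'
#' @slot ptr integer vector of `n + 1` 0-based row offsets.
#' @slot nbr integer vector of 0-based neighbour ids (each undirected edge
#'   appears in both adjacency lists).
#' @slot wt numeric vector of positive edge weights, parallel to `nbr`.
#' @slot loci 1-based original locus indices of the graph's vertices (the
#'   graph is restricted to the largest connected component).
#' @slot chains optional chain labels per vertex.
#'
#' @seealso [buildDistanceGraph()], [shortestPathsFrom()]
#' @export
setClass("DistanceGraph",
  representation(
    ptr = "integer",
    nbr = "integer",
    wt = "numeric",
    loci = "integer",
    chains = "character"
  ),
  prototype(chains = character())
)

setValidity("DistanceGraph", function(object) {
  msg <- character()
  n <- length(object@ptr) - 1L
  if (n < 1L) msg <- c(msg, "graph must have at least one vertex")
  if (length(object@nbr) != length(object@wt)) {
    msg <- c(msg, "nbr and wt must be parallel")
  }
  if (length(object@wt) && any(object@wt <= 0)) {
    msg <- c(msg, "edge weights must be strictly positive")
  }
  if (length(object@loci) != n) msg <- c(msg, "loci must have one id per vertex")
  if (length(msg)) msg else TRUE
})

#' PivotOracle: approximate all-pairs shortest-path distances from pivots
#'
#' Stores shortest-path distances from `l` pivot loci to all `n` vertices
#' (an `l x n` table); any pairwise distance is answered on the fly as
#' \eqn{\min_{p} d_p(i) + d_p(j)}, an upper bound on the true shortest-path
#' distance that is exact whenever some pivot lies on a shortest `i`-`j` path
#' (in particular when `i` or `j` is itself a pivot). Space is
#' `O(l n + e)` instead of `O(n^2)`.
#'
#' @slot pivots integer vector of 1-based vertex ids (distinct).
#' @slot distTable numeric `l x n` matrix, row `p` = distances from pivot `p`.
#' @slot loci original locus indices of the vertices (same as the graph's).
#'
#' @seealso [buildPivotOracle()], [oracleDistance()]
#' @export
setClass("PivotOracle",
  representation(
    pivots = "integer",
    distTable = "matrix",
    loci = "integer"
  )
)

setValidity("PivotOracle", function(object) {
  msg <- character()
  l <- length(object@pivots)
  if (l < 1L) msg <- c(msg, "need at least one pivot")
  if (anyDuplicated(object@pivots)) msg <- c(msg, "pivots must be distinct")
  if (nrow(object@distTable) != l) {
    msg <- c(msg, "distTable must have one row per pivot")
  }
  if (length(object@loci) != ncol(object@distTable)) {
    msg <- c(msg, "loci must have one id per vertex")
  }
  d0 <- object@distTable[cbind(seq_len(l), object@pivots)]
  if (any(d0 != 0)) msg <- c(msg, "pivot self-distance must be zero")
  if (length(msg)) msg else TRUE
})

#' ReconstructionConfig: tunable parameters of the reconstruction pipeline
#'
#' @slot pivotFrac fraction of loci used as shortest-path pivots (default 0.1;
#'   at least 10\% is recommended).
#' @slot pivotMin pivot-count floor (default 50, capped at `n`): small maps
#'   get a near-exact oracle, where a bare 10\% would leave approximation
#'   error dominating the reconstruction.
#' @slot subsetSize number of loci per overlapping subset in the progressive
#'   (iMDS) assembly (default 500).
#' @slot overlap number of anchor loci shared by consecutive subsets (default
#'   50; must be at least 4 non-coplanar points to pin down a rigid motion).
#' @slot weightScheme weighted-MDS weights: `"inv_sq"` (\eqn{w = \hat d^{-2}},
#'   default), `"inv"`, or `"unit"`.
#' @slot smdsBlockSize block size for the scalable weighted-MDS polish
#'   (default 500).
#' @slot smdsMaxRounds maximum polish rounds (default 200).
#' @slot smdsTol polish convergence: mean per-locus displacement per round
#'   below `smdsTol` times the radius of gyration (default 1e-4).
#' @slot smdsMaxIter SMACOF iteration cap per polish block (default 100).
#' @slot alpha fixed power-law exponent, or `NA` to estimate it by
#'   golden-section search (default `NA`).
#' @slot alphaTol bracket width for the golden-section search (default 0.01).
#' @slot balance run matrix balancing before conversion (default `FALSE`).
#'   Balancing removes per-locus coverage bias and is recommended for
#'   measured Hi-C maps; for simulated (bias-free) maps the per-locus
#'   coverage variation is genuine geometric signal, and balancing it away
#'   degrades the reconstruction.
#' @slot balanceTol,balanceMaxIter matrix-balancing controls.
#' @slot backbone add backbone edges between consecutive loci missing a
#'   contact (default `FALSE`).
#' @slot seed integer seed controlling pivot selection, subset permutations
#'   and block permutations.
#'
#' @seealso [reconstructionConfig()], [reconstructStructure()]
#' @export
setClass("ReconstructionConfig",
  representation(
    pivotFrac = "numeric",
    pivotMin = "integer",
    subsetSize = "integer",
    overlap = "integer",
    weightScheme = "character",
    smdsBlockSize = "integer",
    smdsMaxRounds = "integer",
    smdsTol = "numeric",
    smdsMaxIter = "integer",
    alpha = "numeric",
    alphaTol = "numeric",
    balance = "logical",
    balanceTol = "numeric",
    balanceMaxIter = "integer",
    backbone = "logical",
    seed = "integer"
  ),
  prototype(
    pivotFrac = 0.1,
    pivotMin = 50L,
    subsetSize = 500L,
    overlap = 50L,
    weightScheme = "inv_sq",
    smdsBlockSize = 500L,
    smdsMaxRounds = 200L,
    smdsTol = 1e-4,
    smdsMaxIter = 100L,
    alpha = NA_real_,
    alphaTol = 0.01,
    balance = FALSE,
    balanceTol = 1e-5,
    balanceMaxIter = 1000L,
    backbone = FALSE,
    seed = 1L
  )
)

setValidity("ReconstructionConfig", function(object) {
  msg <- character()
  if (object@pivotFrac <= 0 || object@pivotFrac > 1) {
    msg <- c(msg, "pivotFrac must be in (0, 1]")
  }
  if (object@overlap < 4L) msg <- c(msg, "overlap must be at least 4")
  if (object@overlap >= object@subsetSize) {
    msg <- c(msg, "overlap must be smaller than subsetSize")
  }
  if (!object@weightScheme %in% c("inv_sq", "inv", "unit")) {
    msg <- c(msg, "weightScheme must be one of inv_sq, inv, unit")
  }
  if (!is.na(object@alpha) && (object@alpha < 0.1 || object@alpha > 3)) {
    msg <- c(msg, "alpha must lie in [0.1, 3]")
  }
  if (length(msg)) msg else TRUE
})

#' RigidTransform: an optimal rigid (possibly improper) superposition
#'
#' Result of [superpose()]: the orthogonal matrix `R` and translation `T`
#' minimizing the RMSD of `R p_i + T` against the target points. When
#' reflection is allowed and improves the fit, `R` is improper
#' (`det(R) = -1`) and `reflected` is `TRUE`.
#'
#' @slot rotation 3 x 3 orthogonal matrix.
#' @slot translation length-3 numeric vector.
#' @slot reflected logical; `TRUE` when the improper (mirror) solution was
#'   chosen.
#' @slot rmsd the minimized root-mean-square deviation.
#' @slot degenerate logical; `TRUE` when the point set was (near-)coplanar so
#'   the rotation is not unique (the returned transform is still a minimizer).
#'
#' @export
setClass("RigidTransform",
  representation(
    rotation = "matrix",
    translation = "numeric",
    reflected = "logical",
    rmsd = "numeric",
    degenerate = "logical"
  ),
  prototype(reflected = FALSE, degenerate = FALSE)
)

setValidity("RigidTransform", function(object) {
  msg <- character()
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) msg <- c(msg, "rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9) {
    msg <- c(msg, "rotation must be orthogonal")
  }
  dr <- det(R)
  if (!object@reflected && dr < 0) {
    msg <- c(msg, "det(R) must be +1 unless reflected")
  }
  if (length(object@translation) != 3L) {
    msg <- c(msg, "translation must have length 3")
  }
  if (length(msg)) msg else TRUE
})
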