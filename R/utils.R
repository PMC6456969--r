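## Internal helpers shared across modules.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a base seed (kept below 2^31).
.childSeed <- function(seed, stream) {
  (as.numeric(seed) * 48271 + stream) %% 2147483647
}

# Upper-triangle (i <= j) triplet view of a ContactMap's sparse matrix.
.mapTriplets <- function(map) {
  m <- map@contacts
  p <- m@p
  j <- rep.int(seq_len(ncol(m)), diff(p))
  list(i = m@i + 1L, j = j, f = m@x)
}

# Build a ContactMap from 1-based upper-triangle triplets.
.newContactMap <- function(i, j, f, n, resolution = NA_integer_,
                           chains = character()) {
  stopifnot(all(i >= 1L), all(j >= 1L), all(i <= n), all(j <= n))
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  keep <- f > 0
  m <- Matrix::sparseMatrix(
    i = i[keep], j = j[keep], x = f[keep],
    dims = c(n, n), symmetric = TRUE
  )
  new("ContactMap", contacts = as(m, "CsparseMatrix"),
      resolution = as.integer(resolution), chains = as.character(chains))
}

# Pairwise Euclidean distances for given index pairs of a coordinate matrix.
.pairDistances <- function(X, i, j) {
  d <- X[i, , drop = FALSE] - X[j, , drop = FALSE]
  sqrt(rowSums(d * d))
}

#' Construct a ContactMap from triplets
#'
#' @param i,j 1-based locus indices (either triangle; symmetrized internally).
#' @param f non-negative contact frequencies; zeros are not stored.
#' @param nLoci total number of loci.
#' @param resolution optional bin size in bp.
#' @param chains optional chain labels (length `nLoci`).
#' @return a [ContactMap-class].
#' @examples
#' ContactMap(i = c(1, 2), j = c(2, 3), f = c(4, 2), nLoci = 3)
#' @export
ContactMap <- function(i, j, f, nLoci, resolution = NA_integer_,
                       chains = character()) {
  if (any(f < 0)) stop("negative contact frequency")
  .newContactMap(as.integer(i), as.integer(j), as.numeric(f),
                 as.integer(nLoci), resolution, chains)
}

#' Construct a Structure3D
#'
#' @param coords numeric `n x 3` matrix (or coercible data frame).
#' @param loci 1-based original locus indices (default `1:n`).
#' @param chains optional chain labels.
#' @param metadata optional list of run information.
#' @return a [Structure3D-class].
#' @examples
#' Structure3D(matrix(rnorm(30), ncol = 3))
#' @export
Structure3D <- function(coords, loci = seq_len(nrow(coords)),
                        chains = character(), metadata = list()) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  dimnames(coords) <- NULL
  new("Structure3D", coords = coords, loci = as.integer(loci),
      chains = as.character(chains), metadata = metadata)
}

#' Construct a ReconstructionConfig
#'
#' All arguments default to the values documented for
#' [ReconstructionConfig-class]; pass only the ones to override.
#'
#' @param ... named slot values (e.g. `pivotFrac = 0.2`, `alpha = 1`,
#'   `seed = 7`).
#' @return a [ReconstructionConfig-class].
#' @examples
#' reconstructionConfig(alpha = 1, seed = 11)
#' @export
reconstructionConfig <- function(...) {
  args <- list(...)
  proto <- new("ReconstructionConfig")
  for (nm in names(args)) {
    if (!nm %in% slotNames(proto)) stop("unknown config field: ", nm)
    value <- args[[nm]]
    if (is(slot(proto, nm), "integer")) value <- as.integer(value)
    slot(proto, nm) <- value
  }
  validObject(proto)
  proto
}

#' Radius of gyration of a structure
#'
#' Root-mean-square distance of loci from their centroid; the natural length
#' scale of a structure.
#'
#' @param x a [Structure3D-class] or an `n x 3` coordinate matrix.
#' @return non-negative scalar.
#' @export
radiusOfGyration <- function(x) {
  X <- if (is(x, "Structure3D")) x@coords else as.matrix(x)
  Xc <- sweep(X, 2L, colMeans(X))
  sqrt(mean(rowSums(Xc * Xc)))
}
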