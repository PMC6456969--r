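#' Number of loci
#'
#' @param x a [ContactMap-class], [Structure3D-class], [DistanceGraph-class]
#'   or [PivotOracle-class].
#' @return integer count of loci (vertices).
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))

#' Coordinates of a 3D structure
#'
#' @param x a [Structure3D-class].
#' @return numeric `n x 3` matrix.
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' Chain (chromosome) labels
#'
#' @param x an object carrying per-locus chain labels.
#' @return character vector (length `n`, or zero when unset).
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' Original locus indices
#'
#' @param x an object tracking original (pre-filtering) locus indices.
#' @return 1-based integer vector.
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname nLoci
#' @export
setMethod("nLoci", "ContactMap", function(x) nrow(x@contacts))

#' @rdname nLoci
#' @export
setMethod("nLoci", "Structure3D", function(x) nrow(x@coords))

#' @rdname nLoci
#' @export
setMethod("nLoci", "DistanceGraph", function(x) length(x@ptr) - 1L)

#' @rdname nLoci
#' @export
setMethod("nLoci", "PivotOracle", function(x) ncol(x@distTable))

#' @rdname coords
#' @export
setMethod("coords", "Structure3D", function(x) x@coords)

#' @rdname chains
#' @export
setMethod("chains", "ContactMap", function(x) x@chains)

#' @rdname chains
#' @export
setMethod("chains", "Structure3D", function(x) x@chains)

#' @rdname loci
#' @export
setMethod("loci", "Structure3D", function(x) x@loci)

#' @rdname loci
#' @export
setMethod("loci", "DistanceGraph", function(x) x@loci)

#' Contact matrix of a ContactMap
#'
#' @param x a [ContactMap-class].
#' @return the symmetric sparse [Matrix::dsCMatrix-class] of frequencies.
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))

#' @rdname contactMatrix
#' @export
setMethod("contactMatrix", "ContactMap", function(x) x@contacts)

#' Pivot vertex ids of a PivotOracle
#'
#' @param x a [PivotOracle-class].
#' @return 1-based integer vertex ids, in selection order.
#' @export
setGeneric("pivots", function(x) standardGeneric("pivots"))

#' @rdname pivots
#' @export
setMethod("pivots", "PivotOracle", function(x) x@pivots)

setMethod("show", "ContactMap", function(object) {
  m <- object@contacts
  nz <- length(m@x)
  n <- nrow(m)
  cov <- if (n > 1) nz / (n * (n - 1) / 2) else 0
  cat("ContactMap with", n, "loci,", nz, "stored contacts",
      sprintf("(%.1f%% coverage)\n", 100 * cov))
  if (!is.na(object@resolution)) {
    cat("  resolution:", object@resolution, "bp\n")
  }
  if (length(object@chains)) {
    cat("  chains:", length(unique(object@chains)), "\n")
  }
})

setMethod("show", "Structure3D", function(object) {
  cat("Structure3D with", nrow(object@coords), "loci\n")
  rg <- sqrt(mean(rowSums(scale(object@coords, scale = FALSE)^2)))
  cat(sprintf("  radius of gyration: %.4g\n", rg))
  if (length(object@chains)) {
    cat("  chains:", length(unique(object@chains)), "\n")
  }
  if (length(object@metadata)) {
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  }
})

setMethod("show", "DistanceGraph", function(object) {
  n <- length(object@ptr) - 1L
  cat("DistanceGraph with", n, "vertices and", length(object@nbr) %/% 2L,
      "undirected edges\n")
})

setMethod("show", "PivotOracle", function(object) {
  cat("PivotOracle:", length(object@pivots), "pivots x",
      ncol(object@distTable), "vertices\n")
})

setMethod("show", "ReconstructionConfig", function(object) {
  cat("ReconstructionConfig\n")
  cat("  pivotFrac:", object@pivotFrac,
      " subsetSize:", object@subsetSize,
      " overlap:", object@overlap, "\n")
  cat("  weightScheme:", object@weightScheme,
      " smdsBlockSize:", object@smdsBlockSize,
      " smdsMaxRounds:", object@smdsMaxRounds, "\n")
  cat("  alpha:", if (is.na(object@alpha)) "estimate" else object@alpha,
      " seed:", object@seed, "\n")
})

setMethod("show", "RigidTransform", function(object) {
  cat(sprintf("RigidTransform: rmsd = %.6g, reflected = %s%s\n",
              object@rmsd, object@reflected,
              if (object@degenerate) " (degenerate)" else ""))
})
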