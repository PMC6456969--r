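## Accuracy metrics between structures: distance-space correlations and a
## scale-free superposition RMSD.

#' Correlation between pairwise distances of two structures
#'
#' Pearson or Spearman correlation of the upper-triangle pairwise-distance
#' vectors of two structures with positional row correspondence. Both
#' metrics are invariant to rigid motion, reflection, and uniform scaling of
#' either structure. For large `n` (more than 2e6 pairs) or when `sample` is
#' given, the correlation is computed on a seeded uniform sample of pairs.
#'
#' @param A,B [Structure3D-class] objects (or coordinate matrices) with the
#'   same number of loci.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param sample optional number of sampled pairs; default: exhaustive below
#'   2e6 pairs, 1e6 sampled pairs above.
#' @param seed RNG seed for the pair sample.
#' @return correlation in `[-1, 1]`.
#' @export
distanceCorrelation <- function(A, B, method = c("pearson", "spearman"),
                                sample = NULL, seed = 1L) {
  method <- match.arg(method)
  XA <- if (is(A, "Structure3D")) A@coords else as.matrix(A)
  XB <- if (is(B, "Structure3D")) B@coords else as.matrix(B)
  n <- nrow(XA)
  if (nrow(XB) != n) stop("structures must have the same number of loci")
  np <- n * (n - 1) / 2
  if (is.null(sample) && np > 2e6) sample <- 1e6
  if (is.null(sample)) {
    dA <- as.numeric(stats::dist(XA))
    dB <- as.numeric(stats::dist(XB))
  } else {
    pr <- .withSeed(seed, {
      i <- sample.int(n, ceiling(1.1 * sample), replace = TRUE)
      j <- sample.int(n, length(i), replace = TRUE)
      keep <- which(i != j)[seq_len(min(sample, sum(i != j)))]
      cbind(i[keep], j[keep])
    })
    dA <- .pairDistances(XA, pr[, 1L], pr[, 2L])
    dB <- .pairDistances(XB, pr[, 1L], pr[, 2L])
  }
  stats::cor(dA, dB, method = method)
}

#' Normalized RMSD between two structures
#'
#' A scale-free structural deviation: both structures are centered and
#' scaled to unit radius of gyration, then optimally superposed (reflection
#' allowed) and the RMSD of the superposed unit-scale structures is
#' returned. Zero for structures related by any similarity transform
#' (rotation, translation, reflection, uniform scaling); symmetric in its
#' arguments.
#'
#' @param A,B [Structure3D-class] objects (or coordinate matrices) with
#'   positional correspondence.
#' @return non-negative scalar.
#' @export
normalizedRMSD <- function(A, B) {
  XA <- if (is(A, "Structure3D")) A@coords else as.matrix(A)
  XB <- if (is(B, "Structure3D")) B@coords else as.matrix(B)
  if (nrow(XA) != nrow(XB)) stop("structures must have the same number of loci")
  scaleUnit <- function(X) {
    Xc <- sweep(X, 2L, colMeans(X))
    rg <- sqrt(mean(rowSums(Xc * Xc)))
    if (rg == 0) stop("degenerate structure with zero radius of gyration")
    Xc / rg
  }
  superpose(scaleUnit(XA), scaleUnit(XB), allowReflection = TRUE)@rmsd
}
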