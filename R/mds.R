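## Embedding and superposition primitives: classical (Torgerson) MDS,
## weighted MDS by SMACOF stress majorization, Kabsch superposition.

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, takes the top eigenpairs, and
#' returns coordinates `eigenvectors * sqrt(eigenvalues)`. Negative
#' eigenvalues (non-Euclidean input) are clamped at zero; if fewer than `dim`
#' positive eigenvalues exist, the remaining coordinates are zero-padded with
#' a warning. The output is centered at the origin and reproduces the input
#' distances exactly when `D` is Euclidean of rank at most `dim`.
#'
#' @param D symmetric distance matrix with zero diagonal, finite entries.
#' @param dim embedding dimension (default 3).
#' @return `m x dim` coordinate matrix.
#' @export
classicalMDS <- function(D, dim = 3L) {
  D <- as.matrix(D)
  m <- nrow(D)
  stopifnot(m == ncol(D), all(is.finite(D)))
  dim <- as.integer(dim)
  if (m == 1L) return(matrix(0, 1L, dim))
  D2 <- D * D
  rm_ <- rowMeans(D2)
  B <- -0.5 * (D2 - outer(rm_, rep(1, m)) - outer(rep(1, m), rm_) + mean(D2))
  e <- eigen(B, symmetric = TRUE)
  k <- min(dim, m)
  lam <- e$values[seq_len(k)]
  nPos <- sum(lam > 0)
  if (nPos < dim) {
    warning("only ", nPos, " positive eigenvalue(s); zero-padding to dim = ",
            dim)
  }
  lam[lam < 0] <- 0
  X <- e$vectors[, seq_len(k), drop = FALSE] *
    rep(sqrt(lam), each = m)
  if (k < dim) X <- cbind(X, matrix(0, m, dim - k))
  X
}

# Weighted stress sum_{i<j} w_ij (d_ij(X) - Dhat_ij)^2.
.weightedStress <- function(X, Dhat, W) {
  dx <- as.matrix(stats::dist(X))
  sum(W[upper.tri(W)] * (dx[upper.tri(dx)] - Dhat[upper.tri(Dhat)])^2)
}

#' Weighted MDS by SMACOF stress majorization
#'
#' Minimizes the weighted stress
#' \eqn{\sum_{i<j} w_{ij} (d_{ij}(X) - \hat d_{ij})^2} by iterative
#' majorization (the Guttman transform with weights), starting from `init`.
#' The stress is non-increasing at every iteration; iteration stops when the
#' relative stress decrease falls below `tol` or after `maxIter` iterations.
#'
#' @param D symmetric matrix of target distances \eqn{\hat d}.
#' @param W symmetric non-negative weight matrix with zero diagonal
#'   (`NULL` for unit weights). Points whose weights are all zero are
#'   unconstrained: they keep their `init` coordinates (with a warning).
#' @param init `m x dim` starting configuration.
#' @param maxIter iteration cap (default 300).
#' @param tol relative stress-decrease threshold (default 1e-6).
#' @return coordinate matrix with attributes `stress` (final weighted
#'   stress) and `stressTrace` (stress after each iteration, starting with
#'   the initial stress).
#' @export
wmdsSmacof <- function(D, W = NULL, init, maxIter = 300L, tol = 1e-6) {
  D <- as.matrix(D)
  m <- nrow(D)
  X <- as.matrix(init)
  stopifnot(ncol(D) == m, nrow(X) == m)
  if (is.null(W)) {
    W <- matrix(1, m, m)
    diag(W) <- 0
  }
  W <- as.matrix(W)
  stopifnot(all(W >= 0), isTRUE(all.equal(W, t(W), tolerance = 1e-12)))
  active <- rowSums(W) > 0
  if (!all(active)) {
    warning(sum(!active), " point(s) with all-zero weights kept at their ",
            "initial coordinates")
    sub <- wmdsSmacof(D[active, active, drop = FALSE],
                      W[active, active, drop = FALSE],
                      X[active, , drop = FALSE], maxIter, tol)
    X[active, ] <- sub
    attributes(X)[c("stress", "stressTrace")] <-
      attributes(sub)[c("stress", "stressTrace")]
    return(X)
  }
  unitW <- all(W[upper.tri(W)] == W[upper.tri(W)][1L])
  if (!unitW) {
    V <- -W
    diag(V) <- rowSums(W)
    # Moore-Penrose inverse of the (rank m-1) V via the rank-one completion
    Vplus <- solve(V + matrix(1, m, m)) - matrix(1 / m^2, m, m)
  }
  ut <- upper.tri(D)
  wut <- W[ut]
  dut <- D[ut]
  stressOf <- function(dx) sum(wut * (dx[ut] - dut)^2)
  dx <- as.matrix(stats::dist(X))
  stress <- stressOf(dx)
  trace <- stress
  iter <- 0L
  while (iter < maxIter && stress > 0) {
    ratio <- D / dx
    ratio[dx == 0] <- 0
    B <- -W * ratio
    diag(B) <- -rowSums(B)
    X <- if (unitW) {
      (B %*% X) / (m * W[1L, 2L])
    } else {
      Vplus %*% (B %*% X)
    }
    dx <- as.matrix(stats::dist(X))
    newStress <- stressOf(dx)
    iter <- iter + 1L
    trace <- c(trace, newStress)
    done <- stress > 0 && (stress - newStress) / stress < tol
    stress <- newStress
    if (done) break
  }
  X <- unname(as.matrix(X))
  attr(X, "stress") <- stress
  attr(X, "stressTrace") <- trace
  X
}

#' Optimal rigid superposition (Kabsch, with reflection handling)
#'
#' Finds the rotation `R` and translation `T` minimizing the RMSD of
#' `R p_i + T` against `q_i` (row-wise correspondence), via SVD of the
#' cross-covariance of the centered point sets. With
#' `allowReflection = TRUE` the improper (mirror) solution is also
#' considered and returned whenever it achieves a smaller RMSD — this is
#' equivalent to superposing both the point set and its mirror image and
#' keeping the better fit. Near-coplanar or collinear point sets make the
#' rotation non-unique; a valid minimizer is still returned, flagged
#' `degenerate`.
#'
#' @param P,Q `m x 3` matrices of corresponding points (`m >= 3`).
#' @param allowReflection consider the improper solution (default `TRUE`).
#' @return a [RigidTransform-class].
#' @seealso [applyTransform()], [rmsd()]
#' @export
superpose <- function(P, Q, allowReflection = TRUE) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  m <- nrow(P)
  stopifnot(m == nrow(Q), ncol(P) == 3L, ncol(Q) == 3L, m >= 3L)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2L, cp); Qc <- sweep(Q, 2L, cq)
  H <- crossprod(Pc, Qc)
  sv <- svd(H)
  # M acts on row vectors: Pc %*% M ~ Qc
  Mfree <- sv$u %*% t(sv$v)
  detFree <- det(Mfree)
  reflected <- FALSE
  if (detFree < 0 && allowReflection) {
    M <- Mfree
    reflected <- TRUE
  } else {
    M <- sv$u %*% diag(c(1, 1, sign(detFree))) %*% t(sv$v)
  }
  degenerate <- m < 4L || sv$d[3L] <= 1e-9 * max(sv$d[1L], .Machine$double.eps)
  Tvec <- as.numeric(cq - cp %*% M)
  resid <- Qc - Pc %*% M
  r <- sqrt(mean(rowSums(resid * resid)))
  new("RigidTransform", rotation = t(M), translation = Tvec,
      reflected = reflected, rmsd = r, degenerate = degenerate)
}

#' Apply a rigid transform to points
#'
#' @param transform a [RigidTransform-class] from [superpose()].
#' @param P `m x 3` matrix of points (rows).
#' @return transformed `m x 3` matrix (`R p_i + T` per row).
#' @export
applyTransform <- function(transform, P) {
  stopifnot(is(transform, "RigidTransform"))
  P <- as.matrix(P)
  sweep(P %*% t(transform@rotation), 2L, -transform@translation)
}

#' Root-mean-square deviation of corresponding points
#'
#' No superposition is applied; see [superpose()] for the minimized RMSD.
#'
#' @param P,Q matrices of corresponding points (rows).
#' @return non-negative scalar.
#' @export
rmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(all(dim(P) == dim(Q)))
  d <- P - Q
  sqrt(mean(rowSums(d * d)))
}
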