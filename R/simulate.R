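## Synthetic structures (confined random-walk polymer, helix) and the two
## contact-map observation models (binary top-k, Poisson).

#' Simulate a confined random-walk polymer structure
#'
#' Generates chains as fixed-bond-length random walks confined to a sphere,
#' with excluded volume: a step is rejected when it leaves the sphere or
#' comes closer than `minSeparation` to any previously placed locus. After
#' `maxTries` rejected proposals the least-crowded in-sphere proposal is
#' accepted (counted in `attr(, "crowded")`), so generation always
#' terminates. This emulates the coarse features of an equilibrated confined
#' polymer — locally stiff chains, global compaction, excluded volume — and
#' is fully deterministic under a seed.
#'
#' @param n total number of loci.
#' @param chains number of chains (loci split as evenly as possible).
#' @param bondLength distance between consecutive loci (default 1).
#' @param confinementRadius sphere radius; default
#'   `max(3, 1.2 * n^(1/3)) * bondLength`, giving a moderately packed
#'   nucleus-like density.
#' @param minSeparation excluded-volume distance (default `0.7 * bondLength`).
#' @param maxTries proposal cap per step (default 100).
#' @param seed RNG seed.
#' @return a [Structure3D-class] with chain labels `"chr1"`, `"chr2"`, ...
#' @export
simulatePolymer <- function(n, chains = 1L, bondLength = 1,
                            confinementRadius = NULL,
                            minSeparation = 0.7 * bondLength,
                            maxTries = 100L, seed = 1L) {
  n <- as.integer(n)
  stopifnot(n >= 1L, chains >= 1L, bondLength > 0)
  if (is.null(confinementRadius)) {
    confinementRadius <- max(3, 1.2 * n^(1 / 3)) * bondLength
  }
  R <- confinementRadius
  sizes <- diff(floor(seq(0L, n, length.out = chains + 1L)))
  lab <- rep(paste0("chr", seq_len(chains)), times = sizes)
  X <- matrix(0, n, 3L)
  crowded <- 0L
  .withSeed(seed, {
    placed <- 0L
    for (ch in seq_len(chains)) {
      for (s in seq_len(sizes[ch])) {
        if (s == 1L) {
          # chain start: uniform in the inner half-ball
          repeat {
            cand <- stats::runif(3L, -R / 2, R / 2)
            if (sum(cand^2) <= (R / 2)^2) break
          }
          if (placed > 0L) {
            d2 <- (X[seq_len(placed), 1L] - cand[1L])^2 +
              (X[seq_len(placed), 2L] - cand[2L])^2 +
              (X[seq_len(placed), 3L] - cand[3L])^2
            if (min(d2) < minSeparation^2) {
              # rare at default densities; accept regardless
              crowded <- crowded + 1L
            }
          }
        } else {
          prev <- X[placed, ]
          best <- NULL
          bestClear <- -Inf
          ok <- FALSE
          for (try in seq_len(maxTries)) {
            dir <- stats::rnorm(3L)
            dir <- dir / sqrt(sum(dir^2))
            cand <- prev + bondLength * dir
            if (sum(cand^2) > R^2) next
            if (placed > 0L) {
              d2 <- (X[seq_len(placed), 1L] - cand[1L])^2 +
                (X[seq_len(placed), 2L] - cand[2L])^2 +
                (X[seq_len(placed), 3L] - cand[3L])^2
              clear <- min(d2)
            } else {
              clear <- Inf
            }
            if (clear >= minSeparation^2) {
              ok <- TRUE
              break
            }
            if (clear > bestClear) {
              bestClear <- clear
              best <- cand
            }
          }
          if (!ok) {
            crowded <- crowded + 1L
            cand <- if (!is.null(best)) {
              best
            } else {
              # every proposal left the sphere: step toward the center
              prev * max(0, 1 - bondLength / sqrt(sum(prev^2)))
            }
          }
        }
        placed <- placed + 1L
        X[placed, ] <- cand
      }
    }
  })
  out <- Structure3D(X, chains = lab)
  attr(out, "crowded") <- crowded
  out
}

#' Regular helix benchmark structure
#'
#' A parametric helix sampled at `n` equally spaced angles: the classical
#' noise-free benchmark for distance-based reconstruction.
#'
#' @param n number of loci.
#' @param turns number of full turns (default 5).
#' @param radius helix radius (default 1).
#' @param pitch vertical rise per turn (default 1).
#' @return a [Structure3D-class].
#' @export
simulateHelix <- function(n, turns = 5, radius = 1, pitch = 1) {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  theta <- seq(0, turns * 2 * pi, length.out = n)
  Structure3D(cbind(
    radius * cos(theta),
    radius * sin(theta),
    pitch * theta / (2 * pi)
  ))
}

# dist()-order index vectors: element q of dist(X) is pair (jv[q] < iv[q]).
.distPairIndex <- function(n) {
  j <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  i <- sequence((n - 1L):1L) + j
  list(i = i, j = j)
}

#' Binary contact map: top-k nearest pairs
#'
#' Sets the `k` smallest pairwise distances to frequency 1 and everything
#' else to 0; ties are broken lexicographically on `(i, j)` for determinism.
#' For large `n` the selection runs in row chunks so no full distance matrix
#' is held.
#'
#' @param structure a [Structure3D-class].
#' @param k number of contact pairs, `1 <= k <= n (n - 1) / 2`.
#' @return a [ContactMap-class] with exactly `k` stored entries.
#' @export
binaryContactMap <- function(structure, k) {
  stopifnot(is(structure, "Structure3D"))
  X <- structure@coords
  n <- nrow(X)
  np <- n * (n - 1) / 2
  k <- as.integer(round(k))
  if (k < 1L || k > np) stop("k must be in [1, n(n-1)/2]")
  if (n <= 3000L) {
    d <- as.numeric(stats::dist(X))
    idx <- .distPairIndex(n)
    ord <- order(d, idx$j, idx$i)[seq_len(k)]
    return(.newContactMap(idx$j[ord], idx$i[ord], rep(1, k), n,
                          chains = structure@chains))
  }
  # chunked top-k: estimate a distance threshold from sampled pairs, widen
  # until at least k pairs fall below it, then sort the survivors
  samp <- .withSeed(1L, {
    i <- sample.int(n, 2e5, replace = TRUE)
    j <- sample.int(n, 2e5, replace = TRUE)
    keep <- i != j
    .pairDistances(X, i[keep], j[keep])
  })
  thr <- stats::quantile(samp, min(1, 1.5 * k / np), names = FALSE)
  repeat {
    ii <- integer(); jj <- integer(); dd <- numeric()
    cs <- max(1L, floor(2e6 / n))
    acc <- vector("list", ceiling(n / cs))
    ci <- 0L
    for (a in seq(1L, n - 1L, by = cs)) {
      b <- min(a + cs - 1L, n - 1L)
      rows <- a:b
      block <- outer(rowSums(X[rows, , drop = FALSE]^2), rowSums(X^2), "+") -
        2 * X[rows, , drop = FALSE] %*% t(X)
      block[block < 0] <- 0
      block <- sqrt(block)
      sel <- which(block <= thr &
                     col(block) > rows[row(block)], arr.ind = TRUE)
      ci <- ci + 1L
      acc[[ci]] <- cbind(rows[sel[, 1L]], sel[, 2L],
                         block[sel])
    }
    m <- do.call(rbind, acc[seq_len(ci)])
    if (nrow(m) >= k) {
      ord <- order(m[, 3L], m[, 1L], m[, 2L])[seq_len(k)]
      return(.newContactMap(as.integer(m[ord, 1L]), as.integer(m[ord, 2L]),
                            rep(1, k), n, chains = structure@chains))
    }
    thr <- thr * 1.6
  }
}

#' Poisson-model contact map
#'
#' Draws each pair's contact count independently from a Poisson distribution
#' with rate \eqn{\lambda_{ij} = \beta / d_{ij}^{\alpha}}, the power-law
#' inverse of the frequency-to-distance conversion. `beta` controls the
#' signal coverage (fraction of pairs with a nonzero count); see
#' [coverageToBeta()]. Zero counts are not stored. Computation runs in row
#' chunks so no dense pair matrix is held.
#'
#' @param structure a [Structure3D-class].
#' @param alpha power-law exponent (default 1).
#' @param beta positive rate scale.
#' @param seed RNG seed.
#' @return a [ContactMap-class].
#' @export
poissonContactMap <- function(structure, alpha = 1, beta, seed = 1L) {
  stopifnot(is(structure, "Structure3D"), alpha > 0, beta >= 0)
  X <- structure@coords
  n <- nrow(X)
  if (beta == 0) {
    return(.newContactMap(integer(), integer(), numeric(), n,
                          chains = structure@chains))
  }
  sq <- rowSums(X^2)
  cs <- max(1L, floor(4e6 / n))
  .withSeed(seed, {
    acc <- vector("list", ceiling(n / cs))
    ci <- 0L
    for (a in seq(1L, n - 1L, by = cs)) {
      b <- min(a + cs - 1L, n - 1L)
      rows <- a:b
      d2 <- outer(sq[rows], sq, "+") - 2 * X[rows, , drop = FALSE] %*% t(X)
      d2[d2 < 0] <- 0
      ut <- col(d2) > rows[row(d2)]
      d <- sqrt(d2[ut])
      iIdx <- rows[row(d2)[ut]]
      jIdx <- col(d2)[ut]
      lam <- beta / d^alpha
      cnt <- stats::rpois(length(lam), lam)
      nz <- cnt > 0L
      ci <- ci + 1L
      acc[[ci]] <- list(i = iIdx[nz], j = jIdx[nz], f = as.numeric(cnt[nz]))
    }
    .newContactMap(
      unlist(lapply(acc[seq_len(ci)], `[[`, "i")),
      unlist(lapply(acc[seq_len(ci)], `[[`, "j")),
      unlist(lapply(acc[seq_len(ci)], `[[`, "f")),
      n, chains = structure@chains
    )
  })
}

#' Signal coverage of a contact map
#'
#' Fraction of distinct locus pairs with a nonzero stored contact.
#'
#' @param map a [ContactMap-class].
#' @return scalar in `[0, 1]`.
#' @export
contactCoverage <- function(map) {
  stopifnot(is(map, "ContactMap"))
  tr <- .mapTriplets(map)
  n <- nLoci(map)
  sum(tr$i != tr$j) / (n * (n - 1) / 2)
}

#' Calibrate the Poisson rate scale to a target signal coverage
#'
#' The expected coverage at rate scale `beta` is
#' \eqn{1 - \mathrm{mean}_{ij}\, e^{-\beta / d_{ij}^{\alpha}}}, monotonically
#' increasing in `beta`; this solves for `beta` by bisection until the
#' expected coverage is within `tol` of the target. For large structures the
#' mean is taken over a seeded sample of pairs.
#'
#' @param structure a [Structure3D-class].
#' @param alpha power-law exponent.
#' @param targetCoverage desired fraction of nonzero pairs in `[0, 1)`.
#' @param tol coverage tolerance (default 0.005).
#' @param maxPairs pair-sample cap (default 2e6).
#' @param seed RNG seed for the pair sample.
#' @return the calibrated `beta` (0 when `targetCoverage <= 0`).
#' @export
coverageToBeta <- function(structure, alpha = 1, targetCoverage, tol = 0.005,
                           maxPairs = 2e6, seed = 1L) {
  stopifnot(is(structure, "Structure3D"), targetCoverage < 1)
  if (targetCoverage <= 0) return(0)
  X <- structure@coords
  n <- nrow(X)
  np <- n * (n - 1) / 2
  d <- if (np <= maxPairs) {
    as.numeric(stats::dist(X))
  } else {
    .withSeed(seed, {
      i <- sample.int(n, 1.1 * maxPairs, replace = TRUE)
      j <- sample.int(n, 1.1 * maxPairs, replace = TRUE)
      keep <- i != j
      .pairDistances(X, i[keep], j[keep])[seq_len(maxPairs)]
    })
  }
  lamUnit <- d^(-alpha)
  cov <- function(beta) 1 - mean(exp(-beta * lamUnit))
  lo <- 0
  hi <- 1
  while (cov(hi) < targetCoverage) {
    hi <- hi * 2
    if (hi > 1e12) break
  }
  for (it in seq_len(200L)) {
    mid <- (lo + hi) / 2
    c <- cov(mid)
    if (abs(c - targetCoverage) <= tol) return(mid)
    if (c < targetCoverage) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
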