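## Progressive assembly (iMDS), scalable weighted-MDS polish (sMDS) and the
## end-to-end reconstruction pipeline.

# One assembly pass over a given permutation; returns list(coords, degenerate).
.imdsOnce <- function(oracle, config, perm) {
  n <- nLoci(oracle)
  k <- config@subsetSize
  o <- config@overlap
  starts <- seq(1L, n, by = k - o)
  X <- matrix(NA_real_, n, 3L)
  degenerate <- FALSE
  first <- TRUE
  for (s in starts) {
    e <- min(s + k - 1L, n)
    if (!first && e - s + 1L <= o) next # window holds no new locus
    idx <- perm[s:e]
    D <- oracleSubmatrix(oracle, idx)
    local <- classicalMDS(D, dim = 3L)
    if (first) {
      X[idx, ] <- local
      first <- FALSE
      next
    }
    anchors <- idx[seq_len(o)]
    tf <- superpose(local[seq_len(o), , drop = FALSE],
                    X[anchors, , drop = FALSE],
                    allowReflection = TRUE)
    if (tf@degenerate) degenerate <- TRUE
    moved <- applyTransform(tf, local)
    X[anchors, ] <- (X[anchors, , drop = FALSE] +
                       moved[seq_len(o), , drop = FALSE]) / 2
    X[idx[-seq_len(o)], ] <- moved[-seq_len(o), , drop = FALSE]
  }
  list(coords = X, degenerate = degenerate)
}

#' Progressive structure assembly from overlapping random subsets (iMDS)
#'
#' Draws a seeded random permutation of the loci, cuts it into consecutive
#' subsets of `subsetSize` loci sharing exactly `overlap` anchors with their
#' predecessor, embeds each subset's oracle distance matrix by classical MDS,
#' and folds the subsets left-to-right: the shared anchors are superposed
#' (reflection allowed) onto the growing frame, the new subset is moved into
#' that frame, and anchor coordinates are averaged between their two images.
#' Random (rather than genomically contiguous) subsets mix close and distant
#' loci, which anchors each local embedding at the global scale. If an anchor
#' superposition is degenerate (near-coplanar anchors) the permutation is
#' redrawn once; a persistent degeneracy is flagged in the metadata.
#'
#' When `n <= subsetSize` the result is simply classical MDS on the full
#' oracle distance matrix.
#'
#' @param oracle a [PivotOracle-class] covering all loci.
#' @param config a [ReconstructionConfig-class] (fields `subsetSize`,
#'   `overlap`, `seed`).
#' @return a [Structure3D-class] (loci in oracle vertex order).
#' @export
imdsAssemble <- function(oracle, config = reconstructionConfig()) {
  stopifnot(is(oracle, "PivotOracle"), is(config, "ReconstructionConfig"))
  n <- nLoci(oracle)
  if (n <= config@subsetSize) {
    D <- oracleSubmatrix(oracle, seq_len(n))
    return(Structure3D(classicalMDS(D, dim = 3L), loci = oracle@loci))
  }
  perm <- .withSeed(.childSeed(config@seed, 101L), sample.int(n))
  res <- .imdsOnce(oracle, config, perm)
  if (res$degenerate) {
    perm <- .withSeed(.childSeed(config@seed, 102L), sample.int(n))
    res <- .imdsOnce(oracle, config, perm)
  }
  Structure3D(res$coords, loci = oracle@loci,
              metadata = list(degenerateAnchors = res$degenerate))
}

# Weight matrix for a block's target distances under the configured scheme.
.smdsWeights <- function(Dhat, scheme) {
  W <- switch(scheme,
    inv_sq = 1 / (Dhat * Dhat),
    inv = 1 / Dhat,
    unit = matrix(1, nrow(Dhat), ncol(Dhat))
  )
  W[!is.finite(W)] <- 0
  diag(W) <- 0
  W
}

#' Scalable weighted-MDS polish (sMDS)
#'
#' Refines a structure against the oracle distances block by block. Each
#' round randomly permutes the loci, partitions them into disjoint blocks of
#' `smdsBlockSize` (a tail block smaller than 4 is merged into its
#' predecessor), and for each block runs weighted MDS (SMACOF, weights
#' \eqn{w_{ij} = \hat d_{ij}^{-2}} by default so short, more reliable
#' distances dominate) initialized at the current coordinates. The block
#' result is rigidly superposed back onto its previous coordinates and each
#' locus is moved to the average of its old and superposed-new positions.
#' Rounds repeat until the mean per-locus displacement falls below
#' `smdsTol` times the radius of gyration, or `smdsMaxRounds` is reached.
#'
#' @param structure the [Structure3D-class] to polish (e.g. from
#'   [imdsAssemble()]).
#' @param oracle the [PivotOracle-class] providing target distances.
#' @param config a [ReconstructionConfig-class].
#' @return polished [Structure3D-class]; metadata gains `smdsRounds`,
#'   `smdsDisplacement` (per-round mean displacement / radius of gyration)
#'   and `smdsStress` (summed block stresses per round).
#' @export
smdsPolish <- function(structure, oracle, config = reconstructionConfig()) {
  stopifnot(is(structure, "Structure3D"), is(oracle, "PivotOracle"),
            is(config, "ReconstructionConfig"))
  n <- nLoci(structure)
  if (n != nLoci(oracle)) stop("structure and oracle disagree on n")
  if (n < 4L) return(structure)
  X <- structure@coords
  bs <- min(config@smdsBlockSize, n)
  dispTrace <- numeric()
  stressTrace <- numeric()
  rounds <- 0L
  for (r in seq_len(config@smdsMaxRounds)) {
    perm <- .withSeed(.childSeed(config@seed, 200L + r), sample.int(n))
    nb <- max(1L, floor(n / bs))
    bounds <- floor(seq(0L, n, length.out = nb + 1L))
    Xold <- X
    roundStress <- 0
    for (b in seq_len(nb)) {
      S <- perm[(bounds[b] + 1L):bounds[b + 1L]]
      if (length(S) < 4L) next
      Dhat <- oracleSubmatrix(oracle, S)
      W <- .smdsWeights(Dhat, config@weightScheme)
      PS <- X[S, , drop = FALSE]
      PSnew <- wmdsSmacof(Dhat, W, init = PS,
                          maxIter = config@smdsMaxIter, tol = 1e-6)
      roundStress <- roundStress + attr(PSnew, "stress")
      tf <- superpose(PSnew, PS, allowReflection = TRUE)
      moved <- applyTransform(tf, PSnew)
      X[S, ] <- (PS + moved) / 2
    }
    rounds <- r
    rg <- radiusOfGyration(X)
    disp <- mean(sqrt(rowSums((X - Xold)^2))) / rg
    dispTrace <- c(dispTrace, disp)
    stressTrace <- c(stressTrace, roundStress)
    if (disp < config@smdsTol) break
  }
  md <- structure@metadata
  md$smdsRounds <- rounds
  md$smdsDisplacement <- dispTrace
  md$smdsStress <- stressTrace
  Structure3D(X, loci = structure@loci, chains = structure@chains,
              metadata = md)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Reconstruct a 3D structure from a contact map
#'
#' The end-to-end pipeline: optional matrix balancing, power-law exponent
#' (fixed or
#' estimated by golden-section search), frequency-to-distance conversion,
#' (balancing is off by default: it corrects per-locus coverage bias in
#' measured Hi-C maps, but in bias-free simulated maps coverage variation is
#' geometric signal; enable it via `reconstructionConfig(balance = TRUE)`
#' for real data),
#' contact-graph construction (largest connected component), random pivot
#' selection (`ceiling(pivotFrac * n)` pivots, floored at `pivotMin` and
#' capped at `n`), shortest-path oracle,
#' progressive iMDS assembly, and the scalable weighted-MDS polish.
#'
#' @param map a [ContactMap-class].
#' @param config a [ReconstructionConfig-class]; see
#'   [reconstructionConfig()].
#' @return a [Structure3D-class] for the retained loci (`loci()` maps back
#'   to input indices). `metadata(x)$report` records the exponent used,
#'   dropped loci, pivot count, a sampled approximation-ratio estimate,
#'   polish displacement/stress traces, and the seed.
#' @examples
#' s <- simulateHelix(80)
#' m <- poissonContactMap(s, alpha = 1, beta = 20, seed = 1)
#' r <- reconstructStructure(m, reconstructionConfig(alpha = 1, seed = 1))
#' distanceCorrelation(r, s)
#' @export
reconstructStructure <- function(map, config = reconstructionConfig()) {
  stopifnot(is(map, "ContactMap"), is(config, "ReconstructionConfig"))
  if (config@balance) {
    bal <- .stage("balance", balanceContacts(map, config@balanceTol,
                                             config@balanceMaxIter))
    kept <- attr(bal, "keptLoci")
  } else {
    bal <- map
    kept <- seq_len(nLoci(map))
  }
  alpha <- if (is.na(config@alpha)) {
    .stage("alpha", as.numeric(estimateAlpha(
      bal, tol = config@alphaTol, seed = .childSeed(config@seed, 7L)
    )))
  } else {
    config@alpha
  }
  edges <- .stage("convert", contactsToDistances(bal, alpha))
  graph <- .stage("graph", buildDistanceGraph(
    edges, n = nLoci(bal), backbone = config@backbone,
    chainLabels = if (length(bal@chains)) bal@chains else NULL
  ))
  ng <- nLoci(graph)
  nPiv <- min(ng, max(ceiling(config@pivotFrac * ng), config@pivotMin))
  pivotIds <- .stage("pivots", selectPivots(ng, nPiv,
                                            seed = .childSeed(config@seed, 11L)))
  oracle <- .stage("oracle", buildPivotOracle(graph, pivotIds))
  assembled <- .stage("imds", imdsAssemble(oracle, config))
  polished <- .stage("smds", smdsPolish(assembled, oracle, config))
  arEst <- tryCatch(
    oracleAccuracy(oracle, graph, nPairs = 2000L, nSources = 10L,
                   seed = .childSeed(config@seed, 13L))$ar,
    error = function(e) NA_real_
  )
  origLoci <- kept[graph@loci]
  report <- list(
    balanced = config@balance,
    alpha = alpha,
    alphaEstimated = is.na(config@alpha),
    droppedBalance = attr(bal, "dropped"),
    droppedComponent = kept[attr(graph, "dropped")],
    nPivots = nPiv,
    arEstimate = arEst,
    smdsRounds = polished@metadata$smdsRounds,
    smdsDisplacement = polished@metadata$smdsDisplacement,
    smdsStress = polished@metadata$smdsStress,
    seed = config@seed
  )
  Structure3D(polished@coords, loci = origLoci,
              chains = if (length(map@chains)) map@chains[origLoci]
                       else character(),
              metadata = list(report = report))
}
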