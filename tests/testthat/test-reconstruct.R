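test_that("a single subset reduces to classical MDS on the full distance matrix", {
  s <- randomStructure(100, seed = 40, scale = 5)
  o <- exactOracle(s)
  cfg <- reconstructionConfig(subsetSize = 500, seed = 1)
  got <- imdsAssemble(o, cfg)
  direct <- classicalMDS(oracleSubmatrix(o, 1:100))
  expect_equal(coords(got), direct)
})

test_that("progressive assembly recovers a structure from exact distances", {
  s <- randomStructure(500, seed = 41, scale = 8)
  o <- exactOracle(s)
  cfg <- reconstructionConfig(subsetSize = 200, overlap = 50, seed = 3)
  got <- imdsAssemble(o, cfg)
  diam <- max(stats::dist(coords(s)))
  tf <- superpose(coords(got), coords(s), allowReflection = TRUE)
  expect_lt(tf@rmsd, 1e-3 * diam)

  # different permutations give the same structure up to rigid motion
  got2 <- imdsAssemble(o, reconstructionConfig(subsetSize = 200,
                                               overlap = 50, seed = 17))
  expect_gt(distanceCorrelation(got, got2), 0.99)
})

test_that("polish is a fixed point on exact structures and improves noisy ones", {
  s <- randomStructure(300, seed = 42, scale = 6)
  o <- exactOracle(s)
  cfg <- reconstructionConfig(smdsBlockSize = 100, seed = 2,
                              weightScheme = "unit")

  # already-exact coordinates do not move
  polished <- smdsPolish(s, o, cfg)
  expect_equal(polished@metadata$smdsRounds, 1L)
  expect_lt(polished@metadata$smdsDisplacement[1], 1e-9)
  expect_equal(coords(polished), coords(s), tolerance = 1e-9)

  # Gaussian perturbation at 10% of the mean distance is pulled back
  set.seed(43)
  sigma <- 0.1 * mean(stats::dist(coords(s)))
  noisy <- Structure3D(coords(s) + matrix(stats::rnorm(900, 0, sigma),
                                          ncol = 3))
  before <- distanceCorrelation(noisy, s)
  polished2 <- smdsPolish(noisy, o,
                          reconstructionConfig(smdsBlockSize = 100,
                                               smdsMaxRounds = 8, seed = 2))
  expect_gt(distanceCorrelation(polished2, s), before)
})

test_that("inverse-square weights beat unit weights when noise grows with distance", {
  s <- randomStructure(200, seed = 44, scale = 6)
  X <- coords(s)
  D <- as.matrix(stats::dist(X))
  # multiplicative noise increasing with distance, as in contact-derived data
  set.seed(45)
  noise <- matrix(stats::rnorm(200 * 200, 0, 0.3), 200)
  noise <- (noise + t(noise)) / 2
  Dn <- D * (1 + noise * (D / max(D)))
  Dn[Dn <= 0] <- min(D[D > 0]) / 2
  diag(Dn) <- 0
  ut <- which(upper.tri(Dn), arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2], d = Dn[ut])
  g <- buildDistanceGraph(edges, 200)
  o <- buildPivotOracle(g, seq_len(200))
  init <- Structure3D(classicalMDS(oracleSubmatrix(o, 1:200)))

  run <- function(scheme) {
    cfg <- reconstructionConfig(smdsBlockSize = 200, smdsMaxRounds = 6,
                                weightScheme = scheme, seed = 5)
    distanceCorrelation(smdsPolish(init, o, cfg), s)
  }
  expect_gt(run("inv_sq"), run("unit"))
})

test_that("the full pipeline recovers exact-distance input up to similarity", {
  s <- randomStructure(150, seed = 46, scale = 5)
  D <- as.matrix(stats::dist(coords(s)))
  ut <- which(upper.tri(D), arr.ind = TRUE)
  m <- ContactMap(i = ut[, 1], j = ut[, 2], f = 1 / D[ut], nLoci = 150)
  # "noiseless oracle distances": every locus serves as a pivot
  r <- reconstructStructure(m, reconstructionConfig(alpha = 1, seed = 4,
                                                    pivotFrac = 1))
  expect_lt(normalizedRMSD(r, s), 0.01)
})

test_that("the pipeline reconstructs a helix from Poisson and binary maps", {
  h <- simulateHelix(100)
  # high-coverage Poisson map: counts dense enough to determine the shape
  beta <- coverageToBeta(h, 1, 0.95, tol = 0.002)
  mp <- poissonContactMap(h, alpha = 1, beta = beta, seed = 6)
  rp <- reconstructStructure(mp, reconstructionConfig(seed = 7))
  hp <- Structure3D(coords(h)[loci(rp), , drop = FALSE])
  expect_gt(distanceCorrelation(rp, hp), 0.9)

  # binary top-10% map
  mb <- binaryContactMap(h, round(0.1 * choose(100, 2)))
  rb <- reconstructStructure(mb, reconstructionConfig(alpha = 1, seed = 8))
  hb <- Structure3D(coords(h)[loci(rb), , drop = FALSE])
  expect_gt(distanceCorrelation(rb, hb, method = "spearman"), 0.9)
})

test_that("pipeline reports record the stages and propagate stage names on error", {
  s <- randomStructure(80, seed = 47)
  m <- binaryContactMap(s, 600)
  r <- reconstructStructure(m, reconstructionConfig(alpha = 1, seed = 9,
                                                    pivotFrac = 0.2))
  rep <- r@metadata$report
  expect_equal(rep$alpha, 1)
  expect_false(rep$balanced)
  expect_equal(rep$nPivots, 50L) # ceil(0.2 * 80) = 16, floored at pivotMin
  expect_true(is.finite(rep$arEstimate))
  expect_gte(length(rep$smdsDisplacement), 1L)

  empty <- ContactMap(integer(), integer(), numeric(), nLoci = 10)
  expect_error(reconstructStructure(empty,
                                    reconstructionConfig(alpha = 1,
                                                         balance = TRUE)),
               "stage 'balance'")
})
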