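test_that("polymer walks keep bond length, confinement and excluded volume", {
  p <- simulatePolymer(400, chains = 2, bondLength = 1.5, seed = 5)
  X <- coords(p)
  ch <- chains(p)
  # consecutive intra-chain distances equal the bond length
  steps <- sqrt(rowSums((X[-1, ] - X[-400, ])^2))
  intra <- ch[-1] == ch[-400]
  expect_lt(max(abs(steps[intra] - 1.5)), 1e-9)
  # confinement sphere
  R <- max(3, 1.2 * 400^(1 / 3)) * 1.5
  expect_lte(max(sqrt(rowSums(X^2))), R + 1e-9)
  # neighbour distances concentrate far below all-pairs distances
  allPairs <- as.numeric(stats::dist(X))
  expect_lt(stats::median(steps[intra]), 0.2 * stats::median(allPairs))
  # determinism
  p2 <- simulatePolymer(400, chains = 2, bondLength = 1.5, seed = 5)
  expect_identical(coords(p2), X)
  expect_false(identical(coords(simulatePolymer(400, chains = 2,
                                                bondLength = 1.5, seed = 6)),
                         X))
})

test_that("helix sampling is uniform in arc length and radius", {
  h <- simulateHelix(100, turns = 4, radius = 2, pitch = 0.8)
  X <- coords(h)
  steps <- sqrt(rowSums((X[-1, ] - X[-100, ])^2))
  expect_lt(diff(range(steps)), 1e-9)
  expect_lt(max(abs(sqrt(X[, 1]^2 + X[, 2]^2) - 2)), 1e-9)
})

test_that("binary maps select exactly the k nearest pairs", {
  s <- randomStructure(60, seed = 8)
  n <- 60
  np <- n * (n - 1) / 2

  # complete map
  full <- binaryContactMap(s, np)
  expect_equal(length(contactMatrix(full)@x), np)

  # 4 collinear equidistant points, k = 3: the consecutive pairs win
  lin <- Structure3D(cbind(0:3, 0, 0))
  m3 <- as.matrix(contactMatrix(binaryContactMap(lin, 3)))
  expect_equal(m3[cbind(1:3, 2:4)], rep(1, 3))

  # k = 50 matches a brute-force sort of all pairs
  m50 <- binaryContactMap(s, 50)
  expect_equal(length(contactMatrix(m50)@x), 50L)
  D <- as.matrix(stats::dist(coords(s)))
  ut <- which(upper.tri(D), arr.ind = TRUE)
  bruteSel <- ut[order(D[ut], ut[, 1], ut[, 2])[1:50], ]
  got <- chromrec:::.mapTriplets(m50)
  expect_setequal(paste(got$i, got$j), paste(bruteSel[, 1], bruteSel[, 2]))

  # chunked large-n path agrees with the direct path
  big <- randomStructure(3500, seed = 9, scale = 20)
  direct <- randomStructure(3500, seed = 9, scale = 20)
  kBig <- 2000
  mChunk <- binaryContactMap(big, kBig)   # n > 3000 triggers chunking
  expect_equal(length(contactMatrix(mChunk)@x), kBig)
  trChunk <- chromrec:::.mapTriplets(mChunk)
  dd <- .pairDistances(coords(big), trChunk$i, trChunk$j)
  # the k selected distances are all below the (k+1)-th smallest distance
  allD <- sort(as.numeric(stats::dist(coords(big))))[kBig + 1]
  expect_true(all(dd <= allD + 1e-12))
})

test_that("Poisson maps follow the power-law rate model", {
  # beta -> 0 gives an empty map
  s <- randomStructure(30, seed = 10)
  expect_equal(length(contactMatrix(poissonContactMap(s, 1, 0, seed = 1))@x),
               0L)

  # replicate draws for one pair match the analytic mean within 3 SE
  two <- Structure3D(rbind(c(0, 0, 0), c(2, 0, 0)))
  beta <- 6; alpha <- 1.3
  lambda <- beta / 2^alpha
  counts <- vapply(seq_len(4000), function(k) {
    m <- poissonContactMap(two, alpha, beta, seed = k)
    x <- contactMatrix(m)@x
    if (length(x)) x else 0
  }, numeric(1))
  se <- sqrt(lambda / 4000)
  expect_lt(abs(mean(counts) - lambda), 3 * se)

  # determinism under seed
  m1 <- poissonContactMap(s, 1, 3, seed = 77)
  m2 <- poissonContactMap(s, 1, 3, seed = 77)
  expect_equal(as.matrix(contactMatrix(m1)), as.matrix(contactMatrix(m2)))
})

test_that("coverage calibration hits its target and is monotone in beta", {
  h <- simulateHelix(200, turns = 6)
  b50 <- coverageToBeta(h, 1, 0.5)
  m <- poissonContactMap(h, 1, b50, seed = 4)
  expect_lt(abs(contactCoverage(m) - 0.5), 0.03)

  b90 <- coverageToBeta(h, 1, 0.9)
  expect_gt(b90, b50)
  expect_equal(coverageToBeta(h, 1, 0), 0)

  # high-coverage limit
  bHi <- coverageToBeta(h, 1, 0.995, tol = 0.002)
  mHi <- poissonContactMap(h, 1, bHi, seed = 5)
  expect_gt(contactCoverage(mHi), 0.99)
})
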