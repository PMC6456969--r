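test_that("classical MDS reproduces Euclidean inputs exactly", {
  # unit tetrahedron
  P <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0),
             c(0.5, sqrt(3) / 6, sqrt(6) / 3))
  D <- as.matrix(stats::dist(P))
  X <- classicalMDS(D)
  expect_lt(max(abs(as.matrix(stats::dist(X)) - D)), 1e-9)
  expect_lt(max(abs(colMeans(X))), 1e-12)

  # two points two apart: distance preserved, embedded on one axis
  suppressWarnings(X2 <- classicalMDS(matrix(c(0, 2, 2, 0), 2)))
  expect_equal(as.numeric(stats::dist(X2)), 2, tolerance = 1e-12)

  # 100 random 3D points: exact recovery up to rigid motion + reflection
  s <- randomStructure(100, seed = 2, scale = 5)
  D100 <- as.matrix(stats::dist(coords(s)))
  X100 <- classicalMDS(D100)
  expect_lt(superpose(X100, coords(s), allowReflection = TRUE)@rmsd, 1e-6)

  # non-Euclidean rank deficit pads with zeros and warns
  expect_warning(classicalMDS(matrix(c(0, 1, 1, 0), 2), dim = 3), "padding")
})

test_that("SMACOF decreases weighted stress monotonically to a fixed point", {
  s <- randomStructure(30, seed = 6, scale = 2)
  D <- as.matrix(stats::dist(coords(s)))

  # exact distances from the generating configuration: stress 0, no movement
  X <- wmdsSmacof(D, init = coords(s))
  expect_equal(attr(X, "stress"), 0)
  expect_equal(as.numeric(X), as.numeric(coords(s)))

  # noisy distances: stress trace is non-increasing at every iteration
  set.seed(8)
  Dnoisy <- D
  Dnoisy[upper.tri(Dnoisy)] <- D[upper.tri(D)] *
    stats::runif(sum(upper.tri(D)), 0.8, 1.25)
  Dnoisy[lower.tri(Dnoisy)] <- t(Dnoisy)[lower.tri(Dnoisy)]
  init <- coords(randomStructure(30, seed = 9, scale = 2))
  X2 <- wmdsSmacof(Dnoisy, init = init, maxIter = 80)
  trace <- attr(X2, "stressTrace")
  expect_true(all(diff(trace) <= 1e-9 * trace[1]))
  expect_lte(attr(X2, "stress"), trace[1])

  # inverse-square weighting fits short distances better than unit weights
  set.seed(10)
  sBig <- randomStructure(50, seed = 10, scale = 4)
  Db <- as.matrix(stats::dist(coords(sBig)))
  noise <- matrix(stats::rnorm(2500, 0, 0.15), 50)
  noise <- (noise + t(noise)) / 2
  Dv <- pmax(Db * (1 + noise * Db / max(Db)), 0.01) # error grows with distance
  diag(Dv) <- 0
  W <- 1 / Dv^2; diag(W) <- 0
  init2 <- coords(randomStructure(50, seed = 12, scale = 4))
  Xw <- wmdsSmacof(Dv, W, init = init2, maxIter = 200)
  Xu <- wmdsSmacof(Dv, init = init2, maxIter = 200)
  wstress <- function(X) sum(W[upper.tri(W)] *
                               (as.matrix(stats::dist(X))[upper.tri(W)] -
                                  Dv[upper.tri(W)])^2)
  expect_lt(wstress(Xw), wstress(Xu))

  # all-zero weight row: point stays at its init position
  W0 <- matrix(1, 5, 5); diag(W0) <- 0
  W0[3, ] <- 0; W0[, 3] <- 0
  D5 <- as.matrix(stats::dist(coords(randomStructure(5, seed = 3))))
  init5 <- coords(randomStructure(5, seed = 4))
  expect_warning(X5 <- wmdsSmacof(D5, W0, init = init5), "all-zero")
  expect_equal(X5[3, ], unname(init5[3, ]))
})

test_that("superposition recovers rigid transforms and handles reflection", {
  set.seed(14)
  P <- coords(randomStructure(40, seed = 14, scale = 3))
  # random proper rotation via QR
  qr0 <- qr(matrix(stats::rnorm(9), 3))
  R0 <- qr.Q(qr0)
  if (det(R0) < 0) R0[, 1] <- -R0[, 1]
  T0 <- c(4, -2, 7)
  Q <- P %*% t(R0) + rep(1, 40) %o% T0

  tf <- superpose(P, Q, allowReflection = FALSE)
  expect_lt(tf@rmsd, 1e-9)
  expect_lt(max(abs(tf@rotation - R0)), 1e-9)
  expect_lt(max(abs(tf@translation - T0)), 1e-9)
  expect_lt(max(abs(applyTransform(tf, P) - Q)), 1e-8)

  # mirrored target: perfect with reflection, imperfect without
  Qm <- P; Qm[, 3] <- -Qm[, 3]
  tfR <- superpose(P, Qm, allowReflection = TRUE)
  expect_lt(tfR@rmsd, 1e-9)
  expect_true(tfR@reflected)
  expect_lt(det(tfR@rotation), 0)
  tfNoR <- superpose(P, Qm, allowReflection = FALSE)
  expect_gt(tfNoR@rmsd, 0.1)
  expect_gte(det(tfNoR@rotation), 0)

  # superposition RMSD matches an independent numerical optimizer
  Pn <- coords(randomStructure(50, seed = 15, scale = 2))
  Qn <- Pn %*% t(R0) + rep(1, 50) %o% T0 +
    matrix(stats::rnorm(150, 0, 0.2), 50)
  best <- superpose(Pn, Qn, allowReflection = FALSE)@rmsd
  objective <- function(par) {
    # Euler angles + translation
    ca <- cos(par[1]); sa <- sin(par[1])
    cb <- cos(par[2]); sb <- sin(par[2])
    cg <- cos(par[3]); sg <- sin(par[3])
    Rz <- rbind(c(ca, -sa, 0), c(sa, ca, 0), c(0, 0, 1))
    Ry <- rbind(c(cb, 0, sb), c(0, 1, 0), c(-sb, 0, cb))
    Rx <- rbind(c(1, 0, 0), c(0, cg, -sg), c(0, sg, cg))
    rmsd(Pn %*% t(Rz %*% Ry %*% Rx) + rep(1, 50) %o% par[4:6], Qn)
  }
  opt <- stats::optim(c(0.1, 0.1, 0.1, 0, 0, 0), objective,
                      method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(abs(best - opt$value), 1e-6)

  # degenerate (coplanar) inputs are flagged but still minimized
  Pc <- cbind(stats::rnorm(10), stats::rnorm(10), 0)
  tfD <- superpose(Pc, Pc, allowReflection = FALSE)
  expect_true(tfD@degenerate)
  expect_lt(tfD@rmsd, 1e-12)
})

test_that("rmsd matches hand and loop computations and is symmetric", {
  P <- matrix(c(0, 0, 0), 1)
  Q <- matrix(c(3, 4, 0), 1)
  expect_equal(rmsd(P, Q), 5)
  expect_equal(rmsd(P, P), 0)
  A <- coords(randomStructure(25, seed = 18))
  B <- coords(randomStructure(25, seed = 19))
  loop <- sqrt(mean(vapply(1:25, function(i) sum((A[i, ] - B[i, ])^2),
                           numeric(1))))
  expect_equal(rmsd(A, B), loop)
  expect_equal(rmsd(A, B), rmsd(B, A))
})
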