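design10 <- TemporalDesign(50, 50, 10)

test_that("correlation matrix assembly honours the moment model", {
  K <- 4
  cM <- matrix(0.5, K, K); diag(cM) <- 0
  r0 <- diag(K)                         # off-diagonal r0 = 0
  R <- buildR(cM, r0, 1000, design10)
  expect_equal(R, diag(K), tolerance = 1e-12)
  # K = 2, fully linked pair: off-diagonal is r0 itself
  R2 <- buildR(matrix(0, 2, 2), matrix(c(1, 0.3, 0.3, 1), 2), 1000, design10)
  expect_equal(R2[1, 2], 0.3, tolerance = 1e-12)
  expect_identical(diag(R2), rep(1, 2))
  # unlinked entries are near zero: bounded by the c = 0.5 attenuation
  atten <- deltaCorrelation(0.5, 1, 1000, design10)
  R3 <- buildR(matrix(0.5, 2, 2) - diag(2) * 0.5,
               matrix(c(1, 0.8, 0.8, 1), 2), 1000, design10)
  expect_lt(abs(R3[1, 2]), 0.8 * atten + 1e-12)
  expect_error(buildR(matrix(0, 2, 2), matrix(c(1, 1.4, 1.4, 1), 2),
                      1000, design10), "r0 must lie")
})

test_that("pair-table input to buildR matches the matrix input", {
  pairs <- data.frame(i = c(1, 1, 2), j = c(2, 3, 3),
                      c = c(0, 0.1, 0.5), r0 = c(0.3, 0.2, 0.1))
  R <- buildR(pairs, Ne = 1000, design = design10)
  expect_equal(R[1, 2], 0.3, tolerance = 1e-12)
  expect_true(isSymmetric(R))
  expect_identical(dim(R), c(3L, 3L))
})

test_that("weighted eigen input preserves the trace K", {
  R <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(weightedEigenInput(R, c(0.5, 0.5)), R, tolerance = 1e-12)
  w <- c(0.2, 0.3, 0.5)
  W <- weightedEigenInput(diag(3), w)
  expect_equal(diag(W), 3 * w, tolerance = 1e-12)
  expect_equal(sum(diag(weightedEigenInput(R, c(0.7, 0.3)))), 2,
               tolerance = 1e-12)
  expect_error(weightedEigenInput(R, c(1, 2, 3) / 6), "length")
})

test_that("eigen spectrum: closed forms, block additivity, clipping", {
  expect_equal(lambdas(eigenSpectrum(diag(5))), rep(1, 5), tolerance = 1e-12)
  R2 <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(lambdas(eigenSpectrum(R2)), c(1.4, 0.6), tolerance = 1e-12)
  # block-diagonal spectrum is the union of the block spectra
  B <- matrix(0, 4, 4); B[1:2, 1:2] <- R2
  B[3:4, 3:4] <- matrix(c(1, -0.2, -0.2, 1), 2)
  expect_equal(lambdas(eigenSpectrum(B)),
               sort(c(1.4, 0.6, 1.2, 0.8), decreasing = TRUE),
               tolerance = 1e-10)
  # materially negative eigenvalues error under the strict contract ...
  bad <- matrix(c(1, 0.9, 0.9, 0.9, 1, -0.9, 0.9, -0.9, 1), 3)
  expect_error(eigenSpectrum(bad), "positive semi-definite")
  # ... and are clipped with the trace restored for estimated matrices
  l <- lambdas(eigenSpectrum(bad, clip = "all"))
  expect_true(all(l >= 0))
  expect_equal(sum(l), 3, tolerance = 1e-9)
})

test_that("Q-squared draws have the mixture moments and are seeded", {
  q <- sampleQ2(rep(1, 100), M = 50000, seed = 42)
  # chi-square_100: mean 100, variance 200 (3 MC SEs)
  expect_lt(abs(mean(q2Draws(q)) - 100), 3 * sqrt(200 / 50000))
  expect_lt(abs(var(q2Draws(q)) - 200), 3 * sqrt(2 * 200^2 / 50000) * 1.5)
  # degenerate rank-1 spectrum: K * chi-square_1
  K <- 20
  q1 <- sampleQ2(c(K, rep(0, K - 1)), M = 50000, seed = 7)
  expect_equal(unname(quantile(q2Draws(q1), 0.975)), K * qchisq(0.975, 1),
               tolerance = 0.05)
  expect_identical(q2Draws(sampleQ2(rep(1, 5), M = 2000, seed = 9)),
                   q2Draws(sampleQ2(rep(1, 5), M = 2000, seed = 9)))
  expect_error(sampleQ2(rep(1, 5), M = 10), "M must")
})

test_that("adjusted and chi-square F intervals agree for identity R", {
  K <- 200; FHat <- 0.02
  q <- sampleQ2(rep(1, K), M = 200000, seed = 1)
  adj <- ciForF(FHat, q, K)
  chi <- chisqCI(FHat, K)
  expect_equal(adj, chi, tolerance = 0.02)
  expect_identical(ciForF(0, q, K), c(0, 0))
  # chi-square interval anchors at K = 1
  c1 <- chisqCI(0.05, 1)
  expect_equal(c1[1], 0.05 / 5.0239, tolerance = 1e-4)
  expect_equal(c1[2], 0.05 / 0.000982, tolerance = 1e-3)
  # a more dispersed spectrum gives a wider interval at the same K
  disp <- sort(seq(0.1, 1.9, length.out = K), decreasing = TRUE)
  qd <- sampleQ2(disp, M = 200000, seed = 2)
  wide <- ciForF(FHat, qd, K)
  expect_lt(wide[1], adj[1])
  expect_gt(wide[2], adj[2])
  # and the chi-square interval sits inside the dispersed adjusted one
  expect_gt(chisqCI(FHat, K)[1], wide[1])
  expect_lt(chisqCI(FHat, K)[2], wide[2])
})

test_that("F bounds map anti-monotonically to Ne bounds", {
  dAg <- TemporalDesign(92, 45, 20)
  ne <- ciForNe(c(0.0171, 0.0196), dAg)
  expect_equal(ne[1], 3274.3, tolerance = 1e-3)
  expect_equal(ne[2], 18047.7, tolerance = 1e-3)
  expect_lt(ne[1], ne[2])
  # lower F bound below the sampling floor -> infinite upper Ne
  expect_identical(ciForNe(c(0.001, 0.03), design10)[2], Inf)
  degenerate <- ciForNe(c(0.025, 0.025), design10)
  expect_equal(degenerate[1], degenerate[2], tolerance = 1e-12)
  expect_error(ciForNe(c(0.03, 0.02), design10), "FLow")
})

test_that("effective number of independent loci spans its bounds", {
  expect_equal(effectiveNumLoci(rep(1, 50)), 50, tolerance = 1e-12)
  expect_equal(effectiveNumLoci(c(50, rep(0, 49))), 1, tolerance = 1e-12)
  # two perfectly correlated blocks of K/2 loci each
  K <- 10
  expect_equal(effectiveNumLoci(c(K / 2, K / 2, rep(0, K - 2))), 2,
               tolerance = 1e-12)
  expect_equal(effectiveNumLoci(eigenSpectrum(diag(7))), 7, tolerance = 1e-12)
})

test_that("adjustedCI assembles a coherent, reproducible NeEstimate", {
  p <- randomPanel(30, seed = 2)
  fa <- fStat(p, "a")
  spec <- eigenSpectrum(diag(30))
  est1 <- adjustedCI(fa, spec, design10, M = 5000, seed = 33)
  est2 <- adjustedCI(fa, spec, design10, M = 5000, seed = 33)
  expect_identical(est1, est2)
  expect_lte(est1@FciLow, est1@FHat)
  expect_gte(est1@FciHigh, est1@FHat)
  expect_identical(est1@K, 30L)
  expect_equal(est1@KPrime, 30, tolerance = 1e-9)
})
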