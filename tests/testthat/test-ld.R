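test_that("phased LD estimator matches haplotype-count arithmetic", {
  expect_equal(r0Phased(hapBlockFromCounts(25, 25, 25, 25), 1, 2), 0,
               tolerance = 1e-12)
  expect_equal(r0Phased(hapBlockFromCounts(5, 0, 0, 5), 1, 2), 1,
               tolerance = 1e-12)
  # counts (30,20,20,30): D = 0.3 - 0.25 = 0.05, r = 0.05/0.25 = 0.2
  expect_equal(r0Phased(hapBlockFromCounts(30, 20, 20, 30), 1, 2), 0.2,
               tolerance = 1e-12)
  expect_error(r0Phased(hapBlockFromCounts(50, 0, 50, 0), 1, 2),
               "monomorphic")
})

test_that("pairwise phased LD equals the single-pair estimator", {
  h <- withr::with_seed(3, {
    m <- matrix(rbinom(200 * 5, 1, 0.4), 200, 5)
    m[, 2] <- ifelse(runif(200) < 0.7, m[, 1], m[, 2])  # induce LD
    m
  })
  R <- pairwiseR0Phased(h)
  expect_identical(diag(R), rep(1, 5))
  for (pr in list(c(1, 2), c(2, 4), c(3, 5)))
    expect_equal(R[pr[1], pr[2]], r0Phased(h, pr[1], pr[2]),
                 tolerance = 1e-12)
})

test_that("EM estimator equals direct counting when phase is unambiguous", {
  # no double heterozygotes: genotypes resolve haplotypes exactly
  h <- hapBlockFromCounts(30, 20, 20, 30)
  g <- h[seq(1, 99, 2), ] + h[seq(2, 100, 2), ]
  dh <- g[, 1] == 1 & g[, 2] == 1
  g <- g[!dh, , drop = FALSE]
  hNo <- rbind(h[seq(1, 99, 2), ][!dh, ], h[seq(2, 100, 2), ][!dh, ])
  rEm <- r0Unphased(g, 1, 2)
  expect_true(attr(rEm, "converged"))
  expect_equal(as.numeric(rEm), r0Phased(hNo, 1, 2), tolerance = 1e-8)
  # perfectly coupled homozygote-only sample
  gHom <- rbind(matrix(2, 5, 2), matrix(0, 5, 2))
  expect_equal(as.numeric(r0Unphased(gHom, 1, 2)), 1, tolerance = 1e-8)
})

test_that("EM maximizes the Hardy-Weinberg multinomial likelihood", {
  g <- withr::with_seed(11, {
    hap <- hapBlockFromCounts(35, 15, 10, 40)
    o <- sample.int(100)
    hap[o[1:50], ] + hap[o[51:100], ]
  })
  rEm <- as.numeric(r0Unphased(g, 1, 2, tol = 1e-12))
  # brute-force grid over the one free haplotype frequency pAB
  pA <- mean(g[, 1]) / 2; pB <- mean(g[, 2]) / 2
  grid <- seq(max(0, pA + pB - 1) + 1e-9, min(pA, pB) - 1e-9,
              length.out = 40001)
  hapFreq <- cbind(grid, pA - grid, pB - grid, 1 - pA - pB + grid)
  idx <- function(x, y) 1 + (1 - x) * 2 + (1 - y)    # (1,1) -> pAB slot
  combos <- expand.grid(a = 0:1, b = 0:1, c = 0:1, d = 0:1)
  nCat <- table(factor(paste0(g[, 1], g[, 2]),
                       levels = as.vector(outer(0:2, 0:2, paste0))))
  loglik <- 0
  for (cat in names(nCat)) {
    if (nCat[[cat]] == 0) next
    gi <- as.integer(substr(cat, 1, 1)); gj <- as.integer(substr(cat, 2, 2))
    cc <- combos[combos$a + combos$c == gi & combos$b + combos$d == gj, ]
    prob <- rep(0, length(grid))
    for (r in seq_len(nrow(cc)))        # ordered maternal/paternal pairs
      prob <- prob + hapFreq[, idx(cc$a[r], cc$b[r])] *
                     hapFreq[, idx(cc$c[r], cc$d[r])]
    loglik <- loglik + nCat[[cat]] * log(pmax(prob, 1e-300))
  }
  pABbest <- grid[which.max(loglik)]
  D <- pABbest - pA * pB
  rBest <- D / sqrt(pA * (1 - pA) * pB * (1 - pB))
  expect_equal(rEm, rBest, tolerance = 1e-4)
})

test_that("vectorized pairwise EM agrees with the single-pair EM", {
  g <- withr::with_seed(5, {
    hap <- matrix(rbinom(120 * 4, 1, c(0.3, 0.5, 0.6, 0.4)), 120, 4,
                  byrow = TRUE)
    hap[, 3] <- ifelse(runif(120) < 0.6, hap[, 2], hap[, 3])
    hap[seq(1, 119, 2), ] + hap[seq(2, 120, 2), ]
  })
  R <- pairwiseR0Unphased(g)
  for (pr in list(c(1, 2), c(2, 3), c(1, 4)))
    expect_equal(R[pr[1], pr[2]],
                 as.numeric(r0Unphased(g, pr[1], pr[2])), tolerance = 1e-6)
  expect_identical(diag(R), rep(1, 4))
})

test_that("bias correction shrinks toward zero, preserving sign", {
  expect_identical(biasCorrectR0(0, 100), 0)
  expect_lt(abs(biasCorrectR0(0.1, 100)), 1e-6)   # r^2 = 1/n boundary
  expect_equal(biasCorrectR0(0.5, 100), sqrt(0.25 - 0.01), tolerance = 1e-9)
  r <- seq(-0.9, 0.9, by = 0.1)
  out <- biasCorrectR0(r, 50)
  expect_true(all(abs(out) <= abs(r) + 1e-12))
  expect_true(all(sign(out) == sign(r) | out == 0))
})

test_that("correction reduces squared-LD bias for truly unlinked loci", {
  res <- withr::with_seed(21, {
    K <- 60; n <- 100
    h <- matrix(rbinom(n * K, 1, rep(runif(K, 0.2, 0.8), each = n)), n, K)
    raw <- pairwiseR0Phased(h)
    cor0 <- biasCorrectR0(raw, n)
    ut <- upper.tri(raw)
    c(raw = mean(raw[ut]^2), corrected = mean(cor0[ut]^2))
  })
  expect_lt(res["corrected"], res["raw"] / 2)     # at least halves the bias
})

test_that("pairwise linkage table covers all pairs with the right c", {
  h <- withr::with_seed(9, matrix(rbinom(80 * 3, 1, 0.5), 80, 3))
  p <- LocusPanel(c("2L", "2L", "2R"), c(1000L, 1000L + 1e6L, 500L),
                  x0 = colMeans(h), xt = colMeans(h), hap0 = h)
  tab <- pairwiseLinkage(p, map = GeneticMap(rate = 1.4))
  expect_identical(nrow(tab), 3L)                 # K = 3 -> 3 pairs
  fr <- frequencies(p)
  same <- fr$chrom[tab$i] == fr$chrom[tab$j]
  expect_true(all(tab$c[!same] == 0.5))           # inter-arm rule
  d <- abs(fr$pos[tab$i] - fr$pos[tab$j])
  expect_equal(tab$c[same], haldaneC(d[same], GeneticMap(1.4)),
               tolerance = 1e-12)
  # zero distance means zero recombination
  expect_identical(haldaneC(0, GeneticMap(1.4)), 0)
})
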