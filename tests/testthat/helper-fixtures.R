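# Shared fixtures built in code.

# Tiny two-locus panel with hand-computable statistics.
tinyPanel <- function() {
  LocusPanel(chrom = c("1", "1"), pos = c(100L, 900L),
             x0 = c(0.5, 0.2), xt = c(0.6, 0.3))
}

# Haplotype block from the four gamete counts (AB, Ab, aB, ab).
hapBlockFromCounts <- function(nAB, nAb, naB, nab) {
  counts <- c(nAB, nAb, naB, nab)
  m <- cbind(rep(c(1, 1, 0, 0), counts), rep(c(1, 0, 1, 0), counts))
  colnames(m) <- c("L1", "L2")
  m
}

# Random panel of K loci with frequencies clear of the MAF boundary.
randomPanel <- function(K, seed = 1) {
  withr::with_seed(seed, {
    pos <- sort(sample.int(1e6, K))
    x0 <- runif(K, 0.1, 0.9)
    xt <- pmin(pmax(x0 + rnorm(K, 0, 0.05), 0.05), 0.95)
    LocusPanel(chrom = rep("1", K), pos = pos, x0 = x0, xt = xt)
  })
}

# Table 1 parameter grid (Ne, S, t) with the printed expected-F values.
table1Grid <- function() {
  data.frame(Ne = c(1000, 1000, 5000, 10000, 10000),
             S = c(50, 100, 100, 100, 100),
             t = 10,
             trueF = c(0.02494, 0.01496, 0.01099, 0.01050, 0.01050))
}

# Plan-II sample of 2S haplotypes from per-replicate haplotype frequencies
# (rows of freqs: pAB, pAb, paB, pab). Returns observed allele frequencies
# at the two loci, drawn jointly (whole haplotypes, not independent loci).
sampleHapFreqs <- function(freqs, S) {
  n <- nrow(freqs); size <- 2 * S
  n1 <- rbinom(n, size, freqs[, 1])
  r1 <- size - n1
  p2 <- ifelse(freqs[, 1] < 1, freqs[, 2] / (1 - freqs[, 1]), 0)
  n2 <- rbinom(n, r1, pmin(pmax(p2, 0), 1))
  r2 <- r1 - n2
  p3 <- ifelse(freqs[, 1] + freqs[, 2] < 1,
               freqs[, 3] / (1 - freqs[, 1] - freqs[, 2]), 0)
  n3 <- rbinom(n, r2, pmin(pmax(p3, 0), 1))
  list(xi = (n1 + n2) / size, xj = (n1 + n3) / size)
}
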