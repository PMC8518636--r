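#' Standardized LD from phased haplotypes
#'
#' r-hat = D-hat / sqrt(p_i (1-p_i) p_j (1-p_j)) with
#' D-hat = p_AB - p_A p_B estimated from haplotype counts. For 0/1
#' haplotype matrices this equals the Pearson correlation between the two
#' locus columns, which is how [pairwiseR0Phased()] computes all pairs at
#' once.
#'
#' @param block haplotype matrix (haplotypes x loci, entries 0/1).
#' @param i,j locus column indices.
#' @return r-hat in [-1, 1].
#' @export
r0Phased <- function(block, i, j) {
  gi <- block[, i]; gj <- block[, j]
  pA <- mean(gi); pB <- mean(gj)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    stop("monomorphic locus: r is undefined")
  pAB <- mean(gi == 1 & gj == 1)
  (pAB - pA * pB) / sqrt(pA * (1 - pA) * pB * (1 - pB))
}

#' All pairwise standardized LD from phased haplotypes
#'
#' @param block haplotype matrix (haplotypes x loci, entries 0/1); all
#'   loci must be polymorphic.
#' @return K x K symmetric matrix of raw r-hat with unit diagonal.
#' @export
pairwiseR0Phased <- function(block) {
  p <- colMeans(block)
  if (any(p %in% c(0, 1)))
    stop("monomorphic loci present: filter before LD estimation")
  r <- stats::cor(block)
  diag(r) <- 1
  r
}

# EM update machinery shared by the single-pair and pairwise estimators.
# Count layout: Ngh = number of individuals with dosage g at the row locus
# and dosage h at the column locus. Double heterozygotes (1,1) are the only
# phase-ambiguous class; alpha is the posterior coupling probability.
emHaplotypeFreqs <- function(N, nPair, maxIter, tol) {
  known <- list(
    AB = 2 * N[["22"]] + N[["21"]] + N[["12"]],
    Ab = 2 * N[["20"]] + N[["21"]] + N[["10"]],
    aB = 2 * N[["02"]] + N[["12"]] + N[["01"]],
    ab = 2 * N[["00"]] + N[["10"]] + N[["01"]])
  ndh <- N[["11"]]
  tot <- 2 * nPair
  pAB <- (known$AB + 0.5 * ndh) / tot
  pAb <- (known$Ab + 0.5 * ndh) / tot
  paB <- (known$aB + 0.5 * ndh) / tot
  pab <- (known$ab + 0.5 * ndh) / tot
  conv <- FALSE
  for (it in seq_len(maxIter)) {
    den <- pAB * pab + pAb * paB
    alpha <- ifelse(den > 0, pAB * pab / pmax(den, .Machine$double.xmin), 0.5)
    new_pAB <- (known$AB + alpha * ndh) / tot
    new_pAb <- (known$Ab + (1 - alpha) * ndh) / tot
    new_paB <- (known$aB + (1 - alpha) * ndh) / tot
    new_pab <- (known$ab + alpha * ndh) / tot
    delta <- pmax(abs(new_pAB - pAB), abs(new_pAb - pAb),
                  abs(new_paB - paB), abs(new_pab - pab))
    pAB <- new_pAB; pAb <- new_pAb; paB <- new_paB; pab <- new_pab
    if (all(delta < tol)) { conv <- TRUE; break }
  }
  list(pAB = pAB, pAb = pAb, paB = paB, pab = pab,
       converged = if (length(delta) == 1L) conv else delta < tol)
}

ldFromHapFreqs <- function(h) {
  pA <- h$pAB + h$pAb
  pB <- h$pAB + h$paB
  D <- h$pAB - pA * pB
  den <- sqrt(pA * (1 - pA) * pB * (1 - pB))
  ifelse(den > 0, D / den, 0)
}

#' Standardized LD from unphased genotypes (EM under Hardy-Weinberg)
#'
#' Maximum-likelihood haplotype frequencies for a pair of biallelic loci
#' from diploid dosage data, resolving the double-heterozygote phase
#' ambiguity by EM under Hardy-Weinberg. When the EM does not converge
#' within `maxIter` iterations the composite (Burrows) estimate, which
#' does not assume Hardy-Weinberg, is returned instead and flagged.
#'
#' @param block genotype dosage matrix (individuals x loci, entries
#'   0/1/2, NA allowed).
#' @param i,j locus column indices.
#' @param maxIter maximum EM iterations.
#' @param tol convergence tolerance on haplotype frequencies.
#' @return r-hat with attributes `converged` (logical) and `method`
#'   ("em" or "composite").
#' @export
r0Unphased <- function(block, i, j, maxIter = 100, tol = 1e-8) {
  gi <- block[, i]; gj <- block[, j]
  cc <- !is.na(gi) & !is.na(gj)
  gi <- gi[cc]; gj <- gj[cc]
  if (length(gi) < 2L) stop("need >= 2 complete-case individuals")
  if (length(unique(gi)) == 1L || length(unique(gj)) == 1L)
    stop("monomorphic locus: r is undefined")
  N <- list()
  for (g in 0:2) for (h in 0:2)
    N[[paste0(g, h)]] <- sum(gi == g & gj == h)
  fit <- emHaplotypeFreqs(N, length(gi), maxIter, tol)
  if (fit$converged) {
    r <- ldFromHapFreqs(fit)
    structure(r, converged = TRUE, method = "em")
  } else {
    structure(compositeR(gi, gj), converged = FALSE, method = "composite")
  }
}

# Burrows composite LD correlation (no Hardy-Weinberg assumption).
compositeR <- function(gi, gj) {
  n <- length(gi)
  pi <- mean(gi) / 2; pj <- mean(gj) / 2
  Delta <- mean(gi * gj) / 2 - 2 * pi * pj
  den <- sqrt(pi * (1 - pi) * pj * (1 - pj))
  if (den == 0) 0 else Delta / den
}

#' All pairwise standardized LD from unphased genotypes
#'
#' Vectorized EM over all K(K-1)/2 locus pairs at once (the nine genotype
#' joint-count matrices are formed by cross-products of dosage indicator
#' matrices, and the EM update is elementwise). Pairs whose EM has not
#' converged after `maxIter` iterations fall back to the composite
#' (Burrows) estimate.
#'
#' @inheritParams r0Unphased
#' @return K x K symmetric matrix of raw r-hat with unit diagonal and an
#'   attribute `nComposite` counting fallback pairs.
#' @export
pairwiseR0Unphased <- function(block, maxIter = 100, tol = 1e-8) {
  G <- as.matrix(block)
  M <- !is.na(G)
  G0 <- G; G0[!M] <- 0
  Ind <- lapply(0:2, function(g) (G0 == g & M) + 0)
  names(Ind) <- c("0", "1", "2")
  N <- list()
  for (g in 0:2) for (h in 0:2)
    N[[paste0(g, h)]] <- crossprod(Ind[[as.character(g)]],
                                   Ind[[as.character(h)]])
  nPair <- crossprod(M + 0)
  fit <- emHaplotypeFreqs(N, nPair, maxIter, tol)
  r <- ldFromHapFreqs(fit)
  bad <- !fit$converged
  diag(bad) <- FALSE
  if (any(bad)) {
    idx <- which(bad & upper.tri(bad), arr.ind = TRUE)
    for (k in seq_len(nrow(idx))) {
      i <- idx[k, 1]; j <- idx[k, 2]
      cc <- M[, i] & M[, j]
      rc <- compositeR(G[cc, i], G[cc, j])
      r[i, j] <- rc; r[j, i] <- rc
    }
  }
  diag(r) <- 1
  r <- (r + t(r)) / 2
  structure(r, nComposite = sum(bad & upper.tri(bad)))
}

#' Sampling-bias correction for estimated LD
#'
#' Finite samples induce LD even between truly independent loci
#' (E\[r-hat^2\] is inflated by about 1/n for n sampled haplotypes).
#' Uncorrected estimates therefore overstate the eigenvalue dispersion of
#' the delta-correlation matrix and make the adjusted intervals
#' conservative. This corrector subtracts the expected sampling
#' contribution on the r^2 scale and back-transforms preserving sign:
#' r0 = sign(r-hat) sqrt(max(0, r-hat^2 - 1/n)). It shrinks every
#' estimate toward zero and zeroes those within sampling noise.
#'
#' @param rhat raw LD estimate(s) (vector or matrix).
#' @param nUnits number of sampled units behind the estimate: 2*S0
#'   haplotypes for both the phased and the EM (unphased) estimators.
#' @return corrected r0, same shape as `rhat`; a unit diagonal in a
#'   matrix input is preserved.
#' @export
biasCorrectR0 <- function(rhat, nUnits) {
  if (nUnits < 2) stop("nUnits must be >= 2")
  out <- sign(rhat) * sqrt(pmax(0, rhat^2 - 1 / nUnits))
  if (is.matrix(rhat)) diag(out) <- diag(rhat)
  out
}

#' Pairwise linkage table for a locus panel
#'
#' For every unordered locus pair, the recombination fraction (Haldane
#' conversion of the bp distance for same-chromosome pairs; the map's
#' inter-arm rule otherwise) and the bias-corrected standardized LD in the
#' first temporal sample, estimated from the panel's phased haplotypes or
#' unphased genotypes.
#'
#' @param panel a [LocusPanel] with a time-0 sample attached.
#' @param map a [GeneticMap].
#' @param cFun optional function(distanceBp) overriding the map for
#'   same-chromosome pairs (used with simulated data where the
#'   per-adjacent-bp compounding rule is the truth).
#' @param nUnits sampling units for [biasCorrectR0()] (default: number of
#'   haplotypes 2*S0).
#' @param correct apply the bias correction (default TRUE).
#' @param maxIter,tol EM controls for unphased data.
#' @return a data.frame with columns i, j (locus indices into the sorted
#'   panel), c, r0.
#' @export
pairwiseLinkage <- function(panel, map = GeneticMap(), cFun = NULL,
                            nUnits = NULL, correct = TRUE,
                            maxIter = 100, tol = 1e-8) {
  stopifnot(is(panel, "LocusPanel"))
  lm <- linkageMatrices(panel, map = map, cFun = cFun, nUnits = nUnits,
                        correct = correct, maxIter = maxIter, tol = tol)
  K <- nLoci(panel)
  ut <- which(upper.tri(lm$c), arr.ind = TRUE)
  data.frame(i = ut[, 1], j = ut[, 2],
             c = lm$c[ut], r0 = lm$r0[ut])
}

# Matrix form used internally by the pipeline: list(c = K x K recombination
# fractions, r0 = K x K corrected LD).
linkageMatrices <- function(panel, map = GeneticMap(), cFun = NULL,
                            nUnits = NULL, correct = TRUE,
                            maxIter = 100, tol = 1e-8) {
  fr <- frequencies(panel)
  K <- nrow(fr)
  pos <- fr$pos
  if (any(is.na(pos))) stop("missing positions")
  dist <- abs(outer(pos, pos, "-"))
  cMat <- if (is.null(cFun)) haldaneC(dist, map) else cFun(dist)
  same <- outer(fr$chrom, fr$chrom, "==")
  if (any(!same)) {
    if (map@interArmRule != "unlinked")
      stop("through-map inter-arm distances require arm lengths; use pairwiseLinkage on one arm or the 'unlinked' rule")
    cMat[!same] <- 0.5
  }
  hap <- haplotypes0(panel)
  gen <- genotypes0(panel)
  if (!is.null(hap)) {
    r <- pairwiseR0Phased(hap)
    if (is.null(nUnits)) nUnits <- nrow(hap)
  } else if (!is.null(gen)) {
    r <- pairwiseR0Unphased(gen, maxIter = maxIter, tol = tol)
    if (is.null(nUnits)) nUnits <- 2 * nrow(gen)
  } else {
    stop("panel carries no time-0 haplotypes or genotypes for LD estimation")
  }
  if (correct) r <- biasCorrectR0(r, nUnits)
  list(c = cMat, r0 = r)
}
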