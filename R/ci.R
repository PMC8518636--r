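#' Correlation matrix of standardized allele-frequency changes
#'
#' Assembles the K x K matrix R whose (i, j) entry is the model
#' correlation of the standardized temporal changes delta_i, delta_j,
#' computed from the pairwise recombination fractions and first-sample LD
#' via [deltaCorrelation()], with a unit diagonal. The Ne plugged in is
#' normally the point estimate (the resulting intervals are insensitive to
#' even a 10-fold mis-specification of Ne).
#'
#' @param cMat K x K recombination fractions (or a pair data.frame from
#'   [pairwiseLinkage()]).
#' @param r0Mat K x K corrected LD matrix (ignored when `cMat` is a pair
#'   table).
#' @param Ne diploid Ne used in the correlation model.
#' @param design a [TemporalDesign].
#' @return K x K symmetric correlation matrix with unit diagonal.
#' @export
buildR <- function(cMat, r0Mat = NULL, Ne, design) {
  if (is.data.frame(cMat)) {
    pairs <- cMat
    K <- max(pairs$i, pairs$j)
    cM <- matrix(0, K, K); rM <- diag(K)
    ii <- cbind(pairs$i, pairs$j)
    cM[ii] <- pairs$c; cM[ii[, 2:1]] <- pairs$c
    rM[ii] <- pairs$r0; rM[ii[, 2:1]] <- pairs$r0
    cMat <- cM; r0Mat <- rM
  }
  R <- deltaCorrelation(cMat, r0Mat, Ne, design)
  diag(R) <- 1
  R <- (R + t(R)) / 2
  if (any(abs(R) > 1 + 1e-12))
    stop("correlation entries outside [-1, 1]: r0 estimates are invalid upstream")
  R
}

#' Weighted eigen input for the ratio-of-sums statistic
#'
#' The sampling distribution of the heterozygosity-weighted statistic
#' uses the eigenvalues of K W^1/2 R W^1/2, where W is the diagonal
#' matrix of the (unit-sum) weights. Its trace is K, like R's.
#'
#' @param R correlation matrix from [buildR()].
#' @param weights per-locus weights (sum to 1), e.g. from
#'   `fStat(panel, "b")`.
#' @return the K x K symmetric matrix K W^1/2 R W^1/2.
#' @export
weightedEigenInput <- function(R, weights) {
  if (is(weights, "FEstimate")) weights <- weights@weights
  K <- nrow(R)
  if (length(weights) != K) stop("weight length must match dim(R)")
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  sw <- sqrt(weights)
  K * (sw * R * rep(sw, each = K))   # K * W^1/2 R W^1/2
}

#' Eigenvalue spectrum of a delta-correlation model
#'
#' Eigenvalues of the symmetric input, descending. Tiny negative values
#' (numerical noise, > -clipTol) are clipped to zero; anything more
#' negative signals an invalid correlation model and errors unless
#' `clip = "all"`, in which case all negative eigenvalues are clipped and
#' the spectrum rescaled to restore the trace (used for empirically
#' estimated R, which is only approximately positive semi-definite).
#'
#' @param m symmetric matrix (R or its weighted form).
#' @param clip "strict" (default) or "all".
#' @param clipTol negativity tolerance under "strict" (default 1e-8 * K).
#' @return an [EigenSpectrum].
#' @export
eigenSpectrum <- function(m, clip = c("strict", "all"), clipTol = NULL) {
  clip <- match.arg(clip)
  K <- nrow(m)
  if (is.null(clipTol)) clipTol <- 1e-8 * K
  l <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (clip == "strict") {
    if (any(l < -clipTol))
      stop(sprintf("matrix is not positive semi-definite (min eigenvalue %.3g): broken correlation model upstream", min(l)))
    l[l < 0] <- 0
  } else {
    tr <- sum(diag(m))
    l[l < 0] <- 0
    if (sum(l) > 0) l <- l * tr / sum(l)   # restore trace => E[Q^2] preserved
  }
  new("EigenSpectrum", lambdas = sort(l, decreasing = TRUE))
}

#' Monte-Carlo sample of the Q-squared mixture
#'
#' Draws M realizations of Q^2 = sum_i lambda_i Z_i^2 with independent
#' standard-normal Z_i: the approximate distribution of K F-hat / F for
#' linked loci. E\[Q^2\] = sum(lambda) and var(Q^2) = 2 sum(lambda^2).
#' Draws are generated in blocks so very large K remains memory-safe.
#'
#' @param spectrum an [EigenSpectrum] (or numeric eigenvalues).
#' @param M number of draws (>= 1000; 10,000 is typical for simulation
#'   work, 50,000 for data analysis).
#' @param seed RNG seed for reproducibility (NULL leaves the stream).
#' @return a [QSquaredSample].
#' @export
sampleQ2 <- function(spectrum, M = 50000, seed = NULL) {
  l <- if (is(spectrum, "EigenSpectrum")) spectrum@lambdas else spectrum
  if (M < 1000) stop("M must be >= 1000")
  l <- l[l > 0]
  draws <- withSeed(seed, {
    if (length(l) == 0L) rep(0, M) else {
      K <- length(l)
      block <- max(1L, as.integer(ceiling(2e7 / K)))
      out <- numeric(M)
      done <- 0L
      while (done < M) {
        nb <- min(block, M - done)
        Z <- matrix(rnorm(K * nb), nrow = K)
        out[(done + 1L):(done + nb)] <- colSums(l * Z^2)
        done <- done + nb
      }
      out
    }
  })
  new("QSquaredSample", draws = draws,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Linkage-adjusted confidence interval for F
#'
#' Empirical-quantile interval
#' \[ K F-hat / q_{1-alpha/2}(Q^2), K F-hat / q_{alpha/2}(Q^2) \]
#' from a Monte-Carlo Q^2 sample. Quantiles are empirical with linear
#' interpolation between order statistics.
#'
#' @param FHat observed F statistic (numeric or [FEstimate]).
#' @param q2 a [QSquaredSample].
#' @param K number of loci behind FHat.
#' @param alpha two-sided error level (default 0.05).
#' @return c(FLow, FHigh).
#' @export
ciForF <- function(FHat, q2, K, alpha = 0.05) {
  if (is(FHat, "FEstimate")) { if (missing(K)) K <- FHat@K; FHat <- FHat@value }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  q <- quantile(q2Draws(q2), c(1 - alpha / 2, alpha / 2), names = FALSE,
                type = 7)
  c(K * FHat / q[1], K * FHat / q[2])
}

#' Chi-square confidence interval for F (independence assumed)
#'
#' The classical interval \[ K F-hat / chisq_{K,1-alpha/2},
#' K F-hat / chisq_{K,alpha/2} \], valid only when loci are independent;
#' for linked loci it is anti-conservative (too narrow).
#'
#' @inheritParams ciForF
#' @return c(FLow, FHigh).
#' @export
chisqCI <- function(FHat, K, alpha = 0.05) {
  if (is(FHat, "FEstimate")) { if (missing(K)) K <- FHat@K; FHat <- FHat@value }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  c(K * FHat / qchisq(1 - alpha / 2, df = K),
    K * FHat / qchisq(alpha / 2, df = K))
}

#' Convert an F interval into an Ne interval
#'
#' The F -> Ne map is anti-monotone: the lower F bound gives the upper Ne
#' bound and vice versa. A lower F bound at or below the sampling-noise
#' floor maps to an infinite upper Ne bound.
#'
#' @param FBounds c(FLow, FHigh) with FLow <= FHigh.
#' @param design a [TemporalDesign].
#' @param method inversion method passed to [estimateNe()].
#' @return c(NeLow, NeHigh) (NeHigh possibly Inf).
#' @export
ciForNe <- function(FBounds, design, method = "waples") {
  if (FBounds[1] > FBounds[2]) stop("FLow must be <= FHigh")
  c(estimateNe(FBounds[2], design, method),
    estimateNe(FBounds[1], design, method))
}

#' Effective number of independent loci
#'
#' K' = 2 K^2 / var(Q^2) = K^2 / sum(lambda^2): the number of independent
#' loci that would carry the same drift information as the K linked loci.
#' Equals K for an identity R and 1 when all loci are perfectly
#' correlated.
#'
#' @param spectrum an [EigenSpectrum] (or numeric eigenvalues).
#' @return K', in \[1, K\].
#' @export
effectiveNumLoci <- function(spectrum) {
  l <- if (is(spectrum, "EigenSpectrum")) spectrum@lambdas else spectrum
  length(l)^2 / sum(l^2)
}

#' One-call linkage-adjusted Ne interval from prepared components
#'
#' Convenience wrapper tying the interval chain together: eigenvalues ->
#' Q^2 sample -> F interval -> Ne interval, returning a full
#' [NeEstimate] record.
#'
#' @param FHat an [FEstimate] (or numeric; then `K` must be given).
#' @param spectrum an [EigenSpectrum].
#' @param design a [TemporalDesign].
#' @param M Q^2 draws.
#' @param alpha two-sided error level.
#' @param seed RNG seed for the Q^2 draws.
#' @param K number of loci (taken from `FHat` when it is an FEstimate).
#' @return an [NeEstimate].
#' @export
adjustedCI <- function(FHat, spectrum, design, M = 50000, alpha = 0.05,
                       seed = NULL, K = NULL) {
  variant <- "a"
  if (is(FHat, "FEstimate")) {
    variant <- FHat@variant; K <- FHat@K; FHat <- FHat@value
  }
  if (is.null(K)) stop("K is required when FHat is numeric")
  q2 <- sampleQ2(spectrum, M = M, seed = seed)
  fb <- ciForF(FHat, q2, K, alpha)
  ne <- ciForNe(fb, design)
  l <- lambdas(spectrum)
  new("NeEstimate",
      point = estimateNe(FHat, design), ciLow = ne[1], ciHigh = ne[2],
      FHat = FHat, FciLow = fb[1], FciHigh = fb[2],
      variant = variant, K = as.integer(K),
      KPrime = effectiveNumLoci(spectrum), M = as.integer(M),
      alpha = alpha,
      spectrumSummary = c(sumLambda = sum(l), sumLambda2 = sum(l^2)))
}
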