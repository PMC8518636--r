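#' One generation of the two-locus Wright-Fisher model
#'
#' Advances haplotype frequencies (pAB, pAb, paB, pab) by one generation:
#' recombination moves each frequency by +/- c*D (D = pAB*pab - pAb*paB),
#' then the next generation's haplotype counts are multinomial with size
#' 2Ne and the post-recombination gamete frequencies. Vectorized over
#' rows of `state` (independent replicate populations). Uses the current
#' R RNG stream.
#'
#' @param state numeric vector of length 4 or a replicates x 4 matrix of
#'   haplotype frequencies (each row sums to 1).
#' @param c recombination fraction in \[0, 0.5\].
#' @param Ne diploid population size.
#' @return haplotype frequencies after one generation, same shape as
#'   `state`.
#' @export
stepTwoLocus <- function(state, c, Ne) {
  if (c < 0 || c > 0.5) stop("c must lie in [0, 0.5]")
  v <- is.null(dim(state))
  if (v) state <- matrix(state, nrow = 1)
  if (ncol(state) != 4L) stop("state must have four haplotype frequencies")
  D <- state[, 1] * state[, 4] - state[, 2] * state[, 3]
  g1 <- state[, 1] - c * D
  g2 <- state[, 2] + c * D
  g3 <- state[, 3] + c * D
  g4 <- state[, 4] - c * D
  n <- nrow(state)
  size <- 2 * Ne
  # multinomial via conditional binomials, vectorized over replicates
  n1 <- rbinom(n, size, pmin(pmax(g1, 0), 1))
  r1 <- size - n1
  p2 <- ifelse(g1 < 1, g2 / (1 - g1), 0)
  n2 <- rbinom(n, r1, pmin(pmax(p2, 0), 1))
  r2 <- r1 - n2
  p3 <- ifelse(g1 + g2 < 1, g3 / (1 - g1 - g2), 0)
  n3 <- rbinom(n, r2, pmin(pmax(p3, 0), 1))
  n4 <- r2 - n3
  out <- cbind(n1, n2, n3, n4) / size
  colnames(out) <- c("pAB", "pAb", "paB", "pab")
  if (v) out[1, ] else out
}

#' Replicated two-locus Wright-Fisher trajectories
#'
#' Evolves `reps` independent populations from common initial haplotype
#' frequencies for t generations. This is the Monte-Carlo oracle for the
#' closed-form drift covariance and LD decay formulas.
#'
#' @param p0 initial haplotype frequencies (pAB, pAb, paB, pab).
#' @param c recombination fraction.
#' @param Ne diploid population size.
#' @param t generations (>= 0).
#' @param reps number of independent replicates.
#' @param seed RNG seed (NULL leaves the stream).
#' @return a replicates x 4 matrix of haplotype frequencies at generation
#'   t, with attributes `pi` / `pj` (allele-frequency vectors at the two
#'   loci) and `D` (per-replicate LD).
#' @export
simulateTwoLocus <- function(p0, c, Ne, t, reps, seed = NULL) {
  stopifnot(length(p0) == 4L, abs(sum(p0) - 1) < 1e-9, reps >= 1)
  state <- withSeed(seed, {
    s <- matrix(rep(p0, each = reps), nrow = reps)
    for (g in seq_len(t)) s <- stepTwoLocus(s, c, Ne)
    s
  })
  structure(state,
            pi = state[, 1] + state[, 2],
            pj = state[, 1] + state[, 3],
            D = state[, 1] * state[, 4] - state[, 2] * state[, 3])
}

#' Plan-II sample from a population haplotype matrix
#'
#' Draws 2S haplotypes with replacement from the population's gamete pool
#' (columns of the K x 2Ne matrix). Sampling does not perturb the
#' population, so the time-0 and time-t samples have zero cross-time
#' sampling covariance.
#'
#' @param population K x 2Ne haplotype matrix (loci in rows).
#' @param S diploid sample size.
#' @return K x 2S haplotype matrix.
#' @export
samplePlanII <- function(population, S) {
  if (S < 1) stop("S must be >= 1")
  population[, sample.int(ncol(population), 2 * S, replace = TRUE),
             drop = FALSE]
}

#' Collapse a haplotype sample into unphased genotypes
#'
#' Mimics unphased genotyping by randomly pairing the sampled haplotypes
#' into diploids (a random disjoint pairing) and summing each pair into a
#' dosage.
#'
#' @param hapSample K x 2S haplotype matrix.
#' @return S x K genotype dosage matrix (individuals in rows, matching
#'   the orientation expected by the unphased LD estimators).
#' @export
unphase <- function(hapSample) {
  n <- ncol(hapSample)
  if (n %% 2 != 0) stop("haplotype count must be even")
  o <- sample.int(n)
  t(hapSample[, o[seq(1, n, by = 2)], drop = FALSE] +
    hapSample[, o[seq(2, n, by = 2)], drop = FALSE])
}

#' Forward simulation of a two-sample chromosome
#'
#' Simulates a diploid Wright-Fisher population of size Ne carrying
#' `KInit` biallelic marker loci at random positions on a chromosome of
#' length L bp, with recombination between adjacent retained markers given
#' by the per-adjacent-bp compounding rule ([simulatedPairC()] on the bp
#' gap, which reproduces the pairwise rule exactly for every marker pair).
#' Founder allele frequencies are drawn from a neutral-like 1/x spectrum
#' truncated to \[1/(2Ne), 1 - 1/(2Ne)\] with independent loci; a burn-in
#' of max(4 / median pairwise c, Ne, 200) generations (capped at
#' `burnInCap`, overridable via `burnIn`) then lets LD reach
#' quasi-equilibrium with drift and recombination before the generation-0
#' snapshot (tightly linked pairs equilibrate on the drift time scale,
#' hence the Ne term). During burn-in, fixed columns are recycled as
#' singletons (see [SimConfig]), so the marker spectrum sits at its
#' neutral mutation-drift occupancy (density ~ 1/x) when the samples are
#' taken. Loci with population MAF below `maf` at either snapshot are
#' dropped, and at most `KTarget` loci are retained (uniform subsample).
#'
#' @param cfg a [SimConfig].
#' @return a list of class "ChromosomeSim": `H0`, `Ht` (K x 2Ne population
#'   haplotype matrices at generation 0 and t), `pos` (bp positions),
#'   `chrom`, `burnIn` (generations used), and `cfg`.
#' @export
simulateChromosome <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  withSeed(if (is.na(cfg@seed)) NULL else cfg@seed, {
    H <- 2L * cfg@Ne
    pos <- sort(sample.int(cfg@L, cfg@KInit))
    lo <- 1 / (2 * cfg@Ne)
    p0 <- lo * ((1 - lo) / lo)^runif(cfg@KInit)       # density ~ 1/x
    founders <- matrix(rbinom(cfg@KInit * H, 1L, rep(p0, times = H)),
                       nrow = cfg@KInit)
    cAdj <- simulatedPairC(diff(pos), cfg@perBpRate)
    burn <- cfg@burnIn
    if (is.na(burn)) {
      idx <- if (cfg@KInit <= 1000L) {
        d <- abs(outer(pos, pos, "-")); d[upper.tri(d)]
      } else {
        i <- sample.int(cfg@KInit, 2e5, replace = TRUE)
        j <- sample.int(cfg@KInit, 2e5, replace = TRUE)
        abs(pos[i] - pos[j])[i != j]
      }
      cMed <- stats::median(simulatedPairC(idx, cfg@perBpRate))
      burn <- min(cfg@burnInCap,
                  max(ceiling(4 / max(cMed, 1e-6)), cfg@Ne, 200L))
    }
    sim <- .forwardSimCpp(founders, cAdj, as.integer(burn), cfg@t,
                          cfg@mu, cfg@recycle)
    f0 <- rowMeans(sim$H0)
    ft <- rowMeans(sim$Ht)
    keep <- which(pmin(f0, 1 - f0) >= cfg@maf & pmin(ft, 1 - ft) >= cfg@maf)
    if (length(keep) < cfg@KTarget)
      warning(sprintf("only %d of the targeted %d loci passed the population MAF screen",
                      length(keep), cfg@KTarget))
    else if (length(keep) > cfg@KTarget)
      keep <- sort(keep[sample.int(length(keep), cfg@KTarget)])
    structure(list(H0 = sim$H0[keep, , drop = FALSE],
                   Ht = sim$Ht[keep, , drop = FALSE],
                   pos = pos[keep], chrom = "1",
                   burnIn = as.integer(burn), cfg = cfg),
              class = "ChromosomeSim")
  })
}

#' @export
print.ChromosomeSim <- function(x, ...) {
  cat(sprintf("ChromosomeSim: %d retained loci, 2Ne = %d haplotypes, burn-in %d + %d generations\n",
              nrow(x$H0), ncol(x$H0), x$burnIn, x$cfg@t))
  invisible(x)
}

# Analyse one simulated replicate: plan-II sampling, MAF screen, F-hat,
# Ne point, estimated R from the time-0 sample, adjusted + chi-square CI.
analyseReplicate <- function(sim, design, maf, M, alpha,
                             variants = "a", estimators = "phased") {
  cfg <- sim$cfg
  s0 <- samplePlanII(sim$H0, design@S0)
  st <- samplePlanII(sim$Ht, design@St)
  x0 <- rowMeans(s0)
  xt <- rowMeans(st)
  keep <- pmin(x0, 1 - x0) >= maf & pmin(xt, 1 - xt) >= maf
  K <- sum(keep)
  if (K < 2L) return(NULL)
  x0 <- x0[keep]; xt <- xt[keep]
  pos <- sim$pos[keep]
  h0 <- x0 * (1 - x0)
  dsq <- (xt - x0)^2
  cMat <- simulatedPairC(abs(outer(pos, pos, "-")), cfg@perBpRate)
  res <- list(K = K)
  FHat <- c(a = mean(dsq / h0), b = sum(dsq) / sum(h0))
  NeHat <- estimateNe(FHat[["a"]], design)
  res$Fa <- FHat[["a"]]; res$Fb <- FHat[["b"]]; res$Ne <- NeHat
  for (est in estimators) {
    rhat <- if (est == "phased") {
      pairwiseR0Phased(t(s0[keep, , drop = FALSE]))
    } else {
      pairwiseR0Unphased(unphase(s0[keep, , drop = FALSE]))
    }
    r0 <- biasCorrectR0(rhat, 2 * design@S0)
    R <- buildR(cMat, r0, NeHat, design)
    for (v in variants) {
      m <- if (v == "a") R else weightedEigenInput(R, h0 / sum(h0))
      spec <- eigenSpectrum(m, clip = "all")
      q2 <- sampleQ2(spec, M = M)
      res[[paste0("ciF_", v, "_", est)]] <-
        ciForF(FHat[[v]], q2, K, alpha)
      res[[paste0("KPrime_", v, "_", est)]] <- effectiveNumLoci(spec)
    }
  }
  res$ciChisq <- chisqCI(FHat[["a"]], K, alpha)
  res
}

#' Replicate coverage study of the linkage-adjusted intervals
#'
#' Repeats the full estimation chain on independent forward simulations of
#' one parameter regime: simulate a chromosome, take the two plan-II
#' samples, apply the MAF screen, compute the temporal F statistic(s) and
#' the Ne point estimate, estimate pairwise r0 from the generation-0
#' sample (with bias correction), build the delta-correlation matrix using
#' the estimated Ne, and form the linkage-adjusted and chi-square
#' confidence intervals. Reports per-replicate results and the fractions
#' of replicates whose intervals cover the true F implied by the
#' simulation's Ne and design.
#'
#' @param cfg a [SimConfig] describing the regime (its `seed` slot is
#'   ignored in favour of `seed`).
#' @param nReps number of independent replicates.
#' @param M Q^2 draws per replicate (default 10,000, the simulation-study
#'   convention; data analyses typically use 50,000).
#' @param alpha two-sided error level.
#' @param variants F-statistic variants to assess ("a", optionally also
#'   "b").
#' @param estimators LD estimation paths ("phased", optionally also
#'   "unphased").
#' @param seed RNG seed driving the whole study.
#' @return a list of class "ReplicateStudy": `summary` (one-row
#'   data.frame: regime, true F, mean/SD of F-hat, Ne from the mean,
#'   coverage fractions) and `replicates` (per-replicate data.frame).
#' @export
runReplicateStudy <- function(cfg, nReps, M = 10000, alpha = 0.05,
                              variants = "a", estimators = "phased",
                              seed = NULL) {
  stopifnot(is(cfg, "SimConfig"), nReps >= 1)
  design <- TemporalDesign(cfg@S0, cfg@St, cfg@t)
  trueF <- expectedF(cfg@Ne, design)
  cfgNoSeed <- cfg; cfgNoSeed@seed <- NA_integer_
  rows <- withSeed(seed, {
    out <- vector("list", nReps)
    for (r in seq_len(nReps)) {
      # a handful of loci short of KTarget is routine; tolerated silently
      sim <- withCallingHandlers(
        simulateChromosome(cfgNoSeed),
        warning = function(w) invokeRestart("muffleWarning"))
      a <- analyseReplicate(sim, design, cfg@maf, M, alpha,
                            variants = variants, estimators = estimators)
      if (is.null(a)) next
      row <- data.frame(rep = r, K = a$K, Fa = a$Fa, Fb = a$Fb, Ne = a$Ne)
      for (est in estimators) for (v in variants) {
        ci <- a[[paste0("ciF_", v, "_", est)]]
        row[[paste0("cover_", v, "_", est)]] <-
          ci[1] <= trueF && trueF <= ci[2]
        row[[paste0("KPrime_", v, "_", est)]] <-
          a[[paste0("KPrime_", v, "_", est)]]
      }
      row$cover_chisq <- a$ciChisq[1] <= trueF && trueF <= a$ciChisq[2]
      out[[r]] <- row
    }
    do.call(rbind, out)
  })
  summ <- data.frame(Ne = cfg@Ne, meanK = mean(rows$K),
                     S0 = cfg@S0, St = cfg@St, t = cfg@t,
                     nReps = nrow(rows), trueF = trueF,
                     meanFa = mean(rows$Fa), sdFa = stats::sd(rows$Fa),
                     NeFromMeanFa = estimateNe(mean(rows$Fa), design),
                     meanFb = mean(rows$Fb), sdFb = stats::sd(rows$Fb))
  for (nm in grep("^cover", names(rows), value = TRUE))
    summ[[nm]] <- mean(rows[[nm]])
  structure(list(summary = summ, replicates = rows),
            class = "ReplicateStudy")
}

#' @export
print.ReplicateStudy <- function(x, ...) {
  s <- x$summary
  cat(sprintf("ReplicateStudy: Ne = %d, mean K = %.0f, S0/St = %d/%d, t = %d, %d replicates\n",
              s$Ne, s$meanK, s$S0, s$St, s$t, s$nReps))
  cat(sprintf("  true F = %.5f, mean F-hat(a) = %.5f (Ne %.0f), SD %.5f\n",
              s$trueF, s$meanFa, s$NeFromMeanFa, s$sdFa))
  for (nm in grep("^cover", names(s), value = TRUE))
    cat(sprintf("  %s coverage = %.3f\n", sub("^cover_", "", nm), s[[nm]]))
  invisible(x)
}
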