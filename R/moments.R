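#' Haldane mapping function on physical distance
#'
#' Converts a physical distance in bp to a recombination fraction c using a
#' uniform recombination rate (cM/Mb) and Haldane's interference-free
#' mapping function c = (1 - exp(-2d))/2, with d the map distance in
#' Morgans.
#'
#' @param distanceBp physical distance in bp (vectorized, >= 0).
#' @param map a [GeneticMap] (its `rate` slot is used), or a single numeric
#'   rate in cM/Mb.
#' @return recombination fraction(s) in [0, 0.5).
#' @examples
#' haldaneC(1e6, GeneticMap(rate = 1.4))   # ~0.0138
#' @export
haldaneC <- function(distanceBp, map = GeneticMap()) {
  if (any(distanceBp < 0)) stop("distanceBp must be >= 0")
  rate <- if (is(map, "GeneticMap")) map@rate else map
  d <- distanceBp * rate * 1e-8   # Morgans: cM/Mb = 1e-8 Morgan/bp
  0.5 * (1 - exp(-2 * d))
}

#' Pairwise recombination fraction from a per-adjacent-bp rate
#'
#' The recombination fraction between two loci y bp apart when each
#' adjacent-bp interval recombines independently with frequency
#' `perBpRate`: c = (1 - (1 - 2*perBpRate)^y)/2. This is the compounding
#' rule used by the forward simulator.
#'
#' @param distanceBp distance in bp (vectorized, >= 0).
#' @param perBpRate recombination frequency between adjacent bp, in
#'   [0, 0.5].
#' @return recombination fraction(s) in [0, 0.5].
#' @examples
#' simulatedPairC(1e4, 1e-5)   # ~0.0906
#' @export
simulatedPairC <- function(distanceBp, perBpRate = 1e-5) {
  if (any(distanceBp < 0)) stop("distanceBp must be >= 0")
  if (perBpRate < 0 || perBpRate > 0.5)
    stop("perBpRate must lie in [0, 0.5]")
  0.5 * (1 - (1 - 2 * perBpRate)^distanceBp)
}

#' Drift covariance of true allele frequencies at two linked loci
#'
#' Covariance of the true allele frequencies p_it and p_jt after t
#' generations of Wright-Fisher drift with recombination fraction c,
#' starting from linkage disequilibrium D0. This is exact for the discrete
#' two-locus multinomial model:
#' cov = D0 (1-c) \[1 - (1-1/(2Ne))^t (1-c)^t\] / (2Ne c + 1 - c).
#' At c = 0 it reduces to the single-locus drift variance factor
#' D0 \[1 - (1-1/(2Ne))^t\]; at t = 0 it is 0.
#'
#' @param D0 initial (unstandardized) LD between the pair.
#' @param c recombination fraction in [0, 0.5] (vectorized).
#' @param Ne diploid effective size (> 0, may be Inf).
#' @param t generations (>= 0).
#' @return covariance(s) of the two allele frequencies at generation t.
#' @export
driftCovariance <- function(D0, c, Ne, t) {
  if (any(c < 0 | c > 0.5)) stop("c must lie in [0, 0.5]")
  if (t < 0) stop("t must be >= 0")
  a <- driftRetention(Ne, t) * (1 - c)^t
  if (is.infinite(Ne)) return(0 * c)   # no drift
  D0 * (1 - c) * (1 - a) / (2 * Ne * c + 1 - c)
}

#' Expected decay of linkage disequilibrium
#'
#' E\[D_t\] = (1-1/(2Ne))^t (1-c)^t D0: LD decays through recombination and
#' is eroded by drift.
#'
#' @inheritParams driftCovariance
#' @return expected LD at generation t.
#' @export
expectedDDecay <- function(D0, c, Ne, t) {
  if (t < 0) stop("t must be >= 0")
  driftRetention(Ne, t) * (1 - c)^t * D0
}

#' Variance of the standardized allele-frequency change
#'
#' Under sampling plan II the standardized change
#' delta_i = (x_it - x_i0)/sqrt(x_i0 (1 - x_i0)) has variance
#' var(delta) = 1/(2 S0) + 1 - (1-1/(2Ne))^t (1 - 1/(2 St)),
#' identical across loci. This is the expected value F of the temporal F
#' statistics, and the quantity inverted for the Ne point estimate.
#'
#' @param Ne diploid effective size (> 0, may be Inf).
#' @param design a [TemporalDesign].
#' @return var(delta), a single number.
#' @examples
#' deltaVariance(1000, TemporalDesign(50, 50, 10))   # 0.02494
#' @export
deltaVariance <- function(Ne, design) {
  stopifnot(is(design, "TemporalDesign"))
  1 / (2 * design@S0) + 1 -
    driftRetention(Ne, design@t) * (1 - 1 / (2 * design@St))
}

#' Covariance of standardized changes at two linked loci
#'
#' cov(delta_i, delta_j) = r0 \[ 1/(2 S0) + B - (1-1/(2Ne))^t (1-c)^t
#' (B - 1/(2 St)) \] with B = (1-c)/(2Ne c + 1 - c): the between-locus
#' covariance of the temporal drift + sampling signal, proportional to the
#' standardized LD r0 in the first temporal sample. At c = 0, r0 = 1 it
#' reduces exactly to [deltaVariance()].
#'
#' @param c recombination fraction(s) in [0, 0.5] (vectorized).
#' @param r0 standardized LD in the first temporal sample, in [-1, 1]
#'   (vectorized, recycled against c).
#' @param Ne diploid effective size.
#' @param design a [TemporalDesign].
#' @return covariance(s) of the standardized changes.
#' @export
deltaCovariance <- function(c, r0, Ne, design) {
  stopifnot(is(design, "TemporalDesign"))
  if (any(c < 0 | c > 0.5)) stop("c must lie in [0, 0.5]")
  if (any(abs(r0) > 1)) stop("r0 must lie in [-1, 1]")
  B <- if (is.infinite(Ne)) 0 * c else (1 - c) / (2 * Ne * c + 1 - c)
  A <- driftRetention(Ne, design@t) * (1 - c)^design@t
  r0 * (1 / (2 * design@S0) + B - A * (B - 1 / (2 * design@St)))
}

#' Correlation of standardized changes at two linked loci
#'
#' The quotient of [deltaCovariance()] and [deltaVariance()], using the
#' equal-variance property of the standardized changes (the variance
#' depends only on Ne, S0, St, t). Equals r0 at c = 0 and shrinks
#' monotonically toward the unlinked limit as c grows.
#'
#' @inheritParams deltaCovariance
#' @return correlation(s), |corr| <= |r0|.
#' @export
deltaCorrelation <- function(c, r0, Ne, design) {
  deltaCovariance(c, r0, Ne, design) / deltaVariance(Ne, design)
}

#' Expected temporal F
#'
#' The expectation of the temporal F statistics under plan II, identical
#' to [deltaVariance()]: F = 1/(2 S0) + 1 - (1-1/(2Ne))^t (1 - 1/(2 St)).
#' Holds for linked as well as independent loci (linkage changes the
#' sampling distribution of F-hat, not its expectation).
#'
#' @inheritParams deltaVariance
#' @return expected F, a single number.
#' @export
expectedF <- function(Ne, design) deltaVariance(Ne, design)

#' Point estimate of Ne from a temporal F statistic
#'
#' The plan-II moment inversion of the expected-F formula. The default
#' `method = "waples"` is the small-drift approximation
#' Ne = t / (2 (F - 1/(2 S0) - 1/(2 St))); `method = "exact"` solves the
#' expected-F formula exactly for (1-1/(2Ne))^t. When the observed F does
#' not exceed the pure sampling-noise floor 1/(2 S0) + 1/(2 St) the drift
#' signal is indistinguishable from zero and +Inf is returned (never a
#' negative Ne).
#'
#' @param FHat observed temporal F statistic (numeric(1) or an
#'   [FEstimate]).
#' @param design a [TemporalDesign].
#' @param method "waples" (default, matches the classical estimator) or
#'   "exact".
#' @return Ne point estimate in diploids (possibly +Inf).
#' @examples
#' estimateNe(0.02404, TemporalDesign(50, 50, 10))   # ~1238
#' @export
estimateNe <- function(FHat, design, method = c("waples", "exact")) {
  stopifnot(is(design, "TemporalDesign"))
  method <- match.arg(method)
  if (is(FHat, "FEstimate")) FHat <- FHat@value
  floorF <- 1 / (2 * design@S0) + 1 / (2 * design@St)
  if (method == "waples") {
    denom <- 2 * (FHat - floorF)
    if (denom <= 0) return(Inf)
    design@t / denom
  } else {
    # solve F = 1/(2S0) + 1 - G (1 - 1/(2St)) with G = (1-1/(2Ne))^t
    G <- (1 - FHat + 1 / (2 * design@S0)) / (1 - 1 / (2 * design@St))
    if (G >= 1) return(Inf)
    if (G <= 0) stop("FHat too large: no Wright-Fisher Ne reproduces it")
    1 / (2 * (1 - G^(1 / design@t)))
  }
}
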