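#' Temporal sampling design
#'
#' Container for the design constants of a two-sample temporal experiment:
#' the diploid sample sizes at the two time points and the number of
#' Wright-Fisher generations separating them. All moment formulas in the
#' package are conditional on these three constants (sampling plan II:
#' individuals are sampled with replacement, or after reproduction, so
#' sampling does not perturb the breeding population).
#'
#' @slot S0 integer(1), diploid sample size at generation 0 (so 2*S0
#'   haplotypes).
#' @slot St integer(1), diploid sample size at generation t.
#' @slot t integer(1), generations between the two samples.
#'
#' @examples
#' TemporalDesign(S0 = 50, St = 50, t = 10)
#' @name TemporalDesign-class
#' @aliases TemporalDesign-class
#' @exportClass TemporalDesign
setClass("TemporalDesign",
  representation(S0 = "integer", St = "integer", t = "integer"),
  validity = function(object) {
    msg <- character()
    for (s in c("S0", "St", "t")) {
      v <- slot(object, s)
      if (length(v) != 1L || is.na(v) || v < 1L)
        msg <- c(msg, sprintf("%s must be a single integer >= 1", s))
    }
    if (length(msg)) msg else TRUE
  }
)

#' @param S0,St diploid sample sizes at generation 0 and t.
#' @param t generations between samples.
#' @return `TemporalDesign()` returns a TemporalDesign object.
#' @rdname TemporalDesign-class
#' @export
TemporalDesign <- function(S0, St, t) {
  stopifnot(S0 == as.integer(S0), St == as.integer(St), t == as.integer(t))
  new("TemporalDesign", S0 = as.integer(S0), St = as.integer(St),
      t = as.integer(t))
}

setMethod("show", "TemporalDesign", function(object) {
  cat(sprintf("TemporalDesign: S0 = %d, St = %d diploids, t = %d generations\n",
              object@S0, object@St, object@t))
})

#' Uniform genetic map
#'
#' A uniform recombination map: a single genome-wide rate in centimorgan per
#' megabase, plus the rule applied to locus pairs on different chromosomes
#' or chromosome arms ("unlinked" treats them as freely recombining,
#' c = 0.5).
#'
#' @slot rate numeric(1), recombination rate in cM/Mb (> 0).
#' @slot interArmRule character(1), either "unlinked" or "through-map".
#'
#' @examples
#' GeneticMap(rate = 1.4)
#' @name GeneticMap-class
#' @exportClass GeneticMap
setClass("GeneticMap",
  representation(rate = "numeric", interArmRule = "character"),
  prototype(rate = 1.4, interArmRule = "unlinked"),
  validity = function(object) {
    if (length(object@rate) != 1L || !is.finite(object@rate) ||
        object@rate <= 0)
      return("rate must be a single finite value > 0 (cM/Mb)")
    if (!object@interArmRule %in% c("unlinked", "through-map"))
      return("interArmRule must be 'unlinked' or 'through-map'")
    TRUE
  }
)

#' @param rate recombination rate, cM/Mb.
#' @param interArmRule rule for pairs on different chromosomes/arms.
#' @return `GeneticMap()` returns a GeneticMap object.
#' @rdname GeneticMap-class
#' @export
GeneticMap <- function(rate = 1.4, interArmRule = c("unlinked", "through-map")) {
  new("GeneticMap", rate = rate, interArmRule = match.arg(interArmRule))
}

setMethod("show", "GeneticMap", function(object) {
  cat(sprintf("GeneticMap: %.3g cM/Mb, inter-arm rule '%s'\n",
              object@rate, object@interArmRule))
})

#' Panel of biallelic loci observed at two time points
#'
#' Holds, for K biallelic loci, the genomic coordinates and the observed
#' frequencies of the tracked allele at generation 0 (`x0`) and generation
#' t (`xt`), plus — when available — the time-0 haplotype matrix (phased
#' data) or genotype dosage matrix (unphased data) from which pairwise LD
#' in the first temporal sample is estimated.
#'
#' @slot loci a [GenomicRanges::GRanges] with one range per locus (width-1
#'   positions, 1-based) and metadata columns `id`, `x0`, `xt`.
#' @slot hap0 numeric matrix (2*S0 haplotypes x K loci) with 0/1 entries,
#'   or a 0 x 0 matrix when phased data are unavailable.
#' @slot geno0 numeric matrix (S0 individuals x K loci) with dosages
#'   0/1/2 (NA for missing), or a 0 x 0 matrix when unavailable.
#' @slot phased logical(1), whether `hap0` is populated.
#'
#' @examples
#' lp <- LocusPanel(chrom = c("3R", "3R"), pos = c(100L, 900L),
#'                  x0 = c(0.5, 0.2), xt = c(0.6, 0.3))
#' nLoci(lp)
#' @name LocusPanel-class
#' @exportClass LocusPanel
setClass("LocusPanel",
  representation(loci = "GRanges", hap0 = "matrix", geno0 = "matrix",
                 phased = "logical"),
  validity = function(object) {
    msg <- character()
    mc <- S4Vectors::mcols(object@loci)
    if (!all(c("id", "x0", "xt") %in% colnames(mc)))
      return("loci must carry metadata columns id, x0, xt")
    if (length(object@loci) < 1L)
      msg <- c(msg, "panel must contain at least one locus")
    x0 <- mc$x0; xt <- mc$xt
    if (any(x0 < 0 | x0 > 1, na.rm = TRUE) || any(xt < 0 | xt > 1, na.rm = TRUE))
      msg <- c(msg, "frequencies must lie in [0, 1]")
    if (nrow(object@hap0) > 0L && ncol(object@hap0) != length(object@loci))
      msg <- c(msg, "hap0 must have one column per locus")
    if (nrow(object@geno0) > 0L && ncol(object@geno0) != length(object@loci))
      msg <- c(msg, "geno0 must have one column per locus")
    if (length(msg)) msg else TRUE
  }
)

#' @param chrom chromosome / chromosome-arm labels.
#' @param pos 1-based bp positions.
#' @param x0,xt observed tracked-allele frequencies at the two time points.
#' @param id optional locus labels (default chrom:pos).
#' @param hap0 optional time-0 haplotype matrix (rows = haplotypes).
#' @param geno0 optional time-0 genotype dosage matrix (rows = individuals).
#' @return `LocusPanel()` returns a LocusPanel, sorted by (chrom, pos).
#' @rdname LocusPanel-class
#' @export
LocusPanel <- function(chrom, pos, x0, xt, id = NULL,
                       hap0 = NULL, geno0 = NULL) {
  K <- length(pos)
  stopifnot(length(chrom) == K, length(x0) == K, length(xt) == K)
  if (is.null(id)) id <- paste0(chrom, ":", pos)
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(id = id, x0 = x0, xt = xt)
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  gr <- gr[o]
  emptym <- matrix(numeric(0), 0, 0)
  if (!is.null(hap0)) hap0 <- hap0[, o, drop = FALSE]
  if (!is.null(geno0)) geno0 <- geno0[, o, drop = FALSE]
  new("LocusPanel", loci = gr,
      hap0 = if (is.null(hap0)) emptym else hap0,
      geno0 = if (is.null(geno0)) emptym else geno0,
      phased = !is.null(hap0))
}

setMethod("show", "LocusPanel", function(object) {
  cat(sprintf("LocusPanel: %d loci on %d chromosome(s); %s\n",
              length(object@loci),
              length(unique(as.character(GenomicRanges::seqnames(object@loci)))),
              if (object@phased) sprintf("phased time-0 sample (%d haplotypes)",
                                         nrow(object@hap0))
              else if (nrow(object@geno0) > 0L)
                sprintf("unphased time-0 sample (%d diploids)", nrow(object@geno0))
              else "no time-0 genotypes attached"))
})

#' Temporal F statistic
#'
#' Value of a temporal F statistic over K loci, in either the arithmetic
#' ("a", sum-of-ratios) or ratio-of-sums ("b") form, together with the
#' per-locus heterozygosity weights that express variant "b" as a weighted
#' average of squared standardized changes.
#'
#' @slot value numeric(1), the statistic (>= 0).
#' @slot variant "a" or "b".
#' @slot K integer(1), number of loci used.
#' @slot weights numeric(K); for variant "b" the normalized heterozygosity
#'   weights (sum to 1); for variant "a" the uniform weights 1/K.
#' @name FEstimate-class
#' @exportClass FEstimate
setClass("FEstimate",
  representation(value = "numeric", variant = "character", K = "integer",
                 weights = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@value < 0) msg <- c(msg, "value must be >= 0")
    if (!object@variant %in% c("a", "b")) msg <- c(msg, "variant must be 'a' or 'b'")
    if (length(object@weights) != object@K)
      msg <- c(msg, "weights must have length K")
    if (any(object@weights < 0) || abs(sum(object@weights) - 1) > 1e-8)
      msg <- c(msg, "weights must be non-negative and sum to 1")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "FEstimate", function(object) {
  cat(sprintf("FEstimate (variant %s): F = %.6g over K = %d loci\n",
              object@variant, object@value, object@K))
})

#' Eigenvalue spectrum of a delta-correlation model
#'
#' Descending eigenvalues of the K x K correlation matrix R of standardized
#' allele-frequency changes (or of the weighted matrix K W^1/2 R W^1/2 for
#' the ratio-of-sums statistic), clipped at zero. The eigenvalue sum equals
#' the trace K; the sum of squares controls the dispersion of the
#' chi-square mixture and hence the width of linkage-adjusted intervals.
#'
#' @slot lambdas numeric(K), eigenvalues, descending, >= 0.
#' @name EigenSpectrum-class
#' @exportClass EigenSpectrum
setClass("EigenSpectrum",
  representation(lambdas = "numeric"),
  validity = function(object) {
    if (any(object@lambdas < 0)) return("eigenvalues must be >= 0")
    if (is.unsorted(rev(object@lambdas))) return("eigenvalues must be descending")
    TRUE
  }
)

setMethod("show", "EigenSpectrum", function(object) {
  l <- object@lambdas
  cat(sprintf("EigenSpectrum: K = %d, sum = %.4f, sum of squares = %.4f, K' = %.1f\n",
              length(l), sum(l), sum(l^2), length(l)^2 / sum(l^2)))
})

#' Monte-Carlo sample of the Q-squared mixture
#'
#' Realizations of Q^2 = sum_i lambda_i Z_i^2, the approximate distribution
#' of K*F_hat/F for linked loci. Reduces to a chi-square with K degrees of
#' freedom when all eigenvalues equal 1 (independent loci).
#'
#' @slot draws numeric(M), Monte-Carlo realizations (>= 0).
#' @slot seed integer(1), RNG seed used (NA if none supplied).
#' @name QSquaredSample-class
#' @exportClass QSquaredSample
setClass("QSquaredSample",
  representation(draws = "numeric", seed = "integer"),
  validity = function(object) {
    if (length(object@draws) < 1000L)
      return("at least 1000 Q^2 draws are required")
    if (any(object@draws < 0)) return("Q^2 draws must be >= 0")
    TRUE
  }
)

setMethod("show", "QSquaredSample", function(object) {
  cat(sprintf("QSquaredSample: M = %d draws, mean = %.2f, var = %.2f\n",
              length(object@draws), mean(object@draws), var(object@draws)))
})

#' Ne estimate with linkage-adjusted confidence interval
#'
#' Result record of a temporal Ne analysis: the F statistic with its
#' confidence bounds, the implied Ne point estimate and interval (upper
#' bounds may be +Inf when the drift signal is within sampling noise), the
#' number of loci K and the effective number of independent loci K'.
#'
#' @slot point,ciLow,ciHigh Ne point estimate and 95% (by default) bounds.
#' @slot FHat,FciLow,FciHigh the F statistic and its bounds.
#' @slot variant "a" or "b".
#' @slot K integer(1), loci used.
#' @slot KPrime numeric(1), effective number of independent loci.
#' @slot M integer(1), Q^2 draws used; NA for chi-square intervals.
#' @slot alpha numeric(1), two-sided error level.
#' @slot spectrumSummary named numeric: sum and sum of squares of the
#'   eigenvalues behind the interval.
#' @name NeEstimate-class
#' @exportClass NeEstimate
setClass("NeEstimate",
  representation(point = "numeric", ciLow = "numeric", ciHigh = "numeric",
                 FHat = "numeric", FciLow = "numeric", FciHigh = "numeric",
                 variant = "character", K = "integer", KPrime = "numeric",
                 M = "integer", alpha = "numeric",
                 spectrumSummary = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@FciLow > object@FHat + 1e-12 ||
        object@FHat > object@FciHigh + 1e-12)
      msg <- c(msg, "F bounds must bracket FHat")
    fin <- is.finite(c(object@ciLow, object@point, object@ciHigh))
    if (all(fin) && (object@ciLow > object@point || object@point > object@ciHigh))
      msg <- c(msg, "Ne bounds must bracket the point estimate")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "NeEstimate", function(object) {
  fmtNe <- function(x) if (is.finite(x)) format(round(x), big.mark = ",") else "Inf"
  cat(sprintf("NeEstimate (F-hat variant %s, K = %d, K' = %.1f)\n",
              object@variant, object@K, object@KPrime))
  cat(sprintf("  F-hat = %.7g  %d%% CI [%.7g, %.7g]\n", object@FHat,
              round(100 * (1 - object@alpha)), object@FciLow, object@FciHigh))
  cat(sprintf("  Ne    = %s  %d%% CI [%s, %s]\n", fmtNe(object@point),
              round(100 * (1 - object@alpha)), fmtNe(object@ciLow),
              fmtNe(object@ciHigh)))
})

#' Forward Wright-Fisher simulation configuration
#'
#' Parameters of the forward two-sample simulation used to validate the
#' moment formulas and interval coverage: a single chromosome of length L
#' bp carrying `KInit` marker loci, evolving in a diploid Wright-Fisher
#' population of size Ne with per-adjacent-bp recombination, burn-in to
#' quasi-equilibrium LD, and plan-II samples of S0 and St diploids taken t
#' generations apart.
#'
#' Defaults follow the package's reference validation regime: Ne = 1000,
#' L = 1e5 bp, per-bp recombination 1e-5, t = 10, S0 = St = 50, target of
#' 500 retained loci with a 5% MAF screen at both time points.
#'
#' @slot Ne diploid population size.
#' @slot L chromosome length in bp.
#' @slot perBpRate recombination frequency between adjacent bp.
#' @slot mu per-locus symmetric flip-mutation rate per generation, applied
#'   during burn-in only (default 0; site turnover is normally supplied by
#'   `recycle` instead).
#' @slot recycle logical: during burn-in, re-inject any fixed marker
#'   column as a singleton on a random haplotype (forward infinite-sites
#'   site turnover at fixed columns). Keeps the marker frequency spectrum
#'   at its neutral mutation-drift occupancy (density ~ 1/x) while LD
#'   equilibrates; drift between the two samples is always turnover-free.
#' @slot t generations between samples.
#' @slot S0,St diploid sample sizes.
#' @slot burnIn generations of burn-in before the first sample; NA selects
#'   the default max(4 / median pairwise c, Ne, 200), capped at
#'   `burnInCap` (the Ne term is what tightly linked pairs, whose LD
#'   equilibrates on the drift time scale, require).
#' @slot burnInCap upper cap on the automatic burn-in.
#' @slot KTarget number of loci to retain for analysis.
#' @slot KInit number of segregating founder loci simulated (oversampled
#'   so that ~KTarget survive drift and the MAF screen).
#' @slot maf MAF threshold applied at both time points.
#' @slot seed RNG seed (NA for none).
#' @name SimConfig-class
#' @exportClass SimConfig
setClass("SimConfig",
  representation(Ne = "integer", L = "integer", perBpRate = "numeric",
                 mu = "numeric", t = "integer", S0 = "integer",
                 St = "integer", burnIn = "integer", burnInCap = "integer",
                 KTarget = "integer", KInit = "integer", maf = "numeric",
                 recycle = "logical", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@Ne < 2L) msg <- c(msg, "Ne must be >= 2")
    if (object@perBpRate < 0 || object@perBpRate > 0.5)
      msg <- c(msg, "perBpRate must lie in [0, 0.5]")
    if (object@maf < 0 || object@maf >= 0.5)
      msg <- c(msg, "maf must lie in [0, 0.5)")
    if (object@KInit < object@KTarget)
      msg <- c(msg, "KInit must be >= KTarget")
    if (!is.na(object@burnIn) && object@burnIn < 0L)
      msg <- c(msg, "burnIn must be >= 0")
    if (length(msg)) msg else TRUE
  }
)

#' @param Ne,L,perBpRate,mu,t,S0,St,burnIn,burnInCap,KTarget,KInit,maf,recycle,seed
#'   see the corresponding slots.
#' @return `SimConfig()` returns a SimConfig object.
#' @rdname SimConfig-class
#' @export
SimConfig <- function(Ne = 1000, L = 1e5, perBpRate = 1e-5, mu = 0,
                      t = 10, S0 = 50, St = 50, burnIn = NA,
                      burnInCap = 2000, KTarget = 500, KInit = 4 * KTarget,
                      maf = 0.05, recycle = TRUE, seed = NA) {
  new("SimConfig", Ne = as.integer(Ne), L = as.integer(L),
      perBpRate = perBpRate, mu = mu, t = as.integer(t),
      S0 = as.integer(S0), St = as.integer(St),
      burnIn = as.integer(burnIn), burnInCap = as.integer(burnInCap),
      KTarget = as.integer(KTarget), KInit = as.integer(KInit),
      maf = maf, recycle = recycle, seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: Ne = %d, L = %g bp, per-bp c = %g, t = %d, ",
                     "S0/St = %d/%d, K target %d (of %d founders), MAF %.2f\n"),
              object@Ne, as.numeric(object@L), object@perBpRate, object@t,
              object@S0, object@St, object@KTarget, object@KInit, object@maf))
})
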