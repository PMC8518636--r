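---
title: "Temporal Ne estimation with linked loci: model, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal Ne estimation with linked loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TempLinkNe)
```

## The model

Two samples of diploids are taken from one closed, panmictic,
non-overlapping-generation population, `t` Wright–Fisher generations
apart, and genotyped at K biallelic loci. Sampling follows plan II:
individuals are drawn with replacement (or after reproduction), so the
act of sampling does not perturb the breeding population and the two
samples have zero cross-time sampling covariance. Mutation and selection
over the short window `[0, t]` are assumed negligible, and `t` is assumed
known (for the motivating mosquito-surveillance application, calendar
time is converted to generations outside the package).

Per locus the standardized change `standardizedDelta(x0, xt)` has
variance (= the expected temporal F)

```
F = 1/(2 S0) + 1 - (1 - 1/(2 Ne))^t (1 - 1/(2 St)),
```

implemented in `deltaVariance()` / `expectedF()` and inverted by
`estimateNe()`. Two inversions are available: the classical small-drift
approximation `t / (2 (F - 1/(2 S0) - 1/(2 St)))` (default, and what the
field's reference tables print) and an exact solve for
`(1 - 1/(2 Ne))^t` (`method = "exact"`; on the reference parameter grid
the approximation is within 1.5% of truth, the exact solve within
machine precision). Any observed F at or below the sampling floor
`1/(2 S0) + 1/(2 St)` carries no detectable drift signal and maps to the
documented sentinel `+Inf`, never to a negative Ne.

For two loci with recombination fraction `c` and standardized LD `r0` in
the first temporal sample, the covariance of the standardized changes is

```
cov(delta_i, delta_j) = r0 [ 1/(2 S0) + B - (1 - 1/(2 Ne))^t (1 - c)^t (B - 1/(2 St)) ],
B = (1 - c)/(2 Ne c + 1 - c),
```

(`deltaCovariance()`), derived from the discrete two-locus multinomial
Wright–Fisher model; the pure-drift part (`driftCovariance()`) is exact
for that model, as the package's Monte-Carlo oracle tests verify to
3 Monte-Carlo standard errors. Dividing by F gives the correlation
(`deltaCorrelation()`), which uses the equal-variance property of the
standardized changes: var(delta) depends only on (Ne, S0, St, t), not on
the locus, so per-locus variance differences are deliberately ignored.

## Confidence intervals under linkage

With R the K-by-K correlation matrix of the deltas and eigenvalues
lambda_1..lambda_K, `K * FHat / F` is distributed approximately as the
chi-square mixture `Q^2 = sum_i lambda_i Z_i^2` (`sampleQ2()`), which
collapses to a chi-square with K degrees of freedom when R = I. The
interval for F takes the empirical 2.5/97.5 percentiles of M Monte-Carlo
draws (`ciForF()`; quantile type 7, i.e. linear interpolation between
order statistics), and maps anti-monotonically to Ne bounds
(`ciForNe()`). The naive interval `chisqCI()` is retained for comparison
and is exactly what assuming independence would give. `effectiveNumLoci()`
reports K' = K^2 / sum(lambda^2), the equivalent number of independent
loci.

Only a Monte-Carlo treatment of the quadratic form is provided —
closed-form approximations (Satterthwaite, Imhof) are out of scope by
design, since M = 10,000–50,000 draws cost well under a second for any
realistic K.

Choices a user can tune, with defaults:

* `M` — Q^2 draws: 50,000 for data analysis (`runPipeline()`), 10,000 in
  the replicate simulation study (`runReplicateStudy()`); both seeded.
* `alpha` — 0.05 two-sided.
* `maf` — 0.05, applied to the observed frequencies at *both* time
  points, before any window pruning (the order matters and matches the
  pipeline's annotate → MAF → prune narrative).
* `windowBp` — 1,000-bp windows, one uniformly chosen SNP kept per
  window, to thin tightly linked SNPs in dense data.
* `GeneticMap(rate)` — uniform cM/Mb rate (1.4 for the mosquito
  application) fed through Haldane's interference-free mapping function
  `haldaneC()`; locus pairs on different chromosome arms are treated as
  unlinked (c = 0.5) under the default inter-arm rule. This was a
  genuinely open choice (one could instead integrate map distance through
  the centromere); c = 0.5 is the conservative default and the
  cross-arm correlation it induces is near zero either way.
* Ne plugged into R is the point estimate itself; the resulting interval
  is insensitive to even 10-fold mis-specification of Ne, so no iteration
  is performed.

## LD estimation and its bias correction

R needs pairwise `r0` only from the *first* temporal sample (the second
sample may therefore come from cheaper, pool-style sequencing). For
phased haplotypes, `r0` is the haplotype-count correlation
(`pairwiseR0Phased()`, computed for all pairs at once as a Pearson
correlation of indicator columns). For unphased genotypes,
`r0Unphased()` / `pairwiseR0Unphased()` run an EM under Hardy–Weinberg
over the double-heterozygote phase ambiguity (vectorized across all
pairs; convergence when haplotype frequencies move < 1e-8, cap 100
iterations); pairs that fail to converge fall back to the composite
(Burrows) estimator, which does not assume Hardy–Weinberg, and are
counted in an attribute.

Finite samples inflate squared LD by roughly `1/n` (n = sampled
haplotypes) even between independent loci, so raw estimates would
overstate the eigenvalue dispersion of R and make the adjusted intervals
conservative. `biasCorrectR0()` therefore subtracts the expected sampling
contribution on the r^2 scale and back-transforms preserving sign:
`r0 = sign(r) sqrt(max(0, r^2 - 1/n))`, with `n = 2 S0` for both the
phased and the EM paths (exposed as `nUnits`). This corrector is the
package's own: it zeroes estimates within sampling noise and is validated
by the bias-reduction property test (on truly unlinked loci the corrected
mean r0^2 is much closer to zero than the raw mean r^2) and, end to end,
by interval coverage in the replicate study. Alternative empirical
corrections exist in the literature; any corrector that removes the O(1/n)
inflation without flipping signs should behave equivalently here.

## Numerical choices

* **Eigen-decomposition** uses LAPACK's dense symmetric solver via
  `eigen(symmetric = TRUE)`; K in the tens of thousands is feasible on a
  workstation (memory is the binding constraint, ~8 GB at K = 33,000).
  Above `maxDenseK` (default 20,000) the combined multi-chromosome
  analysis switches to a block-diagonal spectrum — the union of
  per-chromosome spectra, dropping the near-zero inter-chromosome entries
  — which is exact for block-diagonal R (unit-tested via the eigenvalue
  union identity).
* **Negative eigenvalues.** The model R is positive semi-definite, and
  `eigenSpectrum()`'s strict mode clips only numerical dust
  (> -1e-8 K) and errors otherwise, since material negativity signals a
  broken correlation model upstream. An *estimated* R, however, is not
  guaranteed PSD: the sign-preserving square-root shrinkage and the
  elementwise product with the recombination attenuation factor both act
  entry-wise. The estimation paths therefore clip all negative
  eigenvalues to zero and rescale the spectrum to restore the trace K,
  preserving E[Q^2] = K; coverage in the replicate study confirms this
  treatment is benign.
* **Weighted statistic.** For the ratio-of-sums variant the spectrum is
  taken from `K W^{1/2} R W^{1/2}` (`weightedEigenInput()`), W the
  diagonal of heterozygosity weights; its trace is K by construction and
  both paths are covered by the trace-conservation test.
* **Determinism.** Every stochastic step (window pruning, Q^2 draws,
  simulation) accepts a seed; `runPipeline(seed =)` makes the whole run,
  including its JSON record, byte-reproducible. Seeds are applied through
  an RNG-state-restoring helper so library calls do not disturb the
  caller's stream.

## The forward simulator and what it does (not) emulate

`simulateChromosome()` is the package's validation engine: a forward
diploid Wright–Fisher population of size Ne carrying `KInit` marker
columns at uniform random positions on an `L`-bp chromosome. Gametes pick
a random parent, start on one of its two haplotypes, and switch template
independently in each adjacent-marker interval with probability
`simulatedPairC(gap)` — the per-adjacent-bp compounding rule, which makes
the realized pairwise recombination fraction between *any* two markers
exactly `0.5 (1 - (1 - 2 perBpRate)^y)` for a y-bp separation
(interference-free, per-gamete Bernoulli). The inner loop is compiled
(Rcpp) and uses R's RNG, so runs are seed-reproducible.

Two properties of real sequence data matter for the method and are built
in deliberately:

1. **Equilibrium LD.** Founders start in linkage equilibrium, so a
   burn-in must run long enough for drift–recombination LD to build up.
   Tight pairs equilibrate on the drift time scale, hence the default
   burn-in `max(4 / median pairwise c, Ne, 200)` generations (capped at
   `burnInCap = 2000`). We verified against the classical equilibrium
   expectation E[r^2] ~ 1/(4 Ne c + 2) that ~Ne generations suffice at
   the reference regime, while a few hundred leave tightly linked pairs
   at a fraction of their equilibrium LD.
2. **A neutral allele-frequency spectrum at sampling time.** Fixed marker
   columns have no site turnover, so over a long burn-in the marker
   spectrum would flatten away from the neutral ~1/x shape — and the
   frequency spectrum is what sets the small downward bias of the
   temporal F statistics under MAF filtering. During burn-in the
   simulator therefore recycles any fixed column as a new singleton on a
   random haplotype (forward infinite-sites behaviour at fixed columns):
   renewal occupancy then holds the segregating-column spectrum at the
   neutral sojourn density ~1/x, and recycled variants arise on single
   haplotype backgrounds, which is also where coalescent-like LD comes
   from. Between the two samples there is no turnover and no mutation —
   pure drift, as the moment formulas assume.

The default `SimConfig()` is the reference validation regime: Ne = 1000,
L = 1e5 bp, per-adjacent-bp recombination 1e-5, t = 10, S0 = St = 50,
target K = 500 (KInit = 4 KTarget founder columns, 5% MAF screen at both
time points, uniform subsample down to the target). `runReplicateStudy()`
repeats the full estimation chain — simulate, plan-II sample, MAF screen,
F-hat, Ne, r0 estimation with bias correction, R, eigenvalues, 10,000
Q^2 draws, adjusted and chi-square intervals — over independent
replicates and reports coverage of the true F. At this regime the
generator reproduces the reference mean and SD of the temporal statistic
within Monte-Carlo error, the adjusted interval covers ~95%, and the
chi-square interval covers only ~72–75%.

What the simulator does *not* emulate: real data's variable recombination
along the genome (a uniform per-bp rate is used), crossover interference,
selection and linked selection, population structure and migration,
genotyping error and missingness (the VCF reader handles missing calls,
the simulator never produces them), and overlapping generations. Passing
coverage tests therefore validates the interval machinery under the
method's own assumptions; it does not certify robustness to selection or
structure, which are explicit non-goals.

Problem sizes in the shipped tests and acceptance script were chosen for
a desk run: the coverage study uses 200 replicates of the reference
regime (binomial SE ~0.016 on a 95% coverage), the Monte-Carlo oracles
2e5 replicates of the two-locus model; full 1,000-replicate reproductions
of every regime are supported by the same functions, just slower.

## Known limitations

* The delta-correlation model is first-order in LD: r0 enters linearly
  and the equal-variance approximation ignores per-locus sampling detail;
  both are adequate at the MAF >= 5%, S >= 50 scales the method targets.
* Very small samples or very short windows bias temporal F (a known
  property of the whole F-statistic family); the ratio-of-sums variant
  alleviates but does not remove this.
* The bias corrector for r0 is an empirical substitute validated by
  coverage, not an unbiased estimator (none is known).
* Per-locus missing data reduce the frequency denominators but S0/St in
  the moment formulas stay fixed (loci with > 10% missing calls are
  dropped by default) — a documented approximation.
* `estimateNe()` and the interval bounds inherit the +Inf sentinel when
  drift is below sampling noise; downstream code must expect infinite
  upper bounds.
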