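# Analyse one chromosome's worth of panel: returns spectrum components.
analyseChrom <- function(panel, NeHat, design, map, cFun, weights = NULL) {
  lm <- linkageMatrices(panel, map = map, cFun = cFun)
  R <- buildR(lm$c, lm$r0, NeHat, design)
  if (!is.null(weights)) R <- weightedEigenInput(R, weights)
  eigenSpectrum(R, clip = "all")
}

#' Full temporal Ne estimation pipeline
#'
#' Runs the estimation chain on VCF input: read the two-time-point panel,
#' apply the MAF screen and optional window pruning, compute the temporal
#' F statistic and the Ne point estimate, estimate pairwise LD in the
#' time-0 sample, build the delta-correlation matrix (with the point
#' estimate of Ne plugged in), eigen-decompose, Monte-Carlo sample Q^2,
#' and convert the empirical F quantile bounds into an Ne interval. With
#' multiple chromosomes, per-chromosome estimates are produced alongside a
#' combined estimate (full cross-chromosome correlation model when the
#' total locus count is at most `maxDenseK`; otherwise a block-diagonal
#' spectrum with the near-zero inter-chromosome entries dropped).
#'
#' @param vcf,samples0,samplest,vcft,phased,chroms passed to [readPanel()]
#'   (`vcf` may instead be a ready-made [LocusPanel], in which case the
#'   VCF arguments are ignored).
#' @param t generations between the two samples.
#' @param map a [GeneticMap] (uniform cM/Mb rate + inter-arm rule).
#' @param cFun optional recombination override for simulated data, passed
#'   to [linkageMatrices()].
#' @param maf MAF threshold applied at both time points.
#' @param windowBp window width for one-SNP-per-window pruning (NULL
#'   disables pruning).
#' @param variant temporal F variant, "a" or "b".
#' @param M Q^2 draws (50,000 by default for data analysis).
#' @param alpha two-sided error level.
#' @param maxDenseK largest locus count for which the combined
#'   cross-chromosome matrix is eigen-decomposed densely.
#' @param seed seed making the whole run (pruning + Q^2 draws)
#'   reproducible.
#' @param out optional path: write the results record as JSON.
#' @return a list of class "NePipeline": `combined` (an [NeEstimate]),
#'   `perChrom` (named list of NeEstimate, one per chromosome when more
#'   than one), `counts` (locus bookkeeping), `design`, `variant`.
#' @export
runPipeline <- function(vcf, samples0 = NULL, samplest = NULL, vcft = NULL,
                        t, map = GeneticMap(), cFun = NULL, maf = 0.05,
                        windowBp = 1000, variant = c("a", "b"), M = 50000,
                        alpha = 0.05, phased = FALSE, chroms = NULL,
                        maxDenseK = 20000, S0 = NULL, St = NULL,
                        seed = NULL, out = NULL) {
  variant <- match.arg(variant)
  panel <- if (is(vcf, "LocusPanel")) vcf else
    readPanel(vcf, samples0 = samples0, samplest = samplest, vcft = vcft,
              phased = phased, chroms = chroms)
  counts <- c(read = nLoci(panel))
  withSeed(seed, {
    panel <- mafFilter(panel, maf)
    counts["afterMAF"] <- nLoci(panel)
    if (!is.null(windowBp)) {
      panel <- windowPrune(panel, windowBp)
      counts["afterPrune"] <- nLoci(panel)
    }
    if (is.null(S0))
      S0 <- if (!is.null(haplotypes0(panel))) nrow(haplotypes0(panel)) / 2
            else if (!is.null(genotypes0(panel))) nrow(genotypes0(panel))
            else stop("S0 cannot be inferred; pass it explicitly")
    if (is.null(St))
      St <- if (!is.null(samplest)) length(samplest)
            else stop("St cannot be inferred; pass it explicitly")
    design <- TemporalDesign(S0 = S0, St = St, t = t)
    fr <- frequencies(panel)
    chromOf <- fr$chrom
    chromLevels <- unique(chromOf)
    fhat <- fStat(panel, variant)
    NeHat <- estimateNe(fhat, design)
    perChrom <- list()
    if (length(chromLevels) > 1L) {
      for (ch in chromLevels) {
        sub <- panel[chromOf == ch]
        fsub <- fStat(sub, variant)
        nesub <- estimateNe(fsub, design)
        spec <- analyseChrom(sub, nesub, design, map, cFun,
                             weights = if (variant == "b") fsub@weights)
        perChrom[[ch]] <- adjustedCI(fsub, spec, design, M = M,
                                     alpha = alpha)
      }
    }
    K <- nLoci(panel)
    spec <- if (K <= maxDenseK || length(chromLevels) == 1L) {
      analyseChrom(panel, NeHat, design, map, cFun,
                   weights = if (variant == "b") fhat@weights)
    } else {
      # block-diagonal fallback: union of per-chromosome spectra
      l <- unlist(lapply(chromLevels, function(ch) {
        sub <- panel[chromOf == ch]
        lambdas(analyseChrom(sub, NeHat, design, map, cFun,
                             weights = if (variant == "b") {
                               w <- fhat@weights[chromOf == ch]
                               w / sum(w)
                             }))
      }))
      if (variant == "b") l <- l * K / sum(l)   # restore global trace
      new("EigenSpectrum", lambdas = sort(l, decreasing = TRUE))
    }
    combined <- adjustedCI(fhat, spec, design, M = M, alpha = alpha)
    res <- structure(list(combined = combined, perChrom = perChrom,
                          counts = counts, design = design,
                          variant = variant),
                     class = "NePipeline")
    if (!is.null(out)) writeResultsJson(res, out, M = M, seed = seed)
    res
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

neRecord <- function(est) {
  list(variant = est@variant, K = est@K, KPrime = est@KPrime,
       FHat = est@FHat, FCI = c(est@FciLow, est@FciHigh),
       Ne = est@point, NeCI = c(est@ciLow, est@ciHigh),
       M = est@M, alpha = est@alpha,
       spectrum = as.list(est@spectrumSummary))
}

#' Serialize pipeline results as JSON
#'
#' @param res an "NePipeline" result from [runPipeline()].
#' @param path output path.
#' @param M,seed run metadata recorded alongside the estimates.
#' @return invisibly, the path.
#' @export
writeResultsJson <- function(res, path, M = NA, seed = NULL) {
  rec <- list(combined = neRecord(res$combined),
              perChrom = lapply(res$perChrom, neRecord),
              counts = as.list(res$counts),
              design = list(S0 = res$design@S0, St = res$design@St,
                            t = res$design@t),
              seed = seed %||% NA)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       na = "string")
  invisible(path)
}

#' @export
print.NePipeline <- function(x, ...) {
  cat(sprintf("Temporal Ne pipeline (variant %s): %d loci read, %d analysed\n",
              x$variant, x$counts[["read"]],
              x$counts[[length(x$counts)]]))
  if (length(x$perChrom)) {
    for (ch in names(x$perChrom)) {
      cat(sprintf("-- chromosome %s --\n", ch))
      show(x$perChrom[[ch]])
    }
    cat("-- combined --\n")
  }
  show(x$combined)
  invisible(x)
}
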