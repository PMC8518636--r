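#' Standardized change in observed allele frequency
#'
#' delta = (xt - x0) / sqrt(x0 (1 - x0)): the per-locus drift + sampling
#' signal, scaled by the initial-sample binomial standard deviation so its
#' variance is comparable across loci. Relabelling the tracked allele at a
#' locus (x -> 1 - x at both time points) flips the sign but preserves the
#' magnitude.
#'
#' @param x0,xt observed frequencies at the two time points (vectorized).
#' @return standardized change(s).
#' @examples
#' standardizedDelta(0.2, 0.3)   # 0.25
#' @export
standardizedDelta <- function(x0, xt) {
  if (any(x0 <= 0 | x0 >= 1))
    stop("x0 must lie strictly in (0, 1); apply the MAF filter first")
  (xt - x0) / sqrt(x0 * (1 - x0))
}

#' Temporal F statistic over a locus panel
#'
#' Variant "a" is the arithmetic average of the K squared standardized
#' changes, F_a = (1/K) sum (x_it - x_i0)^2 / (x_i0 (1 - x_i0)). Variant
#' "b" is its ratio-of-sums counterpart
#' F_b = sum (x_it - x_i0)^2 / sum x_i0 (1 - x_i0), equivalently the
#' heterozygosity-weighted average of delta_i^2 with weights
#' w_i = x_i0 (1 - x_i0) / sum_j x_j0 (1 - x_j0). Both share the same
#' expectation (and hence the same Ne point estimate) but differ in
#' sampling variance; the weights of variant "b" feed the weighted
#' eigen path of the confidence-interval engine.
#'
#' @param panel a [LocusPanel] whose loci all pass the MAF screen (x0
#'   strictly inside (0, 1)).
#' @param variant "a" (default) or "b".
#' @return an [FEstimate].
#' @examples
#' p <- LocusPanel(c("1", "1"), c(100L, 200L), x0 = c(0.5, 0.2),
#'                 xt = c(0.6, 0.3))
#' fStat(p, "a")   # 0.05125
#' fStat(p, "b")   # ~0.04878
#' @export
fStat <- function(panel, variant = c("a", "b")) {
  stopifnot(is(panel, "LocusPanel"))
  variant <- match.arg(variant)
  fr <- frequencies(panel)
  K <- nrow(fr)
  if (K < 1L) stop("empty panel")
  h0 <- fr$x0 * (1 - fr$x0)
  if (any(h0 <= 0))
    stop("loci with x0 in {0, 1} present; apply mafFilter() first")
  num <- (fr$xt - fr$x0)^2
  if (variant == "a") {
    new("FEstimate", value = mean(num / h0), variant = "a", K = K,
        weights = rep(1 / K, K))
  } else {
    new("FEstimate", value = sum(num) / sum(h0), variant = "b", K = K,
        weights = h0 / sum(h0))
  }
}

#' Minor-allele-frequency filter
#'
#' Retains loci whose minor allele frequency min(x, 1-x) is at least
#' `threshold` at *both* time points, preserving locus order. Low-MAF loci
#' destabilize the standardized-change denominator and are excluded before
#' any temporal F computation.
#'
#' @param panel a [LocusPanel].
#' @param threshold MAF threshold in \[0, 0.5) (default 0.05).
#' @param quiet suppress the removal-count message.
#' @return the filtered [LocusPanel].
#' @export
mafFilter <- function(panel, threshold = 0.05, quiet = FALSE) {
  stopifnot(is(panel, "LocusPanel"))
  if (threshold < 0 || threshold >= 0.5)
    stop("threshold must lie in [0, 0.5)")
  fr <- frequencies(panel)
  keep <- pmin(fr$x0, 1 - fr$x0) >= threshold &
          pmin(fr$xt, 1 - fr$xt) >= threshold
  # threshold 0 still needs usable delta denominators later, but is the
  # identity on loci polymorphic at time 0 by contract
  if (!quiet)
    message(sprintf("mafFilter: removed %d of %d loci (MAF < %g at either time point)",
                    sum(!keep), length(keep), threshold))
  if (!any(keep)) stop("no loci left after MAF filter")
  panel[keep]
}

#' Random one-locus-per-window pruning
#'
#' Partitions each chromosome into non-overlapping windows
#' \[1, windowBp\], \[windowBp+1, 2 windowBp\], ... and keeps exactly one
#' uniformly chosen locus per non-empty window. Used to thin tightly
#' linked loci before analysis; deterministic given `seed`.
#'
#' @param panel a [LocusPanel].
#' @param windowBp window width in bp (>= 1).
#' @param seed RNG seed (NULL/NA leaves the RNG stream untouched).
#' @param quiet suppress the survivor-count message.
#' @return the pruned [LocusPanel].
#' @export
windowPrune <- function(panel, windowBp = 1000, seed = NULL, quiet = FALSE) {
  stopifnot(is(panel, "LocusPanel"))
  if (windowBp < 1) stop("windowBp must be >= 1")
  fr <- frequencies(panel)
  win <- paste0(fr$chrom, "#", (fr$pos - 1L) %/% as.integer(windowBp))
  keep <- withSeed(seed, {
    idx <- split(seq_len(nrow(fr)), win)
    sort(vapply(idx, function(i)
      if (length(i) == 1L) i else i[sample.int(length(i), 1L)], integer(1)))
  })
  if (!quiet)
    message(sprintf("windowPrune: kept %d of %d loci (one per %d-bp window)",
                    length(keep), nrow(fr), as.integer(windowBp)))
  panel[keep]
}

#' Per-locus filtering report
#'
#' Tabulates, for every locus of a raw panel, its frequencies, the
#' standardized change where defined, and whether the locus would be kept
#' or removed (and why) by the MAF screen and optional window pruning.
#'
#' @param panel a [LocusPanel] (pre-filter).
#' @param maf MAF threshold.
#' @param windowBp optional pruning window (NULL to skip).
#' @param seed seed for the pruning draw.
#' @param file optional path; when given the table is written as TSV.
#' @return a data.frame with columns id, chrom, pos, x0, xt, delta,
#'   status, reason.
#' @export
locusReport <- function(panel, maf = 0.05, windowBp = NULL, seed = NULL,
                        file = NULL) {
  fr <- as.data.frame(frequencies(panel))
  ok0 <- fr$x0 > 0 & fr$x0 < 1
  fr$delta <- NA_real_
  fr$delta[ok0] <- (fr$xt[ok0] - fr$x0[ok0]) / sqrt(fr$x0[ok0] * (1 - fr$x0[ok0]))
  mafKeep <- pmin(fr$x0, 1 - fr$x0) >= maf & pmin(fr$xt, 1 - fr$xt) >= maf
  status <- ifelse(mafKeep, "kept", "removed")
  reason <- ifelse(mafKeep, "", "maf")
  if (!is.null(windowBp) && any(mafKeep)) {
    sub <- panel[mafKeep]
    pruned <- windowPrune(sub, windowBp, seed = seed, quiet = TRUE)
    kept_ids <- frequencies(pruned)$id
    drop <- mafKeep & !(fr$id %in% kept_ids)
    status[drop] <- "removed"
    reason[drop] <- "prune"
  }
  out <- cbind(fr, status = status, reason = reason)
  if (!is.null(file))
    write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}
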