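#' @name accessors
#' @title Accessors for TempLinkNe containers
#' @description Small accessor generics for the package's S4 containers.
#' @param x an object.
#' @return `nLoci()` the number of loci; `frequencies()` a DataFrame of
#'   per-locus id/chrom/pos/x0/xt; `haplotypes0()` / `genotypes0()` the
#'   time-0 haplotype / genotype matrix (or NULL); `lambdas()` the numeric
#'   eigenvalues; `q2Draws()` the numeric vector of Q^2 realizations.
NULL

#' @rdname accessors
#' @export
setGeneric("nLoci", function(x) standardGeneric("nLoci"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))
#' @rdname accessors
#' @export
setGeneric("haplotypes0", function(x) standardGeneric("haplotypes0"))
#' @rdname accessors
#' @export
setGeneric("genotypes0", function(x) standardGeneric("genotypes0"))
#' @rdname accessors
#' @export
setGeneric("lambdas", function(x) standardGeneric("lambdas"))
#' @rdname accessors
#' @export
setGeneric("q2Draws", function(x) standardGeneric("q2Draws"))

#' @rdname accessors
#' @export
setMethod("nLoci", "LocusPanel", function(x) length(x@loci))

#' @rdname accessors
#' @export
setMethod("frequencies", "LocusPanel", function(x) {
  mc <- S4Vectors::mcols(x@loci)
  S4Vectors::DataFrame(
    id = mc$id,
    chrom = as.character(GenomicRanges::seqnames(x@loci)),
    pos = GenomicRanges::start(x@loci),
    x0 = mc$x0, xt = mc$xt)
})

#' @rdname accessors
#' @export
setMethod("haplotypes0", "LocusPanel", function(x)
  if (x@phased && nrow(x@hap0) > 0L) x@hap0 else NULL)

#' @rdname accessors
#' @export
setMethod("genotypes0", "LocusPanel", function(x)
  if (nrow(x@geno0) > 0L) x@geno0 else NULL)

#' @rdname accessors
#' @export
setMethod("lambdas", "EigenSpectrum", function(x) x@lambdas)

#' @rdname accessors
#' @export
setMethod("q2Draws", "QSquaredSample", function(x) x@draws)

#' Subset a LocusPanel
#'
#' `[` keeps the selected loci and the matching columns of any attached
#' time-0 haplotype/genotype matrices.
#'
#' @param x a LocusPanel.
#' @param i logical or integer locus index.
#' @param j,...,drop ignored.
#' @return a LocusPanel with the selected loci.
#' @export
setMethod("[", "LocusPanel", function(x, i, j, ..., drop = FALSE) {
  emptym <- matrix(numeric(0), 0, 0)
  new("LocusPanel",
      loci = x@loci[i],
      hap0 = if (nrow(x@hap0) > 0L) x@hap0[, i, drop = FALSE] else emptym,
      geno0 = if (nrow(x@geno0) > 0L) x@geno0[, i, drop = FALSE] else emptym,
      phased = x@phased)
})
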