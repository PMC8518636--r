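#' Write a simulated two-sample panel as VCF
#'
#' Serializes plan-II samples from the simulator as a single VCF with the
#' two time points side by side, so the file-based pipeline can be
#' exercised end-to-end on synthetic data. Haplotype matrices are written
#' as phased diploid genotypes ("0|1", consecutive haplotype pairs);
#' genotype dosage matrices as unphased calls ("0/1").
#'
#' @param file output path (vcfR appends gzip compression; use a .vcf.gz
#'   name).
#' @param pos bp positions (length K).
#' @param sample0,samplet either K x 2S haplotype matrices (phased) or
#'   S x K dosage matrices (unphased; as returned by [unphase()]).
#' @param chrom chromosome label.
#' @param phased logical: interpret the sample matrices as haplotypes.
#' @param prefix0,prefixt sample-name prefixes for the two time points.
#' @return invisibly, the two character vectors of sample names.
#' @export
writePanelVcf <- function(file, pos, sample0, samplet, chrom = "1",
                          phased = TRUE, prefix0 = "t0_", prefixt = "t1_") {
  gtStrings <- function(m, prefix) {
    if (phased) {
      stopifnot(nrow(m) == length(pos))
      S <- ncol(m) / 2
      g <- matrix(paste0(m[, seq(1, 2 * S, 2), drop = FALSE], "|",
                         m[, seq(2, 2 * S, 2), drop = FALSE]),
                  nrow = length(pos))
    } else {
      stopifnot(ncol(m) == length(pos))
      S <- nrow(m)
      code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
      g <- matrix(ifelse(is.na(t(m)), "./.", code[as.character(t(m))]),
                  nrow = length(pos))
    }
    colnames(g) <- paste0(prefix, seq_len(S))
    g
  }
  g0 <- gtStrings(sample0, prefix0)
  gt <- gtStrings(samplet, prefixt)
  K <- length(pos)
  fix <- cbind(CHROM = rep(as.character(chrom), K),
               POS = as.character(pos),
               ID = paste0(chrom, ":", pos),
               REF = rep("A", K), ALT = rep("T", K),
               QUAL = rep(".", K), FILTER = rep("PASS", K),
               INFO = rep(".", K))
  gt <- cbind(FORMAT = rep("GT", K), g0, gt)
  obj <- new("vcfR",
             meta = c("##fileformat=VCFv4.2",
                      "##source=TempLinkNe forward simulator",
                      sprintf("##contig=<ID=%s>", chrom),
                      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             fix = fix, gt = gt)
  vcfR::write.vcf(obj, file = file)
  invisible(list(samples0 = colnames(g0), samplest = colnames(gt)[-1][-seq_len(ncol(g0))]))
}

# Parse a GT character matrix (loci x samples) into allele dosages and
# phasing information. Supports haploid and diploid calls, "." missing.
parseGT <- function(gt) {
  gt <- sub(":.*$", "", as.matrix(gt))
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  miss <- is.na(gt) | a1 == "." | (sep %in% c("/", "|") & a2 == ".")
  d1 <- suppressWarnings(as.numeric(a1))
  d2 <- suppressWarnings(as.numeric(a2))
  d2[!(sep %in% c("/", "|"))] <- 0
  dose <- d1 + d2
  dose[miss] <- NA
  list(dose = matrix(dose, nrow = nrow(gt), dimnames = dimnames(gt)),
       phased = sep == "|" & !miss,
       a1 = d1, a2 = d2, miss = miss)
}

#' Read a two-time-point locus panel from VCF
#'
#' Builds a [LocusPanel] from either one VCF containing both samples (with
#' two sample-ID lists) or two VCFs (intersected by chrom, pos, REF, ALT).
#' Only biallelic SNP records are used; multi-allelic and indel records
#' are skipped with a logged count. Frequencies of the ALT allele are
#' computed over non-missing calls; loci whose missing-call fraction
#' exceeds `maxMissing` at either time point are dropped. When `phased =
#' TRUE` and the time-0 genotypes are fully phased, the time-0 haplotype
#' matrix is attached for LD estimation; otherwise genotype dosages are
#' attached.
#'
#' @param vcf path to the (first) VCF.
#' @param samples0,samplest sample IDs for the two time points (required
#'   for the single-VCF dialect; for the two-VCF dialect they default to
#'   all samples of the respective file).
#' @param vcft optional path to a second VCF holding the time-t sample.
#' @param phased attach time-0 haplotypes when the calls are phased.
#' @param maxMissing maximum tolerated missing-call fraction per locus.
#' @param chroms optional chromosome include-list.
#' @return a [LocusPanel].
#' @export
readPanel <- function(vcf, samples0 = NULL, samplest = NULL, vcft = NULL,
                      phased = FALSE, maxMissing = 0.1, chroms = NULL) {
  v0 <- vcfR::read.vcfR(vcf, verbose = FALSE)
  if (is.null(vcft)) {
    if (is.null(samples0) || is.null(samplest))
      stop("single-VCF input needs samples0 and samplest")
    if (length(intersect(samples0, samplest)))
      stop("sample lists must be disjoint")
    keyed <- list(t0 = v0, tt = v0)
  } else {
    vt <- vcfR::read.vcfR(vcft, verbose = FALSE)
    key0 <- paste(v0@fix[, "CHROM"], v0@fix[, "POS"], v0@fix[, "REF"],
                  v0@fix[, "ALT"])
    keyt <- paste(vt@fix[, "CHROM"], vt@fix[, "POS"], vt@fix[, "REF"],
                  vt@fix[, "ALT"])
    common <- intersect(key0, keyt)
    message(sprintf("readPanel: %d loci shared by the two VCFs", length(common)))
    keyed <- list(t0 = v0[key0 %in% common, ], tt = vt[keyt %in% common, ])
    if (is.null(samples0)) samples0 <- colnames(keyed$t0@gt)[-1]
    if (is.null(samplest)) samplest <- colnames(keyed$tt@gt)[-1]
  }
  extract <- function(v, samples) {
    avail <- colnames(v@gt)[-1]
    if (!all(samples %in% avail))
      stop("sample IDs absent from VCF header: ",
           paste(setdiff(samples, avail), collapse = ", "))
    bi <- vcfR::is.biallelic(v)
    snp <- !vcfR::is.indel(v)
    keep <- bi & snp
    nDropped <- sum(!keep)
    v <- v[keep, ]
    gt <- v@gt[, samples, drop = FALSE]
    list(fix = v@fix, parsed = parseGT(gt), nDropped = nDropped)
  }
  e0 <- extract(keyed$t0, samples0)
  et <- extract(keyed$tt, samplest)
  if (e0$nDropped + et$nDropped > 0)
    message(sprintf("readPanel: skipped %d non-biallelic/indel records",
                    max(e0$nDropped, et$nDropped)))
  if (is.null(vcft)) {
    fix <- e0$fix
  } else {
    # align the two record sets by key
    k0 <- paste(e0$fix[, "CHROM"], e0$fix[, "POS"], e0$fix[, "REF"], e0$fix[, "ALT"])
    kt <- paste(et$fix[, "CHROM"], et$fix[, "POS"], et$fix[, "REF"], et$fix[, "ALT"])
    common <- intersect(k0, kt)
    i0 <- match(common, k0); it <- match(common, kt)
    e0$fix <- e0$fix[i0, , drop = FALSE]
    e0$parsed <- lapply(e0$parsed, function(m)
      if (is.matrix(m)) m[i0, , drop = FALSE] else m)
    et$fix <- et$fix[it, , drop = FALSE]
    et$parsed <- lapply(et$parsed, function(m)
      if (is.matrix(m)) m[it, , drop = FALSE] else m)
    fix <- e0$fix
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  d0 <- e0$parsed$dose
  dt <- et$parsed$dose
  ploidy0 <- 2  # diploid VCF contract
  x0 <- rowMeans(d0, na.rm = TRUE) / ploidy0
  xt <- rowMeans(dt, na.rm = TRUE) / ploidy0
  missFrac0 <- rowMeans(is.na(d0))
  missFract <- rowMeans(is.na(dt))
  ok <- is.finite(x0) & is.finite(xt) & missFrac0 <= maxMissing &
        missFract <= maxMissing
  if (!is.null(chroms)) ok <- ok & chrom %in% chroms
  if (sum(ok) == 0L) stop("zero loci left after missingness/chromosome screening")
  if (any(!ok))
    message(sprintf("readPanel: dropped %d loci with > %.0f%% missing calls",
                    sum(!ok), 100 * maxMissing))
  hap0 <- NULL; geno0 <- NULL
  if (phased && all(e0$parsed$phased[ok, ])) {
    a1 <- matrix(e0$parsed$a1, nrow = nrow(d0))[ok, , drop = FALSE]
    a2 <- matrix(e0$parsed$a2, nrow = nrow(d0))[ok, , drop = FALSE]
    hap <- matrix(NA_real_, nrow = 2 * ncol(a1), ncol = nrow(a1))
    hap[seq(1, nrow(hap), 2), ] <- t(a1)
    hap[seq(2, nrow(hap), 2), ] <- t(a2)
    hap0 <- hap
  } else {
    if (phased)
      message("readPanel: time-0 calls not fully phased; falling back to genotype dosages")
    geno0 <- t(d0[ok, , drop = FALSE])
  }
  LocusPanel(chrom = chrom[ok], pos = pos[ok],
             x0 = x0[ok], xt = xt[ok],
             id = paste0(chrom[ok], ":", pos[ok]),
             hap0 = hap0, geno0 = geno0)
}
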