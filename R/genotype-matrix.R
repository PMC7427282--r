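#' Construct a diploid genotype matrix
#'
#' The central container of the package: diploid calls for a set of samples
#' at a set of positioned loci. Calls are stored as two allele-index
#' matrices (`a1`, `a2`, samples x loci, 0-based indices into each locus'
#' allele vector, with `a1 <= a2` so calls are unordered pairs); missing
#' calls are `NA` in both. Loci are kept sorted by (chromosome, position)
#' and duplicate positions are rejected. Both biallelic SNPs and
#' multi-allelic (microsatellite-like) loci are supported.
#'
#' @param sample_ids character vector of unique sample identifiers.
#' @param chrom chromosome label per locus.
#' @param pos 1-based position (bp) per locus.
#' @param alleles list of character vectors, one per locus, in reference
#'   order (first allele is REF when written to VCF).
#' @param a1,a2 integer matrices (samples x loci) of 0-based allele
#'   indices; `NA` for missing. Pairs are reordered so `a1 <= a2`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sample_ids, chrom, pos, alleles, a1, a2) {
  sample_ids <- as.character(sample_ids)
  chrom <- as.character(chrom)
  pos <- as.integer(pos)
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  n_loci <- length(chrom)
  stopifnot(length(pos) == n_loci, length(alleles) == n_loci)
  a1 <- matrix(as.integer(a1), nrow = length(sample_ids), ncol = n_loci)
  a2 <- matrix(as.integer(a2), nrow = length(sample_ids), ncol = n_loci)
  # half-missing treated as fully missing (conservative, PLINK behaviour)
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA_integer_
  a2[miss] <- NA_integer_
  swap <- !miss & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]; alleles <- alleles[ord]
  a1 <- a1[, ord, drop = FALSE]; a2 <- a2[, ord, drop = FALSE]
  if (anyDuplicated(paste(chrom, pos))) {
    stop("duplicate (chromosome, position) pairs in locus table")
  }
  G <- structure(list(
    sample_ids = sample_ids,
    loci = data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE),
    alleles = alleles,
    a1 = a1, a2 = a2
  ), class = "genotype_matrix")
  validate_genotype_matrix(G)
  G
}

#' Validate a genotype matrix
#'
#' Checks the structural invariants: unique sample ids, sorted unique
#' locus coordinates, and every non-missing call referencing a valid
#' allele index for its locus.
#'
#' @param G a `genotype_matrix`.
#' @return `G`, invisibly; errors on violation.
#' @export
validate_genotype_matrix <- function(G) {
  stopifnot(inherits(G, "genotype_matrix"))
  n_all <- lengths(G$alleles)
  bad1 <- sweep(G$a1, 2, n_all, ">=") | G$a1 < 0
  bad2 <- sweep(G$a2, 2, n_all, ">=") | G$a2 < 0
  if (any(bad1 | bad2, na.rm = TRUE)) {
    stop("call references an allele index out of range for its locus")
  }
  invisible(G)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d loci (%s)\n",
              n_samples(x), n_loci(x),
              if (is_biallelic(x)) "biallelic" else "multi-allelic"))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$loci$chrom), collapse = ", ")))
  cat(sprintf("  missingness: %.2f%%\n", 100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @rdname genotype_matrix
#' @export
n_samples <- function(G) length(G$sample_ids)

#' @rdname genotype_matrix
#' @export
n_loci <- function(G) nrow(G$loci)

#' @rdname genotype_matrix
#' @export
is_biallelic <- function(G) all(lengths(G$alleles) == 2L)

#' Logical matrix of missing calls (samples x loci)
#' @param G a `genotype_matrix`.
#' @export
geno_missing <- function(G) is.na(G$a1)

#' Alternate-allele dosage matrix for biallelic loci
#'
#' Dosage of allele index 1 (the first ALT), in {0, 1, 2}, `NA` where the
#' call is missing. Errors on multi-allelic input.
#'
#' @param G a biallelic `genotype_matrix`.
#' @export
alt_dosage <- function(G) {
  if (!is_biallelic(G)) stop("dosages are defined for biallelic matrices only")
  d <- (G$a1 == 1L) + (G$a2 == 1L)
  dimnames(d) <- list(G$sample_ids, NULL)
  d
}

#' Per-locus allele counts and frequencies
#'
#' Counts gene copies of each allele over the genotyped samples (optionally
#' a subset). Returns a list with one counts vector per locus plus the
#' number of genotyped individuals.
#'
#' @param G a `genotype_matrix`.
#' @param samples optional integer or character index of samples to use.
#' @return list with `counts` (list of per-allele integer vectors),
#'   `n_geno` (genotyped individuals per locus).
#' @export
allele_counts <- function(G, samples = NULL) {
  if (!is.null(samples)) G <- subset_genotypes(G, samples = samples)
  L <- n_loci(G)
  counts <- vector("list", L)
  for (l in seq_len(L)) {
    k <- length(G$alleles[[l]])
    tab <- tabulate(c(G$a1[, l], G$a2[, l]) + 1L, nbins = k)
    counts[[l]] <- tab
  }
  list(counts = counts, n_geno = colSums(!is.na(G$a1)))
}

#' Subset a genotype matrix by samples and/or loci
#'
#' @param G a `genotype_matrix`.
#' @param samples integer/logical index or character ids of samples to keep.
#' @param loci integer or logical index of loci to keep.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(G, samples = NULL, loci = NULL) {
  si <- seq_len(n_samples(G))
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, G$sample_ids) else si[samples]
    if (anyNA(si)) stop("unknown sample id in subset")
  }
  li <- seq_len(n_loci(G))
  if (!is.null(loci)) li <- li[loci]
  structure(list(
    sample_ids = G$sample_ids[si],
    loci = G$loci[li, , drop = FALSE],
    alleles = G$alleles[li],
    a1 = G$a1[si, li, drop = FALSE],
    a2 = G$a2[si, li, drop = FALSE]
  ), class = "genotype_matrix")
}

#' Per-locus and per-sample missingness rates
#' @param G a `genotype_matrix`.
#' @export
locus_missing_rate <- function(G) colMeans(is.na(G$a1))

#' @rdname locus_missing_rate
#' @export
sample_missing_rate <- function(G) {
  r <- rowMeans(is.na(G$a1))
  names(r) <- G$sample_ids
  r
}
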