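#' Loiselle pairwise kinship coefficients
#'
#' Multilocus kinship estimator of Loiselle et al. (1995), the estimator
#' SPAGeDi computes: for a pair (i, j),
#' \deqn{k_{ij} = \frac{\sum_l \sum_a (x_{ila}-p_{la})(x_{jla}-p_{la}) +
#'   p_{la}(1-p_{la})/(n_l-1)}{\sum_l \sum_a p_{la}(1-p_{la})}}
#' where \eqn{x_{ila}} is individual i's dosage fraction of allele a at
#' locus l (0, 1/2 or 1 for a diploid), \eqn{p_{la}} the allele frequency
#' over all genotyped individuals, and \eqn{n_l} the number of genotyped
#' individuals at locus l. Sums run over the loci where both pair members
#' are genotyped; monomorphic loci contribute nothing. Works for
#' biallelic and multi-allelic matrices. Negative estimates are retained
#' (the estimator is centred on zero for unrelated outbred pairs;
#' pedigree expectations: self 0.5, full sibs 0.25, half sibs 0.125).
#'
#' @param G a [genotype_matrix] with >= 2 samples and >= 1 polymorphic
#'   locus.
#' @return a `pair_kinship` data.frame with columns `sample_i`,
#'   `sample_j` (i before j in sample order, one row per unordered pair),
#'   `k`, and `n_loci_used`. Pairs sharing no genotyped polymorphic locus
#'   are dropped with a warning.
#' @export
loiselle_kinship <- function(G) {
  n <- n_samples(G)
  if (n < 2L) stop("kinship needs at least 2 samples")
  ac <- allele_counts(G)
  L <- n_loci(G)

  # expand loci into (locus, allele) columns of dosage fractions
  cols_locus <- integer(0)
  X <- NULL
  xlist <- list()
  for (l in seq_len(L)) {
    cnt <- ac$counts[[l]]
    tot <- sum(cnt)
    if (tot == 0 || sum(cnt > 0) < 2L) next  # monomorphic or all-missing
    p <- cnt / tot
    for (a in seq_along(p)) {
      x <- ((G$a1[, l] == a - 1L) + (G$a2[, l] == a - 1L)) / 2
      xlist[[length(xlist) + 1L]] <- x - p[a]
      cols_locus <- c(cols_locus, l)
    }
  }
  if (!length(xlist)) stop("all loci are monomorphic; kinship undefined")
  Xc <- do.call(cbind, xlist)
  Xc[is.na(Xc)] <- 0

  # per-locus summed terms: d_l = sum_a p(1-p); b_l = d_l/(n_l - 1)
  M <- 1 * !is.na(G$a1)  # samples x loci non-missing indicator
  d_l <- rep(0, L); b_l <- rep(0, L)
  for (l in unique(cols_locus)) {
    cnt <- ac$counts[[l]]
    p <- cnt / sum(cnt)
    d_l[l] <- sum(p * (1 - p))
    nl <- ac$n_geno[l]
    b_l[l] <- if (nl > 1) d_l[l] / (nl - 1) else 0
  }
  num <- Xc %*% t(Xc) + M %*% (b_l * t(M))
  den <- M %*% (d_l * t(M))
  shared <- M %*% t(M)

  idx <- which(upper.tri(num), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  k <- num[idx] / den[idx]
  out <- data.frame(sample_i = G$sample_ids[idx[, 1L]],
                    sample_j = G$sample_ids[idx[, 2L]],
                    k = k,
                    n_loci_used = as.integer(shared[idx]),
                    stringsAsFactors = FALSE)
  bad <- !is.finite(out$k)
  if (any(bad)) {
    warning(sum(bad), " pair(s) with no shared polymorphic loci dropped")
    out <- out[!bad, ]
  }
  class(out) <- c("pair_kinship", "data.frame")
  out
}

#' Partition samples into sibling groups
#'
#' Builds a graph with an edge between every pair whose kinship exceeds
#' the threshold and returns its connected components (single linkage);
#' samples connected to nobody form singleton groups. The default
#' threshold 0.1875 is the midpoint between full-sib (0.25) and half-sib
#' (0.125) kinship expectations.
#'
#' @param K a `pair_kinship` table (see [loiselle_kinship]).
#' @param threshold kinship above which a pair is called sibling
#'   (default 0.1875).
#' @param samples optional character vector of all sample ids (defaults
#'   to those appearing in `K`).
#' @return list of character vectors, one per group.
#' @export
sibling_groups <- function(K, threshold = 0.1875, samples = NULL) {
  if (is.null(samples)) samples <- sort(unique(c(K$sample_i, K$sample_j)))
  parent <- seq_along(samples)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  hits <- which(K$k > threshold)
  ii <- match(K$sample_i[hits], samples)
  jj <- match(K$sample_j[hits], samples)
  for (e in seq_along(hits)) {
    ri <- find(ii[e]); rj <- find(jj[e])
    if (ri != rj) parent[ri] <- rj
  }
  roots <- vapply(seq_along(samples), find, 0L)
  unname(split(samples, roots))
}

#' Retain one representative per sibling group
#'
#' Keeps, from each group, the member with the least genotype
#' missingness, breaking ties by lexicographically smaller sample id.
#'
#' @param groups list of sample-id groups (see [sibling_groups]).
#' @param G the [genotype_matrix] the groups refer to.
#' @return character vector of retained sample ids, in `G` sample order.
#' @export
deduplicate_siblings <- function(groups, G) {
  miss <- sample_missing_rate(G)
  kept <- vapply(groups, function(g) {
    m <- miss[g]
    g <- sort(g[m == min(m)])  # tie -> lexicographically smaller id
    g[1L]
  }, "")
  G$sample_ids[G$sample_ids %in% kept]
}
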