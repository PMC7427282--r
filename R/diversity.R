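#' Expected and observed heterozygosity per group
#'
#' Per locus and group, Ho is the fraction of heterozygous calls among
#' genotyped individuals and He the small-sample unbiased expectation
#' \eqn{\frac{2n}{2n-1}(1 - \sum_a p_a^2)} with n genotyped individuals;
#' the group value is the mean over loci (loci with fewer than two
#' genotyped individuals in a group are skipped for that group).
#'
#' @param G a [genotype_matrix].
#' @param groups factor/character of group labels, one per sample of `G`.
#' @return data.frame with one row per group: `group`, `n_samples`, `He`,
#'   `Ho`, `n_loci_used`.
#' @export
heterozygosity <- function(G, groups) {
  stopifnot(length(groups) == n_samples(G))
  out <- lapply(unique(groups), function(g) {
    idx <- which(groups == g)
    if (length(idx) < 2L) stop("group '", g, "' has fewer than 2 samples")
    sub <- subset_genotypes(G, samples = idx)
    ac <- allele_counts(sub)
    he <- ho <- rep(NA_real_, n_loci(sub))
    for (l in seq_len(n_loci(sub))) {
      n <- ac$n_geno[l]
      if (n < 2L) next
      p <- ac$counts[[l]] / (2 * n)
      he[l] <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
      a1 <- sub$a1[, l]; a2 <- sub$a2[, l]
      ho[l] <- mean(a1[!is.na(a1)] != a2[!is.na(a1)])
    }
    used <- !is.na(he)
    data.frame(group = g, n_samples = length(idx),
               He = mean(he[used]), Ho = mean(ho[used]),
               n_loci_used = sum(used), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# rarefaction probability that allele with N_a copies out of N appears in
# a subsample of g gene copies: 1 - C(N - N_a, g)/C(N, g)
.rarefy_present <- function(N, N_a, g) {
  if (g > N - N_a) return(1)
  1 - exp(lchoose(N - N_a, g) - lchoose(N, g))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles in a random subsample of `g` gene
#' copies (the HP-RARE rarefaction):
#' \eqn{AR_g = \sum_a 1 - \binom{N-N_a}{g} / \binom{N}{g}} with N the
#' genotyped gene copies in the group and \eqn{N_a} the copies of allele
#' a. Loci where a group has fewer than `g` genotyped copies are skipped
#' with a warning (rarefy to the smallest sample to avoid this).
#'
#' @param G a [genotype_matrix].
#' @param groups group label per sample.
#' @param g rarefaction size in gene copies (>= 2); `NULL` (default) uses
#'   2 x the smallest group's sample count.
#' @return list with `per_locus` (matrix loci x groups, NA where skipped),
#'   `mean` (named per-group means over usable loci), and `g`.
#' @export
rarefied_allelic_richness <- function(G, groups, g = NULL) {
  stopifnot(length(groups) == n_samples(G))
  glab <- unique(groups)
  if (is.null(g)) g <- 2L * min(table(groups))
  g <- as.integer(g)
  if (g < 2L) stop("rarefaction size g must be >= 2 gene copies")
  ar <- matrix(NA_real_, n_loci(G), length(glab),
               dimnames = list(NULL, glab))
  for (j in seq_along(glab)) {
    ac <- allele_counts(G, samples = which(groups == glab[j]))
    for (l in seq_len(n_loci(G))) {
      N <- 2L * ac$n_geno[l]
      if (N < g) next
      cnt <- ac$counts[[l]]
      ar[l, j] <- sum(vapply(cnt[cnt > 0], function(na)
        .rarefy_present(N, na, g), 0))
    }
  }
  if (anyNA(ar)) {
    warning(sum(is.na(ar)), " locus-group cell(s) with fewer than g copies skipped")
  }
  list(per_locus = ar, mean = colMeans(ar, na.rm = TRUE), g = g)
}

#' Rarefied private allelic richness
#'
#' Expected number of alleles found in a g-copy rarefied sample of one
#' group but in no other group's g-copy rarefied sample:
#' \eqn{pAR_g(j) = \sum_a P(a\ present\ in\ j) \prod_{k \ne j}
#' P(a\ absent\ in\ k)}, with presence probabilities from the same
#' binomial rarefaction as [rarefied_allelic_richness].
#'
#' @inheritParams rarefied_allelic_richness
#' @return list with `per_locus` (loci x groups), `mean` (per-group mean
#'   over usable loci), `total` (per-group sum over loci), and `g`.
#' @export
private_allelic_richness <- function(G, groups, g = NULL) {
  stopifnot(length(groups) == n_samples(G))
  glab <- unique(groups)
  if (length(glab) < 2L) stop("private alleles need at least 2 groups")
  if (is.null(g)) g <- 2L * min(table(groups))
  g <- as.integer(g)
  if (g < 2L) stop("rarefaction size g must be >= 2 gene copies")
  acs <- lapply(glab, function(gr) allele_counts(G, samples = which(groups == gr)))
  par <- matrix(NA_real_, n_loci(G), length(glab),
                dimnames = list(NULL, glab))
  for (l in seq_len(n_loci(G))) {
    Ns <- vapply(acs, function(a) 2 * a$n_geno[l], 0)
    if (any(Ns < g)) next  # skip locus unless rarefiable in every group
    n_all <- length(acs[[1L]]$counts[[l]])
    pres <- matrix(0, n_all, length(glab))
    for (j in seq_along(glab)) {
      cnt <- acs[[j]]$counts[[l]]
      for (a in seq_len(n_all)) {
        pres[a, j] <- .rarefy_present(Ns[j], cnt[a], g)
      }
    }
    for (j in seq_along(glab)) {
      absent_elsewhere <- apply(1 - pres[, -j, drop = FALSE], 1, prod)
      par[l, j] <- sum(pres[, j] * absent_elsewhere)
    }
  }
  if (anyNA(par)) {
    warning(sum(is.na(par[, 1L])), " locus/loci not rarefiable in every group skipped")
  }
  list(per_locus = par, mean = colMeans(par, na.rm = TRUE),
       total = colSums(par, na.rm = TRUE), g = g)
}

#' Group diversity summary table
#'
#' Convenience wrapper combining [heterozygosity],
#' [rarefied_allelic_richness] and [private_allelic_richness] into the
#' per-group summary reported by the pipeline.
#'
#' @inheritParams rarefied_allelic_richness
#' @return data.frame with columns `group`, `n_samples`, `He`, `Ho`,
#'   `AR_g`, `pAR_g` plus attribute `g`.
#' @export
diversity_table <- function(G, groups, g = NULL) {
  het <- heterozygosity(G, groups)
  ar <- rarefied_allelic_richness(G, groups, g)
  par <- if (length(unique(groups)) >= 2L) {
    private_allelic_richness(G, groups, ar$g)
  } else NULL
  het$AR_g <- ar$mean[het$group]
  het$pAR_g <- if (!is.null(par)) par$mean[het$group] else NA_real_
  attr(het, "g") <- ar$g
  het
}
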