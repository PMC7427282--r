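# Per-locus Weir-Cockerham (1984) variance components a (among groups),
# b (among individuals within groups), c (within individuals), summed
# over alleles (multi-allelic safe). Loci where any group has no
# genotyped individual, or with fewer than ~1 individual per group on
# average, get NA components.
.wc_components <- function(G, groups) {
  glab <- unique(groups)
  r <- length(glab)
  if (r < 2L) stop("Fst needs at least 2 groups")
  L <- n_loci(G)
  idx <- lapply(glab, function(g) which(groups == g))
  n <- t(vapply(idx, function(i)
    colSums(!is.na(G$a1[i, , drop = FALSE])), numeric(L)))
  if (any(rowSums(n) == 0)) {
    stop("group '", glab[which(rowSums(n) == 0)[1L]],
         "' has no genotyped individuals at any locus")
  }
  ntot <- colSums(n)
  nbar <- ntot / r
  nc <- (ntot - colSums(n^2) / ntot) / (r - 1)
  valid <- colSums(n >= 1L) == r & nbar > 1 & nc > 0
  A <- B <- C <- rep(0, L)
  K <- max(lengths(G$alleles))
  for (al in seq_len(K) - 1L) {
    p <- h <- matrix(0, r, L)
    for (i in seq_len(r)) {
      a1 <- G$a1[idx[[i]], , drop = FALSE]
      a2 <- G$a2[idx[[i]], , drop = FALSE]
      cnt <- colSums((a1 == al) + (a2 == al), na.rm = TRUE)
      het <- colSums((a1 == al) != (a2 == al), na.rm = TRUE)
      ok <- n[i, ] > 0
      p[i, ok] <- cnt[ok] / (2 * n[i, ok])
      h[i, ok] <- het[ok] / n[i, ok]
    }
    pbar <- colSums(n * p) / ntot
    s2 <- colSums(n * sweep(p, 2, pbar)^2) / ((r - 1) * nbar)
    hbar <- colSums(n * h) / ntot
    inner <- pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4
    a_ <- (nbar / nc) * (s2 - inner / (nbar - 1))
    b_ <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    c_ <- hbar / 2
    contrib <- valid & pbar > 0  # absent alleles contribute nothing
    A[contrib] <- A[contrib] + a_[contrib]
    B[contrib] <- B[contrib] + b_[contrib]
    C[contrib] <- C[contrib] + c_[contrib]
  }
  A[!valid] <- NA_real_; B[!valid] <- NA_real_; C[!valid] <- NA_real_
  list(a = A, b = B, c = C, groups = glab)
}

#' Weir-Cockerham Fst
#'
#' Moment estimator of Weir & Cockerham (1984): per-locus variance
#' components a (among groups), b (among individuals within groups) and
#' c (within individuals) are computed per allele from group sample
#' sizes, allele frequencies and heterozygote frequencies, summed over
#' alleles, and combined as theta = a/(a+b+c). The multilocus estimate
#' `theta_w` is the ratio of sums (sum a over sum a+b+c), the convention
#' of windowed-Fst tools; the mean of per-locus ratios is reported
#' alongside as `theta_mean`. Monomorphic loci contribute (0,0,0) and do
#' not affect the multilocus ratio; missing genotypes are excluded per
#' locus and group. Negative estimates are possible (the estimator is
#' unbiased around zero under no differentiation) and are not clipped.
#'
#' @param G a [genotype_matrix].
#' @param groups group label per sample (>= 2 groups).
#' @return an object of class `fst_result`: list with `per_locus`
#'   (data.frame chrom, pos, a, b, c, theta), `theta_w`, `theta_mean`,
#'   `groups`, `n_loci` (informative loci).
#' @export
wc_fst <- function(G, groups) {
  stopifnot(length(groups) == n_samples(G))
  comp <- .wc_components(G, groups)
  tot <- comp$a + comp$b + comp$c
  denom <- sum(tot, na.rm = TRUE)
  if (!is.finite(denom) || denom == 0) {
    stop("total variance components are zero; Fst undefined")
  }
  theta <- ifelse(is.na(tot) | tot == 0, NA_real_, comp$a / tot)
  structure(list(
    per_locus = data.frame(chrom = G$loci$chrom, pos = G$loci$pos,
                           a = comp$a, b = comp$b, c = comp$c,
                           theta = theta, stringsAsFactors = FALSE),
    theta_w = sum(comp$a, na.rm = TRUE) / denom,
    theta_mean = mean(theta, na.rm = TRUE),
    groups = comp$groups,
    n_loci = sum(!is.na(tot) & tot > 0)
  ), class = "fst_result")
}

#' @export
print.fst_result <- function(x, ...) {
  cat(sprintf("Weir-Cockerham Fst over %s\n", paste(x$groups, collapse = " / ")))
  cat(sprintf("  theta_w (ratio of sums): %.4f\n", x$theta_w))
  cat(sprintf("  mean per-locus theta:    %.4f (over %d informative loci)\n",
              x$theta_mean, x$n_loci))
  invisible(x)
}

#' Pairwise Fst matrix over groups
#'
#' Applies [wc_fst] to every pair of groups; the result is symmetric with
#' an undefined (NA) diagonal.
#'
#' @inheritParams wc_fst
#' @return numeric matrix of pairwise multilocus `theta_w`.
#' @export
pairwise_fst <- function(G, groups) {
  glab <- unique(groups)
  m <- matrix(NA_real_, length(glab), length(glab),
              dimnames = list(glab, glab))
  for (i in seq_along(glab)[-length(glab)]) {
    for (j in seq.int(i + 1L, length(glab))) {
      sel <- groups %in% glab[c(i, j)]
      th <- wc_fst(subset_genotypes(G, samples = which(sel)),
                   groups[sel])$theta_w
      m[i, j] <- m[j, i] <- th
    }
  }
  m
}

#' Permutation test of group differentiation
#'
#' For each group pair, the observed multilocus theta is compared with a
#' null built by permuting group labels over individuals;
#' p = (number of permuted theta >= observed + 1) / (n_perm + 1).
#'
#' @inheritParams wc_fst
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for reproducibility.
#' @return data.frame with `group1`, `group2`, `theta_w`, `p_value`,
#'   `n_perm`, `seed`.
#' @export
fst_permutation_test <- function(G, groups, n_perm = 999L, seed = 1L) {
  if (n_perm < 99L) warning("n_perm < 99 gives coarse p-value granularity")
  set.seed(seed)
  glab <- unique(groups)
  out <- list()
  for (i in seq_along(glab)[-length(glab)]) {
    for (j in seq.int(i + 1L, length(glab))) {
      sel <- which(groups %in% glab[c(i, j)])
      sub <- subset_genotypes(G, samples = sel)
      lab <- groups[sel]
      obs <- wc_fst(sub, lab)$theta_w
      exceed <- 0L
      for (b in seq_len(n_perm)) {
        th <- wc_fst(sub, sample(lab))$theta_w
        if (th >= obs) exceed <- exceed + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        group1 = glab[i], group2 = glab[j], theta_w = obs,
        p_value = (exceed + 1) / (n_perm + 1),
        n_perm = n_perm, seed = seed, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Sliding-window Fst genome scan
#'
#' Computes per-locus Weir-Cockerham components once, then aggregates
#' them in windows of `window_bp` advanced by `step_bp` along each
#' chromosome (windows anchored at position 1, covering
#' [start, start+window_bp-1]; only fully contained windows are
#' generated). The per-window statistic is the ratio-of-sums `theta_w`;
#' the mean of per-locus ratios is emitted alongside. Windows with fewer
#' than `min_snps` informative loci are dropped and the dropped fraction
#' recorded. A chromosome shorter than one window yields a single
#' flagged window spanning it.
#'
#' @inheritParams wc_fst
#' @param window_bp window size in bp (default 1,000,000).
#' @param step_bp step between window starts in bp (default 10,000).
#' @param min_snps minimum informative loci per retained window
#'   (default 3).
#' @param chrom_lengths optional named vector of chromosome lengths (bp);
#'   defaults to the last locus position per chromosome.
#' @return data.frame of class `window_fst` with columns `chrom`,
#'   `start`, `end`, `n_snps`, `theta_w`, `theta_mean`; attributes
#'   `window_bp`, `step_bp`, `min_snps`, `n_windows_total`,
#'   `frac_dropped`, `mean_snps_per_window`, `short_chroms`.
#' @export
sliding_window_fst <- function(G, groups, window_bp = 1000000L,
                               step_bp = 10000L, min_snps = 3L,
                               chrom_lengths = NULL) {
  comp <- .wc_components(G, groups)
  tot <- comp$a + comp$b + comp$c
  inform <- !is.na(tot) & tot > 0
  a <- ifelse(inform, comp$a, 0)
  t3 <- ifelse(inform, tot, 0)
  th <- ifelse(inform, comp$a / tot, 0)
  rows <- list()
  short_chroms <- character(0)
  for (ch in unique(G$loci$chrom)) {
    li <- which(G$loci$chrom == ch)
    pos <- G$loci$pos[li]
    Lc <- if (!is.null(chrom_lengths) && ch %in% names(chrom_lengths)) {
      as.numeric(chrom_lengths[[ch]])
    } else max(pos)
    if (Lc < window_bp) {
      starts <- 1; ends <- Lc
      short_chroms <- c(short_chroms, ch)
    } else {
      starts <- seq(1, Lc - window_bp + 1, by = step_bp)
      ends <- starts + window_bp - 1
    }
    ca <- c(0, cumsum(a[li])); ct <- c(0, cumsum(t3[li]))
    cth <- c(0, cumsum(th[li])); cn <- c(0, cumsum(inform[li]))
    lo <- findInterval(starts - 0.5, pos) + 1L
    hi <- findInterval(ends + 0.5, pos)
    nsnp <- cn[hi + 1L] - cn[lo]
    sum_a <- ca[hi + 1L] - ca[lo]
    sum_t <- ct[hi + 1L] - ct[lo]
    sum_th <- cth[hi + 1L] - cth[lo]
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = ch, start = starts, end = ends, n_snps = as.integer(nsnp),
      theta_w = ifelse(sum_t > 0, sum_a / sum_t, NA_real_),
      theta_mean = ifelse(nsnp > 0, sum_th / nsnp, NA_real_),
      stringsAsFactors = FALSE)
  }
  win <- do.call(rbind, rows)
  total <- nrow(win)
  keep <- win$n_snps >= min_snps
  out <- win[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("window_fst", "data.frame"),
            window_bp = window_bp, step_bp = step_bp, min_snps = min_snps,
            n_windows_total = total,
            frac_dropped = 1 - sum(keep) / total,
            mean_snps_per_window = mean(win$n_snps),
            short_chroms = short_chroms)
}
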