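#' Quality-control filter parameters
#'
#' Thresholds for the six-stage genotype filter cascade, in cascade order:
#' (i) locus missingness, (ii) sample missingness, (iii) per-population
#' exact Hardy-Weinberg tests, (iv) windowed variance-inflation-factor LD
#' pruning, (v) minor allele frequency, (vi) per-sample heterozygosity
#' outliers.
#'
#' @param max_locus_missing remove loci with missingness above this
#'   fraction (default 0.10).
#' @param max_sample_missing remove samples with missingness above this
#'   fraction (default 0.10).
#' @param hwe_alpha remove loci whose exact HWE p-value falls below this
#'   in any population (default 1e-5).
#' @param vif_window_bp window span for VIF pruning in bp (default 75000).
#' @param vif_threshold remove loci with in-window VIF above this
#'   (default 2).
#' @param min_maf remove loci with minor allele frequency below this
#'   (default 0.01).
#' @param het_sd_mult flag samples whose heterozygosity deviates more than
#'   this many standard deviations from the cohort mean (default 3).
#' @return an object of class `filter_params`.
#' @export
filter_params <- function(max_locus_missing = 0.10,
                          max_sample_missing = 0.10,
                          hwe_alpha = 1e-5,
                          vif_window_bp = 75000L,
                          vif_threshold = 2,
                          min_maf = 0.01,
                          het_sd_mult = 3) {
  stopifnot(max_locus_missing >= 0, max_locus_missing <= 1,
            max_sample_missing >= 0, max_sample_missing <= 1,
            hwe_alpha > 0, hwe_alpha <= 1,
            vif_window_bp > 0, vif_threshold > 1,
            min_maf >= 0, min_maf <= 1, het_sd_mult > 0)
  structure(list(max_locus_missing = max_locus_missing,
                 max_sample_missing = max_sample_missing,
                 hwe_alpha = hwe_alpha,
                 vif_window_bp = as.integer(vif_window_bp),
                 vif_threshold = vif_threshold,
                 min_maf = min_maf,
                 het_sd_mult = het_sd_mult),
            class = "filter_params")
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Standard (non-mid-p) exact test on diploid genotype counts,
#' conditioning on the observed allele counts: the p-value is the summed
#' probability of every heterozygote count (same allele totals, same
#' parity) whose conditional probability does not exceed that of the
#' observed configuration.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative; at least one > 0).
#' @return p-value in (0, 1]. A monomorphic table (one allele absent)
#'   returns 1 with attribute `monomorphic = TRUE`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  stopifnot(n_AA >= 0, n_Aa >= 0, n_aa >= 0)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("empty genotype table")
  nA <- 2L * n_AA + n_Aa
  nB <- 2L * n_aa + n_Aa
  if (nA == 0L || nB == 0L) {
    return(structure(1, monomorphic = TRUE))
  }
  hets <- seq.int(nA %% 2L, min(nA, nB), by = 2L)
  # log P(h | nA, n) up to the common normalising constant
  logp <- lfactorial(n) - lfactorial((nA - hets) / 2) - lfactorial(hets) -
    lfactorial((nB - hets) / 2) + hets * log(2)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_Aa, hets)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

#' Windowed variance-inflation-factor LD pruning
#'
#' PLINK-style multicollinearity pruning: within every window of
#' `vif_window_bp` (windows advance by half a window along each
#' chromosome), each retained locus' VIF = 1/(1 - R^2) from the
#' least-squares regression of its 0/1/2 dosage on the other in-window
#' dosages is computed, and the locus with the largest VIF is removed
#' (greedy, worst first) while any VIF exceeds the threshold. Perfectly
#' collinear loci have infinite VIF and are removed first; ties are broken
#' by keeping the locus at the smaller position. Missing dosages are
#' mean-imputed for the regression. Multi-allelic loci are not considered
#' and are always retained.
#'
#' @param G a [genotype_matrix].
#' @param params a [filter_params].
#' @return integer vector of retained locus indices (into `G$loci`).
#' @export
vif_prune <- function(G, params = filter_params()) {
  L <- n_loci(G)
  retained <- rep(TRUE, L)
  bi <- lengths(G$alleles) == 2L
  if (sum(bi) < 2L) return(seq_len(L))
  dos <- (G$a1 == 1L) + (G$a2 == 1L)  # biallelic columns only used
  win <- params$vif_window_bp
  step <- max(1L, win %/% 2L)
  for (ch in unique(G$loci$chrom)) {
    on_ch <- which(bi & G$loci$chrom == ch)
    if (length(on_ch) < 2L) next
    pos <- G$loci$pos[on_ch]
    starts <- seq.int(min(pos), max(pos), by = step)
    for (s in starts) {
      idx <- on_ch[retained[on_ch] & pos >= s & pos <= s + win - 1L]
      if (length(idx) < 2L) next
      retained[idx] <- retained[idx] & .vif_window_keep(dos[, idx, drop = FALSE],
                                                       params$vif_threshold)
    }
  }
  which(retained)
}

# Greedy worst-first VIF pruning inside one window; columns ordered by
# position. Returns logical keep-vector over the columns.
.vif_window_keep <- function(D, threshold) {
  m <- ncol(D)
  keep <- rep(TRUE, m)
  # mean-impute and drop constant columns from consideration
  for (j in seq_len(m)) {
    x <- D[, j]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    D[, j] <- x
  }
  variable <- apply(D, 2, stats::sd) > 0
  repeat {
    act <- which(keep & variable)
    if (length(act) < 2L) break
    R <- stats::cor(D[, act, drop = FALSE])
    off <- abs(R); diag(off) <- 0
    if (max(off) >= 1 - 1e-10) {
      # perfect collinearity: VIF = +Inf; drop the later-position member
      pair <- which(off == max(off), arr.ind = TRUE)[1L, ]
      keep[act[max(pair)]] <- FALSE
      next
    }
    vif <- tryCatch(diag(solve(R)), error = function(e) NULL)
    if (is.null(vif)) {  # numerically singular: treat worst pair as collinear
      pair <- which(off == max(off), arr.ind = TRUE)[1L, ]
      keep[act[max(pair)]] <- FALSE
      next
    }
    if (max(vif) <= threshold) break
    worst <- which(vif >= max(vif) - 1e-12)
    keep[act[max(worst)]] <- FALSE  # tie: keep the smaller position
  }
  keep
}

#' Per-sample heterozygosity outlier detection
#'
#' Flags samples whose heterozygosity statistic deviates more than
#' `het_sd_mult` standard deviations (denominator n-1) from the cohort
#' mean. The default statistic is each sample's observed proportion of
#' heterozygous calls among its non-missing loci; `method = "inbreeding"`
#' uses the method-of-moments inbreeding coefficient
#' F = (observed hom - expected hom) / (loci - expected hom) instead.
#'
#' @param G a [genotype_matrix] with at least 3 samples.
#' @param params a [filter_params].
#' @param method `"observed"` (default) or `"inbreeding"`.
#' @return character vector of flagged sample ids (possibly empty).
#' @export
sample_het_outliers <- function(G, params = filter_params(),
                                method = c("observed", "inbreeding")) {
  method <- match.arg(method)
  if (n_samples(G) < 3L) stop("heterozygosity outlier test needs >= 3 samples")
  het <- !is.na(G$a1) & G$a1 != G$a2
  n_obs <- rowSums(!is.na(G$a1))
  if (any(n_obs == 0)) stop("sample with no genotyped loci")
  if (method == "observed") {
    stat <- rowSums(het) / n_obs
  } else {
    ac <- allele_counts(G)
    exp_het <- vapply(seq_len(n_loci(G)), function(l) {
      ncp <- 2 * ac$n_geno[l]
      if (ncp < 2) return(0)
      p <- ac$counts[[l]] / ncp
      (1 - sum(p^2)) * ncp / (ncp - 1)
    }, 0)
    e_hom <- (1 - exp_het)
    obs_hom <- (!is.na(G$a1)) & G$a1 == G$a2
    E <- (!is.na(G$a1)) %*% e_hom
    stat <- (rowSums(obs_hom) - E) / (n_obs - E)
  }
  mu <- mean(stat)
  sdev <- stats::sd(stat)
  if (sdev == 0) return(character(0))
  G$sample_ids[abs(stat - mu) > params$het_sd_mult * sdev]
}

#' Apply the six-stage filter cascade
#'
#' Runs the ordered cascade (i) locus missingness, (ii) sample
#' missingness, (iii) exact HWE per population (a locus is removed when it
#' fails in any population), (iv) windowed VIF pruning, (v) minor allele
#' frequency, (vi) heterozygosity outlier samples. Because sample removal
#' changes locus statistics, the cascade is repeated until a round removes
#' nothing (at most `max_rounds` rounds). Stages (iii) and (iv) apply to
#' biallelic loci only; multi-allelic loci pass through them. Stage (v)
#' uses 1 - max allele frequency, which for biallelic loci is the minor
#' allele frequency.
#'
#' @param G a [genotype_matrix].
#' @param metadata sample metadata (see [read_metadata]); must cover every
#'   sample in `G`.
#' @param params a [filter_params].
#' @param pop_by how populations for the HWE stage are formed:
#'   `"locality_habitat"` (default), `"habitat"`, `"locality"` or `"site"`.
#' @param max_rounds maximum cascade repetitions (default 5).
#' @return list with `genotypes` (filtered [genotype_matrix]) and
#'   `report` (data.frame: round, stage, unit, n_input, n_removed,
#'   n_retained, removed_ids list-column).
#' @export
apply_filter_cascade <- function(G, metadata, params = filter_params(),
                                 pop_by = c("locality_habitat", "habitat",
                                            "locality", "site"),
                                 max_rounds = 5L) {
  pop_by <- match.arg(pop_by)
  metadata <- validate_metadata(metadata)
  if (!all(G$sample_ids %in% metadata$sample_id)) {
    stop("metadata missing for sample(s): ",
         paste(setdiff(G$sample_ids, metadata$sample_id), collapse = ", "))
  }
  report <- list()
  note <- function(round, stage, unit, n_input, removed_ids) {
    report[[length(report) + 1L]] <<- data.frame(
      round = round, stage = stage, unit = unit, n_input = n_input,
      n_removed = length(removed_ids), n_retained = n_input - length(removed_ids),
      removed_ids = I(list(removed_ids)), stringsAsFactors = FALSE)
  }
  pop_labels <- function(md, ids) {
    md <- md[match(ids, md$sample_id), ]
    switch(pop_by,
           locality_habitat = paste(md$locality, md$habitat, sep = ":"),
           habitat = md$habitat,
           locality = md$locality,
           site = md$site)
  }
  locus_id <- function(g, idx) {
    if (!length(idx)) return(character(0))
    paste0(g$loci$chrom[idx], ":", g$loci$pos[idx])
  }

  for (round in seq_len(max_rounds)) {
    removed_any <- FALSE

    # (i) locus missingness
    drop <- which(locus_missing_rate(G) > params$max_locus_missing)
    note(round, "i_locus_missing", "locus", n_loci(G), locus_id(G, drop))
    if (length(drop)) { G <- subset_genotypes(G, loci = -drop); removed_any <- TRUE }
    if (n_loci(G) == 0) stop("all data filtered: no loci remain")

    # (ii) sample missingness
    drop <- which(sample_missing_rate(G) > params$max_sample_missing)
    note(round, "ii_sample_missing", "sample", n_samples(G), G$sample_ids[drop])
    if (length(drop)) { G <- subset_genotypes(G, samples = -drop); removed_any <- TRUE }
    if (n_samples(G) == 0) stop("all data filtered: no samples remain")

    # (iii) exact HWE within each population; fail in ANY population
    pops <- pop_labels(metadata, G$sample_ids)
    bi <- lengths(G$alleles) == 2L
    fails <- rep(FALSE, n_loci(G))
    for (p in unique(pops)) {
      sub <- subset_genotypes(G, samples = which(pops == p))
      for (l in which(bi)) {
        a1 <- sub$a1[, l]; a2 <- sub$a2[, l]
        ok <- !is.na(a1)
        if (!any(ok)) next
        n_het <- sum(a1[ok] != a2[ok])
        n_ref <- sum(a1[ok] == 0L & a2[ok] == 0L)
        n_alt <- sum(a1[ok] == 1L & a2[ok] == 1L)
        if (hwe_exact_test(n_ref, n_het, n_alt) < params$hwe_alpha) {
          fails[l] <- TRUE
        }
      }
    }
    drop <- which(fails)
    note(round, "iii_hwe", "locus", n_loci(G), locus_id(G, drop))
    if (length(drop)) { G <- subset_genotypes(G, loci = -drop); removed_any <- TRUE }
    if (n_loci(G) == 0) stop("all data filtered: no loci remain")

    # (iv) VIF pruning
    keep <- vif_prune(G, params)
    drop <- setdiff(seq_len(n_loci(G)), keep)
    note(round, "iv_vif", "locus", n_loci(G), locus_id(G, drop))
    if (length(drop)) { G <- subset_genotypes(G, loci = keep); removed_any <- TRUE }

    # (v) minor allele frequency
    ac <- allele_counts(G)
    maf <- vapply(seq_len(n_loci(G)), function(l) {
      tot <- sum(ac$counts[[l]])
      if (tot == 0) return(0)
      1 - max(ac$counts[[l]]) / tot
    }, 0)
    drop <- which(maf < params$min_maf)
    note(round, "v_maf", "locus", n_loci(G), locus_id(G, drop))
    if (length(drop)) { G <- subset_genotypes(G, loci = -drop); removed_any <- TRUE }
    if (n_loci(G) == 0) stop("all data filtered: no loci remain")

    # (vi) heterozygosity outlier samples
    if (n_samples(G) >= 3L) {
      flagged <- sample_het_outliers(G, params)
    } else {
      flagged <- character(0)
    }
    note(round, "vi_het_outlier", "sample", n_samples(G), flagged)
    if (length(flagged)) {
      G <- subset_genotypes(G, samples = setdiff(G$sample_ids, flagged))
      removed_any <- TRUE
    }
    if (n_samples(G) == 0) stop("all data filtered: no samples remain")

    if (!removed_any) break
  }
  list(genotypes = G, report = do.call(rbind, report))
}
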