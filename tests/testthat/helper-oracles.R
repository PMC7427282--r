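# Independent oracles and small fixture builders used across the suite.
# Each oracle is a direct, unvectorised transcription of the defining
# formula, kept deliberately separate from the package implementation.

# Exact HWE test by full enumeration: probability of each heterozygote
# configuration computed from the closed-form count of allele
# arrangements, P(h) = [n! / (nAA! h! naa!)] 2^h / C(2n, nA).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  nB <- 2 * n_aa + n_Aa
  if (nA == 0 || nB == 0) return(1)
  hets <- seq(nA %% 2, min(nA, nB), by = 2)
  prob <- vapply(hets, function(h) {
    nAA_h <- (nA - h) / 2
    naa_h <- (nB - h) / 2
    exp(lfactorial(n) - lfactorial(nAA_h) - lfactorial(h) -
          lfactorial(naa_h) + h * log(2) - lchoose(2 * n, nA))
  }, 0)
  p_obs <- prob[match(n_Aa, hets)]
  min(1, sum(prob[prob <= p_obs * (1 + 1e-12)]))
}

# Loiselle kinship by direct triple loop over pairs, loci and alleles.
loiselle_oracle <- function(G) {
  n <- length(G$sample_ids)
  L <- nrow(G$loci)
  freqs <- vector("list", L)
  ngeno <- integer(L)
  for (l in seq_len(L)) {
    k <- length(G$alleles[[l]])
    cnt <- rep(0, k)
    for (i in seq_len(n)) {
      if (!is.na(G$a1[i, l])) {
        cnt[G$a1[i, l] + 1] <- cnt[G$a1[i, l] + 1] + 1
        cnt[G$a2[i, l] + 1] <- cnt[G$a2[i, l] + 1] + 1
        ngeno[l] <- ngeno[l] + 1
      }
    }
    freqs[[l]] <- if (sum(cnt) > 0) cnt / sum(cnt) else cnt
  }
  out <- NULL
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      num <- 0; den <- 0; used <- 0
      for (l in seq_len(L)) {
        if (is.na(G$a1[i, l]) || is.na(G$a1[j, l])) next
        p <- freqs[[l]]
        if (sum(p > 0) < 2) { used <- used + 1; next }
        for (a in seq_along(p)) {
          xi <- ((G$a1[i, l] == a - 1) + (G$a2[i, l] == a - 1)) / 2
          xj <- ((G$a1[j, l] == a - 1) + (G$a2[j, l] == a - 1)) / 2
          num <- num + (xi - p[a]) * (xj - p[a]) +
            p[a] * (1 - p[a]) / (ngeno[l] - 1)
          den <- den + p[a] * (1 - p[a])
        }
        used <- used + 1
      }
      out <- rbind(out, data.frame(sample_i = G$sample_ids[i],
                                   sample_j = G$sample_ids[j],
                                   k = num / den, n_loci_used = used))
    }
  }
  out
}

# Rarefied allelic richness by brute-force averaging of distinct-allele
# counts over all C(N, g) gene-copy subsets.
ar_oracle <- function(copies, g) {
  subs <- utils::combn(length(copies), g)
  mean(apply(subs, 2, function(s) length(unique(copies[s]))))
}

# Compact builder: genotypes given as a samples x loci character matrix
# of "a/b" strings ("./." = missing), alleles indexed from 0.
make_geno <- function(gt, chrom = NULL, pos = NULL, n_alleles = NULL) {
  gt <- as.matrix(gt)
  n <- nrow(gt); L <- ncol(gt)
  a1 <- matrix(NA_integer_, n, L); a2 <- a1
  for (l in seq_len(L)) {
    sp <- strsplit(gt[, l], "/", fixed = TRUE)
    v1 <- suppressWarnings(as.integer(vapply(sp, `[`, "", 1)))
    v2 <- suppressWarnings(as.integer(vapply(sp, `[`, "", 2)))
    a1[, l] <- v1; a2[, l] <- v2
  }
  if (is.null(chrom)) chrom <- rep("chr1", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000000L
  if (is.null(n_alleles)) {
    n_alleles <- pmax(apply(a2, 2, max, na.rm = TRUE) + 1L, 2L)
  }
  alleles <- lapply(n_alleles, function(k) LETTERS[seq_len(k)])
  genotype_matrix(sprintf("I%02d", seq_len(n)), chrom, pos, alleles, a1, a2)
}

# Minimal metadata for a genotype matrix.
make_meta <- function(G, habitat = NULL, site = NULL, locality = "L",
                      x = NULL, y = NULL) {
  n <- length(G$sample_ids)
  if (is.null(habitat)) habitat <- rep("peridomestic", n)
  if (is.null(site)) site <- ifelse(habitat == "forest", "forest_site", "village_site")
  md <- data.frame(sample_id = G$sample_ids, locality = locality,
                   site = site, habitat = habitat, stringsAsFactors = FALSE)
  if (!is.null(x)) { md$x <- x; md$y <- y }
  validate_metadata(md)
}

# default two-site simulation layout used in many tests
two_site <- function(n1 = 20L, n2 = 20L) {
  data.frame(site = c("forest", "village"),
             habitat = c("forest", "peridomestic"),
             n = c(n1, n2), x = c(0, 5000), y = c(0, 0))
}
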