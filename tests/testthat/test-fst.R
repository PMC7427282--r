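test_that("theta approaches 1 for fixed alternative alleles and 0 for identical groups", {
  gt <- rbind(matrix("0/0", 20, 10), matrix("1/1", 20, 10))
  G <- make_geno(gt)
  groups <- rep(c("g1", "g2"), each = 20)
  fst <- wc_fst(G, groups)
  expect_gt(fst$theta_w, 0.97)
  # one group duplicated into two identical groups: theta ~ 0
  sim <- simulate_cohort(sim_config(
    sites = data.frame(site = "v", habitat = "peridomestic", n = 30L),
    n_loci = 300L, F_div = 1e-9, coords = FALSE, seed = 3))
  Gd <- subset_genotypes(sim$genotypes, samples = c(1:30, 1:30))
  Gd$sample_ids <- sprintf("D%02d", 1:60)
  fd <- wc_fst(Gd, rep(c("a", "b"), each = 30))
  # identical groups: near zero, slightly negative (order -1/(2n-1))
  expect_lt(fd$theta_w, 0.005)
  expect_gt(fd$theta_w, -0.04)
})

test_that("theta matches a direct transcription of the variance components", {
  # independent scalar-loop transcription of the two-group estimator
  wc_oracle <- function(G, groups) {
    glab <- unique(groups)
    r <- length(glab)
    num <- den <- 0
    for (l in seq_len(nrow(G$loci))) {
      n_i <- p_i <- h_i <- numeric(r)
      for (i in seq_len(r)) {
        rows <- which(groups == glab[i] & !is.na(G$a1[, l]))
        n_i[i] <- length(rows)
        p_i[i] <- sum(G$a1[rows, l] == 1) + sum(G$a2[rows, l] == 1)
        p_i[i] <- p_i[i] / (2 * n_i[i])
        h_i[i] <- mean(G$a1[rows, l] != G$a2[rows, l])
      }
      nbar <- mean(n_i)
      nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
      pbar <- sum(n_i * p_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(n_i * h_i) / sum(n_i)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - s2 * (r - 1) / r -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + 2 * a  # both alleles contribute symmetrically
      den <- den + 2 * (a + b + cc)
    }
    num / den
  }
  sim <- simulate_cohort(sim_config(sites = two_site(15L, 15L),
                                    n_loci = 80L, F_div = 0.05,
                                    missing_rate = 0.05, seed = 17))
  groups <- sim$truth$deme_of_sample
  expect_equal(wc_fst(sim$genotypes, groups)$theta_w,
               wc_oracle(sim$genotypes, groups), tolerance = 1e-10)
})

test_that("multilocus theta recovers the Balding-Nichols divergence", {
  st <- two_site(50L, 50L)
  for (s in 1:2) {
    sim <- simulate_cohort(sim_config(sites = st, n_loci = 2000L,
                                      F_div = 0.05, coords = FALSE, seed = s))
    th <- wc_fst(sim$genotypes, sim$truth$deme_of_sample)$theta_w
    expect_lt(abs(th - 0.05), 0.01)
  }
})

test_that("theta is invariant to sample and locus order", {
  sim <- simulate_cohort(sim_config(sites = two_site(12L, 12L),
                                    n_loci = 150L, F_div = 0.03, seed = 9))
  G <- sim$genotypes
  groups <- sim$truth$deme_of_sample
  t0 <- wc_fst(G, groups)$theta_w
  set.seed(1)
  sp <- sample(24)
  expect_equal(wc_fst(subset_genotypes(G, samples = sp), groups[sp])$theta_w,
               t0, tolerance = 1e-12)
  lp <- sample(150)
  Gp <- genotype_matrix(G$sample_ids, G$loci$chrom[lp], G$loci$pos[lp],
                        G$alleles[lp], G$a1[, lp], G$a2[, lp])
  expect_equal(wc_fst(Gp, groups)$theta_w, t0, tolerance = 1e-12)
})

test_that("pairwise matrix is symmetric and orders as constructed", {
  sim <- simulate_cohort(sim_config(
    sites = data.frame(site = c("s1", "s2", "s3"),
                       habitat = c("forest", "peridomestic", "domestic"),
                       n = c(15L, 15L, 15L)),
    n_loci = 400L, F_div = 0.04, coords = FALSE, seed = 13))
  # make A and B genuinely identical populations: copy deme assignment
  G <- sim$genotypes
  site <- sim$truth$site_of_sample
  # A = forest deme, B = forest deme (duplicate individuals), C = village
  idx_f <- which(site == "s1")
  Gd <- subset_genotypes(G, samples = c(idx_f, idx_f, which(site != "s1")[1:15]))
  Gd$sample_ids <- sprintf("X%02d", seq_len(45))
  gl <- rep(c("A", "B", "C"), each = 15)
  m <- pairwise_fst(Gd, gl)
  expect_equal(m, t(m))
  expect_lt(m["A", "B"], 0.005)  # identical groups, small negative offset
  expect_gt(m["A", "B"], -0.07)
  expect_gt(m["A", "C"], m["A", "B"])
  expect_equal(m["A", "C"], m["B", "C"], tolerance = 0.01)
})

test_that("ratio-of-sums and mean-of-ratios coincide only for homogeneous loci", {
  gt <- rbind(matrix("0/0", 10, 4), matrix("1/1", 10, 4))
  G <- make_geno(gt)
  fst <- wc_fst(G, rep(c("a", "b"), each = 10))
  expect_equal(fst$theta_w, fst$theta_mean, tolerance = 1e-12)
  # heterogeneous loci: the two summaries diverge
  sim <- simulate_cohort(sim_config(sites = two_site(15L, 15L),
                                    n_loci = 300L, F_div = 0.05, seed = 19))
  f2 <- wc_fst(sim$genotypes, sim$truth$deme_of_sample)
  expect_false(isTRUE(all.equal(f2$theta_w, f2$theta_mean, tolerance = 1e-6)))
})

test_that("permutation p-value hits its floor when observed exceeds all permutations", {
  gt <- rbind(matrix("0/0", 10, 8), matrix("1/1", 10, 8))
  G <- make_geno(gt)
  res <- fst_permutation_test(G, rep(c("a", "b"), each = 10),
                              n_perm = 999, seed = 2)
  expect_equal(res$p_value, 0.001)
  expect_warning(fst_permutation_test(G, rep(c("a", "b"), each = 10),
                                      n_perm = 49, seed = 2), "granularity")
})

test_that("window arithmetic matches the closed form and wc_fst restricted to windows", {
  sim <- simulate_cohort(sim_config(sites = two_site(15L, 15L),
                                    n_loci = 200L,
                                    chrom_lengths = c(chr1 = 1990000),
                                    F_div = 0.05, seed = 23))
  groups <- sim$truth$deme_of_sample
  sc <- sliding_window_fst(sim$genotypes, groups,
                           chrom_lengths = c(chr1 = 1990000))
  # floor((L - window)/step) + 1 fully contained windows
  expect_equal(attr(sc, "n_windows_total"),
               floor((1990000 - 1e6) / 1e4) + 1)
  expect_equal(sc$end - sc$start + 1, rep(1e6, nrow(sc)))
  expect_equal(diff(unique(sc$start)) %% 1e4, rep(0, length(unique(sc$start)) - 1))
  # consistency: each window equals wc_fst on its loci
  for (i in c(1, nrow(sc) %/% 2, nrow(sc))) {
    inw <- which(sim$genotypes$loci$pos >= sc$start[i] &
                   sim$genotypes$loci$pos <= sc$end[i])
    fw <- wc_fst(subset_genotypes(sim$genotypes, loci = inw), groups)
    expect_equal(sc$theta_w[i], fw$theta_w, tolerance = 1e-10)
    expect_equal(sc$n_snps[i], fw$n_loci)
  }
})

test_that("a chromosome shorter than one window yields a single flagged window", {
  sim <- simulate_cohort(sim_config(sites = two_site(10L, 10L),
                                    n_loci = 50L,
                                    chrom_lengths = c(tiny = 400000),
                                    F_div = 0.02, seed = 27))
  sc <- sliding_window_fst(sim$genotypes, sim$truth$deme_of_sample,
                           chrom_lengths = c(tiny = 400000))
  expect_equal(nrow(sc), 1)
  expect_equal(attr(sc, "short_chroms"), "tiny")
  expect_equal(sc$start, 1)
})
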