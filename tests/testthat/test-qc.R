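test_that("exact HWE test matches its defining examples", {
  # every feasible het count is included when the observed one is modal
  expect_equal(hwe_exact_test(1, 2, 1), 1)
  # single feasible outcome / monomorphic convention
  expect_equal(as.numeric(hwe_exact_test(3, 0, 0)), 1)
  expect_true(attr(hwe_exact_test(3, 0, 0), "monomorphic"))
  # extreme heterozygote deficit fails far below the cascade threshold
  expect_lt(hwe_exact_test(50, 0, 50), 1e-5)
  expect_error(hwe_exact_test(0, 0, 0), "empty")
})

test_that("exact HWE test agrees with the enumeration oracle on random tables", {
  set.seed(1)
  for (rep in 1:200) {
    n <- sample(1:20, 1)
    nAA <- sample(0:n, 1)
    nAa <- sample(0:(n - nAA), 1)
    naa <- n - nAA - nAa
    expect_equal(as.numeric(hwe_exact_test(nAA, nAa, naa)),
                 hwe_oracle(nAA, nAa, naa), tolerance = 1e-12)
  }
})

test_that("VIF pruning removes collinear loci within a window and spares distant ones", {
  set.seed(3)
  d <- matrix(rbinom(200, 2, 0.5), 100, 2)
  d[, 2] <- d[, 1]  # perfect copy
  G <- make_geno(matrix(c("0/0", "0/1", "1/1")[d + 1], 100, 2),
                 pos = c(100000L, 101000L))
  kept <- vif_prune(G)
  expect_equal(kept, 1L)  # tie rule keeps the smaller position
  # same pair but > 75 kb apart: never co-windowed, both kept
  G2 <- G; G2$loci$pos <- c(100000L, 200000L)
  expect_equal(vif_prune(G2), c(1L, 2L))
})

test_that("VIF pruning matches a brute-force maximal retained set on a planted instance", {
  set.seed(11)
  n <- 120
  base <- matrix(rbinom(n * 4, 2, 0.5), n, 4)
  noisy_sum <- pmin(2, pmax(0, round((base[, 1] + base[, 2]) / 2 +
                                       rnorm(n, 0, 0.12))))
  D <- cbind(base[, 1:2], noisy_sum, base[, 3:4])
  gt <- matrix(c("0/0", "0/1", "1/1")[D + 1], n, 5)
  G <- make_geno(gt, pos = c(10000L, 20000L, 30000L, 40000L, 50000L))
  kept <- vif_prune(G)
  expect_false(3L %in% kept)  # the constructed sum-signal locus goes
  # brute force: largest subset with all VIF <= 2
  vif_ok <- function(cols) {
    if (length(cols) < 2) return(TRUE)
    R <- stats::cor(D[, cols])
    all(diag(solve(R)) <= 2 + 1e-12)
  }
  best <- NULL
  for (k in 5:1) {
    cands <- utils::combn(5, k, simplify = FALSE)
    ok <- Filter(vif_ok, cands)
    if (length(ok)) { best <- ok; break }
  }
  expect_true(length(kept) == length(best[[1]]))
  expect_true(any(vapply(best, function(b) setequal(b, kept), TRUE)))
})

test_that("retained loci satisfy the VIF bound in every window (post-hoc)", {
  sim <- simulate_cohort(sim_config(sites = two_site(30L, 30L),
                                    n_loci = 150L,
                                    chrom_lengths = c(chr1 = 2e6),
                                    F_div = 0.02, seed = 5))
  G <- sim$genotypes
  kept <- vif_prune(G)
  Gk <- subset_genotypes(G, loci = kept)
  dos <- alt_dosage(Gk)
  pos <- Gk$loci$pos
  for (s in seq(min(pos), max(pos), by = 37500)) {
    inw <- which(pos >= s & pos <= s + 74999)
    if (length(inw) < 2) next
    R <- stats::cor(dos[, inw, drop = FALSE])
    if (any(!is.finite(R))) next
    expect_true(all(diag(solve(R)) <= 2 + 1e-6))
  }
})

test_that("heterozygosity outlier flagging follows the z-score rule", {
  gt <- matrix(rep(c("0/0", "0/1", "1/1"), length.out = 20 * 10), 20, 10)
  G <- make_geno(gt)
  # identical rotation: positive SD but no 3-SD outliers expected; now
  # plant an all-heterozygous sample
  gt2 <- gt; gt2[20, ] <- "0/1"
  set.seed(8)
  for (i in 1:19) gt2[i, ] <- sample(c("0/0", "0/1", "1/1"), 10, TRUE)
  G2 <- make_geno(gt2)
  flagged <- sample_het_outliers(G2)
  expect_equal(flagged, G2$sample_ids[20])
  # zero SD: identical samples, nobody flagged
  G3 <- make_geno(matrix("0/1", 5, 4))
  expect_length(sample_het_outliers(G3), 0)
  expect_error(sample_het_outliers(make_geno(matrix("0/1", 2, 4))),
               ">= 3 samples")
})

test_that("filter cascade removes exactly the planted fixture violations", {
  fx <- generate_qc_fixture(seed = 1)
  res <- apply_filter_cascade(fx$genotypes, fx$metadata)
  removed <- sort(unlist(res$report$removed_ids))
  expect_identical(removed, sort(fx$manifest$id))
  # stage attribution matches the manifest
  for (i in seq_len(nrow(res$report))) {
    ids <- res$report$removed_ids[[i]]
    if (!length(ids)) next
    expect_setequal(ids,
                    fx$manifest$id[fx$manifest$stage == res$report$stage[i]])
  }
  # report bookkeeping: removed + retained = input at every stage
  expect_true(all(res$report$n_removed + res$report$n_retained ==
                    res$report$n_input))
})

test_that("cascade is idempotent on clean data and errors on all-monomorphic input", {
  fx <- generate_qc_fixture(violations = "maf", seed = 2)
  clean <- generate_qc_fixture(violations = character(0), seed = 2)
  expect_error(generate_qc_fixture(violations = "bogus"))
  res <- apply_filter_cascade(clean$genotypes, clean$metadata)
  expect_equal(sum(res$report$n_removed), 0)
  expect_equal(n_loci(res$genotypes), n_loci(clean$genotypes))
  mono <- make_geno(matrix("0/0", 10, 5))
  md <- make_meta(mono)
  expect_error(apply_filter_cascade(mono, md), "all data filtered")
})

test_that("removal decisions are invariant to input locus order", {
  fx <- generate_qc_fixture(seed = 3)
  G <- fx$genotypes
  set.seed(9)
  perm <- sample(n_loci(G))
  Gp <- genotype_matrix(G$sample_ids, G$loci$chrom[perm], G$loci$pos[perm],
                        G$alleles[perm], G$a1[, perm], G$a2[, perm])
  r1 <- apply_filter_cascade(G, fx$metadata)
  r2 <- apply_filter_cascade(Gp, fx$metadata)
  expect_identical(sort(unlist(r1$report$removed_ids)),
                   sort(unlist(r2$report$removed_ids)))
})
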