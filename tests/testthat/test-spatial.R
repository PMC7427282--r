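test_that("pair categories follow the location and habitat rules", {
  md <- data.frame(
    sample_id = c("f1", "d1", "p1", "d2"),
    locality = "L", site = c("forest_patch", "v1", "v1", "v2"),
    habitat = c("forest", "domestic", "peridomestic", "domestic"))
  K <- data.frame(sample_i = c("f1", "p1", "p1", "d1"),
                  sample_j = c("d1", "d2", "d1", "d2"),
                  k = 0, n_loci_used = 10L)
  loc <- categorize_pairs(K, md, "by_location")$category
  expect_equal(loc, c("forest_village", "between_villages",
                      "within_village", "between_villages"))
  hab <- categorize_pairs(K, md, "by_habitat")$category
  expect_equal(hab, c("forest-domestic", "peridomestic-domestic",
                      "peridomestic-domestic", "domestic-domestic"))
  expect_error(categorize_pairs(
    data.frame(sample_i = "f1", sample_j = "zz", k = 0), md, "by_location"),
    "zz")
})

test_that("Mantel r is exactly -1 for perfectly anticorrelated matrices", {
  set.seed(1)
  n <- 8
  md <- data.frame(sample_id = sprintf("m%d", 1:n), locality = "L",
                   site = "s", habitat = "peridomestic",
                   x = runif(n, 0, 1000), y = runif(n, 0, 1000))
  D <- pair_distances(validate_metadata(md))
  pr <- t(utils::combn(md$sample_id, 2))
  K <- data.frame(sample_i = pr[, 1], sample_j = pr[, 2],
                  k = 5 - 0.001 * D[pr], n_loci_used = 10L)
  m <- mantel_test(K, md, n_perm = 999, seed = 2)
  expect_equal(m$r, -1, tolerance = 1e-12)
  expect_equal(m$p_value, 0.001)
  # zero-variance distances are rejected
  md0 <- md; md0$x <- 5; md0$y <- 5
  expect_error(mantel_test(K, md0, seed = 1), "zero variance")
})

test_that("Mantel statistic agrees with vegan and is affine-invariant", {
  skip_if_not_installed("vegan")
  sim <- simulate_cohort(sim_config_rabai(n_loci = 300L, seed = 14))
  K <- loiselle_kinship(sim$genotypes)
  m <- mantel_test(K, sim$metadata, n_perm = 99, seed = 3)
  ids <- sort(unique(c(K$sample_i, K$sample_j)))
  Km <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  Km[cbind(match(K$sample_i, ids), match(K$sample_j, ids))] <- K$k
  Km <- Km + t(Km)
  D <- pair_distances(sim$metadata, ids)
  vg <- vegan::mantel(stats::as.dist(Km), stats::as.dist(D),
                      permutations = 99)
  expect_equal(m$r, unname(vg$statistic), tolerance = 1e-10)
  # common affine rescaling of either matrix leaves r unchanged
  K2 <- K; K2$k <- 3 * K2$k + 7
  m2 <- mantel_test(K2, sim$metadata, n_perm = 99, seed = 3)
  expect_equal(m2$r, m$r, tolerance = 1e-12)
})

test_that("distance residualisation satisfies OLS identities", {
  set.seed(4)
  n <- 10
  md <- data.frame(sample_id = sprintf("r%d", 1:n), locality = "L",
                   site = "s", habitat = "domestic",
                   x = runif(n, 0, 2000), y = runif(n, 0, 2000))
  D <- pair_distances(validate_metadata(md))
  pr <- t(utils::combn(md$sample_id, 2))
  # k exactly linear in distance: residuals all zero
  K <- data.frame(sample_i = pr[, 1], sample_j = pr[, 2],
                  k = 0.2 - 1e-5 * D[pr], n_loci_used = 5L)
  K1 <- distance_residual_kinship(K, md)
  expect_equal(K1$residual, rep(0, nrow(K)), tolerance = 1e-10)
  expect_equal(attr(K1, "slope"), -1e-5, tolerance = 1e-10)
  # zero-slope data: residuals are the centred values
  K$k <- rnorm(nrow(K))
  K$k <- K$k - stats::lm(k ~ D[pr], data = K)$coefficients[2] * D[pr]
  K2 <- distance_residual_kinship(K, md)
  expect_equal(K2$residual, K$k - mean(K$k), tolerance = 1e-8)
  # orthogonality: residuals uncorrelated with distance
  K$k <- rnorm(nrow(K)) - 1e-5 * D[pr]
  K3 <- distance_residual_kinship(K, md)
  expect_equal(stats::cor(K3$residual, K3$distance), 0, tolerance = 1e-10)
})

test_that("fast F and Welch t helpers match the stats-package fits", {
  set.seed(6)
  v <- rnorm(60)
  f <- sample(1:3, 60, replace = TRUE)
  F_pkg <- vectorpop:::.oneway_F(v, f, 3)
  fit <- stats::anova(stats::lm(v ~ factor(f)))
  expect_equal(F_pkg, fit$`F value`[1], tolerance = 1e-12)
  t_pkg <- vectorpop:::.welch_t(v[f == 1], v[f == 2])
  tt <- stats::t.test(v[f == 1], v[f == 2])
  expect_equal(t_pkg, unname(tt$statistic), tolerance = 1e-12)
})

test_that("resampled ANOVA handles degenerate and structured inputs", {
  sim <- simulate_cohort(sim_config_lalope(n_loci = 200L, F_div = 0.05,
                                           seed = 21))
  K <- loiselle_kinship(sim$genotypes)
  # all pair values equal: F = 0, p = 1
  K0 <- K; K0$k <- 0.1
  a0 <- grouped_anova_resampled(K0, sim$metadata, "by_location",
                                n_iter = 99, seed = 1)
  expect_equal(a0$anova_F, 0)
  expect_equal(a0$anova_p, 1)
  # diverged forest deme: within-forest kinship exceeds forest-village
  a1 <- grouped_anova_resampled(K, sim$metadata, "by_location",
                                n_iter = 199, seed = 1)
  Kc <- categorize_pairs(K, sim$metadata, "by_location")
  expect_gt(mean(Kc$k[Kc$category == "within_forest"]),
            mean(Kc$k[Kc$category == "forest_village"]))
  expect_lt(a1$anova_p, 0.05)
  # Holm adjustment is the step-down of the raw resampled p-values
  expect_equal(a1$posthoc$p_holm,
               stats::p.adjust(a1$posthoc$p_raw, method = "holm"))
  expect_error(grouped_anova_resampled(K0, sim$metadata, "by_location",
                                       value_col = "nope"), "nope")
})

test_that("bootstrap resampling mode runs and reports redraws", {
  sim <- simulate_cohort(sim_config_lalope(n_loci = 150L, F_div = 0.02,
                                           seed = 25))
  K <- loiselle_kinship(sim$genotypes)
  a <- grouped_anova_resampled(K, sim$metadata, "by_location",
                               n_iter = 59, seed = 2, method = "bootstrap")
  expect_true(is.finite(a$anova_F))
  expect_true(a$anova_p > 0 && a$anova_p <= 1)
  expect_gte(a$n_redraws, 0)
  expect_equal(a$method, "bootstrap")
})
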