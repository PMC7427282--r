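# unordered habitat pair label, forest < peridomestic < domestic
.habitat_pair <- function(hi, hj) {
  ord <- c(forest = 1L, peridomestic = 2L, domestic = 3L)
  lab <- names(ord)
  paste(lab[pmin(ord[hi], ord[hj])], lab[pmax(ord[hi], ord[hj])], sep = "-")
}

#' Assign habitat-pair categories to sample pairs
#'
#' Two schemes. `"by_location"`: `within_forest` (both members collected
#' in the forest), `forest_village` (one forest, one village member, where
#' village = peridomestic or domestic), `within_village` (both from the
#' same village site) and `between_villages` (village members from
#' different sites; only arises with >= 2 villages). `"by_habitat"`: the
#' six unordered habitat pairs (forest-forest, forest-peridomestic,
#' forest-domestic, peridomestic-peridomestic, peridomestic-domestic,
#' domestic-domestic).
#'
#' @param K a `pair_kinship` table (see [loiselle_kinship]).
#' @param metadata sample metadata covering every sample in `K`.
#' @param scheme `"by_location"` or `"by_habitat"`.
#' @return `K` with a `category` column added.
#' @export
categorize_pairs <- function(K, metadata,
                             scheme = c("by_location", "by_habitat")) {
  scheme <- match.arg(scheme)
  metadata <- validate_metadata(metadata)
  mi <- match(K$sample_i, metadata$sample_id)
  mj <- match(K$sample_j, metadata$sample_id)
  if (anyNA(mi) || anyNA(mj)) {
    stop("metadata missing for sample(s): ",
         paste(unique(c(K$sample_i[is.na(mi)], K$sample_j[is.na(mj)])),
               collapse = ", "))
  }
  hi <- metadata$habitat[mi]; hj <- metadata$habitat[mj]
  if (scheme == "by_habitat") {
    K$category <- .habitat_pair(hi, hj)
  } else {
    si <- metadata$site[mi]; sj <- metadata$site[mj]
    fi <- hi == "forest"; fj <- hj == "forest"
    K$category <- ifelse(fi & fj, "within_forest",
                  ifelse(xor(fi, fj), "forest_village",
                  ifelse(si == sj, "within_village", "between_villages")))
  }
  K
}

#' Pairwise geographic distances between samples
#'
#' Great-circle (haversine, metres) for `lat`/`lon` metadata, Euclidean
#' for planar `x`/`y`. Errors when the metadata carry no coordinates.
#'
#' @param metadata sample metadata with coordinates.
#' @param sample_ids which samples (default: all metadata rows), in order.
#' @return symmetric distance matrix with sample ids as dimnames.
#' @export
pair_distances <- function(metadata, sample_ids = metadata$sample_id) {
  metadata <- validate_metadata(metadata)
  ct <- attr(metadata, "coord_type")
  md <- metadata[match(sample_ids, metadata$sample_id), ]
  if (ct == "latlon") {
    D <- geosphere::distm(cbind(md$lon, md$lat))
  } else if (ct == "planar") {
    D <- as.matrix(stats::dist(cbind(md$x, md$y)))
  } else {
    stop("metadata carry no coordinates; distance-based analyses unavailable")
  }
  dimnames(D) <- list(sample_ids, sample_ids)
  D
}

# lower-triangle Pearson correlation between two square matrices
.lower_cor <- function(A, B) {
  lt <- lower.tri(A)
  stats::cor(A[lt], B[lt])
}

#' Mantel test between kinship and geographic distance
#'
#' Pearson correlation r over the n(n-1)/2 pair entries of the kinship
#' and geographic-distance matrices, with significance from jointly
#' permuting the sample labels of one matrix:
#' p = (#{permuted r at least as extreme} + 1)/(n_perm + 1). Two-sided by
#' default (|r_perm| >= |r_obs|); one-sided alternatives available.
#'
#' @param K a `pair_kinship` table.
#' @param metadata sample metadata with coordinates for every sample in
#'   `K` (>= 4 samples).
#' @param n_perm permutations (default 999).
#' @param seed integer seed.
#' @param alternative `"two.sided"` (default), `"negative"` or
#'   `"positive"`.
#' @return list with `r`, `p_value`, `n_perm`, `alternative`, `seed`,
#'   `n_samples`.
#' @export
mantel_test <- function(K, metadata, n_perm = 999L, seed = 1L,
                        alternative = c("two.sided", "negative", "positive")) {
  alternative <- match.arg(alternative)
  ids <- sort(unique(c(K$sample_i, K$sample_j)))
  if (length(ids) < 4L) stop("Mantel test needs at least 4 samples")
  Km <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  Km[cbind(match(K$sample_i, ids), match(K$sample_j, ids))] <- K$k
  Km <- Km + t(Km)
  D <- pair_distances(metadata, ids)
  lt <- lower.tri(D)
  if (stats::sd(D[lt]) == 0) stop("zero variance in geographic distances")
  if (stats::sd(Km[lt]) == 0) stop("zero variance in kinship values")
  r_obs <- .lower_cor(Km, D)
  set.seed(seed)
  n <- length(ids)
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pp <- sample.int(n)
    r_perm[b] <- .lower_cor(Km[pp, pp], D)
  }
  extreme <- switch(alternative,
                    two.sided = sum(abs(r_perm) >= abs(r_obs)),
                    negative = sum(r_perm <= r_obs),
                    positive = sum(r_perm >= r_obs))
  list(r = r_obs, p_value = (extreme + 1) / (n_perm + 1), n_perm = n_perm,
       alternative = alternative, seed = seed, n_samples = n)
}

#' Remove the geographic-distance effect from pairwise kinship
#'
#' Ordinary least squares of kinship on pairwise geographic distance
#' (intercept + slope); the residuals become the distance-corrected
#' kinship used for category comparisons where coordinates exist.
#'
#' @param K a `pair_kinship` table.
#' @param metadata sample metadata with coordinates.
#' @return `K` with `distance` and `residual` columns added; attributes
#'   `intercept` and `slope` record the fit.
#' @export
distance_residual_kinship <- function(K, metadata) {
  if (nrow(K) < 3L) stop("need at least 3 pairs to fit the distance model")
  D <- pair_distances(metadata, sort(unique(c(K$sample_i, K$sample_j))))
  K$distance <- D[cbind(K$sample_i, K$sample_j)]
  fit <- stats::lm(k ~ distance, data = K)
  K$residual <- stats::residuals(fit)
  attr(K, "intercept") <- unname(stats::coef(fit)[1L])
  attr(K, "slope") <- unname(stats::coef(fit)[2L])
  K
}

# one-way ANOVA F for integer category codes 1..g (fast path used inside
# resampling loops; cross-checked against anova(lm()) in the tests)
.oneway_F <- function(v, f, g) {
  n_g <- tabulate(f, g)
  use <- n_g > 0
  s_g <- vapply(seq_len(g), function(i) sum(v[f == i]), 0)
  m_g <- s_g[use] / n_g[use]
  gm <- sum(s_g) / sum(n_g)
  ssb <- sum(n_g[use] * (m_g - gm)^2)
  ssw <- sum((v - (s_g / n_g)[f])^2)
  k <- sum(use)
  if (ssw == 0) return(if (ssb == 0) 0 else Inf)
  (ssb / (k - 1)) / (ssw / (length(v) - k))
}

# Welch t statistic between two value vectors
.welch_t <- function(x, y) {
  (mean(x) - mean(y)) /
    sqrt(stats::var(x) / length(x) + stats::var(y) / length(y))
}

#' Category comparison of pairwise kinship with a resampled null
#'
#' One-way ANOVA of a per-pair statistic (raw kinship, or its distance
#' residual) across pair categories, with P-values from a resampling
#' scheme that respects the non-independence of pairs sharing an
#' individual: the exchangeable unit is the individual. Under the default
#' `method = "permute"`, individual habitat/site labels are permuted, the
#' pair categories recomputed and the F statistic recomputed, `n_iter`
#' times; p = (#{F_null >= F_obs} + 1)/(n_iter + 1). Post-hoc Welch t
#' statistics for every category pair take their P-values from the same
#' resampled null (two-sided) and are Holm-adjusted. `method =
#' "bootstrap"` instead resamples individuals with replacement and
#' rebuilds the pairs; iterations that empty a category are redrawn and
#' counted.
#'
#' @param K a `pair_kinship` table.
#' @param metadata sample metadata for every sample in `K`.
#' @param scheme pair-category scheme, see [categorize_pairs].
#' @param value_col column of `K` holding the per-pair statistic
#'   (default `"k"`; use `"residual"` after
#'   [distance_residual_kinship]).
#' @param n_iter resampling iterations (default 1000).
#' @param seed integer seed.
#' @param method `"permute"` (default) or `"bootstrap"`.
#' @return list of class `spatial_anova`: `anova_F`, `anova_p`,
#'   `posthoc` (data.frame cat1, cat2, t, p_raw, p_holm), `n_pairs`
#'   (named per-category counts), `categories`, `value_col`, `method`,
#'   `n_iter`, `n_redraws`, `seed`.
#' @export
grouped_anova_resampled <- function(K, metadata,
                                    scheme = c("by_location", "by_habitat"),
                                    value_col = "k", n_iter = 1000L,
                                    seed = 1L,
                                    method = c("permute", "bootstrap")) {
  scheme <- match.arg(scheme)
  method <- match.arg(method)
  metadata <- validate_metadata(metadata)
  ids <- sort(unique(c(K$sample_i, K$sample_j)))
  md <- metadata[match(ids, metadata$sample_id), ]
  if (anyNA(md$sample_id)) {
    stop("metadata missing for sample(s): ",
         paste(setdiff(ids, metadata$sample_id), collapse = ", "))
  }
  ii <- match(K$sample_i, ids); jj <- match(K$sample_j, ids)
  v <- K[[value_col]]
  if (is.null(v)) stop("no column '", value_col, "' in kinship table")

  cat_of <- function(hab, site) {
    if (scheme == "by_habitat") {
      .habitat_pair(hab[ii], hab[jj])
    } else {
      fi <- hab[ii] == "forest"; fj <- hab[jj] == "forest"
      ifelse(fi & fj, "within_forest",
      ifelse(xor(fi, fj), "forest_village",
      ifelse(site[ii] == site[jj], "within_village", "between_villages")))
    }
  }
  cats_obs <- cat_of(md$habitat, md$site)
  levels_obs <- sort(unique(cats_obs))
  g <- length(levels_obs)
  if (g < 2L) stop("only one pair category present; ANOVA undefined")
  f_obs <- match(cats_obs, levels_obs)
  F_obs <- .oneway_F(v, f_obs, g)

  cat_pairs <- utils::combn(levels_obs, 2L)
  t_obs <- apply(cat_pairs, 2L, function(cp)
    .welch_t(v[cats_obs == cp[1L]], v[cats_obs == cp[2L]]))

  set.seed(seed)
  n <- length(ids)
  Kmat <- NULL
  if (method == "bootstrap") {
    Kmat <- matrix(NA_real_, n, n)
    Kmat[cbind(ii, jj)] <- v; Kmat[cbind(jj, ii)] <- v
  }
  F_ge <- 0L
  t_ge <- integer(ncol(cat_pairs))
  n_redraws <- 0L
  for (b in seq_len(n_iter)) {
    repeat {
      if (method == "permute") {
        pp <- sample.int(n)
        cats_b <- cat_of(md$habitat[pp], md$site[pp])
        v_b <- v
      } else {
        draw <- sample.int(n, n, replace = TRUE)
        pr <- utils::combn(seq_len(n), 2L)
        keep <- draw[pr[1L, ]] != draw[pr[2L, ]]
        ui <- draw[pr[1L, keep]]; uj <- draw[pr[2L, keep]]
        v_b <- Kmat[cbind(ui, uj)]
        hab <- md$habitat; site <- md$site
        fi <- hab[ui] == "forest"; fj <- hab[uj] == "forest"
        cats_b <- if (scheme == "by_habitat") {
          .habitat_pair(hab[ui], hab[uj])
        } else {
          ifelse(fi & fj, "within_forest",
          ifelse(xor(fi, fj), "forest_village",
          ifelse(site[ui] == site[uj], "within_village", "between_villages")))
        }
      }
      if (all(levels_obs %in% cats_b)) break
      n_redraws <- n_redraws + 1L
    }
    f_b <- match(cats_b, levels_obs)
    ok <- !is.na(f_b)
    F_b <- .oneway_F(v_b[ok], f_b[ok], g)
    if (F_b >= F_obs) F_ge <- F_ge + 1L
    for (cp in seq_len(ncol(cat_pairs))) {
      x <- v_b[ok][f_b[ok] == match(cat_pairs[1L, cp], levels_obs)]
      y <- v_b[ok][f_b[ok] == match(cat_pairs[2L, cp], levels_obs)]
      if (length(x) > 1L && length(y) > 1L) {
        t_b <- .welch_t(x, y)
        if (is.finite(t_b) && abs(t_b) >= abs(t_obs[cp])) {
          t_ge[cp] <- t_ge[cp] + 1L
        }
      }
    }
  }
  p_raw <- (t_ge + 1) / (n_iter + 1)
  posthoc <- data.frame(cat1 = cat_pairs[1L, ], cat2 = cat_pairs[2L, ],
                        t = t_obs, p_raw = p_raw,
                        p_holm = stats::p.adjust(p_raw, method = "holm"),
                        stringsAsFactors = FALSE)
  structure(list(anova_F = F_obs, anova_p = (F_ge + 1) / (n_iter + 1),
                 posthoc = posthoc,
                 n_pairs = table(cats_obs), categories = levels_obs,
                 value_col = value_col, method = method, n_iter = n_iter,
                 n_redraws = n_redraws, seed = seed),
            class = "spatial_anova")
}

#' @export
print.spatial_anova <- function(x, ...) {
  cat(sprintf("Resampled one-way ANOVA on '%s' across %d categories (%s)\n",
              x$value_col, length(x$categories), x$method))
  cat(sprintf("  F = %.3f, resampled P = %.4g (%d iterations)\n",
              x$anova_F, x$anova_p, x$n_iter))
  cat("  pairs per category:\n")
  print(x$n_pairs)
  cat("  post-hoc (Holm-adjusted resampled P):\n")
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}
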