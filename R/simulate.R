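#' Simulation configuration for two-habitat mosquito cohorts
#'
#' Describes a cohort with the structure the analysis assumes: a forest
#' deme and a village deme diverged under the Balding-Nichols model
#' (deme allele frequency ~ Beta(p(1-F)/F, (1-p)(1-F)/F) around an
#' ancestral frequency p, so expected Fst between demes equals F),
#' within-container full-sib families, optional site-level substructure
#' that creates isolation by distance, uniform random missingness, and an
#' optional microsatellite-like multi-allelic panel.
#'
#' @param sites data.frame with columns `site`, `habitat` (forest /
#'   peridomestic / domestic), `n` (samples) and optional planar
#'   coordinates `x`, `y` in metres. Forest sites form the forest deme;
#'   all other sites the village deme.
#' @param locality locality label for the metadata.
#' @param n_loci number of biallelic SNP loci.
#' @param chrom_lengths named numeric vector of chromosome lengths in bp;
#'   loci are placed uniformly, proportionally to length.
#' @param F_div Balding-Nichols divergence of each deme from the
#'   ancestral pool (expected between-deme Fst).
#' @param F_site additional site-level divergence within each deme
#'   (> 0 switches on the isolation-by-distance structure: samples from
#'   the same site share extra ancestry, so kinship decays with
#'   distance).
#' @param ancestral_range ancestral allele frequencies are drawn
#'   uniformly on this interval (default [0.05, 0.95]).
#' @param families data.frame with columns `site` and `n_sibs`: each row
#'   plants one full-sib family (two parents drawn from the site's gene
#'   pool, sibs by Mendelian segregation) occupying `n_sibs` of that
#'   site's samples and sharing a breeding-container id.
#' @param missing_rate fraction of calls masked at random.
#' @param n_msat_loci number of multi-allelic (microsatellite-like) loci
#'   emitted as a separate matrix (0 disables).
#' @param msat_alleles alleles per microsatellite locus.
#' @param coords whether metadata carry coordinates (`FALSE` emulates the
#'   La Lope case where positions were not recorded).
#' @param seed integer seed; fixed seed gives byte-identical output.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(sites = data.frame(
                         site = c("forest", "village"),
                         habitat = c("forest", "peridomestic"),
                         n = c(11L, 8L),
                         x = c(0, 8000), y = c(0, 0)),
                       locality = "simulated",
                       n_loci = 1000L,
                       chrom_lengths = c(chr1 = 310e6, chr2 = 474e6,
                                         chr3 = 409e6),
                       F_div = 0.01,
                       F_site = 0,
                       ancestral_range = c(0.05, 0.95),
                       families = NULL,
                       missing_rate = 0,
                       n_msat_loci = 0L,
                       msat_alleles = 6L,
                       coords = TRUE,
                       seed = 1L) {
  stopifnot(is.data.frame(sites),
            all(c("site", "habitat", "n") %in% names(sites)),
            all(sites$habitat %in% c("forest", "peridomestic", "domestic")),
            F_div > 0, F_div < 1, F_site >= 0, F_site < 1,
            missing_rate >= 0, missing_rate < 1,
            n_loci >= 1, length(chrom_lengths) >= 1,
            !is.null(names(chrom_lengths)))
  if (!is.null(families)) {
    stopifnot(all(c("site", "n_sibs") %in% names(families)),
              all(families$site %in% sites$site))
    used <- tapply(families$n_sibs, families$site, sum)
    avail <- sites$n[match(names(used), sites$site)]
    if (any(used > avail)) {
      stop("more family members than samples at site(s): ",
           paste(names(used)[used > avail], collapse = ", "))
    }
  }
  structure(list(sites = sites, locality = locality,
                 n_loci = as.integer(n_loci),
                 chrom_lengths = chrom_lengths, F_div = F_div,
                 F_site = F_site, ancestral_range = ancestral_range,
                 families = families, missing_rate = missing_rate,
                 n_msat_loci = as.integer(n_msat_loci),
                 msat_alleles = as.integer(msat_alleles),
                 coords = coords, seed = as.integer(seed)),
            class = "sim_config")
}

#' La Lope-style and Rabai-style preset configurations
#'
#' Cohort layouts mirroring the two study localities: La Lope (one
#' forest site and one village, no coordinates recorded) and Rabai (one
#' forest patch plus four villages 3-7 km away, coordinates recorded).
#' Sample counts follow the SNP-panel sizes of the study design
#' (forest 11 / village 8; forest 11 and villages 9, 7, 8, 6).
#'
#' @param ... overrides passed on to [sim_config].
#' @return a `sim_config`.
#' @export
sim_config_lalope <- function(...) {
  args <- list(...)
  defaults <- list(
    sites = data.frame(site = c("forest", "lalope_village", "lalope_village"),
                       habitat = c("forest", "peridomestic", "domestic"),
                       n = c(11L, 4L, 4L)),
    locality = "La Lope-like (synthetic)",
    coords = FALSE)
  do.call(sim_config, utils::modifyList(defaults, args))
}

#' @rdname sim_config_lalope
#' @export
sim_config_rabai <- function(...) {
  args <- list(...)
  defaults <- list(
    sites = data.frame(
      site = c("forest", "village_A", "village_A", "village_B", "village_B",
               "village_C", "village_C", "village_D", "village_D"),
      habitat = c("forest", "peridomestic", "domestic", "peridomestic",
                  "domestic", "peridomestic", "domestic", "peridomestic",
                  "domestic"),
      n = c(11L, 6L, 3L, 3L, 4L, 1L, 7L, 2L, 4L),
      x = c(0, 3000, 3000, 4500, 4500, 6000, 6000, 7000, 7000),
      y = c(0, 1500, 1500, -1000, -1000, 800, 800, -500, -500)),
    locality = "Rabai-like (synthetic)",
    F_site = 0.02,
    coords = TRUE)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# draw Balding-Nichols frequencies around p with divergence F
.bn_draw <- function(p, F) {
  if (F <= 1e-12) return(p)
  stats::rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
}

# draw one diploid genotype row (a1, a2 in {0,1}) per locus from
# per-locus alt-allele frequencies
.draw_geno <- function(p) {
  list(a1 = stats::rbinom(length(p), 1L, p),
       a2 = stats::rbinom(length(p), 1L, p))
}

# Mendelian segregation: one random allele from each parent per locus
.segregate <- function(par1, par2) {
  L <- length(par1$a1)
  pick1 <- stats::runif(L) < 0.5
  pick2 <- stats::runif(L) < 0.5
  list(a1 = ifelse(pick1, par1$a1, par1$a2),
       a2 = ifelse(pick2, par2$a1, par2$a2))
}

#' Simulate a two-deme cohort with known ground truth
#'
#' Generates genotypes, metadata and a `SimTruth` record under the model
#' described in [sim_config]: ancestral frequencies uniform on the
#' configured range; forest and village deme frequencies by
#' Balding-Nichols divergence `F_div`; optional site-level divergence
#' `F_site` on top (the isolation-by-distance kernel); unrelated
#' individuals drawn in Hardy-Weinberg proportions within their site's
#' gene pool; full-sib families by Mendelian segregation from two site
#' parents, sharing a container id; uniform random missingness.
#'
#' @param config a [sim_config].
#' @return list of class `sim_cohort`: `genotypes` ([genotype_matrix]),
#'   `metadata` (data.frame), `truth` (list: `ancestral_p`, `deme_freq`
#'   (2 x L), `site_freq` (sites x L), `deme_of_sample`, `site_of_sample`,
#'   `family_of_sample` (NA = unrelated), `families` (list of sample-id
#'   vectors), `F_div`, `F_site`, `missing_rate`, `implant` (NULL until
#'   [implant_divergent_region]), `seed`), and `msat_genotypes`
#'   (multi-allelic [genotype_matrix] or NULL).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$n_loci
  # positions: uniform over the genome, proportional to chromosome length
  tot <- sum(config$chrom_lengths)
  chrom <- sample(names(config$chrom_lengths), L, replace = TRUE,
                  prob = config$chrom_lengths / tot)
  pos <- integer(L)
  for (ch in names(config$chrom_lengths)) {
    i <- chrom == ch
    pos[i] <- sort(sample.int(config$chrom_lengths[[ch]], sum(i)))
  }
  ord <- order(chrom, pos)
  chrom <- chrom[ord]; pos <- pos[ord]

  anc <- stats::runif(L, config$ancestral_range[1L], config$ancestral_range[2L])
  deme_freq <- rbind(forest = .bn_draw(anc, config$F_div),
                     village = .bn_draw(anc, config$F_div))
  sites <- config$sites
  deme_of_site <- ifelse(sites$habitat == "forest", "forest", "village")
  site_freq <- matrix(NA_real_, nrow(sites), L)
  for (s in seq_len(nrow(sites))) {
    base <- deme_freq[deme_of_site[s], ]
    site_freq[s, ] <- if (config$F_site > 0) .bn_draw(base, config$F_site) else base
  }

  n_tot <- sum(sites$n)
  ids <- sprintf("S%03d", seq_len(n_tot))
  site_of <- rep(seq_len(nrow(sites)), sites$n)
  fam_of <- rep(NA_integer_, n_tot)
  container <- paste0("C", seq_len(n_tot))
  if (!is.null(config$families)) {
    taken <- integer(0)
    for (f in seq_len(nrow(config$families))) {
      s <- match(config$families$site[f], sites$site)
      cand <- setdiff(which(site_of == s), taken)
      members <- cand[seq_len(config$families$n_sibs[f])]
      fam_of[members] <- f
      container[members] <- paste0("F", f)
      taken <- c(taken, members)
    }
  }

  a1 <- matrix(NA_integer_, n_tot, L)
  a2 <- matrix(NA_integer_, n_tot, L)
  for (i in which(is.na(fam_of))) {
    gg <- .draw_geno(site_freq[site_of[i], ])
    a1[i, ] <- gg$a1; a2[i, ] <- gg$a2
  }
  if (!is.null(config$families)) {
    for (f in seq_len(nrow(config$families))) {
      members <- which(fam_of == f)
      s <- site_of[members[1L]]
      par1 <- .draw_geno(site_freq[s, ])
      par2 <- .draw_geno(site_freq[s, ])
      for (i in members) {
        gg <- .segregate(par1, par2)
        a1[i, ] <- gg$a1; a2[i, ] <- gg$a2
      }
    }
  }
  if (config$missing_rate > 0) {
    mask <- matrix(stats::runif(n_tot * L) < config$missing_rate, n_tot, L)
    a1[mask] <- NA_integer_; a2[mask] <- NA_integer_
  }
  alleles <- rep(list(c("A", "T")), L)
  G <- genotype_matrix(ids, chrom, pos, alleles, a1, a2)

  md <- data.frame(sample_id = ids,
                   locality = config$locality,
                   site = sites$site[site_of],
                   habitat = sites$habitat[site_of],
                   container_id = container,
                   stringsAsFactors = FALSE)
  if (config$coords && all(c("x", "y") %in% names(sites))) {
    md$x <- sites$x[site_of] + stats::runif(n_tot, -100, 100)
    md$y <- sites$y[site_of] + stats::runif(n_tot, -100, 100)
  }
  md <- validate_metadata(md)

  msat <- NULL
  if (config$n_msat_loci > 0) {
    msat <- .simulate_msat(config, ids, site_of, fam_of, site_freq = NULL)
  }

  fams <- if (any(!is.na(fam_of))) {
    lapply(split(ids[!is.na(fam_of)], fam_of[!is.na(fam_of)]), identity)
  } else list()
  truth <- list(ancestral_p = anc, deme_freq = deme_freq,
                site_freq = site_freq,
                deme_of_sample = deme_of_site[site_of],
                site_of_sample = sites$site[site_of],
                family_of_sample = fam_of, families = fams,
                F_div = config$F_div, F_site = config$F_site,
                missing_rate = config$missing_rate,
                implant = NULL, seed = config$seed)
  structure(list(genotypes = G, metadata = md, truth = truth,
                 msat_genotypes = msat, config = config),
            class = "sim_cohort")
}

# multi-allelic (microsatellite-like) panel: allele frequencies from a
# symmetric Dirichlet per locus, shared across sites (these loci carry
# no divergence signal; they emulate panel structure, not selection)
.simulate_msat <- function(config, ids, site_of, fam_of, site_freq) {
  Lm <- config$n_msat_loci
  k <- config$msat_alleles
  n_tot <- length(ids)
  a1 <- matrix(NA_integer_, n_tot, Lm)
  a2 <- matrix(NA_integer_, n_tot, Lm)
  alleles <- vector("list", Lm)
  for (l in seq_len(Lm)) {
    w <- stats::rgamma(k, 1)
    p <- w / sum(w)
    alleles[[l]] <- as.character(seq(100, by = 2, length.out = k))
    a1[, l] <- sample.int(k, n_tot, replace = TRUE, prob = p) - 1L
    a2[, l] <- sample.int(k, n_tot, replace = TRUE, prob = p) - 1L
  }
  genotype_matrix(ids, chrom = paste0("msat", seq_len(Lm)),
                  pos = rep(1L, Lm), alleles = alleles, a1 = a1, a2 = a2)
}

#' Implant a locally divergent genomic region
#'
#' Re-draws the loci falling inside `[start, end]` on `chrom` with
#' between-deme divergence `F_div + delta` (new Balding-Nichols deme
#' frequencies around the stored ancestral frequencies; site structure,
#' families and missingness are regenerated the same way as in
#' [simulate_cohort]). Loci outside the interval are untouched. The
#' truth record gains the implant coordinates, making the region a
#' recoverable synthetic analogue of a genome-scan Fst peak.
#'
#' @param sim a `sim_cohort` from [simulate_cohort].
#' @param chrom chromosome of the implant.
#' @param start,end implant interval (1-based, inclusive, bp).
#' @param delta added divergence (F becomes `F_div + delta` inside).
#' @param seed integer seed for the re-draw (default: cohort seed + 1).
#' @return the modified `sim_cohort`.
#' @export
implant_divergent_region <- function(sim, chrom, start, end, delta,
                                     seed = sim$truth$seed + 1L) {
  stopifnot(inherits(sim, "sim_cohort"), delta >= 0)
  G <- sim$genotypes
  if (!chrom %in% G$loci$chrom) stop("chromosome '", chrom, "' absent from cohort")
  li <- which(G$loci$chrom == chrom & G$loci$pos >= start & G$loci$pos <= end)
  if (!length(li)) stop("implant interval contains no loci")
  if (delta == 0) return(sim)
  set.seed(seed)
  tr <- sim$truth
  cfg <- sim$config
  anc <- tr$ancestral_p[li]
  F_new <- min(tr$F_div + delta, 0.999)
  deme_new <- rbind(forest = .bn_draw(anc, F_new),
                    village = .bn_draw(anc, F_new))
  sites <- cfg$sites
  deme_of_site <- ifelse(sites$habitat == "forest", "forest", "village")
  site_new <- matrix(NA_real_, nrow(sites), length(li))
  for (s in seq_len(nrow(sites))) {
    base <- deme_new[deme_of_site[s], ]
    site_new[s, ] <- if (tr$F_site > 0) .bn_draw(base, tr$F_site) else base
  }
  site_of <- match(tr$site_of_sample, sites$site)
  fam_of <- tr$family_of_sample
  n_tot <- n_samples(G)
  for (i in which(is.na(fam_of))) {
    gg <- .draw_geno(site_new[site_of[i], ])
    G$a1[i, li] <- gg$a1; G$a2[i, li] <- gg$a2
  }
  if (any(!is.na(fam_of))) {
    for (f in unique(stats::na.omit(fam_of))) {
      members <- which(fam_of == f)
      s <- site_of[members[1L]]
      par1 <- .draw_geno(site_new[s, ])
      par2 <- .draw_geno(site_new[s, ])
      for (i in members) {
        gg <- .segregate(par1, par2)
        G$a1[i, li] <- gg$a1; G$a2[i, li] <- gg$a2
      }
    }
  }
  if (tr$missing_rate > 0) {
    mask <- matrix(stats::runif(n_tot * length(li)) < tr$missing_rate,
                   n_tot, length(li))
    G$a1[, li][mask] <- NA_integer_; G$a2[, li][mask] <- NA_integer_
  }
  # restore unordered-pair canonical form
  swap <- !is.na(G$a1) & G$a1 > G$a2
  if (any(swap)) {
    tmp <- G$a1[swap]; G$a1[swap] <- G$a2[swap]; G$a2[swap] <- tmp
  }
  tr$deme_freq[, li] <- deme_new
  tr$site_freq[, li] <- site_new
  tr$implant <- list(chrom = chrom, start = start, end = end,
                     delta = delta, n_loci = length(li), seed = seed)
  sim$genotypes <- G
  sim$truth <- tr
  sim
}

#' Generate a QC fixture with planted filter violations
#'
#' Builds a deterministic, clean two-population cohort (balanced
#' Hardy-Weinberg genotype multisets rotated across samples, so every
#' clean sample has an identical heterozygosity profile and clean loci
#' sit 80 kb apart, outside any pruning window) and plants one violation
#' per requested filter stage: a >10%-missing locus, a >10%-missing
#' sample, a heterozygote-free locus at intermediate frequency (fails
#' the exact HWE test in every population), a perfectly collinear locus
#' pair 1 kb apart (VIF = Inf), a locus with minor allele frequency
#' below 1%, and an all-heterozygous sample (>3 SD heterozygosity
#' outlier). The manifest lists each planted identifier with the cascade
#' stage expected to remove it.
#'
#' @param n_samples number of samples (multiple of the two populations;
#'   default 60).
#' @param violations character subset of `c("locus_missing",
#'   "sample_missing", "hwe", "vif", "maf", "het_outlier")`; default all.
#' @param seed integer seed (placement of planted missing calls).
#' @return list: `genotypes`, `metadata`, `manifest` (data.frame stage,
#'   unit, id).
#' @export
generate_qc_fixture <- function(n_samples = 60L,
                                violations = c("locus_missing",
                                               "sample_missing", "hwe",
                                               "vif", "maf", "het_outlier"),
                                seed = 1L) {
  if (length(violations)) {
    violations <- match.arg(violations, several.ok = TRUE)
  }
  n <- as.integer(n_samples)
  stopifnot(n >= 20L, n %% 2L == 0L)
  set.seed(seed)
  freqs <- c(0.3, 0.4, 0.5, 0.6)
  blocks <- length(freqs)
  L <- blocks * n  # one rotated block of n loci per frequency
  a1 <- matrix(NA_integer_, n, 0)
  a2 <- matrix(NA_integer_, n, 0)
  for (p in freqs) {
    nAA <- round(n * (1 - p)^2); naa <- round(n * p^2)
    nAa <- n - nAA - naa
    # interleave genotypes so any contiguous run is balanced
    slots <- integer(n); left <- c(nAA, nAa, naa); want <- left / n
    run <- c(0, 0, 0)
    for (s in seq_len(n)) {
      deficit <- want * s - run
      gpick <- which.max(ifelse(left > 0, deficit, -Inf))
      slots[s] <- gpick; run[gpick] <- run[gpick] + 1; left[gpick] <- left[gpick] - 1
    }
    g1 <- c(0L, 0L, 1L)[slots]; g2 <- c(0L, 1L, 1L)[slots]
    for (l in seq_len(n)) {  # rotation l applied to block locus l
      rot <- ((seq_len(n) - 1L + l) %% n) + 1L
      a1 <- cbind(a1, g1[rot]); a2 <- cbind(a2, g2[rot])
    }
  }
  pos <- 100000 + (seq_len(L) - 1L) * 80000
  chrom <- rep("chr1", L)
  manifest <- list()
  add_locus <- function(v1, v2, stage) {
    a1 <<- cbind(a1, as.integer(v1)); a2 <<- cbind(a2, as.integer(v2))
    newpos <- if (stage == "iv_vif") pos[length(pos)] + 1000 else
      max(pos) + 80000
    pos <<- c(pos, newpos); chrom <<- c(chrom, "chr1")
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, unit = "locus", id = paste0("chr1:", newpos),
      stringsAsFactors = FALSE)
  }
  outlier_idx <- if ("het_outlier" %in% violations) n else NA_integer_

  if ("hwe" %in% violations) {
    v <- rep(c(0L, 1L), length.out = n)  # alternating AA / aa, no hets
    g1 <- v; g2 <- v
    if (!is.na(outlier_idx)) { g1[outlier_idx] <- 0L; g2[outlier_idx] <- 1L }
    add_locus(g1, g2, "iii_hwe")
  }
  if ("vif" %in% violations) {
    base1 <- a1[, 1L]; base2 <- a2[, 1L]
    if (!is.na(outlier_idx)) { base1[outlier_idx] <- 0L; base2[outlier_idx] <- 1L }
    # base copy, then its duplicate 1 kb away; the duplicate is removed
    a1 <- cbind(a1, base1); a2 <- cbind(a2, base2)
    pos <- c(pos, max(pos) + 80000); chrom <- c(chrom, "chr1")
    add_locus(base1, base2, "iv_vif")
  }
  if ("maf" %in% violations) {
    g1 <- rep(0L, n); g2 <- rep(0L, n)
    het_at <- if (!is.na(outlier_idx)) outlier_idx else 1L
    g2[het_at] <- 1L
    add_locus(g1, g2, "v_maf")
  }
  if ("locus_missing" %in% violations) {
    g1 <- rep(c(0L, 0L, 1L), length.out = n); g2 <- rep(c(0L, 1L, 1L), length.out = n)
    if (!is.na(outlier_idx)) { g1[outlier_idx] <- 0L; g2[outlier_idx] <- 1L }
    n_miss <- ceiling(0.15 * n)
    drop <- setdiff(seq_len(n), outlier_idx)[seq_len(n_miss)]
    g1[drop] <- NA_integer_; g2[drop] <- NA_integer_
    add_locus(g1, g2, "i_locus_missing")
  }
  ids <- sprintf("Q%03d", seq_len(n))
  if ("het_outlier" %in% violations) {
    a1[outlier_idx, ] <- 0L
    a2[outlier_idx, ] <- ifelse(is.na(a2[outlier_idx, ]), NA_integer_, 1L)
    manifest[[length(manifest) + 1L]] <- data.frame(
      stage = "vi_het_outlier", unit = "sample", id = ids[outlier_idx],
      stringsAsFactors = FALSE)
  }
  if ("sample_missing" %in% violations) {
    bad <- 1L  # first sample loses 12% of the clean loci
    n_miss <- ceiling(0.12 * length(pos))
    drop <- sample(seq_len(L), n_miss)
    a1[bad, drop] <- NA_integer_; a2[bad, drop] <- NA_integer_
    manifest[[length(manifest) + 1L]] <- data.frame(
      stage = "ii_sample_missing", unit = "sample", id = ids[bad],
      stringsAsFactors = FALSE)
  }
  G <- genotype_matrix(ids, chrom, pos,
                       alleles = rep(list(c("A", "T")), length(pos)),
                       a1 = a1, a2 = a2)
  md <- data.frame(sample_id = ids, locality = "fixture",
                   site = rep(c("forest_site", "village_site"), each = n / 2L),
                   habitat = rep(c("forest", "peridomestic"), each = n / 2L),
                   stringsAsFactors = FALSE)
  list(genotypes = G, metadata = validate_metadata(md),
       manifest = do.call(rbind, manifest))
}
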