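#' End-to-end analysis pipeline
#'
#' Runs the full workflow in study order: (1) QC filter cascade,
#' (2) Loiselle kinship, (3) sibling-group detection and deduplication,
#' (4) re-run of the filter cascade on the deduplicated samples,
#' (5) per-habitat diversity plus pairwise Fst with permutation tests,
#' (6) sliding-window Fst scan of forest vs village (peridomestic and
#' domestic grouped as village), (7) spatial inference: pair
#' categorisation, Mantel test and distance residualisation when
#' coordinates exist (otherwise the residual stage is skipped with a
#' warning and raw kinship is analysed), and the resampled ANOVA.
#'
#' @param genotypes a [genotype_matrix] or path to a VCF file.
#' @param metadata a metadata data.frame or path to a metadata TSV.
#' @param params [filter_params] for both cascade runs.
#' @param sib_threshold kinship above which pairs are called siblings
#'   (default 0.1875).
#' @param scheme pair-category scheme for the spatial stage.
#' @param window_bp,step_bp,min_snps genome-scan parameters (defaults
#'   1 Mb / 10 kb / 3).
#' @param chrom_lengths optional chromosome lengths for the scan.
#' @param n_perm permutations for the Fst and Mantel tests (default 999).
#' @param n_iter resampling iterations for the ANOVA (default 1000).
#' @param seed master seed; stage seeds are derived from it and recorded.
#' @param out_dir optional directory; when given, per-stage artifacts
#'   (filtered VCF, kinship TSV, diversity TSV, Fst TSV, window TSV,
#'   spatial JSON, report) are written there.
#' @return list of class `pipeline_report` with per-stage results,
#'   parameters, seeds and counts.
#' @export
run_pipeline <- function(genotypes, metadata, params = filter_params(),
                         sib_threshold = 0.1875,
                         scheme = c("by_location", "by_habitat"),
                         window_bp = 1000000L, step_bp = 10000L,
                         min_snps = 3L, chrom_lengths = NULL,
                         n_perm = 999L, n_iter = 1000L, seed = 1L,
                         out_dir = NULL) {
  scheme <- match.arg(scheme)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  G <- if (is.character(genotypes)) stage("input", read_vcf(genotypes)) else genotypes
  md <- if (is.character(metadata)) stage("input", read_metadata(metadata)) else validate_metadata(metadata)
  warnings_log <- character(0)

  # 1. filter cascade
  f1 <- stage("filter", apply_filter_cascade(G, md, params))

  # 2-3. kinship, sibling groups, deduplication
  K0 <- stage("kinship", loiselle_kinship(f1$genotypes))
  groups <- sibling_groups(K0, threshold = sib_threshold,
                           samples = f1$genotypes$sample_ids)
  kept <- deduplicate_siblings(groups, f1$genotypes)
  n_sib_removed <- n_samples(f1$genotypes) - length(kept)
  G2 <- subset_genotypes(f1$genotypes, samples = kept)

  # 4. refilter
  f2 <- stage("refilter", apply_filter_cascade(G2, md, params))
  Gf <- f2$genotypes
  habitat <- md$habitat[match(Gf$sample_ids, md$sample_id)]
  habitat2 <- ifelse(habitat == "forest", "forest", "village")

  # 5. diversity + pairwise Fst + permutation tests (per habitat)
  div <- stage("diversity", tryCatch(diversity_table(Gf, habitat),
                                     error = function(e) {
                                       warnings_log <<- c(warnings_log,
                                         paste("diversity not run:",
                                               conditionMessage(e)))
                                       NULL
                                     }))
  fst_pair <- stage("fst", if (length(unique(habitat)) >= 2L)
    pairwise_fst(Gf, habitat) else NULL)
  fst_tests <- stage("fst", if (length(unique(habitat)) >= 2L)
    fst_permutation_test(Gf, habitat, n_perm = n_perm, seed = seed + 1L)
    else NULL)

  # 6. forest vs village sliding-window scan
  scan <- stage("scan", if (length(unique(habitat2)) == 2L)
    sliding_window_fst(Gf, habitat2, window_bp = window_bp,
                       step_bp = step_bp, min_snps = min_snps,
                       chrom_lengths = chrom_lengths) else NULL)

  # 7. spatial inference on the final kinship table
  K <- stage("kinship", loiselle_kinship(Gf))
  K <- categorize_pairs(K, md, scheme)
  has_coords <- attr(md, "coord_type") != "none"
  mantel <- NULL
  value_col <- "k"
  if (has_coords) {
    mantel <- stage("spatial", mantel_test(K, md, n_perm = n_perm,
                                           seed = seed + 2L))
    K <- stage("spatial", distance_residual_kinship(K, md))
    value_col <- "residual"
  } else {
    msg <- "no coordinates in metadata: distance residualisation skipped, raw kinship analysed"
    warning(msg)
    warnings_log <- c(warnings_log, msg)
  }
  anova <- stage("spatial", grouped_anova_resampled(
    K, md, scheme = scheme, value_col = value_col,
    n_iter = n_iter, seed = seed + 3L))

  rep <- structure(list(
    params = params, sib_threshold = sib_threshold, scheme = scheme,
    seed = seed,
    scan_params = list(window_bp = window_bp, step_bp = step_bp,
                       min_snps = min_snps),
    n_input = c(samples = n_samples(G), loci = n_loci(G)),
    filter1 = f1$report,
    n_after_filter1 = c(samples = n_samples(f1$genotypes),
                        loci = n_loci(f1$genotypes)),
    sibling_groups = groups, n_sib_removed = n_sib_removed,
    filter2 = f2$report,
    n_final = c(samples = n_samples(Gf), loci = n_loci(Gf)),
    diversity = div, fst_pairwise = fst_pair, fst_tests = fst_tests,
    scan = scan, kinship = K, mantel = mantel, anova = anova,
    value_col = value_col, warnings = warnings_log
  ), class = "pipeline_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_vcf(Gf, file.path(out_dir, "filtered.vcf"))
    utils::write.table(K, file.path(out_dir, "kinship.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(div)) {
      utils::write.table(div, file.path(out_dir, "diversity.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(fst_tests)) {
      utils::write.table(fst_tests, file.path(out_dir, "fst.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(scan)) {
      utils::write.table(as.data.frame(scan),
                         file.path(out_dir, "windows.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(make_report(rep)$json, file.path(out_dir, "report.json"))
    writeLines(make_report(rep)$text, file.path(out_dir, "report.txt"))
  }
  rep
}

#' Summarise a pipeline run
#'
#' Produces a human-readable text summary and a machine-readable JSON
#' twin of a [run_pipeline] result: parameter echo, per-stage counts,
#' the pairwise Fst matrix, the fraction of scan windows dropped for
#' having fewer than the minimum SNPs, and the Mantel/ANOVA statistics.
#'
#' @param rep a `pipeline_report`.
#' @return list with `text` (character lines) and `json` (string).
#' @export
make_report <- function(rep) {
  stopifnot(inherits(rep, "pipeline_report"))
  fmt_counts <- function(x) sprintf("%d samples x %d loci", x[["samples"]], x[["loci"]])
  txt <- c(
    "== vectorpop pipeline report ==",
    sprintf("seed: %d; sibling threshold: k > %.4f; scheme: %s",
            rep$seed, rep$sib_threshold, rep$scheme),
    sprintf("filters: locus missing > %.2f, sample missing > %.2f, HWE alpha %g,",
            rep$params$max_locus_missing, rep$params$max_sample_missing,
            rep$params$hwe_alpha),
    sprintf("         VIF > %.1f in %d kb windows, MAF < %.3f, het outliers > %.1f SD",
            rep$params$vif_threshold, rep$params$vif_window_bp %/% 1000,
            rep$params$min_maf, rep$params$het_sd_mult),
    sprintf("input:           %s", fmt_counts(rep$n_input)),
    sprintf("after filter 1:  %s", fmt_counts(rep$n_after_filter1)),
    sprintf("siblings removed: %d (of %d groups)", rep$n_sib_removed,
            length(rep$sibling_groups)),
    sprintf("final dataset:   %s", fmt_counts(rep$n_final))
  )
  if (!is.null(rep$diversity)) {
    txt <- c(txt, "diversity (per habitat):",
             utils::capture.output(print(rep$diversity, row.names = FALSE)))
  } else txt <- c(txt, "diversity: not run")
  if (!is.null(rep$fst_pairwise)) {
    txt <- c(txt, "pairwise Fst (theta_w):",
             utils::capture.output(print(round(rep$fst_pairwise, 4))))
  } else txt <- c(txt, "pairwise Fst: not run")
  if (!is.null(rep$scan)) {
    txt <- c(txt, sprintf(
      "scan: %d windows retained of %d (%.1f%% dropped for < %d SNPs); mean SNPs/window %.1f",
      nrow(rep$scan), attr(rep$scan, "n_windows_total"),
      100 * attr(rep$scan, "frac_dropped"), attr(rep$scan, "min_snps"),
      attr(rep$scan, "mean_snps_per_window")))
    top <- rep$scan[which.max(rep$scan$theta_w), ]
    txt <- c(txt, sprintf("scan top window: %s:%d-%d theta_w = %.4f (%d SNPs)",
                          top$chrom, top$start, top$end, top$theta_w,
                          top$n_snps))
  } else txt <- c(txt, "scan: not run")
  if (!is.null(rep$mantel)) {
    txt <- c(txt, sprintf("Mantel: r = %.3f, P = %.4g (%d permutations)",
                          rep$mantel$r, rep$mantel$p_value, rep$mantel$n_perm))
  } else txt <- c(txt, "Mantel: not run (no coordinates)")
  txt <- c(txt, sprintf("ANOVA on %s: F = %.3f, resampled P = %.4g (%d iterations)",
                        rep$value_col, rep$anova$anova_F, rep$anova$anova_p,
                        rep$anova$n_iter))
  for (w in rep$warnings) txt <- c(txt, paste("warning:", w))

  js <- list(
    seed = rep$seed, sib_threshold = rep$sib_threshold,
    scheme = rep$scheme, params = unclass(rep$params),
    scan_params = rep$scan_params,
    n_input = as.list(rep$n_input),
    n_after_filter1 = as.list(rep$n_after_filter1),
    n_sib_removed = rep$n_sib_removed,
    n_final = as.list(rep$n_final),
    fst_pairwise = rep$fst_pairwise,
    scan_frac_dropped = if (!is.null(rep$scan)) attr(rep$scan, "frac_dropped") else NULL,
    scan_mean_snps = if (!is.null(rep$scan)) attr(rep$scan, "mean_snps_per_window") else NULL,
    mantel = rep$mantel,
    anova = list(F = rep$anova$anova_F, p = rep$anova$anova_p,
                 value_col = rep$value_col,
                 n_pairs = as.list(rep$anova$n_pairs),
                 posthoc = rep$anova$posthoc),
    warnings = rep$warnings
  )
  list(text = txt,
       json = as.character(jsonlite::toJSON(js, auto_unbox = TRUE,
                                            digits = NA, null = "null")))
}

#' @export
print.pipeline_report <- function(x, ...) {
  writeLines(make_report(x)$text)
  invisible(x)
}
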