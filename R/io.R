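#' Read diploid genotypes from a VCF file
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into a [genotype_matrix].
#' Phased (`|`) and unphased (`/`) separators are treated identically,
#' `./.` and half-missing calls (`0/.`) become missing, and multi-allelic
#' records are preserved with all ALT alleles.
#'
#' @param path path to a VCF file.
#' @return a [genotype_matrix] with loci sorted by (chromosome, position).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2L) stop("VCF contains no sample columns")
  n_header <- length(v@meta) + 1L  # meta lines plus the #CHROM line
  sample_ids <- colnames(gt)[-1L]
  fmt <- vapply(strsplit(gt[, 1L], ":", fixed = TRUE), `[`, "", 1L)
  if (any(fmt != "GT")) {
    stop("FORMAT without leading GT at line ",
         n_header + which(fmt != "GT")[1L])
  }
  nrec <- nrow(fix)
  alt <- fix[, "ALT"]
  alt[is.na(alt) | alt == "."] <- ""
  alleles <- mapply(function(ref, a) {
    if (nzchar(a)) c(ref, strsplit(a, ",", fixed = TRUE)[[1L]]) else ref
  }, fix[, "REF"], alt, SIMPLIFY = FALSE, USE.NAMES = FALSE)

  # first colon-field of every call, then split on / or |
  calls <- sub(":.*$", "", gt[, -1L, drop = FALSE])
  cv <- as.vector(calls)
  cv[is.na(cv)] <- "."  # vcfR encodes missing GT as NA
  parts <- strsplit(cv, "[/|]")
  len <- lengths(parts)
  g1 <- vapply(parts, function(p) if (length(p)) p[1L] else ".", "")
  bad <- len > 2L | (len == 1L & g1 != ".")
  if (any(bad)) {
    rec <- ((which(bad)[1L] - 1L) %% nrec) + 1L
    stop("non-diploid GT at line ", n_header + rec)
  }
  g2 <- vapply(parts, function(p) if (length(p) >= 2L) p[2L] else ".", "")
  g1[g1 == "."] <- NA_character_
  g2[g2 == "."] <- NA_character_
  a1 <- t(matrix(as.integer(g1), nrow = nrec))
  a2 <- t(matrix(as.integer(g2), nrow = nrec))
  genotype_matrix(sample_ids,
                  chrom = fix[, "CHROM"],
                  pos = as.integer(fix[, "POS"]),
                  alleles = alleles, a1 = a1, a2 = a2)
}

#' Write a genotype matrix to VCF 4.2
#'
#' Output is plain text with deterministic bytes for a fixed input (no
#' timestamps); the first allele of each locus is written as REF and the
#' rest as the ALT list. Calls are written unphased (`0/1`), missing as
#' `./.`.
#'
#' @param G a [genotype_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(G, path) {
  validate_genotype_matrix(G)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=vectorpop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", G$sample_ids), collapse = "\t")
  )
  L <- n_loci(G)
  body <- character(L)
  if (L > 0) {
    gts <- matrix(paste0(G$a1, "/", G$a2), nrow = n_samples(G))
    gts[is.na(G$a1)] <- "./."
    for (l in seq_len(L)) {
      al <- G$alleles[[l]]
      alt <- if (length(al) > 1L) paste(al[-1L], collapse = ",") else "."
      body[l] <- paste(c(G$loci$chrom[l], G$loci$pos[l], ".", al[1L], alt,
                         ".", ".", ".", "GT", gts[, l]), collapse = "\t")
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' Tab- (or comma-) separated text with a header; required columns
#' `sample_id`, `locality`, `site`, `habitat`. Habitat must be one of
#' `forest`, `peridomestic`, `domestic`. Optional coordinate columns are
#' either `lat`/`lon` (degrees; great-circle distances downstream) or
#' `x`/`y` (planar metric; Euclidean distances); optional `container_id`
#' labels the breeding container. When no coordinates are present,
#' distance-dependent analyses are disabled downstream.
#'
#' @param path path to the delimited file.
#' @param sep field separator (default tab).
#' @return a `data.frame` with attribute `coord_type` in
#'   `c("latlon", "planar", "none")`.
#' @export
read_metadata <- function(path, sep = "\t") {
  md <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_metadata(md)
}

#' @rdname read_metadata
#' @param md a data.frame to validate in place of a file.
#' @export
validate_metadata <- function(md) {
  req <- c("sample_id", "locality", "site", "habitat")
  missing_cols <- setdiff(req, names(md))
  if (length(missing_cols)) {
    stop("metadata missing required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id)) {
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  }
  ok <- md$habitat %in% c("forest", "peridomestic", "domestic")
  if (!all(ok)) {
    stop("invalid habitat value(s) in metadata rows ",
         paste(which(!ok), collapse = ", "), ": ",
         paste(unique(md$habitat[!ok]), collapse = ", "),
         " (allowed: forest, peridomestic, domestic)")
  }
  coord_type <- if (all(c("lat", "lon") %in% names(md))) "latlon"
  else if (all(c("x", "y") %in% names(md))) "planar"
  else "none"
  attr(md, "coord_type") <- coord_type
  md
}

#' Write a sample metadata table
#' @param md metadata data.frame.
#' @param path output path (tab-separated).
#' @export
write_metadata <- function(md, path) {
  utils::write.table(md, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read multi-allelic genotypes from a tabular sidecar format
#'
#' Long-format table for microsatellite-like loci, one row per sample and
#' locus: columns `sample_id`, `locus`, `allele1`, `allele2`, with alleles
#' coded as repeat-size integers and 0 or NA meaning missing. Each locus
#' becomes its own "chromosome" (position 1) since these loci carry no
#' genomic coordinates.
#'
#' @param path path to the tab-separated file.
#' @return a multi-allelic [genotype_matrix].
#' @export
read_genotype_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("sample_id", "locus", "allele1", "allele2")
  if (!all(req %in% names(tab))) {
    stop("genotype table requires columns: ", paste(req, collapse = ", "))
  }
  tab$allele1[tab$allele1 %in% 0] <- NA
  tab$allele2[tab$allele2 %in% 0] <- NA
  samples <- unique(tab$sample_id)
  loci <- sort(unique(tab$locus))
  alleles <- lapply(loci, function(l) {
    as.character(sort(unique(stats::na.omit(
      c(tab$allele1[tab$locus == l], tab$allele2[tab$locus == l])))))
  })
  a1 <- matrix(NA_integer_, length(samples), length(loci))
  a2 <- a1
  si <- match(tab$sample_id, samples)
  li <- match(tab$locus, loci)
  for (r in seq_len(nrow(tab))) {
    a1[si[r], li[r]] <- match(as.character(tab$allele1[r]),
                              alleles[[li[r]]]) - 1L
    a2[si[r], li[r]] <- match(as.character(tab$allele2[r]),
                              alleles[[li[r]]]) - 1L
  }
  genotype_matrix(samples, chrom = loci, pos = rep(1L, length(loci)),
                  alleles = alleles, a1 = a1, a2 = a2)
}
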