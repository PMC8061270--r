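#' Locale-labelled SNP dataset
#'
#' The unit of all genetic computation: a samples x loci matrix of allele
#' dosages (0..ploidy, NA = missing) for biallelic SNPs, with each sample
#' assigned to exactly one sampling locale. `n_sites` records the number of
#' surveyed nucleotide sites (the sequence length over which the SNPs were
#' ascertained) used for per-site scaling of diversity statistics; for
#' SNP-only panels it defaults to the number of loci.
#'
#' @param geno integer matrix, samples x loci, values in 0..ploidy or NA.
#' @param locale_id character vector, one locale per sample.
#' @param ploidy 1 (haploid, e.g. chloroplast haplotypes) or 2 (diploid
#'   nuclear genotypes as minor-allele dosages).
#' @param sample_id optional sample names (default S0001...).
#' @param locus_id optional locus names (default snp0001...).
#' @param n_sites surveyed sequence length L (>= number of loci).
#' @return object of class `snp_dataset`.
#' @export
snp_dataset <- function(geno, locale_id, ploidy = 1L, sample_id = NULL,
                        locus_id = NULL, n_sites = NULL) {
  if (!is.matrix(geno)) geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(1L, 2L)) stop_popland("ploidy must be 1 or 2")
  if (length(locale_id) != nrow(geno))
    stop_popland("locale_id length (%d) != number of samples (%d)",
                 length(locale_id), nrow(geno))
  rng <- range(geno, na.rm = TRUE)
  if (any(!is.na(geno)) && (rng[1] < 0 || rng[2] > ploidy))
    stop_popland("dosages must lie in 0..ploidy or be NA")
  sample_id <- sample_id %||% sprintf("S%04d", seq_len(nrow(geno)))
  locus_id <- locus_id %||% sprintf("snp%04d", seq_len(ncol(geno)))
  n_sites <- as.integer(n_sites %||% ncol(geno))
  if (n_sites < ncol(geno))
    stop_popland("n_sites (%d) must be >= number of loci (%d)", n_sites, ncol(geno))
  dimnames(geno) <- list(sample_id, locus_id)
  structure(
    list(geno = geno, sample_id = sample_id,
         locale_id = as.character(locale_id), ploidy = ploidy,
         locus_id = locus_id, n_sites = n_sites),
    class = "snp_dataset"
  )
}

#' @export
print.snp_dataset <- function(x, ...) {
  cat(sprintf("snp_dataset: %d samples (ploidy %d) x %d loci, %d locales, L = %d sites\n",
              nrow(x$geno), x$ploidy, ncol(x$geno),
              length(unique(x$locale_id)), x$n_sites))
  mono <- sum(monomorphic_loci(x))
  if (mono) cat(sprintf("  %d monomorphic loci (kept, flagged)\n", mono))
  invisible(x)
}

#' Flag monomorphic loci
#'
#' A locus is monomorphic when all non-missing alleles carry the same state.
#' Monomorphic loci are retained in datasets and files but excluded from
#' diversity/differentiation statistics and allele encoding.
#'
#' @param dataset an `snp_dataset`.
#' @return logical vector over loci.
#' @export
monomorphic_loci <- function(dataset) {
  x <- colSums(dataset$geno, na.rm = TRUE)
  n <- colSums(!is.na(dataset$geno)) * dataset$ploidy
  x == 0 | x == n
}

#' Tabulate allele counts per locale
#'
#' For each locale and locus, the count of alternate alleles and the number
#' of non-missing alleles (pairwise deletion: a missing genotype removes
#' that sample's alleles at that locus only).
#'
#' @param dataset an `snp_dataset`.
#' @return list with matrices `x` (alt-allele counts) and `n` (allele
#'   totals), rows = locales (sorted unique), cols = loci.
#' @export
allele_counts <- function(dataset) {
  loc <- factor(dataset$locale_id, levels = sort(unique(dataset$locale_id)))
  g <- dataset$geno
  miss <- is.na(g)
  g0 <- g; g0[miss] <- 0L
  x <- rowsum(g0, loc)
  n <- rowsum((!miss) * dataset$ploidy, loc)
  list(x = x, n = n, locales = levels(loc))
}

#' Write / read a locale-labelled SNP CSV
#'
#' Plain CSV with columns `sample_id`, `locale_id`, then one dosage column
#' per locus (NA for missing).
#'
#' @param dataset an `snp_dataset`.
#' @param path file path.
#' @export
write_snp_csv <- function(dataset, path) {
  df <- data.frame(sample_id = dataset$sample_id,
                   locale_id = dataset$locale_id,
                   dataset$geno, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snp_csv
#' @param ploidy ploidy of the stored dosages.
#' @param n_sites surveyed sequence length (default: number of loci).
#' @export
read_snp_csv <- function(path, ploidy = 1L, n_sites = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  geno <- as.matrix(df[, -(1:2), drop = FALSE])
  snp_dataset(geno, locale_id = df$locale_id, ploidy = ploidy,
              sample_id = df$sample_id, locus_id = colnames(geno),
              n_sites = n_sites)
}

#' Write an snp_dataset as VCF
#'
#' Minimal VCFv4.2 with GT-only genotypes; haploid datasets write "0"/"1"
#' calls, diploid datasets write unphased "a/b" calls with the dosage split
#' as 0 -> 0/0, 1 -> 0/1, 2 -> 1/1. Locale assignment travels in a
#' `##SAMPLE=<ID=...,Locale=...>` header line per sample and should also be
#' kept as a side-car locale CSV for interoperability.
#'
#' @param dataset an `snp_dataset`.
#' @param path output path (plain text).
#' @export
write_vcf <- function(dataset, path) {
  nl <- ncol(dataset$geno)
  gt <- if (dataset$ploidy == 1L) {
    m <- matrix(as.character(t(dataset$geno)), nrow = nl)
    m[is.na(m)] <- "."
    m
  } else {
    codes <- c("0/0", "0/1", "1/1")
    m <- matrix(codes[t(dataset$geno) + 1L], nrow = nl)
    m[is.na(m)] <- "./."
    m
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=popland",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    sprintf("##SAMPLE=<ID=%s,Locale=%s>", dataset$sample_id, dataset$locale_id),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", dataset$sample_id), collapse = "\t")
  )
  body <- cbind("1", seq_len(nl), dataset$locus_id, "A", "T", ".", "PASS",
                ".", "GT", gt)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(body, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a VCF into an snp_dataset
#'
#' Uses vcfR to parse; accepts haploid ("0"/"1") and diploid ("0/1", "0|1")
#' GT dialects. Locale assignment is taken from `##SAMPLE=<ID=..,Locale=..>`
#' header lines when present, else from `locale_map`.
#'
#' @param path VCF path.
#' @param locale_map optional named character vector sample_id -> locale_id.
#' @param n_sites surveyed sequence length (default: number of loci).
#' @return an `snp_dataset`.
#' @export
read_vcf <- function(path, locale_map = NULL, n_sites = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  first <- gt[!is.na(gt)][1]
  ploidy <- if (grepl("[/|]", first)) 2L else 1L
  if (ploidy == 1L) {
    geno <- t(apply(gt, 1, function(z) suppressWarnings(as.integer(z))))
  } else {
    count_alt <- function(z) {
      ifelse(is.na(z) | z %in% c("./.", ".|."), NA_integer_,
             vapply(strsplit(z, "[/|]"), function(a)
               sum(as.integer(a)), integer(1)))
    }
    geno <- t(apply(gt, 1, count_alt))
  }
  geno <- t(geno)  # samples x loci
  if (is.null(locale_map)) {
    meta <- v@meta
    sm <- meta[grepl("^##SAMPLE=", meta)]
    if (length(sm)) {
      ids <- sub('.*ID=([^,>]+).*', '\\1', sm)
      locs <- sub('.*Locale=([^,>]+).*', '\\1', sm)
      locale_map <- stats::setNames(locs, ids)
    }
  }
  if (is.null(locale_map))
    stop_popland("no locale assignment: supply locale_map or SAMPLE header lines")
  locale <- unname(locale_map[samples])
  if (anyNA(locale)) stop_popland("locale_map missing entries for some samples")
  snp_dataset(geno, locale_id = locale, ploidy = ploidy, sample_id = samples,
              locus_id = rownames(gt), n_sites = n_sites)
}

#' Locale coordinate table
#'
#' @param locale_id unique locale identifiers.
#' @param x,y planar map-unit coordinates.
#' @param n_samples samples collected per locale.
#' @return data.frame of class `locale_frame`.
#' @export
locale_frame <- function(locale_id, x, y, n_samples) {
  if (anyDuplicated(locale_id)) stop_popland("locale ids must be unique")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop_popland("locale coordinates must be finite")
  structure(
    data.frame(locale_id = as.character(locale_id), x = x, y = y,
               n_samples = as.integer(n_samples)),
    class = c("locale_frame", "data.frame")
  )
}

#' @rdname locale_frame
#' @param path CSV path with columns locale_id, x, y (n_samples optional).
#' @export
read_locales_csv <- function(path) {
  df <- utils::read.csv(path)
  locale_frame(df$locale_id, df$x, df$y, df$n_samples %||% NA_integer_)
}

#' @rdname locale_frame
#' @param locales a `locale_frame`.
#' @export
write_locales_csv <- function(locales, path) {
  utils::write.csv(as.data.frame(locales), path, row.names = FALSE)
  invisible(path)
}
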