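#' Write a phased haplotype matrix to VCF
#'
#' Consecutive haplotype-column pairs become one diploid individual with a
#' phased genotype (`0|1` separator); missing haplotypes are written as
#' `.`. Locus/position metadata default to one synthetic locus per SNP.
#'
#' @param m A `hap_matrix` (loci x haplotypes, values 0/1/NA) with an even
#'   number of columns.
#' @param path Output file path.
#' @param locus,pos Optional per-SNP CHROM and POS fields.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(m, path, locus = NULL, pos = NULL) {
  stopifnot(is.matrix(m), ncol(m) %% 2 == 0)
  n_ind <- ncol(m) / 2
  part <- attr(m, "pop_partition")
  ind_names <- if (!is.null(part)) {
    unlist(lapply(seq_len(nrow(part)), function(i) {
      k <- (part$to[i] - part$from[i] + 1) / 2
      paste0(part$population[i], "_", seq_len(k))
    }))
  } else paste0("ind", seq_len(n_ind))
  if (is.null(locus)) locus <- paste0("locus", seq_len(nrow(m)))
  if (is.null(pos)) pos <- rep(1L, nrow(m))

  gt_char <- matrix(".", nrow(m), ncol(m))
  gt_char[!is.na(m)] <- as.character(unclass(m)[!is.na(m)])
  gt <- matrix("", nrow(m), n_ind)
  for (i in seq_len(n_ind))
    gt[, i] <- paste0(gt_char[, 2 * i - 1], "|", gt_char[, 2 * i])

  header <- c(
    "##fileformat=VCFv4.2",
    "##source=coalcnn",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ind_names), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(m)), function(s) {
    paste(c(locus[s], pos[s], paste0("snp", s), "A", "T", ".", "PASS", ".",
            "GT", gt[s, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a VCF into a phased haplotype matrix
#'
#' Each individual contributes two haplotype columns. Records with
#' unphased separators are rejected unless `allow_unphased = TRUE`, in
#' which case alleles are assigned to haplotypes in file order (random
#' phase is not simulated).
#'
#' @param path VCF file path.
#' @param populations Optional tibble (`population`, individual count) to
#'   attach as partition; by default every individual whose name looks
#'   like `pop_k` is grouped by prefix.
#' @param allow_unphased Accept `/`-separated genotypes.
#' @return A `hap_matrix`.
#' @export
read_vcf_hap <- function(path, populations = NULL, allow_unphased = FALSE) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE), na.rm = TRUE) && !allow_unphased)
    abort("VCF contains unphased genotypes; set allow_unphased = TRUE")
  n_snp <- nrow(gt)
  n_ind <- ncol(gt)
  m <- matrix(NA_integer_, n_snp, 2 * n_ind)
  allele <- function(x, k) {
    a <- vapply(strsplit(x, "[|/]"), function(z)
      if (length(z) >= k) z[k] else ".", character(1))
    out <- suppressWarnings(as.integer(a))
    out
  }
  for (i in seq_len(n_ind)) {
    gi <- gt[, i]
    gi[is.na(gi)] <- ".|."
    m[, 2 * i - 1] <- allele(gi, 1)
    m[, 2 * i] <- allele(gi, 2)
  }
  nm <- colnames(gt)
  if (is.null(populations)) {
    prefix <- sub("_[^_]*$", "", nm)
    rle_p <- rle(prefix)
    populations <- tibble::tibble(population = rle_p$values,
                                  n = rle_p$lengths)
  }
  hap_matrix(m, populations$population, 2L * populations$n)
}

#' Read a VCF into a SNP genotype table
#'
#' Collapses each individual's genotype to alternate-allele dosage
#' (phased or unphased) and records CHROM as the locus and POS as the
#' 0-based offset.
#'
#' @param path VCF file path.
#' @return A [snp_table()].
#' @export
read_vcf_snp_table <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    abort("reading VCF requires the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- matrix(NA_integer_, nrow(gt), ncol(gt))
  for (i in seq_len(ncol(gt))) {
    parts <- strsplit(ifelse(is.na(gt[, i]), ".|.", gt[, i]), "[|/]")
    dose[, i] <- vapply(parts, function(z) {
      z <- suppressWarnings(as.integer(z))
      if (anyNA(z)) NA_integer_ else sum(z)
    }, integer(1))
  }
  fix <- vcfR::getFIX(v)
  snp_table(fix[, "CHROM"], as.integer(fix[, "POS"]) - 1L, dose)
}

#' Collapse a haplotype matrix to diploid dosages
#'
#' @param m A `hap_matrix` with an even number of columns.
#' @param locus,pos Optional per-SNP locus/position metadata.
#' @return A [snp_table()] with one column per individual.
#' @export
hap_to_snp_table <- function(m, locus = NULL, pos = NULL) {
  stopifnot(is.matrix(m), ncol(m) %% 2 == 0)
  x <- unclass(m)
  dose <- x[, seq(1, ncol(x), 2), drop = FALSE] +
    x[, seq(2, ncol(x), 2), drop = FALSE]
  if (is.null(locus)) locus <- paste0("locus", seq_len(nrow(m)))
  if (is.null(pos)) pos <- rep(0L, nrow(m))
  snp_table(locus, pos, dose)
}
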