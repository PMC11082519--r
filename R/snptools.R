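#' Construct a SNP genotype table
#'
#' Container for diploid genotype calls with per-SNP positions, used by
#' the post-filters and diversity statistics. Genotypes are coded as the
#' dosage of the alternate allele (0, 1, 2) with NA for missing calls;
#' positions are 0-based offsets within their locus.
#'
#' @param locus Locus identifier per SNP.
#' @param pos 0-based position of each SNP within its locus.
#' @param genotypes Integer matrix, SNPs x individuals, values 0/1/2/NA.
#' @return A `snp_table`: `info` tibble (locus, pos, missing fraction) and
#'   the genotype matrix.
#' @export
snp_table <- function(locus, pos, genotypes) {
  genotypes <- as.matrix(genotypes)
  stopifnot(length(locus) == nrow(genotypes),
            length(pos) == nrow(genotypes))
  ok <- is.na(genotypes) | genotypes %in% 0:2
  if (!all(ok)) abort("genotypes must be 0, 1, 2 or NA")
  info <- tibble::tibble(
    locus = as.character(locus), pos = as.integer(pos),
    missing = rowMeans(is.na(genotypes))
  )
  structure(list(info = info, geno = genotypes), class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat("<snp_table>", nrow(x$geno), "SNPs x", ncol(x$geno), "individuals in",
      length(unique(x$info$locus)), "loci;",
      sprintf("%.1f%% missing\n", 100 * mean(is.na(x$geno))))
  invisible(x)
}

subset_snps <- function(table, keep) {
  structure(list(info = table$info[keep, , drop = FALSE],
                 geno = table$geno[keep, , drop = FALSE]),
            class = "snp_table")
}

#' Remove SNPs with excessive missing data
#'
#' Drops every SNP whose missing fraction strictly exceeds `max_missing`
#' (a SNP at exactly the threshold is kept); row order is preserved and
#' the operation is idempotent.
#'
#' @param table A [snp_table()].
#' @param max_missing Missing-fraction threshold (default 0.35).
#' @return The filtered `snp_table`.
#' @export
filter_missing <- function(table, max_missing = 0.35) {
  stopifnot(inherits(table, "snp_table"))
  subset_snps(table, table$info$missing <= max_missing)
}

#' Thin clustered SNPs by position
#'
#' Within each locus, SNPs chained together by pairwise gaps of at most
#' `min_gap` positions form a cluster (transitive closure of the
#' proximity relation); only the cluster member with the lowest missing
#' fraction survives, the leftmost on ties. Every adjacent within-locus
#' gap of the output exceeds `min_gap`.
#'
#' @param table A [snp_table()] with positions sorted within each locus.
#' @param min_gap Proximity threshold in positions (default 25).
#' @return The thinned `snp_table`.
#' @export
thin_snps <- function(table, min_gap = 25) {
  stopifnot(inherits(table, "snp_table"))
  info <- table$info
  keep <- logical(nrow(info))
  for (lc in unique(info$locus)) {
    idx <- which(info$locus == lc)
    p <- info$pos[idx]
    if (is.unsorted(p)) abort("positions must be sorted within each locus")
    cluster <- cumsum(c(1L, as.integer(diff(p) > min_gap)))
    for (cl in unique(cluster)) {
      members <- idx[cluster == cl]
      best <- members[which.min(info$missing[members])] # leftmost on ties
      keep[best] <- TRUE
    }
  }
  subset_snps(table, keep)
}

#' Per-population diversity statistics
#'
#' Mean per-SNP statistics over a set of individuals, skipping missing
#' calls: observed heterozygosity (fraction of heterozygous genotypes),
#' expected heterozygosity \eqn{(1 - \sum p_i^2) \cdot 2n/(2n-1)} with
#' the small-sample gene-copy correction, allelic richness rarefied to
#' `rarefaction_n` gene copies (SNPs with fewer non-missing copies are
#' skipped for Ar), and Shannon diversity over the three genotype classes
#' in bits (log base 2).
#'
#' @param table A [snp_table()].
#' @param individuals Columns (indices or names) of the population;
#'   defaults to all.
#' @param rarefaction_n Rarefaction depth in gene copies (default 10,
#'   twice the smallest population sample of the default panel).
#' @return One-row tibble: `Ho`, `He`, `Ar`, `shannon`, `n_snps`,
#'   `n_snps_ar`.
#' @export
#' @examples
#' tab <- snp_table("L1", 0, matrix(c(0L, 1L, 2L), 1))
#' diversity_stats(tab, rarefaction_n = 4)
diversity_stats <- function(table, individuals = NULL, rarefaction_n = 10) {
  stopifnot(inherits(table, "snp_table"))
  g <- table$geno
  if (!is.null(individuals)) g <- g[, individuals, drop = FALSE]
  if (ncol(g) == 0) abort("empty population")

  n_obs <- rowSums(!is.na(g))
  n1 <- rowSums(g == 1, na.rm = TRUE)
  n2 <- rowSums(g == 2, na.rm = TRUE)
  n0 <- n_obs - n1 - n2
  use <- n_obs > 0

  ho <- n1[use] / n_obs[use]

  copies <- 2 * n_obs
  alt <- n1 + 2 * n2
  p <- alt[use] / copies[use]
  he <- (1 - p^2 - (1 - p)^2) * copies[use] / pmax(1, copies[use] - 1)

  # rarefied allele count: E[alleles in k copies] = sum_a 1 - C(N-Na,k)/C(N,k)
  ar_one <- function(N, Na, k) {
    miss <- exp(lchoose(N - Na, k) - lchoose(N, k))
    sum(1 - miss[Na > 0])
  }
  ar_ok <- use & copies >= rarefaction_n
  ar <- mapply(function(N, a) ar_one(N, c(a, N - a), rarefaction_n),
               copies[ar_ok], alt[ar_ok])

  q <- cbind(n0[use], n1[use], n2[use]) / n_obs[use]
  sh <- -rowSums(ifelse(q > 0, q * log2(q), 0))

  tibble::tibble(
    Ho = mean(ho), He = mean(he),
    Ar = if (any(ar_ok)) mean(ar) else NA_real_,
    shannon = mean(sh),
    n_snps = sum(use), n_snps_ar = sum(ar_ok)
  )
}

#' Watterson's theta
#'
#' \eqn{\theta_W = S / \sum_{i=1}^{n-1} 1/i} for `S` segregating sites
#' observed in `n` sequences.
#'
#' @param S Number of segregating sites.
#' @param n Number of sequences (haploid sample size).
#' @return Watterson's estimator.
#' @export
#' @examples
#' watterson_theta(10, 5) # 4.8
watterson_theta <- function(S, n) {
  if (n < 2) abort("need at least two sequences")
  stopifnot(S >= 0)
  S / sum(1 / seq_len(n - 1))
}

#' Tajima's D
#'
#' The standard normalized difference between mean pairwise diversity and
#' Watterson's estimator, \eqn{D = (\pi - S/a_1) / \sqrt{e_1 S + e_2
#' S(S-1)}}, with the canonical coefficients of the neutrality test.
#' \eqn{\pi} is computed through the frequency-spectrum identity
#' \eqn{\sum_s 2 p_s q_s \, n/(n-1)}.
#'
#' @param alignment Matrix, sequences x sites (any discrete coding;
#'   columns with more than two states are rejected).
#' @return Tajima's D (signals an error when no site segregates or fewer
#'   than 4 sequences are given, mirroring the "n.d." convention for
#'   insufficient data).
#' @export
tajimas_d <- function(alignment) {
  stopifnot(is.matrix(alignment))
  n <- nrow(alignment)
  if (n < 4) abort("need at least 4 sequences")
  segregating <- apply(alignment, 2, function(col) {
    u <- unique(col[!is.na(col)])
    if (length(u) > 2) abort("site with more than two states")
    length(u) == 2
  })
  S <- sum(segregating)
  if (S == 0) abort("no segregating sites: D is undefined (n.d.)")

  pi_sum <- 0
  for (j in which(segregating)) {
    col <- alignment[, j]
    col <- col[!is.na(col)]
    nn <- length(col)
    p <- mean(col == col[1])
    pi_sum <- pi_sum + 2 * p * (1 - p) * nn / (nn - 1)
  }

  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}
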