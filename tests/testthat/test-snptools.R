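toy_table <- function(missing_fracs, pos = NULL, locus = NULL) {
  # 20 individuals; per SNP, set exactly round(f*20) calls to NA
  n_ind <- 20
  g <- matrix(1L, length(missing_fracs), n_ind)
  for (i in seq_along(missing_fracs)) {
    k <- round(missing_fracs[i] * n_ind)
    if (k > 0) g[i, seq_len(k)] <- NA
  }
  if (is.null(pos)) pos <- seq(0, by = 100, length.out = nrow(g))
  if (is.null(locus)) locus <- rep("L1", nrow(g))
  snp_table(locus, pos, g)
}

test_that("missing-data filter keeps the boundary and drops above it", {
  tab <- toy_table(c(0.0, 0.35, 0.40))
  out <- filter_missing(tab, 0.35)
  expect_equal(nrow(out$geno), 2)
  expect_equal(out$info$missing, c(0.0, 0.35))
  expect_identical(filter_missing(out, 0.35)$info, out$info)
  expect_equal(nrow(filter_missing(tab, 1)$geno), 3)
  full <- toy_table(c(0, 0, 0))
  expect_equal(nrow(filter_missing(full)$geno), 3)
})

test_that("proximity thinning keeps the least-missing SNP per cluster", {
  tab <- toy_table(c(0.1, 0.0, 0.2), pos = c(10, 30, 120))
  out <- thin_snps(tab, 25)
  expect_equal(out$info$pos, c(30L, 120L))
  expect_identical(thin_snps(out, 25)$info, out$info)

  single <- toy_table(0.1, pos = 7)
  expect_equal(thin_snps(single, 25)$info$pos, 7L)

  ties <- toy_table(c(0.1, 0.1, 0.1), pos = c(0, 20, 40))
  expect_equal(thin_snps(ties, 25)$info$pos, 0L) # leftmost on ties

  unsorted <- snp_table(c("L1", "L1"), c(50, 10), matrix(1L, 2, 4))
  expect_error(thin_snps(unsorted), "sorted")
})

test_that("thinning output never contains close within-locus pairs", {
  set.seed(1)
  for (rep in 1:20) {
    n <- 30
    tab <- snp_table(rep(c("A", "B"), each = n / 2),
                     c(sort(sample(0:500, n / 2)),
                       sort(sample(0:500, n / 2))),
                     matrix(sample(c(0:2, NA), n * 10, TRUE), n, 10))
    out <- thin_snps(tab, 25)
    gaps <- unlist(tapply(out$info$pos, out$info$locus, diff))
    if (length(gaps)) expect_true(all(gaps > 25))
    expect_identical(thin_snps(out, 25)$info, out$info)
  }
})

test_that("diversity statistics reproduce the hand-worked example", {
  # one SNP with genotypes AA, Aa, aa: p = q = 1/2, 6 gene copies
  tab <- snp_table("L1", 0, matrix(c(0L, 1L, 2L), 1))
  st <- diversity_stats(tab, rarefaction_n = 4)
  expect_equal(st$Ho, 1 / 3)
  expect_equal(st$He, 0.5 * 6 / 5)
  mono <- diversity_stats(snp_table("L1", 0, matrix(c(0L, 0L, 0L), 1)),
                          rarefaction_n = 4)
  expect_equal(mono$Ho, 0)
  expect_equal(mono$He, 0)
  expect_equal(mono$Ar, 1)
  expect_equal(mono$shannon, 0)
  hets <- diversity_stats(snp_table("L1", 0, matrix(c(1L, 1L, 1L), 1)),
                          rarefaction_n = 4)
  expect_equal(hets$Ho, 1)
})

test_that("rarefied allelic richness stays within [1, 2] and skips thin SNPs", {
  set.seed(2)
  g <- matrix(sample(c(0:2, NA), 200 * 10, TRUE, c(.4, .2, .2, .2)),
              200, 10)
  tab <- snp_table(rep("L", 200), seq_len(200) * 50, g)
  st <- diversity_stats(tab, rarefaction_n = 10)
  expect_gte(st$Ar, 1)
  expect_lte(st$Ar, 2)
  expect_lte(st$n_snps_ar, st$n_snps)
})

test_that("Watterson's theta matches hand arithmetic", {
  expect_equal(watterson_theta(10, 5), 4.8)
  expect_equal(watterson_theta(0, 7), 0)
  expect_equal(watterson_theta(13, 2), 13)
  expect_error(watterson_theta(3, 1), "two sequences")
})

test_that("Tajima's D matches the brute-force oracle to 1e-6", {
  set.seed(3)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    s <- sample(8:25, 1)
    aln <- matrix(0L, n, s)
    for (j in seq_len(s)) {
      k <- sample(1:(n - 1), 1)
      aln[sample(n, k), j] <- 1L
    }
    expect_equal(tajimas_d(aln), oracle_tajima(aln)$D, tolerance = 1e-6)
  }
})

test_that("an excess of singletons on one sequence forces D < 0", {
  aln <- matrix(0L, 10, 16)
  aln[1, ] <- 1L
  expect_lt(tajimas_d(aln), 0)
})

test_that("pairwise and spectrum-based pi agree to 1e-9", {
  set.seed(4)
  aln <- matrix(rbinom(8 * 30, 1, 0.3), 8, 30)
  orc <- oracle_tajima(aln)
  pi_sfs <- 0
  n <- nrow(aln)
  for (j in seq_len(ncol(aln))) {
    p <- mean(aln[, j])
    pi_sfs <- pi_sfs + 2 * p * (1 - p) * n / (n - 1)
  }
  expect_equal(orc$pi, pi_sfs, tolerance = 1e-9)
})

test_that("D is undefined without segregation or enough sequences", {
  expect_error(tajimas_d(matrix(0L, 10, 5)), "n.d.")
  expect_error(tajimas_d(matrix(c(0L, 1L), 2, 4)), "4 sequences")
})

test_that("expected heterozygosity dominates observed under drift", {
  # coalescent samples are inbred relative to Hardy-Weinberg, so the
  # bias-corrected He exceeds Ho on average
  dem <- custom_demography(N = 500, samples = 40)
  set.seed(5)
  diff <- replicate(30, {
    m <- simulate_snp_matrix(dem, 60)
    tab <- hap_to_snp_table(m)
    st <- diversity_stats(tab, rarefaction_n = 10)
    st$He - st$Ho
  })
  expect_gt(mean(diff), 0)
})

test_that("Tajima's D is near zero for constant-size panmixia", {
  dem <- custom_demography(N = 500, samples = 20)
  set.seed(6)
  d_vals <- replicate(200, {
    m <- simulate_snp_matrix(dem, 50)
    tajimas_d(t(unclass(m)))
  })
  expect_gt(mean(d_vals), -0.5)
  expect_lt(mean(d_vals), 0.5)
})
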