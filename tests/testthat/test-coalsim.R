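test_that("pairwise TMRCA matches the closed form E[T2] = 2N", {
  dem <- custom_demography(N = 1000, samples = 2)
  set.seed(1)
  tm <- replicate(8000, max(simulate_genealogy(dem)$time_gen))
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 2000), 3 * se)
})

test_that("TMRCA for n = 10 matches 4N(1 - 1/n)", {
  dem <- custom_demography(N = 1000, samples = 10)
  set.seed(2)
  tm <- replicate(8000, max(simulate_genealogy(dem)$time_gen))
  se <- stats::sd(tm) / sqrt(length(tm))
  expect_lt(abs(mean(tm) - 4000 * (1 - 0.1)), 3 * se)
})

test_that("disconnected demes raise a simulation error", {
  dem <- custom_demography(N = c(500, 500), samples = c(2, 2))
  set.seed(3)
  expect_error(simulate_genealogy(dem), "coalesce")
})

test_that("a two-leaf tree yields a singleton column", {
  dem <- custom_demography(N = 100, samples = 2)
  set.seed(4)
  for (i in 1:20) {
    g <- simulate_genealogy(dem)
    col <- drop_mutation(g)
    expect_setequal(col, c(0L, 1L))
  }
})

test_that("a star tree mutates each leaf equally often", {
  g <- star_genealogy(4)
  set.seed(5)
  hits <- integer(4)
  for (i in 1:10000) hits <- hits + drop_mutation(g)
  p <- hits / 10000
  expect_true(all(abs(p - 0.25) < 3 * sqrt(0.25 * 0.75 / 10000)))
})

test_that("every simulated SNP row is segregating", {
  dem <- compile_demography("SSH_BC",
                            draw_parameters("SSH_BC", prior_set(),
                                            seed = 6))
  m <- simulate_snp_matrix(dem, 300, seed = 7)
  counts <- rowSums(m)
  expect_true(all(counts > 0 & counts < ncol(m)))
  expect_equal(dim(m), c(300L, 232L))
})

test_that("identical seeds reproduce the matrix bit for bit", {
  dem <- compile_demography("SSH", draw_parameters("SSH", prior_set(),
                                                   seed = 8))
  m1 <- simulate_snp_matrix(dem, 50, seed = 9)
  m2 <- simulate_snp_matrix(dem, 50, seed = 9)
  expect_identical(unclass(m1), unclass(m2))
})

test_that("stronger founder effects depress diversity in the colony", {
  # two demes: colony splits from source at 2000 generations; smaller
  # founder fractions must lower expected heterozygosity in the colony
  mean_het <- function(frac, seed) {
    n_col <- 1000
    r <- log(n_col / max(2, frac * 1000)) / 2000
    dem <- custom_demography(
      N = c(1000, n_col), samples = c(4, 20), r = c(0, r),
      t_split = c(NA, 2000), parent = c(NA, "D1"))
    m <- simulate_snp_matrix(dem, 3000, seed = seed)
    colony <- unclass(m)[, 5:24]
    p <- rowMeans(colony)
    mean(2 * p * (1 - p))
  }
  set.seed(10)
  hets <- c(mean_het(0.005, 11), mean_het(0.05, 12), mean_het(1, 13))
  expect_true(all(diff(hets) > 0))
})

test_that("fixed-S mode also produces segregating deterministic rows", {
  dem <- custom_demography(N = 500, samples = 12)
  m1 <- simulate_snp_matrix(dem, 200, seed = 14, mutation_model = "fixed_s")
  m2 <- simulate_snp_matrix(dem, 200, seed = 14, mutation_model = "fixed_s")
  expect_identical(unclass(m1), unclass(m2))
  expect_true(all(rowSums(m1) > 0 & rowSums(m1) < 12))
})
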