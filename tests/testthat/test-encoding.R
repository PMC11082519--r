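test_that("major/minor recoding follows the worked examples", {
  expect_equal(to_major_minor(matrix(c(1, 1, 1, 0), 1)),
               matrix(c(0, 0, 0, 1), 1))
  tie <- matrix(c(0, 1, 1, 0), 1)
  expect_equal(to_major_minor(tie), tie)
  expect_equal(to_major_minor(matrix(1, 1, 4)), matrix(0, 1, 4))
  expect_equal(to_major_minor(matrix(0, 1, 4)), matrix(0, 1, 4))
})

test_that("recoded rows always have minor count at most half", {
  set.seed(1)
  m <- matrix(rbinom(50 * 12, 1, runif(50)), 50, 12)
  out <- to_major_minor(m)
  expect_true(all(rowSums(out == 1) <= 6))
})

test_that("recoding is idempotent and commutes with column permutation", {
  set.seed(2)
  m <- matrix(rbinom(40 * 10, 1, 0.7), 40, 10)
  m[sample(length(m), 30)] <- NA
  once <- to_major_minor(m)
  expect_equal(to_major_minor(once), once)
  perm <- sample(10)
  expect_equal(to_major_minor(m[, perm]), to_major_minor(m)[, perm])
})

test_that("missing injection hits the target rate and nothing else", {
  set.seed(3)
  m <- matrix(rbinom(1000 * 232, 1, 0.3), 1000, 232)
  expect_identical(inject_missing(m, 0), m)
  out <- inject_missing(m, 0.044, seed = 4)
  frac <- mean(is.na(out))
  expect_lt(abs(frac - 0.044), 0.002) # 3-sigma binomial bound
  expect_identical(out[!is.na(out)], m[!is.na(out)])
  expect_identical(inject_missing(m, 0.044, seed = 4), out)
  expect_error(inject_missing(m, 1.2), "rate")
})

test_that("batch assembly splits 25% into validation", {
  mats <- replicate(8, matrix(rbinom(12, 1, 0.5), 4, 3), simplify = FALSE)
  b <- assemble_batch(mats, rep("SSH", 8), val_frac = 0.25, seed = 5,
                      missing_rate = 0)
  expect_equal(sum(b$split == "validation"), 2)
  expect_equal(sum(b$split == "train"), 6)
  b0 <- assemble_batch(mats, rep("SSH", 8), val_frac = 0, seed = 5,
                       missing_rate = 0)
  expect_equal(sum(b0$split == "validation"), 0)
  expect_error(assemble_batch(mats, rep("SSH", 7)), "labels")
})

test_that("validation scenario shares stay near the batch shares", {
  set.seed(6)
  mats <- replicate(3000, matrix(rbinom(8, 1, 0.5), 4, 2),
                    simplify = FALSE)
  labs <- rep(scenarios(), each = 1000)
  b <- assemble_batch(mats, labs, val_frac = 0.25, seed = 7,
                      missing_rate = 0)
  val_labs <- b$labels[b$split == "validation"]
  shares <- table(factor(val_labs, scenarios())) / length(val_labs)
  expect_true(all(abs(shares - 1 / 3) < 0.06))
})

test_that("empirical subsampling is deterministic and well shaped", {
  set.seed(8)
  m <- matrix(rbinom(2305 * 20, 1, 0.4), 2305, 20)
  subs <- subsample_empirical(m, n_snps = 1000, reps = 5, seed = 9)
  expect_length(subs, 5)
  expect_true(all(vapply(subs, function(s) all(dim(s) == c(1000, 20)),
                         logical(1))))
  subs2 <- subsample_empirical(m, n_snps = 1000, reps = 5, seed = 9)
  expect_identical(subs, subs2)
  expect_error(subsample_empirical(m, n_snps = 3000), "fewer rows")
})

test_that("full-size subsamples are row permutations of the input", {
  set.seed(10)
  m <- matrix(rbinom(50 * 6, 1, 0.5), 50, 6)
  sub <- subsample_empirical(m, n_snps = 50, reps = 1, seed = 11)[[1]]
  ref <- to_major_minor(m)
  key <- function(x) sort(apply(x, 1, paste, collapse = ""))
  expect_equal(key(sub), key(ref))
})
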