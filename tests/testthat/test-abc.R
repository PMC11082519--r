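test_that("perfectly separated summaries give a degenerate posterior", {
  s <- rbind(diag(3), diag(3))
  labs <- rep(scenarios(), 2)
  res <- abc_model_posterior(c(0, 0, 1), s, labs, tolerance = 1 / 3)
  expect_equal(res$posterior$posterior[res$posterior$scenario == "SSH_BC"],
               1)
  expect_equal(sum(res$posterior$posterior), 1)
})

test_that("tolerance one returns the label proportions", {
  set.seed(1)
  s <- matrix(runif(40 * 3), 40)
  labs <- sample(scenarios(), 40, TRUE, prob = c(0.5, 0.3, 0.2))
  res <- abc_model_posterior(c(1, 0, 0), s, labs, tolerance = 1)
  expect_equal(res$posterior$posterior,
               as.numeric(table(factor(labs, scenarios()))) / 40)
})

test_that("a six-point worked example retains the three nearest", {
  s <- rbind(c(0, 0.1), c(0.2, 0), c(0.15, 0.15),
             c(1, 0), c(0, 2), c(3, 0))
  labs <- c("A", "B", "A", "B", "C", "C")
  res <- abc_model_posterior(c(0, 0), s, labs, tolerance = 0.5)
  expect_setequal(res$retained, c(1L, 2L, 3L))
  expect_equal(res$posterior$posterior[match(c("A", "B", "C"),
                                             res$posterior$scenario)],
               c(2 / 3, 1 / 3, 0))
})

test_that("ties at equal distance break by simulation index", {
  s <- matrix(0.5, 10, 2)
  res <- abc_model_posterior(c(0, 0), s, rep("SSH", 10), tolerance = 0.3)
  expect_equal(res$retained, 1:3)
})

test_that("the posterior ignores the order of the reference table", {
  set.seed(2)
  s <- matrix(runif(60 * 3), 60)
  labs <- sample(scenarios(), 60, TRUE)
  obs <- runif(3)
  a <- abc_model_posterior(obs, s, labs, 0.1)
  perm <- sample(60)
  b <- abc_model_posterior(obs, s[perm, ], labs[perm], 0.1)
  expect_equal(dplyr::arrange(a$posterior, scenario),
               dplyr::arrange(b$posterior, scenario))
})

test_that("the smallest tolerance collapses to the nearest label", {
  set.seed(3)
  s <- matrix(runif(50 * 3), 50)
  labs <- sample(scenarios(), 50, TRUE)
  obs <- runif(3)
  res <- abc_model_posterior(obs, s, labs, tolerance = 1 / 50)
  nearest <- labs[which.min(sqrt(colSums((t(s) - obs)^2)))]
  expect_equal(res$posterior$posterior[res$posterior$scenario == nearest],
               1)
})

test_that("parameter posterior retains ceil(tol * N) draws", {
  set.seed(4)
  n <- 10000
  s <- matrix(runif(n * 3), n)
  draws <- tibble::tibble(theta_LZFU = runif(n, 1, 5))
  res <- abc_parameter_posterior(c(0.5, 0.5, 0.5), s, draws,
                                 tolerance = 0.001)
  expect_equal(nrow(res$retained_draws), 10)
  expect_error(abc_parameter_posterior(c(0, 0, 0), s[0, , drop = FALSE],
                                       draws[0, ], 0.001), "")
})

test_that("parameter posterior recovers an informative parameter", {
  # summaries carry a noisy signal of theta; an observation generated at
  # theta = 3 must retain draws spanning 3
  set.seed(5)
  n <- 5000
  theta <- runif(n, 1, 5)
  s <- cbind(theta / 5 + rnorm(n, 0, 0.02),
             1 - theta / 5 + rnorm(n, 0, 0.02))
  obs <- c(3 / 5, 1 - 3 / 5)
  res <- abc_parameter_posterior(obs, s, tibble::tibble(theta = theta),
                                 tolerance = 0.01)
  expect_gt(3, min(res$retained_draws$theta))
  expect_lt(3, max(res$retained_draws$theta))
  est <- res$point_estimates
  expect_lt(abs(est$median[est$parameter == "theta"] - 3), 0.5)
})

test_that("cross-validation is diagonal for separated clusters", {
  set.seed(6)
  centers <- diag(3) * 10
  s <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(60 * 3, 0, 0.1), 60), 2, centers[k, ], `+`)))
  labs <- rep(scenarios(), each = 60)
  cv <- abc_cross_validate(s, labs, n_pseudo = 10, tolerance = 0.05,
                           seed = 7)
  tab <- cv$table
  for (sc in scenarios())
    expect_equal(tab[[sc]][tab$truth == sc], 10L)
})

test_that("a pseudo-observed point never retains itself", {
  # one far outlier per class: its posterior must come from the rest
  s <- rbind(c(100, 100, 100), matrix(runif(30 * 3), 30))
  labs <- c("CIH", rep(scenarios(), 10))
  res <- abc_model_posterior(s[1, ], s[-1, , drop = FALSE], labs[-1],
                             tolerance = 0.1)
  expect_false(any(res$distances == 0))
  cv <- abc_cross_validate(s, labs, n_pseudo = 1, tolerance = 0.1,
                           seed = 8)
  expect_equal(sum(as.matrix(cv$table[, scenarios()])), 3)
})
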