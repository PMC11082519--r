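# small toy problem helpers: class-constant column blocks are linearly
# separable; label shuffling destroys all signal
toy_images <- function(n_per_class, L = 30, C = 12, seed = 1) {
  set.seed(seed)
  mk <- function(cl) {
    m <- matrix(rbinom(L * C, 1, 0.2), L, C)
    m[, ((cl - 1) * 4 + 1):((cl - 1) * 4 + 4)] <- 1L
    m
  }
  list(mats = lapply(rep(1:3, each = n_per_class), mk),
       labs = scenarios()[rep(1:3, each = n_per_class)])
}

small_config <- function(L = 30, C = 12, ...) {
  args <- utils::modifyList(
    list(n_loci = L, n_samples = C, batch_size = 64L,
         patience_epochs = 20L, max_epochs = 40L),
    list(...))
  do.call(network_config, args)
}

test_that("untrained softmax output is a probability vector", {
  net <- build_network(30, 12, small_config(), seed = 1)
  img <- matrix(rbinom(30 * 12, 1, 0.5), 30, 12)
  p <- predict(net, img)
  expect_equal(sum(p$CIH + p$SSH + p$SSH_BC), 1, tolerance = 1e-5)
  expect_true(all(as.matrix(p[scenarios()]) >= 0))
})

test_that("identical seeds give identical initial weights", {
  a <- build_network(30, 12, small_config(), seed = 2)
  b <- build_network(30, 12, small_config(), seed = 2)
  expect_identical(a$params$W1, b$params$W1)
  expect_identical(a$params$Wd1, b$params$Wd1)
})

test_that("a linearly separable problem is learned perfectly", {
  toy <- toy_images(100)
  b <- assemble_batch(toy$mats, toy$labs, val_frac = 0.25,
                      missing_rate = 0.02, seed = 3)
  net <- build_network(30, 12, small_config(), seed = 4)
  fit <- train_classifier(net, b, seed = 5)
  expect_equal(max(fit$history$val_accuracy), 1)
  expect_lte(fit$best_epoch, 50)
})

test_that("shuffled labels stay at chance-level validation accuracy", {
  toy <- toy_images(300)
  set.seed(6)
  labs <- sample(toy$labs)
  b <- assemble_batch(toy$mats, labs, val_frac = 0.3, missing_rate = 0,
                      seed = 7)
  net <- build_network(30, 12, small_config(max_epochs = 10L), seed = 8)
  fit <- train_classifier(net, b, seed = 9)
  final_acc <- tail(fit$history$val_accuracy, 1)
  expect_lt(abs(final_acc - 1 / 3), 0.08)
})

test_that("training is deterministic under a fixed seed", {
  toy <- toy_images(40)
  b <- assemble_batch(toy$mats, toy$labs, val_frac = 0.25,
                      missing_rate = 0, seed = 10)
  net <- build_network(30, 12, small_config(max_epochs = 4L), seed = 11)
  f1 <- train_classifier(net, b, seed = 12)
  f2 <- train_classifier(net, b, seed = 12)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params$W1, f2$params$W1)
})

test_that("checkpointed weights come from the best validation epoch", {
  toy <- toy_images(60)
  b <- assemble_batch(toy$mats, toy$labs, val_frac = 0.25,
                      missing_rate = 0.3, seed = 13)
  net <- build_network(30, 12, small_config(max_epochs = 15L), seed = 14)
  fit <- train_classifier(net, b, seed = 15)
  expect_equal(fit$history$val_accuracy[fit$best_epoch],
               max(fit$history$val_accuracy))
})

test_that("temperature fitting satisfies the scaling identities", {
  # draw labels from the softmax of known logits: fitted T is near 1,
  # and scaling the logits by 10 scales the fitted T by exactly 10
  set.seed(16)
  n <- 5000
  lg <- matrix(rnorm(n * 3, 0, 2), n)
  p <- exp(lg) / rowSums(exp(lg))
  y <- vapply(seq_len(n), function(i) sample.int(3, 1, prob = p[i, ]),
              integer(1))
  t1 <- fit_temperature(lg, y)
  expect_lt(abs(t1 - 1), 0.1)
  t10 <- fit_temperature(lg * 10, y)
  expect_lt(abs(t10 / t1 - 10), 0.1) # 1% of the ratio
})

test_that("calibration changes confidence but never the argmax", {
  toy <- toy_images(80)
  b <- assemble_batch(toy$mats, toy$labs, val_frac = 0.25,
                      missing_rate = 0.1, seed = 17)
  net <- build_network(30, 12, small_config(max_epochs = 6L), seed = 18)
  fit <- train_classifier(net, b, seed = 19)
  before <- predict(fit, b)
  cal <- calibrate_temperature(fit, b)
  expect_gt(cal$temperature, 0)
  after <- predict(cal, b)
  expect_identical(before$pred, after$pred)
})

test_that("prediction is consistent across duplicates and averages", {
  net <- build_network(30, 12, small_config(), seed = 20)
  img <- matrix(rbinom(30 * 12, 1, 0.5), 30, 12)
  p <- predict(net, replicate(5, img, simplify = FALSE))
  probs <- as.matrix(p[scenarios()])
  # single-precision GEMM may round edge columns differently
  expect_lt(max(abs(sweep(probs, 2, probs[1, ]))), 1e-5)
  expect_equal(unique(p$pred), p$pred[1])
  avg <- average_prediction(p)
  expect_equal(sum(avg), 1, tolerance = 1e-6)
  expect_error(predict(net, matrix(0L, 10, 12)), "shape")
})

test_that("network shape guards reject impossible inputs", {
  expect_error(network_config(5, 12), "too small")
  expect_error(
    train_classifier(build_network(30, 12, small_config(), seed = 21),
                     structure(list(images = matrix(as.raw(0), 360, 2),
                                    n_loci = 30L, n_samples = 12L,
                                    labels = c("SSH", "SSH"),
                                    split = c("train", "train")),
                               class = "sim_batch")),
    "validation")
})
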