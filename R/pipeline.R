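#' Pseudo-empirical SNP dataset with known truth
#'
#' Simulates a stand-in for the empirical phased SNP matrix: one
#' parameter draw under the requested scenario, a matrix of unlinked
#' SNPs at the empirical dimensions (2305 SNPs x 232 haplotypes by
#' default), and missing genotypes injected at the empirical rate. The
#' generating scenario and draw are stored alongside so recovery can be
#' checked.
#'
#' @param scenario One of [scenarios()].
#' @param priors A [prior_set()].
#' @param n_snps SNP count (default 2305).
#' @param missing_rate Missing fraction (default 0.044).
#' @param seed Optional integer seed.
#' @return A `pseudo_empirical`: `matrix` (`hap_matrix` with NAs) and
#'   `truth` (scenario + `parameter_draw`).
#' @export
make_pseudo_empirical <- function(scenario, priors = prior_set(),
                                  n_snps = 2305, missing_rate = 0.044,
                                  seed = NULL) {
  scenario <- match.arg(scenario, scenarios())
  if (!is.null(seed)) set.seed(seed)
  draw <- draw_parameters(scenario, priors)
  dem <- compile_demography(scenario, draw)
  m <- simulate_snp_matrix(dem, n_snps)
  m2 <- inject_missing(unclass(m), missing_rate)
  attributes(m2) <- attributes(m)[c("dim", "pop_partition", "class")]
  dim(m2) <- dim(m)
  structure(list(matrix = m2, truth = list(scenario = scenario,
                                           draw = draw)),
            class = "pseudo_empirical")
}

#' @export
print.pseudo_empirical <- function(x, ...) {
  cat("<pseudo_empirical> truth:", x$truth$scenario, "\n")
  print(x$matrix)
  invisible(x)
}

#' Configuration of the full simulation--training--ABC analysis
#'
#' The default is the desk-scale profile: 1500 training and 1000 test
#' simulations per scenario of 250 SNPs each. [study_profile()] returns
#' the study-scale configuration (10 000 + 10 000 per scenario, 1000
#' SNPs, 0.1\% parameter tolerance, patience 150).
#'
#' @param n_train,n_test Simulations per scenario for training (incl.
#'   validation) and for the test/reference set.
#' @param n_snps SNPs per simulated image.
#' @param priors A [prior_set()].
#' @param populations Population panel.
#' @param pseudo_scenario Scenario generating the pseudo-empirical
#'   matrix when no observed matrix is supplied.
#' @param n_snps_empirical SNP count of the (pseudo-)empirical matrix.
#' @param n_subsamples Random SNP subsamples of the empirical matrix fed
#'   to the classifier (default 100).
#' @param missing_rate Missing-injection rate.
#' @param val_frac Validation fraction of the training batch.
#' @param tol_model ABC tolerance for model choice (default 0.05).
#' @param tol_param ABC tolerance for parameter estimation within the
#'   preferred scenario; the desk default 0.01 retains 10 of 1000
#'   reference simulations, matching the retained count of the
#'   study-scale 0.001 x 10 000.
#' @param n_pseudo_cv Pseudo-observed simulations per scenario in the
#'   ABC cross-validation.
#' @param ... Overrides passed to [network_config()] (e.g.
#'   `max_epochs`, `patience_epochs`, `learning_rate`).
#' @return An `analysis_config` list.
#' @export
analysis_config <- function(n_train = 1500, n_test = 1000, n_snps = 250,
                            priors = prior_set(),
                            populations = default_populations(),
                            pseudo_scenario = "SSH_BC",
                            n_snps_empirical = 2305,
                            n_subsamples = 100,
                            missing_rate = 0.044, val_frac = 0.25,
                            tol_model = 0.05, tol_param = 0.01,
                            n_pseudo_cv = 10, ...) {
  net_args <- list(...)
  structure(list(
    n_train = n_train, n_test = n_test, n_snps = n_snps,
    priors = priors, populations = populations,
    pseudo_scenario = pseudo_scenario,
    n_snps_empirical = n_snps_empirical, n_subsamples = n_subsamples,
    missing_rate = missing_rate, val_frac = val_frac,
    tol_model = tol_model, tol_param = tol_param,
    n_pseudo_cv = n_pseudo_cv, net_args = net_args
  ), class = "analysis_config")
}

#' @rdname analysis_config
#' @export
study_profile <- function(...) {
  analysis_config(n_train = 10000, n_test = 10000, n_snps = 1000,
                  tol_param = 0.001, patience_epochs = 150L,
                  max_epochs = 1000L, ...)
}

# simulate one scenario set and encode each matrix straight into the raw
# byte store (recode to major/minor, inject missing), so full matrices
# are never all held in memory at once
sim_encode_set <- function(scenario, n, config) {
  n_hap <- 2L * sum(config$populations$n_diploid)
  images <- matrix(as.raw(0), nrow = config$n_snps * n_hap, ncol = n)
  draws <- vector("list", n)
  for (i in seq_len(n)) {
    d <- draw_parameters(scenario, config$priors,
                         populations = config$populations)
    dem <- compile_demography(scenario, d)
    m <- to_major_minor(simulate_snp_matrix(dem, config$n_snps))
    if (config$missing_rate > 0) m <- inject_missing(m, config$missing_rate)
    images[, i] <- encode_raw(m)
    draws[[i]] <- d
  }
  list(images = images, draws = dplyr::bind_rows(lapply(draws, tidy)))
}

# batch assembly over pre-encoded raw images (shared shuffle/split rules
# with assemble_batch)
assemble_raw_batch <- function(images, n_loci, n_samples, labels, draws,
                               val_frac, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(images)
  perm <- sample.int(n)
  n_val <- ceiling(val_frac * n)
  structure(list(
    images = images[, perm, drop = FALSE],
    n_loci = n_loci, n_samples = n_samples,
    labels = labels[perm],
    draws = if (!is.null(draws)) draws[perm, , drop = FALSE],
    split = c(rep("validation", n_val), rep("train", n - n_val))
  ), class = "sim_batch")
}

#' Run the full simulate-train-calibrate-predict-ABC analysis
#'
#' Executes the pipeline end to end: simulates labeled SNP matrices
#' under the three colonization scenarios, encodes them, trains and
#' temperature-calibrates the convolutional classifier, evaluates the
#' test-set confusion matrix, averages the classifier's predictions over
#' random SNP subsamples of the (pseudo-)empirical matrix, and runs the
#' ABC rejection steps (model posterior, within-model parameter
#' posterior, pseudo-observed cross-validation).
#'
#' Stage seeds are derived from `seed` by fixed offsets so every stage
#' is independently reproducible.
#'
#' @param config An [analysis_config()].
#' @param seed Integer master seed.
#' @param observed Optional observed `hap_matrix` (or
#'   `pseudo_empirical`); simulated under `config$pseudo_scenario` when
#'   omitted.
#' @param verbose Print stage progress.
#' @return A `run_report`; see [print.run_report()].
#' @export
run_full_analysis <- function(config = analysis_config(), seed = 1,
                              observed = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "analysis_config"))
  t_start <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating %d training + %d test datasets per scenario (%d SNPs)",
      config$n_train, config$n_test, config$n_snps)
  n_hap <- 2L * sum(config$populations$n_diploid)
  set.seed(seed)
  train_sets <- lapply(scenarios(), sim_encode_set, n = config$n_train,
                       config = config)
  set.seed(seed + 1L)
  test_sets <- lapply(scenarios(), sim_encode_set, n = config$n_test,
                      config = config)

  train_labs <- rep(scenarios(), each = config$n_train)
  test_labs <- rep(scenarios(), each = config$n_test)
  test_draws <- dplyr::bind_rows(lapply(test_sets, `[[`, "draws"))

  say("assembling batches")
  batch <- assemble_raw_batch(
    do.call(cbind, lapply(train_sets, `[[`, "images")),
    config$n_snps, n_hap, train_labs, NULL, config$val_frac,
    seed = seed + 2L)
  rm(train_sets)
  test_batch <- assemble_raw_batch(
    do.call(cbind, lapply(test_sets, `[[`, "images")),
    config$n_snps, n_hap, test_labs, test_draws, 0, seed = seed + 3L)
  rm(test_sets)

  say("training the classifier")
  net_cfg <- do.call(network_config,
                     c(list(n_loci = config$n_snps,
                            n_samples = 2L * sum(config$populations$n_diploid)),
                       config$net_args))
  net <- build_network(net_cfg$n_loci, net_cfg$n_samples, net_cfg,
                       seed = seed + 4L)
  net <- train_classifier(net, batch, seed = seed + 5L, verbose = verbose)
  net <- calibrate_temperature(net, batch)
  say("best epoch %d, validation accuracy %.3f, temperature %.3f",
      net$best_epoch, max(net$history$val_accuracy), net$temperature)

  say("evaluating on the test set")
  test_pred <- predict(net, test_batch)
  truth <- test_batch$labels
  conf <- prop.table(table(truth = truth, predicted = test_pred$pred), 1)
  conf_tbl <- tibble::as_tibble(as.data.frame.matrix(conf),
                                rownames = "truth")
  for (sc in scenarios()) if (!sc %in% names(conf_tbl)) conf_tbl[[sc]] <- 0
  conf_tbl <- conf_tbl[match(scenarios(), conf_tbl$truth),
                       c("truth", scenarios())]
  accuracy <- vapply(scenarios(), function(sc) conf_tbl[[sc]][
    match(sc, conf_tbl$truth)], numeric(1))

  if (is.null(observed)) {
    say("simulating the pseudo-empirical matrix (truth %s)",
        config$pseudo_scenario)
    observed <- make_pseudo_empirical(config$pseudo_scenario,
                                      config$priors,
                                      config$n_snps_empirical,
                                      config$missing_rate,
                                      seed = seed + 6L)
  }
  obs_matrix <- if (inherits(observed, "pseudo_empirical"))
    observed$matrix else observed
  truth_info <- if (inherits(observed, "pseudo_empirical"))
    observed$truth else NULL

  say("predicting %d empirical subsamples", config$n_subsamples)
  subs <- subsample_empirical(obs_matrix, n_snps = config$n_snps,
                              reps = config$n_subsamples,
                              seed = seed + 7L)
  sub_pred <- predict(net, subs)
  obs_summary <- average_prediction(sub_pred)

  say("ABC rejection steps")
  test_summaries <- as.matrix(test_pred[scenarios()])
  model_post <- abc_model_posterior(obs_summary, test_summaries,
                                    truth, config$tol_model,
                                    levels = scenarios())
  preferred <- model_post$posterior$scenario[
    which.max(model_post$posterior$posterior)]
  pref_rows <- which(truth == preferred)
  param_post <- abc_parameter_posterior(
    obs_summary, test_summaries[pref_rows, , drop = FALSE],
    test_batch$draws[pref_rows, , drop = FALSE], config$tol_param)
  cv <- abc_cross_validate(test_summaries, truth,
                           n_pseudo = config$n_pseudo_cv,
                           tolerance = config$tol_model,
                           seed = seed + 8L, levels = scenarios())

  structure(list(
    confusion = conf_tbl, accuracy = accuracy,
    test_summaries = test_summaries, test_labels = truth,
    empirical_summary = obs_summary,
    model_posterior = model_post, preferred = preferred,
    parameter_posterior = param_post, cross_validation = cv,
    truth = truth_info, model = net, config = config, seed = seed,
    elapsed = as.numeric(Sys.time() - t_start, units = "secs")
  ), class = "run_report")
}

#' Print a pipeline run report
#'
#' @param x A `run_report` from [run_full_analysis()].
#' @param ... Unused.
#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, sprintf("(%.1f min)\n", x$elapsed / 60))
  cat("\nTest-set confusion (rows = simulated truth):\n")
  print(as.data.frame(x$confusion), row.names = FALSE, digits = 3)
  cat("\nAveraged classifier summary of the observed matrix:\n")
  print(round(x$empirical_summary, 4))
  cat("\nABC model posterior (tolerance", x$model_posterior$tolerance,
      "):\n")
  print(as.data.frame(x$model_posterior$posterior), row.names = FALSE)
  cat("\nPreferred model:", x$preferred)
  if (!is.null(x$truth)) cat(" | truth:", x$truth$scenario)
  cat("\n")
  invisible(x)
}

#' @export
glance.run_report <- function(x, ...) {
  tibble::tibble(
    preferred = x$preferred,
    posterior = max(x$model_posterior$posterior$posterior),
    truth = if (!is.null(x$truth)) x$truth$scenario else NA_character_,
    min_accuracy = min(x$accuracy),
    acc_CIH = x$accuracy[["CIH"]],
    acc_SSH = x$accuracy[["SSH"]],
    acc_SSH_BC = x$accuracy[["SSH_BC"]],
    temperature = x$model$temperature,
    elapsed_s = x$elapsed
  )
}

#' Confusion-matrix heat map of a run report
#'
#' @param object A `run_report`.
#' @param ... Unused.
#' @return A ggplot tile plot of the test confusion matrix.
#' @export
autoplot.run_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$confusion, -"truth",
                              names_to = "predicted",
                              values_to = "rate")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                     fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.3f", .data$rate)), color = "white") +
    ggplot2::scale_y_discrete(limits = rev(scenarios())) +
    ggplot2::labs(x = "predicted model", y = "simulated model",
                  fill = "rate")
}
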