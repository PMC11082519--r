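#' Rejection-ABC model posterior from classifier summaries
#'
#' Treats the classifier's class-probability vector of the observed data
#' as the summary statistic, computes unweighted Euclidean distances to
#' the summaries of labeled test-set simulations, retains the
#' `ceiling(tolerance * N)` nearest (ties broken by simulation index),
#' and estimates each scenario's posterior probability as its share of
#' the retained simulations.
#'
#' @param observed Numeric summary vector (class probabilities).
#' @param summaries Numeric matrix, simulations x summary dimensions.
#' @param labels Scenario label of each simulation.
#' @param tolerance Retained fraction (default 0.05).
#' @param levels Scenario levels for the posterior table.
#' @return An `abc_result`: posterior tibble, retained indices, distances.
#' @export
#' @examples
#' s <- rbind(diag(3), diag(3))
#' abc_model_posterior(c(0, 0, 1), s, rep(scenarios(), 2), tolerance = 1/3)
abc_model_posterior <- function(observed, summaries, labels,
                                tolerance = 0.05, levels = NULL) {
  summaries <- as.matrix(summaries)
  n <- nrow(summaries)
  if (n == 0) abort("empty test set")
  stopifnot(length(observed) == ncol(summaries), length(labels) == n,
            tolerance > 0, tolerance <= 1)
  if (is.null(levels)) levels <- sort(unique(as.character(labels)))
  d <- sqrt(colSums((t(summaries) - observed)^2))
  keep <- ceiling(tolerance * n)
  retained <- order(d)[seq_len(keep)] # order() is stable: index breaks ties
  tab <- table(factor(as.character(labels)[retained], levels = levels))
  structure(list(
    observed = observed,
    posterior = tibble::tibble(scenario = levels,
                               posterior = as.numeric(tab) / keep),
    retained = retained, distances = d, tolerance = tolerance, n = n
  ), class = "abc_result")
}

#' @export
print.abc_result <- function(x, ...) {
  cat("<abc_result>", length(x$retained), "of", x$n,
      "simulations retained (tolerance", x$tolerance, ")\n")
  print(as.data.frame(x$posterior), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.abc_result <- function(x, ...) x$posterior

#' @export
glance.abc_result <- function(x, ...) {
  best <- which.max(x$posterior$posterior)
  tibble::tibble(
    preferred = x$posterior$scenario[best],
    posterior = x$posterior$posterior[best],
    n_retained = length(x$retained), tolerance = x$tolerance
  )
}

#' Rejection-ABC parameter posterior within the preferred scenario
#'
#' Restricts the reference table to simulations of the preferred scenario
#' and retains the `ceiling(tolerance * N)` parameter draws whose
#' summaries are nearest the observed summary (simple rejection, no
#' regression adjustment). Reports per-parameter posterior medians and
#' central 95\% intervals.
#'
#' @param observed Numeric summary vector.
#' @param summaries Summaries of the preferred scenario's simulations.
#' @param draws Data frame of parameter draws aligned with `summaries`.
#' @param tolerance Retained fraction (default 0.001).
#' @return A `param_posterior`: retained draws and a summary tibble.
#' @export
abc_parameter_posterior <- function(observed, summaries, draws,
                                    tolerance = 0.001) {
  summaries <- as.matrix(summaries)
  n <- nrow(summaries)
  stopifnot(n > 0, nrow(draws) == n, tolerance > 0, tolerance <= 1)
  keep <- ceiling(tolerance * n)
  if (keep < 1) abort("tolerance retains no simulations")
  d <- sqrt(colSums((t(summaries) - observed)^2))
  retained <- order(d)[seq_len(keep)]
  kept <- tibble::as_tibble(draws[retained, , drop = FALSE])
  num <- names(kept)[vapply(kept, is.numeric, logical(1))]
  est <- dplyr::bind_rows(lapply(num, function(p) {
    v <- kept[[p]]
    tibble::tibble(parameter = p, median = stats::median(v, na.rm = TRUE),
                   q2.5 = unname(stats::quantile(v, 0.025, na.rm = TRUE)),
                   q97.5 = unname(stats::quantile(v, 0.975, na.rm = TRUE)))
  }))
  structure(list(retained_draws = kept, point_estimates = est,
                 retained = retained, tolerance = tolerance, n = n),
            class = "param_posterior")
}

#' @export
print.param_posterior <- function(x, ...) {
  cat("<param_posterior>", nrow(x$retained_draws), "retained of", x$n,
      "simulations\n")
  print(as.data.frame(x$point_estimates), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.param_posterior <- function(x, ...) x$point_estimates

#' Cross-validate the ABC model choice with pseudo-observed simulations
#'
#' Holds out `n_pseudo` test simulations per scenario, treats each as the
#' observed summary, recomputes the ABC model posterior against the
#' remaining reference table (the pseudo-observed point never retains
#' itself), and tabulates the argmax assignments.
#'
#' @inheritParams abc_model_posterior
#' @param n_pseudo Pseudo-observed simulations per scenario (default 10).
#' @param seed Optional integer seed for the hold-out choice.
#' @return An `abc_cv`: tibble of truth x assigned counts.
#' @export
abc_cross_validate <- function(summaries, labels, n_pseudo = 10,
                               tolerance = 0.05, seed = NULL,
                               levels = NULL) {
  summaries <- as.matrix(summaries)
  labels <- as.character(labels)
  if (is.null(levels)) levels <- sort(unique(labels))
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (sc in levels) {
    pool <- which(labels == sc)
    if (length(pool) < n_pseudo)
      abort("not enough test simulations to hold out pseudo-observed points")
    held <- sample(pool, n_pseudo)
    for (i in held) {
      res <- abc_model_posterior(summaries[i, ],
                                 summaries[-i, , drop = FALSE],
                                 labels[-i], tolerance, levels = levels)
      assigned <- res$posterior$scenario[which.max(res$posterior$posterior)]
      rows[[length(rows) + 1]] <- tibble::tibble(truth = sc,
                                                 assigned = assigned)
    }
  }
  long <- dplyr::count(dplyr::bind_rows(rows), .data$truth,
                       .data$assigned, name = "n")
  wide <- tidyr::pivot_wider(long, names_from = "assigned",
                             values_from = "n", values_fill = 0L)
  for (sc in levels) if (!sc %in% names(wide)) wide[[sc]] <- 0L
  wide <- wide[match(levels, wide$truth), c("truth", levels)]
  structure(list(table = wide, n_pseudo = n_pseudo,
                 tolerance = tolerance), class = "abc_cv")
}

#' @export
print.abc_cv <- function(x, ...) {
  cat("<abc_cv>", x$n_pseudo, "pseudo-observed per scenario\n")
  print(as.data.frame(x$table), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.abc_cv <- function(x, ...) x$table
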