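#' @useDynLib coalcnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr bind_rows
#' @importFrom rlang .data abort
#' @importFrom stats rnorm runif setNames
NULL

#' Colonization scenario labels
#'
#' The three colonization hypotheses compared by the pipeline, in the fixed
#' order used for class indices and probability vectors throughout the
#' package: central island hub (`CIH`), surfing syngameon (`SSH`), and
#' surfing syngameon with back-colonization of the mainland (`SSH_BC`).
#'
#' @return Character vector of the three scenario labels.
#' @export
scenarios <- function() c("CIH", "SSH", "SSH_BC")

#' Default population panel
#'
#' The eight-deme sampling design: six island populations (Tenerife split
#' into its eastern and western halves), the pooled
#' Lanzarote--Fuerteventura deme (`LZFU`, individuals of the two islands are
#' genetically intermingled), and the pooled north-west African mainland
#' deme (`NWA`). Sample sizes total 116 diploid individuals.
#'
#' @return A tibble with columns `name` and `n_diploid`.
#' @export
#' @examples
#' default_populations()
default_populations <- function() {
  tibble::tibble(
    name      = c("NWA", "LZFU", "GC", "eTEN", "wTEN", "GO", "LP", "HI"),
    n_diploid = c(15L,   15L,    19L,  21L,    7L,     29L,  5L,   5L)
  )
}

#' Prior distributions for the demographic parameters
#'
#' Builds the prior set used to draw simulation parameters. Defaults:
#' the initial divergence (crown) age is normal with mean 2.09 Ma truncated
#' to its 95\% interval (0.92, 3.38) Ma; the mutation--drift parameter
#' \eqn{\theta} of the LZFU deme is uniform on (1, 5) per locus and every
#' other deme's \eqn{\theta} is a uniform (0.2, 2) multiple of it;
#' generation time is uniform on (5, 6) years; every colonization carries a
#' founder effect reducing the new deme to a uniform (0, 0.05) fraction of
#' its source, followed by exponential recovery to the present size;
#' migration rates are uniform on (0, 10) migrants per generation, active
#' only inside the window 14 kyr--1.25 Myr before present; the mutation
#' rate is 0.001 substitutions per site per million years and loci average
#' 1700 sites (used to convert per-locus \eqn{\theta} to \eqn{N_e} via
#' \eqn{\theta = 4 N_e \mu}).
#'
#' @param t_root_mean Mean of the crown-age prior, years.
#' @param t_root_ci95 Length-2 vector, the 95\% interval of the crown age
#'   (also its truncation bounds), years.
#' @param theta_lzfu Uniform bounds for the per-locus \eqn{\theta} of LZFU.
#' @param theta_ratio Uniform bounds for the relative \eqn{\theta} ratio of
#'   the remaining demes.
#' @param gen_time Uniform bounds for the generation time, years.
#' @param founder_frac Uniform bounds for the founder-effect fraction.
#' @param mig_rate Uniform bounds for migration, migrants per generation.
#' @param mig_window Closed interval, years before present, inside which
#'   migration is active.
#' @param mu_site_per_My Mutation rate, substitutions per site per million
#'   years.
#' @param locus_length Average locus length in sites, used only for the
#'   \eqn{\theta}-per-site conversion.
#' @return An object of class `prior_set` (a named list).
#' @export
#' @examples
#' pr <- prior_set()
#' pr$theta_lzfu
prior_set <- function(t_root_mean = 2.09e6,
                      t_root_ci95 = c(0.92e6, 3.38e6),
                      theta_lzfu = c(1, 5),
                      theta_ratio = c(0.2, 2),
                      gen_time = c(5, 6),
                      founder_frac = c(0.0, 0.05),
                      mig_rate = c(0, 10),
                      mig_window = c(14000, 1.25e6),
                      mu_site_per_My = 0.001,
                      locus_length = 1700) {
  chk_iv <- function(x, nm, lo = -Inf, hi = Inf) {
    if (length(x) != 2 || !is.numeric(x) || x[1] > x[2])
      abort(paste0("`", nm, "` must be an ordered numeric interval"))
    if (x[1] < lo || x[2] > hi)
      abort(paste0("`", nm, "` must lie within [", lo, ", ", hi, "]"))
  }
  chk_iv(t_root_ci95, "t_root_ci95", 0)
  chk_iv(theta_lzfu, "theta_lzfu", 0)
  chk_iv(theta_ratio, "theta_ratio", 0)
  chk_iv(gen_time, "gen_time", 0)
  chk_iv(founder_frac, "founder_frac", 0, 1)
  chk_iv(mig_rate, "mig_rate", 0)
  chk_iv(mig_window, "mig_window", 0)
  stopifnot(mu_site_per_My > 0, locus_length > 0)
  structure(list(
    t_root_mean = t_root_mean, t_root_ci95 = t_root_ci95,
    theta_lzfu = theta_lzfu, theta_ratio = theta_ratio,
    gen_time = gen_time, founder_frac = founder_frac,
    mig_rate = mig_rate, mig_window = mig_window,
    mu_site_per_My = mu_site_per_My, locus_length = locus_length
  ), class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat("<prior_set>\n")
  cat(sprintf("  crown age: N(%.3g) truncated to [%.3g, %.3g] yr\n",
              x$t_root_mean, x$t_root_ci95[1], x$t_root_ci95[2]))
  cat(sprintf("  theta(LZFU) ~ U(%g, %g) per locus; ratio ~ U(%g, %g)\n",
              x$theta_lzfu[1], x$theta_lzfu[2],
              x$theta_ratio[1], x$theta_ratio[2]))
  cat(sprintf("  generation time ~ U(%g, %g) yr; founder ~ U(%g, %g)\n",
              x$gen_time[1], x$gen_time[2],
              x$founder_frac[1], x$founder_frac[2]))
  cat(sprintf("  migration ~ U(%g, %g) migrants/gen in [%g, %g] yr BP\n",
              x$mig_rate[1], x$mig_rate[2],
              x$mig_window[1], x$mig_window[2]))
  cat(sprintf("  mu = %g /site/My; locus length = %g sites\n",
              x$mu_site_per_My, x$locus_length))
  invisible(x)
}

runif1 <- function(iv) if (iv[1] == iv[2]) iv[1] else runif(1, iv[1], iv[2])

# truncated-normal crown age: sd chosen so the stated bounds are the
# central 95% interval of the untruncated normal
rtrunc_root <- function(priors) {
  m <- priors$t_root_mean
  ci <- priors$t_root_ci95
  if (ci[1] == ci[2]) return(ci[1])
  s <- (ci[2] - ci[1]) / (2 * stats::qnorm(0.975))
  repeat {
    x <- rnorm(1, m, s)
    if (x >= ci[1] && x <= ci[2]) return(x)
  }
}

# forward-colonization order of each scenario: child -> parent (backward
# merge target) for every non-root deme
scenario_topology <- function(scenario) {
  switch(scenario,
    SSH = list(
      root = "NWA",
      parents = c(LZFU = "NWA", GC = "LZFU", eTEN = "GC", wTEN = "eTEN",
                  GO = "wTEN", LP = "GO", HI = "LP"),
      chain = c("LZFU", "GC", "eTEN", "wTEN", "GO", "LP", "HI"),
      bc = NA_character_
    ),
    SSH_BC = list(
      root = "ANC",
      parents = c(LZFU = "ANC", GC = "LZFU", eTEN = "GC", wTEN = "eTEN",
                  GO = "wTEN", LP = "GO", HI = "LP", NWA = "LZFU"),
      chain = c("LZFU", "GC", "eTEN", "wTEN", "GO", "LP", "HI"),
      bc = "NWA"
    ),
    CIH = list(
      root = "eTEN",
      parents = c(wTEN = "eTEN", GC = "eTEN", LZFU = "GC",
                  GO = "wTEN", LP = "GO", HI = "LP", NWA = "LZFU"),
      chain = NULL,
      bc = "NWA"
    ),
    abort(paste0("unknown scenario: ", scenario))
  )
}

#' Draw one parameter set from the priors
#'
#' Samples every free parameter of a colonization scenario: the crown age,
#' per-deme \eqn{\theta} (and from it \eqn{N_e}), the generation time,
#' per-colonization founder fractions, migration rates, and the internal
#' split times. Intermediate split times are drawn sequentially, each
#' uniform on (0, parent split time), which encodes only the ordering
#' constraints of the colonization chain. The back-colonization time of the
#' mainland (scenarios `SSH_BC` and `CIH`) is uniform over the migration
#' window, truncated below the split time of its source deme.
#'
#' @param scenario One of [scenarios()].
#' @param priors A [prior_set()].
#' @param seed Optional integer seed (applied with [set.seed()]).
#' @param populations Population panel, as [default_populations()].
#' @return An object of class `parameter_draw`: a named list holding
#'   `t_root_yr`, `split_times_yr`, `theta`, `Ne`, `g_yr`, `founder_frac`,
#'   `migration` (a tibble of forward edges), and `t_bc_yr`.
#' @export
#' @examples
#' d <- draw_parameters("SSH", prior_set(), seed = 1)
#' d$t_root_yr
draw_parameters <- function(scenario, priors = prior_set(), seed = NULL,
                            populations = default_populations()) {
  scenario <- match.arg(scenario, scenarios())
  stopifnot(inherits(priors, "prior_set"))
  if (!is.null(seed)) set.seed(seed)
  topo <- scenario_topology(scenario)
  pops <- populations$name

  g_yr <- runif1(priors$gen_time)
  t_root <- rtrunc_root(priors)

  # per-deme theta: LZFU from its own prior, others as a ratio of it;
  # the unsampled ancestral mainland deme of SSH_BC gets a ratio draw too
  demes <- c(pops, if (topo$root == "ANC") "ANC")
  theta <- setNames(numeric(length(demes)), demes)
  theta["LZFU"] <- runif1(priors$theta_lzfu)
  for (p in setdiff(demes, "LZFU"))
    theta[p] <- theta["LZFU"] * runif1(priors$theta_ratio)
  Ne <- vapply(theta, theta_to_Ne, numeric(1),
               locus_length = priors$locus_length,
               mu_site_per_My = priors$mu_site_per_My, g_yr = g_yr)

  # split times: root first, then sequentially down each chain
  split_yr <- setNames(rep(NA_real_, length(topo$parents)),
                       names(topo$parents))
  if (scenario %in% c("SSH", "SSH_BC")) {
    split_yr["LZFU"] <- t_root
    for (p in topo$chain[-1])
      split_yr[p] <- runif(1, 0, split_yr[topo$parents[p]])
  } else { # CIH: the root divides the central island; two chains follow
    split_yr["wTEN"] <- t_root
    split_yr["GC"] <- runif(1, 0, t_root)
    split_yr["LZFU"] <- runif(1, 0, split_yr["GC"])
    split_yr["GO"] <- runif(1, 0, t_root)
    split_yr["LP"] <- runif(1, 0, split_yr["GO"])
    split_yr["HI"] <- runif(1, 0, split_yr["LP"])
  }

  t_bc <- NA_real_
  if (!is.na(topo$bc)) {
    hi <- min(priors$mig_window[2], split_yr[topo$parents[topo$bc]])
    lo <- min(priors$mig_window[1], hi / 2)
    t_bc <- if (lo == hi) lo else runif(1, lo, hi)
    split_yr[topo$bc] <- t_bc
  }

  founder <- setNames(vapply(names(topo$parents), function(p)
    runif1(priors$founder_frac), numeric(1)), names(topo$parents))

  migration <- if (scenario %in% c("SSH", "SSH_BC")) {
    tibble::tibble(
      from = c("eTEN", "GC", "eTEN"),
      to   = c("LZFU", "LZFU", "GC"),
      rate = c(runif1(priors$mig_rate), runif1(priors$mig_rate),
               runif1(priors$mig_rate)),
      t_on_yr  = priors$mig_window[1],
      t_off_yr = priors$mig_window[2]
    )
  } else {
    tibble::tibble(from = character(), to = character(), rate = numeric(),
                   t_on_yr = numeric(), t_off_yr = numeric())
  }

  structure(list(
    scenario = scenario, t_root_yr = t_root,
    split_times_yr = split_yr, theta = theta, Ne = Ne, g_yr = g_yr,
    founder_frac = founder, migration = migration, t_bc_yr = unname(t_bc),
    locus_length = priors$locus_length,
    mu_site_per_My = priors$mu_site_per_My,
    populations = populations
  ), class = "parameter_draw")
}

#' @export
print.parameter_draw <- function(x, ...) {
  cat("<parameter_draw> scenario", x$scenario, "\n")
  cat(sprintf("  crown age %.0f yr; generation time %.2f yr\n",
              x$t_root_yr, x$g_yr))
  cat("  Ne:", paste(sprintf("%s=%.0f", names(x$Ne), x$Ne), collapse = " "),
      "\n")
  if (!is.na(x$t_bc_yr))
    cat(sprintf("  back-colonization at %.0f yr\n", x$t_bc_yr))
  invisible(x)
}

#' Flatten a parameter draw to a one-row tibble
#'
#' @param x A `parameter_draw`.
#' @param ... Unused.
#' @return A one-row tibble with one column per scalar parameter
#'   (`theta_*`, `Ne_*`, `t_*`, `founder_*`, `mig_*`).
#' @export
tidy.parameter_draw <- function(x, ...) {
  out <- c(
    list(scenario = x$scenario, t_root_yr = x$t_root_yr, g_yr = x$g_yr,
         t_bc_yr = x$t_bc_yr),
    setNames(as.list(x$theta), paste0("theta_", names(x$theta))),
    setNames(as.list(x$split_times_yr),
             paste0("t_", names(x$split_times_yr), "_yr")),
    setNames(as.list(x$founder_frac),
             paste0("founder_", names(x$founder_frac)))
  )
  if (nrow(x$migration) > 0)
    out <- c(out, setNames(as.list(x$migration$rate),
                           paste0("mig_", x$migration$from, "_",
                                  x$migration$to)))
  tibble::as_tibble(out)
}

#' Convert a per-locus theta to a diploid effective size
#'
#' Inverts \eqn{\theta = 4 N_e \mu} at the per-site scale:
#' \eqn{N_e = (\theta/L) / (4\,\mu\,g)} with \eqn{\mu} given per site per
#' million years and \eqn{g} the generation time in years, so that
#' \eqn{\mu g \times 10^{-6}} is the per-site per-generation rate.
#'
#' @param theta_locus Per-locus mutation--drift parameter.
#' @param locus_length Locus length in sites.
#' @param mu_site_per_My Mutation rate per site per million years.
#' @param g_yr Generation time in years.
#' @return Diploid effective population size.
#' @export
#' @examples
#' theta_to_Ne(3.4, 1700, 0.001, 5) # 1e5
theta_to_Ne <- function(theta_locus, locus_length, mu_site_per_My, g_yr) {
  if (any(c(theta_locus, locus_length, mu_site_per_My, g_yr) <= 0))
    abort("all arguments of theta_to_Ne() must be positive")
  (theta_locus / locus_length) / (4 * mu_site_per_My * 1e-6 * g_yr)
}

#' Compile a parameter draw into an executable demography
#'
#' Turns a sampled `parameter_draw` into the time-ordered event list the
#' coalescent simulator executes: for each non-root deme a backward-time
#' merge (split) into its source at the sampled colonization time, a
#' founder-effect bottleneck at that time (the new deme starts at
#' `founder_frac` times the source's size at colonization) followed by
#' deterministic exponential growth reaching the present size at time 0,
#' and, for the surfing-syngameon scenarios, migration epochs active only
#' inside the migration window. All times are converted from years to
#' generations with the drawn generation time.
#'
#' @param scenario One of [scenarios()]; must match the draw.
#' @param draw A [draw_parameters()] result.
#' @return An object of class `demography`: deme table (present size,
#'   backward growth rate, split time and parent), migration epochs
#'   (backward convention), haploid sample sizes, and a display-ready
#'   `events` tibble sorted by time.
#' @export
#' @examples
#' d <- draw_parameters("SSH", prior_set(), seed = 1)
#' compile_demography("SSH", d)
compile_demography <- function(scenario, draw) {
  scenario <- match.arg(scenario, scenarios())
  stopifnot(inherits(draw, "parameter_draw"))
  if (!identical(scenario, draw$scenario))
    abort(paste0("draw was made for scenario ", draw$scenario,
                 ", not ", scenario))
  topo <- scenario_topology(scenario)
  g <- draw$g_yr
  demes <- names(draw$theta)

  tab <- tibble::tibble(
    name = demes,
    N = unname(draw$Ne[demes]),
    parent = ifelse(demes == topo$root, NA_character_,
                    unname(topo$parents[demes])),
    t_split_gen = ifelse(demes == topo$root, NA_real_,
                         unname(draw$split_times_yr[demes]) / g),
    r = 0, N_founder = NA_real_
  )

  # deme size backward in time: N(t) = N * exp(-r t) while t <= t_split
  size_at <- function(tbl, deme, t) {
    i <- match(deme, tbl$name)
    tbl$N[i] * exp(-tbl$r[i] * t)
  }
  # parents before children so source sizes at colonization are final
  ord <- order(tab$t_split_gen, decreasing = TRUE, na.last = FALSE)
  for (i in ord) {
    if (is.na(tab$parent[i])) next
    ts <- tab$t_split_gen[i]
    n_src <- size_at(tab, tab$parent[i], ts)
    n0 <- max(2, draw$founder_frac[tab$name[i]] * n_src)
    tab$N_founder[i] <- n0
    tab$r[i] <- if (ts > 0) log(tab$N[i] / n0) / ts else 0
  }

  mig <- draw$migration
  if (nrow(mig) > 0) {
    # backward convention: lineages in `dest` jump to `source`
    mig <- tibble::tibble(
      dest = mig$to, source = mig$from, M = mig$rate,
      t_on_gen = mig$t_on_yr / g, t_off_gen = mig$t_off_yr / g
    )
    # an epoch exists only while both demes exist
    lim <- function(d) {
      t <- tab$t_split_gen[match(d, tab$name)]
      ifelse(is.na(t), Inf, t)
    }
    mig$t_off_gen <- pmin(mig$t_off_gen, lim(mig$dest), lim(mig$source))
    mig <- mig[mig$t_off_gen > mig$t_on_gen & mig$M > 0, , drop = FALSE]
  } else {
    mig <- tibble::tibble(dest = character(), source = character(),
                          M = numeric(), t_on_gen = numeric(),
                          t_off_gen = numeric())
  }

  samples <- setNames(rep(0L, length(demes)), demes)
  samples[draw$populations$name] <- 2L * draw$populations$n_diploid

  ev <- dplyr::bind_rows(
    tibble::tibble(
      time_gen = tab$t_split_gen[!is.na(tab$parent)],
      kind = "split+bottleneck",
      detail = sprintf("%s -> %s (founder N = %.1f)",
                       tab$name[!is.na(tab$parent)],
                       tab$parent[!is.na(tab$parent)],
                       tab$N_founder[!is.na(tab$parent)])
    ),
    if (nrow(mig) > 0) tibble::tibble(
      time_gen = mig$t_on_gen, kind = "migration-on",
      detail = sprintf("%s <- %s (backward), %.2f migrants/gen",
                       mig$source, mig$dest, mig$M)),
    if (nrow(mig) > 0) tibble::tibble(
      time_gen = mig$t_off_gen, kind = "migration-off",
      detail = sprintf("%s <- %s (backward)", mig$source, mig$dest))
  )
  ev <- ev[order(ev$time_gen), , drop = FALSE]

  structure(list(
    scenario = scenario, g_yr = g, demes = tab, migration = mig,
    samples = samples, events = ev, draw = draw
  ), class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  cat("<demography>", x$scenario, "|", sum(x$samples) / 2,
      "diploids in", sum(x$samples > 0), "demes\n")
  cat(sprintf("  generation time %.2f yr; root deme %s\n", x$g_yr,
              x$demes$name[is.na(x$demes$parent)]))
  print(as.data.frame(x$events), row.names = FALSE)
  invisible(x)
}
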