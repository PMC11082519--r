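dem_to_args <- function(dem) {
  tab <- dem$demes
  idx <- function(nm) match(nm, tab$name) - 1L
  list(
    N = tab$N, r = tab$r,
    t_split = tab$t_split_gen,
    parent = ifelse(is.na(tab$parent), -1L, idx(tab$parent)),
    samples = as.integer(unname(dem$samples[tab$name])),
    m_dest = as.integer(idx(dem$migration$dest)),
    m_src = as.integer(idx(dem$migration$source)),
    m_M = dem$migration$M,
    m_on = dem$migration$t_on_gen, m_off = dem$migration$t_off_gen
  )
}

default_ceiling <- function(dem) {
  n_root <- max(dem$demes$N[is.na(dem$demes$parent)])
  1e4 * 4 * n_root
}

#' Simulate one gene genealogy under a compiled demography
#'
#' Draws a single coalescent tree over all sampled haplotypes: within-deme
#' pairs coalesce at rate \eqn{1/(2N_d(t))} per pair per generation with
#' exponential size change handled by exact time rescaling, migration moves
#' single lineages between demes inside the migration window, and splits
#' transfer all lineages of a deme to its source.
#'
#' @param realization A [compile_demography()] result.
#' @param seed Optional integer seed.
#' @param ceiling Time ceiling in generations after which a non-coalescing
#'   configuration raises an error; defaults to \eqn{10^4 \times 4
#'   N_{root}}.
#' @return A `genealogy`: list with `parent` (1-based, 0 = root), `time_gen`
#'   node times, `leaf_population` labels, and `n_leaves`.
#' @export
#' @examples
#' dem <- compile_demography("SSH", draw_parameters("SSH", seed = 1))
#' g <- simulate_genealogy(dem, seed = 2)
#' max(g$time_gen) # TMRCA in generations
simulate_genealogy <- function(realization, seed = NULL, ceiling = NULL) {
  stopifnot(inherits(realization, "demography"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ceiling)) ceiling <- default_ceiling(realization)
  a <- dem_to_args(realization)
  tr <- sim_genealogies_cpp(a$N, a$r, a$t_split, a$parent, a$samples,
                            a$m_dest, a$m_src, a$m_M, a$m_on, a$m_off,
                            1L, ceiling)[[1]]
  structure(list(
    parent = tr$parent + 1L, # 1-based; root gets 0
    time_gen = tr$time,
    leaf_population = realization$demes$name[tr$leaf_deme + 1L],
    n_leaves = tr$n_leaves
  ), class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("<genealogy>", x$n_leaves, "leaves, TMRCA",
      format(max(x$time_gen), digits = 4), "generations\n")
  invisible(x)
}

#' Place a single mutation on a genealogy
#'
#' Chooses one branch with probability proportional to its length and
#' returns the biallelic column it induces: leaves below the mutation carry
#' the derived allele 1, all others 0. The column is segregating by
#' construction.
#'
#' @param tree A [simulate_genealogy()] result.
#' @param seed Optional integer seed.
#' @return Integer vector of 0/1 alleles, one per leaf.
#' @export
drop_mutation <- function(tree, seed = NULL) {
  stopifnot(inherits(tree, "genealogy"))
  if (!is.null(seed)) set.seed(seed)
  if (sum(tree$time_gen[tree$parent[tree$parent > 0]]) <= 0 &&
      max(tree$time_gen) <= 0)
    abort("degenerate genealogy: zero total branch length")
  drop_mutation_cpp(tree$parent - 1L, tree$time_gen, tree$n_leaves)
}

#' Simulate a matrix of unlinked SNPs
#'
#' Stacks `n_snps` independent (genealogy, mutation) draws into a phased
#' haplotype matrix: each SNP has its own coalescent tree and carries
#' exactly one mutation, so every row is segregating and the mutation rate
#' plays no role in genealogy shape. Columns are haplotypes in the fixed
#' population order of the demography (two consecutive columns per diploid
#' individual).
#'
#' Each genealogy receives SNPs in proportion to its total branch length
#' (`mutation_model = "length_weighted"`, the default), which is the
#' small-rate limit of infinite-sites mutation conditioned on segregation
#' and reproduces the pooled neutral site-frequency spectrum
#' \eqn{\propto 1/i}. `mutation_model = "fixed_s"` instead places exactly
#' one mutation on every simulated genealogy (the `ms -s 1` convention),
#' which slightly over-represents rare variants.
#'
#' @inheritParams simulate_genealogy
#' @param n_snps Number of unlinked SNPs (rows).
#' @param mutation_model `"length_weighted"` (default) or `"fixed_s"`; see
#'   Details.
#' @return A `hap_matrix`: integer matrix `n_snps` x haplotypes with values
#'   0/1, with a `pop_partition` attribute (tibble of population column
#'   ranges).
#' @export
#' @examples
#' dem <- compile_demography("SSH", draw_parameters("SSH", seed = 1))
#' m <- simulate_snp_matrix(dem, n_snps = 10, seed = 2)
#' dim(m)
simulate_snp_matrix <- function(realization, n_snps, seed = NULL,
                                ceiling = NULL,
                                mutation_model = c("length_weighted",
                                                   "fixed_s")) {
  stopifnot(inherits(realization, "demography"), n_snps > 0)
  mutation_model <- match.arg(mutation_model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ceiling)) ceiling <- default_ceiling(realization)
  a <- dem_to_args(realization)
  m <- sim_snp_matrix_cpp(a$N, a$r, a$t_split, a$parent, a$samples,
                          a$m_dest, a$m_src, a$m_M, a$m_on, a$m_off,
                          as.integer(n_snps), ceiling,
                          if (mutation_model == "fixed_s") 1L else 0L)
  pops <- realization$demes$name[a$samples > 0]
  sizes <- a$samples[a$samples > 0]
  hap_matrix(m, pops, sizes)
}

#' Construct a phased haplotype matrix
#'
#' @param m Integer matrix, loci x haplotype columns, values 0/1 (or NA for
#'   missing).
#' @param populations Population labels, in column-block order.
#' @param n_haplotypes Haplotype count per population (must sum to
#'   `ncol(m)`).
#' @return A `hap_matrix` with a `pop_partition` attribute.
#' @export
hap_matrix <- function(m, populations, n_haplotypes) {
  stopifnot(is.matrix(m), sum(n_haplotypes) == ncol(m),
            length(populations) == length(n_haplotypes))
  ends <- cumsum(n_haplotypes)
  part <- tibble::tibble(
    population = populations,
    from = c(1L, utils::head(ends, -1) + 1L),
    to = as.integer(ends)
  )
  structure(m, pop_partition = part, class = c("hap_matrix", class(m)))
}

#' @export
print.hap_matrix <- function(x, ...) {
  part <- attr(x, "pop_partition")
  cat("<hap_matrix>", nrow(x), "SNPs x", ncol(x), "haplotypes;",
      sum(is.na(x)) / length(x) * 100, "% missing\n")
  cat("  populations:",
      paste0(part$population, "(", part$to - part$from + 1, ")",
             collapse = " "), "\n")
  invisible(x)
}

#' Population partition of a haplotype matrix
#'
#' @param m A `hap_matrix`.
#' @return Tibble with `population`, `from`, `to` column ranges.
#' @export
pop_partition <- function(m) attr(m, "pop_partition")

#' Build a demography directly from deme tables
#'
#' Low-level constructor used for small, hand-specified demographies
#' (single demes, island pairs) in validation work; the scenario
#' generators use [compile_demography()] instead. Sizes follow the
#' backward-time convention \eqn{N_d(t) = N_d e^{-r_d t}}.
#'
#' @param N Present diploid sizes, one per deme.
#' @param samples Haploid sample sizes per deme.
#' @param r Backward exponential rates (0 = constant size).
#' @param t_split Split times in generations (NA for the root).
#' @param parent Parent deme names (NA for the root).
#' @param names Deme names.
#' @param migration Tibble with `dest`, `source`, `M`, `t_on_gen`,
#'   `t_off_gen` (backward convention: lineages in `dest` move to
#'   `source` at rate `M / N_dest(t)`).
#' @param g_yr Generation time in years (bookkeeping only).
#' @return A `demography` object.
#' @export
#' @examples
#' dem <- custom_demography(N = 1000, samples = 2)
#' g <- simulate_genealogy(dem, seed = 1)
custom_demography <- function(N, samples, r = rep(0, length(N)),
                              t_split = rep(NA_real_, length(N)),
                              parent = rep(NA_character_, length(N)),
                              names = paste0("D", seq_along(N)),
                              migration = NULL, g_yr = 5.5) {
  tab <- tibble::tibble(name = names, N = N, parent = parent,
                        t_split_gen = t_split, r = r,
                        N_founder = NA_real_)
  if (is.null(migration))
    migration <- tibble::tibble(dest = character(), source = character(),
                                M = numeric(), t_on_gen = numeric(),
                                t_off_gen = numeric())
  structure(list(
    scenario = "custom", g_yr = g_yr, demes = tab, migration = migration,
    samples = stats::setNames(as.integer(samples), names),
    events = tibble::tibble(time_gen = numeric(), kind = character(),
                            detail = character()),
    draw = NULL
  ), class = "demography")
}
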