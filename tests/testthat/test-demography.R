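test_that("default panel matches the sampling design", {
  pops <- default_populations()
  expect_equal(sum(pops$n_diploid), 116)
  expect_equal(nrow(pops), 8)
  expect_false(any(duplicated(pops$name)))
  expect_equal(pops$n_diploid[pops$name == "GO"], 29)
})

test_that("theta-to-Ne conversion is exact and linear", {
  expect_equal(theta_to_Ne(3.4, 1700, 0.001, 5), 1e5)
  # per-site theta equal to 4*mu_per_gen gives Ne = 1
  g <- 5
  theta <- 4 * 1700 * 0.001 * 1e-6 * g
  expect_equal(theta_to_Ne(theta, 1700, 0.001, g), 1)
  expect_equal(theta_to_Ne(6.8, 1700, 0.001, 5),
               2 * theta_to_Ne(3.4, 1700, 0.001, 5))
  expect_error(theta_to_Ne(-1, 1700, 0.001, 5), "positive")
})

test_that("point-mass priors give a deterministic draw", {
  pr <- prior_set(t_root_mean = 2e6, t_root_ci95 = c(2e6, 2e6),
                  theta_lzfu = c(1, 1), theta_ratio = c(1, 1),
                  gen_time = c(5, 5), founder_frac = c(0.05, 0.05),
                  mig_rate = c(0, 0))
  d <- draw_parameters("SSH", pr, seed = 1)
  expect_equal(d$t_root_yr, 2e6)
  expect_equal(unname(d$theta), rep(1, 8))
  expect_equal(d$g_yr, 5)
  expect_equal(unname(d$founder_frac), rep(0.05, 7))
  expect_equal(theta_to_Ne(1, 1700, 0.001, 5), unname(d$Ne[["LZFU"]]))
})

test_that("crown age prior respects its bounds and split times are ordered", {
  set.seed(42)
  for (sc in scenarios()) {
    for (i in 1:100) {
      d <- draw_parameters(sc, prior_set())
      expect_gte(d$t_root_yr, 0.92e6)
      expect_lte(d$t_root_yr, 3.38e6)
      # every child splits strictly more recently than its parent
      topo_parents <- switch(sc,
        SSH = c(GC = "LZFU", eTEN = "GC", wTEN = "eTEN", GO = "wTEN",
                LP = "GO", HI = "LP"),
        SSH_BC = c(GC = "LZFU", eTEN = "GC", wTEN = "eTEN", GO = "wTEN",
                   LP = "GO", HI = "LP", NWA = "LZFU"),
        CIH = c(LZFU = "GC", GO = "wTEN", LP = "GO", HI = "LP",
                NWA = "LZFU"))
      for (child in names(topo_parents)) {
        expect_lt(d$split_times_yr[[child]],
                  d$split_times_yr[[topo_parents[child]]])
      }
      if (!is.na(d$t_bc_yr)) expect_lte(d$t_bc_yr, 1.25e6)
    }
  }
})

test_that("generation-time draws have the Uniform(5,6) mean", {
  set.seed(7)
  g <- replicate(10000, draw_parameters("SSH", prior_set())$g_yr)
  expect_lt(abs(mean(g) - 5.5), 0.02)
})

test_that("compiled SSH has the full event complement", {
  d <- draw_parameters("SSH", prior_set(), seed = 3)
  dem <- compile_demography("SSH", d)
  ev <- dem$events
  expect_equal(sum(ev$kind == "split+bottleneck"), 7)
  expect_equal(sum(ev$kind == "migration-on"), 3)
  expect_equal(sum(ev$kind == "migration-off"), 3)
  expect_false(is.unsorted(ev$time_gen))
  # merge chain ends at the mainland root
  expect_equal(dem$demes$name[is.na(dem$demes$parent)], "NWA")
})

test_that("CIH places the mainland as a recent LZFU offshoot", {
  d <- draw_parameters("CIH", prior_set(), seed = 4)
  dem <- compile_demography("CIH", d)
  expect_equal(dem$demes$parent[dem$demes$name == "NWA"], "LZFU")
  expect_equal(dem$demes$name[is.na(dem$demes$parent)], "eTEN")
  expect_equal(nrow(dem$migration), 0)
})

test_that("SSH_BC roots in an unsampled continental deme", {
  d <- draw_parameters("SSH_BC", prior_set(), seed = 5)
  dem <- compile_demography("SSH_BC", d)
  expect_equal(dem$demes$name[is.na(dem$demes$parent)], "ANC")
  expect_equal(unname(dem$samples["ANC"]), 0L)
  expect_equal(dem$demes$parent[dem$demes$name == "NWA"], "LZFU")
  expect_lt(d$t_bc_yr, d$t_root_yr)
})

test_that("no bottleneck and equal sizes give zero growth", {
  pr <- prior_set(theta_lzfu = c(2, 2), theta_ratio = c(1, 1),
                  founder_frac = c(1, 1), gen_time = c(5.5, 5.5))
  d <- draw_parameters("SSH", pr, seed = 6)
  dem <- compile_demography("SSH", d)
  expect_equal(dem$demes$r, rep(0, 8), tolerance = 1e-12)
  expect_equal(length(unique(round(dem$demes$N, 6))), 1)
})

test_that("growth rates solve the founder boundary condition exactly", {
  set.seed(8)
  for (sc in scenarios()) {
    d <- draw_parameters(sc, prior_set())
    dem <- compile_demography(sc, d)
    tab <- dem$demes
    for (i in seq_len(nrow(tab))) {
      if (is.na(tab$parent[i])) next
      n_at_split <- tab$N[i] * exp(-tab$r[i] * tab$t_split_gen[i])
      expect_equal(n_at_split, tab$N_founder[i], tolerance = 1e-9)
    }
  }
})

test_that("every deme reaches the root through the split chain", {
  set.seed(9)
  for (sc in scenarios()) {
    dem <- compile_demography(sc, draw_parameters(sc, prior_set()))
    tab <- dem$demes
    root <- tab$name[is.na(tab$parent)]
    for (nm in tab$name) {
      cur <- nm
      for (hop in 1:20) {
        if (cur == root) break
        cur <- tab$parent[match(cur, tab$name)]
      }
      expect_equal(cur, root)
    }
  }
})

test_that("migration epochs never leave the stated window", {
  set.seed(10)
  for (i in 1:200) {
    sc <- sample(c("SSH", "SSH_BC"), 1)
    d <- draw_parameters(sc, prior_set())
    dem <- compile_demography(sc, d)
    if (nrow(dem$migration) == 0) next
    expect_true(all(dem$migration$t_on_gen * d$g_yr >= 14000 - 1e-6))
    expect_true(all(dem$migration$t_off_gen * d$g_yr <= 1.25e6 + 1e-6))
  }
})

test_that("scenario mismatches and unknown labels are rejected", {
  d <- draw_parameters("SSH", prior_set(), seed = 11)
  expect_error(compile_demography("CIH", d), "scenario")
  expect_error(draw_parameters("XXX", prior_set()), "'arg'")
})
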