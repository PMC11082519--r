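# brute-force Tajima's D oracle: explicit pairwise differences and the
# textbook coefficients, kept independent of the packaged implementation
oracle_tajima <- function(aln) {
  n <- nrow(aln)
  seg <- which(apply(aln, 2, function(col) length(unique(col)) == 2))
  S <- length(seg)
  pi_pairwise <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      pi_pairwise <- pi_pairwise + sum(aln[i, seg] != aln[j, seg])
  pi_pairwise <- pi_pairwise / choose(n, 2)
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  list(D = (pi_pairwise - S / a1) / sqrt(e1 * S + e2 * S * (S - 1)),
       pi = pi_pairwise, S = S)
}

# hand-built star genealogy with k leaves at depth h
star_genealogy <- function(k, h = 1) {
  structure(list(
    parent = c(rep(k + 1L, k), 0L),
    time_gen = c(rep(0, k), h),
    leaf_population = rep("D1", k),
    n_leaves = k
  ), class = "genealogy")
}

# python interpreter for the msprime cross-check oracle
find_python <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  p
}

# run msprime with matched parameters and return the pooled SFS of
# unlinked segregating sites (counts for derived allele count 1..n-1)
msprime_sfs <- function(spec_json, n_hap, seed, min_snps = 15000) {
  py <- find_python()
  script <- sprintf('
import json, msprime, sys
spec = json.loads(sys.argv[1])
seed = int(sys.argv[2]); min_snps = int(sys.argv[3]); n = int(sys.argv[4])
dem = msprime.Demography()
for p in spec["pops"]:
    dem.add_population(name=p["name"], initial_size=p["N"],
                       growth_rate=p.get("growth", 0.0))
for s in spec.get("splits", []):
    # msprime keeps split ancestors inactive before the split time, so
    # the ancestral deme must be distinct from every sampled deme
    dem.add_population_split(time=s["time"], derived=s["derived"],
                             ancestral=s["ancestral"])
if "migration" in spec:
    # backward convention on both sides: lineages in "dest" jump to
    # "source" (msprime set_migration_rate source/dest are the
    # backward-in-time movement of lineages)
    for m in spec["migration"]:
        dem.set_migration_rate(source=m["dest"], dest=m["source"],
                               rate=m["rate"])
dem.sort_events()
samples = {p["name"]: p["n"] // 2 for p in spec["pops"] if p["n"] > 0}
counts = [0] * (n - 1)
total = 0
rep_seed = seed
while total < min_snps:
    rep_seed += 1
    ts = msprime.sim_ancestry(samples=samples, demography=dem, ploidy=2,
                              sequence_length=1, discrete_genome=False,
                              random_seed=rep_seed)
    mts = msprime.sim_mutations(ts, rate=spec["mu"], random_seed=rep_seed,
                                discrete_genome=False)
    for var in mts.variants():
        c = int(sum(var.genotypes))
        if 0 < c < n:
            counts[c - 1] += 1
            total += 1
print(" ".join(str(c) for c in counts))
')
  out <- system2(py, c("-c", shQuote(script), shQuote(spec_json), seed,
                       min_snps, n_hap), stdout = TRUE)
  as.numeric(strsplit(out[length(out)], " ")[[1]])
}
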