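# coalcnn

Simulation-based phylogeographic model selection for island colonization
histories, packaged as a reusable R pipeline.

## The problem

Oceanic archipelagos can be colonized along very different routes, and
distinguishing them from standing genetic variation is hard because the
competing histories differ in subtle, high-dimensional ways. `coalcnn`
implements a likelihood-free analysis for a Canary Island plant lineage
sampled in eight populations (116 diploid individuals, 232 phased
haplotypes): six island demes, the pooled Lanzarote–Fuerteventura deme
(`LZFU`), and the north-west African mainland (`NWA`). Three colonization
scenarios are compared:

* **CIH** — central island hub: Tenerife first (split into eastern and
  western halves), spreading east (`GC`, `LZFU`) and west (`GO`, `LP`,
  `HI`), the mainland population a recent offshoot of `LZFU`;
* **SSH** — surfing syngameon: east-to-west stepping stones from the
  mainland, with later central-to-eastern migration;
* **SSH_BC** — SSH plus a recent back-colonization of the mainland from
  `LZFU`.

## The method

1. **Structured coalescent simulation.** Each scenario compiles to a
   backward-time event list: colonization splits, a founder-effect
   bottleneck at every colonization (`f ~ U(0, 0.05)` of the source size,
   followed by exponential recovery to the present size), and migration
   (`U(0, 10)` migrants/generation) active only inside a 14 kyr–1.25 Myr
   window. Priors: crown age normal 2.09 Ma truncated to (0.92, 3.38) Ma;
   per-locus `theta(LZFU) ~ U(1, 5)` with other demes a `U(0.2, 2)` ratio
   of it, converted through `theta = 4 Ne mu`; generation time
   `U(5, 6)` yr. Unlinked SNPs are simulated one genealogy per SNP,
   weighted by total branch length so the pooled site-frequency spectrum
   matches neutral theory.
2. **Image encoding.** Matrices are recoded to major/minor alleles
   (rows = loci, columns = haplotypes), 4.4% missing entries injected to
   mirror the empirical matrix, 25% of simulations held out for
   validation.
3. **Convolutional classifier.** Three 1-D convolutions (125/250/250
   filters, kernel 3, no bias) with batch normalization and ReLU, one
   max-pooling step, two dense layers (125 units, 50% dropout), softmax
   over the three scenarios; SGD (lr 0.01, momentum 0.9), minibatch 500,
   model checkpoint and early stopping on validation accuracy; implemented
   in single-threaded RcppArmadillo, fully reproducible under a seed.
4. **Temperature scaling.** A scalar `T` fitted on the validation set
   recalibrates the softmax without changing any predicted class.
5. **ABC rejection.** The averaged calibrated probability vector of the
   observed matrix is the summary statistic; the 5% nearest test-set
   simulations give the model posterior, and a rejection step within the
   preferred scenario gives parameter posteriors. Cross-validation uses
   ten pseudo-observed simulations per scenario with self-exclusion.

Raw sequencing data are not shipped, so a **pseudo-empirical
generator** stands in for a real matrix: it simulates a dataset at the
empirical dimensions (2305 SNPs x 232 haplotypes, 4.4% missing) under a
known scenario so end-to-end recovery can be verified. The package also
implements the SNP post-filters (missing-data > 35% removal, ≤ 25-position
proximity thinning) and per-population diversity statistics (Ho, He,
rarefied allelic richness, Shannon diversity, Watterson's theta,
Tajima's D).

## Worked example

```r
library(coalcnn)

# one simulated dataset under the surfing-syngameon scenario
draw <- draw_parameters("SSH", prior_set(), seed = 1)
dem  <- compile_demography("SSH", draw)
m    <- simulate_snp_matrix(dem, n_snps = 250, seed = 2)
m
#> <hap_matrix> 250 SNPs x 232 haplotypes; 0 % missing
#>   populations: NWA(30) LZFU(30) GC(38) eTEN(42) wTEN(14) GO(58) LP(10) HI(10)

# full desk-scale analysis: simulate, train, calibrate, predict, ABC
report <- run_full_analysis(
  analysis_config(n_train = 1500, n_test = 600, n_snps = 250,
                  max_epochs = 10L, patience_epochs = 10L),
  seed = 1)
report
```

A desk-scale run (about a quarter of an hour on one CPU) prints a report
like:

```
<run_report> seed 1 (17.3 min)

Test-set confusion (rows = simulated truth):
  truth     CIH   SSH  SSH_BC
    CIH 0.99833 0.000 0.00167
    SSH 0.00333 0.922 0.07500
 SSH_BC 0.02000 0.133 0.84667

Averaged classifier summary of the observed matrix:
   CIH    SSH SSH_BC
 0.001  0.935  0.064

ABC model posterior (tolerance 0.05 ):
 scenario posterior
      CIH       0.0
      SSH       0.9
   SSH_BC       0.1

Preferred model: SSH | truth: SSH_BC
```

Read it as: the trained network separates the central-island-hub history
almost perfectly and distinguishes the two surfing-syngameon variants in
roughly nine cases out of ten — they differ only in the origin of the 30
mainland haplotype columns, and a draw whose back-colonization time sits
near the old end of its prior (here 1.23 Ma) is intrinsically SSH-like,
which is exactly what happened to this particular pseudo-empirical draw.
Most draws are recovered as SSH_BC with high posterior support (the test
suite checks the recovery rate over several pseudo-observed datasets).
`tidy()`, `glance()` and `autoplot()` methods expose the training
history, the report summary and the confusion heat map.

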