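---
title: "Simulation-based selection of island colonization scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation-based selection of island colonization scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The inference problem

`coalcnn` asks which of three colonization histories best explains a phased
biallelic SNP matrix sampled from eight populations of a Canary Island
plant lineage (six island demes, the pooled Lanzarote–Fuerteventura deme
`LZFU`, and the north-west African mainland `NWA`; 116 diploid individuals
in total):

* **CIH** (central island hub): Tenerife is colonized first and splits
  into eastern and western halves; the eastern half seeds Gran Canaria and
  then `LZFU`, the western half seeds La Gomera, La Palma and El Hierro;
  the mainland population is a recent offshoot of `LZFU`.
* **SSH** (surfing syngameon): east-to-west stepping-stone colonization
  starting from the mainland
  (`NWA -> LZFU -> GC -> eTEN -> wTEN -> GO -> LP -> HI`), with later
  migration from the central islands back to the eastern islands.
* **SSH_BC**: as SSH, but the *sampled* mainland population derives from a
  recent back-colonization out of `LZFU`, while the ancestral continental
  deme remains unsampled.

Because the likelihood of a SNP matrix under these structured-coalescent
models is intractable, the package follows a simulation-based route:
simulate labeled datasets under each scenario, train a convolutional
network to discriminate them, and treat the network's class-probability
vector as a low-dimensional summary statistic for approximate Bayesian
computation (ABC).

## The demographic model and its priors

Each simulated dataset draws one parameter vector from the priors:

| parameter | prior | units |
|---|---|---|
| crown age (initial divergence) | Normal(2.09 Ma) truncated to (0.92, 3.38) Ma | years |
| per-locus theta of `LZFU` | Uniform(1, 5) | – |
| theta ratio of every other deme | Uniform(0.2, 2) x theta(LZFU) | – |
| generation time | Uniform(5, 6) | years |
| founder fraction at each colonization | Uniform(0, 0.05) | – |
| migration rate per active edge | Uniform(0, 10) | migrants/generation |
| migration window | fixed (14 kyr, 1.25 Myr) before present | years |
| mutation rate | fixed 0.001 | /site/My |
| locus length | fixed 1700 | sites |

Theta converts to a diploid effective size through `theta = 4 Ne mu` at
the per-site scale: `Ne = (theta/1700) / (4 x 0.001e-6 x g)`, giving
sizes of order 1e5. Every colonization event bottlenecks the new deme to
`founder_frac` times its source's size at that moment, followed by
deterministic exponential recovery that reaches the present size at time
zero (the backward-time size is `N(t) = N e^{-rt}` with `r` solved from
the boundary condition; founder sizes are floored at 2 diploids so a
founder fraction of exactly zero stays simulable). Migration, present
only in the SSH scenarios, runs on three forward-time edges
(`eTEN -> LZFU`, `GC -> LZFU`, `eTEN -> GC`) and only inside the
migration window, clipped to the lifetime of both demes.

Where the colonization chain fixes only an ordering, interior split times
are drawn sequentially, each uniform between zero and its parent's split
time — the least-informative choice consistent with the chain. The
back-colonization time is uniform over the migration window truncated
below the source deme's split time (in CIH the source's split can be very
recent, so the lower bound is relaxed to half the upper bound when the
window floor is unreachable). The unsampled continental root of `SSH_BC`
receives its own theta-ratio draw. In CIH the initial east/west division
of Tenerife is treated like every other split, founder effect included;
it is an island-internal division rather than a new colonization, but a
uniform rule keeps the three scenario generators structurally identical.

## The coalescent simulator

SNPs are unlinked: each one has its own genealogy, simulated backward in
time with per-pair within-deme coalescence rate `1/(2 N_d(t))`,
per-lineage migration rate `M / N_d(t)` on active edges, and splits that
move all lineages of a deme into its source. Exponential size change is
handled exactly by inverting the integrated rate (no time discretization),
and candidate event times are cached between events, which is valid
because the competing processes are independent Poisson processes.

A site enters a SNP panel only if it segregates, and the probability that
a locus yields a segregating site is proportional to the total branch
length of its genealogy (in the small-mutation-rate limit of the
infinite-sites model). The default mutation model therefore samples
genealogies *weighted by total branch length* — implemented by simulating
one genealogy per requested SNP and then allocating the SNPs across
genealogies by systematic resampling proportional to length, each SNP
receiving one uniformly placed mutation. This reproduces the pooled
neutral site-frequency spectrum (proportional to `1/i`), matches what
standard simulators produce under Poisson mutation, and is how SNPs
ascertained from sequenced loci actually arise. The strict
one-tree-one-mutation convention of `ms -s 1` is retained as
`mutation_model = "fixed_s"`; it over-represents rare variants (it draws
the frequency spectrum `E[L_i/L]` rather than `E[L_i]/E[L]`), measurably
so at 50 000 SNPs, which is why it is not the default. Systematic (rather
than multinomial) resampling adds the least extra noise; rows are
shuffled afterwards so SNPs sharing a genealogy are not adjacent.

Non-coalescing configurations (e.g. two demes with no migration and no
split) abort with an error at a time ceiling of `1e4 x 4 N_root`
generations.

## Image encoding

A simulated matrix becomes a classifier input by recoding each row to
major (0) / minor (1) allele — ties left unchanged, monomorphic rows
all-0 — and then masking each entry independently with probability 0.044,
the missing-genotype rate of the empirical matrix, encoded as −1 inside
the network. Images are loci x haplotypes, columns in the fixed
population order `NWA, LZFU, GC, eTEN, wTEN, GO, LP, HI` with no
within-population sorting. Batches shuffle image order and hold out 25%
for validation. Empirical (or pseudo-empirical) matrices are not
re-masked — they already carry their own missingness — and are fed to the
trained network as repeated random subsamples of `n_snps` rows whose
predictions are averaged.

## The classifier

Three 1-D convolutions along the locus axis (samples are the input
channels; 125, 250, 250 filters of width 3, no bias), each followed by
batch normalization and ReLU; one max-pooling step (window 2) after the
convolutional stack; two dense layers of 125 units with 50% dropout;
softmax over the three scenarios. Training is plain SGD (learning rate
0.01, momentum 0.9) on categorical cross-entropy in minibatches of 500,
with a model checkpoint keeping the best-validation-accuracy weights and
early stopping. Batch-normalization statistics are frozen at inference;
convolution precedes normalization which precedes the nonlinearity. The
implementation is single-precision, single-threaded C++ driven entirely
by R's RNG, so a fixed seed reproduces training bit for bit.

After training, a single temperature `T` is fitted by minimizing the
validation negative log-likelihood of `softmax(logits / T)`; this
recalibrates confidence without ever changing a predicted class. The
calibrated probabilities — not the raw ones — are used both for the
test-set confusion matrix and as ABC summaries.

## The ABC step

The averaged calibrated probability vector of the observed matrix is the
summary statistic. Model choice retains the 5% of test-set simulations
nearest in (unweighted) Euclidean distance — the summaries already live on
a common [0, 1] scale — and reads the posterior off the retained label
frequencies; ties at the cutoff break by simulation index. Parameter
estimation repeats the rejection within the preferred scenario only and
reports medians and central 95% intervals of the retained draws, without
regression adjustment. Cross-validation holds out ten pseudo-observed
simulations per scenario, each assigned by the argmax of its posterior
computed with itself excluded from the reference table.

## Problem sizes and the desk-scale profile

The study-scale configuration (`study_profile()`) uses 10 000 training
and 10 000 test simulations per scenario of 1000 SNPs each, early
stopping with patience 150, and a 0.1% parameter-estimation tolerance.
Routine validation, the test suite and `scripts/acceptance.R` use the
desk-scale profile: 1500 training simulations per scenario of 250 SNPs,
a test/reference set of several hundred per scenario, a fixed ~10-epoch
training schedule (the validation-accuracy curve has flattened by then at
this data size; the checkpoint still protects against a late dip), and a 1%
parameter tolerance so that the retained count (10 by default short of
the study-scale 0.001 x 10 000) is comparable. Desk-scale discrimination
is necessarily somewhat below study scale — each image carries a quarter
of the SNPs and the network sees about a tenth of the training data — and
the gap concentrates entirely on the SSH/SSH_BC pair, which differ only
in the origin of the 30 mainland haplotype columns; CIH remains almost
perfectly separable at any scale, structurally matching the study-scale
confusion pattern.

The pseudo-empirical generator replaces the study's raw sequencing data:
it simulates one dataset at the empirical dimensions (2305 SNPs x 232
haplotypes, 4.4% missing) under a known scenario and parameter draw, so
end-to-end recovery can be verified. What passing recovery tests show is
that the pipeline identifies data generated *by its own model family*;
they cannot certify model adequacy for real data, which additionally
contains linkage within loci, non-uniform missingness, genotyping error
and reference bias that the generator does not emulate.

## Numerical choices and limitations

* Exact ties in major/minor recoding keep the original coding; ABC
  distance ties break by simulation index; both for determinism.
* The temperature search runs on `log T` over [0.01, 100] with
  `stats::optimize`.
* Systematic resampling guards against the rounding pathologies of
  multinomial SNP allocation; a final guard assigns any rounding
  remainder to the last genealogy.
* Missing data enter the network as a plain −1 channel value; no masking
  layer is used.
* The simulator conditions every row on segregation, so invariant sites
  and ascertainment of *which* loci get sequenced are outside the model.
* Selection, recombination within loci, and more than eight demes are out
  of scope.
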