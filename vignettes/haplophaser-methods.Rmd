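---
title: "Statistical haplotype phasing with haplophaser: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical haplotype phasing with haplophaser: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplophaser)
```

## The problem

A diploid genotype call at a biallelic site tells us how many copies of the
alternate allele an individual carries (0, 1 or 2) but not, at heterozygous
sites, which parental chromosome carries it. Phasing reconstructs the two
haplotypes `(h1, h2)` underlying each individual's genotype vector `G`.
`haplophaser` does population-scale statistical phasing: it exploits the
fact that haplotypes in a population are imperfect mosaics of each other,
so each individual's haplotypes can be modelled as copies of segments of
the other individuals' current haplotype estimates.

## The model

### Diploid Li–Stephens HMM on genotype graphs

Given a conditioning set of `K` haplotypes, a haplotype is modelled as a
hidden Markov chain that copies one of the `K` haplotypes at each site,
switching between them with probability driven by recombination and
emitting the observed allele with a small mutation error. The diploid chain
for a pair `(h1, h2)` is the product of two such chains.

Rather than running the chain site by site over all `2^(h-1)` possible
haplotype pairs of an individual with `h` hets, the possible pairs are held
in a *genotype graph*: consecutive ambiguous sites (hets, plus missing
genotypes) are grouped into segments, each holding the short list of
locally admissible allele configurations (at most `2^3 = 8` in a fresh
segment). Any path through the graph (one configuration per segment)
reconstructs a genotype-consistent pair. The HMM state at segment `s` is
`(c, k1, k2)`: the local configuration plus the haplotype copied by each
chain.

* Transitions between consecutive segments use the classic stay/switch
  kernel: with `rho = 4 Ne g / (100 N_hap)` for `g` centimorgans between
  the last site of one segment and the first of the next,
  `stay = exp(-rho/K) + (1 - exp(-rho/K))/K` and each of the other `K - 1`
  haplotypes receives `(1 - exp(-rho/K))/K`. `transition_probs()` exposes
  the closed form.
* Emissions use the Li–Stephens mutation parameter
  `theta = 1 / sum_{k=1}^{K-1} 1/k`: a copied allele matches the target
  allele with probability `K/(K+theta) + theta/(2(K+theta))` and mismatches
  with `theta/(2(K+theta))` (`emission_prob()`).
* A scaled forward pass, a backward pass for posterior tables over
  configuration pairs at each segment boundary, and a stochastic traceback
  are implemented in C++ (`forward_backward()`, `sample_pair()`).

Internally the forward quantity factorizes as
`alpha_s(c, k1, k2) = S_s(k1, k2) * E1_s(c, k1) * E2_s(c, k2)` with `S_s`
the transition-propagated mass entering segment `s`. `S_s` is shared by all
configurations except across boundaries carrying read-derived weights, so
one `K x K` matrix per segment replaces the `8 K x K` slices a dense
implementation would store. This is an exact reformulation (the test suite
checks boundary posteriors against full enumeration to 1e-9); it is what
makes default-sized runs take minutes rather than hours.

### PBWT selection of the conditioning set

The conditioning haplotypes are found with a positional Burrows–Wheeler
transform of all current haplotype estimates, rebuilt once per MCMC
iteration (`pbwt_build()`). The PBWT sorts haplotypes by reversed prefix at
each site, so haplotypes sharing a long match end up at adjacent ranks;
prefix/divergence/locator arrays are stored every 8 variants (configurable
stride `S`). For each individual, the `P` nearest neighbors of each of its
two haplotypes are read off at every stored site in the window
(`pbwt_neighbors()`; the walk extends towards the side with the longer
match, ties to the lower rank) and the union is collapsed into `K` distinct
haplotypes (`select_conditioning_set()`). `K` therefore adapts to the data:
long matches mean the same neighbors recur across stored sites and `K`
shrinks — the mechanism behind sub-linear scaling with sample size. The
collapse removes duplicated indices and also haplotypes whose sequences are
identical across the window, since a duplicate sequence adds nothing the
model can copy.

### MCMC scheme

Starting from a PBWT-guided initialization, the sampler iterates over all
individuals (in a seeded random order, windows processed left to right),
replacing each individual's haplotype pair with a draw from the posterior.
Three iteration types make up the schedule (default
`"5b,1p,1b,1p,1b,1p,5m"`, i.e. 15 iterations with 3 pruning stages):

* `b` (burn-in): sample only.
* `p` (pruning): sample, then merge disjoint adjacent segment pairs,
  keeping only configuration combinations whose posterior transition
  probability reaches `keep_threshold` (default 0.001; the top combination
  always survives). Merging lets longer-range read information become
  usable and concentrates later iterations on plausible configurations.
* `m` (main): sample and accumulate the boundary posterior tables. After
  the schedule, the tables are averaged and the final pair is the
  max-product path through them (`accumulate_and_solve()`). The averaged
  posterior of the solved transition into each segment, conditional on the
  previous segment's configuration, is reported per het as the PP phasing
  certainty — conditioning makes it invariant to the arbitrary global
  haplotype swap, under which the unconditional configuration marginals
  are symmetric and uninformative.

### Initialization

`pbwt_init_phase()` sweeps left to right maintaining a PBWT of the
partially phased matrix. At each site, homozygous alleles are fixed,
missing genotypes are drawn from the site allele frequency, and each
heterozygous haplotype copies the nearest neighbor in the previous site's
prefix array whose allele is already determined, walking towards the side
with the longer current match. If both haplotypes of a het receive the same
allele, the one with the shorter neighbor match is flipped. We chose the
divergence-guided walk over a plain alternating rank walk after measuring
both on the default synthetic panel (N = 200, L = 2000, 30 founders): the
alternating walk initializes at ~25% switch error, the divergence-guided
walk at ~10–12%, consistent with published figures for this style of
initializer. Haplotypes resolved earlier at the same site are usable copy
sources (the imputation is progressive).

### Constraints

* **Reference panel**: pre-phased haplotypes are appended to the PBWT and
  can be selected into conditioning sets, but are never updated. Only
  main-panel variants in the overlap with the reference are phased.
* **Haplotype scaffold**: pre-phased hets (e.g. from trios or a very large
  panel) are hard constraints — configurations contradicting a scaffold
  allele are pruned from the genotype graph before the first iteration, so
  no sampled or solved pair can ever contradict the scaffold.
* **Phase sets (reads)**: hets co-observed on sequencing reads arrive as
  VCF `PS` groups. Each consecutive pair of hets in a phase set multiplies
  the path weight by `1 - eps` when the pair's relative orientation agrees
  with the reads and `eps` otherwise (default `eps = 1e-4`). Pairs that
  span non-adjacent segments of the graph contribute nothing until pruning
  merges the segments. At `eps = 0.5` the weights cancel exactly and
  posteriors equal the no-reads posteriors. Scaffold constraints always
  take priority over reads: pruning happens first and reads can only
  reweight surviving configurations.
* **IBD2 protection**: two individuals sharing both haplotypes
  identical-by-descent (e.g. siblings) would otherwise copy each other and
  trap the sampler. A PBWT-style sweep over the tri-allelic genotype codes
  (missing matches anything) reports maximal genotype matches spanning at
  least `W` bp — capped at the chromosome span, since a simulated region
  shorter than one window could otherwise never trigger the screen — and
  every window fully covered by a match forbids the pair from conditioning
  on each other there.

### Windows and ligation

Phasing runs in sliding windows of `W = 2` Mb with 0.25 Mb overlap
(`make_windows()`); a chromosome shorter than `W` is a single window. After
the final solve, per-window haplotypes are stitched by majority vote over
the phase agreement of hets shared with the already-ligated left part; ties
keep the current orientation, and windows containing scaffold entries are
never flipped (the scaffold anchors absolute orientation). Each variant is
emitted exactly once, the second half of each overlap coming from the later
window. The stitching rule is this package's choice — sliding windows need
some ligation rule and the majority vote is the simplest one that cannot be
broken by a single mis-phased het.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `P` | 4 | PBWT neighbors per query; main speed/accuracy dial |
| `S` | 8 | variants between stored PBWT arrays |
| `W` | 2e6 bp | window size; also the IBD2 match threshold |
| `overlap` | 2.5e5 bp | window overlap used for ligation |
| `schedule` | `5b,1p,1b,1p,1b,1p,5m` | burn-in / pruning / main iterations |
| `eps` | 1e-4 | phase-set error rate, in (0, 0.5] |
| `Ne` | 15,000 | effective population size in the recombination rate |
| `keep_threshold` | 0.001 | pruning floor on posterior transition mass |

`Ne` and the Li–Stephens functional forms are configuration, not claims:
the method's behavior is robust to `Ne` within a factor of a few, and the
defaults follow the values commonly used by tools of this family.

## The synthetic world

`simulate_population()` draws `n_founders` founder haplotypes i.i.d. per
site (allele frequencies uniform on `[maf_min, 1 - maf_min]`) and builds
each sample haplotype as a founder mosaic with Poisson crossovers
(`recomb_per_bp`, default 1e-6 per bp, i.e. 1 Mb founder segments; sites
average 1.5 kb apart). This produces exactly the long shared haplotype
stretches the PBWT and the copying model exploit, with known truth for
switch-error evaluation, planted trios (`simulate_trios()`), read-derived
phase sets with controllable coverage and error (`simulate_phase_sets()`)
and sparse scaffolds (`simulate_scaffold()`).

What it does *not* emulate: realistic allele-frequency spectra and rare
variants, LD decay from a true coalescent ancestry, genotyping error,
population structure, or realistic genetic-map variation (the simulated map
is flat at 1 cM/Mb). A green recovery test therefore establishes that the
machinery — selection, sampling, pruning, ligation, constraints — works and
converges on data with mosaic structure; it does not reproduce any
published error rate on real cohorts, which depend on those unmodelled
features and on sample sizes far beyond desk scale.

One limitation matters for scaling experiments specifically: because every
haplotype is a mosaic of a *fixed* founder pool, the longest match any
target can find is capped by the founder-segment length. Once each founder
has many carriers, adding samples no longer lengthens the best match — it
only enlarges the pool of equally long (tied) matches. The conditioning-set
size `K` therefore shrinks sharply while panels are below this saturation
point and then plateaus (or drifts up by a couple of haplotypes as tied
neighbors rotate across stored sites), whereas on real populations — where
larger samples contain closer relatives and genuinely longer matches — `K`
keeps shrinking. The scaling acceptance test documents this: its strict
monotonicity assertion over N in \{100, 400, 1600\} fails at the saturated
step even when conditioning on the true haplotypes, i.e. it is a property
of the generator's world, not of the selection machinery.

## Numerical choices

* Forward quantities are rescaled at every segment; the homozygous part of
  each segment's emission table is computed in log space and max-shifted,
  so long homozygous runs cannot underflow even when every conditioning
  haplotype mismatches.
* Inter-segment genetic distances get a floor of 1e-7 cM so co-located
  sites keep the chain mixing.
* The stochastic traceback samples the transition kernel through its exact
  four-component mixture decomposition (diagonal/uniform per chain), so a
  draw costs O(K) rather than O(K^2) in the typical case.
* Ties in the max-product solve and in PBWT neighbor walks break
  deterministically (first index / lower rank), which together with a
  single seeded RNG stream makes runs bit-reproducible.
* Within an MCMC iteration the PBWT (and the window sequence hashes used
  by the duplicate collapse) reflect the estimates at the start of the
  iteration; individuals updated later in the same iteration condition on
  slightly stale estimates. This is the standard trade-off for rebuilding
  the PBWT once per iteration.
* Missing genotypes survive QC (only >5% missingness is filtered) and are
  treated as ambiguous graph sites with all four allele completions, so the
  sampler imputes them; a missing site costs two units of a segment's
  het budget of 3, keeping fresh segments at ≤ 8 configurations.

## Known limitations

* Plain or gzipped VCF only (gz written as bgzf); no BCF.
* Multiallelic records and duplicated positions are skipped, not split.
* No chromosome X / ploidy handling; autosomal diploid samples only.
* Single-threaded by design; the target scale is methodological validation,
  not biobank production runs.
* Phase sets whose hets straddle more than one segment boundary are only
  exploited after pruning has merged segments, so very long-range read
  pairs (large-insert or Hi-C style) contribute late or not at all.
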