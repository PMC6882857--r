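# haplophaser

Statistical haplotype phasing for multi-sample diploid genotype panels.

A genotype call at a biallelic site gives an allele count, not the
assignment of alleles to the two parental chromosomes. `haplophaser`
reconstructs each individual's haplotype pair from a panel of unphased
genotypes (VCF), by modelling every haplotype as an imperfect mosaic of the
other haplotypes in the panel. It is aimed at method development and
validation: everything is reproducible from a seed, and a built-in
simulator provides truth-known panels, trios, read-derived phase sets and
scaffolds without any external data.

## The method in brief

* **Conditioning-set selection by PBWT.** A positional Burrows–Wheeler
  transform of all current haplotype estimates is rebuilt every MCMC
  iteration; prefix/divergence arrays are stored every 8 variants. For each
  individual, the `P` (default 4) haplotypes sharing the longest prefixes
  with its two current haplotypes are read off at every stored site of a
  2 Mb window and collapsed into `K` distinct conditioning haplotypes, so
  `K` adapts to the local match structure.
* **Diploid Li–Stephens HMM on genotype graphs.** All haplotype pairs
  consistent with an individual's genotypes are held in a segmented graph
  (≤ 3 hets per fresh segment). The state `(c, k1, k2)` combines the local
  configuration with the haplotype copied by each chain; transitions use
  the stay/switch kernel with `rho = 4 Ne g / (100 N_hap)`, emissions the
  Li–Stephens mutation parameter `theta = (sum_{k<K} 1/k)^{-1}`.
* **MCMC schedule** `5b,1p,1b,1p,1b,1p,5m` (15 iterations): burn-in
  iterations resample haplotype pairs; pruning iterations additionally
  merge adjacent graph segments, dropping configuration combinations with
  posterior transition probability below 0.001; main iterations accumulate
  boundary posteriors, which are averaged at the end and solved by
  max-product dynamic programming.
* **Constraints.** Reference panels join the PBWT (never updated);
  haplotype scaffolds prune the genotype graphs (hard constraints); VCF
  `PS` phase sets reweight paths with error rate `eps = 1e-4`
  (`P(D|H,R) ∝ P(D|H) P(D|R)`); IBD2 pairs (detected by long tri-allelic
  genotype matches) are barred from conditioning on each other.
* **Evaluation.** Switch error rate (fraction of consecutive het pairs
  with wrong relative phase), mean error-free segment length, and trio
  phasing by Mendelian logic.

See `vignettes/haplophaser-methods.Rmd` for the full model description,
parameter table, numerical choices and limitations.

## Worked example

```r
library(haplophaser)

# simulate a mosaic panel with known truth: 80 samples, 600 sites,
# 20 founder haplotypes
truth <- simulate_population(n_founders = 20, N = 80, L = 600, seed = 42)

# phase it with the defaults
res <- phase(truth$gm, truth$vt, run_config(seed = 42))

# evaluate against the simulated truth
ser <- sapply(1:80, function(i) {
  hets <- which(truth$gm$codes[i, ] == 1L)
  if (length(hets) < 2) return(NA)
  switch_error_rate(
    list(h1 = res$haplotypes[2*i-1, ], h2 = res$haplotypes[2*i, ]),
    list(h1 = truth$hap[2*i-1, ],      h2 = truth$hap[2*i, ]),
    hets)
})
sprintf("mean switch error rate: %.4f", mean(ser, na.rm = TRUE))
head(res$stats, 3)
```

This prints (exact output of the code above):

```
mean switch error rate: 0.0041
  iteration type  mean_K
1         1    b 85.8125
2         2    b 41.8000
3         3    b 34.3500
```

0.41% of consecutive het pairs are mis-phased (the PBWT initialization
alone sits at 15.6% on this panel), and the mean conditioning-set size `K`
drops from ~86 in the first burn-in iteration to ~28 as the estimates
converge — longer matches mean fewer distinct conditioning haplotypes.
`write_phased_vcf()` writes the result with phased `a|b` genotypes and a
`PP` FORMAT field carrying each het's phasing certainty.

## Command line

```sh
exec/haplophaser --input panel.vcf --map genetic_map.txt \
    --output phased.vcf --seed 1 \
    [--region chr:start-end] [--reference ref.vcf] [--scaffold scaffold.vcf] \
    [--use-ps 0.0001] [--pbwt-depth 4] [--pbwt-modulo 8] [--window 2000000] \
    [--mcmc-iterations 5b,1p,1b,1p,1b,1p,5m] [--ne 15000] [--log run.log]
```

Input is plain or gzipped VCF with `GT` (and optionally `PS`); QC drops
variants, then individuals, with more than 5% missing genotypes.

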