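# Shared fixtures built in code.

# small mosaic panel with truth
make_panel <- function(N = 40, L = 300, founders = 10, seed = 1, ...) {
  simulate_population(n_founders = founders, N = N, L = L, seed = seed, ...)
}

# switch error rate of individual i of a 2N x L estimate against the truth
ser_of <- function(H, truth, i) {
  hets <- which(truth$gm$codes[i, ] == 1L)
  if (length(hets) < 2) return(NA_real_)
  switch_error_rate(list(h1 = H[2 * i - 1, ], h2 = H[2 * i, ]),
                    list(h1 = truth$hap[2 * i - 1, ], h2 = truth$hap[2 * i, ]),
                    hets)
}

mean_ser <- function(H, truth) {
  mean(vapply(seq_len(nrow(truth$gm$codes)), function(i) ser_of(H, truth, i),
              numeric(1)), na.rm = TRUE)
}

# genotype consistency of a full haplotype matrix
hap_consistent <- function(H, codes) {
  N <- nrow(codes)
  g <- H[seq(1, 2 * N, 2), , drop = FALSE] + H[seq(2, 2 * N, 2), , drop = FALSE]
  ok <- is.na(codes) | g == codes
  all(ok)
}

# random genotype matrix with optional missingness
rand_genotypes <- function(N, L, miss = 0, p = 0.5) {
  G <- matrix(rbinom(N * L, 2L, p), N, L)
  if (miss > 0) G[runif(N * L) < miss] <- NA_integer_
  G
}

# minimal VCF writer for crafted records (header + given body lines)
write_mini_vcf <- function(path, samples, body, extra_format = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=1>",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           extra_format,
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, body), path)
  path
}
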