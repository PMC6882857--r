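# Synthetic data with known truth, plus the evaluation metrics used to
# score haplotype estimates (switch error rate, mean error-free length,
# trio phasing by Mendelian logic).
#
# The simulator builds sample haplotypes as mosaics of a founder pool:
# founder haplotypes are drawn i.i.d. per site with frequency bounded away
# from 0/1, and each sample haplotype switches founders at Poisson
# crossovers. This yields the long shared haplotype stretches the PBWT and
# the Li-Stephens model exploit, with none of the external downloads a
# coalescent panel would need.

#' Simulate a mosaic population with known haplotypes
#'
#' @param n_founders founder haplotype count (>= 2).
#' @param N number of diploid samples.
#' @param L number of variant sites.
#' @param recomb_per_bp per-bp crossover rate of the founder mosaic
#'   (default 1e-6, i.e. mean founder-segment length 1 Mb).
#' @param maf_min lower bound on founder allele frequencies.
#' @param seed RNG seed; the same seed reproduces the TruthSet exactly.
#' @param bp_length chromosome length in bp (default 1500 bp mean spacing).
#' @return object of class `truth_set`: `hap` (2N x L), `gm`, `vt`,
#'   `founders`, `freq`, `pedigree` (NULL until [simulate_trios()]).
#' @export
simulate_population <- function(n_founders = 30L, N = 100L, L = 1000L,
                                recomb_per_bp = 1e-6, maf_min = 0.05,
                                seed = 1L, bp_length = 1500L * L) {
  stopifnot(n_founders >= 2, N >= 1, L >= 2, bp_length >= L)
  set.seed(seed)
  pos <- sort(sample.int(bp_length, L))
  p <- runif(L, maf_min, 1 - maf_min)
  founders <- matrix(rbinom(n_founders * L, 1L, rep(p, each = n_founders)),
                     nrow = n_founders)
  hap <- matrix(0L, 2L * N, L)
  for (h in seq_len(2L * N)) hap[h, ] <- mosaic_hap(founders, pos, bp_length,
                                                    recomb_per_bp)
  geno <- hap[seq(1, 2 * N, 2), , drop = FALSE] +
    hap[seq(2, 2 * N, 2), , drop = FALSE]
  vt <- variant_table(chrom = "1", pos = pos, ref = "A", alt = "C",
                      cm = pos / 1e6)  # flat 1 cM/Mb
  gm <- genotype_matrix(geno, paste0("S", seq_len(N)))
  structure(list(hap = hap, gm = gm, vt = vt, founders = founders,
                 freq = p, bp_length = bp_length,
                 recomb_per_bp = recomb_per_bp, pedigree = NULL),
            class = "truth_set")
}

mosaic_hap <- function(founders, pos, bp_length, recomb_per_bp,
                       sources = NULL) {
  src <- if (is.null(sources)) founders else sources
  nx <- rpois(1, bp_length * recomb_per_bp)
  breaks <- sort(runif(nx, 1, bp_length))
  seg <- findInterval(pos, breaks) + 1L
  pick <- sample.int(nrow(src), nx + 1L, replace = TRUE)
  src[cbind(pick[seg], seq_along(pos))]
}

#' Append trio children to a simulated population
#'
#' Children are built by meiosis from sample pairs (parents 1&2, 3&4, ...):
#' each child haplotype is a crossover mosaic of one parent's two
#' haplotypes, so the children's genotypes are Mendel-consistent with their
#' parents by construction.
#'
#' @param truth a [simulate_population()] result.
#' @param n_trios number of trios to append.
#' @param seed RNG seed.
#' @return the augmented `truth_set` with a `pedigree` data.frame
#'   (`child`, `father`, `mother` sample indices).
#' @export
simulate_trios <- function(truth, n_trios, seed = 1L) {
  stopifnot(2L * n_trios <= nrow(truth$gm$codes))
  set.seed(seed)
  L <- ncol(truth$hap)
  ped <- data.frame(child = integer(n_trios), father = integer(n_trios),
                    mother = integer(n_trios))
  kids <- matrix(0L, 2L * n_trios, L)
  N0 <- nrow(truth$gm$codes)
  for (t in seq_len(n_trios)) {
    fa <- 2L * t - 1L; mo <- 2L * t
    kids[2L * t - 1L, ] <- mosaic_hap(NULL, truth$vt$pos, truth$bp_length,
                                      truth$recomb_per_bp,
                                      truth$hap[c(2 * fa - 1, 2 * fa), , drop = FALSE])
    kids[2L * t, ] <- mosaic_hap(NULL, truth$vt$pos, truth$bp_length,
                                 truth$recomb_per_bp,
                                 truth$hap[c(2 * mo - 1, 2 * mo), , drop = FALSE])
    ped[t, ] <- c(N0 + t, fa, mo)
  }
  truth$hap <- rbind(truth$hap, kids)
  geno <- truth$hap[seq(1, nrow(truth$hap), 2), , drop = FALSE] +
    truth$hap[seq(2, nrow(truth$hap), 2), , drop = FALSE]
  truth$gm <- genotype_matrix(geno, paste0("S", seq_len(nrow(geno))))
  truth$pedigree <- ped
  truth
}

#' Plant read-derived phase sets from the truth
#'
#' Consecutive hets are grouped into phase sets of geometric length (mean
#' `mean_set_len_hets`); within-set first-haplotype alleles are copied from
#' the truth and then flipped independently at `flip_error_rate`. Only a
#' `coverage_fraction` of hets is covered, emulating partial read coverage;
#' singleton sets are dropped (they carry no phase information).
#'
#' @param truth a [simulate_population()] result.
#' @param mean_set_len_hets mean hets per phase set.
#' @param flip_error_rate per-het probability of a planted orientation flip.
#' @param coverage_fraction fraction of hets covered by reads.
#' @param seed RNG seed.
#' @return data.frame `ind`, `var`, `ps`, `allele1`.
#' @export
simulate_phase_sets <- function(truth, mean_set_len_hets = 6,
                                flip_error_rate = 0, coverage_fraction = 1,
                                seed = 1L) {
  stopifnot(flip_error_rate >= 0, flip_error_rate <= 1,
            coverage_fraction >= 0, coverage_fraction <= 1)
  set.seed(seed)
  out <- list()
  N <- nrow(truth$gm$codes)
  for (i in seq_len(N)) {
    h1 <- truth$hap[2L * i - 1L, ]
    hets <- which(truth$gm$codes[i, ] == 1L)
    if (length(hets) < 2) next
    covered <- hets[runif(length(hets)) < coverage_fraction]
    if (length(covered) < 2) next
    # geometric set lengths over the covered hets
    sets <- integer(length(covered))
    t <- 1L; id <- 0L
    while (t <= length(covered)) {
      len <- 1L + rgeom(1, 1 / mean_set_len_hets)
      id <- id + 1L
      sets[t:min(t + len - 1L, length(covered))] <- id
      t <- t + len
    }
    a1 <- h1[covered]
    flip <- runif(length(covered)) < flip_error_rate
    a1[flip] <- 1L - a1[flip]
    df <- data.frame(ind = i, var = covered, ps = sets, allele1 = a1)
    # drop singleton sets and make ps ids unique per individual via the
    # first covered position of each set (VCF convention)
    tab <- table(df$ps)
    df <- df[df$ps %in% as.integer(names(tab)[tab >= 2]), , drop = FALSE]
    if (!nrow(df)) next
    first_var <- tapply(df$var, df$ps, min)
    df$ps <- as.integer(first_var[as.character(df$ps)])
    out[[length(out) + 1L]] <- df
  }
  if (!length(out)) return(empty_phase_sets())
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Plant a sparse haplotype scaffold from the truth
#'
#' @param truth a [simulate_population()] result.
#' @param coverage_fraction fraction of hets scaffolded.
#' @param error_rate per-entry probability of a wrong scaffold allele.
#' @param seed RNG seed.
#' @return data.frame `ind`, `var`, `allele` (class `scaffold`).
#' @export
simulate_scaffold <- function(truth, coverage_fraction = 0.1,
                              error_rate = 0, seed = 1L) {
  set.seed(seed)
  out <- list()
  for (i in seq_len(nrow(truth$gm$codes))) {
    hets <- which(truth$gm$codes[i, ] == 1L)
    pick <- hets[runif(length(hets)) < coverage_fraction]
    if (!length(pick)) next
    al <- truth$hap[2L * i - 1L, pick]
    flip <- runif(length(pick)) < error_rate
    al[flip] <- 1L - al[flip]
    out[[length(out) + 1L]] <- data.frame(ind = i, var = pick, allele = al)
  }
  sc <- if (length(out)) do.call(rbind, out) else
    data.frame(ind = integer(), var = integer(), allele = integer())
  rownames(sc) <- NULL
  class(sc) <- c("scaffold", "data.frame")
  sc
}

#' Phase a trio child by Mendelian inheritance
#'
#' At each child het with at least one homozygous parent the paternal and
#' maternal alleles are determined; triple-het sites and Mendel-inconsistent
#' sites are excluded.
#'
#' @param child,father,mother genotype code vectors (0/1/2/NA).
#' @return data.frame `site`, `paternal`, `maternal` over the phasable
#'   child hets.
#' @export
trio_phase <- function(child, father, mother) {
  sites <- which(!is.na(child) & child == 1L & !is.na(father) & !is.na(mother))
  out <- lapply(sites, function(s) {
    pa <- switch(father[s] + 1L, 0L, c(0L, 1L), 1L)
    ma <- switch(mother[s] + 1L, 0L, c(0L, 1L), 1L)
    combos <- expand.grid(p = pa, m = ma)
    combos <- combos[combos$p + combos$m == 1L, , drop = FALSE]
    if (nrow(combos) != 1L) return(NULL)  # triple het or Mendel error
    data.frame(site = s, paternal = combos$p, maternal = combos$m)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(site = integer(), paternal = integer(), maternal = integer()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Switch error rate
#'
#' Fraction of successive pairs of evaluated hets whose relative phase in
#' the estimate disagrees with the truth, over all such pairs. Invariant to
#' globally swapping either argument's two haplotypes.
#'
#' @param estimate,truth `list(h1, h2)` or 2 x L matrices.
#' @param eval_sites het site indices to evaluate (>= 2).
#' @return the switch error rate in `[0, 1]`.
#' @export
switch_error_rate <- function(estimate, truth, eval_sites) {
  if (length(eval_sites) < 2) stop("switch error rate needs at least 2 hets")
  e1 <- if (is.list(estimate)) estimate$h1 else estimate[1, ]
  t1 <- if (is.list(truth)) truth$h1 else truth[1, ]
  o <- e1[eval_sites] == t1[eval_sites]
  sum(o[-1] != o[-length(o)]) / (length(o) - 1)
}

#' Mean length of haplotype segments free of switch errors
#'
#' The evaluated span (first to last evaluated het) is cut at the midpoint
#' between every consecutive het pair carrying a switch error; the mean bp
#' length of the resulting segments is returned (the full span when there
#' is no error).
#'
#' @param estimate,truth as in [switch_error_rate()].
#' @param positions bp positions of all sites.
#' @param eval_sites het site indices to evaluate.
#' @export
mean_error_free_length <- function(estimate, truth, positions, eval_sites) {
  if (length(eval_sites) < 2) stop("needs at least 2 hets")
  e1 <- if (is.list(estimate)) estimate$h1 else estimate[1, ]
  t1 <- if (is.list(truth)) truth$h1 else truth[1, ]
  o <- e1[eval_sites] == t1[eval_sites]
  sw <- which(o[-1] != o[-length(o)])  # switch between het t and t+1
  p <- positions[eval_sites]
  cuts <- (p[sw] + p[sw + 1]) / 2
  bounds <- c(p[1], cuts, p[length(p)])
  mean(diff(bounds))
}
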