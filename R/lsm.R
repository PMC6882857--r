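# Diploid Li-Stephens HMM over a genotype graph and a conditioning set of K
# haplotypes. The state at each segment is (configuration, copied haplotype
# for each of the two target haplotypes); transitions factorize per haploid
# chain with the classic stay/switch kernel, emissions use the Li-Stephens
# mutation model with theta from the harmonic-number formula, and phase-set
# factors weight configurations locally. The heavy lifting is in C++
# (cpp_hmm_run); the R functions here expose the model surface and carry
# the final max-product solve over averaged transition tables.

#' Li-Stephens mutation parameter
#'
#' theta = (sum_{k=1}^{K-1} 1/k)^{-1}; for K = 1 (degenerate conditioning
#' set) theta is fixed at 1.
#'
#' @param K conditioning-set size.
#' @export
ls_theta <- function(K) {
  if (K < 2) return(1)
  1 / sum(1 / seq_len(K - 1))
}

#' Haploid stay/switch transition probabilities
#'
#' rho = 4 Ne (g/100) / N_hap; stay = exp(-rho/K) + (1 - exp(-rho/K))/K and
#' each of the K-1 switch targets gets (1 - exp(-rho/K))/K, so
#' stay + (K-1) switch = 1.
#'
#' @param g_cm genetic distance in centimorgans.
#' @param K conditioning-set size.
#' @param Ne effective population size (default 15000).
#' @param n_hap total number of haplotypes in the panel.
#' @return named vector `stay`, `switch_each`.
#' @export
transition_probs <- function(g_cm, K, Ne = 15000, n_hap = 2 * K) {
  stopifnot(g_cm >= 0, K >= 1)
  rho <- 4 * Ne * (g_cm / 100) / n_hap
  e <- exp(-rho / K)
  sw <- (1 - e) / K
  c(stay = e + sw, switch_each = sw)
}

#' Li-Stephens emission probability
#'
#' Match: K/(K+theta) + (theta/(K+theta))/2; mismatch: (theta/(K+theta))/2.
#' The two sum to 1 over \{match, mismatch\} for a given copied allele.
#'
#' @param copied_allele,observed_allele alleles in \{0, 1\}.
#' @param K conditioning-set size (>= 2).
#' @export
emission_prob <- function(copied_allele, observed_allele, K) {
  stopifnot(K >= 2)
  theta <- ls_theta(K)
  mis <- (theta / (K + theta)) / 2
  ifelse(copied_allele == observed_allele, K / (K + theta) + mis, mis)
}

#' LSM parameters
#'
#' @param Ne effective population size.
#' @param cm per-site genetic positions (cM) over the window.
#' @param n_hap total haplotypes in the panel (main + reference); defaults
#'   to twice the conditioning-set size at run time when NULL.
#' @export
lsm_params <- function(Ne = 15000, cm = NULL, n_hap = NULL) {
  structure(list(Ne = Ne, cm = cm, n_hap = n_hap), class = "lsm_params")
}

# Flatten a genotype_graph into the argument lists cpp_hmm_run expects.
# sites_global: optional mapping window-local -> global site index (0-based
# passed down); cm: per-site genetic positions aligned with the graph sites.
graph_cpp_args <- function(graph, cm, constraints = NULL,
                           sites_global = NULL) {
  nseg <- length(graph$segments)
  wt <- ps_graph_weights(graph, constraints)
  seg_sites <- vector("list", nseg)
  seg_fixed <- vector("list", nseg)
  seg_amb <- vector("list", nseg)
  seg_conf1 <- vector("list", nseg)
  seg_conf2 <- vector("list", nseg)
  bound_gcm <- numeric(max(nseg - 1L, 0L))
  for (s in seq_len(nseg)) {
    sg <- graph$segments[[s]]
    loc <- sg$sites
    seg_sites[[s]] <- if (is.null(sites_global)) loc - 1L else sites_global[loc] - 1L
    seg_fixed[[s]] <- sg$fixed
    seg_amb[[s]] <- sg$amb - 1L
    seg_conf1[[s]] <- sg$conf1
    seg_conf2[[s]] <- sg$conf2
    if (s > 1) {
      prev <- graph$segments[[s - 1]]
      bound_gcm[s - 1] <- cm[loc[1]] - cm[prev$sites[length(prev$sites)]]
    }
  }
  list(seg_sites = seg_sites, seg_fixed = seg_fixed, seg_amb = seg_amb,
       seg_conf1 = seg_conf1, seg_conf2 = seg_conf2,
       seg_wt = wt$seg_wt, bound_wt = wt$bound_wt, bound_gcm = bound_gcm)
}

#' Forward-backward over a genotype graph
#'
#' Runs the scaled forward pass and the backward pass of the diploid
#' Li-Stephens HMM, folding phase-set weights in as local factors, and
#' returns the posterior distribution over configuration pairs at every
#' adjacent-segment boundary (each table sums to 1) together with
#' per-segment configuration marginals and the data log-likelihood.
#'
#' @param graph a [build_graph()] result.
#' @param cond K x L binary matrix of conditioning haplotypes over the
#'   window (rows = haplotypes).
#' @param params an [lsm_params()] object; `params$cm` must cover the
#'   window's sites.
#' @param constraints optional [phase_set_constraints()].
#' @return object of class `lsm_forward` with elements `post` (list of
#'   boundary tables), `marg`, `loglik`, plus the inputs needed by
#'   [sample_pair()].
#' @export
forward_backward <- function(graph, cond, params, constraints = NULL) {
  cond <- as.matrix(cond)
  storage.mode(cond) <- "integer"
  K <- nrow(cond)
  n_hap <- if (is.null(params$n_hap)) 2L * K else params$n_hap
  cm <- if (is.null(params$cm)) (seq_len(ncol(cond)) - 1) * 1e-7 else params$cm
  args <- graph_cpp_args(graph, cm, constraints)
  res <- cpp_hmm_run(args$seg_sites, args$seg_fixed, args$seg_amb,
                     args$seg_conf1, args$seg_conf2, args$seg_wt,
                     args$bound_wt, args$bound_gcm,
                     seq_len(K) - 1L, cond, params$Ne, n_hap,
                     0L, TRUE, -1L, -1L)
  structure(list(graph = graph, cond = cond, params = params,
                 constraints = constraints, args = args, n_hap = n_hap,
                 post = res$post, marg = res$marg, loglik = res$loglik),
            class = "lsm_forward")
}

config_to_pair <- function(graph, configs) {
  h1 <- integer(graph$n_sites); h2 <- integer(graph$n_sites)
  for (s in seq_along(graph$segments)) {
    sg <- graph$segments[[s]]
    fx <- sg$fixed >= 0L
    h1[sg$sites[fx]] <- sg$fixed[fx]
    h2[sg$sites[fx]] <- sg$fixed[fx]
    if (length(sg$amb)) {
      h1[sg$sites[sg$amb]] <- sg$conf1[configs[s], ]
      h2[sg$sites[sg$amb]] <- sg$conf2[configs[s], ]
    }
  }
  list(h1 = h1, h2 = h2)
}

#' Sample haplotype pairs by stochastic traceback
#'
#' Draws paths through the genotype graph from the posterior encoded by the
#' forward quantities; every sampled pair is genotype- and
#' scaffold-consistent by construction.
#'
#' @param fwd a [forward_backward()] result.
#' @param n number of draws.
#' @return for `n = 1` a `list(h1, h2)`; otherwise a list of such pairs.
#'   The per-segment configuration indices are attached as attribute
#'   `configs` (segments x draws).
#' @export
sample_pair <- function(fwd, n = 1L) {
  a <- fwd$args
  K <- nrow(fwd$cond)
  res <- cpp_hmm_run(a$seg_sites, a$seg_fixed, a$seg_amb, a$seg_conf1,
                     a$seg_conf2, a$seg_wt, a$bound_wt, a$bound_gcm,
                     seq_len(K) - 1L, fwd$cond, fwd$params$Ne, fwd$n_hap,
                     as.integer(n), FALSE, -1L, -1L)
  configs <- res$samples + 1L
  pairs <- lapply(seq_len(n), function(d) config_to_pair(fwd$graph, configs[, d]))
  out <- if (n == 1L) pairs[[1]] else pairs
  attr(out, "configs") <- configs
  out
}

#' Final solve from averaged transition tables
#'
#' Averages the boundary transition tables stored over the main iterations
#' and returns the highest-probability configuration path through them
#' (max-product dynamic programming over the product of averaged boundary
#' probabilities; deterministic, first-index tie-break). A single-segment
#' graph is solved from its averaged configuration marginal.
#'
#' @param graph a [build_graph()] result (post-pruning structure).
#' @param stored list with `post` (list of summed boundary tables), `marg`
#'   (summed per-segment marginals) and `n` (number of main iterations).
#' @return list `h1`, `h2`, `configs`, `certainty` (per segment: averaged
#'   posterior of the solved transition into the segment's configuration,
#'   conditional on the previous segment's; `NA` for the orientation-
#'   anchoring first segment).
#' @export
accumulate_and_solve <- function(graph, stored) {
  if (is.null(stored) || stored$n < 1) stop("no stored main iterations")
  nseg <- length(graph$segments)
  if (nseg == 1) {
    m <- stored$marg[[1]] / stored$n
    best <- which.max(m)
    pair <- config_to_pair(graph, best)
    # a single segment carries no transition, hence no certainty estimate
    return(c(pair, list(configs = best, certainty = NA_real_)))
  }
  tabs <- lapply(stored$post, function(x) x / stored$n)
  # max-product over the chain of averaged boundary tables
  nconf1 <- nrow(tabs[[1]])
  score <- rep(1, nconf1)
  back <- vector("list", nseg - 1L)
  for (s in seq_len(nseg - 1L)) {
    Tm <- tabs[[s]]
    cand <- score * Tm            # recycles score down columns
    back[[s]] <- apply(cand, 2, which.max)
    score <- apply(cand, 2, max)
  }
  configs <- integer(nseg)
  configs[nseg] <- which.max(score)
  for (s in rev(seq_len(nseg - 1L)))
    configs[s] <- back[[s]][configs[s + 1L]]
  pair <- config_to_pair(graph, configs)
  # certainty of a segment's configuration = averaged posterior of the
  # solved transition into it, conditional on the previous segment's
  # configuration (invariant to the global haplotype swap); the first
  # segment anchors the orientation and gets no certainty
  cert <- rep(NA_real_, nseg)
  for (s in 2:nseg) {
    row <- tabs[[s - 1L]][configs[s - 1L], ]
    cert[s] <- row[configs[s]] / sum(row)
  }
  c(pair, list(configs = configs, certainty = cert))
}
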