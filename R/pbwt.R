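# Positional Burrows-Wheeler transform: R surface over the C++ sweeps.
#
# All haplotype matrices are M x L (rows = haplotypes, columns = sites).
# Indices exposed to R are 1-based; the divergence value D[r] at stored site
# l means ranks r and r-1 agree on sites [D[r], l], with D[r] == l + 1
# signalling no match.

#' Build a PBWT of a haplotype set
#'
#' Runs a single left-to-right O(LN) sweep, retaining prefix, divergence and
#' locator arrays at every `stride`-th site plus the last site.
#'
#' @param H binary haplotype matrix, 2N x L.
#' @param stride store arrays every `stride` variants (default 8).
#' @param store_sites optional explicit 1-based site indices to store
#'   (overrides `stride`).
#' @return list of class `pbwt`: `A` (prefix), `D` (divergence), `I`
#'   (locator), all M x n_stored, and `sites` (stored site indices).
#' @export
pbwt_build <- function(H, stride = 8L, store_sites = NULL) {
  H <- as.matrix(H)
  storage.mode(H) <- "integer"
  L <- ncol(H)
  if (is.null(store_sites)) {
    store_sites <- unique(c(seq(1L, L, by = as.integer(stride)), L))
  }
  store_sites <- sort(unique(as.integer(store_sites)))
  if (any(store_sites < 1L | store_sites > L)) stop("store_sites out of range")
  res <- cpp_pbwt_build(H, store_sites - 1L)
  structure(list(A = res$A + 1L, D = res$D + 1L, I = res$I + 1L,
                 sites = store_sites, stride = as.integer(stride),
                 M = res$M, H = H),
            class = "pbwt")
}

#' Longest-prefix neighbors of a haplotype at a stored site
#'
#' Walks outwards from the haplotype's rank in the prefix array, always
#' extending towards the neighbor with the longer shared prefix ending at
#' `site` (divergence comparison); ties prefer the up (lower-rank) side.
#' Excluded haplotypes are skipped but traversed.
#'
#' @param state a [pbwt_build()] result.
#' @param hap 1-based haplotype index.
#' @param site a stored site.
#' @param P number of neighbors requested.
#' @param exclude haplotype indices never to return.
#' @return integer vector of up to `P` haplotype indices, attribute
#'   `starts` giving each match's 1-based start site.
#' @export
pbwt_neighbors <- function(state, hap, site, P, exclude = integer()) {
  col <- match(site, state$sites)
  if (is.na(col)) stop("site ", site, " is not a stored PBWT site")
  res <- cpp_pbwt_neighbors(state$A[, col] - 1L, state$D[, col] - 1L,
                            state$I[, col] - 1L, site - 1L, hap - 1L,
                            as.integer(P), as.integer(exclude) - 1L)
  structure(res$haps + 1L, starts = res$starts + 1L)
}

#' Select the conditioning set for a haplotype pair over a window
#'
#' Takes the union of [pbwt_neighbors()] results for both target haplotypes
#' over every stored site inside the window and collapses it into a list of
#' K distinct haplotypes: repeated indices are dropped, and haplotypes whose
#' sequences are identical over the window collapse to one representative
#' (a duplicate sequence adds nothing the model can copy from). K is
#' bounded by 2 P (stored sites in window).
#'
#' @param state a [pbwt_build()] result.
#' @param d length-2 vector with the pair's haplotype indices.
#' @param window length-2 vector `c(from, to)` of 1-based variant indices.
#' @param P neighbors per query.
#' @param exclude haplotype indices to exclude (the pair itself is always
#'   excluded).
#' @return sorted integer vector of K distinct haplotype indices.
#' @export
select_conditioning_set <- function(state, d, window, P, exclude = integer()) {
  cols <- which(state$sites >= window[1] & state$sites <= window[2])
  if (!length(cols)) stop("window contains no stored PBWT site")
  hashes <- cpp_hash_window(state$H, window[1] - 1L, window[2] - 1L)
  out <- cpp_select_conditioning(state$A - 1L, state$D - 1L, state$I - 1L,
                                 state$sites - 1L, cols - 1L,
                                 d[1] - 1L, d[2] - 1L, as.integer(P),
                                 as.integer(exclude) - 1L, hashes)
  if (!length(out))
    stop("conditioning set empty after exclusions; widen P or reduce exclusions")
  out + 1L
}

#' Long genotype matches between individuals (IBD2 screening)
#'
#' Reports all maximal pairwise runs of genotype equality over the
#' tri-allelic code alphabet \{0,1,2\} spanning at least `min_span` bp
#' (`pos[end] - pos[start] >= min_span`). Missing genotypes are wildcards
#' that match anything. Individuals with complete data go through a PBWT
#' sweep; pairs touching missing data use direct run scans.
#'
#' @param gm [genotype_matrix()].
#' @param vt [variant_table()].
#' @param min_span minimum bp span (default 2 Mb, the phasing window size).
#' @return data.frame `i`, `j` (individual indices, `i < j`), `start`, `end`
#'   (1-based site indices of the maximal match).
#' @export
pbwt_long_genotype_matches <- function(gm, vt, min_span = 2e6) {
  m <- cpp_genotype_long_matches(gm$codes, as.integer(vt$pos),
                                 as.numeric(min_span))
  df <- data.frame(i = m[, 1] + 1L, j = m[, 2] + 1L,
                   start = m[, 3] + 1L, end = m[, 4] + 1L)
  df[order(df$i, df$j, df$start), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Convert long genotype matches into per-window IBD2 constraints
#'
#' A pair (i, j) is constrained in window w when the match covers every
#' variant of the window, so neither individual may condition on the other
#' there.
#'
#' @param matches a [pbwt_long_genotype_matches()] result.
#' @param windows a [make_windows()] result.
#' @return data.frame `i`, `j`, `w`.
#' @export
ibd2_constraints <- function(matches, windows) {
  out <- list()
  for (w in seq_len(nrow(windows))) {
    from <- windows$from[w]; to <- windows$to[w]
    hit <- matches$start <= from & matches$end >= to
    if (any(hit))
      out[[length(out) + 1L]] <- data.frame(i = matches$i[hit],
                                            j = matches$j[hit], w = w)
  }
  if (!length(out)) return(data.frame(i = integer(), j = integer(), w = integer()))
  res <- do.call(rbind, out)
  res[!duplicated(res), , drop = FALSE]
}

#' PBWT-guided haplotype initialization
#'
#' Left-to-right sweep: at each site, alleles implied by homozygous
#' genotypes are fixed; each heterozygous haplotype copies the nearest
#' neighbor in the previous site's prefix array whose allele is already
#' determined, walking towards the side with the longer current match
#' (divergence comparison, ties up); complementarity is then enforced at
#' each het by flipping the haplotype with the shorter neighbor match; and
#' the PBWT advances one site. The first site and missing genotypes are
#' randomized from the site allele frequency.
#'
#' @param gm [genotype_matrix()].
#' @param vt [variant_table()] (shape check only).
#' @param seed RNG seed.
#' @return 2N x L binary haplotype matrix consistent with the genotypes.
#' @export
pbwt_init_phase <- function(gm, vt, seed = 1L) {
  if (ncol(gm$codes) != nrow(vt)) stop("genotype/variant shape mismatch")
  set.seed(seed)
  freq <- colMeans(gm$codes, na.rm = TRUE) / 2
  freq[is.nan(freq)] <- 0.5
  cpp_pbwt_init(gm$codes, freq)
}
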