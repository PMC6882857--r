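# Independent brute-force oracles. These deliberately share no code with
# the implementation: the PBWT oracle sorts reversed prefixes with order(),
# the match oracles scan all pairs, and the HMM oracle enumerates every
# (path, copying-sequence) combination.

# PBWT arrays at site l by stable sort of reversed prefixes
oracle_pbwt <- function(H, l) {
  M <- nrow(H)
  A <- do.call(order, lapply(l:1, function(s) H[, s]))
  D <- integer(M)
  D[1] <- l + 1L
  if (M > 1) {
    for (r in 2:M) {
      a <- H[A[r - 1], 1:l]; b <- H[A[r], 1:l]
      neq <- which(a != b)
      D[r] <- if (length(neq)) max(neq) + 1L else 1L
    }
  }
  I <- integer(M); I[A] <- seq_len(M)
  list(A = A, D = D, I = I)
}

# match start (1-based) of the suffix shared by haplotypes x and y ending
# at site l; l + 1 when they differ at l
oracle_match_start <- function(H, x, y, l) {
  s <- l + 1L
  while (s > 1L && H[x, s - 1L] == H[y, s - 1L]) s <- s - 1L
  s
}

# neighbor list at a stored site, replicating the documented tie-break:
# longer match first, then up (lower-rank) side, then rank distance
oracle_neighbors <- function(H, hap, l, P, exclude = integer()) {
  M <- nrow(H)
  ord <- oracle_pbwt(H, l)
  r <- ord$I[hap]
  cand <- setdiff(seq_len(M), c(hap, exclude))
  start <- vapply(cand, function(h) oracle_match_start(H, hap, h, l), integer(1))
  side <- ifelse(ord$I[cand] < r, 0L, 1L)
  dist <- abs(ord$I[cand] - r)
  o <- order(start, side, dist)
  head(cand[o], P)
}

# all maximal pairwise genotype matches (wildcard NA) spanning >= min_span
oracle_long_matches <- function(G, pos, min_span) {
  N <- nrow(G); L <- ncol(G)
  out <- list()
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    eq <- is.na(G[i, ]) | is.na(G[j, ]) | G[i, ] == G[j, ]
    runs <- rle(eq)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (t in which(runs$values)) {
      if (ends[t] > starts[t] && pos[ends[t]] - pos[starts[t]] >= min_span)
        out[[length(out) + 1L]] <- c(i, j, starts[t], ends[t])
    }
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), start = integer(),
                      end = integer()))
  m <- do.call(rbind, out)
  df <- data.frame(i = m[, 1], j = m[, 2], start = m[, 3], end = m[, 4])
  df[order(df$i, df$j, df$start), , drop = FALSE]
}

# exhaustive diploid-LSM enumeration over (config path, k1 path, k2 path);
# honours the same 1e-7 cM distance floor the implementation applies
oracle_hmm <- function(graph, cond, cm, nhap, Ne = 15000, cons = NULL) {
  K <- nrow(cond)
  theta <- if (K < 2) 1 else 1 / sum(1 / seq_len(K - 1))
  pm <- (K + theta / 2) / (K + theta)
  px <- (theta / 2) / (K + theta)
  segs <- graph$segments
  nseg <- length(segs)
  counts <- vapply(segs, function(s) nrow(s$conf1), integer(1))
  tp <- NULL
  if (nseg > 1) {
    tp <- lapply(2:nseg, function(s) {
      g <- max(cm[segs[[s]]$sites[1]] - cm[tail(segs[[s - 1]]$sites, 1)], 1e-7)
      transition_probs(g, K, Ne, nhap)
    })
  }
  # phase-set pair weights on the sampled pair, by the stated model
  seg_of <- integer(graph$n_sites)
  for (s in seq_len(nseg)) seg_of[segs[[s]]$sites] <- s
  pair_wt <- function(h1) {
    if (is.null(cons)) return(1)
    w <- 1
    df <- cons$entries[order(cons$entries$ps, cons$entries$site), ]
    for (id in unique(df$ps)) {
      e <- df[df$ps == id, ]
      if (nrow(e) < 2) next
      for (t in seq_len(nrow(e) - 1)) {
        u <- e$site[t]; v <- e$site[t + 1]
        if (abs(seg_of[u] - seg_of[v]) > 1) next
        agree <- (h1[u] != h1[v]) == (e$allele1[t] != e$allele1[t + 1])
        w <- w * if (agree) 1 - cons$eps else cons$eps
      }
    }
    w
  }
  paths <- enumerate_paths(graph)
  path_cfg <- function(p) vapply(seq_len(nseg), function(s) {
    sg <- segs[[s]]
    if (!length(sg$amb)) return(1L)
    which(apply(sg$conf1, 1, function(cc) all(cc == p$h1[sg$sites[sg$amb]])) &
          apply(sg$conf2, 1, function(cc) all(cc == p$h2[sg$sites[sg$amb]])))
  }, integer(1))
  kseqs <- as.matrix(expand.grid(rep(list(seq_len(K)), nseg)))
  # joint over config paths plus boundary pair tables
  cfg_paths <- as.matrix(do.call(expand.grid, lapply(counts, seq_len)))
  path_prob <- numeric(nrow(cfg_paths))
  key <- apply(cfg_paths, 1, paste, collapse = "-")
  bound <- lapply(seq_len(max(nseg - 1, 0)), function(s)
    matrix(0, counts[s], counts[s + 1]))
  for (p in paths) {
    cfg <- path_cfg(p)
    w <- pair_wt(p$h1)
    tot_p <- 0
    for (r1 in seq_len(nrow(kseqs))) for (r2 in seq_len(nrow(kseqs))) {
      k1 <- kseqs[r1, ]; k2 <- kseqs[r2, ]
      pr <- w / K^2
      for (s in seq_len(nseg)) {
        sg <- segs[[s]]
        for (t in seq_along(sg$sites)) {
          site <- sg$sites[t]
          pr <- pr * (if (p$h1[site] == cond[k1[s], site]) pm else px)
          pr <- pr * (if (p$h2[site] == cond[k2[s], site]) pm else px)
        }
        if (s > 1) {
          pr <- pr * (if (k1[s] == k1[s - 1]) tp[[s - 1]][1] else tp[[s - 1]][2])
          pr <- pr * (if (k2[s] == k2[s - 1]) tp[[s - 1]][1] else tp[[s - 1]][2])
        }
      }
      tot_p <- tot_p + pr
    }
    idx <- match(paste(cfg, collapse = "-"), key)
    path_prob[idx] <- path_prob[idx] + tot_p
    for (s in seq_len(nseg - 1))
      bound[[s]][cfg[s], cfg[s + 1]] <- bound[[s]][cfg[s], cfg[s + 1]] + tot_p
  }
  tot <- sum(path_prob)
  marg <- lapply(seq_len(nseg), function(s)
    vapply(seq_len(counts[s]), function(c)
      sum(path_prob[cfg_paths[, s] == c]), numeric(1)) / tot)
  list(bound = lapply(bound, function(b) b / tot), marg = marg,
       loglik = log(tot), cfg_paths = cfg_paths, path_prob = path_prob / tot)
}
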