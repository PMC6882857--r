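# Genotype graphs: segmented representation of every haplotype pair
# consistent with an individual's genotypes over a window.
#
# A segment holds a run of consecutive sites; its ambiguous sites (hets and
# missing genotypes) carry a list of admissible local configurations, stored
# as two allele matrices (first and second haplotype; at hets the second is
# the complement, at missing sites the four completions are independent).
# Homozygous sites are fixed alleles attached to the enclosing segment.
# Segmentation packs ambiguous sites under a configuration budget of 2^B:
# a het costs one bit, a missing site two, so a fresh segment holds at most
# B hets (default 3) and at most 2^B configurations.

seg_configs <- function(is_het) {
  # enumerate admissible (h1, h2) allele matrices over the ambiguous sites
  n <- length(is_het)
  if (n == 0) {
    return(list(conf1 = matrix(integer(), 1, 0), conf2 = matrix(integer(), 1, 0)))
  }
  per <- ifelse(is_het, 2L, 4L)
  nconf <- prod(per)
  conf1 <- matrix(0L, nconf, n)
  conf2 <- matrix(0L, nconf, n)
  rep_each <- 1L
  for (a in seq_len(n)) {
    if (is_het[a]) {
      states1 <- c(0L, 1L); states2 <- c(1L, 0L)
    } else {
      states1 <- c(0L, 1L, 0L, 1L); states2 <- c(0L, 0L, 1L, 1L)
    }
    k <- length(states1)
    idx <- rep(rep(seq_len(k), each = rep_each), length.out = nconf)
    conf1[, a] <- states1[idx]
    conf2[, a] <- states2[idx]
    rep_each <- rep_each * k
  }
  list(conf1 = conf1, conf2 = conf2)
}

#' Build a genotype graph for one individual over a window
#'
#' Groups consecutive ambiguous sites (hets and missing genotypes) into
#' segments holding at most `B` hets each (a missing site consumes two units
#' of the budget since it admits four completions); the last segment may
#' hold fewer. Homozygous sites are attached to the enclosing segment as
#' fixed alleles. An individual with h hets and no missing data has
#' 2^(h-1) distinct unordered haplotype pairs through the graph.
#'
#' @param g genotype codes over the window (0/1/2/NA).
#' @param B het budget per fresh segment (default 3).
#' @return object of class `genotype_graph`.
#' @export
build_graph <- function(g, B = 3L) {
  n <- length(g)
  if (n == 0) stop("empty window")
  amb <- which(g == 1L | is.na(g))
  cost <- ifelse(is.na(g[amb]), 2L, 1L)
  seg_of <- integer(length(amb))
  bits <- 0L; s <- 1L
  for (t in seq_along(amb)) {
    if (bits > 0L && bits + cost[t] > B) { s <- s + 1L; bits <- 0L }
    seg_of[t] <- s
    bits <- bits + cost[t]
  }
  nseg <- max(seg_of, 1L)
  segments <- vector("list", nseg)
  start <- 1L
  for (s in seq_len(nseg)) {
    in_s <- which(seg_of == s)
    last_amb <- if (length(in_s)) amb[max(in_s)] else n
    end <- if (s == nseg) n else last_amb
    sites <- start:end
    fixed <- ifelse(!is.na(g[sites]) & g[sites] != 1L, g[sites] %/% 2L, -1L)
    amb_local <- which(fixed < 0L)
    cf <- seg_configs(!is.na(g[sites[amb_local]]))
    segments[[s]] <- list(sites = sites, fixed = as.integer(fixed),
                          amb = amb_local,
                          is_het = !is.na(g[sites[amb_local]]),
                          conf1 = cf$conf1, conf2 = cf$conf2)
    start <- end + 1L
  }
  structure(list(n_sites = n, g = g, B = as.integer(B), segments = segments),
            class = "genotype_graph")
}

n_paths <- function(graph) {
  prod(vapply(graph$segments, function(s) nrow(s$conf1), numeric(1)))
}

#' Enumerate every haplotype pair encoded by a graph
#'
#' Test oracle for small cases; errors if the path count exceeds 2^16.
#'
#' @param graph a [build_graph()] result.
#' @return list of `list(h1, h2)` pairs, one per path.
#' @export
enumerate_paths <- function(graph) {
  np <- n_paths(graph)
  if (np > 2^16) stop("path count ", np, " too large to enumerate")
  counts <- vapply(graph$segments, function(s) nrow(s$conf1), integer(1))
  combos <- as.matrix(do.call(expand.grid, lapply(counts, seq_len)))
  lapply(seq_len(nrow(combos)), function(r) {
    h1 <- integer(graph$n_sites); h2 <- integer(graph$n_sites)
    for (s in seq_along(graph$segments)) {
      sg <- graph$segments[[s]]
      c_idx <- combos[r, s]
      fx <- sg$fixed >= 0L
      h1[sg$sites[fx]] <- sg$fixed[fx]
      h2[sg$sites[fx]] <- sg$fixed[fx]
      if (length(sg$amb)) {
        h1[sg$sites[sg$amb]] <- sg$conf1[c_idx, ]
        h2[sg$sites[sg$amb]] <- sg$conf2[c_idx, ]
      }
    }
    list(h1 = h1, h2 = h2)
  })
}

#' Prune graph configurations inconsistent with a haplotype scaffold
#'
#' Removes every configuration whose first-haplotype allele contradicts a
#' scaffold entry. Scaffolded phase is absolute: no surviving path can
#' contradict it, and later phase-set weighting cannot resurrect a pruned
#' configuration.
#'
#' @param graph a [build_graph()] result.
#' @param entries data.frame `site` (window-local index), `allele`
#'   (first-haplotype allele at that het).
#' @return the pruned graph.
#' @export
apply_scaffold <- function(graph, entries) {
  if (is.null(entries) || nrow(entries) == 0) return(graph)
  for (s in seq_along(graph$segments)) {
    sg <- graph$segments[[s]]
    if (!length(sg$amb)) next
    amb_sites <- sg$sites[sg$amb]
    hit <- which(entries$site %in% amb_sites)
    keep <- rep(TRUE, nrow(sg$conf1))
    for (h in hit) {
      a <- match(entries$site[h], amb_sites)
      if (!sg$is_het[a]) next  # scaffold is defined at hets only
      keep <- keep & sg$conf1[, a] == entries$allele[h]
    }
    if (!any(keep))
      stop("scaffold inconsistent with genotypes at site ",
           entries$site[hit[1]])
    graph$segments[[s]]$conf1 <- sg$conf1[keep, , drop = FALSE]
    graph$segments[[s]]$conf2 <- sg$conf2[keep, , drop = FALSE]
  }
  graph
}

#' Phase-set constraints for one individual
#'
#' @param df data.frame `site` (window-local variant index), `ps` (phase-set
#'   id), `allele1` (first-haplotype allele given by the reads).
#' @param eps phase-set error rate, in (0, 0.5]; 0.5 makes phase sets
#'   carry no information.
#' @return object of class `phase_set_constraints`.
#' @export
phase_set_constraints <- function(df, eps = 1e-4) {
  stopifnot(eps > 0, eps <= 0.5)
  df <- df[order(df$ps, df$site), , drop = FALSE]
  if (anyDuplicated(df$site)) stop("a variant may belong to at most one phase set")
  structure(list(entries = df, eps = eps), class = "phase_set_constraints")
}

ps_pairs <- function(constraints) {
  # consecutive het pairs within each phase set, with their relative
  # orientation (TRUE = first-haplotype alleles differ)
  df <- constraints$entries
  out <- list()
  for (id in unique(df$ps)) {
    e <- df[df$ps == id, , drop = FALSE]
    e <- e[order(e$site), , drop = FALSE]
    if (nrow(e) < 2) next
    for (t in seq_len(nrow(e) - 1)) {
      out[[length(out) + 1L]] <- data.frame(
        u = e$site[t], v = e$site[t + 1],
        rel = e$allele1[t] != e$allele1[t + 1])
    }
  }
  if (!length(out)) return(data.frame(u = integer(), v = integer(), rel = logical()))
  do.call(rbind, out)
}

graph_seg_of <- function(graph) {
  # map window-local site index -> segment index
  seg <- integer(graph$n_sites)
  for (s in seq_along(graph$segments)) seg[graph$segments[[s]]$sites] <- s
  seg
}

#' Phase-set weights aligned with a graph's segmentation
#'
#' Classifies each consecutive-het pair of every phase set: pairs inside one
#' segment become per-configuration weights, pairs straddling adjacent
#' segments become boundary weight tables, and pairs spanning non-adjacent
#' segments are unusable (contribute nothing) until segments merge.
#'
#' @param graph a [build_graph()] result.
#' @param constraints a [phase_set_constraints()] object (or NULL).
#' @return list `seg_wt` (per segment, numeric or NULL) and `bound_wt` (per
#'   boundary, matrix or NULL).
#' @keywords internal
ps_graph_weights <- function(graph, constraints) {
  nseg <- length(graph$segments)
  seg_wt <- vector("list", nseg)
  bound_wt <- vector("list", max(nseg - 1L, 0L))
  if (is.null(constraints) || nrow(constraints$entries) == 0)
    return(list(seg_wt = seg_wt, bound_wt = bound_wt))
  eps <- constraints$eps
  pairs <- ps_pairs(constraints)
  if (!nrow(pairs)) return(list(seg_wt = seg_wt, bound_wt = bound_wt))
  seg_of <- graph_seg_of(graph)
  for (r in seq_len(nrow(pairs))) {
    u <- pairs$u[r]; v <- pairs$v[r]; rel <- pairs$rel[r]
    su <- seg_of[u]; sv <- seg_of[v]
    sgu <- graph$segments[[su]]; sgv <- graph$segments[[sv]]
    au <- match(u, sgu$sites[sgu$amb]); av <- match(v, sgv$sites[sgv$amb])
    if (is.na(au) || is.na(av)) next  # not ambiguous here (e.g. filtered)
    if (su == sv) {
      agree <- (sgu$conf1[, au] != sgu$conf1[, av]) == rel
      w <- ifelse(agree, 1 - eps, eps)
      seg_wt[[su]] <- if (is.null(seg_wt[[su]])) w else seg_wt[[su]] * w
    } else if (sv == su + 1L) {
      w <- outer(sgu$conf1[, au], sgv$conf1[, av],
                 function(x, y) ifelse((x != y) == rel, 1 - eps, eps))
      bound_wt[[su]] <- if (is.null(bound_wt[[su]])) w else bound_wt[[su]] * w
    }
    # pairs spanning non-adjacent segments contribute nothing until merging
  }
  list(seg_wt = seg_wt, bound_wt = bound_wt)
}

#' Log-weight of a haplotype pair under phase-set constraints
#'
#' Each usable consecutive-het pair of a phase set (both hets within one
#' segment or in adjacent segments of `graph`) contributes `log(1 - eps)`
#' when the pair's relative orientation agrees with the phase set and
#' `log(eps)` otherwise; unusable pairs contribute 0.
#'
#' @param pair `list(h1, h2)` over the graph's window.
#' @param constraints a [phase_set_constraints()] object.
#' @param graph the current [build_graph()] result (segmentation decides
#'   usability).
#' @return the summed log-probability.
#' @export
phase_set_log_weight <- function(pair, constraints, graph) {
  pairs <- ps_pairs(constraints)
  if (!nrow(pairs)) return(0)
  eps <- constraints$eps
  seg_of <- graph_seg_of(graph)
  total <- 0
  for (r in seq_len(nrow(pairs))) {
    u <- pairs$u[r]; v <- pairs$v[r]
    if (abs(seg_of[u] - seg_of[v]) > 1L) next
    agree <- (pair$h1[u] != pair$h1[v]) == pairs$rel[r]
    total <- total + log(if (agree) 1 - eps else eps)
  }
  total
}

#' Merge consecutive segment pairs, trimming unlikely configurations
#'
#' Disjoint adjacent segment pairs (1,2), (3,4), ... are merged once; in a
#' merged segment only configuration combinations whose posterior transition
#' probability reaches `keep_threshold` survive (the top combination always
#' does). The path count never increases.
#'
#' @param graph a [build_graph()] result.
#' @param posteriors list of boundary posterior tables from the most recent
#'   sampling pass ([forward_backward()] or the engine).
#' @param keep_threshold minimum posterior transition probability (default
#'   0.001).
#' @return the merged graph.
#' @export
merge_segments <- function(graph, posteriors, keep_threshold = 0.001) {
  nseg <- length(graph$segments)
  if (nseg < 2) return(graph)
  new_segments <- list()
  s <- 1L
  while (s <= nseg) {
    if (s + 1L <= nseg) {
      a <- graph$segments[[s]]; b <- graph$segments[[s + 1L]]
      P <- posteriors[[s]]
      keep <- which(P >= keep_threshold, arr.ind = TRUE)
      if (!nrow(keep)) keep <- which(P == max(P), arr.ind = TRUE)[1, , drop = FALSE]
      top <- which(P == max(P), arr.ind = TRUE)[1, ]
      if (!any(keep[, 1] == top[1] & keep[, 2] == top[2]))
        keep <- rbind(keep, top)
      conf1 <- cbind(a$conf1[keep[, 1], , drop = FALSE],
                     b$conf1[keep[, 2], , drop = FALSE])
      conf2 <- cbind(a$conf2[keep[, 1], , drop = FALSE],
                     b$conf2[keep[, 2], , drop = FALSE])
      new_segments[[length(new_segments) + 1L]] <- list(
        sites = c(a$sites, b$sites),
        fixed = c(a$fixed, b$fixed),
        amb = c(a$amb, b$amb + length(a$sites)),
        is_het = c(a$is_het, b$is_het),
        conf1 = conf1, conf2 = conf2)
      s <- s + 2L
    } else {
      new_segments[[length(new_segments) + 1L]] <- graph$segments[[s]]
      s <- s + 1L
    }
  }
  graph$segments <- new_segments
  graph
}
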