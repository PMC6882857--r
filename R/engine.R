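# Run orchestration: sliding windows, the MCMC schedule over burn-in /
# pruning / main iterations, per-individual updates with IBD2 exclusions,
# reference-panel haplotypes in the PBWT, window ligation, and the CLI.

#' Phasing run configuration
#'
#' Defaults reproduce the method's stated defaults: P = 4 PBWT neighbors,
#' arrays stored every 8 variants, 2 Mb windows with 0.25 Mb overlap, the
#' 15-iteration schedule `5b,1p,1b,1p,1b,1p,5m` (3 pruning stages), phase-set
#' error rate 1e-4 and Ne = 15000.
#'
#' @param P PBWT neighbors per query.
#' @param S PBWT storage stride (variants).
#' @param W window size in bp.
#' @param overlap window overlap in bp.
#' @param schedule iteration schedule string over \{b, p, m\}.
#' @param eps phase-set error rate.
#' @param Ne effective population size.
#' @param seed RNG seed for the whole run.
#' @param keep_threshold pruning threshold on posterior transition
#'   probabilities when merging segments.
#' @param ibd2_protection screen for long genotype matches and forbid IBD2
#'   pairs from conditioning on each other (default TRUE; disabling exists
#'   for benchmarking the protection itself).
#' @export
run_config <- function(P = 4L, S = 8L, W = 2e6, overlap = 2.5e5,
                       schedule = "5b,1p,1b,1p,1b,1p,5m", eps = 1e-4,
                       Ne = 15000, seed = 1L, keep_threshold = 0.001,
                       ibd2_protection = TRUE) {
  stopifnot(W > overlap, overlap >= 0, P >= 1, S >= 1)
  its <- parse_schedule(schedule)
  structure(list(P = as.integer(P), S = as.integer(S), W = W,
                 overlap = overlap, schedule = schedule, iterations = its,
                 eps = eps, Ne = Ne, seed = as.integer(seed),
                 keep_threshold = keep_threshold,
                 ibd2_protection = isTRUE(ibd2_protection)),
            class = "run_config")
}

#' Parse an iteration schedule string
#'
#' `"5b,1p,1b,1p,1b,1p,5m"` expands to 15 one-letter iteration types.
#'
#' @param schedule comma-separated `<count><type>` tokens, types b/p/m.
#' @return character vector of iteration types.
#' @export
parse_schedule <- function(schedule) {
  toks <- strsplit(schedule, ",")[[1]]
  out <- character()
  for (tk in toks) {
    m <- regmatches(tk, regexec("^([0-9]+)([bpm])$", trimws(tk)))[[1]]
    if (length(m) != 3) stop("bad schedule token: ", tk)
    out <- c(out, rep(m[3], as.integer(m[2])))
  }
  if (!length(out)) stop("empty schedule")
  out
}

#' Build sliding phasing windows
#'
#' Half-open bp windows `[start, start + W)` advancing by `W - overlap`; a
#' chromosome shorter than `W` yields a single window. Every variant belongs
#' to at least one window and the union of windows covers all variants.
#' Ligation cut points sit at the middle of each overlap.
#'
#' @param vt [variant_table()].
#' @param W window size (bp).
#' @param overlap overlap between consecutive windows (bp).
#' @return data.frame with bp bounds, 1-based site index ranges
#'   (`from`, `to`) and the owned (post-ligation) site range per window.
#' @export
make_windows <- function(vt, W = 2e6, overlap = 2.5e5) {
  stopifnot(W > overlap)
  pos <- vt$pos
  lo <- min(pos); hi <- max(pos)
  if (hi - lo < W) {
    starts <- lo
  } else {
    starts <- seq(lo, hi, by = W - overlap)
    # drop trailing starts whose window adds no new sites
    starts <- starts[c(TRUE, starts[-1] <= hi - 1)]
    while (length(starts) > 1 &&
           starts[length(starts) - 1] + W > hi) starts <- starts[-length(starts)]
  }
  win <- data.frame(start_bp = starts, end_bp = starts + W)
  win$end_bp[nrow(win)] <- hi + 1  # last window absorbs the chromosome tail
  win$from <- vapply(win$start_bp, function(s) which(pos >= s)[1], integer(1))
  win$to <- vapply(win$end_bp, function(e) max(which(pos < e)), integer(1))
  keep <- !is.na(win$from) & win$from <= win$to
  win <- win[keep, , drop = FALSE]
  # owned ranges: the overlap's second half belongs to the later window
  nw <- nrow(win)
  cut <- integer(nw + 1L)
  cut[1] <- win$from[1]
  if (nw > 1) {
    for (w in 2:nw) {
      cb <- win$start_bp[w] + overlap / 2
      cs <- which(pos >= cb)[1]
      cut[w] <- min(max(cs, win$from[w]), win$to[w - 1] + 1L)
    }
  }
  cut[nw + 1L] <- win$to[nw] + 1L
  win$own_from <- cut[seq_len(nw)]
  win$own_to <- cut[-1] - 1L
  rownames(win) <- NULL
  win
}

# Build the per-(window, individual) graph state: genotype graph with
# scaffold applied, window-local phase-set constraints, and the flattened
# argument list for cpp_hmm_run.
build_graph_state <- function(run, w, i) {
  from <- run$windows$from[w]; to <- run$windows$to[w]
  g <- run$gm$codes[i, from:to]
  graph <- build_graph(g, B = 3L)
  sc <- run$scaffold
  if (!is.null(sc) && nrow(sc)) {
    e <- sc[sc$ind == i & sc$var >= from & sc$var <= to, , drop = FALSE]
    if (nrow(e))
      graph <- apply_scaffold(graph, data.frame(site = e$var - from + 1L,
                                                allele = e$allele))
  }
  cons <- NULL
  ps <- run$phase_sets
  if (!is.null(ps) && nrow(ps)) {
    e <- ps[ps$ind == i & ps$var >= from & ps$var <= to, , drop = FALSE]
    if (nrow(e) >= 2) {
      cons <- phase_set_constraints(
        data.frame(site = e$var - from + 1L, ps = e$ps, allele1 = e$allele1),
        eps = run$config$eps)
      # scaffold phase is always prioritized over reads: entries at
      # scaffolded hets are pinned by pruning above, reads only reweight
    }
  }
  cm_local <- run$cm[from:to]
  args <- graph_cpp_args(graph, cm_local, cons, sites_global = from:to)
  list(graph = graph, cons = cons, args = args, version = 1L)
}

#' Create a phasing run object
#'
#' Assembles the mutable state [phase()] iterates over: initialized
#' haplotypes (PBWT initialization), windows, genotype graphs with scaffold
#' pruning and phase-set constraints, IBD2 exclusion triplets, and posterior
#' accumulators. Exposed so single updates can be driven directly (see
#' [update_individual()]).
#'
#' @inheritParams phase
#' @return an environment of class `phasing_run`.
#' @export
phasing_run <- function(gm, vt, config = run_config(), reference = NULL,
                        scaffold = NULL, phase_sets = NULL) {
  run <- new.env(parent = emptyenv())
  run$gm <- gm; run$vt <- vt; run$config <- config
  run$N <- nrow(gm$codes); run$L <- ncol(gm$codes)
  cm <- vt$cm
  if (all(is.na(cm))) cm <- vt$pos / 1e6  # default 1 cM/Mb
  run$cm <- cm
  run$scaffold <- scaffold
  run$phase_sets <- if (is.null(phase_sets)) gm$phase_sets else phase_sets
  set.seed(config$seed)
  H <- pbwt_init_phase(gm, vt, seed = config$seed)
  if (!is.null(reference)) {
    reference <- as.matrix(reference)
    storage.mode(reference) <- "integer"
    if (ncol(reference) != run$L) stop("reference haplotypes must cover the main panel sites")
    H <- rbind(H, reference)
  }
  run$H <- H
  run$M <- nrow(H)
  run$windows <- make_windows(vt, config$W, config$overlap)
  nw <- nrow(run$windows)
  run$stores0 <- sort(unique(c(seq(0L, run$L - 1L, by = config$S),
                               run$windows$to - 1L, run$L - 1L)))
  run$win_cols0 <- lapply(seq_len(nw), function(w) {
    which(run$stores0 >= run$windows$from[w] - 1L &
          run$stores0 <= run$windows$to[w] - 1L) - 1L
  })
  # IBD2 constraints, computed once: genotypes never change. The span
  # threshold is W, capped at the chromosome span so that full-chromosome
  # matches still register when the region is shorter than one window.
  run$ibd2 <- if (config$ibd2_protection) {
    span <- max(vt$pos) - min(vt$pos)
    matches <- pbwt_long_genotype_matches(gm, vt,
                                          min_span = min(config$W, span))
    ibd2_constraints(matches, run$windows)
  } else {
    data.frame(i = integer(), j = integer(), w = integer())
  }
  run$ibd2_excl <- lapply(seq_len(nw), function(w) {
    ex <- vector("list", run$N)
    hit <- run$ibd2[run$ibd2$w == w, , drop = FALSE]
    for (r in seq_len(nrow(hit))) {
      i <- hit$i[r]; j <- hit$j[r]
      ex[[i]] <- c(ex[[i]], 2L * j - 2L, 2L * j - 1L)
      ex[[j]] <- c(ex[[j]], 2L * i - 2L, 2L * i - 1L)
    }
    ex
  })
  run$graphs <- lapply(seq_len(nw), function(w)
    lapply(seq_len(run$N), function(i) build_graph_state(run, w, i)))
  run$acc <- lapply(seq_len(nw), function(w)
    lapply(seq_len(run$N), function(i) list(post = NULL, marg = NULL,
                                            n = 0L, version = 0L)))
  run$pb <- NULL
  run$stats <- data.frame(iteration = integer(), type = character(),
                          mean_K = numeric())
  class(run) <- "phasing_run"
  run
}

#' Rebuild the PBWT of the current haplotype estimates
#'
#' Called once per MCMC iteration before any individual update.
#'
#' @param run a [phasing_run()] object.
#' @export
rebuild_pbwt <- function(run) {
  run$pb <- cpp_pbwt_build(run$H, run$stores0)
  # window-sequence hashes for conditioning-set collapse, once per rebuild
  run$win_hash <- lapply(seq_len(nrow(run$windows)), function(w)
    cpp_hash_window(run$H, run$windows$from[w] - 1L, run$windows$to[w] - 1L))
  invisible(run)
}

#' Update one individual in one window
#'
#' Selects the conditioning set by PBWT interrogation (excluding the
#' individual's own haplotypes and any IBD2 partners in this window), runs
#' the diploid Li-Stephens forward pass, samples a new haplotype pair, and
#' writes it into the current estimates. Pruning iterations additionally
#' merge graph segments; main iterations accumulate boundary posteriors.
#'
#' @param run a [phasing_run()] object with a current PBWT
#'   ([rebuild_pbwt()]).
#' @param i individual index.
#' @param window window index.
#' @param iteration_type one of `"b"`, `"p"`, `"m"`.
#' @param P PBWT neighbors per query (default from the run config).
#' @return the conditioning-set size K, invisibly.
#' @export
update_individual <- function(run, i, window, iteration_type = "b",
                              P = run$config$P) {
  if (is.null(run$pb)) stop("call rebuild_pbwt() before updating")
  w <- window
  st <- run$graphs[[w]][[i]]
  excl <- run$ibd2_excl[[w]][[i]]
  if (is.null(excl)) excl <- integer()
  h1 <- 2L * i - 2L; h2 <- 2L * i - 1L
  cond <- cpp_select_conditioning(run$pb$A, run$pb$D, run$pb$I,
                                  run$stores0, run$win_cols0[[w]],
                                  h1, h2, P, excl, run$win_hash[[w]])
  if (!length(cond))
    stop("empty conditioning set for individual ", i, " in window ", w,
         "; widen P")
  want_post <- iteration_type %in% c("p", "m")
  a <- st$args
  res <- cpp_hmm_run(a$seg_sites, a$seg_fixed, a$seg_amb, a$seg_conf1,
                     a$seg_conf2, a$seg_wt, a$bound_wt, a$bound_gcm,
                     cond, run$H, run$config$Ne, run$M,
                     1L, want_post, h1, h2)
  if (iteration_type == "p") {
    if (length(st$graph$segments) > 1) {
      g2 <- merge_segments(st$graph, res$post, run$config$keep_threshold)
      from <- run$windows$from[w]; to <- run$windows$to[w]
      st$graph <- g2
      st$args <- graph_cpp_args(g2, run$cm[from:to], st$cons,
                                sites_global = from:to)
      st$version <- st$version + 1L
      run$graphs[[w]][[i]] <- st
    }
  } else if (iteration_type == "m") {
    acc <- run$acc[[w]][[i]]
    if (acc$version != st$version) {
      acc <- list(post = NULL, marg = NULL, n = 0L, version = st$version)
    }
    if (is.null(acc$post)) {
      acc$post <- res$post
      acc$marg <- res$marg
    } else {
      for (s in seq_along(res$post)) acc$post[[s]] <- acc$post[[s]] + res$post[[s]]
      for (s in seq_along(res$marg)) acc$marg[[s]] <- acc$marg[[s]] + res$marg[[s]]
    }
    acc$n <- acc$n + 1L
    run$acc[[w]][[i]] <- acc
  }
  invisible(res$K)
}

#' Phase a panel of genotypes
#'
#' Full run: PBWT initialization, IBD2 screening, then the MCMC schedule
#' (PBWT rebuilt once per iteration, every individual updated in every
#' window in a seeded random order), the final max-product solve from
#' averaged transition tables, and window ligation. Deterministic given the
#' seed in `config`.
#'
#' @param gm [genotype_matrix()] (QC'd; see [apply_qc_filters()]).
#' @param vt [variant_table()] with genetic positions (`cm`); a flat
#'   1 cM/Mb map is assumed when absent.
#' @param config a [run_config()].
#' @param reference optional 2R x L matrix of reference haplotypes aligned
#'   to `vt` (appended to the PBWT, never updated).
#' @param scaffold optional [read_scaffold()]/[simulate_scaffold()]
#'   data.frame; scaffolded phase is enforced exactly.
#' @param phase_sets optional phase-set annotations (defaults to
#'   `gm$phase_sets`); set to `empty_phase_sets()` to ignore reads.
#' @return list with `haplotypes` (2N x L), `certainty` (N x L posterior of
#'   the solved configuration at ambiguous sites, NA elsewhere), `stats`
#'   (per-iteration mean conditioning-set size K) and `run` internals.
#' @export
phase <- function(gm, vt, config = run_config(), reference = NULL,
                  scaffold = NULL, phase_sets = NULL) {
  run <- phasing_run(gm, vt, config, reference, scaffold, phase_sets)
  nw <- nrow(run$windows)
  for (it in seq_along(config$iterations)) {
    type <- config$iterations[it]
    rebuild_pbwt(run)
    ks <- numeric(0)
    order_i <- sample.int(run$N)
    for (w in seq_len(nw)) {
      for (i in order_i) {
        k <- update_individual(run, i, w, type, config$P)
        ks <- c(ks, k)
      }
    }
    run$stats <- rbind(run$stats,
                       data.frame(iteration = it, type = type,
                                  mean_K = mean(ks)))
  }
  # final solve per window, then ligation
  pieces <- lapply(seq_len(nw), function(w) {
    from <- run$windows$from[w]; to <- run$windows$to[w]
    Lw <- to - from + 1L
    h1 <- matrix(0L, run$N, Lw); h2 <- matrix(0L, run$N, Lw)
    pp <- matrix(NA_real_, run$N, Lw)
    for (i in seq_len(run$N)) {
      st <- run$graphs[[w]][[i]]
      sol <- accumulate_and_solve(st$graph, run$acc[[w]][[i]])
      h1[i, ] <- sol$h1; h2[i, ] <- sol$h2
      for (s in seq_along(st$graph$segments)) {
        sg <- st$graph$segments[[s]]
        if (length(sg$amb)) pp[i, sg$sites[sg$amb]] <- sol$certainty[s]
      }
    }
    list(h1 = h1, h2 = h2, pp = pp)
  })
  lig <- ligate_windows(pieces, run$windows, vt, scaffold = run$scaffold)
  list(haplotypes = lig$hap, certainty = lig$certainty, stats = run$stats,
       windows = run$windows, ibd2 = run$ibd2, config = config, run = run)
}

#' Ligate per-window haplotypes into chromosome-wide estimates
#'
#' For each individual the relative orientation between consecutive windows
#' is chosen by majority vote over the phase agreement of hets shared with
#' the already-ligated left part; ties keep the current orientation, zero
#' shared hets keep it with a warning. Windows containing scaffold entries
#' are never flipped (the scaffold anchors the orientation). Each variant is
#' emitted exactly once: the second half of every overlap comes from the
#' later window.
#'
#' @param pieces list per window of `list(h1, h2, pp)` matrices (N x Lw).
#' @param windows a [make_windows()] result.
#' @param vt [variant_table()].
#' @param scaffold optional scaffold data.frame (orientation anchor).
#' @return list `hap` (2N x L), `certainty` (N x L).
#' @export
ligate_windows <- function(pieces, windows, vt, scaffold = NULL) {
  nw <- nrow(windows)
  N <- nrow(pieces[[1]]$h1)
  L <- nrow(vt)
  h1 <- matrix(NA_integer_, N, L); h2 <- matrix(NA_integer_, N, L)
  pp <- matrix(NA_real_, N, L)
  for (i in seq_len(N)) {
    for (w in seq_len(nw)) {
      from <- windows$from[w]; to <- windows$to[w]
      c1 <- pieces[[w]]$h1[i, ]; c2 <- pieces[[w]]$h2[i, ]
      flip <- FALSE
      if (w > 1) {
        shared <- from:min(windows$to[w - 1], to)
        het <- !is.na(h1[i, shared]) & h1[i, shared] != h2[i, shared] &
          c1[shared - from + 1L] != c2[shared - from + 1L]
        sh <- shared[het]
        if (!length(sh)) {
          warning(sprintf("no shared hets for individual %d between windows %d-%d; keeping orientation",
                          i, w - 1, w))
        } else {
          agree <- sum(h1[i, sh] == c1[sh - from + 1L])
          flip <- agree < length(sh) - agree  # strict majority to flip
        }
        anchored <- !is.null(scaffold) && nrow(scaffold) &&
          any(scaffold$ind == i & scaffold$var >= from & scaffold$var <= to)
        if (anchored) flip <- FALSE
      }
      if (flip) { tmp <- c1; c1 <- c2; c2 <- tmp }
      own <- windows$own_from[w]:windows$own_to[w]
      h1[i, own] <- c1[own - from + 1L]
      h2[i, own] <- c2[own - from + 1L]
      pp[i, own] <- pieces[[w]]$pp[i, own - from + 1L]
    }
  }
  hap <- matrix(NA_integer_, 2L * N, L)
  hap[seq(1, 2 * N, 2), ] <- h1
  hap[seq(2, 2 * N, 2), ] <- h2
  list(hap = hap, certainty = pp)
}

#' Read reference haplotypes from a phased VCF
#'
#' Returns the phased haplotypes of a reference panel restricted to the
#' overlap with the main panel (allele-swapped records are flipped).
#'
#' @param vcf_path phased reference VCF.
#' @param main [variant_table()] of the main panel.
#' @return list `haps` (2R x n_overlap), `main_idx` (main-panel sites in
#'   the overlap).
#' @export
read_reference_haplotypes <- function(vcf_path, main) {
  rf <- read_vcf_core(vcf_path)
  ov <- intersect_with_reference(main, rf$vt)
  gt <- rf$gt[ov$ref_idx, , drop = FALSE]
  if (any(!grepl("|", gt, fixed = TRUE)))
    stop("reference panel must be fully phased")
  R <- ncol(gt)
  a1 <- matrix(as.integer(substr(gt, 1, 1)), ncol = R)
  a2 <- matrix(as.integer(substr(gt, 3, 3)), ncol = R)
  if (any(ov$flip)) {
    a1[ov$flip, ] <- 1L - a1[ov$flip, ]
    a2[ov$flip, ] <- 1L - a2[ov$flip, ]
  }
  haps <- matrix(0L, 2L * R, nrow(a1))
  haps[seq(1, 2 * R, 2), ] <- t(a1)
  haps[seq(2, 2 * R, 2), ] <- t(a2)
  list(haps = haps, main_idx = ov$main_idx)
}

#' Command-line interface
#'
#' `--input` and `--output` are required; see the README for the full flag
#' list. Returns an exit code (0 on success) rather than quitting, so it
#' can be driven from wrapper scripts and tests.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--input", type = "character", help = "unphased genotype VCF"),
    optparse::make_option("--output", type = "character", help = "phased output VCF"),
    optparse::make_option("--map", type = "character", default = NULL, help = "genetic map"),
    optparse::make_option("--region", type = "character", default = NULL),
    optparse::make_option("--reference", type = "character", default = NULL, help = "phased reference VCF"),
    optparse::make_option("--scaffold", type = "character", default = NULL, help = "phased scaffold VCF"),
    optparse::make_option("--use-ps", type = "double", default = 1e-4, dest = "use_ps",
                          help = "phase-set error rate; 0 disables phase sets"),
    optparse::make_option("--pbwt-depth", type = "integer", default = 4L, dest = "pbwt_depth"),
    optparse::make_option("--pbwt-modulo", type = "integer", default = 8L, dest = "pbwt_modulo"),
    optparse::make_option("--window", type = "double", default = 2e6),
    optparse::make_option("--mcmc-iterations", type = "character",
                          default = "5b,1p,1b,1p,1b,1p,5m", dest = "mcmc_iterations"),
    optparse::make_option("--ne", type = "integer", default = 15000L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--log", type = "character", default = NULL)
  )
  parser <- optparse::OptionParser(option_list = spec, prog = "haplophaser")
  opt <- tryCatch(optparse::parse_args(parser, args = argv),
                  error = function(e) NULL)
  if (is.null(opt) || is.null(opt$input) || is.null(opt$output)) {
    optparse::print_help(parser)
    return(1L)
  }
  status <- tryCatch({
    dat <- read_genotypes(opt$input, region = opt$region)
    qc <- apply_qc_filters(dat$gm, dat$vt)
    gm <- qc$gm; vt <- qc$vt
    if (!is.null(opt$map)) {
      map <- read_genetic_map(opt$map)
      vt$cm <- interpolate_cm(map, vt$pos)
    }
    reference <- NULL
    if (!is.null(opt$reference)) {
      rf <- read_reference_haplotypes(opt$reference, vt)
      keep <- rf$main_idx   # only the overlap with the reference is phased
      vt <- vt[keep, , drop = FALSE]
      class(vt) <- c("variant_table", "data.frame")
      ps <- gm$phase_sets
      vmap <- match(seq_len(ncol(gm$codes)), keep)
      if (nrow(ps)) {
        ps$var <- vmap[ps$var]
        ps <- ps[!is.na(ps$var), , drop = FALSE]
      }
      gm <- genotype_matrix(gm$codes[, keep, drop = FALSE], gm$samples, ps)
      reference <- rf$haps
    }
    scaffold <- if (!is.null(opt$scaffold)) read_scaffold(opt$scaffold, vt, gm) else NULL
    phase_sets <- if (opt$use_ps > 0) gm$phase_sets else empty_phase_sets()
    config <- run_config(P = opt$pbwt_depth, S = opt$pbwt_modulo,
                         W = opt$window, schedule = opt$mcmc_iterations,
                         eps = if (opt$use_ps > 0) opt$use_ps else 1e-4,
                         Ne = opt$ne, seed = opt$seed)
    t0 <- Sys.time()
    res <- phase(gm, vt, config, reference = reference, scaffold = scaffold,
                 phase_sets = phase_sets)
    write_phased_vcf(opt$output, vt, res$haplotypes, gm$samples,
                     certainty = res$certainty)
    if (!is.null(opt$log)) {
      lines <- c(sprintf("haplophaser run: N=%d L=%d windows=%d seed=%d",
                         nrow(gm$codes), ncol(gm$codes),
                         nrow(res$windows), opt$seed),
                 sprintf("iteration %d [%s]: mean K = %.1f",
                         res$stats$iteration, res$stats$type, res$stats$mean_K),
                 sprintf("elapsed: %.1f s",
                         as.numeric(difftime(Sys.time(), t0, units = "secs"))))
      writeLines(lines, opt$log)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  status
}
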