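# Windows, schedule parsing, ligation, the full phasing loop, constraints
# and the CLI.

test_that("make_windows covers every variant with the stated geometry", {
  # chromosome shorter than W: one window
  vt <- variant_table("1", sort(sample.int(1e6, 200)))
  w1 <- make_windows(vt, W = 2e6, overlap = 2.5e5)
  expect_equal(nrow(w1), 1)
  expect_equal(w1$from, 1)
  expect_equal(w1$to, 200)
  # long chromosome: starts advance by W - overlap, coverage is complete,
  # owned ranges partition the sites
  set.seed(10)
  vt2 <- variant_table("1", sort(sample.int(7e6, 900)))
  w2 <- make_windows(vt2, W = 2e6, overlap = 2.5e5)
  expect_gt(nrow(w2), 2)
  expect_equal(diff(w2$start_bp), rep(2e6 - 2.5e5, nrow(w2) - 1))
  covered <- sort(unique(unlist(lapply(seq_len(nrow(w2)), function(w)
    w2$from[w]:w2$to[w]))))
  expect_equal(covered, 1:900)
  owned <- unlist(lapply(seq_len(nrow(w2)), function(w)
    w2$own_from[w]:w2$own_to[w]))
  expect_equal(owned, 1:900)  # exactly once, in order
  # consecutive windows overlap in sites
  for (w in 2:nrow(w2)) expect_lte(w2$from[w], w2$to[w - 1])
})

test_that("parse_schedule expands the default to 15 iterations, 3 prunings", {
  its <- parse_schedule("5b,1p,1b,1p,1b,1p,5m")
  expect_length(its, 15)
  expect_equal(sum(its == "p"), 3)
  expect_equal(sum(its == "m"), 5)
  expect_equal(its[1:5], rep("b", 5))
  expect_equal(parse_schedule("2b,3m"), c("b", "b", "m", "m", "m"))
  expect_error(parse_schedule("5x"), "bad schedule")
  expect_error(parse_schedule(""), "bad schedule|empty")
})

test_that("ligate_windows recovers planted window orientations", {
  set.seed(12)
  ts <- make_panel(N = 6, L = 300, founders = 10, seed = 12,
                   bp_length = 360000, recomb_per_bp = 1e-5)
  win <- make_windows(ts$vt, W = 2e5, overlap = 5e4)
  expect_gte(nrow(win), 2)
  N <- 6
  flips <- matrix(rbinom(N * nrow(win), 1, 0.5) == 1, N)
  flips[, 1] <- FALSE
  pieces <- lapply(seq_len(nrow(win)), function(w) {
    idx <- win$from[w]:win$to[w]
    h1 <- ts$hap[seq(1, 2 * N, 2), idx, drop = FALSE]
    h2 <- ts$hap[seq(2, 2 * N, 2), idx, drop = FALSE]
    for (i in seq_len(N)) if (flips[i, w]) { tmp <- h1[i, ]; h1[i, ] <- h2[i, ]; h2[i, ] <- tmp }
    list(h1 = h1, h2 = h2, pp = matrix(1, N, length(idx)))
  })
  lig <- suppressWarnings(ligate_windows(pieces, win, ts$vt))
  # ligation can only fix orientation up to a global flip per individual
  for (i in seq_len(N)) {
    hets <- which(ts$gm$codes[i, ] == 1L)
    if (length(hets) < 2) next
    expect_equal(switch_error_rate(
      list(h1 = lig$hap[2 * i - 1, ], h2 = lig$hap[2 * i, ]),
      list(h1 = ts$hap[2 * i - 1, ], h2 = ts$hap[2 * i, ]), hets), 0)
  }
  # identical overlap phases: concatenation unchanged
  pieces0 <- lapply(seq_len(nrow(win)), function(w) {
    idx <- win$from[w]:win$to[w]
    list(h1 = ts$hap[seq(1, 2 * N, 2), idx, drop = FALSE],
         h2 = ts$hap[seq(2, 2 * N, 2), idx, drop = FALSE],
         pp = matrix(1, N, length(idx)))
  })
  lig0 <- suppressWarnings(ligate_windows(pieces0, win, ts$vt))
  expect_equal(lig0$hap, ts$hap, ignore_attr = TRUE)
})

test_that("phase is deterministic, genotype-consistent and improves on init", {
  ts <- make_panel(N = 40, L = 300, founders = 8, seed = 21)
  cfg <- run_config(seed = 5)
  res1 <- phase(ts$gm, ts$vt, cfg)
  res2 <- phase(ts$gm, ts$vt, cfg)
  expect_identical(res1$haplotypes, res2$haplotypes)
  expect_identical(res1$certainty, res2$certainty)
  expect_true(hap_consistent(res1$haplotypes, ts$gm$codes))
  # byte-identical VCF output
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_phased_vcf(f1, ts$vt, res1$haplotypes, ts$gm$samples, res1$certainty)
  write_phased_vcf(f2, ts$vt, res2$haplotypes, ts$gm$samples, res2$certainty)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed gives a different (but still consistent) answer
  res3 <- phase(ts$gm, ts$vt, run_config(seed = 6))
  expect_true(hap_consistent(res3$haplotypes, ts$gm$codes))
  # accuracy: better than the initialization
  Hi <- pbwt_init_phase(ts$gm, ts$vt, seed = 5)
  expect_lt(mean_ser(res1$haplotypes, ts), mean_ser(Hi, ts))
  # stats carry one mean-K row per iteration
  expect_equal(nrow(res1$stats), 15)
  expect_true(all(res1$stats$mean_K >= 1))
  # certainty lies in [0, 1] at het sites
  pp <- res1$certainty[!is.na(res1$certainty)]
  expect_true(all(pp >= 0 & pp <= 1 + 1e-12))
})

test_that("a perfect scaffold is enforced exactly", {
  ts <- make_panel(N = 25, L = 250, founders = 8, seed = 31)
  sc <- simulate_scaffold(ts, coverage_fraction = 0.3, seed = 2)
  res <- phase(ts$gm, ts$vt, run_config(seed = 3), scaffold = sc)
  H <- res$haplotypes
  agree <- vapply(seq_len(nrow(sc)), function(r)
    H[2 * sc$ind[r] - 1, sc$var[r]] == sc$allele[r], logical(1))
  expect_true(all(agree))
  expect_true(hap_consistent(H, ts$gm$codes))
})

test_that("update_individual applies IBD2 exclusions", {
  ts <- make_panel(N = 16, L = 220, founders = 6, seed = 41)
  gm <- ts$gm
  gm$codes[2, ] <- gm$codes[1, ]    # exact duplicate pair
  cfg <- run_config(seed = 9)
  run <- phasing_run(gm, ts$vt, cfg)
  expect_true(any(run$ibd2$i == 1 & run$ibd2$j == 2))
  rebuild_pbwt(run)
  # neither conditions on the other in any window
  for (w in seq_len(nrow(run$windows))) {
    cond1 <- haplophaser:::cpp_select_conditioning(
      run$pb$A, run$pb$D, run$pb$I, run$stores0, run$win_cols0[[w]],
      0L, 1L, cfg$P, run$ibd2_excl[[w]][[1]], run$win_hash[[w]])
    expect_false(any(cond1 %in% c(2L, 3L)))  # 0-based rows of individual 2
    cond2 <- haplophaser:::cpp_select_conditioning(
      run$pb$A, run$pb$D, run$pb$I, run$stores0, run$win_cols0[[w]],
      2L, 3L, cfg$P, run$ibd2_excl[[w]][[2]], run$win_hash[[w]])
    expect_false(any(cond2 %in% c(0L, 1L)))
  }
  # the run completes using the remaining samples
  res <- phase(gm, ts$vt, cfg)
  expect_true(hap_consistent(res$haplotypes, gm$codes))
})

test_that("reference haplotypes join the PBWT and help conditioning", {
  ts <- make_panel(N = 15, L = 200, founders = 6, seed = 51)
  # a reference panel that contains the truth of every individual
  run <- phasing_run(ts$gm, ts$vt, run_config(seed = 1), reference = ts$hap)
  expect_equal(run$M, 4 * 15)
  rebuild_pbwt(run)
  w <- 1
  cond <- haplophaser:::cpp_select_conditioning(
    run$pb$A, run$pb$D, run$pb$I, run$stores0, run$win_cols0[[w]],
    0L, 1L, 4L, integer(), run$win_hash[[w]])
  expect_true(any(cond >= 30))   # reference rows appear in K
  res <- phase(ts$gm, ts$vt, run_config(seed = 1), reference = ts$hap)
  expect_true(hap_consistent(res$haplotypes, ts$gm$codes))
  # with its own truth present in the panel, phasing is near perfect
  expect_lt(mean_ser(res$haplotypes, ts), 0.02)
})

test_that("read_reference_haplotypes extracts the phased overlap", {
  ts <- make_panel(N = 10, L = 60, founders = 6, seed = 71)
  fref <- tempfile(fileext = ".vcf")
  write_phased_vcf(fref, ts$vt, ts$hap, ts$gm$samples)
  # main panel missing some reference sites, plus one site of its own
  main <- ts$vt[seq(1, 60, 2), , drop = FALSE]
  class(main) <- c("variant_table", "data.frame")
  suppressMessages(rf <- read_reference_haplotypes(fref, main))
  expect_equal(rf$main_idx, 1:30)
  expect_equal(rf$haps, ts$hap[, seq(1, 60, 2)], ignore_attr = TRUE)
  # an unphased reference is rejected
  fbad <- tempfile(fileext = ".vcf")
  gm <- ts$gm
  write_genotype_vcf(fbad, ts$vt, gm)
  expect_error(suppressMessages(read_reference_haplotypes(fbad, main)),
               "phased")
})

test_that("run_cli wires files end to end and is seeded", {
  ts <- make_panel(N = 20, L = 150, founders = 6, seed = 61)
  fin <- tempfile(fileext = ".vcf")
  write_genotype_vcf(fin, ts$vt, ts$gm)
  fmap <- tempfile()
  writeLines(c("position rate cM", "1 1.0 0.000001",
               sprintf("%d 1.0 %.6f", max(ts$vt$pos), max(ts$vt$pos) / 1e6)),
             fmap)
  fout <- tempfile(fileext = ".vcf")
  flog <- tempfile()
  st <- run_cli(c("--input", fin, "--output", fout, "--map", fmap,
                  "--seed", "4", "--log", flog))
  expect_equal(st, 0L)
  out <- read_genotypes(fout)
  expect_equal(out$gm$codes, ts$gm$codes, ignore_attr = TRUE)
  # output genotypes are phased ("|"), none unphased
  gtline <- grep("^1\t", readLines(fout), value = TRUE)[1]
  expect_false(grepl("[0-9]/[0-9]", gtline))
  expect_true(file.exists(flog))
  expect_match(paste(readLines(flog), collapse = "\n"), "mean K")
  # determinism across invocations
  fout2 <- tempfile(fileext = ".vcf")
  st2 <- run_cli(c("--input", fin, "--output", fout2, "--map", fmap,
                   "--seed", "4"))
  expect_equal(st2, 0L)
  expect_identical(readLines(fout), readLines(fout2))
  # missing --input: usage and nonzero exit
  expect_output(st3 <- run_cli(c("--output", fout)), "Usage|usage|help")
  expect_gt(st3, 0)
  # schedule flag is honoured
  st4 <- run_cli(c("--input", fin, "--output", tempfile(fileext = ".vcf"),
                   "--mcmc-iterations", "1b,1m", "--seed", "1"))
  expect_equal(st4, 0L)
})
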