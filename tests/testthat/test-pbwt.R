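# PBWT construction, neighbor queries, long genotype matches and the
# phase initialization sweep, checked against the brute-force oracles in
# helper-oracles.R.

test_that("pbwt_build matches the reversed-prefix stable-sort oracle", {
  # the worked 4-haplotype example
  H <- rbind(c(1, 0, 1), c(0, 0, 1), c(1, 1, 0), c(0, 0, 0))
  pb <- pbwt_build(H, store_sites = 1:3)
  for (ci in 1:3) {
    o <- oracle_pbwt(H, ci)
    expect_equal(pb$A[, ci], o$A)
    expect_equal(pb$D[, ci], o$D)
    expect_equal(pb$I[, ci], o$I)
  }
  # identical haplotypes: stable sort of equal keys keeps identity order
  Hi <- matrix(1L, 6, 10)
  pbi <- pbwt_build(Hi, stride = 4)
  for (ci in seq_along(pbi$sites)) expect_equal(pbi$A[, ci], 1:6)

  set.seed(41)
  for (rep in 1:25) {
    M <- sample(4:30, 1); L <- sample(5:60, 1)
    H <- matrix(rbinom(M * L, 1, runif(1, 0.2, 0.8)), M, L)
    pb <- pbwt_build(H, stride = sample(2:8, 1))
    for (ci in seq_along(pb$sites)) {
      o <- oracle_pbwt(H, pb$sites[ci])
      expect_identical(pb$A[, ci], as.integer(o$A))
      expect_identical(pb$D[, ci], as.integer(o$D))
      expect_identical(pb$I[, ci], as.integer(o$I))
    }
  }
})

test_that("pbwt_build rejects non-binary input and validates invariants", {
  H <- matrix(sample(0:1, 50, TRUE), 5, 10)
  H[2, 3] <- 2L
  expect_error(pbwt_build(H), "non-binary")
  H[2, 3] <- 0L
  pb <- pbwt_build(H, stride = 3)
  for (ci in seq_along(pb$sites)) {
    l <- pb$sites[ci]
    expect_setequal(pb$A[, ci], 1:5)                 # permutation
    expect_true(all(pb$D[, ci] <= l + 1))
    expect_equal(pb$I[cbind(pb$A[, ci], ci)], 1:5)   # locator inverts A
    # adjacent ranks share the span [D, l]
    for (r in 2:5) {
      d <- pb$D[r, ci]
      if (d <= l)
        expect_equal(H[pb$A[r, ci], d:l], H[pb$A[r - 1, ci], d:l])
    }
  }
})

test_that("pbwt_neighbors returns the longest-prefix neighbors", {
  # an exact duplicate is always the first neighbor
  set.seed(7)
  H <- matrix(rbinom(10 * 20, 1, 0.5), 10, 20)
  H <- rbind(H, H[3, ])
  pb <- pbwt_build(H, stride = 5)
  expect_equal(pbwt_neighbors(pb, 11, 20, 1)[1], 3)

  for (rep in 1:20) {
    M <- sample(6:20, 1); L <- sample(8:40, 1)
    H <- matrix(rbinom(M * L, 1, 0.5), M, L)
    pb <- pbwt_build(H, stride = 4)
    hap <- sample(M, 1)
    l <- sample(pb$sites, 1)
    P <- sample(1:5, 1)
    expect_equal(as.integer(pbwt_neighbors(pb, hap, l, P)),
                 oracle_neighbors(H, hap, l, P))
    # exhaustion: P >= M - 1 returns all other haplotypes
    expect_setequal(as.integer(pbwt_neighbors(pb, hap, l, M - 1)),
                    setdiff(1:M, hap))
  }
})

test_that("pbwt_neighbors match lengths are maximal and honour exclusions", {
  set.seed(13)
  for (rep in 1:10) {
    M <- 16; L <- 30
    H <- matrix(rbinom(M * L, 1, 0.5), M, L)
    pb <- pbwt_build(H, stride = 6)
    hap <- sample(M, 1)
    l <- sample(pb$sites, 1)
    excl <- sample(setdiff(1:M, hap), 3)
    got <- pbwt_neighbors(pb, hap, l, 4, exclude = excl)
    expect_length(intersect(as.integer(got), excl), 0)
    # no unreturned haplotype has a strictly longer match than the worst
    # returned one
    starts <- vapply(1:M, function(h) oracle_match_start(H, hap, h, l), integer(1))
    worst <- max(starts[as.integer(got)])
    others <- setdiff(1:M, c(hap, excl, as.integer(got)))
    if (length(others)) expect_true(all(starts[others] >= worst))
  }
})

test_that("select_conditioning_set collapses, bounds K and excludes the pair", {
  # many copies of one haplotype collapse to K = 1
  H <- matrix(rep(c(0L, 1L, 1L, 0L, 1L, 0L, 0L, 1L), each = 12), 12, 8)
  pb <- pbwt_build(H, stride = 3)
  cs <- select_conditioning_set(pb, c(1, 2), c(1, 8), P = 3)
  expect_length(cs, 1)

  set.seed(23)
  H <- matrix(rbinom(20 * 40, 1, 0.5), 20, 40)
  S <- 8
  pb <- pbwt_build(H, stride = S)
  cs <- select_conditioning_set(pb, c(5, 6), c(1, 40), P = 4)
  expect_false(any(c(5, 6) %in% cs))
  n_stored <- sum(pb$sites >= 1 & pb$sites <= 40)
  expect_lte(length(cs), 2 * 4 * n_stored)      # K <= 2 L P / S
  expect_lte(length(cs), 2 * 40 * 4 / S + 2 * 4)  # stated collapse bound
  # excluding everything errors with advice
  expect_error(select_conditioning_set(pb, c(5, 6), c(1, 40), P = 2,
                                       exclude = setdiff(1:20, 5:6)),
               "widen P")
})

test_that("pbwt_long_genotype_matches equals the all-pairs oracle", {
  set.seed(31)
  for (rep in 1:12) {
    N <- sample(5:25, 1); L <- sample(10:60, 1)
    miss <- sample(c(0, 0, 0.05, 0.15), 1)
    G <- rand_genotypes(N, L, miss)
    pos <- sort(sample.int(L * 100, L))
    span <- sample(c(50, 200, 1000), 1)
    gm <- genotype_matrix(G)
    vt <- variant_table("1", pos)
    got <- pbwt_long_genotype_matches(gm, vt, min_span = span)
    want <- oracle_long_matches(G, pos, span)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
})

test_that("identical individuals yield IBD2 constraints in every window", {
  ts <- make_panel(N = 20, L = 200, founders = 6, seed = 5)
  gm <- ts$gm
  gm$codes[2, ] <- gm$codes[1, ]   # duplicate pair (1, 2)
  win <- make_windows(ts$vt, W = 1e5, overlap = 2e4)
  m <- pbwt_long_genotype_matches(gm, ts$vt, min_span = 1e5)
  cons <- ibd2_constraints(m, win)
  hit <- cons[cons$i == 1 & cons$j == 2, ]
  expect_setequal(hit$w, seq_len(nrow(win)))
})

test_that("sibling IBD2 region constrains only fully contained windows", {
  set.seed(11)
  ts <- make_panel(N = 12, L = 400, founders = 8, seed = 9)
  gm <- ts$gm
  half <- 1:200
  gm$codes[4, half] <- gm$codes[3, half]  # IBD2 over the left half only
  win <- make_windows(ts$vt, W = 1e5, overlap = 2e4)
  span_bp <- ts$vt$pos[200] - ts$vt$pos[1]
  m <- pbwt_long_genotype_matches(gm, ts$vt, min_span = 1e5)
  cons <- ibd2_constraints(m, win)
  hit <- cons[cons$i == 3 & cons$j == 4, ]
  inside <- which(win$to <= 200)
  # every constrained window lies inside the planted region (the random
  # background may or may not extend the match, never shrink it)
  expect_true(all(hit$w %in% which(win$from >= 1 & win$to <= 230)))
  expect_true(all(inside %in% hit$w))
})

test_that("pbwt_init_phase is genotype-consistent, seeded, and sane", {
  ts <- make_panel(N = 30, L = 250, founders = 8, seed = 3)
  H1 <- pbwt_init_phase(ts$gm, ts$vt, seed = 42)
  H2 <- pbwt_init_phase(ts$gm, ts$vt, seed = 42)
  H3 <- pbwt_init_phase(ts$gm, ts$vt, seed = 43)
  expect_identical(H1, H2)
  expect_false(identical(H1, H3))
  expect_true(hap_consistent(H1, ts$gm$codes))
  # an individual with zero hets gets genotype/2 everywhere
  gm2 <- ts$gm
  gm2$codes[5, ] <- 2L * rbinom(250, 1, 0.5)
  H <- pbwt_init_phase(gm2, ts$vt, seed = 1)
  expect_equal(H[9, ], gm2$codes[5, ] %/% 2L)
  expect_equal(H[10, ], gm2$codes[5, ] %/% 2L)
  # missing genotypes get imputed alleles, both haplotypes defined
  gm3 <- ts$gm
  gm3$codes[1, c(3, 50)] <- NA_integer_
  H <- pbwt_init_phase(gm3, ts$vt, seed = 1)
  expect_true(all(H[1:2, c(3, 50)] %in% 0:1))
})
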