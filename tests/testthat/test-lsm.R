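# Diploid Li-Stephens model: closed forms, forward-backward vs exhaustive
# enumeration, stochastic traceback, and the final max-product solve.

test_that("transition_probs matches the stated closed form", {
  # no recombination
  expect_equal(unname(transition_probs(0, 5, 15000, 10)), c(1, 0))
  # stationary limit
  tp <- transition_probs(1e9, 4, 15000, 10)
  expect_equal(unname(tp), c(0.25, 0.25), tolerance = 1e-12)
  # rho/K = 1 with K = 4: choose g so 4 Ne (g/100) / n_hap = 4
  Ne <- 15000; n_hap <- 100
  g <- 4 * n_hap * 100 / (4 * Ne)
  tp <- transition_probs(g, 4, Ne, n_hap)
  sw <- (1 - exp(-1)) / 4
  expect_equal(unname(tp), c(exp(-1) + sw, sw), tolerance = 1e-12)
  # stay + (K-1) switch = 1 over a grid
  for (g in c(0.001, 0.1, 2, 40)) for (K in c(1, 2, 7, 33)) {
    tp <- transition_probs(g, K, 15000, 2 * K)
    expect_equal(unname(tp[1] + (K - 1) * tp[2]), 1, tolerance = 1e-12)
  }
})

test_that("emission_prob matches the Li-Stephens mutation model", {
  # theta from the harmonic formula, evaluated independently
  K <- 10
  theta <- 1 / sum(1 / (1:9))
  mis <- (theta / (K + theta)) / 2
  expect_equal(emission_prob(1, 1, K), K / (K + theta) + mis)
  expect_equal(emission_prob(1, 0, K), mis)
  expect_equal(ls_theta(K), theta)
  # probabilities over {match, mismatch} sum to 1
  for (K in c(2, 5, 50))
    expect_equal(emission_prob(0, 0, K) + emission_prob(0, 1, K), 1)
  # K large: mismatch probability vanishes
  expect_lt(emission_prob(1, 0, 1e6), 1e-6)
})

test_that("forward_backward equals exhaustive enumeration", {
  set.seed(17)
  cases <- 0
  while (cases < 10) {
    L <- sample(4:8, 1)
    g <- sample(c(0L, 1L, 1L, 2L), L, TRUE)
    if (sum(g == 1L) < 2) next
    cases <- cases + 1
    graph <- build_graph(g)
    K <- sample(1:3, 1)
    cond <- matrix(sample(0:1, K * L, TRUE), K, L)
    cm <- cumsum(runif(L, 0, 1))
    nhap <- 2 * K + 2
    par <- lsm_params(cm = cm, n_hap = nhap)
    fwd <- forward_backward(graph, cond, par)
    o <- oracle_hmm(graph, cond, cm, nhap)
    expect_equal(fwd$loglik, o$loglik, tolerance = 1e-9)
    for (s in seq_along(fwd$post)) {
      expect_equal(as.matrix(fwd$post[[s]]), o$bound[[s]], tolerance = 1e-9,
                   ignore_attr = TRUE)
      expect_equal(sum(fwd$post[[s]]), 1, tolerance = 1e-9)
    }
    for (s in seq_along(fwd$marg))
      expect_equal(as.numeric(fwd$marg[[s]]), o$marg[[s]], tolerance = 1e-9)
  }
})

test_that("forward_backward folds phase-set weights in exactly", {
  set.seed(19)
  for (rep in 1:4) {
    g <- c(1L, 1L, 1L, 0L, 1L, 1L)
    graph <- build_graph(g)
    K <- 2
    cond <- matrix(sample(0:1, K * 6, TRUE), K, 6)
    cm <- cumsum(runif(6, 0, 0.5))
    cons <- phase_set_constraints(
      data.frame(site = c(1, 3, 5), ps = 1L,
                 allele1 = sample(0:1, 3, TRUE)), eps = 0.05)
    par <- lsm_params(cm = cm, n_hap = 6)
    fwd <- forward_backward(graph, cond, par, cons)
    o <- oracle_hmm(graph, cond, cm, 6, cons = cons)
    expect_equal(as.matrix(fwd$post[[1]]), o$bound[[1]], tolerance = 1e-9,
                 ignore_attr = TRUE)
    expect_equal(fwd$loglik, o$loglik, tolerance = 1e-9)
  }
})

test_that("eps = 0.5 phase sets leave posteriors exactly unchanged", {
  set.seed(29)
  g <- c(1L, 1L, 1L, 1L, 1L)
  graph <- build_graph(g)
  cond <- matrix(sample(0:1, 3 * 5, TRUE), 3, 5)
  par <- lsm_params(cm = cumsum(runif(5, 0, 0.3)), n_hap = 8)
  cons <- phase_set_constraints(
    data.frame(site = c(1, 2, 4), ps = 1L, allele1 = c(0L, 1L, 0L)), eps = 0.5)
  a <- forward_backward(graph, cond, par)
  b <- forward_backward(graph, cond, par, cons)
  for (s in seq_along(a$post))
    expect_equal(as.matrix(a$post[[s]]), as.matrix(b$post[[s]]))
  expect_equal(as.numeric(a$marg[[1]]), as.numeric(b$marg[[1]]))
})

test_that("sample_pair draws from the path posterior", {
  set.seed(37)
  # degenerate posterior: scaffold all hets -> unique path every draw
  g <- c(1L, 0L, 1L, 1L)
  graph <- apply_scaffold(build_graph(g),
                          data.frame(site = c(1, 3, 4), allele = c(1L, 0L, 1L)))
  cond <- matrix(sample(0:1, 2 * 4, TRUE), 2, 4)
  fwd <- forward_backward(graph, cond, lsm_params(cm = 1:4 * 0.01, n_hap = 6))
  for (p in sample_pair(fwd, n = 5)) {
    expect_equal(p$h1, c(1L, 0L, 0L, 1L))
    expect_true(all(p$h1 + p$h2 == g))
  }
  # sampled pairs always genotype-consistent, including missing sites
  g2 <- c(1L, NA, 2L, 1L, 1L, 0L, 1L)
  gr2 <- build_graph(g2)
  cond2 <- matrix(sample(0:1, 3 * 7, TRUE), 3, 7)
  fwd2 <- forward_backward(gr2, cond2, lsm_params(cm = 1:7 * 0.02, n_hap = 8))
  for (p in sample_pair(fwd2, n = 20)) {
    ok <- is.na(g2) | p$h1 + p$h2 == g2
    expect_true(all(ok))
  }
  # empirical path frequencies track the enumerated posterior
  g3 <- c(1L, 1L, 0L, 1L, 1L)
  gr3 <- build_graph(g3)
  cond3 <- matrix(sample(0:1, 2 * 5, TRUE), 2, 5)
  cm3 <- cumsum(runif(5, 0, 0.4))
  fwd3 <- forward_backward(gr3, cond3, lsm_params(cm = cm3, n_hap = 6))
  o <- oracle_hmm(gr3, cond3, cm3, 6)
  n <- 4000
  cf <- attr(sample_pair(fwd3, n = n), "configs")
  key <- apply(t(cf), 1, paste, collapse = "-")
  okey <- apply(o$cfg_paths, 1, paste, collapse = "-")
  emp <- as.numeric(table(factor(key, levels = okey))) / n
  chi <- sum((n * (emp - o$path_prob))^2 / pmax(n * o$path_prob, 1e-9))
  df <- sum(o$path_prob > 1e-9) - 1
  expect_gt(pchisq(chi, df, lower.tail = FALSE), 0.001)
})

test_that("a duplicated-truth conditioning set recovers truth off the hets", {
  set.seed(51)
  truth <- c(1L, 0L, 1L, 1L, 0L, 1L)
  g <- c(2L, 0L, NA, 2L, NA, 1L)
  g[1] <- 2L * truth[1]; g[2] <- 2L * truth[2]; g[4] <- 2L * truth[4]
  graph <- build_graph(g)
  cond <- rbind(truth, truth)
  fwd <- forward_backward(graph, cond, lsm_params(cm = rep(0, 6), n_hap = 4))
  hom <- which(!is.na(g) & g != 1L)
  mis <- which(is.na(g))
  draws <- sample_pair(fwd, n = 200)
  for (p in draws) {
    # homozygous sites are forced to the genotype
    expect_equal(p$h1[hom], truth[hom])
    expect_equal(p$h2[hom], truth[hom])
  }
  # missing sites are imputed towards the copied (true) haplotype: the
  # match/mismatch emission odds favor truth on a clear majority of draws
  for (s in mis) {
    frac <- mean(vapply(draws, function(p) p$h1[s] == truth[s], logical(1)))
    expect_gt(frac, 0.6)
  }
})

test_that("accumulate_and_solve averages tables and takes the best path", {
  g <- rep(1L, 6)
  graph <- build_graph(g)  # 8 x 8 boundary
  # single degenerate iteration returns that path
  tab <- matrix(0, 8, 8); tab[2, 7] <- 1
  sol <- accumulate_and_solve(graph, list(post = list(tab),
                                          marg = list(rep(1, 8) / 8, rep(1, 8) / 8),
                                          n = 1L))
  expect_equal(sol$configs, c(2L, 7L))
  # averaging identical tables equals a single table
  sol2 <- accumulate_and_solve(graph, list(post = list(tab * 3),
                                           marg = list(rep(1, 8), rep(1, 8)),
                                           n = 3L))
  expect_equal(sol2$configs, sol$configs)
  expect_error(accumulate_and_solve(graph, list(post = NULL, marg = NULL, n = 0L)),
               "no stored")
  # DP equals argmax over enumerated paths of the product of averaged tables
  set.seed(43)
  for (rep in 1:6) {
    g <- sample(c(0L, 1L), 10, TRUE)
    if (sum(g == 1L) < 4) next
    gr <- build_graph(g)
    nseg <- length(gr$segments)
    if (nseg < 2) next
    tabs <- lapply(seq_len(nseg - 1), function(s) {
      m <- matrix(runif(nrow(gr$segments[[s]]$conf1) *
                        nrow(gr$segments[[s + 1]]$conf1)),
                  nrow(gr$segments[[s]]$conf1))
      m / sum(m)
    })
    sol <- accumulate_and_solve(gr, list(post = tabs, marg = NULL, n = 1L))
    counts <- vapply(gr$segments, function(s) nrow(s$conf1), integer(1))
    paths <- as.matrix(do.call(expand.grid, lapply(counts, seq_len)))
    score <- apply(paths, 1, function(cf)
      prod(vapply(seq_len(nseg - 1), function(s) tabs[[s]][cf[s], cf[s + 1]],
                  numeric(1))))
    expect_equal(unname(sol$configs), unname(paths[which.max(score), ]))
  }
})
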