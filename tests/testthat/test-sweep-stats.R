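test_that("window_pi matches closed forms and the exhaustive pairwise oracle", {
  # 4 haplotypes, one site with derived count 2, 100 bp window
  hm <- hm_fixture(matrix(c(1, 1, 0, 0), ncol = 1), positions = 50L)
  res <- window_pi(hm, list(start = 0, end = 100))
  expect_equal(res$pi, (2 * 2 / 6) / 100)
  expect_equal(res$S, 1)

  # monomorphic window
  res0 <- window_pi(hm, list(start = 100, end = 200))
  expect_equal(res0$pi, 0)
  expect_equal(res0$S, 0)

  # 2 haplotypes differing at 1 of 100 bp
  hm2 <- hm_fixture(matrix(c(0, 1), ncol = 1), positions = 10L)
  expect_equal(window_pi(hm2, list(start = 0, end = 100))$pi, 0.01)

  # brute-force oracle on random matrices
  for (seed in 1:3) {
    hm3 <- random_hm(20, 150, seed = seed, maxpos = 20000L)
    w <- list(start = 0, end = 20000)
    expect_equal(window_pi(hm3, w)$pi, oracle_pi(hm3, 0, 20000),
                 tolerance = 1e-12)
  }
  expect_error(window_pi(hm, list(start = 200, end = 100)), "window")
})

test_that("Tajima's D follows the canonical constants and sign conventions", {
  # direct independent evaluation of the eight constants for n = 4
  n <- 4
  a1 <- 1 + 1/2 + 1/3
  a2 <- 1 + 1/4 + 1/9
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  k <- tajima_constants(4)
  expect_equal(unlist(k), c(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1,
                            c2 = c2, e1 = e1, e2 = e2))

  # n = 4, S = 1, derived count 2: pi_total = 2*2/6
  pi_total <- 2 * 2 / 6
  expected <- (pi_total - 1 / a1) / sqrt(e1 * 1)
  expect_equal(tajimas_d(1, pi_total, 4), expected)

  # numerator vanishes when pi_total = S / a1
  expect_equal(tajimas_d(5, 5 / a1, 4), 0)

  # S = 0 -> 0 with undefined flag
  d0 <- tajimas_d(0, 0, 10)
  expect_equal(as.numeric(d0), 0)
  expect_true(attr(d0, "undefined"))
  expect_error(tajimas_d(1, 1, 1), "n >= 2")
})

test_that("WC84 per-site components match an independent evaluation", {
  # fixed difference, equal sizes -> theta = 1
  full <- wc_fst_site(c(10, 0), c(0, 10))
  expect_equal(full$theta, 1)
  expect_equal(full$b, 0)

  # identical frequencies -> theta <= 0, reported as computed
  same <- wc_fst_site(c(5, 5), c(5, 5))
  expect_true(same$theta <= 0)
  orc <- oracle_wc84(5, 10, 5, 10)
  expect_equal(same$theta, orc$theta, tolerance = 1e-12)

  # the spec's 9/1 vs 1/9 case against the independent oracle
  got <- wc_fst_site(c(9, 1), c(1, 9))
  orc <- oracle_wc84(1, 10, 9, 10)
  expect_equal(got$a, orc$a, tolerance = 1e-12)
  expect_equal(got$b, orc$b, tolerance = 1e-12)
  expect_equal(got$theta, orc$theta, tolerance = 1e-12)

  # empty population -> site skipped
  expect_null(wc_fst_site(c(0, 0), c(3, 4)))

  # 100 random sites, uneven sizes, tolerance 1e-10
  set.seed(7)
  for (i in 1:100) {
    n1 <- sample(4:40, 1); n2 <- sample(4:40, 1)
    alt1 <- sample(0:n1, 1); alt2 <- sample(0:n2, 1)
    got <- wc_fst_site(c(n1 - alt1, alt1), c(n2 - alt2, alt2))
    orc <- oracle_wc84(alt1, n1, alt2, n2)
    expect_equal(got$a, orc$a, tolerance = 1e-10)
    expect_equal(got$b, orc$b, tolerance = 1e-10)
  }
})

test_that("windowed F_ST is the ratio of summed components", {
  comp <- data.frame(pos = c(10L, 20L), a = c(0.5, 0), den = c(0.5, 0.5),
                     theta = c(1, 0))
  expect_equal(window_fst(comp, list(start = 0, end = 100)), 0.5)

  # single-site window equals the per-site theta
  expect_equal(window_fst(comp, list(start = 0, end = 15)), 1)

  # no usable site -> NA
  expect_true(is.na(window_fst(comp, list(start = 50, end = 100))))

  # 50 simulated sites: matches independent re-summation, and label swap
  hm <- random_hm(24, 50, seed = 11)
  groups <- data.frame(sample_id = hm$sample_ids,
                       group = rep(c("A", "B"), c(5, 7)))
  comp <- fst_components(hm, groups)
  w <- list(start = 0, end = max(hm$positions))
  idx <- !is.na(comp$den) & comp$den > 0
  expect_equal(window_fst(comp, w), sum(comp$a[idx]) / sum(comp$den[idx]),
               tolerance = 1e-12)
  # per-site check against the oracle
  hap_grp <- rep(groups$group, each = 2)
  for (j in seq_len(50)) {
    alt1 <- sum(hm$alleles[hap_grp == "A", j])
    alt2 <- sum(hm$alleles[hap_grp == "B", j])
    orc <- oracle_wc84(alt1, 10, alt2, 14)
    expect_equal(comp$a[j], orc$a, tolerance = 1e-10)
  }
  # label invariance
  groups2 <- groups
  groups2$group <- ifelse(groups$group == "A", "B", "A")
  comp2 <- fst_components(hm, groups2)
  expect_equal(window_fst(comp2, w), window_fst(comp, w), tolerance = 1e-12)
})

test_that("background SFS counts derived classes and rejects monomorphic input", {
  hm <- hm_fixture(rbind(c(1, 0, 1), c(0, 0, 1), c(0, 1, 0), c(0, 0, 0)))
  # derived counts {1, 1, 2} in n = 4
  bg <- background_sfs(hm)
  expect_equal(bg$prob, c(2 / 3, 1 / 3, 0))
  hm_mono <- hm_fixture(matrix(1, 4, 2))
  expect_error(background_sfs(hm_mono), "no segregating sites")
})

test_that("sweep_scan emits a row per window with missing values where undefined", {
  hm <- random_hm(10, 60, seed = 3, maxpos = 50000L)
  win <- make_windows(60000, 10000, 10000)
  ws <- sweep_scan(hm, win, methods = c("pi", "tajima_d"))
  expect_equal(nrow(ws), nrow(win))
  empty <- ws$n_sites == 0
  expect_true(all(ws$pi[!empty] >= 0))
  expect_true(all(is.na(ws$tajima_d[empty])))
})
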