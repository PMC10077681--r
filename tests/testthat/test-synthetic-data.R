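test_that("simulators are fully deterministic under a fixed seed", {
  p <- sim_params(N = 60, L = 5e4, burnin = 300, sample_n = 8, seed = 5)
  hm1 <- simulate_population(p)
  hm2 <- simulate_population(p)
  expect_identical(hm1$alleles, hm2$alleles)
  expect_identical(hm1$positions, hm2$positions)

  p2 <- sim_params(N = 60, L = 5e4, burnin = 300, sample_n = 8, seed = 6)
  hm3 <- simulate_population(p2)
  expect_false(identical(hm1$positions, hm3$positions))

  two1 <- simulate_two_groups(sim_params(N = 60, L = 5e4, burnin = 300,
                                         seed = 9), c(0.1, 0.9))
  two2 <- simulate_two_groups(sim_params(N = 60, L = 5e4, burnin = 300,
                                         seed = 9), c(0.1, 0.9))
  expect_identical(two1$hm$alleles, two2$hm$alleles)

  groups <- two1$groups
  tr1 <- simulate_cnv_truth(groups, n_neutral = 10, seed = 3)
  tr2 <- simulate_cnv_truth(groups, n_neutral = 10, seed = 3)
  expect_identical(tr1$cn, tr2$cn)
  c1 <- simulate_cnv_callsets(tr1, seed = 4)
  c2 <- simulate_cnv_callsets(tr2, seed = 4)
  expect_identical(c1, c2)
})

test_that("neutral simulations behave like equilibrium Wright-Fisher samples", {
  # Tajima's D across replicates near 0; SFS close in shape to 1/i
  ds <- numeric(12)
  sfs_tot <- NULL
  for (i in seq_len(12)) {
    p <- sim_params(N = 100, L = 1e5, burnin = 1500, sample_n = 15,
                    seed = 200 + i)
    hm <- simulate_population(p)
    res <- window_pi(hm, list(start = 0, end = 1e5))
    ds[i] <- tajimas_d(res$S, res$pi_total, nrow(hm$alleles))
    cnt <- tabulate(derived_counts(hm), nbins = nrow(hm$alleles) - 1)
    sfs_tot <- if (is.null(sfs_tot)) cnt else sfs_tot + cnt
  }
  expect_lt(abs(mean(ds)), 0.5)
  exp_shape <- (1 / seq_len(29)) / sum(1 / seq_len(29))
  obs_shape <- sfs_tot / sum(sfs_tot)
  # pooled spectrum within a loose multiplicative band of the neutral shape
  expect_lt(max(abs(obs_shape - exp_shape)), 0.08)
  # low-frequency classes dominate
  expect_gt(sum(obs_shape[1:5]), sum(obs_shape[25:29]))
})

test_that("two-group generator plants the differentiated site as requested", {
  p <- sim_params(N = 60, L = 5e4, burnin = 400, seed = 11)
  two <- simulate_two_groups(p, c(0, 1))
  expect_equal(table(two$groups$group)[["HSM"]], 14)
  expect_equal(table(two$groups$group)[["PSM"]], 16)
  j <- which(two$hm$positions == two$diff_pos)
  hap_grp <- rep(two$groups$group, each = 2)
  a1 <- sum(two$hm$alleles[hap_grp == "HSM", j])
  a2 <- sum(two$hm$alleles[hap_grp == "PSM", j])
  # fixed difference -> per-site theta = 1
  comp <- wc_fst_site(c(28 - a1, a1), c(32 - a2, a2))
  expect_equal(comp$theta, 1)

  # equal frequencies: mean per-site theta across replicates near 0
  thetas <- numeric(10)
  for (i in seq_len(10)) {
    two2 <- simulate_two_groups(sim_params(N = 60, L = 5e4, burnin = 400,
                                           seed = 300 + i), c(0.5, 0.5))
    j <- which(two2$hm$positions == two2$diff_pos)
    a1 <- sum(two2$hm$alleles[hap_grp == "HSM", j])
    a2 <- sum(two2$hm$alleles[hap_grp == "PSM", j])
    cmp <- wc_fst_site(c(28 - a1, a1), c(32 - a2, a2))
    thetas[i] <- if (is.null(cmp)) NA else cmp$theta
  }
  expect_lt(abs(mean(thetas, na.rm = TRUE)), 0.15)
})

test_that("CNV call-set generator respects its error-model contracts", {
  groups <- data.frame(sample_id = sprintf("S%02d", 1:10),
                       group = rep(c("A", "B"), 5))
  truth <- simulate_cnv_truth(groups, n_neutral = 20, seed = 8)

  # zero-noise model reproduces truth exactly for every carrier
  calls <- simulate_cnv_callsets(truth, jitter_sd = c(0, 0, 0), fn_rate = 0,
                                 fp_mean = 0, imprecise_frac = 0, cn_sd = 0,
                                 seed = 9)
  carriers <- sum(truth$cn != 2L)
  expect_equal(nrow(calls), 3 * carriers)
  m <- merge(calls, truth$regions, by = "chrom")
  hit <- calls$start %in% truth$regions$start &
    calls$end %in% truth$regions$end
  expect_true(all(hit))

  # FN = 1 silences everything
  none <- simulate_cnv_callsets(truth, fn_rate = 1, fp_mean = 0, seed = 10)
  expect_equal(nrow(none), 0)

  # planted differentiated deletion: CN 0 in all of group B, half of A
  tr <- truth$regions[truth$regions$differentiated, ]
  cn <- truth$cn[tr$region_id, ]
  expect_true(all(cn[groups$group == "B"] == 0))
  expect_equal(sum(cn[groups$group == "A"] == 0), 2)  # floor(5/2)
  expect_true(all(cn %in% c(0L, 2L)))
})

test_that("fixture generator writes round-trippable GFF3 and QTL files", {
  dir <- tempfile()
  fx <- make_fixtures(n_genes = 8, n_qtls = 10, chrom_length = 1e6,
                      dir = dir, seed = 12)
  gm <- read_gff(fx$gff)
  expect_equal(nrow(gm$genes), 8)
  expect_equal(gm$genes[order(gm$genes$start),
                        c("gene_id", "start", "end")],
               fx$gene_models$genes[order(fx$gene_models$genes$start),
                                    c("gene_id", "start", "end")],
               ignore_attr = TRUE)
  # exons contained in their gene span
  for (i in seq_len(nrow(gm$exons))) {
    g <- gm$genes[gm$genes$gene_id == gm$exons$gene_id[i], ]
    expect_gte(gm$exons$start[i], g$start)
    expect_lte(gm$exons$end[i], g$end)
  }
  q <- read_qtl_table(fx$qtl, p_max = 1)
  expect_equal(nrow(q), 10)
  # same seed -> identical files
  dir2 <- tempfile()
  fx2 <- make_fixtures(n_genes = 8, n_qtls = 10, chrom_length = 1e6,
                       dir = dir2, seed = 12)
  expect_identical(readLines(fx$gff), readLines(fx2$gff))
  expect_identical(readLines(fx$qtl), readLines(fx2$qtl))

  # empty GFF is still valid
  fx0 <- make_fixtures(n_genes = 0, n_qtls = 0, dir = tempfile(), seed = 1)
  gm0 <- read_gff(fx0$gff)
  expect_equal(nrow(gm0$genes), 0)
})
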