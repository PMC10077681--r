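test_that("V_ST matches direct arithmetic and flags degenerate input", {
  # complete between-group partition -> vst = 1
  v <- vst(c(1, 1, 1, 3, 3, 3), rep(c("A", "B"), each = 3))
  expect_equal(v$v_t, 1)
  expect_equal(v$v_s, 0)
  expect_equal(v$vst, 1)

  # all values equal -> v_t = 0 -> missing
  v0 <- vst(rep(2, 6), rep(c("A", "B"), each = 3))
  expect_true(is.na(v0$vst))

  # (2,2,2,2) vs (2,2,0,0): v_t = 0.75, v_s = 0.5, vst = 1/3 (ddof 0)
  v2 <- vst(c(2, 2, 2, 2, 2, 2, 0, 0), rep(c("A", "B"), each = 4))
  expect_equal(v2$v_t, 0.75)
  expect_equal(v2$v_s, 0.5)
  expect_equal(v2$vst, 1 / 3)

  expect_error(vst(1:4, rep("A", 4)), "two non-empty groups")

  # affine invariance: x -> a x + b
  set.seed(3)
  x <- rnorm(30, 2, 0.7)
  g <- rep(c("A", "B"), c(14, 16))
  expect_equal(vst(3.7 * x - 1.2, g)$vst, vst(x, g)$vst, tolerance = 1e-12)

  # vst = 1 iff within-group variances vanish while total > 0
  expect_lt(vst(c(1, 1, 2, 3, 3, 3), rep(c("A", "B"), each = 3))$vst, 1)
})

test_that("copy-number matrix imputes diploid and translates call annotations", {
  cons <- rbind(
    sv_calls("consensus", "s1", "1", 100, 200, "DEL", TRUE, 9,
             copy_number = 0.2),
    sv_calls("consensus", "s2", "1", 120, 220, "DEL", TRUE, 9),
    sv_calls("consensus", "s1", "1", 5000, 5400, "DUP", TRUE, 9),
    sv_calls("consensus", "s3", "1", 5100, 5500, "DUP", TRUE, 9))
  cs <- build_cnvrs(cons)
  samples <- c("s1", "s2", "s3")
  M <- copy_number_matrix(cs, samples)
  del_id <- cs$cnvrs$cnvr_id[cs$cnvrs$cnvr_type == "deletion"]
  dup_id <- cs$cnvrs$cnvr_id[cs$cnvrs$cnvr_type == "duplication"]
  expect_equal(M[del_id, "s1"], 0.2)          # caller CN annotation
  expect_equal(M[del_id, "s2"], 1)            # DEL without CN, unknown gt
  expect_equal(M[del_id, "s3"], 2)            # no call -> diploid default
  expect_equal(M[dup_id, "s1"], 3)            # DUP without CN
  groups <- data.frame(sample_id = c("s1", "s2"), group = c("A", "B"))
  expect_error(copy_number_matrix(cs, samples, groups), "absent from group")
})

test_that("scan selection sizes follow the ceiling rule with deterministic ties", {
  set.seed(23)
  cnvrs <- data.frame(cnvr_id = sprintf("C%03d", 1:100), chrom = "1",
                      start = seq(0, by = 1000, length.out = 100),
                      end = seq(500, by = 1000, length.out = 100))
  cnm <- matrix(rnorm(100 * 30, 2, 0.3), 100, 30,
                dimnames = list(cnvrs$cnvr_id, sprintf("s%d", 1:30)))
  groups <- data.frame(sample_id = sprintf("s%d", 1:30),
                       group = rep(c("A", "B"), c(14, 16)))
  scan <- vst_scan(cnm, groups, cnvrs, top_fraction = 0.02)
  expect_equal(nrow(scan$top), 2)  # ceil(0.02 * 100)
  expect_equal(scan$top$vst, sort(scan$table$vst, decreasing = TRUE)[1:2])

  # 10 CNVRs -> ceiling gives 1
  scan10 <- vst_scan(cnm[1:10, ], groups, cnvrs[1:10, ], top_fraction = 0.02)
  expect_equal(nrow(scan10$top), 1)

  # planted deletion (one group all CN 0, other mixed 0/2) ranks first:
  # its V_ST exceeds the noise-driven maxima in this replicate
  cnm2 <- cnm
  cnm2["C050", groups$group == "A"] <- rep(c(0, 2), c(7, 7))
  cnm2["C050", groups$group == "B"] <- 0
  scan2 <- vst_scan(cnm2, groups, cnvrs)
  expect_equal(scan2$table$cnvr_id[1], "C050")

  # windowed top-1% rule with bookended region merge
  win <- data.frame(chrom = "1",
                    start = seq(0, by = 20000, length.out = 400))
  win$end <- win$start + 50000
  set.seed(5)
  win$fst <- runif(400)
  sel <- fst_scan(win, top_fraction = 0.01)
  expect_equal(nrow(sel$selected), 4)
  # force two overlapping top windows -> single merged region
  win$fst[10:11] <- c(2, 2.1)
  win$fst[-(10:11)] <- runif(398, 0, 0.5)
  sel2 <- fst_scan(win, top_fraction = 0.005)
  expect_equal(nrow(sel2$selected), 2)
  expect_equal(nrow(sel2$regions), 1)
  expect_equal(sel2$regions$start, win$start[10])
  expect_equal(sel2$regions$end, win$end[11])
})

test_that("PSG consensus keeps genes supported by at least two methods", {
  sets <- list(pi = c("g1", "g2", "g3"), ihs = c("g2", "g4"),
               clr = c("g3", "g4", "g5"))
  psg <- psg_consensus(sets)
  expect_setequal(psg, c("g2", "g3", "g4"))
  expect_error(psg_consensus(sets["pi"]), "two method")

  # monotone: adding a method never removes a consensus gene
  sets2 <- c(sets, list(fst = c("g1", "g5", "g9")))
  expect_true(all(psg %in% psg_consensus(sets2)))
})

test_that("interval overlap engines agree with the quadratic all-pairs oracle", {
  regions <- random_intervals(200, prefix = "R", seed = 41)
  genes <- random_intervals(200, prefix = "G", seed = 42)
  gm <- data.frame(gene_id = genes$id, chrom = genes$chrom,
                   start = genes$start, end = genes$end,
                   stringsAsFactors = FALSE)
  hits <- genes_in_regions(regions, gm)
  brute <- 0L
  for (i in seq_len(nrow(regions)))
    for (j in seq_len(nrow(gm))) {
      if (min(regions$end[i], gm$end[j]) -
          max(regions$start[i], gm$start[j]) > 0) {
        brute <- brute + 1L
        expect_true(any(hits$region == i & hits$gene_id == gm$gene_id[j]))
      }
    }
  expect_equal(nrow(hits), brute)

  qtls <- random_intervals(150, prefix = "Q", seed = 43)
  qtls <- data.frame(qtl_id = qtls$id, chrom = qtls$chrom,
                     start = qtls$start, end = qtls$end,
                     trait_class = "milk", p_value = 0.01,
                     stringsAsFactors = FALSE)
  ov <- qtl_overlap(regions, qtls)
  brute2 <- 0L
  for (i in seq_len(nrow(regions)))
    for (j in seq_len(nrow(qtls)))
      if (min(regions$end[i], qtls$end[j]) -
          max(regions$start[i], qtls$start[j]) > 0) brute2 <- brute2 + 1L
  expect_equal(attr(ov, "n_pairs"), brute2)
  expect_true(all(ov$overlap_bp >= 1))

  # containment counts as one pair
  one <- qtl_overlap(data.frame(chrom = "1", start = 150L, end = 160L,
                                id = "x"), qtls[1, , drop = FALSE][0, ])
  expect_equal(attr(one, "n_pairs"), 0L)
})

test_that("CNVR summary reproduces the published internal arithmetic", {
  # a CNVR table with the published composition: 1,651 + 126 + 1,167
  n <- c(deletion = 1651L, duplication = 126L, both = 1167L)
  total_len <- 4661581
  lens <- rep(floor(total_len / 2944), 2944)
  lens[seq_len(total_len - sum(lens))] <-
    lens[seq_len(total_len - sum(lens))] + 1
  cn <- data.frame(
    cnvr_id = sprintf("C%04d", 1:2944), chrom = "1",
    start = 0L, end = lens, length = lens,
    cnvr_type = rep(names(n), n),
    context = rep(c("intergenic", "intronic", "exonic"),
                  c(1782L, 1141L, 21L)),
    stringsAsFactors = FALSE)
  s <- summarize_cnvrs(cn, genome_size = 2.59e9)
  expect_equal(s$n_total, 2944)
  expect_equal(sum(s$n_by_type), s$n_total)  # count conservation
  expect_equal(s$total_length, 4661581)
  expect_equal(s$mean_length, 1583)          # round(4661581 / 2944)
  expect_equal(unname(s$context_pct[["intergenic"]]), 60.53)
  expect_equal(unname(s$context_pct[["exonic"]]), 0.71)
  expect_equal(sum(s$context_pct), 100, tolerance = 0.01)
  expect_equal(s$genome_fraction_pct, 0.18)

  # empty set flagged
  s0 <- summarize_cnvrs(cn[0, ])
  expect_true(s0$empty)
  expect_equal(s0$n_total, 0)
})
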