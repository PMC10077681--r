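test_that("SV filter applies the three removal rules inclusively and is idempotent", {
  calls <- sv_calls(
    caller = "c1", sample_id = "s1", chrom = "1",
    start = c(0, 0, 0, 0), end = c(60, 40, 60, 60),
    svtype = "DEL",
    precise = c(FALSE, TRUE, TRUE, TRUE),
    support_reads = c(5, 5, 3, 5))
  kept <- filter_sv_calls(calls)
  expect_equal(nrow(kept), 1)
  expect_equal(attr(kept, "rejected"),
               c(imprecise_or_lowqual = 1L, too_short = 1L, low_support = 1L))

  # boundary call (50 bp, 4 reads) survives: removals are strict inequalities
  boundary <- sv_calls("c1", "s1", "1", 0, 50, "DEL", TRUE, 4)
  expect_equal(nrow(filter_sv_calls(boundary)), 1)

  # empty input passes through
  expect_equal(nrow(filter_sv_calls(calls[0, ])), 0)

  # idempotence
  twice <- filter_sv_calls(kept)
  expect_equal(twice$start, kept$start)
  expect_equal(nrow(twice), nrow(kept))

  # failing caller filter counts as low quality
  failing <- sv_calls("c1", "s1", "1", 0, 100, "DEL", TRUE, 9,
                      filter = "LowQual")
  expect_equal(nrow(filter_sv_calls(failing)), 0)
})

test_that("cross-caller consensus requires same type, overlap and CN direction", {
  # DEL by A [100,200) + DEL by B [150,250) with CN 0.9 -> DEL [150,200)
  calls <- rbind(
    sv_calls("A", "s1", "1", 100, 200, "DEL", TRUE, 10),
    sv_calls("B", "s1", "1", 150, 250, "DEL", TRUE, 8, copy_number = 0.9))
  cons <- consensus_calls(calls)
  expect_equal(nrow(cons), 1)
  expect_equal(c(cons$start, cons$end), c(150, 200))
  expect_equal(cons$svtype, "DEL")

  # DEL overlapping DUP -> type conflict, rejected
  conflict <- rbind(
    sv_calls("A", "s1", "1", 100, 200, "DEL", TRUE, 10),
    sv_calls("B", "s1", "1", 150, 250, "DUP", TRUE, 8))
  expect_equal(nrow(consensus_calls(conflict)), 0)

  # CN annotation pointing the wrong way rejects the locus
  wrongcn <- rbind(
    sv_calls("A", "s1", "1", 100, 200, "DEL", TRUE, 10),
    sv_calls("B", "s1", "1", 150, 250, "DEL", TRUE, 8, copy_number = 2.6))
  expect_equal(nrow(consensus_calls(wrongcn)), 0)

  # CN inside the neutral band also rejects
  neutral <- rbind(
    sv_calls("A", "s1", "1", 100, 200, "DEL", TRUE, 10),
    sv_calls("B", "s1", "1", 150, 250, "DEL", TRUE, 8, copy_number = 2.0))
  expect_equal(nrow(consensus_calls(neutral)), 0)

  # one caller only -> no consensus; different chromosomes never grouped
  single <- rbind(
    sv_calls("A", "s1", "1", 100, 200, "DEL", TRUE, 10),
    sv_calls("B", "s1", "2", 100, 200, "DEL", TRUE, 10))
  expect_equal(nrow(consensus_calls(single)), 0)
})

test_that("CNVR construction merges transitively and enforces the 2-animal rule", {
  cons <- rbind(
    sv_calls("consensus", "s1", "1", 100, 200, "DEL", TRUE, 10),
    sv_calls("consensus", "s2", "1", 150, 250, "DEL", TRUE, 10))
  cs <- build_cnvrs(cons)
  expect_equal(nrow(cs$cnvrs), 1)
  expect_equal(c(cs$cnvrs$start, cs$cnvrs$end), c(100, 250))
  expect_equal(cs$cnvrs$n_samples, 2)

  # single-sample locus discarded
  lone <- rbind(cons, sv_calls("consensus", "s1", "1", 5000, 6000, "DEL",
                               TRUE, 10))
  cs2 <- build_cnvrs(lone)
  expect_equal(nrow(cs2$cnvrs), 1)

  # transitive chain over three calls from 2 samples -> one CNVR [0, 300)
  chain <- rbind(
    sv_calls("consensus", "s1", "1", 0, 100, "DEL", TRUE, 10),
    sv_calls("consensus", "s2", "1", 90, 150, "DEL", TRUE, 10),
    sv_calls("consensus", "s1", "1", 140, 300, "DEL", TRUE, 10))
  cs3 <- build_cnvrs(chain)
  expect_equal(nrow(cs3$cnvrs), 1)
  expect_equal(c(cs3$cnvrs$start, cs3$cnvrs$end), c(0, 300))

  # sweep-line oracle on random calls: CNVRs disjoint, contain members
  set.seed(31)
  rnd <- sv_calls("consensus",
                  sample(sprintf("s%d", 1:6), 60, replace = TRUE), "1",
                  start = st <- sample.int(50000, 60),
                  end = st + sample(100:3000, 60, replace = TRUE),
                  svtype = sample(c("DEL", "DUP"), 60, replace = TRUE),
                  precise = TRUE, support_reads = 10)
  cs4 <- build_cnvrs(rnd, min_animals = 2)
  cn <- cs4$cnvrs[order(cs4$cnvrs$start), ]
  if (nrow(cn) > 1)
    expect_true(all(cn$start[-1] >= cn$end[-nrow(cn)]))
  for (id in cn$cnvr_id) {
    m <- cs4$members[cs4$members$cnvr_id == id, ]
    expect_true(all(m$start >= cn$start[cn$cnvr_id == id]))
    expect_true(all(m$end <= cn$end[cn$cnvr_id == id]))
    expect_gte(length(unique(m$sample_id)), 2)
  }
})

test_that("CNVR type classification covers the three categories", {
  expect_equal(classify_cnvr(c("DEL", "DEL")), "deletion")
  expect_equal(classify_cnvr(c("DUP", "DUP")), "duplication")
  expect_equal(classify_cnvr(c("DEL", "DUP")), "both")
  expect_error(classify_cnvr(c("DEL", "INV")), "unexpected")
  expect_error(classify_cnvr(character(0)), "no member")
})

test_that("genomic context uses exon > intron > intergenic precedence", {
  gm <- structure(list(
    genes = data.frame(gene_id = "G1", chrom = "1", start = 1000L,
                       end = 5000L, stringsAsFactors = FALSE),
    exons = data.frame(gene_id = "G1", chrom = "1", start = 2000L,
                       end = 2500L, stringsAsFactors = FALSE)),
    class = "gene_models")
  cons <- rbind(
    sv_calls("consensus", c("s1", "s2"), "1", 3000, 3400, "DEL", TRUE, 9),
    sv_calls("consensus", c("s1", "s2"), "1", 2400, 2600, "DEL", TRUE, 9),
    sv_calls("consensus", c("s1", "s2"), "1", 8000, 8500, "DEL", TRUE, 9))
  cs <- annotate_cnvr(build_cnvrs(cons), gm)
  ctx <- cs$cnvrs$context[order(cs$cnvrs$start)]
  expect_equal(ctx, c("exonic", "intronic", "intergenic"))
})

test_that("length histogram partitions the set with overflow bins", {
  cn <- data.frame(length = c(120, 300, 700))
  h <- length_histogram(cn, bin_edges = c(100, 500, 1000))
  expect_equal(sum(h$count), 3)
  expect_equal(h$count[h$bin == "[100,500)"], 2)
  expect_equal(h$count[h$bin == "[500,1000)"], 1)
  expect_equal(sum(h$fraction), 1)

  # empty set -> zero counts
  h0 <- length_histogram(data.frame(length = numeric(0)),
                         bin_edges = c(100, 500))
  expect_true(all(h0$count == 0))

  # 1,000 simulated CNVRs: fractions re-derived by brute-force tally
  set.seed(17)
  lens <- sample(50:20000, 1000, replace = TRUE)
  h2 <- length_histogram(data.frame(length = lens),
                         bin_edges = c(100, 500, 1000, 5000, 10000))
  expect_equal(sum(h2$count), 1000)
  expect_equal(h2$count[h2$bin == "[500,1000)"],
               sum(lens >= 500 & lens < 1000))
  expect_equal(h2$fraction, h2$count / 1000)
})

test_that("planted CNVR recovery: jittered multi-caller calls reconstruct truth", {
  groups <- data.frame(sample_id = sprintf("S%02d", 1:10),
                       group = rep(c("A", "B"), 5))
  set.seed(99)
  truth <- simulate_cnv_truth(groups, n_neutral = 0, planted = TRUE,
                              planted_length = 2000L, chrom_length = 1e5)
  calls <- simulate_cnv_callsets(truth, chrom_length = 1e5,
                                 jitter_sd = c(10, 20, 30), fn_rate = 0,
                                 fp_mean = 0, imprecise_frac = 0, seed = 100)
  cs <- build_cnvrs(consensus_calls(filter_sv_calls(calls)))
  expect_equal(nrow(cs$cnvrs), 1)
  tr <- truth$regions[truth$regions$differentiated, ]
  ov <- min(cs$cnvrs$end, tr$end) - max(cs$cnvrs$start, tr$start)
  expect_gte(ov / (tr$end - tr$start), 0.9)
  expect_gte(ov / cs$cnvrs$length, 0.9)
})
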