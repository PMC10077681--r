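#' @useDynLib sweepcnvr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Simulation parameter set
#'
#' Parameters of the forward Wright-Fisher simulator. Defaults are the
#' package's desk-scale study conditions: N = 200 diploids on a 500 kb
#' chromosome with per-bp rates rescaled so that theta/bp = 4e-4 and the
#' expected sweep footprint, about 1/(rec x T_fix) with T_fix ~ 2 ln(2N)/s,
#' is on the order of the 50 kb analysis windows; burn-in 10N generations;
#' sample of 30 diploids (matching a 30-animal resequencing panel).
#'
#' @param N Population size in diploids.
#' @param L Chromosome length (bp).
#' @param mu Per-bp per-generation mutation rate.
#' @param rec Per-bp per-generation recombination rate.
#' @param s Selection coefficient (additive; diploid fitness 1, 1+s, 1+2s);
#'   0 for neutral runs.
#' @param sweep_pos Position of the selected site (default mid-chromosome).
#' @param burnin Neutral burn-in generations (default 10N).
#' @param max_sweep_gen Cap on post-introduction generations.
#' @param retry_cap Retries when conditioning on fixation (default 200).
#' @param sample_n Diploids sampled at the end (default 30).
#' @param seed Optional integer seed fixing the full output.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(N = 200L, L = 5e5, mu = 5e-7, rec = 1.5e-7, s = 0,
                       sweep_pos = round(L / 2), burnin = 10L * N,
                       max_sweep_gen = 5000L, retry_cap = 200L,
                       sample_n = 30L, seed = NULL) {
  stopifnot(N >= 2, L > 0, mu >= 0, rec >= 0, s >= 0,
            sweep_pos >= 1, sweep_pos <= L, sample_n >= 1)
  structure(list(N = as.integer(N), L = L, mu = mu, rec = rec, s = s,
                 sweep_pos = as.integer(sweep_pos),
                 burnin = as.integer(burnin),
                 max_sweep_gen = as.integer(max_sweep_gen),
                 retry_cap = as.integer(retry_cap),
                 sample_n = as.integer(sample_n), seed = seed),
            class = "sim_params")
}

#' Forward Wright-Fisher simulation of a phased sample
#'
#' Discrete-generation Wright-Fisher simulation with Poisson mutation
#' (infinite sites on the integer grid), Poisson crossovers, and optional
#' additive selection at a single sweep site. When `s > 0` the run is
#' conditioned on fixation of the beneficial allele: lost trajectories are
#' restarted from the introduction state up to `retry_cap` times, after
#' which an error is raised. The sample is drawn immediately at fixation
#' (or after burn-in for neutral runs).
#'
#' @param p A [sim_params()] object.
#' @return A [haplotype_matrix()] of `2 * sample_n` haplotypes restricted
#'   to sites segregating in the sample; attributes `retries` and
#'   `sweep_generations` record the conditioning effort.
#' @export
simulate_population <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (!is.null(p$seed)) set.seed(p$seed)
  res <- wf_simulate_cpp(p$N, p$L, p$mu, p$rec, p$s, p$sweep_pos,
                         p$burnin, p$max_sweep_gen, p$retry_cap, p$sample_n)
  ids <- sprintf("S%02d", seq_len(p$sample_n))
  hm <- haplotype_matrix(chrom = "1", positions = res$positions,
                         alleles = res$alleles, sample_ids = ids)
  attr(hm, "retries") <- res$retries
  attr(hm, "sweep_generations") <- res$sweep_generations
  hm
}

#' Two phenotype groups sharing a neutral background
#'
#' Simulates a neutral population sample, splits it into two groups
#' (default sizes 14 and 16, the high/poor sperm-motility design), and
#' plants one differentiated site whose allele is drawn per haplotype as
#' Bernoulli(f1) in group A and Bernoulli(f2) in group B.
#'
#' @param p A [sim_params()] (its `s` is ignored; the background is
#'   neutral).
#' @param diff_site_freqs Length-2 vector `c(f1, f2)` of group allele
#'   frequencies at the planted site.
#' @param group_sizes Diploids per group (default `c(14, 16)`).
#' @param group_labels Group names (default `c("HSM", "PSM")`).
#' @param diff_pos Position of the planted site (default mid-chromosome,
#'   nudged off any existing site).
#' @return List with `hm` (haplotype matrix including the planted site),
#'   `groups` (sample/group table) and `diff_pos`.
#' @export
simulate_two_groups <- function(p, diff_site_freqs, group_sizes = c(14L, 16L),
                                group_labels = c("HSM", "PSM"),
                                diff_pos = NULL) {
  stopifnot(length(diff_site_freqs) == 2,
            all(diff_site_freqs >= 0 & diff_site_freqs <= 1))
  p$sample_n <- sum(group_sizes)
  p$s <- 0
  hm <- simulate_population(p)
  if (is.null(diff_pos)) diff_pos <- as.integer(round(p$L / 2))
  while (diff_pos %in% hm$positions) diff_pos <- diff_pos + 1L
  grp <- rep(group_labels, group_sizes)
  hap_grp <- rep(grp, each = 2L)
  col <- as.integer(stats::rbinom(length(hap_grp), 1L,
                                  ifelse(hap_grp == group_labels[1],
                                         diff_site_freqs[1],
                                         diff_site_freqs[2])))
  ins <- findInterval(diff_pos, hm$positions)
  pos2 <- append(hm$positions, diff_pos, after = ins)
  al2 <- cbind(hm$alleles[, seq_len(ins), drop = FALSE], col,
               hm$alleles[, setdiff(seq_along(hm$positions),
                                    seq_len(ins)), drop = FALSE])
  colnames(al2) <- NULL
  hm2 <- haplotype_matrix(hm$chrom, pos2, al2, hm$sample_ids)
  list(hm = hm2,
       groups = data.frame(sample_id = hm$sample_ids, group = grp,
                           stringsAsFactors = FALSE),
       diff_pos = diff_pos)
}

#' Ground-truth copy-number landscape
#'
#' Draws `n_neutral` non-overlapping CNV regions whose carriers are
#' assigned independently of group, and optionally plants one
#' group-differentiated deletion emulating a fully penetrant case: copy
#' number 0 in every sample of the second group and in half of the first
#' group, diploid (2) elsewhere.
#'
#' @param groups Group table (`sample_id`, `group`).
#' @param n_neutral Number of neutral regions (default 100).
#' @param chrom_length Chromosome length (bp, default 5e6).
#' @param planted Plant the differentiated deletion (default `TRUE`).
#' @param planted_length Length of the planted deletion (default 2416 bp,
#'   a realistic intronic deletion size).
#' @param len_range Neutral region length range (bp, default 100..5000).
#' @param carrier_freq_range Range of per-region carrier frequencies.
#' @param seed Optional seed.
#' @return List of class `cnv_truth`: `regions` (`region_id`, `chrom`,
#'   `start`, `end`, `type`, `differentiated`) and `cn` matrix (region x
#'   sample true integer copy numbers).
#' @export
simulate_cnv_truth <- function(groups, n_neutral = 100L, chrom_length = 5e6,
                               planted = TRUE, planted_length = 2416L,
                               len_range = c(100L, 5000L),
                               carrier_freq_range = c(0.1, 0.5),
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  validate_groups(groups)
  samples <- groups$sample_id
  labs <- unique(groups$group)
  n_tot <- n_neutral + as.integer(planted)
  # non-overlapping placement by rejection
  lens <- as.integer(round(stats::runif(n_tot, len_range[1], len_range[2])))
  if (planted) lens[n_tot] <- as.integer(planted_length)
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(n_tot)) {
    tries <- 0L
    repeat {
      st <- as.integer(floor(stats::runif(1, 0, chrom_length - lens[i])))
      en <- st + lens[i]
      if (!length(starts) || all(en <= starts | st >= ends)) break
      tries <- tries + 1L
      if (tries > 10000L)
        stop("cannot place ", n_tot, " non-overlapping CNV regions on a ",
             chrom_length, " bp chromosome")
    }
    starts <- c(starts, st); ends <- c(ends, en)
  }
  cn <- matrix(2L, nrow = n_tot, ncol = length(samples),
               dimnames = list(sprintf("TRUE_%03d", seq_len(n_tot)), samples))
  type <- character(n_tot)
  differentiated <- logical(n_tot)
  for (i in seq_len(n_neutral)) {
    type[i] <- if (stats::runif(1) < 0.85) "DEL" else "DUP"
    f <- stats::runif(1, carrier_freq_range[1], carrier_freq_range[2])
    carrier <- stats::runif(length(samples)) < f
    if (type[i] == "DEL") {
      cn[i, carrier] <- ifelse(stats::runif(sum(carrier)) < 0.3, 0L, 1L)
    } else {
      cn[i, carrier] <- ifelse(stats::runif(sum(carrier)) < 0.3, 4L, 3L)
    }
  }
  if (planted) {
    i <- n_tot
    type[i] <- "DEL"
    differentiated[i] <- TRUE
    in_b <- groups$group == labs[2]
    a_ids <- samples[!in_b]
    half_a <- a_ids[seq_len(floor(length(a_ids) / 2))]
    cn[i, samples[in_b]] <- 0L
    cn[i, half_a] <- 0L
  }
  ord <- order(starts)
  structure(list(
    regions = data.frame(region_id = rownames(cn)[ord], chrom = "1",
                         start = starts[ord], end = ends[ord],
                         type = type[ord], differentiated = differentiated[ord],
                         stringsAsFactors = FALSE),
    cn = cn[ord, , drop = FALSE]), class = "cnv_truth")
}

#' Emit noisy multi-caller SV call sets from a copy-number truth
#'
#' Three pseudo-callers with distinct error models re-emit every true
#' event for each carrier sample with probability `1 - fn_rate`, jittering
#' breakpoints by caller-specific Gaussian noise, drawing supporting reads
#' from a Poisson, flagging a fraction IMPRECISE, and adding uniform false
#' positives. Only the read-depth caller annotates copy number (truth plus
#' Gaussian noise).
#'
#' @param truth A [simulate_cnv_truth()] result.
#' @param chrom_length Chromosome length (for FP placement).
#' @param callers Caller names (default sniffles/lumpy/cnvnator-like).
#' @param jitter_sd Per-caller breakpoint jitter SD in bp.
#' @param fn_rate Per-caller false-negative rate.
#' @param fp_mean Per-caller expected false positives per sample.
#' @param support_mean Mean supporting reads (Poisson).
#' @param imprecise_frac Fraction of true calls flagged IMPRECISE.
#' @param cn_sd SD of the Gaussian copy-number annotation noise.
#' @param cn_caller Which caller annotates copy number (default the third).
#' @param seed Optional seed.
#' @return SV call `data.frame` across all callers and samples.
#' @export
simulate_cnv_callsets <- function(truth, chrom_length = 5e6,
                                  callers = c("sniffles", "lumpy", "cnvnator"),
                                  jitter_sd = c(10, 25, 40),
                                  fn_rate = 0.05, fp_mean = 0.3,
                                  support_mean = 12, imprecise_frac = 0.08,
                                  cn_sd = 0.15, cn_caller = "cnvnator",
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(jitter_sd >= 0), fn_rate >= 0, fn_rate <= 1)
  reg <- truth$regions
  samples <- colnames(truth$cn)
  rows <- list()
  for (ci in seq_along(callers)) {
    for (s in samples) {
      for (ri in seq_len(nrow(reg))) {
        tc <- truth$cn[reg$region_id[ri], s]
        if (tc == 2L) next
        if (stats::runif(1) < fn_rate) next
        st <- reg$start[ri] + round(stats::rnorm(1, 0, jitter_sd[ci]))
        en <- reg$end[ri] + round(stats::rnorm(1, 0, jitter_sd[ci]))
        st <- max(0L, as.integer(st))
        en <- as.integer(max(en, st + 1L))
        svt <- if (tc < 2L) "DEL" else "DUP"
        cnval <- if (callers[ci] == cn_caller)
          max(0, tc + stats::rnorm(1, 0, cn_sd)) else NA_real_
        rows[[length(rows) + 1L]] <- sv_calls(
          caller = callers[ci], sample_id = s, chrom = reg$chrom[ri],
          start = st, end = en, svtype = svt,
          precise = stats::runif(1) >= imprecise_frac,
          support_reads = stats::rpois(1, support_mean),
          copy_number = cnval,
          genotype = if (tc %in% c(0L, 4L)) "hom" else "het")
      }
      nfp <- stats::rpois(1, fp_mean)
      for (k in seq_len(nfp)) {
        len <- as.integer(round(stats::runif(1, 50, 1000)))
        st <- as.integer(floor(stats::runif(1, 0, chrom_length - len)))
        rows[[length(rows) + 1L]] <- sv_calls(
          caller = callers[ci], sample_id = s, chrom = "1",
          start = st, end = st + len,
          svtype = if (stats::runif(1) < 0.8) "DEL" else "DUP",
          precise = stats::runif(1) >= imprecise_frac,
          support_reads = stats::rpois(1, support_mean / 2),
          copy_number = NA_real_)
      }
    }
  }
  if (!length(rows))
    return(sv_calls(character(0), character(0), character(0),
                    integer(0), integer(0), character(0)))
  do.call(rbind, rows)
}

#' Random annotation fixtures: gene models and a QTL table
#'
#' Generates non-pathological random gene models (2-8 exons each,
#' non-overlapping gene spans) and QTL intervals with trait classes and
#' P-values, writing them as GFF3 and TSV consumable by [read_gff()] and
#' [read_qtl_table()].
#'
#' @param n_genes,n_qtls Feature counts.
#' @param chrom_length Chromosome length (bp).
#' @param dir Output directory (created if needed).
#' @param seed Optional seed.
#' @return List with `gff` and `qtl` file paths plus the generated
#'   `gene_models` object and QTL data frame (pre-filter).
#' @export
make_fixtures <- function(n_genes = 20L, n_qtls = 15L, chrom_length = 5e6,
                          dir = tempdir(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes <- data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  exons <- genes
  starts <- integer(0); ends <- integer(0)
  max_len <- max(500, min(50000, floor(chrom_length / max(1, 3 * n_genes))))
  for (i in seq_len(n_genes)) {
    len <- as.integer(round(stats::runif(1, max(200, max_len / 10), max_len)))
    tries <- 0L
    repeat {
      st <- as.integer(floor(stats::runif(1, 0, chrom_length - len)))
      en <- st + len
      if (!length(starts) || all(en <= starts | st >= ends)) break
      tries <- tries + 1L
      if (tries > 10000L)
        stop("cannot place ", n_genes, " non-overlapping genes on a ",
             chrom_length, " bp chromosome")
    }
    starts <- c(starts, st); ends <- c(ends, en)
    gid <- sprintf("GENE%03d", i)
    genes <- rbind(genes, data.frame(gene_id = gid, chrom = "1",
                                     start = st, end = en,
                                     stringsAsFactors = FALSE))
    n_ex <- sample(2:8, 1)
    bounds <- sort(sample(seq(st, en), 2L * n_ex))
    for (j in seq_len(n_ex))
      exons <- rbind(exons, data.frame(gene_id = gid, chrom = "1",
                                       start = bounds[2 * j - 1],
                                       end = max(bounds[2 * j],
                                                 bounds[2 * j - 1] + 1L),
                                       stringsAsFactors = FALSE))
  }
  gm <- structure(list(genes = genes, exons = exons), class = "gene_models")
  gff_path <- file.path(dir, "genes.gff3")
  write_gff(gm, gff_path)

  classes <- c("immunity", "meat", "milk", "production", "reproduction",
               "health", "other")
  if (n_qtls > 0) {
    lo <- max(500, chrom_length / 1000)
    hi <- max(lo + 1, chrom_length / 25)
    len <- as.integer(round(stats::runif(n_qtls, lo, hi)))
    start <- as.integer(floor(stats::runif(n_qtls, 1, chrom_length - len)))
    qtl <- data.frame(qtl_id = sprintf("QTL%03d", seq_len(n_qtls)),
                      chrom = "1",
                      start = start, end = start + len,  # 1-based inclusive
                      trait_class = sample(classes, n_qtls, replace = TRUE),
                      p_value = round(stats::runif(n_qtls, 0, 0.1), 4),
                      stringsAsFactors = FALSE)
  } else {
    qtl <- data.frame(qtl_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      trait_class = character(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  }
  qtl_path <- file.path(dir, "qtl.tsv")
  write_tsv(qtl, qtl_path)
  list(gff = gff_path, qtl = qtl_path, gene_models = gm, qtl_table = qtl)
}
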