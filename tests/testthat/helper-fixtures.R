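# Small in-code fixtures shared across test files.

# haplotype matrix from a plain 0/1 matrix
hm_fixture <- function(mat, positions = NULL, chrom = "1") {
  mat <- as.matrix(mat)
  if (is.null(positions)) positions <- seq_len(ncol(mat)) * 100L
  haplotype_matrix(chrom, positions, mat,
                   sample_ids = sprintf("S%02d", seq_len(nrow(mat) / 2)))
}

# random haplotype matrix (iid sites; no LD structure, fine for oracles)
random_hm <- function(n_hap, n_sites, seed = 1, maxpos = n_sites * 1000L) {
  set.seed(seed)
  pos <- sort(sample.int(maxpos, n_sites))
  repeat {
    mat <- matrix(rbinom(n_hap * n_sites, 1, runif(1, 0.2, 0.8)),
                  nrow = n_hap)
    if (all(colSums(mat) > 0 & colSums(mat) < n_hap)) break
  }
  haplotype_matrix("1", pos, mat,
                   sample_ids = sprintf("S%02d", seq_len(n_hap / 2)))
}

# brute-force nucleotide diversity: mean per-bp differences over all pairs
oracle_pi <- function(hm, start, end) {
  idx <- which(hm$positions > start & hm$positions <= end)
  n <- nrow(hm$alleles)
  tot <- 0
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + sum(hm$alleles[i, idx] != hm$alleles[j, idx])
  tot / choose(n, 2) / (end - start)
}

# direct WC84 evaluation (haploid, two pops) written independently of the
# package: follows the published component formulas term by term
oracle_wc84 <- function(alt1, n1, alt2, n2) {
  p <- c(alt1 / n1, alt2 / n2)
  nvec <- c(n1, n2)
  r <- 2
  nbar <- mean(nvec)
  nc <- (sum(nvec) - sum(nvec^2) / sum(nvec)) / (r - 1)
  pbar <- sum(nvec * p) / sum(nvec)
  s2 <- sum(nvec * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- 0
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                              hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc,
       theta = if (a + b + cc > 0) a / (a + b + cc) else NA_real_)
}

# naive EHH via pairwise homozygosity enumeration over carriers
oracle_ehh <- function(hm, core_site, core_allele, direction) {
  carriers <- which(hm$alleles[, core_site] == core_allele)
  sites <- if (direction == "right")
    core_site:ncol(hm$alleles) else core_site:1
  out <- numeric(length(sites))
  for (k in seq_along(sites)) {
    span <- sites[1:k]
    same <- 0
    for (i in seq_along(carriers)[-length(carriers)])
      for (j in (i + 1):length(carriers))
        if (all(hm$alleles[carriers[i], span] ==
                hm$alleles[carriers[j], span])) same <- same + 1
    out[k] <- same / choose(length(carriers), 2)
  }
  data.frame(pos = hm$positions[sites], ehh = out)
}

# naive trapezoid iHH from the oracle EHH curve, truncated below cutoff
oracle_ihh <- function(hm, site, allele, cutoff = 0.05) {
  tot <- 0
  for (direction in c("left", "right")) {
    cur <- oracle_ehh(hm, site, allele, direction)
    stop_at <- which(cur$ehh < cutoff)
    if (length(stop_at)) cur <- cur[seq_len(stop_at[1]), , drop = FALSE]
    d <- abs(cur$pos - hm$positions[site])
    if (nrow(cur) >= 2)
      tot <- tot + sum(diff(d) * (head(cur$ehh, -1) + tail(cur$ehh, -1)) / 2)
  }
  tot
}

# random interval data frame
random_intervals <- function(n, chrom_length = 1e6, min_len = 100,
                             max_len = 20000, prefix = "IV", seed = 1) {
  set.seed(seed)
  len <- round(runif(n, min_len, max_len))
  start <- floor(runif(n, 0, chrom_length - len))
  data.frame(chrom = "1", start = as.integer(start),
             end = as.integer(start + len),
             id = sprintf("%s%03d", prefix, seq_len(n)),
             stringsAsFactors = FALSE)
}

# minimal phased VCF writer for read_genotypes tests
write_test_vcf <- function(path, records, samples = c("A", "B")) {
  hdr <- c("##fileformat=VCFv4.2", "##contig=<ID=1>",
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"anc\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
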