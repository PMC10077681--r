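#' Per-site heterozygosity contributions
#'
#' For each site, the expected pairwise difference n1*n0 / C(n,2), the
#' per-site term of nucleotide diversity.
#' @param hm A [haplotype_matrix()].
#' @return Numeric vector, one value per site.
#' @keywords internal
site_het <- function(hm) {
  n <- nrow(hm$alleles)
  n1 <- colSums(hm$alleles)
  n1 * (n - n1) / choose(n, 2)
}

# indices of sites falling in a 0-based half-open window
.sites_in_window <- function(positions, start, end) {
  which(positions > start & positions <= end)
}

#' Windowed nucleotide diversity
#'
#' Nucleotide diversity per bp in a window: the sum over sites of
#' n1*n0 / C(n,2) divided by the window length, with `S` the number of
#' segregating sites in the window.
#'
#' @param hm A [haplotype_matrix()].
#' @param w One-row data frame (or list) with `start`, `end` (0-based
#'   half-open) on `hm`'s chromosome.
#' @return List with `pi` (per bp), `pi_total` (summed pairwise differences)
#'   and `S`.
#' @export
window_pi <- function(hm, w) {
  if (nrow(hm$alleles) < 2L) stop("at least 2 haplotypes required")
  if (w$start < 0 || w$end <= w$start)
    stop("invalid window [", w$start, ",", w$end, ")")
  idx <- .sites_in_window(hm$positions, w$start, w$end)
  het <- site_het(hm)[idx]
  n1 <- colSums(hm$alleles[, idx, drop = FALSE])
  n <- nrow(hm$alleles)
  S <- sum(n1 > 0L & n1 < n)
  pi_total <- sum(het)
  list(pi = pi_total / (w$end - w$start), pi_total = pi_total, S = S)
}

#' Tajima's D
#'
#' The classical standardized difference between the mean-pairwise-difference
#' and segregating-sites estimators of the population mutation rate, with
#' the canonical sample-size constants a1, a2, b1, b2, c1, c2, e1, e2.
#' `S = 0` yields `D = 0` with attribute `undefined = TRUE`.
#'
#' @param S Number of segregating sites.
#' @param pi_total Sum of per-site pairwise-difference terms (NOT per bp).
#' @param n Number of haplotypes (>= 2).
#' @return Tajima's D (numeric scalar).
#' @export
tajimas_d <- function(S, pi_total, n) {
  if (n < 2L) stop("Tajima's D requires n >= 2 haplotypes")
  if (S < 0) stop("S must be non-negative")
  if (S == 0) return(structure(0, undefined = TRUE))
  k <- tajima_constants(n)
  D <- (pi_total - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  D
}

#' Tajima sample-size constants
#' @param n Number of haplotypes.
#' @return List a1, a2, b1, b2, c1, c2, e1, e2.
#' @export
tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Weir-Cockerham variance components at one site (haploid data)
#'
#' The 1984 variance-component estimator for two populations with
#' haplotype-level (haploid) allele counts, so the heterozygosity term is 0
#' and the genotype component c vanishes.
#'
#' @param counts_pop1,counts_pop2 Length-2 vectors `c(n_ref, n_alt)` of
#'   allele counts in each population.
#' @return List with components `a`, `b`, `c`, `theta` (`a/(a+b+c)`, `NA`
#'   when the denominator is 0) and the intermediates `p_bar`, `s2`,
#'   `n_bar`, `n_c`, `r`; `NULL` when either population has no
#'   observations (site skipped).
#' @export
wc_fst_site <- function(counts_pop1, counts_pop2) {
  n1 <- sum(counts_pop1)
  n2 <- sum(counts_pop2)
  if (n1 == 0 || n2 == 0) return(NULL)
  p1 <- counts_pop1[2] / n1
  p2 <- counts_pop2[2] / n2
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  # h_bar = 0 for haploid data
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) * (p_bar * (1 - p_bar) - (r - 1) / r * s2))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) - (r - 1) / r * s2)
  cc <- 0
  den <- a + b + cc
  list(a = a, b = b, c = cc, theta = if (den > 0) a / den else NA_real_,
       p_bar = p_bar, s2 = s2, n_bar = n_bar, n_c = n_c, r = r)
}

#' Per-site WC84 components for all sites of a haplotype matrix
#'
#' @param hm A [haplotype_matrix()].
#' @param groups Data frame with `sample_id`, `group` (two groups).
#' @return `data.frame` with `pos`, `a`, `den` (= a + b + c) and per-site
#'   `theta`; sites unusable in either group carry `NA`.
#' @export
fst_components <- function(hm, groups) {
  validate_groups(groups)
  grp <- groups$group[match(hm$sample_ids, groups$sample_id)]
  if (anyNA(grp))
    stop("samples missing from group table: ",
         paste(hm$sample_ids[is.na(grp)], collapse = ", "))
  hap_grp <- rep(grp, each = 2L)
  labs <- sort(unique(grp))
  a1 <- hm$alleles[hap_grp == labs[1], , drop = FALSE]
  a2 <- hm$alleles[hap_grp == labs[2], , drop = FALSE]
  n1 <- nrow(a1); n2 <- nrow(a2)
  alt1 <- colSums(a1); alt2 <- colSums(a2)
  p1 <- alt1 / n1; p2 <- alt2 / n2
  r <- 2
  n_bar <- (n1 + n2) / r
  n_c <- (r * n_bar - (n1^2 + n2^2) / (r * n_bar)) / (r - 1)
  p_bar <- (n1 * p1 + n2 * p2) / (r * n_bar)
  s2 <- (n1 * (p1 - p_bar)^2 + n2 * (p2 - p_bar)^2) / ((r - 1) * n_bar)
  a <- (n_bar / n_c) *
    (s2 - (1 / (n_bar - 1)) * (p_bar * (1 - p_bar) - (r - 1) / r * s2))
  b <- (n_bar / (n_bar - 1)) * (p_bar * (1 - p_bar) - (r - 1) / r * s2)
  den <- a + b
  data.frame(pos = hm$positions, a = a, den = den,
             theta = ifelse(den > 0, a / den, NA_real_))
}

#' Windowed F_ST as a ratio of sums
#'
#' The "weighted" windowed Weir-Cockerham estimate: summed numerator
#' components over summed denominators for all usable sites in the window.
#' Negative values are reported as computed, not truncated.
#'
#' @param comp Output of [fst_components()].
#' @param w Window (list/row with `start`, `end`, 0-based half-open).
#' @return F_ST for the window, or `NA` if no usable site.
#' @export
window_fst <- function(comp, w) {
  idx <- .sites_in_window(comp$pos, w$start, w$end)
  use <- idx[!is.na(comp$den[idx]) & comp$den[idx] > 0]
  if (!length(use)) return(NA_real_)
  sum(comp$a[use]) / sum(comp$den[use])
}

#' Empirical background site-frequency spectrum
#'
#' Distribution of derived-allele counts over segregating sites
#' (polymorphic classes 1..n-1 only), normalized to sum to 1.
#' @param hm A [haplotype_matrix()].
#' @return List of class `sfs_background` with `n` (haplotypes) and `prob`
#'   (length n-1 vector over derived counts 1..n-1).
#' @export
background_sfs <- function(hm) {
  n <- nrow(hm$alleles)
  cnt <- derived_counts(hm)
  cnt <- cnt[cnt > 0L & cnt < n]
  if (!length(cnt)) stop("no segregating sites; cannot build background SFS")
  prob <- tabulate(cnt, nbins = n - 1L)
  structure(list(n = n, prob = prob / sum(prob)), class = "sfs_background")
}

#' Full selective-sweep window scan
#'
#' Computes, per window, any subset of: nucleotide diversity and segregating
#' sites (`pi`), Tajima's D (`tajima_d`), windowed Weir-Cockerham F_ST
#' (`fst`, needs `groups`), SweepFinder-style CLR at the window's grid point
#' (`clr`), and mean absolute standardized iHS over sites in the window
#' (`ihs`). Failures in one window are recorded as `NA` for that window;
#' the scan never aborts.
#'
#' @param hm A [haplotype_matrix()].
#' @param windows Data frame from [make_windows()].
#' @param methods Character subset of `c("pi","tajima_d","fst","clr","ihs")`.
#' @param groups Group table, required for `"fst"`.
#' @param clr_grid_size Grid spacing for the CLR scan (default one point per
#'   50 kb window).
#' @param ... Passed to [ihs_scan()] (MAF bound, EHH cutoff, bins).
#' @return `data.frame`: one row per window with requested statistic columns.
#' @export
sweep_scan <- function(hm, windows,
                       methods = c("pi", "tajima_d", "fst", "clr", "ihs"),
                       groups = NULL, clr_grid_size = 50000L, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- windows
  n <- nrow(hm$alleles)
  nw <- nrow(windows)
  if (any(c("pi", "tajima_d") %in% methods)) {
    out$n_sites <- NA_integer_
    out$pi <- NA_real_
    if ("tajima_d" %in% methods) out$tajima_d <- NA_real_
    for (i in seq_len(nw)) {
      res <- tryCatch(window_pi(hm, windows[i, ]), error = function(e) NULL)
      if (is.null(res)) next
      out$n_sites[i] <- res$S
      out$pi[i] <- res$pi
      if ("tajima_d" %in% methods)
        out$tajima_d[i] <- if (res$S > 0)
          tajimas_d(res$S, res$pi_total, n) else NA_real_
    }
  }
  if ("fst" %in% methods) {
    if (is.null(groups)) stop("F_ST scan requires a group table")
    comp <- fst_components(hm, groups)
    out$fst <- vapply(seq_len(nw), function(i)
      window_fst(comp, windows[i, ]), numeric(1))
  }
  if ("clr" %in% methods) {
    cs <- tryCatch(clr_scan(hm, chrom_length = max(windows$end),
                            grid_size = clr_grid_size),
                   error = function(e) NULL)
    out$clr <- NA_real_
    if (!is.null(cs)) {
      for (i in seq_len(nw)) {
        mid <- (windows$start[i] + windows$end[i]) / 2
        j <- which.min(abs(cs$pos - mid))
        out$clr[i] <- cs$clr[j]
      }
    }
  }
  if ("ihs" %in% methods) {
    rec <- tryCatch(ihs_scan(hm, ...), error = function(e) NULL)
    out$mean_abs_ihs <- NA_real_
    if (!is.null(rec) && nrow(rec)) {
      for (i in seq_len(nw)) {
        idx <- which(rec$pos > windows$start[i] & rec$pos <= windows$end[i] &
                       !is.na(rec$ihs_std))
        if (length(idx)) out$mean_abs_ihs[i] <- mean(abs(rec$ihs_std[idx]))
      }
    }
  }
  out
}
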