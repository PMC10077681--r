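#' Sweep-model emission probabilities for every escape count
#'
#' Precomputes P(observed derived count = c | k of n lineages escaped the
#' sweep) for k = 0..n and polymorphic c = 1..n-1, given a background SFS.
#' Conditional on k escapees, a pre-sweep sample of size k+1 (the k
#' escapees plus one lineage representing every swept chromosome) has its
#' derived count drawn by hypergeometric downsampling of the background
#' spectrum; the swept lineage then contributes n-k copies of its allele,
#' each escapee one copy. The k = n row is the background spectrum itself,
#' so the fully-escaped limit reproduces the background model exactly.
#'
#' @param bg An `sfs_background` from [background_sfs()].
#' @return `(n+1) x (n-1)` matrix; rows k = 0..n, columns c = 1..n-1. Rows
#'   need not sum to 1: mass on monomorphic outcomes (c = 0 or n) is
#'   dropped. [clr_at()] conditions on polymorphism by renormalizing with
#'   the row sums, since only segregating sites enter the scan.
#' @export
sweep_emission_matrix <- function(bg) {
  n <- bg$n
  probs <- bg$prob  # over derived counts 1..n-1
  M <- matrix(0, nrow = n + 1L, ncol = n - 1L)
  i <- seq_len(n - 1L)  # background derived counts
  for (k in 0:(n - 1L)) {
    m <- k + 1L
    # downsampled distribution over j = 0..m derived among the m pre-sweep lineages
    Dj <- vapply(0:m, function(j)
      sum(probs * stats::dhyper(j, i, n - i, m)), numeric(1))
    for (j in 0:m) {
      pj <- Dj[j + 1L]
      if (pj == 0) next
      p_der <- j / m                     # swept lineage is derived
      c_der <- j - 1L + (n - k)          # swept lineage expands to n-k copies
      c_anc <- j
      if (p_der > 0 && c_der >= 1L && c_der <= n - 1L)
        M[k + 1L, c_der] <- M[k + 1L, c_der] + pj * p_der
      if (p_der < 1 && c_anc >= 1L && c_anc <= n - 1L)
        M[k + 1L, c_anc] <- M[k + 1L, c_anc] + pj * (1 - p_der)
    }
  }
  M[n + 1L, ] <- probs
  M
}

#' Default sweep-intensity grid
#'
#' Geometric grid of alpha values (1/bp) spanning effectively fully-swept
#' to effectively background at the scales of a 50 kb window, plus the
#' exact background limit `Inf` (escape probability 1 everywhere), which
#' guarantees CLR >= 0 after maximization.
#' @param n_alpha Number of finite grid values (default 20).
#' @return Numeric vector of alpha values including `Inf`.
#' @export
default_alpha_grid <- function(n_alpha = 20L) {
  c(10^seq(log10(1e-8), log10(1e-2), length.out = n_alpha), Inf)
}

#' Composite likelihood ratio at one grid position
#'
#' Nielsen-style sweep model: each of the n sampled lineages escapes the
#' sweep independently with probability `p_e = 1 - exp(-alpha * d)` at
#' distance d from the grid position. The per-site sweep likelihood sums
#' binomial escape configurations against [sweep_emission_matrix()],
#' conditioned on the site being polymorphic (only segregating sites enter
#' the composite likelihood, so the model is compared on the shape of the
#' polymorphic spectrum); the composite log-likelihood ratio against the
#' background spectrum is maximized over the alpha grid. Because the grid
#' contains the background limit, the reported CLR is always >= 0.
#'
#' @param grid_pos Test position (bp).
#' @param sites `data.frame` with `pos` and derived `count` (1..n-1).
#' @param bg An `sfs_background`.
#' @param alpha_grid Alpha values to maximize over; see
#'   [default_alpha_grid()].
#' @param M Optional precomputed [sweep_emission_matrix()] (re-used across
#'   grid positions).
#' @return List with `clr` (= 2 * max log-likelihood difference), the
#'   maximizing `alpha`, and `loglik_bg`.
#' @export
clr_at <- function(grid_pos, sites, bg, alpha_grid = default_alpha_grid(),
                   M = NULL) {
  if (is.null(M)) M <- sweep_emission_matrix(bg)
  n <- bg$n
  stopifnot(all(sites$count >= 1L & sites$count <= n - 1L))
  d <- abs(sites$pos - grid_pos)
  lbg <- sum(log(bg$prob[sites$count]))
  Mc <- M[, sites$count, drop = FALSE]  # (n+1) x nsites
  poly_mass <- rowSums(M)               # P(polymorphic outcome | k)
  k <- 0:n
  best <- -Inf
  best_alpha <- Inf
  for (alpha in alpha_grid) {
    pe <- if (is.infinite(alpha)) rep(1, length(d)) else 1 - exp(-alpha * d)
    W <- outer(k, pe, function(ki, pi_) stats::dbinom(ki, n, pi_))
    ll <- sum(log(colSums(W * Mc) / colSums(W * poly_mass)))
    if (is.finite(ll) && ll > best) { best <- ll; best_alpha <- alpha }
  }
  list(clr = max(0, 2 * (best - lbg)), alpha = best_alpha, loglik_bg = lbg)
}

#' CLR scan over a chromosome
#'
#' Evaluates [clr_at()] at one grid point per `grid_size` bp (window
#' midpoints). Every segregating site of the chromosome enters each grid
#' point's composite likelihood — distant sites have escape probability
#' near 1 and revert to the background model, so the sweep signal is
#' intrinsically local — against the genome-wide background spectrum of
#' `hm`.
#'
#' @param hm A [haplotype_matrix()].
#' @param chrom_length Chromosome length (bp).
#' @param grid_size Spacing between grid points (default 50 kb).
#' @param alpha_grid See [default_alpha_grid()].
#' @return `data.frame` with `pos` (grid point), `clr`, `alpha`, `n_sites`
#'   (sites within the grid window, for reference).
#' @export
clr_scan <- function(hm, chrom_length, grid_size = 50000L,
                     alpha_grid = default_alpha_grid()) {
  bg <- background_sfs(hm)
  M <- sweep_emission_matrix(bg)
  cnt <- derived_counts(hm)
  poly <- cnt > 0L & cnt < bg$n
  sites <- data.frame(pos = hm$positions[poly], count = cnt[poly])
  grid <- seq.int(as.integer(grid_size), by = as.integer(grid_size),
                  length.out = floor((chrom_length - 1) / grid_size))
  res <- lapply(grid, function(g) {
    n_in <- sum(abs(sites$pos - g) <= grid_size / 2)
    fit <- clr_at(g, sites, bg, alpha_grid = alpha_grid, M = M)
    data.frame(pos = g, clr = fit$clr, alpha = fit$alpha, n_sites = n_in)
  })
  do.call(rbind, res)
}
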