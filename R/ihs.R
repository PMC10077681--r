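#' Extended haplotype homozygosity from a core site
#'
#' EHH at distance x from the core: among haplotypes carrying the core
#' allele, the probability that two randomly drawn carriers are identical
#' over every site from the core out to x, i.e.
#' `sum_h C(count_h, 2) / C(n_core, 2)` over distinct extended haplotypes h.
#' EHH(0) = 1 by definition. The curve is walked site by site in one
#' direction and truncated at the first site where it drops below `cutoff`
#' (that site is included, so the crossing is observable).
#'
#' @param hm A [haplotype_matrix()].
#' @param core_site Column index of the core site.
#' @param core_allele 0 or 1: which allele defines the carrier set.
#' @param direction `"right"` (increasing positions) or `"left"`.
#' @param cutoff Truncation threshold (default 0.05).
#' @return `data.frame` with `pos` and `ehh`, first row the core site with
#'   `ehh = 1`; attribute `reached_cutoff` says whether the curve fell below
#'   `cutoff` before the end of the data.
#' @export
ehh <- function(hm, core_site, core_allele, direction = c("right", "left"),
                cutoff = 0.05) {
  direction <- match.arg(direction)
  carriers <- which(hm$alleles[, core_site] == core_allele)
  if (length(carriers) < 2L)
    stop("core allele carried by fewer than 2 haplotypes")
  nc2 <- choose(length(carriers), 2)
  sites <- if (direction == "right") {
    seq_len(ncol(hm$alleles))[-seq_len(core_site)]
  } else rev(seq_len(core_site - 1L))

  pos <- hm$positions[core_site]
  vals <- 1
  grp <- rep(1L, length(carriers))  # haplotype-identity classes so far
  reached <- FALSE
  for (s in sites) {
    key <- grp * 2L + hm$alleles[carriers, s]
    grp <- match(key, key)  # compact class ids after the split
    e <- sum(choose(tabulate(grp, nbins = length(grp)), 2)) / nc2
    pos <- c(pos, hm$positions[s])
    vals <- c(vals, e)
    if (e < cutoff) { reached <- TRUE; break }
  }
  structure(data.frame(pos = pos, ehh = vals), reached_cutoff = reached)
}

# trapezoidal integral of an EHH curve against physical distance from core
.ihh_integral <- function(curve, core_pos) {
  d <- abs(curve$pos - core_pos)
  if (nrow(curve) < 2L) return(0)
  sum(diff(d) * (utils::head(curve$ehh, -1) + utils::tail(curve$ehh, -1)) / 2)
}

#' Integrated haplotype score at one site
#'
#' iHH for each core allele is the trapezoidal integral of the EHH curve
#' against physical distance, summed over the left and right directions;
#' `ihs_raw = ln(ihh_a / ihh_d)` (ancestral over derived). Sites where any
#' of the four EHH curves fails to fall below `cutoff` before the end of
#' the data are flagged (`keep = FALSE`) and carry `NA` scores, matching
#' the usual practice of dropping unbounded integrals.
#'
#' @param hm A [haplotype_matrix()].
#' @param site Column index of the core site.
#' @param maf Minimum minor (derived) allele frequency (default 0.05).
#' @param cutoff EHH truncation threshold (default 0.05).
#' @return One-row `data.frame`: `pos`, `derived_freq`, `ihh_a`, `ihh_d`,
#'   `ihs_raw`, `keep`.
#' @export
ihs <- function(hm, site, maf = 0.05, cutoff = 0.05) {
  n <- nrow(hm$alleles)
  derived_allele <- if (hm$ancestral_is_ref[site]) 1L else 0L
  n_der <- sum(hm$alleles[, site] == derived_allele)
  f <- n_der / n
  rec <- data.frame(pos = hm$positions[site], derived_freq = f,
                    ihh_a = NA_real_, ihh_d = NA_real_,
                    ihs_raw = NA_real_, keep = FALSE)
  if (f < maf || f > 1 - maf) return(rec)
  ok <- TRUE
  ihh <- c(a = 0, d = 0)
  for (al in c("a", "d")) {
    allele <- if (al == "d") derived_allele else 1L - derived_allele
    for (dir in c("left", "right")) {
      cur <- ehh(hm, site, allele, dir, cutoff = cutoff)
      if (!attr(cur, "reached_cutoff")) ok <- FALSE
      ihh[al] <- ihh[al] + .ihh_integral(cur, hm$positions[site])
    }
  }
  rec$ihh_a <- ihh[["a"]]
  rec$ihh_d <- ihh[["d"]]
  if (ok && ihh[["a"]] > 0 && ihh[["d"]] > 0) {
    rec$ihs_raw <- log(ihh[["a"]] / ihh[["d"]])
    rec$keep <- TRUE
  }
  rec
}

#' Standardize iHS scores within derived-frequency bins
#'
#' Within equal-width derived-allele-frequency bins, subtract the bin mean
#' and divide by the bin standard deviation (population denominator, so a
#' two-score bin {-1, 1} standardizes to exactly {-1, 1}). Bins with fewer
#' than 2 usable records or zero spread yield flagged missing scores.
#'
#' @param records `data.frame` with at least `derived_freq` and `ihs_raw`.
#' @param n_bins Number of equal-width frequency bins on (0, 1), default 50.
#' @return `records` with an added `ihs_std` column.
#' @export
standardize_ihs <- function(records, n_bins = 50L) {
  if (!nrow(records)) {
    records$ihs_std <- numeric(0)
    return(records)
  }
  edges <- seq(0, 1, length.out = n_bins + 1L)
  bin <- cut(records$derived_freq, breaks = edges, include.lowest = TRUE)
  records$ihs_std <- NA_real_
  for (b in levels(bin)) {
    idx <- which(bin == b & !is.na(records$ihs_raw))
    if (length(idx) < 2L) next
    m <- mean(records$ihs_raw[idx])
    s <- sqrt(mean((records$ihs_raw[idx] - m)^2))
    if (s == 0) next
    records$ihs_std[idx] <- (records$ihs_raw[idx] - m) / s
  }
  records
}

#' iHS over all eligible sites of a haplotype matrix
#'
#' Runs [ihs()] at every site within the MAF bounds and standardizes the
#' raw scores within derived-frequency bins.
#'
#' @inheritParams ihs
#' @param n_bins Frequency bins for standardization (default 50).
#' @return `data.frame` with one row per scored site: `pos`, `derived_freq`,
#'   `ihh_a`, `ihh_d`, `ihs_raw`, `keep`, `ihs_std`.
#' @export
ihs_scan <- function(hm, maf = 0.05, cutoff = 0.05, n_bins = 50L) {
  n <- nrow(hm$alleles)
  der <- derived_counts(hm) / n
  eligible <- which(der >= maf & der <= 1 - maf)
  if (!length(eligible))
    return(data.frame(pos = integer(0), derived_freq = numeric(0),
                      ihh_a = numeric(0), ihh_d = numeric(0),
                      ihs_raw = numeric(0), keep = logical(0),
                      ihs_std = numeric(0)))
  rows <- lapply(eligible, function(s)
    tryCatch(ihs(hm, s, maf = maf, cutoff = cutoff),
             error = function(e) NULL))
  rec <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  standardize_ihs(rec, n_bins = n_bins)
}
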