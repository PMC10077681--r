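#' Normalized copy-number matrix over CNVRs
#'
#' One row per CNVR, one column per sample. A sample's entry is its member
#' call's copy-number annotation when present (mean over multiple calls);
#' a DEL call without copy number contributes 0 (hom) or 1 (het, the
#' default when the genotype is unknown); a DUP call without copy number
#' contributes 3; samples without a call at the CNVR are imputed at the
#' diploid baseline 2.
#'
#' @param cnvr_set A [build_cnvrs()] result.
#' @param samples Character vector of all sample ids (matrix columns).
#' @param groups Optional group table; when given, every sample must appear
#'   in it.
#' @return Numeric matrix with CNVR ids as row names, sample ids as columns.
#' @export
copy_number_matrix <- function(cnvr_set, samples, groups = NULL) {
  if (!is.null(groups)) {
    missing_s <- setdiff(samples, groups$sample_id)
    if (length(missing_s))
      stop("samples absent from group table: ",
           paste(missing_s, collapse = ", "))
  }
  cn <- cnvr_set$cnvrs
  mem <- cnvr_set$members
  M <- matrix(2, nrow = nrow(cn), ncol = length(samples),
              dimnames = list(cn$cnvr_id, samples))
  if (!nrow(mem)) return(M)
  val <- ifelse(!is.na(mem$copy_number), mem$copy_number,
                ifelse(mem$svtype == "DUP", 3,
                       ifelse(!is.na(mem$genotype) & mem$genotype == "hom",
                              0, 1)))
  agg <- stats::aggregate(val,
                          by = list(cnvr_id = mem$cnvr_id,
                                    sample_id = mem$sample_id), FUN = mean)
  for (i in seq_len(nrow(agg))) {
    if (!agg$sample_id[i] %in% samples)
      stop("member call sample not in sample list: ", agg$sample_id[i])
    M[agg$cnvr_id[i], agg$sample_id[i]] <- agg$x[i]
  }
  M
}

#' V_ST copy-number differentiation statistic
#'
#' `VST = (VT - VS) / VT`, where VT is the variance of copy number across
#' all individuals and VS the average within-group variance weighted by
#' group size. Variances use the population denominator by default
#' (`ddof = 0`). `VT = 0` yields a flagged missing value.
#'
#' @param values Numeric per-sample copy numbers.
#' @param groups Character/factor group label per value (two groups).
#' @param ddof Delta degrees of freedom for the variance (default 0).
#' @return List `v_t`, `v_s`, `vst`, `n` (named group sizes).
#' @export
vst <- function(values, groups, ddof = 0) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  tab <- table(groups)
  if (length(tab) != 2L || any(tab == 0))
    stop("V_ST requires exactly two non-empty groups")
  varfun <- function(x) {
    if (length(x) <= ddof) return(0)
    sum((x - mean(x))^2) / (length(x) - ddof)
  }
  v_t <- varfun(values)
  v_g <- tapply(values, groups, varfun)
  n_g <- as.numeric(tab[names(v_g)])
  v_s <- sum(n_g * v_g) / sum(n_g)
  out <- list(v_t = v_t, v_s = v_s,
              vst = if (v_t > 0) (v_t - v_s) / v_t else NA_real_,
              n = stats::setNames(as.integer(tab), names(tab)))
  out
}

#' V_ST scan over CNVRs with the top-fraction rule
#'
#' Computes V_ST per CNVR from a copy-number matrix and returns the full
#' record table plus the top `ceil(top_fraction * N_defined)` CNVRs by
#' descending V_ST, ties at the cut resolved by (chrom, start).
#'
#' @param cnm A [copy_number_matrix()].
#' @param groups Group table (`sample_id`, `group`).
#' @param cnvrs CNVR `data.frame` (for coordinates; a `cnvr_set` is also
#'   accepted).
#' @param top_fraction Fraction selected (default 0.02, the top-2% rule).
#' @param ddof Variance denominator convention (default 0).
#' @return List with `table` (per-CNVR `v_t`, `v_s`, `vst`, `rank`,
#'   `percentile`, `selected`) and `top` (the selected subset).
#' @export
vst_scan <- function(cnm, groups, cnvrs, top_fraction = 0.02, ddof = 0) {
  if (inherits(cnvrs, "cnvr_set")) cnvrs <- cnvrs$cnvrs
  validate_groups(groups)
  grp <- groups$group[match(colnames(cnm), groups$sample_id)]
  if (anyNA(grp))
    stop("samples absent from group table: ",
         paste(colnames(cnm)[is.na(grp)], collapse = ", "))
  recs <- lapply(seq_len(nrow(cnm)), function(i) {
    v <- vst(cnm[i, ], grp, ddof = ddof)
    data.frame(cnvr_id = rownames(cnm)[i], v_t = v$v_t, v_s = v$v_s,
               vst = v$vst, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, recs)
  tab <- merge(cnvrs[, c("cnvr_id", "chrom", "start", "end")], tab,
               by = "cnvr_id", sort = FALSE)
  defined <- !is.na(tab$vst)
  n_def <- sum(defined)
  if (n_def == 0) {
    warning("all V_ST values undefined (no copy-number variance)")
    tab$rank <- NA_integer_; tab$percentile <- NA_real_
    tab$selected <- FALSE
    return(list(table = tab, top = tab[0, , drop = FALSE]))
  }
  ord <- order(-tab$vst, tab$chrom, tab$start, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab$rank <- ifelse(is.na(tab$vst), NA_integer_, seq_len(nrow(tab)))
  tab$percentile <- ifelse(is.na(tab$vst), NA_real_,
                           100 * (1 - (tab$rank - 1) / n_def))
  k <- ceiling(top_fraction * n_def)
  tab$selected <- !is.na(tab$rank) & tab$rank <= k
  rownames(tab) <- NULL
  list(table = tab, top = tab[tab$selected, , drop = FALSE])
}

#' F_ST candidate regions from a window scan
#'
#' Selects the top `ceil(top_fraction * N_defined)` windows by descending
#' F_ST (ties at the cut by chrom, start) and merges touching or
#' overlapping selected windows into candidate regions (bookended merge).
#'
#' @param window_table `data.frame` with `chrom`, `start`, `end`, `fst`.
#' @param top_fraction Fraction selected (default 0.01, the top-1% rule).
#' @param stat Column name holding the ranking statistic (default
#'   `"fst"`; pass e.g. `"clr"` or `"mean_abs_ihs"` to reuse the rule, or
#'   `"-pi"` style by pre-negating).
#' @return List with `selected` (window subset) and `regions` (merged
#'   `chrom`, `start`, `end`, `n_windows`, `max_stat`).
#' @export
fst_scan <- function(window_table, top_fraction = 0.01, stat = "fst") {
  x <- window_table[[stat]]
  defined <- which(!is.na(x))
  n_def <- length(defined)
  if (!n_def)
    return(list(selected = window_table[0, , drop = FALSE],
                regions = data.frame(chrom = character(0), start = integer(0),
                                     end = integer(0), n_windows = integer(0),
                                     max_stat = numeric(0))))
  k <- ceiling(top_fraction * n_def)
  ord <- defined[order(-x[defined], window_table$chrom[defined],
                       window_table$start[defined])]
  sel <- window_table[sort(ord[seq_len(k)]), , drop = FALSE]
  regions <- merge_intervals(sel, stat = stat)
  list(selected = sel, regions = regions)
}

#' Merge touching or overlapping intervals (bookended)
#' @param df Data frame with `chrom`, `start`, `end` sorted or not.
#' @param stat Optional statistic column to carry the max of.
#' @return Merged intervals with `n_windows` and, if given, `max_stat`.
#' @export
merge_intervals <- function(df, stat = NULL) {
  if (!nrow(df))
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_windows = integer(0),
                      max_stat = numeric(0)))
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  cur <- df[1, , drop = FALSE]
  cur_n <- 1L
  cur_max <- if (!is.null(stat)) cur[[stat]] else NA_real_
  flush <- function() data.frame(chrom = cur$chrom, start = cur$start,
                                 end = cur$end, n_windows = cur_n,
                                 max_stat = cur_max,
                                 stringsAsFactors = FALSE)
  for (i in seq_len(nrow(df))[-1]) {
    row <- df[i, , drop = FALSE]
    if (row$chrom == cur$chrom && row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      cur_n <- cur_n + 1L
      if (!is.null(stat)) cur_max <- max(cur_max, row[[stat]])
    } else {
      out[[length(out) + 1L]] <- flush()
      cur <- row; cur_n <- 1L
      cur_max <- if (!is.null(stat)) row[[stat]] else NA_real_
    }
  }
  out[[length(out) + 1L]] <- flush()
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Positively-selected-gene consensus across scan methods
#'
#' Genes present in the top-window gene sets of at least `min_methods`
#' scan statistics. Monotone: adding a method's set never removes a gene.
#'
#' @param gene_sets Named list of character vectors (method -> gene ids).
#' @param min_methods Minimum number of supporting methods (default 2).
#' @return Character vector of consensus gene ids (sorted).
#' @export
psg_consensus <- function(gene_sets, min_methods = 2L) {
  if (length(gene_sets) < 2L)
    stop("at least two method gene sets are required")
  all_genes <- unlist(lapply(gene_sets, unique))
  tab <- table(all_genes)
  sort(names(tab)[tab >= min_methods])
}

#' Genes overlapping candidate regions
#'
#' Lists every gene whose span overlaps a region by at least 1 bp.
#' @param regions Data frame with `chrom`, `start`, `end` (0-based
#'   half-open).
#' @param genes A `gene_models` object (or its `genes` data frame).
#' @return Data frame of (region index, `chrom`, `start`, `end`,
#'   `gene_id`) pairs.
#' @export
genes_in_regions <- function(regions, genes) {
  g <- if (inherits(genes, "gene_models")) genes$genes else genes
  empty <- data.frame(region = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      gene_id = character(0), stringsAsFactors = FALSE)
  if (!nrow(regions) || !nrow(g)) return(empty)
  hits <- GenomicRanges::findOverlaps(.as_granges(regions), .as_granges(g))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (!length(qi)) return(empty)
  data.frame(region = qi, chrom = regions$chrom[qi],
             start = regions$start[qi], end = regions$end[qi],
             gene_id = g$gene_id[si], stringsAsFactors = FALSE)
}

#' Overlap of candidate items with QTL records
#'
#' Emits every (item, QTL) pair overlapping by at least 1 bp, with both
#' records side by side (the `-wa -wb` contract). An optional reciprocal
#' overlap fraction restricts pairs further.
#'
#' @param items Data frame with `chrom`, `start`, `end` and an id column
#'   (first non-coordinate column is used as `item_id`).
#' @param qtls QTL table from [read_qtl_table()] (already P-filtered).
#' @param reciprocal Optional minimum reciprocal-overlap fraction
#'   (default 0 = any overlap).
#' @return Data frame of pairs: item columns, then QTL columns, plus
#'   `overlap_bp`; also distinct-QTL and pair counts as attributes.
#' @export
qtl_overlap <- function(items, qtls, reciprocal = 0) {
  idcol <- setdiff(colnames(items), c("chrom", "start", "end"))[1]
  empty <- data.frame(item_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      qtl_id = character(0), qtl_start = integer(0),
                      qtl_end = integer(0), trait_class = character(0),
                      p_value = numeric(0), overlap_bp = integer(0),
                      stringsAsFactors = FALSE)
  if (!nrow(items) || !nrow(qtls)) {
    attr(empty, "n_pairs") <- 0L
    attr(empty, "n_distinct_qtls") <- 0L
    return(empty)
  }
  hits <- GenomicRanges::findOverlaps(.as_granges(items), .as_granges(qtls))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (length(qi)) {
    ov <- pmin(items$end[qi], qtls$end[si]) -
      pmax(items$start[qi], qtls$start[si])
    if (reciprocal > 0) {
      keep <- ov / (items$end[qi] - items$start[qi]) >= reciprocal &
        ov / (qtls$end[si] - qtls$start[si]) >= reciprocal
      qi <- qi[keep]; si <- si[keep]; ov <- ov[keep]
    }
  }
  if (!length(qi)) {
    attr(empty, "n_pairs") <- 0L
    attr(empty, "n_distinct_qtls") <- 0L
    return(empty)
  }
  out <- data.frame(
    item_id = if (is.na(idcol)) as.character(qi) else
      as.character(items[[idcol]][qi]),
    chrom = items$chrom[qi], start = items$start[qi], end = items$end[qi],
    qtl_id = qtls$qtl_id[si], qtl_start = qtls$start[si],
    qtl_end = qtls$end[si], trait_class = qtls$trait_class[si],
    p_value = qtls$p_value[si], overlap_bp = ov, stringsAsFactors = FALSE)
  attr(out, "n_pairs") <- nrow(out)
  attr(out, "n_distinct_qtls") <- length(unique(out$qtl_id))
  out
}

#' Summary statistics of a CNVR set
#'
#' Per-type counts (always summing to the total), total and mean length
#' (mean rounded to the nearest bp), context counts and percentages
#' (2 decimals, summing to 100 up to rounding), and, when a genome size is
#' supplied, the genome fraction covered.
#'
#' @param cnvr_set A `cnvr_set` (or a CNVR `data.frame`).
#' @param genome_size Optional genome length (bp) for coverage.
#' @return List of class `cnvr_summary`.
#' @export
summarize_cnvrs <- function(cnvr_set, genome_size = NULL) {
  cn <- if (inherits(cnvr_set, "cnvr_set")) cnvr_set$cnvrs else cnvr_set
  n <- nrow(cn)
  types <- c("deletion", "duplication", "both")
  type_counts <- stats::setNames(
    vapply(types, function(t) sum(cn$cnvr_type == t), integer(1)), types)
  total_len <- sum(cn$length)
  out <- list(
    n_total = n,
    n_by_type = type_counts,
    total_length = total_len,
    mean_length = if (n > 0) round(total_len / n) else NA_real_,
    empty = n == 0)
  if ("context" %in% colnames(cn) && n > 0) {
    ctx <- c("exonic", "intronic", "intergenic")
    cc <- stats::setNames(
      vapply(ctx, function(x) sum(cn$context == x), integer(1)), ctx)
    out$context_counts <- cc
    out$context_pct <- round(100 * cc / n, 2)
  }
  if (!is.null(genome_size) && n > 0)
    out$genome_fraction_pct <- round(100 * total_len / genome_size, 2)
  structure(out, class = "cnvr_summary")
}

#' @export
print.cnvr_summary <- function(x, ...) {
  cat(sprintf("CNVRs: %d (%s)\n", x$n_total,
              paste(names(x$n_by_type), x$n_by_type, sep = "=",
                    collapse = ", ")))
  cat(sprintf("total length: %d bp, mean length: %s bp\n",
              x$total_length, format(x$mean_length)))
  if (!is.null(x$context_pct))
    cat("context: ", paste(names(x$context_pct),
                           sprintf("%.2f%%", x$context_pct),
                           sep = " ", collapse = ", "), "\n", sep = "")
  invisible(x)
}
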