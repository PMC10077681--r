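#' Construct a structural-variant call table
#'
#' Normalizes a per-caller SV call set into the column layout used
#' throughout the CNV chain. Coordinates are 0-based half-open.
#'
#' @param caller,sample_id,chrom,start,end,svtype Vectors (recycled).
#' @param precise Logical: breakpoints precise (no IMPRECISE flag).
#' @param support_reads Supporting-read count.
#' @param filter Caller filter status (`"PASS"` or other).
#' @param copy_number Optional read-depth copy number (diploid baseline 2);
#'   `NA` when the caller does not annotate it.
#' @param genotype Optional `"het"`/`"hom"` for calls without copy number.
#' @return `data.frame` of SV calls.
#' @export
sv_calls <- function(caller, sample_id, chrom, start, end, svtype,
                     precise = TRUE, support_reads = 0L, filter = "PASS",
                     copy_number = NA_real_, genotype = NA_character_) {
  if (length(caller) == 0L)
    return(data.frame(caller = character(0), sample_id = character(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), svtype = character(0),
                      precise = logical(0), support_reads = integer(0),
                      filter = character(0), copy_number = numeric(0),
                      genotype = character(0), stringsAsFactors = FALSE))
  d <- data.frame(caller = caller, sample_id = sample_id,
                  chrom = as.character(chrom),
                  start = as.integer(start), end = as.integer(end),
                  svtype = as.character(svtype), precise = precise,
                  support_reads = as.integer(support_reads),
                  filter = filter, copy_number = copy_number,
                  genotype = genotype, stringsAsFactors = FALSE)
  if (any(d$end <= d$start)) stop("SV calls must have end > start")
  if (any(d$support_reads < 0)) stop("support_reads must be >= 0")
  d
}

#' Read an SV call set from a tab-separated file
#'
#' Expects the documented 8+ column layout written by [write_sv_calls()]:
#' `caller, sample_id, chrom, start, end, svtype, precise, support_reads`
#' and optionally `filter, copy_number, genotype`.
#' @param path Path to the TSV file.
#' @return SV call `data.frame`.
#' @export
read_sv_calls <- function(path) {
  if (!file.exists(path)) stop("SV call set not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("caller", "sample_id", "chrom", "start", "end", "svtype",
            "precise", "support_reads")
  if (!all(need %in% colnames(d)))
    stop("SV call table must have columns: ", paste(need, collapse = ", "))
  if (!"filter" %in% colnames(d)) d$filter <- "PASS"
  if (!"copy_number" %in% colnames(d)) d$copy_number <- NA_real_
  if (!"genotype" %in% colnames(d)) d$genotype <- NA_character_
  d$chrom <- as.character(d$chrom)
  d$precise <- as.logical(d$precise)
  d
}

#' Write an SV call set as TSV
#' @param calls SV call `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sv_calls <- function(calls, path) write_tsv(calls, path)

#' Filter raw SV calls
#'
#' Applies the three-step quality filter: drop calls with ambiguous
#' (IMPRECISE) breakpoints or a failing caller filter; drop calls shorter
#' than `min_len` bp; drop calls with fewer than `min_support` supporting
#' reads. Thresholds are inclusive: length 50 and support 4 survive the
#' defaults. Idempotent.
#'
#' @param calls SV call `data.frame`.
#' @param min_len Minimum length in bp (default 50).
#' @param min_support Minimum supporting reads (default 4).
#' @param drop_failing Drop calls whose `filter` is not `PASS`/`.` (default
#'   `TRUE`); this is the "low-quality" criterion, delegated to the caller's
#'   own filter status.
#' @return Filtered calls; attribute `rejected` counts rejections by reason
#'   (a call failing several rules is counted once, by the first rule).
#' @export
filter_sv_calls <- function(calls, min_len = 50L, min_support = 4L,
                            drop_failing = TRUE) {
  if (!nrow(calls)) {
    attr(calls, "rejected") <- c(imprecise_or_lowqual = 0L, too_short = 0L,
                                 low_support = 0L)
    return(calls)
  }
  lowq <- !calls$precise |
    (drop_failing & !(calls$filter %in% c("PASS", ".", NA)))
  short <- !lowq & (calls$end - calls$start) < min_len
  weak <- !lowq & !short & calls$support_reads < min_support
  keep <- !(lowq | short | weak)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- c(imprecise_or_lowqual = sum(lowq),
                             too_short = sum(short),
                             low_support = sum(weak))
  out
}

# transitive overlap clusters among intervals (assumes same chrom)
.overlap_clusters <- function(start, end) {
  ord <- order(start, end)
  cl <- integer(length(start))
  cur <- 0L
  cur_end <- -Inf
  for (i in ord) {
    if (start[i] < cur_end) {
      cl[i] <- cur
      cur_end <- max(cur_end, end[i])
    } else {
      cur <- cur + 1L
      cl[i] <- cur
      cur_end <- end[i]
    }
  }
  cl
}

#' Cross-caller consensus calls per sample
#'
#' A per-sample locus is retained when at least `min_callers` distinct
#' callers report overlapping calls of identical SV type there, and every
#' copy-number annotation among the agreeing calls points in the type's
#' direction (CN below the neutral band for deletions, above it for
#' duplications; annotations inside the band are treated as neutral and
#' reject the locus). The retained consensus call takes the intersection
#' interval of the agreeing calls; clusters whose intersection is empty are
#' dropped with a log message.
#'
#' @param calls Filtered SV calls.
#' @param min_callers Minimum distinct callers (default 2).
#' @param require_same_type Cluster calls within SV type (default `TRUE`).
#' @param cn_neutral Copy-number neutrality band (default `c(1.75, 2.25)`).
#' @return Consensus calls: one row per retained per-sample locus with
#'   `caller = "consensus"`, mean copy number of the annotating callers,
#'   maximal support, and a `callers` column listing the agreeing callers.
#' @export
consensus_calls <- function(calls, min_callers = 2L, require_same_type = TRUE,
                            cn_neutral = c(1.75, 2.25)) {
  if (!nrow(calls)) return(calls[0, , drop = FALSE])
  keyvars <- c("sample_id", "chrom", if (require_same_type) "svtype")
  key <- do.call(paste, c(calls[keyvars], sep = "\r"))
  out <- list()
  dropped_empty <- 0L
  for (k in unique(key)) {
    g <- calls[key == k, , drop = FALSE]
    cl <- .overlap_clusters(g$start, g$end)
    for (ci in unique(cl)) {
      m <- g[cl == ci, , drop = FALSE]
      if (length(unique(m$caller)) < min_callers) next
      svt <- m$svtype[1]
      cn <- m$copy_number[!is.na(m$copy_number)]
      if (length(cn)) {
        dir_ok <- if (svt == "DEL") all(cn < cn_neutral[1]) else
          if (svt == "DUP") all(cn > cn_neutral[2]) else FALSE
        if (!dir_ok) next
      }
      s <- max(m$start); e <- min(m$end)
      if (e <= s) { dropped_empty <- dropped_empty + 1L; next }
      out[[length(out) + 1L]] <- data.frame(
        caller = "consensus", sample_id = m$sample_id[1],
        chrom = m$chrom[1], start = s, end = e, svtype = svt,
        precise = TRUE, support_reads = max(m$support_reads),
        filter = "PASS",
        copy_number = if (length(cn)) mean(cn) else NA_real_,
        genotype = if (any(!is.na(m$genotype)))
          m$genotype[!is.na(m$genotype)][1] else NA_character_,
        callers = paste(sort(unique(m$caller)), collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (dropped_empty)
    message(sprintf(
      "consensus_calls: dropped %d cluster(s) with empty intersection",
      dropped_empty))
  if (!length(out)) {
    res <- calls[0, , drop = FALSE]
    res$callers <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$sample_id), , drop = FALSE]
}

#' Build copy-number-variable regions across samples
#'
#' Per chromosome, consensus calls overlapping by at least one bp are
#' transitively merged; each CNVR spans the union of its member intervals.
#' CNVRs supported by fewer than `min_animals` distinct samples are
#' discarded. An optional reciprocal-overlap fraction restricts which call
#' pairs may seed a merge.
#'
#' @param calls Consensus calls (per-sample).
#' @param min_animals Minimum distinct supporting samples (default 2).
#' @param reciprocal Minimum reciprocal overlap fraction for merging
#'   (default 0 = any overlap).
#' @return Object of class `cnvr_set`: list with `cnvrs` (`cnvr_id`,
#'   `chrom`, `start`, `end`, `cnvr_type`, `n_samples`, `length`) and
#'   `members` (the member calls with their `cnvr_id`).
#' @export
build_cnvrs <- function(calls, min_animals = 2L, reciprocal = 0) {
  cn_rows <- list()
  mem_rows <- list()
  for (chr in sort(unique(calls$chrom))) {
    g <- calls[calls$chrom == chr, , drop = FALSE]
    g <- g[order(g$start, g$end), , drop = FALSE]
    if (reciprocal > 0) {
      cl <- .reciprocal_clusters(g$start, g$end, reciprocal)
    } else {
      cl <- .overlap_clusters(g$start, g$end)
    }
    for (ci in sort(unique(cl))) {
      m <- g[cl == ci, , drop = FALSE]
      ns <- length(unique(m$sample_id))
      if (ns < min_animals) next
      id <- sprintf("CNVR_%s_%d", chr, length(cn_rows) + 1L)
      m$cnvr_id <- id
      cn_rows[[length(cn_rows) + 1L]] <- data.frame(
        cnvr_id = id, chrom = chr, start = min(m$start), end = max(m$end),
        cnvr_type = classify_cnvr(m$svtype), n_samples = ns,
        length = max(m$end) - min(m$start), stringsAsFactors = FALSE)
      mem_rows[[length(mem_rows) + 1L]] <- m
    }
  }
  cnvrs <- if (length(cn_rows)) do.call(rbind, cn_rows) else
    data.frame(cnvr_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               cnvr_type = character(0), n_samples = integer(0),
               length = integer(0), stringsAsFactors = FALSE)
  members <- if (length(mem_rows)) do.call(rbind, mem_rows) else
    cbind(calls[0, , drop = FALSE], cnvr_id = character(0))
  rownames(cnvrs) <- rownames(members) <- NULL
  structure(list(cnvrs = cnvrs, members = members), class = "cnvr_set")
}

# union-find clustering with a reciprocal-overlap requirement
.reciprocal_clusters <- function(start, end, frac) {
  n <- length(start)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      ov <- min(end[i], end[j]) - max(start[i], start[j])
      if (ov <= 0) next
      if (ov / (end[i] - start[i]) >= frac && ov / (end[j] - start[j]) >= frac) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(factor(roots, levels = unique(roots)))
}

#' @export
print.cnvr_set <- function(x, ...) {
  cat(sprintf("cnvr_set: %d CNVRs (%d member calls)\n",
              nrow(x$cnvrs), nrow(x$members)))
  invisible(x)
}

#' Classify a CNVR by its member call types
#'
#' `deletion` when every member is a DEL, `duplication` when every member
#' is a DUP, `both` when at least one of each is present.
#' @param svtypes Character vector of member SV types.
#' @return One of `"deletion"`, `"duplication"`, `"both"`.
#' @export
classify_cnvr <- function(svtypes) {
  if (!length(svtypes)) stop("CNVR with no member calls")
  u <- unique(svtypes)
  if (!all(u %in% c("DEL", "DUP")))
    stop("unexpected member SV type(s): ",
         paste(setdiff(u, c("DEL", "DUP")), collapse = ", "))
  if (identical(u, "DEL")) "deletion"
  else if (identical(u, "DUP")) "duplication"
  else "both"
}

#' Annotate CNVRs with genomic context
#'
#' Context is `exonic` when the CNVR overlaps any exon by at least 1 bp,
#' else `intronic` when it overlaps any gene span, else `intergenic`
#' (precedence exon > intron > intergenic).
#'
#' @param cnvr_set A [build_cnvrs()] result.
#' @param genes A `gene_models` object from [read_gff()].
#' @return The `cnvr_set` with a `context` column added to `$cnvrs`.
#' @export
annotate_cnvr <- function(cnvr_set, genes) {
  cn <- cnvr_set$cnvrs
  if (!nrow(cn)) {
    cn$context <- character(0)
    cnvr_set$cnvrs <- cn
    return(cnvr_set)
  }
  gr <- .as_granges(cn)
  in_exon <- if (nrow(genes$exons))
    GenomicRanges::countOverlaps(gr, .as_granges(genes$exons)) > 0 else
      rep(FALSE, nrow(cn))
  in_gene <- if (nrow(genes$genes))
    GenomicRanges::countOverlaps(gr, .as_granges(genes$genes)) > 0 else
      rep(FALSE, nrow(cn))
  cn$context <- ifelse(in_exon, "exonic",
                       ifelse(in_gene, "intronic", "intergenic"))
  cnvr_set$cnvrs <- cn
  cnvr_set
}

#' CNVR length histogram
#'
#' Counts CNVR lengths into `[e1,e2), [e2,e3), ...` bins defined by
#' `bin_edges`, with explicit underflow/overflow bins so the counts always
#' partition the set and fractions sum to 1.
#'
#' @param cnvrs CNVR `data.frame` (or a `cnvr_set`).
#' @param bin_edges Ascending numeric vector of bin edges (bp).
#' @return `data.frame` with `bin`, `count`, `fraction`.
#' @export
length_histogram <- function(cnvrs, bin_edges = c(0, 100, 500, 1000, 5000,
                                                  10000, 50000)) {
  if (inherits(cnvrs, "cnvr_set")) cnvrs <- cnvrs$cnvrs
  if (is.unsorted(bin_edges, strictly = TRUE))
    stop("bin edges must be strictly ascending")
  len <- cnvrs$length
  breaks <- c(-Inf, bin_edges, Inf)
  labs <- c(sprintf("<%g", bin_edges[1]),
            sprintf("[%g,%g)", utils::head(bin_edges, -1),
                    utils::tail(bin_edges, -1)),
            sprintf(">=%g", bin_edges[length(bin_edges)]))
  cnt <- if (length(len))
    table(cut(len, breaks = breaks, right = FALSE, labels = labs)) else
      stats::setNames(rep(0L, length(labs)), labs)
  data.frame(bin = labs, count = as.integer(cnt),
             fraction = if (sum(cnt) > 0) as.integer(cnt) / sum(cnt) else
               rep(0, length(labs)),
             stringsAsFactors = FALSE)
}

#' Flag CNVRs supported by a long-read validation track
#'
#' When one caller's call set covers a single animal only (a long-read
#' overlay), it can be excluded from the per-sample consensus and instead
#' used region-wise: this marks each CNVR that any overlay call overlaps.
#'
#' @param cnvr_set A [build_cnvrs()] result.
#' @param overlay_calls SV calls of the overlay caller (filtered).
#' @return `cnvr_set` with a logical `longread_support` column.
#' @export
annotate_longread_support <- function(cnvr_set, overlay_calls) {
  cn <- cnvr_set$cnvrs
  if (!nrow(cn)) {
    cn$longread_support <- logical(0)
  } else if (!nrow(overlay_calls)) {
    cn$longread_support <- FALSE
  } else {
    cn$longread_support <- GenomicRanges::countOverlaps(
      .as_granges(cn), .as_granges(overlay_calls)) > 0
  }
  cnvr_set$cnvrs <- cn
  cnvr_set
}
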