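#' Default analysis configuration
#'
#' The parameter set driving the two analyses, with defaults equal to the
#' published protocol: 50 kb windows / 20 kb steps, top 1% for the
#' selection and F_ST scans, top 2% for V_ST, SV filters of 50 bp and 4
#' supporting reads, at least 2 animals per CNVR and at least 2 methods
#' per consensus gene, QTL P <= 0.05.
#'
#' @param ... Named overrides of any default.
#' @return List of class `run_config`.
#' @export
default_config <- function(...) {
  cfg <- list(window_size = 50000L, window_step = 20000L,
              top_fraction_selection = 0.01, top_fraction_fst = 0.01,
              top_fraction_vst = 0.02, sv_min_len = 50L, sv_min_support = 4L,
              min_animals = 2L, min_methods = 2L, qtl_p_max = 0.05,
              maf = 0.05, ehh_cutoff = 0.05, ihs_bins = 50L,
              cn_neutral = c(1.75, 2.25), seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

.write_config <- function(cfg, outdir) {
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Selection-signature analysis over a VCF
#'
#' Reads phased genotypes, runs the windowed scan (pi, Tajima's D, CLR,
#' mean |iHS|, and F_ST when a group table is given), applies the top-1%
#' outlier rule per statistic, intersects the outlier regions with gene
#' models, and reports the consensus genes supported by at least two
#' statistics.
#'
#' @param vcf Path to a phased VCF.
#' @param gff Path to a GFF3 with gene models.
#' @param groups_path Optional path to a group table (enables F_ST).
#' @param outdir Output directory; result tables are written there.
#' @param chrom_length Chromosome length (default: max position in VCF).
#' @param config A [default_config()].
#' @return List with `windows` (statistics table), `candidates` (per-method
#'   merged outlier regions), `genes` (per-method gene sets) and `psg`
#'   (consensus genes).
#' @export
sweep_pipeline <- function(vcf, gff, groups_path = NULL, outdir,
                           chrom_length = NULL, config = default_config()) {
  for (f in c(vcf, gff, groups_path))
    if (!is.null(f) && !file.exists(f)) stop("input file missing: ", f)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hm <- read_genotypes(vcf)
  genes <- read_gff(gff)
  groups <- NULL
  if (!is.null(groups_path)) {
    groups <- read_group_table(groups_path)
    miss <- setdiff(hm$sample_ids, groups$sample_id)
    if (length(miss))
      stop("VCF samples missing from group table: ",
           paste(miss, collapse = ", "))
  }
  if (is.null(chrom_length)) chrom_length <- max(hm$positions)
  win <- make_windows(chrom_length, config$window_size, config$window_step,
                      chrom = hm$chrom)
  methods <- c("pi", "tajima_d", "clr", "ihs", if (!is.null(groups)) "fst")
  wstats <- sweep_scan(hm, win, methods = methods, groups = groups,
                       maf = config$maf, cutoff = config$ehh_cutoff,
                       n_bins = config$ihs_bins)
  # outlier selection per statistic: high CLR / |iHS| / FST, low pi
  scans <- list()
  wl <- wstats
  wl$neg_pi <- -wl$pi
  scans$pi <- fst_scan(wl, config$top_fraction_selection, stat = "neg_pi")
  scans$clr <- fst_scan(wl, config$top_fraction_selection, stat = "clr")
  scans$ihs <- fst_scan(wl, config$top_fraction_selection,
                        stat = "mean_abs_ihs")
  if (!is.null(groups))
    scans$fst <- fst_scan(wl, config$top_fraction_fst, stat = "fst")
  gene_sets <- lapply(scans, function(s)
    unique(genes_in_regions(s$regions, genes)$gene_id))
  psg <- psg_consensus(gene_sets, min_methods = config$min_methods)

  write_tsv(wstats, file.path(outdir, "window_stats.tsv"))
  for (m in names(scans))
    write_bed(scans[[m]]$regions, file.path(outdir,
                                            paste0("candidates_", m, ".bed")))
  writeLines(psg, file.path(outdir, "psg.txt"))
  .write_config(config, outdir)
  list(windows = wstats, candidates = lapply(scans, `[[`, "regions"),
       genes = gene_sets, psg = psg)
}

#' CNV consensus analysis over multi-caller call sets
#'
#' Filters each caller's calls, forms the cross-caller per-sample
#' consensus, builds CNVRs with the minimum-animal rule, annotates genomic
#' context, and writes the CNVR BED plus a JSON summary.
#'
#' @param callset_paths Character vector of SV call-set TSV paths (all
#'   callers may also be concatenated in one file).
#' @param gff Path to gene models (GFF3).
#' @param outdir Output directory.
#' @param config A [default_config()].
#' @return List with `cnvr_set`, `summary`, `histogram`, and `log`
#'   (per-stage kept/rejected counts).
#' @export
cnv_pipeline <- function(callset_paths, gff, outdir,
                         config = default_config()) {
  for (f in c(callset_paths, gff))
    if (!file.exists(f)) stop("input file missing: ", f)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  calls <- do.call(rbind, lapply(callset_paths, read_sv_calls))
  filt <- filter_sv_calls(calls, min_len = config$sv_min_len,
                          min_support = config$sv_min_support)
  cons <- consensus_calls(filt, cn_neutral = config$cn_neutral)
  cnvrs <- build_cnvrs(cons, min_animals = config$min_animals)
  genes <- read_gff(gff)
  cnvrs <- annotate_cnvr(cnvrs, genes)
  summ <- summarize_cnvrs(cnvrs)
  hist <- length_histogram(cnvrs)
  log <- list(input_calls = nrow(calls),
              kept_after_filter = nrow(filt),
              rejected = as.list(attr(filt, "rejected")),
              consensus_calls = nrow(cons),
              cnvrs = nrow(cnvrs$cnvrs))
  write_bed(cnvrs$cnvrs[, c("chrom", "start", "end", "cnvr_id", "cnvr_type",
                            "n_samples", "context")],
            file.path(outdir, "cnvrs.bed"))
  jsonlite::write_json(
    list(summary = unclass(summ), histogram = hist, log = log),
    file.path(outdir, "cnv_summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  .write_config(config, outdir)
  list(cnvr_set = cnvrs, summary = summ, histogram = hist, log = log)
}

#' V_ST differentiation analysis over a CNVR set
#'
#' Builds the normalized copy-number matrix (diploid imputation for absent
#' calls), computes V_ST per CNVR between the two groups, and applies the
#' top-2% rule.
#'
#' @param cnvr_set A `cnvr_set` from [cnv_pipeline()] / [build_cnvrs()].
#' @param groups_path Path to the group table.
#' @param outdir Output directory.
#' @param samples Optional explicit sample vector (default: group table).
#' @param config A [default_config()].
#' @return The [vst_scan()] result.
#' @export
vst_pipeline <- function(cnvr_set, groups_path, outdir, samples = NULL,
                         config = default_config()) {
  if (!file.exists(groups_path)) stop("input file missing: ", groups_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  groups <- read_group_table(groups_path)
  if (is.null(samples)) samples <- groups$sample_id
  cnm <- copy_number_matrix(cnvr_set, samples, groups)
  scan <- vst_scan(cnm, groups, cnvr_set,
                   top_fraction = config$top_fraction_vst)
  write_tsv(scan$table, file.path(outdir, "vst.tsv"))
  write_bed(scan$top[, c("chrom", "start", "end", "cnvr_id", "vst")],
            file.path(outdir, "vst_top.bed"))
  .write_config(config, outdir)
  scan
}

#' Candidate/QTL overlap report
#'
#' Intersects candidate regions (and their genes) with a P-filtered QTL
#' table, emitting every overlapping pair plus both counting conventions
#' (pairs and distinct QTLs).
#'
#' @param regions Candidate regions (`chrom`, `start`, `end`, id column).
#' @param genes A `gene_models` object.
#' @param qtl_path Path to the QTL TSV.
#' @param outdir Output directory.
#' @param config A [default_config()].
#' @return List with `pairs` (overlap table), `n_pairs`,
#'   `n_distinct_qtls`, and `region_genes`.
#' @export
report_pipeline <- function(regions, genes, qtl_path, outdir,
                            config = default_config()) {
  if (!file.exists(qtl_path)) stop("input file missing: ", qtl_path)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  qtls <- read_qtl_table(qtl_path, p_max = config$qtl_p_max)
  ov <- qtl_overlap(regions, qtls)
  rg <- genes_in_regions(regions, genes)
  write_tsv(ov, file.path(outdir, "qtl_overlap.tsv"))
  write_tsv(rg, file.path(outdir, "region_genes.tsv"))
  .write_config(config, outdir)
  list(pairs = ov, n_pairs = attr(ov, "n_pairs"),
       n_distinct_qtls = attr(ov, "n_distinct_qtls"), region_genes = rg)
}
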