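#' Construct a phased haplotype matrix
#'
#' Container for phased biallelic SNP data: one row per haplotype, one
#' column per site, entries 0 (ancestral-state reference coding) / 1.
#' Positions are 1-based physical coordinates as in VCF.
#'
#' @param chrom Chromosome identifier (scalar).
#' @param positions Strictly increasing integer vector of site positions (bp).
#' @param alleles Integer matrix of 0/1 with `2 * length(sample_ids)` rows and
#'   `length(positions)` columns.
#' @param sample_ids Character vector of diploid sample names; haplotype row
#'   `2i-1` and `2i` belong to sample `i`.
#' @param ancestral_is_ref Logical per site: `TRUE` when the REF allele is
#'   ancestral (so allele 1 is derived); defaults to all `TRUE`.
#' @return An object of class `haplotype_matrix`.
#' @export
haplotype_matrix <- function(chrom, positions, alleles, sample_ids,
                             ancestral_is_ref = rep(TRUE, length(positions))) {
  positions <- as.integer(positions)
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (length(positions) != ncol(alleles))
    stop("positions length must equal number of allele columns")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (length(positions) && !all(alleles %in% c(0L, 1L)))
    stop("alleles must contain only 0/1 (biallelic sites)")
  if (nrow(alleles) != 2L * length(sample_ids))
    stop("haplotype rows must be 2 x sample count")
  structure(
    list(chrom = as.character(chrom)[1], positions = positions,
         alleles = alleles, sample_ids = as.character(sample_ids),
         ancestral_is_ref = as.logical(ancestral_is_ref)),
    class = "haplotype_matrix")
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d haplotypes (%d samples) x %d sites on %s\n",
              nrow(x$alleles), length(x$sample_ids), ncol(x$alleles), x$chrom))
  invisible(x)
}

#' Derived-allele count per site
#'
#' Column sums of the haplotype matrix after polarizing by
#' `ancestral_is_ref`: at sites where the reference allele is derived the
#' count is flipped.
#' @param hm A [haplotype_matrix()].
#' @return Integer vector of derived-allele counts, one per site.
#' @export
derived_counts <- function(hm) {
  n <- nrow(hm$alleles)
  cnt <- colSums(hm$alleles)
  flip <- !hm$ancestral_is_ref
  cnt[flip] <- n - cnt[flip]
  as.integer(cnt)
}

#' Sliding windows over a chromosome
#'
#' Windows of `size` bp advancing by `step` bp, 0-based half-open. Every
#' start `0, step, 2*step, ...` strictly below `chrom_length` is emitted;
#' trailing windows are clipped at the chromosome end, so the union of
#' windows covers exactly `[0, chrom_length)`.
#'
#' @param chrom_length Chromosome length in bp.
#' @param size Window size in bp (default 50 kb).
#' @param step Step in bp (default 20 kb); must satisfy `0 < step <= size`.
#' @param chrom Optional chromosome label attached to each window.
#' @return `data.frame` with columns `chrom`, `start`, `end`, sorted by start.
#' @export
make_windows <- function(chrom_length, size = 50000L, step = 20000L,
                         chrom = "1") {
  if (size <= 0 || step <= 0) stop("window size and step must be positive")
  if (step > size) stop("step must not exceed window size")
  starts <- seq.int(0L, by = as.integer(step),
                    length.out = ceiling(chrom_length / step))
  starts <- starts[starts < chrom_length]
  data.frame(chrom = as.character(chrom), start = starts,
             end = pmin(starts + as.integer(size), as.integer(chrom_length)),
             stringsAsFactors = FALSE)
}

#' Read phased biallelic SNPs from a VCF into a haplotype matrix
#'
#' Retains biallelic SNP records with fully phased genotypes (`a|b`);
#' multiallelic records, indels, and records with any unphased or missing
#' genotype are skipped and counted. Derived-allele polarity is taken from
#' an `AA=` INFO annotation when present; otherwise ALT is treated as
#' derived, with a warning.
#'
#' @param path Path to a VCF file.
#' @param region Optional chromosome name; only records on it are kept.
#' @return A [haplotype_matrix()]; attribute `skipped` holds a named vector
#'   of per-reason skip counts.
#' @export
read_genotypes <- function(path, region = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE),
                       stringsAsFactors = FALSE)
  if (!"FORMAT" %in% colnames(v@gt) || !any(grepl("GT", v@gt[, "FORMAT"])))
    stop("VCF has no GT field; phased genotypes are required")
  gt <- vcfR::extract.gt(v, element = "GT")
  if (!is.null(region)) {
    keep_chr <- fix$CHROM == as.character(region)
    fix <- fix[keep_chr, , drop = FALSE]
    gt <- gt[keep_chr, , drop = FALSE]
  }
  n_rec <- nrow(fix)
  if (n_rec == 0L) stop("no VCF records", if (!is.null(region))
    paste0(" on chromosome ", region))

  bases <- c("A", "C", "G", "T")
  is_snp <- fix$REF %in% bases & fix$ALT %in% bases
  phased <- apply(gt, 1, function(x) all(grepl("^[01]\\|[01]$", x)))
  dup <- duplicated(fix$POS)
  keep <- is_snp & phased & !dup
  skipped <- c(not_biallelic_snp = sum(!is_snp),
               unphased_or_missing = sum(is_snp & !phased),
               duplicate_position = sum(is_snp & phased & dup))
  if (any(skipped > 0))
    message(sprintf("read_genotypes: skipped %d record(s) (%s)", sum(skipped),
                    paste(names(skipped), skipped, sep = "=", collapse = ", ")))
  if (!any(keep))
    stop("no records left after filtering to phased biallelic SNPs")

  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  ord <- order(as.integer(fix$POS))
  fix <- fix[ord, , drop = FALSE]
  gt <- gt[ord, , drop = FALSE]

  samples <- colnames(gt)
  nhap <- 2L * length(samples)
  alle <- matrix(0L, nrow = nhap, ncol = nrow(gt))
  for (j in seq_along(samples)) {
    sp <- strsplit(gt[, j], "|", fixed = TRUE)
    alle[2L * j - 1L, ] <- as.integer(vapply(sp, `[`, "", 1L))
    alle[2L * j, ] <- as.integer(vapply(sp, `[`, "", 2L))
  }

  aa <- rep(NA_character_, nrow(fix))
  info <- fix$INFO
  if (!is.null(info)) {
    m <- regmatches(info, regexpr("(?<=(^|;)AA=)[ACGTacgt]", info, perl = TRUE))
    has <- grepl("(^|;)AA=", info)
    aa[has] <- toupper(m)
  }
  anc_ref <- rep(TRUE, nrow(fix))
  known <- !is.na(aa)
  anc_ref[known] <- aa[known] == fix$REF[known]
  if (!all(known))
    warning(sprintf(
      "%d site(s) lack an AA (ancestral allele) annotation; ALT treated as derived",
      sum(!known)))

  hm <- haplotype_matrix(chrom = fix$CHROM[1],
                         positions = as.integer(fix$POS),
                         alleles = alle, sample_ids = samples,
                         ancestral_is_ref = anc_ref)
  attr(hm, "skipped") <- skipped
  hm
}

#' Write a haplotype matrix as a phased VCF
#'
#' Minimal VCF 4.2 writer: biallelic SNPs (REF `A`, ALT `T` placeholders),
#' phased `GT`-only genotypes, `AA=` INFO tag carrying the ancestral state.
#' @param hm A [haplotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(hm, path) {
  n_s <- length(hm$sample_ids)
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s>", hm$chrom),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", hm$sample_ids), collapse = "\t"))
  nsites <- length(hm$positions)
  if (nsites) {
    gt <- vapply(seq_len(n_s), function(j)
      paste(hm$alleles[2L * j - 1L, ], hm$alleles[2L * j, ], sep = "|"),
      character(nsites))
    gt <- matrix(gt, nrow = nsites)
    aa <- ifelse(hm$ancestral_is_ref, "A", "T")
    body <- paste(hm$chrom, hm$positions, ".", "A", "T", ".", "PASS",
                  paste0("AA=", aa), "GT",
                  apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  } else body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Parses `gene` and `exon` features via rtracklayer and converts them to
#' the package-internal 0-based half-open convention. Rows whose end
#' coordinate precedes their start are rejected and logged rather than
#' aborting the import.
#'
#' @param path Path to a GFF3 file.
#' @return An object of class `gene_models`: list with `genes` and `exons`
#'   data frames (`gene_id`, `chrom`, `start`, `end`), plus a `rejected`
#'   attribute with the count of malformed rows.
#' @export
read_gff <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  feat <- lines[!startsWith(lines, "#") & nzchar(lines)]
  bad <- 0L
  if (length(feat)) {
    parts <- strsplit(feat, "\t", fixed = TRUE)
    ok <- vapply(parts, function(p)
      length(p) >= 9 && !is.na(suppressWarnings(as.numeric(p[4]))) &&
        !is.na(suppressWarnings(as.numeric(p[5]))) &&
        as.numeric(p[5]) >= as.numeric(p[4]), logical(1))
    bad <- sum(!ok)
    if (bad > 0) {
      message(sprintf("read_gff: rejected %d malformed record(s)", bad))
      feat <- feat[ok]
    }
  }
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp))
  writeLines(c("##gff-version 3", feat), tmp)
  gr <- rtracklayer::import(tmp, format = "gff3")

  take <- function(type, id_col) {
    sel <- gr[tolower(as.character(gr$type)) == type]
    if (length(sel) == 0)
      return(data.frame(gene_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        stringsAsFactors = FALSE))
    ids <- if (id_col == "ID") as.character(sel$ID) else
      vapply(sel$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
             "")
    data.frame(gene_id = ids,
               chrom = as.character(GenomicRanges::seqnames(sel)),
               start = GenomicRanges::start(sel) - 1L,
               end = GenomicRanges::end(sel),
               stringsAsFactors = FALSE)
  }
  genes <- take("gene", "ID")
  exons <- take("exon", "Parent")
  out <- structure(list(genes = genes, exons = exons), class = "gene_models")
  attr(out, "rejected") <- bad
  out
}

#' Write gene models as GFF3
#' @param gm A `gene_models` object (internal 0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff <- function(gm, path) {
  g <- gm$genes
  e <- gm$exons
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(g))) {
    lines <- c(lines, paste(g$chrom[i], "sweepcnvr", "gene", g$start[i] + 1L,
                            g$end[i], ".", "+", ".",
                            paste0("ID=", g$gene_id[i]), sep = "\t"))
    ei <- e[e$gene_id == g$gene_id[i], , drop = FALSE]
    for (j in seq_len(nrow(ei)))
      lines <- c(lines, paste(ei$chrom[j], "sweepcnvr", "exon",
                              ei$start[j] + 1L, ei$end[j], ".", "+", ".",
                              paste0("ID=", g$gene_id[i], ".e", j,
                                     ";Parent=", g$gene_id[i]), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a QTL table, applying the significance filter
#'
#' Expects a tab-separated file with header columns `qtl_id`, `chrom`,
#' `start`, `end` (1-based inclusive), `trait_class`, `p_value`. Records
#' with `p_value > p_max` are dropped; rows with `end < start` are rejected
#' and logged. Coordinates are converted to 0-based half-open.
#'
#' @param path Path to the TSV file.
#' @param p_max Retain records with P-value at or below this (default 0.05).
#' @return `data.frame` of retained QTL records; attribute `rejected` counts
#'   malformed rows, `filtered` counts rows above `p_max`.
#' @export
read_qtl_table <- function(path, p_max = 0.05) {
  if (!file.exists(path)) stop("QTL table not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("qtl_id", "chrom", "start", "end", "trait_class", "p_value")
  if (!all(need %in% colnames(d)))
    stop("QTL table must have columns: ", paste(need, collapse = ", "))
  bad <- is.na(d$start) | is.na(d$end) | d$end < d$start
  if (any(bad)) {
    message(sprintf("read_qtl_table: rejected %d record(s) with end < start",
                    sum(bad)))
    d <- d[!bad, , drop = FALSE]
  }
  hi <- d$p_value > p_max
  d <- d[!hi, , drop = FALSE]
  d$chrom <- as.character(d$chrom)
  d$start <- as.integer(d$start) - 1L  # to 0-based half-open
  d$end <- as.integer(d$end)
  rownames(d) <- NULL
  attr(d, "rejected") <- sum(bad)
  attr(d, "filtered") <- sum(hi)
  d
}

#' Read a sample-to-group assignment table
#'
#' Tab-separated, header columns `sample_id` and `group`; exactly two
#' distinct non-empty groups are required.
#' @param path Path to the TSV file.
#' @return `data.frame` with `sample_id` and `group`.
#' @export
read_group_table <- function(path) {
  if (!file.exists(path)) stop("group table not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(d)))
    stop("group table must have columns sample_id and group")
  validate_groups(d)
  d
}

validate_groups <- function(groups) {
  tab <- table(groups$group)
  if (length(tab) != 2L || any(tab == 0))
    stop("exactly two non-empty groups are required; got: ",
         paste(names(tab), collapse = ", "))
  invisible(groups)
}

#' Write intervals as a BED file (0-based half-open, native)
#' @param df Data frame with at least `chrom`, `start`, `end`; further
#'   columns are appended in order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  first <- c("chrom", "start", "end")
  rest <- setdiff(colnames(df), first)
  out <- df[, c(first, rest), drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV with header
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# GRanges helper: internal 0-based half-open -> 1-based closed
.as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start + 1L, end = df$end))
}
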