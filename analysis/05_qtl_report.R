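#!/usr/bin/env Rscript
# Final integration: overlap the top-V_ST CNVRs and the F_ST candidate
# regions with the gene models and the P-filtered (P <= 0.05) QTL table,
# reporting both counting conventions (item/QTL pairs and distinct QTLs).

suppressPackageStartupMessages(library(sweepcnvr))

datadir <- "results/data"
outdir <- "results/report"

run <- cnv_pipeline(file.path(datadir, "sv_calls.tsv"),
                    file.path(datadir, "genes.gff3"), "results/cnv")
scan <- vst_pipeline(run$cnvr_set, file.path(datadir, "groups.tsv"),
                     "results/vst")
genes <- read_gff(file.path(datadir, "genes.gff3"))

rep <- report_pipeline(scan$top[, c("chrom", "start", "end", "cnvr_id")],
                       genes, file.path(datadir, "qtl.tsv"), outdir)
message("top-V_ST CNVRs vs QTLs: ", rep$n_pairs, " overlapping pairs over ",
        rep$n_distinct_qtls, " distinct QTLs")
message("genes overlapped by top-V_ST CNVRs: ",
        length(unique(rep$region_genes$gene_id)))
if (nrow(rep$pairs)) {
  message("trait classes involved: ",
          paste(sort(unique(rep$pairs$trait_class)), collapse = ", "))
}

# the same overlap over the full CNVR set, for the genome-wide bookkeeping
all_rep <- report_pipeline(
  run$cnvr_set$cnvrs[, c("chrom", "start", "end", "cnvr_id")],
  genes, file.path(datadir, "qtl.tsv"), file.path(outdir, "all_cnvrs"))
message("all CNVRs vs QTLs: ", all_rep$n_pairs, " pairs over ",
        all_rep$n_distinct_qtls, " distinct QTLs; CNVR genes: ",
        length(unique(all_rep$region_genes$gene_id)))
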