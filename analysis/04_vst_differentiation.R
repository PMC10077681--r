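#!/usr/bin/env Rscript
# Copy-number differentiation between the two phenotype groups: build the
# normalized copy-number matrix over the consensus CNVRs (absent calls
# imputed at the diploid baseline 2), compute V_ST = (V_T - V_S)/V_T per
# CNVR, and apply the top-2% rule. The planted fully penetrant deletion
# (copy number 0 in all PSM and half of HSM animals) should head the list.

suppressPackageStartupMessages(library(sweepcnvr))

datadir <- "results/data"
cnvdir <- "results/cnv"
outdir <- "results/vst"

run <- cnv_pipeline(file.path(datadir, "sv_calls.tsv"),
                    file.path(datadir, "genes.gff3"), cnvdir)
scan <- vst_pipeline(run$cnvr_set, file.path(datadir, "groups.tsv"), outdir)

message("CNVRs with defined V_ST: ", sum(!is.na(scan$table$vst)),
        "; selected (top 2%): ", nrow(scan$top))
message("top of the V_ST ranking:")
print(utils::head(scan$table[, c("cnvr_id", "chrom", "start", "end",
                                 "v_t", "v_s", "vst")], 5), row.names = FALSE)

truth <- utils::read.delim(file.path(datadir, "cnv_truth_regions.tsv"))
tr <- truth[truth$differentiated, ]
hit <- any(scan$top$chrom == tr$chrom & scan$top$start < tr$end &
             scan$top$end > tr$start)
message("planted differentiated deletion in the top-2% list: ",
        if (hit) "yes" else "no")
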