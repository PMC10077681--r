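#!/usr/bin/env Rscript
# CNV identification chain: per-caller quality filtering (precise
# breakpoints, >= 50 bp, >= 4 supporting reads), cross-caller same-type
# consensus per sample, CNVR construction with the >= 2-animal rule, and
# genomic-context annotation, ending in the summary that mirrors the
# count/length/context bookkeeping of a resequencing CNV survey.

suppressPackageStartupMessages(library(sweepcnvr))

datadir <- "results/data"
outdir <- "results/cnv"
stopifnot(file.exists(file.path(datadir, "sv_calls.tsv")))

run <- cnv_pipeline(file.path(datadir, "sv_calls.tsv"),
                    file.path(datadir, "genes.gff3"), outdir)
message("raw calls: ", run$log$input_calls,
        "; after filter: ", run$log$kept_after_filter,
        " (rejected ", paste(names(run$log$rejected),
                             unlist(run$log$rejected),
                             sep = "=", collapse = ", "), ")")
message("consensus per-sample calls: ", run$log$consensus_calls)
print(run$summary)
message("length histogram:")
print(run$histogram, row.names = FALSE)

# recovery against the simulated truth
truth <- utils::read.delim(file.path(datadir, "cnv_truth_regions.tsv"))
cn <- run$cnvr_set$cnvrs
hit <- vapply(seq_len(nrow(truth)), function(i)
  any(cn$chrom == truth$chrom[i] & cn$start < truth$end[i] &
        cn$end > truth$start[i]), logical(1))
message(sprintf("true regions recovered as CNVRs: %d / %d",
                sum(hit), nrow(truth)))
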