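#!/usr/bin/env Rscript
# Generate the synthetic study inputs: a phased SNP panel for two phenotype
# groups (14 vs 16 diploids) with a strongly differentiated site, a
# separate hard-sweep panel, multi-caller structural-variant call sets with
# a planted group-differentiated deletion, and annotation fixtures
# (gene models + QTL table). Everything downstream reads only these files.

suppressPackageStartupMessages(library(sweepcnvr))

seed <- 42L
outdir <- "results/data"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

message("Two-group neutral panel (HSM n=14 vs PSM n=16) ...")
two <- simulate_two_groups(sim_params(seed = seed), c(0.05, 0.95))
write_vcf(two$hm, file.path(outdir, "snps_groups.vcf"))
write_tsv(two$groups, file.path(outdir, "groups.tsv"))
message("  ", ncol(two$hm$alleles), " segregating sites; differentiated site at ",
        two$diff_pos)

message("Hard-sweep panel (s = 0.05, conditioned on fixation) ...")
hm_sweep <- simulate_population(sim_params(s = 0.05, seed = seed + 1L))
write_vcf(hm_sweep, file.path(outdir, "snps_sweep.vcf"))
message("  ", ncol(hm_sweep$alleles), " segregating sites; sweep fixed after ",
        attr(hm_sweep, "sweep_generations"), " generations (",
        attr(hm_sweep, "retries"), " restarts)")

message("Copy-number truth and pseudo-caller call sets ...")
truth <- simulate_cnv_truth(two$groups, n_neutral = 100, seed = seed + 2L)
calls <- simulate_cnv_callsets(truth, seed = seed + 3L)
write_tsv(truth$regions, file.path(outdir, "cnv_truth_regions.tsv"))
write_sv_calls(calls, file.path(outdir, "sv_calls.tsv"))
message("  ", nrow(truth$regions), " true regions (1 group-differentiated), ",
        nrow(calls), " raw calls from 3 pseudo-callers")

message("Annotation fixtures ...")
fx <- make_fixtures(n_genes = 40, n_qtls = 25, chrom_length = 5e6,
                    dir = outdir, seed = seed + 4L)
message("  wrote ", fx$gff, " and ", fx$qtl, " (CNV chromosome, 5 Mb)")
snpdir <- file.path(outdir, "snp_annotation")
fx2 <- make_fixtures(n_genes = 15, n_qtls = 10, chrom_length = 5e5,
                     dir = snpdir, seed = seed + 5L)
message("  wrote ", fx2$gff, " and ", fx2$qtl, " (SNP chromosome, 500 kb)")
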