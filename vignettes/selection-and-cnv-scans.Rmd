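---
title: "Selection-signature and copy-number differentiation scans: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selection-signature and copy-number differentiation scans: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sweepcnvr implements the two analysis chains of a population-resequencing
study of paired phenotype groups (here styled after a 30-bull panel split
into 14 high- and 16 poor-sperm-motility animals): selective-sweep scans
over phased SNPs, and a multi-caller structural-variant consensus that
yields copy-number-variable regions (CNVRs) scanned for group
differentiation with V~ST~. Everything runs on synthetic data with known
truth, generated by the package itself, so each stage's behaviour is
testable end to end without any sequencing data.

## Windowed SNP statistics

All scans share one window engine: windows of 50 kb advancing by 20 kb
(both parameters), 0-based half-open, clipped at the chromosome end so the
windows exactly tile `[0, L)`. Internally every coordinate is 0-based
half-open; VCF and GFF3 (1-based inclusive) are converted at the I/O
boundary and BED is written natively.

**Nucleotide diversity.** Per site with derived count $n_1$ of $n$
haplotypes, the expected pairwise difference is $n_1 (n-n_1) / \binom{n}{2}$;
window $\pi$ is the sum over the window's sites divided by the window
length in bp.

**Tajima's D** uses the canonical constants $a_1, a_2, b_1, b_2, c_1,
c_2, e_1, e_2$ of the sample size, $D = (\pi_{tot} - S/a_1) /
\sqrt{e_1 S + e_2 S (S-1)}$, with $D = 0$ flagged undefined when $S = 0$.

**F~ST~** is the Weir–Cockerham (1984) variance-component estimator for
two populations on haplotype-level (haploid) data, so the heterozygosity
term vanishes and only the among- ($a$) and between-haplotype-within-
population ($b$) components remain. Windows aggregate as the ratio of
sums $\sum a / \sum (a+b)$ (the "weighted" convention). Negative windowed
values are reported as computed; truncation is a presentation choice.

**iHS.** EHH from a core allele is the probability that two random
carriers are identical over all sites from the core to distance $x$;
curves are truncated below 0.05 (parameter) and integrated trapezoidally
against physical distance in both directions. `ihs_raw` is
$\ln(\mathrm{iHH}_A/\mathrm{iHH}_D)$; sites whose EHH never falls below
the cutoff before the data end are dropped, as is common practice. Raw
scores are standardized within 50 equal-width derived-frequency bins
(population-variance denominator), and windows aggregate the mean
absolute standardized score. The derived allele is taken from an `AA=`
INFO annotation when present, else ALT is treated as derived with a
warning — polarization is a genuine open choice and is surfaced, not
hidden.

**Composite likelihood ratio.** The sweep model follows the classical
escape construction: at distance $d$ from a putative sweep position, each
of the $n$ sampled lineages escapes the sweep independently with
$p_e = 1 - e^{-\alpha d}$. Conditional on $k$ escapees, a pre-sweep
sample of size $k+1$ (the escapees plus one lineage standing for every
swept chromosome) receives its derived count by hypergeometric
downsampling of the genome-wide background spectrum; the swept lineage
then expands to $n-k$ copies. Two numerical choices matter:

* the background spectrum is polymorphic-only (classes $1..n-1$), and the
  per-site sweep likelihood is **conditioned on polymorphism** — only
  segregating sites enter the scan, so the model is compared on the shape
  of the polymorphic spectrum. Without this conditioning the sweep model
  leaks probability mass onto unobservable monomorphic outcomes and loses
  at every site by construction;
* $\alpha$ is maximized over a geometric grid of 20 values spanning
  $10^{-8}$–$10^{-2}$ per bp plus the exact background limit
  ($p_e \equiv 1$), which guarantees CLR $\ge 0$ deterministically.

Grid points sit at multiples of 50 kb ("one point per 50-kb window");
every segregating site of the chromosome contributes to every grid point,
distant sites reverting to the background model automatically.

**Outlier rules.** Each statistic's candidate set is the top
$\lceil f N_{\mathrm{defined}} \rceil$ windows ($f$ = 1% for the
selection statistics and F~ST~), ties resolved by (chrom, start);
adjacent or overlapping selected windows merge bookended into candidate
regions. Consensus genes are those hit by the top windows of at least two
statistics.

## CNV consensus and V~ST~

Raw per-caller calls pass three removal rules: imprecise breakpoints or a
failing caller filter; length under 50 bp; fewer than 4 supporting reads.
Thresholds are inclusive (a 50 bp, 4-read call survives) because the
removals are phrased as strict inequalities. A per-sample locus is kept
when at least two distinct callers report overlapping calls of identical
type and every copy-number annotation points the type's way; copy numbers
inside the neutral band [1.75, 2.25] (parameter) reject the locus. The
consensus interval is the intersection of the agreeing calls —
conservative breakpoints per sample — while CNVRs take the union of their
member intervals: overlapping consensus calls merge transitively
(minimum overlap 1 bp by default; a reciprocal-overlap fraction is
exposed), and CNVRs supported by fewer than two distinct animals are
discarded. Types classify as deletion / duplication / both from the
member calls; genomic context is exonic if any exon is touched, else
intronic if any gene span is touched, else intergenic.

A long-read call set covering a single animal can either participate as
an ordinary caller for that animal or be applied region-wise as a
validation overlay (`annotate_longread_support()`); the published
three-method intersection is ambiguous on this point, so both modes exist
and neither is asserted as canonical.

V~ST~ per CNVR is $(V_T - V_S)/V_T$ with $V_T$ the copy-number variance
over all individuals and $V_S$ the group-size-weighted mean within-group
variance, population denominators (`ddof = 0`, parameter). Samples
without a call at a CNVR are imputed at the diploid baseline 2: absence
of a call is evidence of the reference state in this pipeline, and V~ST~
needs complete vectors. The top-2% rule mirrors the windowed one.
QTL tables are filtered at P ≤ 0.05 on read-in; overlaps are emitted as
every (item, QTL) pair with ≥ 1 bp shared, with both records side by side,
and both counting conventions (pairs, distinct QTLs) are reported because
published counts are ambiguous between them.

## The synthetic cohort

The generator is a discrete-generation forward Wright–Fisher simulator
(compiled, driven by R's RNG so one seed fixes everything): per-bp
Poisson mutation on an infinite-sites integer grid, Poisson crossovers,
and optional additive selection (fitness $1, 1+s, 1+2s$) at one site,
conditioned on fixation by restarting lost trajectories from the
introduction state. Defaults: N = 200 diploids, L = 500 kb, burn-in 10N
generations, 30 diploids sampled at fixation.

Mutation and recombination rates are desk-scale rescalings, chosen once:
$\mu = 5\times10^{-7}$ gives $\theta = 4N\mu = 4\times10^{-4}$/bp
(roughly 90 segregating sites per 50 kb window in a 60-haplotype sample,
enough that window $\pi$ is genealogy- rather than counting-noise
limited) and $r = 1.5\times10^{-7}$ places the expected sweep footprint
on the order of the 50 kb analysis window. At this population scale the
two dimensionless quantities that would both need to match reality —
$\rho/\theta$ and the footprint/window ratio — cannot be matched
simultaneously; the footprint was prioritized because the window
machinery is what the package exists to exercise.

What the generator does **not** emulate: demography (bottlenecks,
migration, inbreeding typical of cattle pedigrees), recombination-map
heterogeneity, genotyping/phasing error, and — most consequentially —
strong selection. With the desk-scale population, $2Ns = 20$, a weak
sweep whose fixation takes an appreciable fraction of the coalescent
timescale; its post-fixation spectrum is heavily drifted, the diversity
valley is shallow relative to the variance of 25 correlated windows, and
single-replicate outlier detection is intrinsically noisy. A cross-check
with an independent coalescent sweep simulator at identical parameters
shows the same detection ceiling, so passing or failing the recovery
checks here reflects this regime, not the estimators; on genome-scale
data with realistic $2Ns$ the same code faces a much easier problem.
Tajima's D at the sweep window is the most robust of the three signals at
this scale.

The CNV truth generator plants up to 101 non-overlapping regions on a
5 Mb chromosome: 100 neutral regions (85% deletions, carrier frequencies
0.1–0.5 drawn independently of group, het/hom mixed) and one fully
penetrant differentiated deletion — copy number 0 in every sample of the
second group and in half of the first — of 2,416 bp, a realistic
intronic deletion size. Three pseudo-callers re-emit carrier events with
breakpoint jitter (SD 10/25/40 bp), a 5% false-negative rate, 8%
IMPRECISE flags, Poisson(12) supporting reads, uniform false positives,
and Gaussian copy-number annotation noise (SD 0.15) from the read-depth
caller only. The noiseless limit reproduces truth exactly, which the
tests assert. Note one deliberate consequence of the imputation rule: a
false-negative carrier in an otherwise fully deleted group is imputed
diploid and sharply lowers V~ST~, so end-to-end recovery through the
noisy chain is a strictly harder event than the scan-level property.

## Problem sizes and determinism

The test-suite and acceptance workloads use 20 sweep replicates at the
default study conditions, 10 CNV seeds with 100 neutral regions, and
oracle fixtures of at most a few hundred elements; all brute-force
oracles (pairwise $\pi$, direct WC84, naive EHH enumeration, quadratic
interval overlap) agree at 1e-10 (1e-8 for iHS integrals). There is no
randomness outside the generators; ranking ties break by (chrom, start);
reruns with one seed are byte-identical, which the pipeline tests assert
on the written files.
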