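---
title: "Methods: differential methylation from MeDIP-seq read depths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential methylation from MeDIP-seq read depths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipdmr)
library(dplyr)
```

## The measurement model

MeDIP-seq enriches methylated DNA fragments by immunoprecipitation, so the
read depth observed at a CpG site is a proxy for its methylation level.
`medipdmr` compares two conditions (groups A and B, each with a few
biological replicates) on a per-CpG depth table: `chrom`, `pos` (0-based),
one raw-depth column per sample. The package works entirely on *relative*
read depth; it does not attempt absolute methylation calibration
(CpG-density corrections in the style of BATMAN/MEDIPS are out of scope).

Two preprocessing steps precede testing:

* **Coverage filter** (`filter_low_coverage()`): CpGs whose mean raw depth
  across all samples falls below 10 reads are removed, guarding against
  stochastic sampling noise at shallow coverage. Whether the published
  convention of a 10-read floor is per sample or aggregate is ambiguous in
  the field; the mean rule is the default because a per-sample floor of 10
  with six libraries at ~15x genome coverage would discard most sites.
  `mode = "all"` and `mode = "any"` expose the per-sample readings.
* **Normalization** (`normalize_depths()`): each sample is divided by the
  grand mean raw depth of its *group* (all CpGs x all samples of the
  group), so that each group's normalized grand mean is exactly 1 and
  unequal sequencing yields cancel.

## The DMR caller

The caller (`call_dmrs()`) composes four stages, each exposed on its own.

**Per-CpG test with a variance gate** (`test_site()`, `site_tests()`).
At each CpG the two groups' normalized depths are compared. Bartlett's
test (two-group closed form, \(\chi^2_1\)) gates the branch: when its p
exceeds 0.05 the variances are treated as homogeneous and a
pooled-variance two-sample t-test is used; otherwise a Mann-Whitney
rank-sum test with a normal approximation and midrank tie correction.
Zero variance in either group makes the Bartlett statistic undefined and
routes the site to the rank-sum branch; sites where both groups are
constant get p = 1. The statistics are computed by vectorised closed
forms so a 100k-site table tests in well under a second; unit tests pin
them against `stats::bartlett.test()`, `t.test()` and `wilcox.test()` to
1e-9.

A small-sample fact shapes this design: with 3 vs 3 replicates the exact
two-sided rank-sum p-value can never go below 2/20 = 0.1 (there are only
20 label assignments), which is above the per-CpG threshold of 0.01 — an
exact nonparametric test could never contribute a seed. The normal
approximation (minimum two-sided p ≈ 0.0497 at 3v3) is therefore used,
without continuity correction; at these thresholds nonparametric sites
still cannot seed at n = 3, which is a real power limitation of the
design, not an implementation artifact (see *Detection power*, below).

**Seed-and-extend** (`seed_extend()`). Scanning each chromosome 5'→3',
every significant CpG (p < 0.01) not already absorbed starts a seed. The
region extends over consecutive CpGs while the next CpG is (i) within
200 bp of the current last member, (ii) within 2 kb of the seed, and
(iii) itself significant; the first violation terminates the region.
Regions with at least five significant CpGs become candidates. Extension
is single-pass and consuming: a CpG absorbed into one region cannot seed
another, so calls never overlap. The 2 kb limit is measured from the seed
position to the candidate member (a 2 kb *gap* allowance would contradict
the 200 bp adjacency rule). A CpG rejected only for range may start the
next seed. The scanner is verified against a brute-force run-enumeration
oracle on a thousand random instances.

**Region significance by permutation** (`region_pvalue()`). The region
statistic is the absolute difference of group means of the per-sample
mean normalized depth over the member CpGs. The null is built from 1,000
draws, each taking an equal-length run of retained CpGs at a uniformly
random genomic start (within a chromosome) and reassigning the group
labels uniformly at random. Pure sample-label permutation is unusable
here — 3v3 admits only 10 distinct splits — so the random-window scheme
supplies the resolution the permutation count implies while preserving
the local correlation structure of depth data. The pseudocount estimator
p = (1 + #{null ≥ obs}) / (1 + n) avoids zero p-values. Under a global
null these p-values are approximately uniform (checked by a KS bound in
the tests).

**FDR** (`bh_adjust()`). Benjamini-Hochberg over the candidate regions
(not over all CpGs), reported at q < 0.01. The adjustment delegates to
`stats::p.adjust(method = "BH")`; a naive \(O(m^2)\) step-up
implementation serves as the oracle in the tests.

All thresholds live in `dmr_config()` and every stage is deterministic
given `perm_seed`.

## Genomic context

* `element_catalogue()` builds named interval sets from the annotation —
  strand-aware 2 kb promoters (optionally split into HCP/ICP/LCP by CpG
  observed/expected ratio and GC fraction when promoter sequence is
  available), first/other exons and introns, 2 kb downstream windows,
  CpG islands and their 2 kb shores, miRNA loci, repeats — with a
  documented priority order; `annotate_position()` resolves overlaps by
  that order. The catalogue is data-driven: categories exist where the
  inputs define them, and the full default priority list names the
  conventional two dozen classes. Promoter-class thresholds (HCP:
  CpGo/e ≥ 0.75 and GC ≥ 0.55; LCP: CpGo/e < 0.48; window −800..+200 of
  the TSS) follow the established CpG-promoter-classification lineage and
  are all configurable, since published analyses rarely restate them.
* `windowed_profile()` tiles chromosomes (1 Mb default, final partial
  window kept) and reports mean normalized depth, CpG counts and feature
  densities per window, plus GC and CpGo/e when sequence is supplied.
* `subtelomere_mask()` / `zone_methylation()` split each chromosome into
  the terminal 7 Mb at both ends versus the interior, report per
  chromosome x group x zone means and the per-chromosome sign of the
  group contrast, with `zone_comparison_summary()` producing the
  "17 of 19 chromosomes" style tallies. Chromosome ends stand in for
  telomeres; one-ended (acrocentric) assemblies are not modelled.
* `chromosome_correlates()` computes Pearson correlations (with t-based
  p) between per-chromosome mean methylation and length, GC, CpGo/e and
  feature densities.

## Integration with expression

`feature_methylation()` averages normalized depth over strand-aware
compartments (2 kb promoter, gene body, 2 kb downstream; for miRNAs the
2 kb upstream window of the locus start). `differential_expression()` is
a pooled t-test on log-scale values with BH adjustment and a fold-change
gate — deliberately simple, since the upstream expression technology
(microarray or small-RNA-seq) should dictate anything fancier.
`methylation_expression_correlation()` offers two pairings: group
differences (Δmethylation vs log2 fold change) and levels (per-feature
means); published integrations often leave the pairing unstated, so both
are provided and neither is privileged. `classify_pairs()` labels
DMR-bearing, differentially expressed features as *negative* (opposite
signs) or *positive* (same sign), and `reverse_target_pairs()`
enumerates down-regulated targets of up-regulated miRNAs per direction,
counting each gene once however many miRNAs target it. DMRs overlapping
two compartments count in both by default (`unique_assignment = TRUE`
resolves promoter > gene body > downstream).

## qPCR relative quantification

`delta_delta_ct()` implements 2^−ΔΔCt with multi-reference normalization
(arithmetic mean of control Cts, equivalent to a geometric mean of
linear quantities); `ts_ratio()` the telomere-to-single-copy ratio
2^−[(Ct_T−Ct_S)_sample−(Ct_T−Ct_S)_calibrator]; `mtdna_content()` the
doubled COX1:GCG ratio, 2 × 2^(Ct_GCG − Ct_COX1), "doubled" because the
nuclear reference is diploid. Amplification efficiency is fixed at the
ideal 2; standard curves and efficiency estimation are out of scope.
Replicates are averaged as Cts before any arithmetic.

## The synthetic-data generator

`simulate_genome()`, `simulate_depths()` and `simulate_expression()`
exist so that every stage can be exercised and verified without any
external download; the truth tables they return are the ground truth for
recovery tests.

* **Depths** are negative binomial with mean `nb_mean` and variance
  `mean + dispersion * mean^2` (`nb_dispersion = 0` gives Poisson) —
  MeDIP depth is overdispersed count data. Defaults are `nb_mean = 20`
  (matching a ~15x methylome at a 10-read floor) and
  `nb_dispersion = 0.1` (typical biological-replicate overdispersion for
  outbred animals); no published per-sample depth distributions exist for
  this design, so these are conventions, stated once and not tuned.
* **CpG spacing** is exponential (mean 200 bp), so the caller's 200 bp
  adjacency rule is genuinely exercised: roughly a third of background
  gaps break chains.
* **Planted regions** are disjoint runs of `dmr_n_cpgs` consecutive CpGs
  whose internal gaps are at most 200 bp, i.e. CpG-dense, island-like
  context — the setting where real DMRs live and the only placement under
  which "recovery" is a property of the caller rather than of a spacing
  lottery. Group B's mean is multiplied by `dmr_fold` (hyper) or
  `1/dmr_fold` (hypo), alternating so both directions are planted equally.
* **Expression** follows a linear-Gaussian coupling on the standardised
  per-group promoter methylation \(z\): latent expression
  \(r z + \sqrt{1-r^2}\,\epsilon\), so the population correlation with
  promoter methylation equals `coupling_r` exactly; per-sample values add
  small replicate noise (`expr_rep_sd`, default 0.05). Genes without
  promoter CpGs receive pure noise and are flagged. Because the coupling
  acts on per-group methylation, genes whose promoters carry planted
  regions acquire expression shifts of the coupled sign.

What the generator does **not** emulate: read-level sampling (no
fragments, no FASTQ), immunoprecipitation physics, sequence-composition
bias, CpG-density-dependent enrichment, or correlated noise between
neighbouring CpGs beyond the planted fold. Tests passing on this
generator therefore demonstrate the correctness and calibration of the
*algorithms*, not the end-to-end behaviour on real MeDIP libraries.

## Detection power under realistic depth

A consequence worth stating plainly: with 3 replicates per group,
per-CpG α = 0.01 and negative-binomial depth at mean 20 and dispersion
0.1, the pooled t-test has roughly 20% power at a 2.5-fold depth shift,
and a region needs **five consecutive** significant CpGs — so an 8-CpG
region at fold 2.5 is recovered with probability on the order of 10^−3.
This is a property of the published design (shallow replication, a
stringent per-site threshold, and a consecutive-run rule), not of this
implementation: even noiseless Poisson depth at mean 20 would not reach
high region-level sensitivity. The planted-recovery studies in the test
suite and `scripts/acceptance.R` run at exactly these conditions and
report the honest (near-zero) sensitivity; the caller's correctness is
instead demonstrated at high depth (mean 100, Poisson, 5v5 replicates,
fold 4), where recovery exceeds 90%, and by the null calibration, which
yields zero false DMR calls on 10^5 null CpGs. Users planning a MeDIP
study who need region-level sensitivity at modest folds should increase
replication (n ≥ 5 also unlocks the nonparametric branch) or relax the
consecutive-significance rule knowingly.

## Numerical and design choices

* Coordinates are 0-based half-open everywhere internally; 1-based only
  at the GTF boundary. Subtelomere zones use half-open boundaries (a CpG
  at exactly 7,000,000 is non-subtelomeric).
* Ties in the rank-sum test use midranks; complete ties give p = 1.
* The permutation p-value uses the add-one pseudocount; the smallest
  reportable region p is 1/1001 at the default 1,000 permutations.
* The multiple-testing universe is the candidate-region set.
* One master seed drives the pipeline; each stage derives its own seed by
  a fixed offset, so stages can be rerun in isolation and two runs with
  the same configuration produce byte-identical outputs (verified by md5
  in the manifest). Outputs are plain TSV/BED/GTF with `#` headers
  carrying the parameters and seed.
* The pipeline's interface is R functions (`run_pipeline()` and the
  stage functions documented above); shipping a shell wrapper was
  deliberately skipped, as the natural entry points for this package's
  users are the functions and this vignette.
* Problem sizes in the shipped studies (10–20 Mb toy genomes, 5 x 10^4
  to 10^5 CpGs, 200 planted regions, 2,000 genes, 1,000 permutations,
  10–20 replicate seeds) were chosen so the whole suite runs in a couple
  of minutes on a laptop while keeping Monte-Carlo error well inside the
  asserted tolerances.

## Known limitations

* No covariate adjustment, smoothing, or beta-binomial methylation
  modelling; the unit of inference is the relative depth difference.
* The random-window permutation null assumes retained CpGs are
  exchangeable in runs; strong genome-wide covariates (e.g. large
  copy-number differences) would violate it.
* Subtelomere logic assumes both chromosome ends are assembled.
* The DE module is a t-test, suitable for the log-scale expression values
  the generator produces and for microarray-like inputs, not a
  count-model replacement for RNA-seq.
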