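---
title: "Methods and design of splicepop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of splicepop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

splicepop implements the analysis chain of a two-population integrative
genotype/transcriptome study: splicing quantification from junction reads,
differential expression and splicing, cis-QTL mapping with permutation
nulls, allele-frequency differentiation and selection statistics,
isoform-consequence annotation, and the qPCR/phenotype validation
statistics. This vignette records the models, the parameter choices, and the
design decisions taken where the methodology left genuine freedom.

## Splicing quantification

Events are enumerated by pairwise comparison of exon chains within a gene.
Classification works on intron sets: an internal exon of one isoform whose
two flanking introns are fused into a single intron of another isoform is
exon skipping (ES); two introns sharing one boundary while the differing
stretch is exonic and contiguous in the short-intron isoform are alternative
5'/3' splice sites (which side is "5'" depends on strand); an intron of one
isoform entirely contained in an exon of another is intron retention (IR);
two non-overlapping internal exons, each private to one isoform, with shared
outer flanking-intron boundaries are mutually exclusive exons (MXE). Events
are deduplicated across transcript pairs by type and coordinates. The test
suite checks this enumerator exactly against an independently written
per-base-mask comparator on hundreds of random gene models (up to 6 exons,
all five classes generated by random exon drops, splice-site shifts, intron
merges and exon swaps).

PSI is computed from junction counts only: `I` is the arithmetic mean of the
event's inclusion-junction counts, `S` the mean of the skipping-junction
counts, and `PSI = I/(I + S)`, undefined (missing) when `I + S` falls below
`min_reads = 10` informative reads. There is no effective-length
normalisation and no hierarchical read model — the estimator is transparent
and its boundary semantics exact (only skipping reads gives 0, only
inclusion reads gives 1). Two consequences of this definition are worth
stating explicitly:

* IR events have no junction-level inclusion evidence (reads spanning the
  exon–intron boundary are not junction reads), so IR inclusion counts must
  be supplied as pseudo-junction rows keyed by the retained intron with
  `:IR5`/`:IR3` suffixes. This keeps a single input format.
* For ES events the two inclusion junctions are averaged while skipping has
  one junction, so if a fraction `p` of transcripts includes the exon, the
  expected junction-count PSI is `p/(2 - p)`, not `p`. The boundary values 0
  and 1 are preserved and the statistic is monotone in `p`, so two-group
  tests are unaffected; but anything that compares an estimated quantity
  against a latent isoform fraction (the simulator's truth, the planted
  effect-recovery checks) must map the truth through `g(p) = p/(2 - p)`
  first. The tests do exactly that, and the recovery estimand for a planted
  logit-scale allele effect is defined as the least-squares slope of
  `g(true PSI)` on dosage.

Differential splicing uses a two-sided rank-sum test on per-sample PSI
(exact enumeration when both groups have at most 8 untied observations,
tie-corrected normal approximation otherwise), BH correction across tested
events, and the compound call `adj_p < 0.05` and `|dPSI| > 0.1`. Events with
fewer than 3 informative samples in either group are skipped and reported
with a reason rather than silently dropped. The rank-sum-on-PSI test is a
deliberate, documented substitute for likelihood-based splicing models: the
package's claims are about pipeline logic and thresholds, not about
reproducing any specific read-model implementation.

## Isoform consequence and the NMD rule

For an exon-skipping isoform the skipped exon is removed from the transcript
and the reading frame re-threaded from the original CDS start. Removed
coding length mod 3 decides `in_frame` vs `frameshift`; events that do not
touch the CDS (or remove its start codon) are `non_coding`. The altered ORF
is scanned codon by codon for the first stop; NMD is predicted when that
stop lies strictly more than 55 nt upstream of the final exon–exon junction
of the altered transcript. The junction (not the last exon boundary) is the
anchor — the standard exon-junction-complex formulation — and the threshold
is strict (`> 55`). Every constructed test case is verified against a
manual base-by-base translation oracle, including minus-strand transcripts.

## cis-QTL mapping

Promoter windows are anchored at the transcript start site, strand-aware:
TSS −1500/+200 on the transcribed strand, clipped at position 1 (length 1701
unless clipped). Genes with several transcripts contribute one window per
transcript under the gene's feature id; overlapping windows are unioned at
lookup. Splicing windows are the event target plus flanking introns: for ES
and MXE the span from the upstream flanking intron start to the downstream
flanking intron end; for A5SS/A3SS the long-intron bounds (covering both
alternative sites); for IR the retained intron itself, which is both the
alternative region and its own flank.

Association is ordinary least squares of the feature (PSI, or TPM for
expression) on additive dosage, two-sided t-test on the slope, pairwise
deletion of missing data, and explicit reason codes (`monomorphic`,
`too_few_pairs` below 4 complete pairs) instead of silent NAs. A constant
feature vector yields p = 1 by convention. An optional `log_features` flag
regresses on log2(TPM + 1) for eQTL mapping; the default is TPM directly.

The empirical null permutes the feature's sample labels relative to the
genotypes — the standard QTL permutation scheme, chosen over permuting
genotypes or population labels because it preserves the feature's marginal
distribution while breaking the genotype link. One permutation schedule is
drawn per seed and shared across associations, and the empirical p-value is
the pseudo-count estimator `(1 + #{p_perm <= p_nom})/(n_perm + 1)`, bounded
below by `1/(n_perm + 1)`; 1000 permutations by default. Under the global
null the empirical p-values are uniform to Kolmogorov–Smirnov precision
(checked at 200 permutations over 200 associations).

## Population differentiation

The adapted-variant test is a 2×2 Pearson chi-square on allele counts
(study population vs reference), without continuity correction — the
reference counts come from large database exports, so Yates' correction
would only bias the statistic. Calls require `adj_p < 0.05` *and* an allele
frequency difference above 0.3. The frequency difference is the unfolded
same-allele `|af_pop − af_ref|` by default: folding each population to its
own minor allele (available via `fold_maf = TRUE`) can hide exactly the
strong flips the test is meant to find — a variant at alternate-allele
frequencies 0.878 vs 0.334 has unfolded difference 0.544 but folded
difference only 0.212, and the unfolded reading is the one under which such
a variant is called adapted.

Fst uses Hudson's estimator with finite-sample correction; multi-variant
windows use the ratio of averages (sum of numerators over sum of
denominators), which is the aggregation this estimator is designed for. The
per-variant ratio is slightly conservative in the mean (Jensen's
inequality); on Balding–Nichols data at F = 0.1 with 500 + 500 samples and
2000 variants the mean per-variant estimate lands within 0.02 of F. For the
branch statistics, Fst is floored at 0 and capped just below 1 before
`T = −log(1 − Fst)`; `PBS_A = (T_AB + T_AC − T_BC)/2` cyclically, and
`PBSn1 = max(PBS_A, 0)/(1 + Σ max(PBS, 0))`, which lies in [0, 1). The
PBSn1 normalisation follows the standard normalised-PBS formulation.

## Expression

TPM divides counts by gene length in kb and rescales each sample to 1e6.
Differential expression is a Welch t-test on log2(TPM + 1) with BH
correction and the compound call `adj_p < 0.05` and linear |fold change|
> 1.5, where the fold change is computed on group mean TPM with a
pseudo-count of 1. The fold-change threshold is read on the linear scale
(1.5× in either direction). This Welch-on-log-TPM test is a documented
substitute for negative-binomial count models; the compound-rule logic, not
distributional sophistication, is what the package is exercising. Note one
interaction worth knowing: because TPM is compositional, planting many
same-direction expression changes deflates the observed fold changes of the
planted genes (and creates small opposite shifts elsewhere); power
statements in the tests use a planted fraction (10%) at which this
distortion is mild.

## The qPCR and phenotype arm

2^−ΔΔCt quantification: `dCt = Ct_target − Ct_reference` per sample,
`ddCt = dCt − mean(control-group dCt)` (arithmetic mean calibrator, per
gene), `fold = 2^−ddCt` with amplification efficiency fixed at 2. A plate
shift that moves a sample's target and reference Ct equally cancels exactly.
Group comparisons: Mann–Whitney (exact for both groups ≤ 8 untied values,
tie-corrected normal otherwise, p = 1 by convention for fully tied input),
pooled-variance unpaired t, or paired t. Spearman correlation uses average
ranks, exact p below n = 10 and the t approximation from n = 10.

## The synthetic-data generator

The generator defines the study conditions under which the package is
validated. Defaults: 67 + 18 samples (the emulated granulocyte cohort and
its control group), 200 variants at Balding–Nichols divergence F = 0.1,
20 two-isoform genes each contributing one ES event, coverage ~100
informative junction reads per event and sample, allele effects 0.8 on
logit-PSI and 1.0 on log2 expression for the causal half of features,
logit-PSI noise sd 0.3, log2-expression noise sd 0.5, a 2-fold
population-level expression shift in 20% of genes, hemoglobin coupled to the
focal event's PSI at 5 g/dL per PSI unit with noise sd 1.5 (giving
realistic moderate rank correlations), and Ct noise 0.1 cycles. Causal
variants are placed inside their feature's cis window by construction, and
this cross-module consistency is itself tested. Junction reads are binomial
given a Poisson total (a beta-binomial overdispersion option exists,
defaulted off). Phenotypes are coupled to splicing, not genotype, so
mediation through PSI is the planted causal structure.

What the generator does not emulate — and hence what green tests do not
establish about real data: linkage disequilibrium beyond independent
variants, read-mapping artefacts and coverage biases, admixture and
population substructure within a cohort, batch effects, overdispersed or
length-dependent junction capture, and multi-event genes sharing junctions.
The generator validates statistical logic, not upstream bioinformatics.

## Numerical and reproducibility choices

All generators set their RNG state from `(seed + fixed stage offset)` so
each is a pure function of its configuration; the pipeline writes every
stage table to disk with a JSON provenance block (config hash, seed,
package version) and a manifest of MD5 hashes, and reruns of one
configuration are byte-identical. Result tables are written at 6
significant digits with a declared sort key, so output equality is
well-defined. Permutation schedules are drawn once per seed and shared
across associations. Degenerate inputs are resolved by convention rather
than error where a convention is standard: constant features give p = 1,
monomorphic variants are reported with reason codes, fully tied rank tests
give p = 1, both-fixed-same-allele Fst is NA, and Fst is clamped before the
PBS log.

Problem sizes in the test suite are chosen to make the statistical
assertions sharp but cheap: 500 random genes for the enumeration oracle,
500 null associations for nominal calibration, 200 associations × 200
permutations for empirical-p uniformity, 200 replicates for planted-effect
recovery, 2000 variants for divergence calibration and the adapted-variant
null, and a 40-sample pipeline configuration for the end-to-end determinism
check.

## Known limitations

Single-variant association only (no conditional analysis, covariates or
PEER factors); junction-count PSI without effective-length normalisation;
biallelic SNPs only, rejected loudly otherwise; missing genotypes are
propagated, never imputed; no admixture correction of allele frequencies
(the reference counts are taken as given); the A5SS/A3SS and MXE windows
are conventions documented above, as the junction-export coordinate
conventions of upstream aligners vary.
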