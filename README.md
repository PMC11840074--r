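# splicepop

Integrative analysis of paired genotype (WGS) and bulk RNA-seq data from two
diverged human populations, built around the question of how *cis*-regulated
alternative splicing contributes to population-specific physiology (the
motivating setting is granulocyte transcriptomes of a high-altitude
population versus lowland controls). The package is aimed at statistical
geneticists and computational biologists who need the full chain — splicing
quantification, differential testing, QTL mapping, selection statistics and
wet-lab validation statistics — as composable, tested R functions, plus a
synthetic-data generator with recorded ground truth so every stage can be
validated without access to controlled cohort data.

## What it computes

**Splicing.** Alternative-splicing events (exon skipping ES, alternative
5'/3' splice sites A5SS/A3SS, intron retention IR, mutually exclusive exons
MXE) are enumerated from GTF transcript models by pairwise exon-chain
comparison. Each event's usage is quantified from junction reads as percent
spliced in,

    PSI = I / (I + S),

where `I` is the mean read count over the event's inclusion junctions and
`S` over its skipping junctions; PSI = 0 means every transcript skips the
alternative exon, PSI = 1 means every transcript includes it. Differential
splicing between populations uses a two-sided rank-sum test per event with
Benjamini–Hochberg correction and the compound rule FDR < 0.05 and
|ΔPSI| > 0.1. The coding consequence of exon skipping is annotated by
re-threading the open reading frame: removed length mod 3 decides
in-frame vs frameshift, and a premature termination codon more than 55 nt
upstream of the final exon–exon junction predicts nonsense-mediated decay
(NMD).

**cis-QTL mapping.** Expression QTLs are sought in promoter windows (TSS
−1500/+200, strand-aware); splicing QTLs within the alternative exon and its
flanking introns. Each (variant, feature) pair is tested by ordinary least
squares of the molecular phenotype on allele dosage (additive 0/1/2 coding);
empirical p-values come from permuting the feature's sample labels, with the
pseudo-count estimator

    p_emp = (1 + #{p_perm <= p_nominal}) / (n_perm + 1),  n_perm = 1000.

**Population differentiation.** Per-variant allele frequencies; a 2×2
chi-square adapted-variant test against a reference population's allele
counts with the rule FDR < 0.05 and |ΔAF| > 0.3; Hudson's Fst estimator
(ratio of averages across windows); the population branch statistic
PBS_A = (T_AB + T_AC − T_BC)/2 with T = −log(1 − Fst), and its normalised
form PBSn1 = PBS_A / (1 + PBS_A + PBS_B + PBS_C); composite LD r²; and a
contingency chi-square trend test (e.g. allele frequency across altitudes).

**Validation statistics.** Relative qPCR quantification by the 2^−ΔΔCt
method, Mann–Whitney / t-test group comparisons, and Spearman correlation of
transcript measures with blood phenotypes (hemoglobin, WBC, platelets).

**Synthetic data.** `simulate_dataset()` draws two populations under the
Balding–Nichols model (Beta-distributed population frequencies around an
ancestral frequency, divergence parameter F), Hardy–Weinberg genotypes,
planted additive cis effects on logit-PSI and log2 expression, Poisson
junction coverage with binomial inclusion sampling, phenotypes linearly
coupled to splicing, and qPCR Ct tables — recording the full ground truth.

## Worked example

```r
library(splicepop)

cfg <- sim_config(n_pop1 = 40, n_pop2 = 20, n_variants = 150, n_genes = 10,
                  seed = 42)
ds <- simulate_dataset(cfg)
ds$genotypes
#> genotype_matrix: 60 samples x 150 variants
#> populations: pop1=40, pop2=20

psi <- compute_psi(ds$events, ds$junctions, min_reads = 10)
dsg <- diff_splicing(psi, ds$genotypes$population)
head(dsg[order(dsg$adj_p), c("event_id", "delta_psi", "p", "adj_p", "significant")], 3)
#>                       event_id   delta_psi            p       adj_p significant
#> 5 ES|gene005|1:342797-342962:+  0.15278964 0.0004987418 0.004987418        TRUE
#> 1 ES|gene001|1:102839-103057:- -0.08250196 0.0980379504 0.490189752       FALSE
#> 2 ES|gene002|1:163684-163983:+  0.04993006 0.3841181084 0.658712084       FALSE

sqtl <- map_cis_qtl(ds$genotypes, psi, define_splice_windows(ds$events))
sqtl <- empirical_pvalues(ds$genotypes, psi, sqtl, n_perm = 1000, seed = 1)
head(sqtl[order(sqtl$p_empirical),
          c("variant_id", "feature_id", "beta", "p_nominal", "p_empirical")], 3)
#>   variant_id                   feature_id      beta    p_nominal p_empirical
#> 1    var0001 ES|gene001|1:102839-103057:- 0.2019946 2.783223e-18 0.000999001
#> 3    var0002 ES|gene002|1:163684-163983:+ 0.2116544 2.527540e-10 0.000999001
#> 5    var0003 ES|gene003|1:225318-225479:+ 0.1614792 1.283869e-11 0.000999001
```

The first event (ΔPSI = 0.15, adjusted p = 0.005) passes both halves of the
compound differential-splicing rule; the three top sQTLs are the planted
causal variants, each hitting the permutation floor 1/(1000 + 1) ≈ 0.000999
with positive dosage slopes on the PSI scale. Population differentiation on
the same cohort:

```r
af <- allele_frequencies(ds$genotypes)
a1 <- af[af$population == "pop1", ]; a2 <- af[af$population == "pop2", ]
fst <- hudson_fst(a1$af, a1$total / 2, a2$af, a2$total / 2)
mean(fst$fst, na.rm = TRUE)
#> [1] 0.08

pbs <- pbs_stat(0.25, 0.30, 0.05)
c(pbs = pbs$pbs_a, pbsn1 = pbsn1_stat(pbs$pbs_a, pbs$pbs_b, pbs$pbs_c))
#>       pbs     pbsn1
#> 0.2965051 0.2185928
```

The mean per-variant Hudson Fst (0.08) sits close to the generator's
divergence parameter F = 0.1 (the estimator of the per-variant ratio is
slightly conservative; the ratio-of-averages form is unbiased). The PBS
example shows a focal population whose branch carries most of the
differentiation.

`run_pipeline(pipeline_config(...))` chains all stages (PSI → differential
expression/splicing → consequence annotation → e/sQTL with permutations →
differentiation and Fst scan → qPCR/phenotype statistics → final
adapted-sQTL intersection), writing one TSV per stage plus a manifest of MD5
hashes; reruns of the same configuration are byte-identical.

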