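# mobileBF

Exact Bayes factors for detecting graft-mobile transcripts from RNA-Seq
read counts.

## The problem

Grafting two plants of different genotypes (the rooted **stock** and the
grafted-on **scion**) and sequencing mRNA from one side is a standard way to
find transcripts that travel across the graft junction. At each SNP that
distinguishes the two genotypes, the reads covering the position split into
those matching the sampled (**local**) genotype and `n` reads matching the
other (**distal**) genotype. The catch: sequencing and mapping errors also
produce distal-looking reads, so `n > 0` is not evidence of transport by
itself. mobileBF is for researchers analysing heterograft RNA-Seq count
tables who want a principled, rankable measure of the evidence that a
transcript moved — instead of an absolute read-count cut-off.

## The model

At a SNP with `N` total reads, homograft data (same genotype on both sides,
so every distal read is an error) give a conjugate posterior for the
SNP-specific error rate θ:

    θ | D_hom  ~  Beta(u1 + Σ n_i,  u2 + Σ (N_i − n_i))

with a flat prior `u1 = u2 = 1` by default. In the heterograft, the unknown
number of genuinely distal-origin reads `N2 ∈ {0, …, N}` gets a uniform
prior, and the likelihood of observing `n` distal reads is a convolution of
two beta-binomial terms: errors among the `N − N2` local reads (rate θ1 from
the local homograft) and distal reads kept as distal (rate 1 − θ2, θ2 from
the distal homograft). The per-SNP evidence for the two-genotype hypothesis
H2 over the errors-only hypothesis H1 is the maximum posterior odds ratio

    log10 BF21 = log10 [ max_{N2>0} P(N2 | D) / P(N2 = 0 | D) ]

and, because parameters are independent across SNPs, a transcript's total
evidence is the plain **sum** of its per-SNP, per-replicate log10 BFs. A
transcript is called graft-mobile when the total reaches 1 (odds 10:1,
"substantial"). The posterior over `N2` also yields the expected number of
transported reads `⟨N2⟩` and the ratio `r2 = ⟨N2⟩/N`. All probabilities are
computed exactly in log space (log-gamma lookup tables in C++); no Monte
Carlo integration is involved.

The package also ships the two classical baselines it is benchmarked
against: **Method A** (distal reads strictly above 3 in 2 of 3 replicates)
and **Method B** (Method A after discarding every SNP with any homograft
error), plus a labelled-cohort simulator, a blending generator that titrates
one homograft count table into another, and confusion-matrix evaluation
with read-depth and SNP-count sweeps.

## Worked example

Simulate a balanced cohort of 6 transcripts (2 SNPs, 3 replicates, depth
1000, error rate 1%, 30 mobile reads in the positive arm) and score it:

```r
library(mobileBF)
cfg <- simulation_config(error_rate = 0.01, homograft_depth = 1000,
                         heterograft_depth = 1000, mobile_reads = 30,
                         snps_per_transcript = 2, replicates = 3,
                         n_transcripts = 6, seed = 42)
cohort <- simulate_cohort(cfg)
res <- infer_mobility(cohort$heterograft, cohort$homograft_local,
                      cohort$homograft_distal)
print(res, digits = 3)
#>   transcript_id n_snps n_obs total_log_bf mean_expected_n2 mean_r2      label
#> 1        T00001      2     6       38.559            28.81 0.02797     mobile
#> 2        T00002      2     6       31.441            26.70 0.02593     mobile
#> 3        T00003      2     6       49.023            30.46 0.02957     mobile
#> 4        T00004      2     6       -0.093             2.26 0.00226 non-mobile
#> 5        T00005      2     6        0.161             3.14 0.00314 non-mobile
#> 6        T00006      2     6       -0.396             2.03 0.00203 non-mobile
confusion(cohort$truth, res[, c("transcript_id", "label")])
#> <confusion_table> TP=3 FP=0 TN=3 FN=0 | TPR=1.0000 FPR=0.0000 accuracy=1.0000
```

The three mobile transcripts accumulate overwhelming evidence
(total log10 BF 31–49, `⟨N2⟩ ≈ 29` of the 30 planted mobile reads per
observation recovered), while the errors-only transcripts hover around 0 —
neither arm of the hypothesis favoured — and stay below the threshold.

## Count-table schema

All tables are delimited text (TSV by default, CSV auto-detected) with one
row per (transcript, SNP, replicate):

| column | meaning |
|---|---|
| `transcript_id` | opaque transcript key |
| `snp_id` | opaque SNP key (no genomic interpretation) |
| `replicate_id` | opaque replicate key |
| `tissue` | optional: `scion` or `stock` |
| `genotype_sampled` | optional: genotype of the sampled tissue |
| `total_reads` | N, total reads over the SNP |
| `distal_reads` | n, reads matching the distal genotype (0 ≤ n ≤ N) |

A conformance fixture ships in `inst/extdata/example_counts.tsv`.

## Command line

```sh
mobileBF simulate --n-transcripts 100 --seed 7 --out-prefix sim
mobileBF infer --het sim_het.tsv --hom-local sim_hom_local.tsv \
               --hom-distal sim_hom_distal.tsv --out evidence.tsv
mobileBF evaluate --truth sim_truth.tsv --pred evidence.tsv --out metrics.tsv
```

(the executable lives at `system.file("exec", "mobileBF", package =
"mobileBF")`; `blend` and `baseline` subcommands work the same way, and
every command takes `--seed` and an optional `--config key=value` file).

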