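# medipnet

CpG-density-corrected MeDIP-seq methylome analysis and signed
co-methylation networks, with a synthetic multi-tissue methylome
generator for end-to-end validation.

## What problem this solves

MeDIP-seq (methylated-DNA immunoprecipitation sequencing) measures DNA
methylation through antibody enrichment, so local read density confounds
two things: how methylated a region is, and how many CpGs the antibody
could have captured there. `medipnet` is for epigenomics analysts who
want to go from per-sample read intervals (or bin counts) to
CpG-density-corrected methylation scores, annotated feature-level
summaries, tissue-specific differentially methylated region (TS-DMR)
rankings, and co-methylation network modules — the analysis stack of
multi-tissue, multi-individual MeDIP-seq studies of brain and blood.

## The core methods

**Coupling-factor normalization.** The genome is tiled with 500 bp bins
every 250 bp. Each bin gets a coupling factor

    CF(bin) = #{CpG positions p : start − d ≤ p < end + d},   d = 500 bp,

a proxy for the maximal possible MeDIP signal. A calibration curve of
mean reads-per-million against CF is estimated per sample (bins pooled
per integer CF level); its ascending range, up to the signal maximum at
`CF_hi`, captures the CpG-density dependence. The relative methylation
score of a bin is its rpm divided by the calibration-expected signal at
`min(CF, CF_hi)`, scaled into [0, 1] by the 99th percentile. Bins with
CF = 0 are flagged `NA` — no CpG, no interpretable MeDIP signal.

**Feature universe.** CpG islands sub-typed by location with precedence
promoter > 3'UTR > intragenic > intergenic; CGI shores spanning 2,000 bp
up- and downstream of each island (island bases subtracted); CDS spans;
and promoters classified by CpG content into HCP / ICP / LCP via
sliding-window GC fraction and CpG observed/expected ratio
(HCP: GC ≥ 0.55 and o/e ≥ 0.75 in any 500 bp sub-window; LCP: o/e < 0.48
everywhere; ICP otherwise).

**TS-DMR ranking.** Per feature, methylation is summarized per sample
(mean bin score, or RPKM-style normalized read depth), and variability
across tissues is ranked by the coefficient of variance

    CV = SD / (mean + 1)

computed over per-tissue-group mean profiles (or over samples). DMR sets
(top-k or CV > threshold) are tested for feature-class enrichment with
observed/expected ratios against genome-wide class proportions and a
chi-square goodness of fit.

**Sample structure and individual differences.** Pearson correlation
matrices, average-linkage hierarchical clustering on 1 − r, PCA, genic
metaprofiles, and per-feature between-individual differences computed
within each tissue and correlated across tissues (permutation p-values).

**Co-methylation networks.** Signed weighted adjacency
`A_ij = ((1 + cor(x_i, x_j))/2)^β`, topological overlap

    TOM_ij = (Σ_{u≠i,j} A_iu A_uj + A_ij) / (min(k_i, k_j) + 1 − A_ij),

average-linkage clustering of 1 − TOM with a static height cut, module
eigengenes (first principal component per module, sign-aligned, unit
variance), module membership `MM = |cor(profile, ME)|`, trait
significance `GS = |cor(profile, trait)|`, and module–trait
correlations with Student-t p-values. β can be chosen by scale-free
topology fit.

**Synthetic studies.** `simulate_study()` generates a toy genome (CpG
landscape with island clusters, gene models), true methylomes with
planted TS-DMRs concentrated in chosen feature classes and correlated
per-individual effects, and MeDIP-like Poisson bin counts whose
expectation is `L_s · (m_b · CF/(CF+K) + background)` — jointly driven
by methylation and CpG density, exactly the confounding the
normalization must remove.

## Worked example

```r
library(medipnet)

cfg   <- sim_config(seed = 7)            # 2 x 300 kb chroms, 3 tissues x 3 individuals
study <- simulate_study(cfg)
study$genome
#> SyntheticGenome: 2 chrom(s), 600,000 bp total, 8337 CpGs, 24 CGIs, 30 genes
study$experiment
#> MedipExperiment: 2400 bins x 9 samples, median depth 199,842

norm <- medip_normalize(study$experiment$counts, study$experiment$bins,
                        study$genome$cpg)
norm$calibrations[["cortex_ind1"]]
#> CalibrationCurve: 41 CF levels, fit rpm = 378.6 + 2.412 * CF on [5.53333, 73.5833]

se      <- quantify_features(norm$rms, study$experiment$bins,
                             study$methylome$features,
                             study$experiment$metadata, mode = "rms")
records <- cv_rank(se)
head(records[, c("feature_id", "class", "cv", "rank")], 3)
#>        feature_id            class        cv rank
#> 1        cds_g029              CDS 0.1513600    1
#> 2 shore_0002_left   SHORE_PROMOTER 0.1337408    2
#> 3 shore_0011_left SHORE_INTRAGENIC 0.1205711    3

sum(head(records$feature_id, 10) %in% study$methylome$planted_dmrs$feature_id)
#> [1] 7      # 7 of the top 10 ranked features are planted TS-DMRs

net <- comethylation_network(se, beta = 6, min_size = 10)
net
#> ComethylationNetwork: beta = 6, 132 features, modules:
#> turquoise      blue     brown    yellow      grey
#>        55        32        30        12         3
head(net$stats$module_trait[order(net$stats$module_trait$p), ], 1)
#>   module trait          r          p
#> 6 yellow blood -0.9429078 0.00013842
```

The calibration line confirms signal rises with CpG density; the CV
table ranks features by cross-tissue variability (here the top ranks are
dominated by planted DMRs); the network decomposes features into
co-methylated modules, one of which tracks the blood/brain contrast
(eigengene correlation −0.94 with the blood indicator).

A one-command demo of the full pipeline (simulate → annotate →
normalize → quantify → DMR → enrichment → structure → individual
differences → network, with all tables, bedGraph tracks and a manifest):

```r
run_pipeline(demo_config())
```

A thin command-line front end is at `inst/scripts/medipnet.R`
(`run`, `validate`, `simulate` subcommands).

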