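---
title: "Models and methods behind medipnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind medipnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medipnet)
```

# The measurement problem

MeDIP-seq estimates DNA methylation from antibody enrichment of
methylated fragments. Read density over a genomic bin therefore mixes
two signals: the fraction of methylated CpGs, and the number of CpGs
available for capture. A CpG-poor but fully methylated promoter flank
can yield fewer reads than a CpG island at half methylation. All of
`medipnet`'s downstream analyses — tissue-specific DMR ranking,
sample-structure summaries, co-methylation networks — depend on first
removing this CpG-density confound.

# Coupling factors and the calibration curve

The genome is tiled with overlapping bins (`make_bins()`, defaults
500 bp bins every 250 bp, last bins clipped; a chromosome shorter than
one bin yields a single full-length bin). Reads are assigned to bins by
their midpoint (`count_reads_in_bins()`): on a two-fold overlapping grid
a read touches at most two bins and is never double counted within a
step window, keeping counting O(n log n).

The coupling factor of a bin (`coupling_factor()`) counts CpG positions
within `max_distance` of it:

$$\mathrm{CF}(b) = \#\{p : s_b - d \le p < e_b + d\}.$$

`max_distance` defaults to 500 bp — the scale of a sequencing library
fragment, which is what physically carries captured CpGs into a bin's
signal. It is configurable since protocols differ.

`calibration_curve()` groups bins by integer-rounded CF, pools levels
with fewer than `min_bins = 10` bins into the next level up, and
computes the mean reads-per-million per level. The dependence of signal
on CpG density is summarized two ways:

* a least-squares line over the ascending range (CF = 1 up to the level
  of maximal mean signal, `cf_hi`), weighted by the number of bins per
  level so it is anchored where the genome's CF mass lies. A
  non-positive slope aborts normalization — it means the data show no
  CpG-density dependence and dividing by the "expected" signal would
  only inject noise;
* the pooled per-level means themselves, linearly interpolated
  (`expected_signal()`).

The relative methylation score (`rms_normalize()`) divides each bin's
rpm by the interpolated expected signal at `min(CF, cf_hi)` and scales
into $[0,1]$ by the 99th percentile of the ratio over CpG-containing
bins (the quantile, not the maximum, so a single outlier bin cannot
compress the scale). Bins with CF = 0 are reported `NA`: with no CpG
nearby there is no interpretable MeDIP signal. A small guard
$\varepsilon = 10^{-6}$ protects the division.

**Why interpolation rather than the fitted line.** Antibody capture
saturates with CpG density; the per-level mean curve is concave. A
straight line over the ascending range systematically over-estimates the
expected signal at both ends of the range and under-estimates it in the
middle, which leaves a residual correlation between corrected scores and
CF of up to ~0.13 in magnitude on simulated data even when true
methylation is constant. Dividing by the interpolated level means keeps
that residual below ~0.05 while preserving every invariance the line
gives (exactness on linear data, invariance to library-size rescaling
after refit). The line is still fitted and returned — as the validity
check, the definition of the ascending range, and a summary of the
dependence.

# The feature universe

`annotate_features()` assembles the regions on which methylation is
summarized:

* **CGIs sub-typed by location** (`classify_cgi_location()`), precedence
  promoter > 3'UTR > intragenic > intergenic. The promoter window is
  $[\mathrm{TSS}-1000, \mathrm{TSS}+500)$ in transcription direction —
  wide enough to capture immediate-TSS islands; configurable. Promoter
  status wins when a CGI spans several contexts because it is the
  functionally dominant label; a CGI touching several promoter windows
  is linked to the nearest TSS.
* **CGI shores** (`make_shores()`): 2,000 bp up- and downstream of each
  island, clipped at chromosome ends, with bases inside any island
  subtracted so shores never overlap island bases; shores inherit the
  parent island's location subtype. Whether to trim shores against
  neighboring islands was an open design choice; subtraction keeps the
  shore/island contrast clean.
* **CDS** spans (gene body minus the terminal 3'UTR).
* **Promoter CpG classes** (`classify_promoters()`): the window
  $[\mathrm{TSS}-700, \mathrm{TSS}+200)$ is scanned with 500 bp
  sub-windows sliding by 5 bp; a promoter is HCP if any sub-window has
  GC $\ge 0.55$ and CpG observed/expected ratio $\ge 0.75$, LCP if no
  sub-window reaches $0.48$, ICP otherwise. The ratio is
  $\#\mathrm{CpG} \cdot L / (\#C \cdot \#G)$; since the synthetic genome
  carries no literal sequence, $\#C$ and $\#G$ derive from a configured
  GC fraction per gene, with $\#C = \#G = \mathrm{GC}\cdot L/2$. All
  four thresholds and both window sizes are arguments. Windows too short
  for one sub-window are classified on the full window and counted in a
  message.

Coordinates are 0-based half-open on disk (BED convention; I/O through
`rtracklayer`) and 1-based closed in memory (`GRanges`).

# DMR ranking, enrichment and sample structure

`quantify_features()` offers the two feature-level summaries in common
use: the mean corrected bin score over the feature (`mode = "rms"`), and
RPKM-style normalized read depth
$10^9 \cdot \mathrm{reads} / (\mathrm{total} \cdot \mathrm{length})$
(`mode = "rpkm"`). Results live in a `RangedSummarizedExperiment`.

The tissue-specificity statistic is the coefficient of variance
$\mathrm{CV} = \mathrm{SD}/(\mathrm{mean}+1)$ with sample SD ($n-1$
denominator — with three tissue groups the denominator choice materially
changes CV, so it is documented and fixed rather than silent). "Across
tissues/samples" is genuinely ambiguous, so both modes exist: CV over
per-tissue-group mean profiles (the cortex/cerebellum/blood contrast;
cortical sub-regions average into their group), or CV over individual
samples (within-cortex variability). Ranking is descending with ties
broken by feature id, so runs are reproducible.

`enrichment_oe()` compares the class composition of a DMR set with
genome-wide class proportions: expected counts
$E_c = |\mathrm{DMR}| \cdot n_c/N$, ratios $o/e_c = O_c/E_c$, and a
Pearson chi-square goodness of fit over classes ($df = K-1$; classes
with $E_c < 1$ pooled into "other"). The contingency structure of the
test was an open choice; the K-class goodness-of-fit uses all classes
symmetrically and reduces to the textbook hand formula on integer
tables.

Sample structure uses plain Pearson correlation, average-linkage
clustering on $1-r$, and PCA of the feature-centered matrix. Between-
individual analysis (`individual_differences()`) computes per-feature
differences between two named individuals within each tissue group and
correlates the reference-tissue (blood) differences with each brain
tissue; significance is by feature-label permutation (default 1,000,
seeded) since no distributional form is assumed for per-feature
differences.

`metagene_profile()` scales each gene body to a fixed number of
positions, adds fixed-width flanks, reverses minus-strand genes, and
averages — genes shorter than the body resolution are skipped and
counted.

# Co-methylation networks

Profiles are log-transformed ($\log_2(x + 1)$), and features default to
a variance-ranked subset (top 2,000) so the TOM stays desk-scale in
memory; a full-matrix mode exists. The signed adjacency
$A_{ij} = ((1+r_{ij})/2)^\beta$ maps anti-correlated features to 0 —
appropriate here because hypo- vs hyper-methylation is a directional
distinction worth preserving. Topological overlap combines direct
adjacency and shared neighbors; module detection is average-linkage
clustering of $1-\mathrm{TOM}$ with a **static** cut at 0.95 of the
maximal merge height (clusters under `min_size = 30` become grey).
A static cut is deterministic and sufficient for planted-block
recovery; a dynamic tree cut is a possible extension, not a need.
Module labels follow the conventional color order by decreasing size.

Module eigengenes are first principal components of the standardized
module profiles, sign-aligned with the module mean (PCA sign is
arbitrary; the alignment makes "hypomethylated in cortex" read as a
negative trait correlation) and unit-variance. Traits are one-hot
tissue indicators; point-biserial correlation is plain Pearson on the
indicator. Module membership and trait significance are absolute
correlations. When $\beta$ is not supplied, `pick_soft_power()` chooses
the smallest power whose scale-free fit $R^2$ (regression of
$\log_{10} p(k)$ on $\log_{10} k$ over connectivity bins, signed by the
negative slope) reaches 0.8, falling back to the best-fitting power.

# The synthetic-data generator

The generator defines the package's standard study conditions, not a
tunable benchmark:

* genome: 2 chromosomes x 300 kb, ~40 CGIs/Mb of 500–1,500 bp, CpG rates
  0.01/bp background and 0.10/bp inside islands (≈10x contrast, the
  island/ocean structure of vertebrate genomes), 15 non-overlapping
  genes of 3–8 kb per chromosome. CGIs are anchored at promoters, gene
  bodies, 3'UTRs or intergenic space (35/25/15/25%) so all location
  classes arise; promoter-anchored genes get high promoter GC so the
  HCP/ICP/LCP spectrum is populated.
* methylome: class baselines follow the canonical ordering (promoter
  CGIs and HCPs hypomethylated ~0.10–0.15, shores intermediate, gene
  bodies ~0.7, LCPs highest ~0.8). A per-class fraction of features
  (default 5%, intragenic CGIs 10% — a planted two-fold concentration)
  receives a tissue-specific shift of `delta = 0.4` in one random
  tissue, directed away from the nearer bound. Individual deviations
  (SD 0.1) are built from a shared and a tissue-private component scaled
  by $\sqrt{\rho}$ and $\sqrt{1-\rho}$ (default $\rho = 0.7$), giving
  the target cross-tissue correlation exactly in expectation; the
  construction requires $\rho \in [0,1]$. Residual noise SD 0.05.
  Values are clipped to $[0,1]$ and clips are counted.
* background: unannotated genome varies continuously bin-to-bin
  (Gaussian around 0.7, SD 0.1, shared across samples). A flat constant
  would make most of the genome's true methylation exactly tied, and
  rank-based recovery of a tied truth is ill-defined no matter how good
  the estimator.
* counts: per bin and sample,
  $\mathrm{count} \sim \mathrm{Poisson}(L_s (m_b\, g(\mathrm{CF}_b) +
  \mathrm{bg}))$ with saturating capture $g(\mathrm{CF}) =
  \mathrm{CF}/(\mathrm{CF}+K)$, $K = 10$, nonspecific background 0.02,
  and $L_s$ scaled so expected totals equal the configured library size
  (2x10^5 by default). Poisson keeps every marginal analytically
  checkable; optional Gamma mixing adds overdispersion and is off by
  default. Fragment-level read simulation is deliberately skipped —
  counts are generated at bin level, and the read-counting operation is
  tested separately on hand-made interval fixtures.

`simulate_feature_matrix()` is the feature-level counterpart used for
statistical validation at exact feature counts (e.g. 2,000 features with
100 planted DMRs, or three orthogonalized co-methylation blocks —
orthogonalized because with 9 samples, independently drawn block factors
can be strongly correlated by chance, which would misrepresent a
"between-block correlation 0" design).

**What the generator does not emulate:** sequence composition (no
FASTA), bisulfite chemistry, fragment-length distributions, batch and
technical artifacts beyond library size, copy-number variation, and the
genuine biological covariance structure of real methylomes. Passing
tests therefore demonstrate internal correctness and statistical
recovery under a known generative model — not performance on any real
cohort, whose headline quantities (enrichment ratios, between-tissue CVs,
blood–brain correlations, module counts) depend on data this package
does not ship.

# Numerical and degenerate-input choices

* Ties in CV ranking break by feature id; hierarchical clustering uses
  `stats::hclust` (deterministic); module colors are assigned by
  decreasing size.
* CF levels are integer-rounded for calibration; sparse levels pool
  upward; `cf_hi` caps extrapolation.
* Zero-variance samples (correlation), constant traits, constant
  matrices (PCA), modules with constant profiles, and single tissue
  groups raise informative errors naming the offender.
* Empty inputs degrade gracefully where that is meaningful: empty CGI
  sets give empty shore sets, empty BED files round-trip, an all-zero
  signal yields all-zero scores.
* The pipeline derives per-stage seeds from one global seed via a stable
  string hash (`derive_seed()`), so stages are individually reproducible
  and reruns are byte-identical; the manifest records md5 checksums of
  every output and a hash of the effective parameters (the output
  directory is excluded from the hash).

# Problem sizes used in validation

The test-suite and acceptance studies use: a 1 Mb genome with
5x10^5-read libraries for normalization recovery; 2,000 features (100
planted, effect 0.4, noise SD 0.05, 3 tissues x 3 individuals) for DMR
recovery; 600 features in three blocks over 9 samples for module
recovery; 1,000 random instances for the coupling-factor oracle; 50-node
matrices for the TOM oracle; and the bundled 2 x 200 kb demo
configuration for end-to-end determinism. These sizes were chosen so
each check is statistically decisive while the whole suite stays
comfortably desk-scale.

# Known limitations

* The normalization is a self-contained analog of coupling-factor
  methods, parameter-compatible in spirit with established tools but not
  bit-compatible with any of them.
* CV ranking has no per-feature significance model; it is a ranking
  statistic, faithful to its source, not a test.
* The static tree cut can split one block across modules at unlucky cut
  heights; dynamic cutting would be the next refinement.
* `rho_individual` is restricted to $[0,1]$ by the shared/private
  construction; anti-correlated individual effects across tissues are
  not representable.
* Genome-scale (human) runs are out of tested scope; the TOM is
  $O(n^2)$ memory in the feature subset size.
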