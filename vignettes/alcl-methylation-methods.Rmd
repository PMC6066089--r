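---
title: "Models and methods behind alclmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind alclmeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alclmeth)
```

# Scope

`alclmeth` implements a genome-wide DNA-methylation analysis for anaplastic
large-cell lymphoma (ALCL) style cohorts measured on Illumina 450K-type
arrays: probe-level differential calling (MVPs), region-level calling
(DMRs) over the Illumina annotation categories, sample clustering and
ordination against reference thymic developmental stages, promoter
methylation versus gene-expression concordance, chromatin-feature overlap
enrichment and epigenetic-switching detection, a k-mer motif scan around
hypomethylated sites, and MethyLight-style PMR quantification. A seeded
synthetic-cohort generator with recorded ground truth makes all of it
testable without external data.

Input beta values are assumed to be already normalised; array
preprocessing, probe-type bias correction and cell-composition
deconvolution are out of scope.

# Differential methylation model

A probe's methylation fraction is the beta value $\beta \in [0,1]$. All
hypothesis testing runs on the variance-stabilised M-value

$$M = \log_2 \frac{\beta + \epsilon}{1 - \beta + \epsilon},$$

with $\epsilon = 10^{-6}$ (configurable) guarding the boundaries. Per
probe, groups are compared with a Welch two-sample t-test on M-values;
Welch was chosen as the dependency-free default because no shrinkage or
moderation details are assumed, and it is exact under normality without an
equal-variance assumption. Effect sizes are reported on the beta scale as
the difference of group means, $\Delta\beta$, so the dual significance
filter operates on both scales:

* MVPs: Benjamini–Hochberg adjusted $p < 0.01$ **and** $|\Delta\beta| >
  0.2$ (both strict), BH taken across all probes of one comparison.
* DMRs: per-region mean beta over member probes, tested the same way on
  M-transformed region means, then adjusted $p < 0.05$ (strict) **and**
  $|\Delta\beta| \ge 0.15$ (inclusive, matching the stated region
  criterion). BH is applied within each category, so each annotation
  family (for example all islands) forms its own multiple-testing family
  and per-category counts remain self-contained.

Degenerate probes are handled explicitly: identical values in both groups
are exact ties ($t = 0$, $p = 1$); zero within-group variance with
differing means gets a variance floor ($10^{-10}$) and a flag rather than
an infinite statistic.

Regions are formed from the annotation: one region per gene × category for
gene-linked categories, a merged `TSS` view pooling TSS200 and TSS1500
probes per gene (the unit used for expression integration), and runs of
consecutive same-relation probes (split at gaps > 2 kb) for island, shore
and shelf categories. Probes multi-mapped to several genes or categories
are expanded to one membership record each; probe-level statistics are
computed once.

# Clustering, ordination and stage assignment

Two normalisation paths are exposed deliberately. Percent-methylation
views cluster raw beta values; cross-cohort views (for example comparing
tumors with reference developmental stages hybridised on different chips)
first z-score every sample to mean 0 and population variance 1 to absorb
chip-intensity differences. The default sample distance is
$1 - \mathrm{Pearson}$ correlation with average linkage — the standard
recipe for methylation heatmaps — with Euclidean distance available for
z-scored data.

PCA is computed on the sample-space covariance; each component's sign is
fixed so its largest-magnitude loading is positive, which makes
coordinates reproducible across runs and sample orderings.

"Resembles stage X" is made assertable: each tumor sample is assigned to
the reference stage whose centroid (mean normalised profile over the
selected probes) is nearest in Euclidean distance, with a deterministic
first-in-input-order tie-break and a tie flag. Top-probe selection ranks
by ascending p with ties broken by larger $|\Delta\beta|$ and then probe
id, so a "top 1%" selection is reproducible.

# Expression integration

Significant promoter (TSS) DMRs are crossed with linear-scale expression.
A gene is called up- or downregulated when the tumor/control ratio of
group means exceeds 1.5 or falls below 1/1.5, both strict ("more than
1.5-fold"). Four classes result — hyper∧down and hypo∧up (concordant),
hyper∧up and hypo∧down (discordant) — with the hyper- and hypomethylated
TSS counts as denominators and percentages rounded half-up to integers.
DMRs without a gene symbol are dropped from numerator and denominator
(counted and reported); genes with a symbol but missing from the
expression table stay in the denominator as non-concordant, so absent
expression evidence never inflates a percentage. The join is at
gene-symbol level; isoform-level discordance is out of scope.

# Enrichment, switching and ChIP arithmetic

Feature-overlap enrichment uses the half-open point-in-interval rule
throughout (a probe at 0-based position $p$ overlaps $[s, e)$ iff
$s \le p < e$; BED native). The reported background percentage is over
the full probe universe (all manifest probes, mirroring an
array-annotation control set), while the Fisher exact test contrasts the
set with the background probes *not* in the set so the 2×2 table has
disjoint groups. Odds ratios of degenerate tables are capped at $10^6$
and flagged.

Epigenetic switching — Polycomb repression in stem cells replaced by DNA
hypermethylation in tumors — is operationalised as the intersection of
the tumor-hypermethylated set with a reference Polycomb occupancy track,
with a per-gene rollup. ChIP-qPCR fold enrichment is
(signal/normaliser at target) / (signal/normaliser at control region),
which reduces algebraically to $2^{\Delta\Delta C_t}$ at 100% efficiency.

# Motif scan

Full PWM-based motif discovery (MEME-style expectation maximisation) is
deliberately replaced by a deterministic, oracle-testable canonical k-mer
scan: 100-bp windows are extracted around hypomethylated probes
($[p - 50, p + 50)$, clipped at chromosome ends; Ns never match), every
k-mer is collapsed with its reverse complement, and each canonical k-mer
(default $k = 8$) is tested with a one-sided binomial test of its
foreground count against the rate estimated from background windows
(user-supplied, or simulated per window from the foreground's
dinucleotide composition). The reported `e_value` is the Bonferroni
product $p \times 4^k/2$ over canonical k-mers; it is *not* numerically
comparable to a MEME E-value. Hits carry an AP1 similarity: the best
strand-aware ungapped alignment against the consensus TGA(C/G)TCA,
scored as matching positions out of 7.

# PMR quantification

MethyLight-style quantification converts Ct to relative quantity as
$(1+E)^{-C_t}$ (efficiency fixed at 1 by default, as appropriate for a
SYBR protocol without a standard curve) and computes

$$\mathrm{PMR} = 100 \times
\frac{(\text{GeneX mean}/\text{Alu mean})_{\text{sample}}}
     {(\text{GeneX mean}/\text{Alu mean})_{\text{M.SssI}}},$$

with means taken over replicate *quantities* (not mean Ct; the two differ
under noise, and the formula's "mean value" is read as mean measured
quantity — configurable in principle, documented here as the default).
PMR is 0 exactly for no-amplification reactions, may exceed 100 (flagged,
never clipped), and is invariant to rescaling all quantities of one
sample. Group comparisons use one-way ANOVA gating ($p < 0.05$) followed
by pairwise Welch t-tests against the control group only; all-constant
input is reported as $p = 1$ with a zero-variance flag rather than NaN.

# The synthetic cohort generator

The generator defines the study conditions the tests run under: two tumor
groups (`ALK_POS`, `ALK_NEG`) and one control group of **5 samples
each**; baseline probe means drawn from a two-component Beta mixture
(unmethylated component mean 0.1, methylated mean 0.85, precision 15),
with the methylated-component weight following the island relation
(islands 8%, shores 35%, shelves 60%, open sea 75% — islands are mostly
kept unmethylated, as in somatic tissue); spiked effects of
$\Delta\beta = 0.3$ applied to whole probe blocks (2–8 probes per block;
blocks are the regions, separated by 5-kb gaps so region identity is
unambiguous); per-sample noise Beta-distributed around the probe-group
mean.

Choices worth recording:

* **Noise precision 150** (beta sd ≈ 0.02–0.03 at mid-range): the level of
  technical plus residual biological variation expected for
  high-tumor-content (> 90%) fresh-frozen samples on this array family.
* **Spike placement**: hypermethylation is spiked into blocks whose
  baseline can absorb $+\Delta\beta$ without truncation (predominantly
  unmethylated islands), hypomethylation into methylated blocks — both
  matching the biology (tumor hypermethylation targets unmethylated CpG
  islands; hypomethylation hits methylated open-sea/body probes) and
  keeping the realised effect size equal to the nominal one. Truncation
  to $[0.02, 0.98]$ still exists for configurations that force it, and
  warns.
* **Expression coupling**: each spiked promoter gene is made concordant
  with probability 0.13 (the observed hyper∧down / hypo∧up rate scale),
  planting a 2.5-fold change against lognormal noise (sd 0.15), so the
  1.5-fold rule recovers planted genes essentially always and the
  recovered concordant fraction estimates the rate.
* **Seeding**: one run seed fans out to fixed per-generator child seeds,
  so adding a generator never reshuffles another's draws; everything is
  byte-deterministic given the seed.

What the generator does **not** emulate: probe-type (Infinium I/II)
chemistry differences, batch effects, cross-hybridisation, correlated
noise between neighbouring probes, cell-composition mixtures, and
realistic gene/region size distributions. Passing recovery tests on this
generator therefore demonstrates correctness of the statistical machinery
under the declared model, not performance on raw array data.

# Problem sizes and numerical behaviour

The shipped checks use cohorts of 10,000 probes (null-calibration and
spike-recovery experiments), 3,000 probes for clustering, 500-probe
cohorts over 100 replicates for stage assignment, and 20 replicates of
500 windows for motif recovery — sizes at which every property is stable
while the full suite runs in a couple of minutes.

Known limitations:

* With n = 5 per group, Welch-t p-values on M-transformed Beta noise are
  mildly **conservative** (null fraction with $p < 0.05$ ≈ 0.042–0.045,
  most visibly for probes near the beta boundaries where the logit of a
  Beta variate is skewed). A Kolmogorov–Smirnov uniformity test on 10,000
  null p-values can therefore reject on some seeds even though the
  direction of the deviation protects the FDR (BH-significant null counts
  are ~0). This is a property of small-sample t-testing on transformed
  bounded noise, not of the implementation, which matches
  `stats::t.test` to 1e-12.
* The binomial k-mer scan treats k-mer occurrences as independent draws;
  overlapping occurrences of periodic k-mers violate this mildly. The
  Bonferroni `e_value` is conservative.
* `percentOf` rounds half away from zero; summaries always recompute
  percentages from their own counts, so no independent rounding drift is
  possible.
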