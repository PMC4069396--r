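---
title: "Methods: community ordination, functional comparison and metabolic turnover in oil-impacted sediments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community ordination, functional comparison and metabolic turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedimeta)
```

`sedimeta` analyses microbial communities in oil-contaminated marine
sediments along three complementary axes: who is there (16S community
structure), what they can do (metagenome functional profiles), and what
that capacity implies for chemistry (predicted relative metabolic
turnover, PRMT). This vignette describes the models and procedures, the
parameters that matter, the synthetic-data generator used for validation,
and the numerical and design choices that were genuinely open.

## Community structure

The community stage consumes an OTU count table (features × samples) and
per-sample environmental metadata.

**Filtering and rarefaction.** OTUs with fewer than 10 total sequences are
removed (`filter_min_count`, boundary inclusive), then every sample is
subsampled without replacement to a common depth (`rarefy_table`). The
depth convention is the minimum per-sample total after filtering; in the
motivating field study that minimum was 122 804 sequences, which is the
pipeline default. A single draw is taken per sample (no averaging over
draws), so post-rarefaction counts are exactly multivariate hypergeometric:
the test suite checks both the hard invariant (each column sums exactly to
the depth) and unbiasedness against the hypergeometric expectation
`depth * x / total`.

**Ordination.** Sample dissimilarity is Bray–Curtis,
`d(u,v) = Σ|u_f − v_f| / Σ(u_f + v_f)`, computed with vegan. (The
upstream study names the ordination software but not the metric;
Bray–Curtis is that software's default and the field's standard for
abundance data, with abundance-based Jaccard available as an option.)
Ordination is non-metric multidimensional scaling minimising Kruskal
stress-1,

$$\mathrm{stress} = \sqrt{\frac{\sum_{i<j} (\delta_{ij} - \hat d_{ij})^2}
{\sum_{i<j} \delta_{ij}^2}},$$

where the $\delta_{ij}$ are configuration distances and $\hat d_{ij}$ their
monotone regression onto the rank order of the input dissimilarities
(pool-adjacent-violators, primary tie approach: tied dissimilarities may
take any relative order). The optimiser alternates a Guttman transform
toward the current disparities with a step-halving line search that accepts
only stress-decreasing steps, so the recorded stress trace is
non-increasing by construction; if no step improves, the configuration is a
local minimum and iteration stops. The first start is the principal
coordinates (metric MDS) configuration — for dissimilarities that are
exactly embeddable in `k` dimensions this start already has zero stress —
and the remaining `n_restarts` (default 20) starts are random. The
best-of-restarts solution (ties to the lowest restart index) is centered
and rotated to principal axes with a deterministic sign convention.
Defaults: `k = 2`, `tol = 1e-6` relative stress change, `max_iter = 200`.
On non-embeddable dissimilarities the implementation lands within 0.01
stress of vegan's `metaMDS` on the same input (tested), but the two are
independent codes.

**Environmental vectors.** `envfit_vector` regresses a centered
environmental variable on the ordination coordinates; the coefficient
vector, normalised to unit length, is the fitted direction and the
regression R² the strength. Significance comes from permuting the
variable's values across samples (vegan's convention: raw values, not
residuals), with the add-one estimator
`p = (1 + #{r²_perm ≥ r²_obs}) / (1 + n_permutations)`, default 999
permutations, so the smallest attainable p is 1/1000. Samples missing the
variable are excluded from that variable's fit only. One subtlety: with
very few samples a random permutation can reproduce the observed
arrangement (at n = 5 the identity permutation recurs about once per 120
draws), so even a perfect fit then has p > 1/1000 — that is correct
behaviour of the estimator, not a defect.

**Species scores.** Selected OTUs are overlaid on the ordination at the
weighted average of sample coordinates, weighted by the OTU's per-sample
relative abundance — the standard way to show which samples a dominant,
contamination-responding taxon occupies.

## Functional profiles

The functional stage consumes per-sample tabular alignment hits
(BLAST/USEARCH outfmt-6 dialect) against a functional gene database.

**Filtering and best-hit assignment.** Hits are kept at e-value ≤ 1e-5,
identity ≥ 60% and alignment length ≥ 15 (all boundaries inclusive); per
query the single highest-bit-score hit at ≥ 40 bits is assigned. Equal bit
scores resolve to the lexicographically smallest subject id, which makes
assignment independent of input row order (the upstream description is
silent on ties; any deterministic rule would do, this one needs no extra
state). Counts aggregate per (gene family, sample), and
`aggregate_hierarchy` sums them up a three-level functional hierarchy with
per-sample totals conserved.

**Two-group comparison.** Gene-family tables are normalised to percent
proportions per sample and compared between the EPA-benchmark exceed and
non-exceed groups with a two-sided Welch (unequal-variance) t-test at 0.95
confidence, plus the effect filter used in the field: only features whose
group mean proportions differ by at least 1.00 percentage point count as
candidate effects. Benjamini–Hochberg q-values are computed over the
features passing the effect filter and reported alongside raw p-values; the
default significance call (raw p ≤ 0.05 and effect filter) mirrors common
practice with this test, and the q column lets stricter users switch.
Features with zero variance in both groups and equal means return p = 1
rather than NaN. Calibration is tested: under a 7-vs-7 null the empirical
type-I error at α = 0.05 stays within Monte-Carlo error of nominal over
5000 features.

**Sample–function network.** A bipartite edge list (sample, function,
weight = count) keeps cells with count ≥ 20 ("observed fewer than 20
times" omitted, so exactly 20 keeps its edge). Layout and drawing are out
of scope; the edge list imports directly into network tools.

## Predicted relative metabolic turnover

PRMT converts EC-number abundance profiles into per-metabolite scores.

**Environmental transformation matrix (ETM).** From a reaction database
(EC numbers plus signed stoichiometry), each EC column holds the average
over its reactions of the signed coefficients: `+ν` for a substrate
(consumed), `−ν` for a product. Averaging over an EC's reaction set keeps
promiscuous ECs from dominating; a `weighting = "sum"` flag restores plain
summation. Reversible reactions score in their written direction (the
database convention), with a flag to drop them instead. Currency
metabolites (water, protons, ATP/ADP, NAD(P)(H), CoA, orthophosphate) get
no rows by default — their turnover is uninformative — and nitrogen species
are never excluded by default. These three policies are declared package
choices: the original turnover formulation leaves them unstated.

**Scores.** EC abundances are quantile-normalised (ties receive the mean
of their rank positions' reference values) and log2-transformed with a +1
pseudocount (zeros are common in annotation counts; the upstream
description does not state a zero policy). With the mean of all samples as
the reference,

$$S_{mj} = \sum_e W_{me}\,\bigl(A_{ej} - \overline{A_{e\cdot}}\bigr),$$

so each metabolite's scores sum to zero across samples — an exact
structural invariant in the tests. Positive scores predict relative
consumption of the metabolite in that sample, negative relative
accumulation. Note that tie-averaging in quantile normalization means
per-column value multisets are only exactly identical when the data are
tie-free; the tests check that property on continuous data.

**Group comparison.** The upstream description pairs a "Wilcoxon signed
rank" name with 1000 permutation tests, but the exceed / non-exceed groups
are independent samples, for which a signed-rank (paired) test is not
defined without a pairing. The default here is therefore the unpaired
Wilcoxon rank-sum statistic with a two-sided group-label permutation
p-value centered on the null expectation `E0 = nA(nA+nB+1)/2`, 1000
permutations, add-one estimator (minimum p = 1/1001); a `paired = TRUE`
mode provides the sign-flip signed-rank test for designs that do pair
samples. Direction labels come from the sign of the group mean score
difference: higher in the exceed group means consumption up under
contamination.

## Synthetic study generator

Because the field study's reads and chemistry are not redistributable, the
package validates itself on synthetic data shaped like the study, with
known ground truth (`study_config`, `generate_metadata`,
`generate_otu_table`, `generate_functional_data`). The generator's defaults
encode the study conditions:

* 64 samples, the 19 nearest the wellhead (0.3–5 km) flagged as exceeding
  the EPA benchmark; the rest at 5–256 km.
* TPH spanning 18–65 643 μg kg⁻¹, decaying exponentially with distance
  (e-folding 4 km, log-scale noise SD 0.2); with these choices the exceed
  group's mean TPH lands near the observed ~19 000 μg kg⁻¹. Ammonia and
  nitrate rise with TPH so inorganic nitrogen co-varies with contamination.
* Three responder OTUs whose expected relative abundance follows a
  saturating Hill function of TPH (`f_max · TPH² / (TPH² + K²)`,
  `K = 1000 μg kg⁻¹`). The Hill form (rather than plain Monod) is needed to
  satisfy both stated endpoints at once: the leading responder reaches 18%
  of the community at maximum TPH yet stays below 0.01% at background TPH.
  A plain hyperbola cannot do both.
* A log-normal rank-abundance background community (σ = 1.5 on the log
  scale, 400 OTUs by default) and multinomial sampling per sample at a
  depth drawn uniformly from `depth_range` (default 122 804–200 000 reads,
  so the published rarefaction depth is feasible on default output).
* A metagenome subset of 7 exceed + 7 non-exceed samples; ~47 gene
  families (nitrogen cycle, BTEX/PAH/alkane degradation, anonymous
  background) with Poisson counts around a family-specific mean (≈60 reads,
  log-normal spread), and the denitrification (narG/napA/nirS/norB/nosZ)
  and BTEX families multiplied by `enrichment_fold` (default 4) in exceed
  samples. Setting `enrichment_fold = 1` and `responder_max_fraction ≈ 0`
  yields a null study on which all significance calls should occur at the
  nominal rate — and do, in the tests.
* Forged hit tables that reproduce the planted counts exactly under the
  filter + best-hit rules: each counted read has one passing hit (bit score
  ~ N(80, 10) truncated at 41), plus competing lower-bit hits, high-bit
  hits that fail exactly one quality filter, and decoy-only queries below
  40 bits. This makes the annotation stage testable to zero mismatches.
* A toy nine-reaction nitrogen-cycle database (synthetic fixture, not a
  KEGG extract) with real nitrogen-cycle EC labels, covering fixation,
  nitrification and denitrification. Under planted denitrification
  enrichment the PRMT stage must report nitrate as consumed and dinitrogen
  as accumulated in the exceed group.

What the generator does **not** emulate: sequencing error and chimeras,
taxonomic correlation structure (OTUs are independent given their means),
compositional coupling between the OTU and gene-family layers, spatial
autocorrelation beyond the single distance axis, and measurement error in
the chemistry. Passing recovery tests therefore demonstrates that the
pipeline's statistics recover planted effects of realistic size and are
calibrated under a clean null — not that they are robust to every artefact
of real sequence data.

## Problem sizes and reproducibility

The recovery and calibration experiments in the test suite and the
acceptance script run on scaled-down studies (150 OTUs, 4000–6000 reads
per sample) chosen so that effect recovery stays informative while a full
validation sweep — tens of replicate studies — completes in well under a
minute each; the single end-to-end pipeline run uses the full default
configuration including the 122 804-read rarefaction rule. Every random
step takes an explicit seed; `run_all` derives per-stage seeds by hashing
(master seed, stage name), so any stage can be reproduced in isolation,
and two runs with the same master seed produce byte-identical run
directories (stage timings go to the console rather than into the
manifest for exactly this reason).

## Known limitations

* NMDS line-search majorisation guarantees monotone stress but, like all
  NMDS, only local optimality; restarts mitigate this and the default of
  20 matches common practice.
* The ETM policies (per-EC averaging, written-direction reversibility,
  currency list) are declared defaults, not inferred ground truth; all
  three are configurable.
* The hit-table dialect is a clean-room 12-column outfmt-6; annotation
  pipelines with other export schemas need a one-line conversion.
* Proportion-scale Welch tests ignore the compositional dependence between
  features; this matches the field-standard procedure being reproduced,
  and the q-value column is provided for users who want multiplicity
  control beyond it.
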