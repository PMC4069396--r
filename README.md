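# sedimeta

Analysis of microbial communities in oil-spill-impacted marine sediments.

After a large offshore spill, deposited hydrocarbons restructure the
sediment microbiome: a handful of oil-degrading taxa bloom along the
contamination gradient, hydrocarbon-degradation genes become enriched in
the most contaminated samples, and the nitrogen cycle tips toward
denitrification. `sedimeta` packages the computational side of that kind
of study — for microbial ecologists working with an OTU table,
per-sample chemistry, and tabular functional-annotation hits — as a
tested, reproducible R pipeline with three stages:

1. **Community structure.** OTU filtering, rarefaction (single
   subsampling draw without replacement to even depth), Bray–Curtis
   dissimilarity `d(u,v) = Σ|u_f − v_f| / Σ(u_f + v_f)`, non-metric
   multidimensional scaling minimising Kruskal stress-1
   `√(Σ(δ − d̂)² / Σδ²)` (isotonic disparities d̂, Guttman-transform
   updates with a monotone line search, metric-MDS + random restarts),
   environmental vector fitting with permutation p-values
   `p = (1 + #{r²_perm ≥ r²_obs})/(1 + N)`, and abundance-weighted
   species scores for highlighted OTUs.
2. **Functional profiles.** BLAST/USEARCH outfmt-6 hit filtering
   (e-value ≤ 1e-5, identity ≥ 60%, length ≥ 15), best-hit gene-family
   assignment at ≥ 40 bits, hierarchical aggregation, percent-proportion
   normalisation, two-sided Welch *t*-tests between EPA-benchmark exceed
   and non-exceed groups with 0.95 confidence intervals and a
   1.00-percentage-point effect filter (BH q-values alongside), and a
   bipartite sample–function network (edges kept at count ≥ 20).
3. **Predicted relative metabolic turnover (PRMT).** An environmental
   transformation matrix W (metabolites × ECs) built from reaction
   stoichiometry (substrate +ν, product −ν, averaged over each EC's
   reactions), quantile-normalised log2 EC abundances, scores
   `S = W (A − Ā)` against the mean-of-samples reference (positive =
   consumption, negative = accumulation), and group comparison by
   Wilcoxon rank-sum statistics with 1000-permutation p-values.

A synthetic-study generator with known ground truth (contamination
gradient, responder OTUs, planted gene-family enrichment, a toy
nitrogen-cycle reaction database) makes every stage testable end to end,
and `run_all()` orchestrates the whole pipeline from one master seed with
byte-identical reruns. See `vignettes/sedimeta-methods.Rmd` for the full
methods account.

## Worked example

Simulate a study shaped like a 64-sample sediment survey (19 contaminated
near-well samples, TPH 18–65 643 μg kg⁻¹, three oil-responder OTUs, a
7-vs-7 metagenome subset with denitrification and BTEX gene families
enriched 4× under contamination), then run each stage:

```r
library(sedimeta)

cfg  <- study_config(seed = 11, n_otus = 150, depth_range = c(4000, 6000))
meta <- generate_metadata(cfg)

## community: filter, rarefy, ordinate, fit the TPH vector
otu  <- generate_otu_table(cfg, meta)
filt <- filter_min_count(otu$table, 10)
rar  <- rarefy_table(filt, min(colSums(filt$counts)), seed = 11)
rar
#> feature_table: 150 features x 64 samples [counts]
ord <- nmds(bray_curtis(rar), k = 2, seed = 11)
ord
#> ordination: 64 samples, 2 axes, stress = 0.01034 (converged)
envfit_vector(ord, setNames(meta$tph, meta$sample_id), seed = 11,
              variable = "tph")
#> envfit: tph  r2 = 0.3714  p = 0.021  (999 permutations, n = 64)

## functional comparison: exceed vs non-exceed gene-family proportions
fun <- generate_functional_data(cfg, meta, hit_tables = FALSE)
cmp <- compare_groups_welch(relative_abundance(fun$family_table),
                            fun$groups$exceed, fun$groups$non_exceed)
#> 16 of 47 families significant (p <= 0.05 and >= 1 pp effect);
#> top hits: xylM, norB, bssA, narG, nosZ

## PRMT: metabolite turnover shifts under contamination
etm <- build_etm(fun$reactions)
sc  <- prmt_scores(normalize_ec_abundance(fun$ec_table), etm)
pr  <- compare_prmt_groups(sc, fun$groups$exceed, fun$groups$non_exceed,
                           seed = 11)
subset(annotate_metabolite_directions(pr),
       metabolite %in% c("NO3-", "NO2-", "N2", "NH3"))
#>  metabolite       direction     p_value
#>          N2 accumulation_up 0.000999001
#>         NH3  consumption_up 0.694305694
#>        NO2- accumulation_up 0.000999001
#>        NO3-  consumption_up 0.000999001
```

Reading the output: the ordination separates samples along the
contamination gradient at low stress (0.01 — an excellent fit); TPH is a
significant environmental vector (r² = 0.37, permutation p = 0.021). The
Welch stage recovers the planted enriched families (denitrification and
BTEX markers top the list). PRMT reports increased potential consumption
of nitrate and accumulation of nitrite and dinitrogen in the contaminated
group at the smallest attainable permutation p (1/1001) — exactly the
denitrification signature planted in the generator.

The full pipeline, writing every input and result file plus a manifest
under one directory:

```r
run_all(run_config(out_dir = "run1", seed = 11, depth = NULL))
```

(`depth = NULL` rarefies at the minimum per-sample total after filtering;
the numeric default, 122 804, is the published study's depth.) A thin
shell wrapper lives at `inst/scripts/sedimeta.R`.

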