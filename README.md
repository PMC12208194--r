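# crossmetsig

Cross-species metabolic signature scoring and tumor similarity
classification.

## The problem

Fly tumors driven by loss of a single cell-polarity gene (*scrib*/*dlg*)
become malignant within days, apparently through metabolic collapse —
depletion of acetyl-CoA and S-adenosyl methionine — and the epigenetic
reprogramming that follows, rather than through mutation accumulation. If
that route to tumorigenesis is evolutionarily ancient, a subset of human
tumors should carry the same metabolic transcriptional signature.
`crossmetsig` is for computational biologists who want to ask that
question of their own cohorts: it scores fly-reference and human-query
expression profiles over conserved metabolic pathways, classifies each
query sample as metabolically similar or non-similar to the fly-tumor
signature, and runs the downstream group contrasts.

## The method

For each sample, every conserved pathway gene set *G* (|G| = m out of N
measured genes) receives a single-sample enrichment score: rank genes by
descending abundance, give gene *j* the bottom-up rank weight *r<sub>j</sub>*,
and accumulate

> ES(G) = Σ<sub>i=1..N</sub> [ P<sub>G</sub>(i) − P<sub>NG</sub>(i) ],
> &nbsp; P<sub>G</sub>(i) = Σ<sub>j≤i, j∈G</sub> r<sub>j</sub><sup>α</sup> / Σ<sub>j∈G</sub> r<sub>j</sub><sup>α</sup>,
> &nbsp; P<sub>NG</sub>(i) = #{j≤i, j∉G} / (N − m)

with α = 0.25 by default. Each query sample's K-vector of pathway scores
(K = 72 conserved pathways in the motivating design) is tested against the
fly-tumor reference vector by the Pearson correlation test
(t = r·√((K−2)/(1−r²)), K−2 df, two-sided), P-values are
Benjamini–Hochberg adjusted across the cohort, and a sample is *similar*
when adjusted P < 10⁻⁶ and r > 0. The similar / non-similar groups are
then contrasted by Fisher's exact test (mutation events, odds ratio
ad/bc), Welch t-tests (age, log2 mutation load, mean methylation beta) and
the two-group log-rank test. A metabolomics module normalizes LC-MS
machine concentrations to nmol/g
(C<sub>M</sub> = c<sub>machine</sub> × dilution × V<sub>F</sub> / M<sub>s</sub>)
and compares genotypes by the Wilcoxon rank-sum test. A seeded synthetic
cohort generator reproduces the full statistical structure (planted
similar subpopulation, enriched mutations, group-shifted covariates) so
every stage is testable without external downloads.

## A worked example

```r
library(crossmetsig)

sim <- simulate_cohort(simulation_config(
  n_genes_per_species = 600L, n_pathways = 20L, n_fly_samples = 4L,
  n_query_samples = 400L, seed = 1))

fly_scores   <- score_matrix(sim$fly_expr,
                             restrict_to_measured(sim$pathways, sim$fly_expr))
query_scores <- score_matrix(sim$query_expr,
                             restrict_to_measured(sim$pathways, sim$query_expr))

cls <- classify_cohort(query_scores, build_reference(fly_scores))
glance(cls)
#> # A tibble: 1 × 5
#>   n_similar n_total frac_similar threshold adjust
#>       <int>   <int>        <dbl>     <dbl> <chr>
#> 1        28     400         0.07  0.000001 BH
```

28 of 400 query samples (7%) correlate with the fly-tumor signature at
adjusted P < 10⁻⁶ — exactly the planted similar subpopulation. The groups
then differ in the planted directions:

```r
group_contrast(sim$cohort, cls, "age")
#> # A tibble: 1 × 8
#>   variable transform mean_similar mean_other n_similar n_other     t          p
#> 1 age      identity          45.4       61.2        28     372 -5.43 0.00000631

head(mutation_landscape(sim$cohort, cls), 3)
#> # A tibble: 3 × 9
#>   gene      a     b     c     d odds_ratio       p direction           highlight
#> 1 mutA      9    42    19   330       3.72 0.00452 enriched_in_similar FALSE
#> 2 mg019     3     7    25   365       6.26 0.0265  enriched_in_similar FALSE
#> 3 mg023     5    24    23   348       3.15 0.0422  enriched_in_similar FALSE
```

The similar group is ~16 years younger (Welch t = −5.4), and the planted
mutation gene `mutA` tops the Fisher screen with odds ratio 3.7 in this
small cohort (at the default 2000-sample scale it is highlighted at
P < 10⁻³). `autoplot(cls)`, `autoplot(mutation_landscape(...))` and
`tidy()`/`glance()` methods cover plotting and tidying;
`run_pipeline(config, out_dir)` executes score → classify → contrast end
to end, writing all TSV artifacts plus a run manifest, byte-identically
for a fixed seed. See `vignettes/metabolic-similarity.Rmd` for the model,
assumptions and design choices.

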