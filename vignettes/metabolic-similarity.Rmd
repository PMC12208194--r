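---
title: "Cross-species metabolic similarity: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species metabolic similarity: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossmetsig)
library(dplyr)
```

## The scientific question

Fly tumors caused by loss of a single cell-polarity gene reach malignancy
within days, without accumulating mutations, apparently driven by metabolic
collapse (depletion of acetyl-CoA and S-adenosyl methionine) and the
epigenetic reprogramming that follows. If that route to tumorigenesis is
evolutionarily ancient, some human tumors should carry the same metabolic
transcriptional signature. `crossmetsig` implements the comparative
pipeline that asks this question: score every tumor sample — fly reference
and human query alike — over a curated set of metabolic pathways conserved
between the two species, then test each human sample's pathway-score vector
for positive correlation with the fly-tumor signature, and contrast the
resulting similar / non-similar groups on clinical and genomic covariates.

## The enrichment statistic

For one sample with $N$ measured genes and a pathway gene set $G$ with
$|G| = m$, genes are ranked by descending abundance. Let $r_j$ be the rank
counted from the bottom (the highest-expressed gene has $r_j = N$). The
single-sample enrichment score is the sum over ranked positions $i$ of the
difference between two cumulative distributions,

$$ES(G) \;=\; \sum_{i=1}^{N}\Big[P_G(i) - P_{NG}(i)\Big],
\qquad
P_G(i) = \frac{\sum_{j \le i,\, j \in G} r_j^{\alpha}}
              {\sum_{j \in G} r_j^{\alpha}},
\qquad
P_{NG}(i) = \frac{\#\{j \le i,\, j \notin G\}}{N - m}.$$

The implementation uses the algebraically equivalent closed form (each
position's cumulative contribution is counted once per remaining position),
which is $O(N)$ per pathway after one sort per sample; the test suite pins
it against a brute-force version that materializes both cumulative
distributions explicitly.

Properties worth knowing:

* **Rank invariance.** The score depends on abundances only through ranks,
  so FPKM vs TPM vs log-scale input makes no difference within a sample.
* **Weighting exponent.** `alpha = 0.25` by default, the original ssGSEA
  weighting; it is recorded in the result's `params` for provenance, as is
  the tie rule.
* **Ties.** The running-sum order is always abundance-descending with
  input-order tie breaking. `tie_rule = "average"` (default) gives tied
  genes the mean of their positional weights, which makes the *weights*
  invariant to permutations of tied genes; `"stable"` keeps strictly
  positional weights for exact replication of rank-tools that break ties
  by input order. Real abundance data are effectively tie-free.
* **Degenerate sets.** An empty set or a set equal to the whole universe
  leaves one of the two distributions undefined; `restrict_to_measured()`
  removes such pathways up front and reports them, and the scorer refuses
  them with an error rather than guessing.
* **Normalization.** Min–max normalization of the score matrix is an
  affine transform shared by all samples; it provably leaves the
  downstream Pearson correlation (and hence the classification) unchanged,
  so it is off by default.

## The similarity test

The fly reference signature is the per-pathway mean (optionally median)
score over the supplied fly tumor samples; which samples and which
aggregation are kept in the result's provenance. Each query sample's
$K$-vector of pathway scores (here $K = 72$ conserved pathways) is compared
to the reference by the Pearson correlation test: with
$t = r\sqrt{(K-2)/(1-r^2)}$ on $K - 2$ degrees of freedom, two-sided. Raw
P-values are adjusted across the cohort — Benjamini–Hochberg by default,
Bonferroni available — and a sample is labelled *similar* when its adjusted
P falls below $10^{-6}$ **and** $r > 0$.

Two of these choices were genuinely open and are package decisions:

* The multiple-testing method is not dictated by the analysis itself; BH is
  the standard choice for cohorts of this size and is recorded in the
  output attributes.
* A two-sided test can be passed by a strongly *anti*-correlated sample.
  Calling such a sample metabolically similar would be semantically wrong,
  so the positive-sign requirement is imposed by default and exposed as
  `require_positive` for users who want the pure two-sided behaviour.

Scores enter the correlation raw (not z-scored per pathway): per-pathway
standardization changes $r$ and is therefore opt-in upstream rather than a
silent default.

## Downstream contrasts

With labels in hand the cohort contrasts are standard and deliberately so:

* **Mutation events** — per recurrent gene (default: mutated in at least 2
  samples; singletons cannot approach the $10^{-3}$ highlight threshold
  and only inflate the screen), a 2×2 Fisher exact test, two-sided by the
  minimum-likelihood convention, with the odds ratio reported as the
  cross-product $ad/bc$ so direction reads directly off the table.
* **Age, mutation load, methylation** — unpaired two-tailed Welch t-tests
  (the unequal-variance form is the safer default when group sizes differ
  by an order of magnitude; a pooled-variance toggle exists). Mutation
  load is compared on the log2 scale; zero counts are excluded with a
  warning rather than silently pseudo-counted (`pseudocount` is available).
* **Survival** — the two-group log-rank test with P from $\chi^2_1$.

## Metabolomics

Machine-reported LC-MS concentrations (µmol/l) are converted to per-mass
tissue concentrations via
$C_M = c_{\text{machine}} \times \text{dilution} \times V_F / M_s$
(µmol/l × µl / mg = nmol/g — the only dimensionally consistent combination
of the measured quantities, so the numeric formula needs no unit
constants). Genotype differences are tested with the Wilcoxon rank-sum
test: exact enumeration when the pooled sample is ≤ 20 without ties (at
the study's 4 + 4 replicate design the smallest achievable two-sided P is
$2/70$), the tie-corrected normal approximation otherwise, with the branch
reported. Fold changes are ratios of replicate means (geometric-mean and
log2 options exist for log-scale colouring).

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the full statistical structure the analysis
assumes, with one mandatory seed feeding a documented sub-stream scheme
(one sub-seed per output table, so adding a table never perturbs earlier
draws):

* exact 1:1 synthetic orthologs in distinct namespaces (`fg####` /
  `HG####`), partitioned into 72 disjoint conserved pathways of 8–25
  genes out of 2400 per species — disjointness makes the gene-level shift
  unambiguous and still exercises all of the conservation logic;
* log-normal expression, $\log x = \mu_g + \delta + \varepsilon$ with
  per-species baselines $\mu_g \sim N(\log 50, 1)$ drawn independently per
  species and unit noise; each pathway draws one shift
  $\delta_p = \pm\,\texttt{pathway\_effect\_sd}$ (default 3, in units of
  the baseline log-sd) applied to fly tumor samples and, via the ortholog
  map, to the planted similar query subpopulation (default fraction 0.07,
  mirroring the ~7% similar rate the design targets);
* clinical covariates per group: ages $N(45, 15^2)$ vs $N(60, 15^2)$,
  mutation loads log-normal with medians 20 vs 80, methylation betas
  $\mathrm{Beta}(10,12)$ vs $\mathrm{Beta}(14,10)$, exponential survival
  with equal default hazards $1/1500$ per day (the survival contrast is
  predominantly null in this design) and administrative censoring at 10
  years;
* mutation events per gene with baseline rates drawn in 0.02–0.15, and
  planted genes whose mutation odds are multiplied by a target odds ratio
  (default one gene at OR 8) in the similar group.

Because the two species' gene baselines are independent, a null query
sample's pathway-score vector shares no systematic component with the fly
reference; empirically the null correlations stay far below the
significance region and the false-positive fraction at the $10^{-6}$
threshold is ~0. What the simulator does **not** model: negative-binomial
count noise with gene-wise dispersion trends, batch effects, overlapping
pathway membership, copy-number structure, or realistic linkage between
mutations and expression. Passing the recovery tests therefore shows the
pipeline is correct and well calibrated under its own assumptions — not
that real cohorts will separate this cleanly.

## Numerical choices and degenerate inputs

* Correlation P-values are floored at the smallest positive double rather
  than reported as 0 (a perfectly correlated vector is otherwise an
  underflow).
* Zero-variance score vectors are an error (`correlation undefined`), not
  an `NA` that propagates.
* Fisher tables with a zero margin return $p = 1$ with the odds ratio
  flagged undefined; $bc = 0$ with $ad > 0$ reports an infinite odds
  ratio.
* All TSV output is UTF-8, Unix newlines, `NA` for missing; probabilities
  are serialized in scientific notation with 6 significant digits while
  full double precision is kept in memory, which makes byte-identical
  reruns a meaningful (and tested) property of `run_pipeline()`.

## Problem sizes used by the test suite

The unit and property tests run the generator at reduced sizes chosen to
keep the whole suite around a minute while preserving every structural
feature (500 genes, 15 pathways, 100–600 query samples, 40 replicated
null cohorts). The acceptance checks run the study-scale conditions: a
2000-sample query cohort at the default effect size for recovery, a
10,000-sample null cohort for calibration, 1000 log-rank replicates for
test size, 500-instance oracle sweeps for the enrichment score and 100
seeded replicates of the 500-sample mutation screen.

## A worked example

```{r example, fig.width = 6, fig.height = 3.5}
sim <- simulate_cohort(simulation_config(
  n_genes_per_species = 600L, n_pathways = 20L, n_fly_samples = 4L,
  n_query_samples = 400L, seed = 1))

fly_scores   <- score_matrix(sim$fly_expr,
                             restrict_to_measured(sim$pathways, sim$fly_expr))
query_scores <- score_matrix(sim$query_expr,
                             restrict_to_measured(sim$pathways, sim$query_expr))

cls <- classify_cohort(query_scores, build_reference(fly_scores))
glance(cls)
autoplot(cls)

group_contrast(sim$cohort, cls, "age")
head(mutation_landscape(sim$cohort, cls), 3)
```

## Known limitations

The pipeline classifies against a *single* reference signature; cohorts
mixing several distinct metabolic states would need one reference per
state. The conserved-pathway table is taken as curated truth — no ortholog
inference, no symbol-alias resolution — so identifier mismatches surface
as dropped pathways rather than being repaired. And the $10^{-6}$
adjusted-P cutoff is a declared operating point, not an optimized one: the
similar-count is monotone in the threshold (tested), so sensitivity
analyses amount to re-running `classify_cohort()` with a different
`threshold`.
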