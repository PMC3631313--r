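---
title: "Methods: case-control driver burden testing and methylation consensus clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control driver burden testing and methylation consensus clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glioburden)
```

## The problem

Tumour exome cohorts often lack matched normal DNA, so somatic mutations
cannot be called by tumour-normal subtraction. `glioburden` implements the
standard workaround for driver discovery in that setting: treat *private*
variants — absent from population databases (1000 Genomes, NHLBI exomes) and
from a large panel of control exomes — as candidate somatic mutations, and
ask, gene by gene, whether tumours carry them more often than controls do.
Because the control panel is sequenced and annotated through the same
pipeline, this case–control comparison implicitly corrects for gene length,
local mutability and systematic calling artefacts, which is what makes the
simple 2×2 test defensible.

The package covers four analysis stages behind one pipeline surface:

1. **Variant filtering** (`filter_cohort`): private → predicted damaging →
   optionally truncating-only.
2. **Gene burden scan** (`run_burden_scan`): per-gene carrier 2×2 tables,
   exact testing, Benjamini–Hochberg FDR.
3. **Cohort association** (`frequency_table`, `grade_association`,
   `location_association`, `mutual_exclusivity`): stratified frequency
   reporting and contingency tests on clinical metadata.
4. **Methylation consensus clustering** (`filter_probes`,
   `select_top_variable`, `consensus_kmeans`, `cdf_delta_area`) and
   **histone-mark quantification** (`normalized_ratios`, `compare_groups`)
   for the downstream epigenomic characterisation of the discovered driver.

## Filtering rules and their reading

A variant is **private** iff both database flags are false; membership in
either a population database *or* any control exome disqualifies it.

The **damaging filter** removes variants called non-damaging by *both*
missense predictors: a missense variant is kept if SIFT says damaging *or*
PolyPhen-2 says damaging, and removed only when SIFT ∈ {tolerated, unknown}
*and* PolyPhen-2 ∈ {benign, unknown}. Two deliberate choices:

* **Truncating variants bypass the predictors.** SIFT and PolyPhen-2 score
  amino-acid substitutions; they cannot rate frameshifts, nonsense or
  splice-site changes, which are presumed function-abolishing. A filter that
  consulted them would silently discard exactly the variants with the
  clearest effect.
* **Conservation is a flag, not a filter** (default). Highly conserved
  residue status is carried through to output for prioritisation, and a
  `require_conserved` switch makes it a hard requirement for missense
  variants when an analyst wants the stricter behaviour. The default is off
  because conservation annotations are frequently missing and a hard filter
  would conflate "not conserved" with "not annotated".

Every input variant receives a trace recording the *first* rule it failed,
in the fixed order `population_db → control_exomes → not_damaging →
not_truncating`, so dropped records are always accountable and
`|kept| + |failed| = |input|` holds by construction.

## The burden test

For gene $g$, let $a$ = tumour samples carrying ≥1 kept variant in $g$, $b$
= remaining tumours, $c, d$ likewise for controls. Counting **carriers**
rather than variants keeps the margins equal to the cohort sizes, so the
hypergeometric null is exact; a variant-level Poisson comparison would need
an overdispersion model and is out of scope.

`fisher_exact_two_sided` enumerates the hypergeometric support of $a$
directly and sums the point probabilities of all tables at the fixed margins
whose probability does not exceed the observed table's — the
minimum-likelihood two-sided definition used by mainstream statistical
software. A relative slack of $10^{-7}$ guards against floating-point ties
splitting equal-probability tables. Degenerate margins (an empty carrier
column) admit one table and give $p = 1$. The implementation is checked in
the test suite against an independent log-factorial enumeration oracle on
*every* 2×2 table with total ≤ 30, and against `stats::fisher.test` on
random larger tables. A one-sided (`greater`) alternative is available
behind a flag; two-sided is the default because the scan should also flag
genes significantly *depleted* in tumours as anomalies.

**FDR.** `bh_fdr` applies the step-up rule
$q_{(i)} = \min_{j \ge i} p_{(j)} \, m / j$ (clipped to 1). The universe
size $m$ defaults to the number of genes with at least one kept variant in
either arm — the only universe observable from the data — and can be set
larger when the scan is conceptually genome-wide. Reported q-values
therefore depend on $m$, and the package makes that dependence explicit
rather than hiding a default exome size.

## Association statistics

All contingency tests — grade (high = III+IV vs low = II), brain location
(hemispheric vs rest), and pairwise gene mutual exclusivity — delegate to
the single `fisher_exact_two_sided` code path, so one oracle validates them
all. Samples with `unknown` mutation status are dropped per test (numerator
and denominator), reflecting that assay coverage varies by sample; nothing
is imputed. Mutual-exclusivity direction is called from the sign of the
observed minus expected double-mutant count under independence at the
observed margins. The pediatric/adult boundary is a metadata field supplied
by the analyst, not an age cutoff applied by code: cohorts differ in where
they draw it, and the packaged reference fixture encodes its source cohort's
own assignment.

## Methylation consensus clustering

**Probe filtering** keeps a probe iff it is not cross-reactive, has no
binding-region SNP with minor allele frequency ≥ 2/120 (probes with no
catalogued SNP pass), and is autosomal. The rule is a predicate over the
supplied annotation table; the surviving count depends on the manifest and
SNP build, which are inputs, not package constants.

**Probe selection** ranks by across-sample standard deviation (denominator
$n-1$), ties broken lexicographically by probe id so runs are reproducible.
The default of 8,000 probes is the conventional scale for whole-array
clustering.

**Hierarchical view**: distance $1 - r$ (Pearson) with average linkage via
`stats::hclust`. Pearson distance is invariant to positive affine transforms
of a sample's profile, the right equivalence class for arrays with
per-sample intensity scaling.

**Consensus k-means** (`consensus_kmeans`): for each candidate $k$, $B$
rounds each draw `ceiling(0.8 n)` samples without replacement and run one
k-means (Euclidean on raw beta vectors — no M-value transform — k-means++
seeding, Lloyd capped at 100 iterations, one restart). The consensus entry
for a pair is co-clustering frequency among rounds sampling both. Choices
worth stating:

* *Item resampling at 0.8* is the canonical consensus-clustering default;
  it is exposed (`item_frac`) because the literature varies.
* *k-means++ seeding with a single restart per round* trades per-round
  optimality for round diversity: the resampling loop itself supplies the
  restarts.
* *Final labels* come from average-linkage clustering of `1 − consensus`
  cut at $k$, so labels reflect the stable structure rather than any single
  k-means run.
* A pair never co-sampled after $B$ rounds is an error advising a larger
  $B$, not a silent `NaN`.

**Model selection** (`cdf_delta_area`): the empirical CDF of the
upper-triangle consensus values is evaluated on a fixed 101-point grid and
integrated by trapezoid to give $A(k)$; $\Delta(k)$ is the relative
increase. The advisory `selected_k` stops when the relative gain falls
below 0.025. Two caveats are documented deliberately: the threshold is a
convention, and on *perfectly* separated data $A(k)$ keeps growing past the
true $k$ (over-split clusters still add zeros to the consensus), so
`selected_k` is advisory output — the per-k matrices, CDF curves and
delta-areas are the primary product, and decisions should be read off them.

A per-sample quantile-normalisation helper is included for betas that
arrive completely unnormalised. It is a generic distribution-matching step,
**not** the SWAN within-array method (which corrects Infinium type-I/II
probe chemistry and needs the array manifest); the pipeline expects
already-normalised betas.

## Histone-mark quantification

`normalized_ratios` divides the H3K36me3 band intensity by the total-H3
loading control within each blot, then averages each sample over the blots
it appears on: within-blot normalisation cancels exposure and loading,
cross-blot averaging shrinks measurement noise. `compare_groups` applies a
two-sided Welch t-test to the per-sample means. Welch is the default
because group variances have no reason to be equal when one group has lost
the mark; the pooled Student variant sits behind `var_equal = TRUE`. The
test is across samples (blots averaged first), not across blot replicates,
which would pseudo-replicate.

## Synthetic data: what it emulates, and what passing shows

`simulate_variant_cohort` emulates a 60-tumour / 543-control exome study.
`background_rate` is the expected number of *kept* (private, damaging)
variants per gene per sample; the generator inflates the raw Poisson rate by
the inverse keep probability so that database flagging (default 30%) and the
damaging filter (default: 5% of background variants truncating, 30% of
background missense predicted damaging) thin it back exactly. Those two
fractions are generator defaults chosen to give the filter non-degenerate
work to do; both are spec parameters. Injected drivers add an independent
Poisson stream of always-private, always-damaging variants in tumours only.

Two calibrations deserve an explicit rationale:

* **Driver recovery experiments use a 100× kept-rate multiplier** over the
  1e-3 background, i.e. an expected ~6 tumour carriers of 60 versus ~0.5
  control carriers of 543. That is the magnitude of a real discovery-scale
  driver signal in cohorts of this size (a handful of carriers against
  near-zero controls); a 10× driver over this background (~0.5 expected
  carriers) is statistically invisible to any method and would test nothing.
* **Densitometry noise is blot-dominated** (`blot_sd = 0.15`,
  `sample_sd = 0.05`), and the simulated mark loss is expressed in
  single-blot SD units. Averaging four blots is exactly the design that
  makes a 3-SD single-measurement effect detectable at $p < 0.001$ with six
  samples per group (effective standardised separation ≈ 5); if per-sample
  biological spread dominated instead, that detection claim would be
  unattainable at this sample size (power ≈ 0.70).

`simulate_beta_matrix` plants $k$ clusters as blocks of informative probes
shifted ±`shift` around 0.5, adds Gaussian noise and clips to
[0.001, 0.999]. It emulates the *cluster geometry* of methylation subgroups,
not real array features: no probe-type chemistry, no correlated CpG blocks,
no batch structure, no bimodal beta distributions. Consequently, passing the
recovery tests shows the consensus machinery is correct and stable — it does
not show that real tumour methylation subgroups are separable at any given
noise level.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run the burden operating
characteristics at 20 replicates (200-gene null scans; 100-gene driver
scans) and consensus recovery at 60 samples × 500 probes with $B = 250$
resampling rounds over 20 seeds — sizes chosen so the full suite documents
the methods' behaviour in minutes while keeping every Monte-Carlo fraction
at a resolution (1/20) coarser than the effects being demonstrated. All
generators take explicit integer seeds and are bit-reproducible; no global
RNG state leaks between calls. Betas outside [0, 1] and negative counts are
errors naming the offending probe/sample or file line — never clipped or
coerced — because silent repair of impossible values hides upstream bugs.

## Known limitations

* Carrier-level testing cannot see allelic series within a sample, and the
  2×2 test conditions on cohort sizes; covariate adjustment (ancestry,
  coverage) is out of scope.
* Genome-wide q-values depend on the supplied universe size $m$; comparing
  q-values across runs requires fixing $m$.
* The consensus loop is $O(B \cdot \text{kmeans})$ per $k$ and is written
  for cohort-scale sample counts (tens to a few hundred), not single-cell
  scale.
* Annotation quality bounds everything upstream: the package consumes
  consequence classes and predictor calls as given and never re-derives
  them.
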