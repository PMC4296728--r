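---
title: "Case-control beta-diversity testing: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control beta-diversity testing: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microbiomeCC)
```

## The scientific question

Does a binary exposure recorded decades earlier — delivery by cesarean
section, or removal of the appendix — leave a detectable imprint on the
composition of the adult fecal microbiome? The package frames this as a
case-control problem on a rarefied 16S OTU table: within-sample (alpha)
diversity is compared between groups, between-sample (beta) diversity is
tested for case-group clustering, and individual taxa are screened for
abundance differences with covariate adjustment.

## Divergence model

For $K$ taxa at a given taxonomic level, let
$P^i = (p^i_1, \dots, p^i_K)$ be the relative abundances of sample $i$.
The Kullback-Leibler divergence of $j$ from $i$ is

$$D_{KL}(P^i \,\|\, P^j) = \sum_{k:\,p^i_k > 0} p^i_k
  \log\!\frac{p^i_k}{p^j_k},$$

with $0 \log(0/q) = 0$. Because $D_{KL}$ is asymmetric and infinite when
supports disagree, pairwise distances use the Jensen-Shannon divergence

$$JSD(P^i, P^j) = \tfrac12 D_{KL}(P^i \| Q_{ij}) +
  \tfrac12 D_{KL}(P^j \| Q_{ij}), \qquad Q_{ij} = \tfrac{P^i + P^j}{2},$$

which is symmetric, finite, zero iff $P^i = P^j$, and bounded by
$\log 2$. All entropies and divergences are in nats by default; every
function takes a `base` argument (base 2 reproduces the bit-scaled
convention of older 16S pipelines), and the $\log 2$ bound scales
accordingly.

`js_divergence()` implements the two-term K-L definition literally.
`divergence_matrix()` instead vectorises the algebraically identical
entropy form $JSD = H(Q_{ij}) - \tfrac12\{H(P^i) + H(P^j)\}$ over all
pairs; the test suite checks the two routes against each other to
$10^{-10}$, and clamps nothing beyond floating-point fuzz (negative
round-off is truncated at 0, the bound at $\log 2$).

## The permutation test and its statistic

The clustering test asks whether cases are more mutually similar than a
random subset of the cohort of the same size. The published description of
this family of analyses names only "average J-S divergence", which leaves
the test statistic underdetermined. This is the largest interpretive
decision in the package and is exposed rather than hidden:

* **Primary statistic** (`statistic = "within"`): the mean pairwise JSD
  among case samples. Small values mean a tight case group.
* **Alternative** (`statistic = "within_minus_between"`): the within-case
  mean minus the case-to-control mean, for users who prefer a contrast
  centred near zero under the null.

The null distribution permutes the case labels over all samples `B` times
(default 10,000) and the one-sided p-value for tighter clustering applies
the add-one correction $p = (1 + \#\{S_b \le S_{obs}\})/(1 + B)$, which
can never report zero. One-sided "cases cluster more tightly" is the
default direction because that is how significance is interpreted
scientifically; a two-sided option reports $\min(2\min(p_\le, p_\ge), 1)$.
Note that the two-sided p-value is not exactly invariant to swapping which
group is called "case": the within-group mean of the complement is a
different statistic, so the two tails are not mirror images. For small
cohorts `exact = TRUE` enumerates all $\binom{n}{m}$ label arrangements
(capped at $2 \times 10^5$) and returns the exact proportion at or below
the observed value.

## Community clusters

Samples are clustered agglomeratively on the JSD matrix and cut to `K`
groups (default `K = 4`, mirroring the community-state-type convention
for this analysis family; fully configurable). Average linkage on raw JSD
is the default; `method = "ward"` applies Ward's criterion to
$\sqrt{JSD}$, which is a metric while JSD itself is not. Agglomeration and
its tie-breaking are delegated to `stats::hclust`, whose behaviour is
deterministic for a fixed matrix; no custom tie-break rule is layered on
top. Cluster-phenotype association uses the Pearson chi-square test on
the $K \times 2$ count table without continuity correction
($df = K - 1$).

## Alpha diversity

Five estimators per sample, at the finest level of the supplied table:
observed richness; Shannon entropy (nats); bias-corrected Chao1
$S_{obs} + F_1(F_1 - 1)/\{2(F_2 + 1)\}$, chosen over the classical form
because it stays finite when no doubletons are observed and requires
integer counts (it is refused on proportions); inverse Simpson
$1/\sum p_k^2$; and Faith's phylogenetic diversity in the root-inclusive
"whole tree" variant — the total branch length of the minimal subtree
spanning the root and all observed taxa. The PD traversal is implemented
directly (a single post-order pass) so that missing-taxon errors and root
handling are explicit; the test suite cross-checks it against both an
exhaustive path-enumeration oracle and `picante::pd(include.root = TRUE)`.

## Exclusion filters

`apply_exclusions()` applies, in a fixed order: age below 4 years, missing
sex, missing race, non-fecal specimen, antibiotic use within the past
month, diabetes, inflammatory bowel disease, then duplicate samples per
participant (keeping the lexicographically first sample id). Published
attrition tables for cohorts of this kind often report overlapping
per-filter counts whose sum does not match the total removed; for
reproducibility this package instead attributes each sample to the first
filter it violates, so the attrition column always sums exactly.
`case_subset()` then drops samples whose case field is missing or
uncertain, since self-reported early-life history is kept only when
definite.

## The taxon screen

Each taxon in the pooled phylum-through-species testing set (each
collapsed level contributes its lineages once) is tested by logistic
regression of case status on its relative abundance plus age, sex and
race, with the Wald p-value of the abundance coefficient as the primary
result and Benjamini-Hochberg q-values across the full set. Abundances
enter untransformed by default — matching the plain-regression convention
of the source analyses — with an arcsine-square-root option
(`transform = "arcsinsqrt"`) for users who want variance stabilisation.
Zero-variance taxa are skipped and excluded from the FDR denominator.
Covariate associations for cohort-description tables use one unadjusted
model per variable (`covariate_logistic()`), because that is how such
tables are conventionally presented; quasi-separated levels (empty cells
produce coefficients near $\pm 14$ with standard errors in the hundreds)
are flagged rather than dropped.

## What the simulator emulates — and what it does not

`simulate_dataset()` draws a Dirichlet-multinomial community:
sample $i$'s composition is
$P^i \sim \mathrm{Dirichlet}(\theta w)$ and counts are multinomial at
exactly `depth` reads (default 10,000, the conventional rarefaction
depth). Defaults were fixed once, on these grounds:

* **Baseline weights** $w_k \propto 1/k$, a power-law with a few dominant
  and many rare taxa, as in real stool profiles; **total concentration**
  $\theta = 50$, giving the strong overdispersion of 16S data (many rare
  taxa have per-taxon concentration well below 1 and are absent from many
  samples).
* **Effects** multiply the Dirichlet concentrations of a ground-truth
  affected subset (`effect_taxa_fraction`, default 10%) by `effect_size`
  in cases, so compositional renormalisation is handled inside the model
  rather than patched on afterwards. `effect_size = 1` is an exact null:
  the two groups are exchangeable.
* **Confounding**: case status must both hit the exact configured group
  sizes and follow a logistic model in age. Both hold simultaneously via
  the normal-discriminant duality: ages are $N(46, 16)$ for controls and
  $N(46 + \beta \sigma^2, 16)$ for cases, which induces exactly
  $\mathrm{logit}\, P(\text{case} \mid \text{age}) = \alpha + \beta \,
  \text{age}$ with $\beta =$ `age_effect` (default $-0.04$ per year:
  cases about ten years younger, the direction seen for cesarean birth in
  adult volunteers). Ages are truncated at 18 so the default cohort is
  adult.
* **Metadata categories** (race 5 levels, region 8, diet 5, alcohol 5,
  smoking 3, antibiotic recency 3, weight change 3, plus binary
  gluten/lactose/asthma) are drawn with the frequencies of a large US
  adult volunteer cohort, so the cleaning and covariate stages run on
  synthetic data unmodified.
* **Trees** (`simulate_tree()`) have random binary topology with
  exponential branch lengths; any positive-branch-length rooted tree
  exercises the PD code, and no attempt is made to make the topology
  mirror the simulated taxonomy.

Passing tests on this generator therefore demonstrates calibration and
power under compositional overdispersed sampling with age confounding.
They do **not** demonstrate robustness to features the generator omits:
phylogenetic correlation between taxon abundances, covariates that
actually influence composition (only age-case coupling is modelled),
twin/household dependence between samples, spatial or temporal structure,
or taxonomic misassignment.

## Numerical and degenerate-input conventions

* $0 \log 0 = 0$ throughout; K-L returns `Inf` on support violations;
  JSD never does.
* Relative-mode rows must sum to 1 within $10^{-9}$; collapse conserves
  row totals to $10^{-12}$ and is idempotent.
* All-zero samples are an error (they have no composition), as are
  all-case or all-control label vectors and `K` outside $[1, n]$.
* Every stochastic function takes or consumes an explicit seed; a fixed
  seed fixes all emitted artifacts bit-for-bit, including on-disk output
  (`run_pipeline()` run twice with one seed produces byte-identical
  directories).

## Validation problem sizes

The shipped test and acceptance suites validate at sizes chosen to make
Monte-Carlo error small while keeping a laptop run short: type-I error of
the permutation test over 500 null replicates (n = 20 + 20, B = 199,
genus level), power over 100 replicates of a four-fold shift on 10% of
taxa (n = 100 + 100), BH-FDR control over 500 null screens, JSD
invariants over 10,000 random Dirichlet pairs, and exact-enumeration
agreement at n = 6. Marginal-abundance convergence is checked at 2,000
samples within three Monte-Carlo standard errors.

## Known limitations

* The permutation statistic is an interpretive choice (see above); with
  heavily imbalanced groups the within-case mean statistic has modest
  power and the `within_minus_between` contrast may behave better.
* Wald p-values for very rare taxa at moderate n rely on asymptotics;
  under the null simulator they are calibrated at the sizes tested, but
  taxa observed in only a handful of samples have little power and can
  dominate neither the screen nor the FDR set.
* The chi-square cluster test uses the asymptotic reference distribution;
  with small clusters an exact test on the $K \times 2$ table is the
  usual fallback and is not built in.
* Alpha-diversity group comparisons are exposed through the covariate
  regression machinery rather than asserted against any external
  reference values.

## A minimal session

```{r example, eval = FALSE}
sim <- simulate_dataset(sim_config(n_cases = 20, n_controls = 20,
                                   n_taxa = 60, effect_size = 3, seed = 7))
tree <- simulate_tree(sim$table$taxon_ids, seed = 2)
fit <- cc_divergence_analysis(sim$table, sim$metadata,
                              case_field = "cesarean", tree = tree,
                              B = 499, seed = 3)
print(fit)
summary(fit)
plot(fit)
```
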