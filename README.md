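# microbiomeCC

Case-control association analysis of fecal 16S microbiome profiles.

Epidemiological microbiome studies routinely ask whether a binary
phenotype — here, history of cesarean birth or appendectomy in adult
volunteers — is associated with the composition of the gut microbial
community. This package implements that workflow end to end for anyone
holding a classic OTU table (greengenes-style lineage strings, samples
rarefied to a fixed read depth) and a sample metadata sheet:

* **Table handling** — classic OTU-TSV reader/writer, lineage parsing,
  collapse to any taxonomic level from phylum to species, pooling of
  levels into a single testing set.
* **Exclusion filters** — the standard cohort cleaning sequence (age,
  missing sex/race, non-fecal specimens, recent antibiotics, diabetes,
  IBD, duplicate participants) with an exact attrition report.
* **Alpha diversity** — richness, Shannon, bias-corrected Chao1, inverse
  Simpson, and Faith's root-inclusive phylogenetic diversity from a
  newick tree.
* **Beta diversity** — Jensen-Shannon divergence matrices; for sample
  pair (i, j) with compositions `P_i`, `P_j` and midpoint
  `Q = (P_i + P_j)/2`,

  `JSD(P_i, P_j) = [ D_KL(P_i || Q) + D_KL(P_j || Q) ] / 2`,

  bounded by `log 2` (nats). Case-group clustering is tested by permuting
  case labels and comparing the observed mean within-case divergence to
  its permutation null (add-one corrected, one-sided by default, exact
  enumeration available at small n).
* **Community clusters** — hierarchical clustering of the JSD matrix
  (average linkage by default, Ward on the square root as an option),
  cut to K clusters and tested against case status by Pearson chi-square.
* **Taxon screen** — per-taxon logistic regression of case status on
  relative abundance adjusted for age, sex and race; Wald p-values and
  Benjamini-Hochberg q-values, plus group means and differences.
* **Simulator** — a Dirichlet-multinomial case-control community
  generator (fixed depth, power-law baseline, concentration-multiplied
  effects, age-confounded case status) used by the test suite to verify
  calibration and power without any external data.

## Worked example

```r
library(microbiomeCC)

sim  <- simulate_dataset(sim_config(n_cases = 20, n_controls = 20,
                                    n_taxa = 60, effect_size = 3, seed = 7))
tree <- simulate_tree(sim$table$taxon_ids, seed = 2)
fit  <- cc_divergence_analysis(sim$table, sim$metadata,
                               case_field = "cesarean", tree = tree,
                               B = 499, seed = 3)
print(fit)
```

```
Case-control microbiome divergence analysis (cesarean)
  20 cases, 20 controls after exclusions
  clustering permutation tests (B = 499, one-sided):
    phylum   p = 0.002
    class    p = 0.002
    order    p = 0.002
    family   p = 0.002
    genus    p = 0.002
    species  p = 0.002
  4 clusters at genus level: chi-square p = 7.017e-06
  taxon screen: 53 of 167 taxa with Wald p < 0.05 (min q = 0.079)
```

With a three-fold concentration shift on 10% of taxa, the case group is
significantly clustered at every taxonomic level: p = 0.002 is the
smallest value a one-sided permutation p with B = 499 and the add-one
correction can take, i.e. no permuted labelling produced a within-case
mean divergence as small as the observed one. The genus-level dendrogram
cut at K = 4 concentrates 19 of 20 cases in one cluster (chi-square
p = 7.0e-06), and 53 of the 167 pooled phylum-to-species taxa reach
nominal Wald significance, led by the lineages the simulation actually
shifted — though none survives FDR at 0.05 in a cohort this small
(min q = 0.079), the expected behaviour for n = 40.

`summary(fit)` prints the attrition report, the per-level permutation
table, the K x 2 cluster-by-case table and the top taxa;
`plot(fit)` draws the dendrogram; `run_pipeline()` writes every table
(attrition, alpha diversity, per-level JSD matrices, covariate
regressions, clustering tests, taxon associations, newick dendrogram and
a JSON manifest) to a run directory, byte-identically for a fixed seed.
A thin command-line wrapper with `simulate`, `analyze` and `report`
subcommands ships in `inst/cli/microbiome-cc`.

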