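Package: microbiomeCC
Title: Case-Control Analysis of Fecal Microbiome Composition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control association analysis of 16S fecal
    microbiome profiles: reading and collapsing classic OTU tables with
    greengenes-style lineage strings, alpha-diversity estimators (richness,
    Shannon, Chao1, inverse Simpson, Faith's phylogenetic diversity),
    Jensen-Shannon divergence beta diversity with permutation tests for
    case-group clustering, hierarchical community clusters with contingency
    tests, covariate logistic regressions, and covariate-adjusted per-taxon
    Wald screening with false discovery rate control. Includes a
    Dirichlet-multinomial simulator of case-control communities with
    age-confounded case status for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    picante,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
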