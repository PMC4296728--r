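# shared fixture builders

# tiny counts table with a two-phylum, nested lineage structure
toy_table <- function() {
  vals <- matrix(c(5000, 5000, 0, 0,
                   1, 2, 3, 9994,
                   2500, 2500, 2500, 2500), nrow = 3, byrow = TRUE,
                 dimnames = list(c("S1", "S2", "S3"),
                                 c("t1", "t2", "t3", "t4")))
  lin <- c("k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae;g__Roseburia;s__sp1",
           "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Lachnospiraceae;g__;s__",
           "k__Bacteria;p__Firmicutes;c__Clostridia;o__Clostridiales;f__Ruminococcaceae;g__Faecalibacterium;s__prausnitzii",
           "k__Bacteria;p__Bacteroidetes;c__Bacteroidia;o__Bacteroidales;f__Prevotellaceae;g__Prevotella;s__copri")
  taxon_table(vals, lineages = lin, mode = "counts")
}

# metadata frame passing every exclusion filter
clean_metadata <- function(ids, subject = ids) {
  data.frame(SAMPLE_ID = ids, HOST_SUBJECT_ID = subject, AGE = 40,
             SEX = "female", RACE = "Caucasian", BODY_SITE = "feces",
             ANTIBIOTIC_SELECT = "Not in the last year", DIABETES = "no",
             IBD = "no", CSECTION = "no", APPENDIX_REMOVED = "no",
             stringsAsFactors = FALSE)
}

# random Dirichlet compositions
rdirich <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  sweep(g, 1, rowSums(g), "/")
}
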