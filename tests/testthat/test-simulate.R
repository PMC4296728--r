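test_that("config validation rejects impossible parameters", {
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(n_cases = 1, n_controls = 2), ">= 4")
  expect_error(sim_config(effect_taxa_fraction = 1.2), "fraction")
  expect_error(sim_config(base_concentration = -1), "positive")
  expect_error(sim_config(effect_size = 0.5), "effect_size")
})

test_that("every sample's counts sum to the configured depth", {
  sim <- simulate_dataset(sim_config(n_cases = 10, n_controls = 10,
                                     n_taxa = 30, depth = 10000, seed = 4))
  expect_true(all(rowSums(sim$table$values) == 10000))
  expect_identical(sim$table$mode, "counts")
  expect_equal(nrow(sim$table$values), 20L)
})

test_that("a fixed seed fixes every emitted artifact bit-for-bit", {
  cfg <- sim_config(n_cases = 8, n_controls = 8, n_taxa = 25, seed = 99)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$table$values, b$table$values)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$affected, b$affected)
  c <- simulate_dataset(sim_config(n_cases = 8, n_controls = 8,
                                   n_taxa = 25, seed = 100))
  expect_false(identical(a$table$values, c$table$values))
})

test_that("lineages are well-formed seven-rank greengenes paths", {
  sim <- simulate_dataset(sim_config(n_cases = 5, n_controls = 5,
                                     n_taxa = 200, seed = 2))
  ranks <- lapply(sim$lineages, parse_lineage)
  expect_true(all(vapply(ranks, function(r) !anyNA(r), logical(1))))
  expect_true(all(grepl("^k__Bacteria;p__", sim$lineages)))
  expect_true(any(vapply(ranks, function(r) r[["species"]] == "", logical(1))))
})

test_that("metadata carries the cohort variables with declared vocabularies", {
  sim <- simulate_dataset(sim_config(n_cases = 30, n_controls = 30, seed = 5))
  md <- sim$metadata
  expect_setequal(unique(md$CSECTION), c("yes", "no"))
  expect_equal(sum(md$CSECTION == "yes"), 30)
  expect_true(all(md$RACE %in% c("Caucasian", "African American", "Hispanic",
                                 "Asian or Pacific Islander", "Other")))
  expect_equal(length(unique(md$SAMPLE_ID)), 60L)
  expect_true(all(c("AGE", "SEX", "BMI", "REGION", "DIET_TYPE",
                    "ALCOHOL_FREQUENCY", "SMOKING_FREQUENCY",
                    "ANTIBIOTIC_SELECT", "WEIGHT_CHANGE", "GLUTEN",
                    "LACTOSE", "ASTHMA", "APPENDIX_REMOVED") %in% names(md)))
})

test_that("null construction is exchangeable: within- and between-group JSD agree", {
  sim <- simulate_dataset(sim_config(n_cases = 60, n_controls = 60,
                                     n_taxa = 40, effect_size = 1,
                                     age_effect = 0, seed = 11))
  d <- divergence_matrix(to_relative(sim$table))
  is_case <- sim$metadata$CSECTION == "yes"
  i <- which(is_case); j <- which(!is_case)
  within <- mean(d[i, i][upper.tri(d[i, i])])
  between <- mean(d[i, j])
  # equal in expectation; allow Monte-Carlo slack relative to the JSD scale
  expect_lt(abs(within - between) / between, 0.05)
  expect_length(sim$affected, 4L)  # affected set reported even under the null
})

test_that("affected taxa dominate the smallest Wald p-values under a strong effect", {
  sim <- simulate_dataset(sim_config(n_cases = 100, n_controls = 100,
                                     n_taxa = 100, effect_size = 4,
                                     effect_taxa_fraction = 0.1, seed = 21))
  md <- case_subset(sim$metadata, "cesarean")
  tw <- taxon_wald_tests(to_relative(sim$table), md)
  rk <- rank(tw$wald_p)
  aff <- tw$taxon_id %in% sim$affected
  expect_lt(median(rk[aff]), median(rk[!aff]))
  expect_lt(median(rk[aff]), 0.15 * length(rk))
})

test_that("marginal abundances converge to normalised base concentrations", {
  cfg <- sim_config(n_cases = 1000, n_controls = 1000, n_taxa = 20,
                    effect_size = 1, seed = 31)
  sim <- simulate_dataset(cfg)
  props <- sweep(sim$table$values, 1, rowSums(sim$table$values), "/")
  expected <- cfg$base_concentration / sum(cfg$base_concentration)
  mc_se <- apply(props, 2, stats::sd) / sqrt(nrow(props))
  expect_true(all(abs(colMeans(props) - expected) <= 3 * mc_se + 1e-12))
})

test_that("age-case link follows the configured logistic slope", {
  b <- 0.05
  sim <- simulate_dataset(sim_config(n_cases = 1000, n_controls = 1000,
                                     n_taxa = 10, age_effect = b, seed = 41))
  md <- case_subset(sim$metadata, "cesarean")
  fit <- covariate_logistic(md, "AGE")
  expect_lt(abs(fit$estimate - b), 3 * fit$std_error)
  expect_lt(fit$p_value, 0.001)
})

test_that("simulated trees are rooted, complete and deterministic", {
  taxa <- sprintf("OTU_%03d", 1:50)
  tr <- simulate_tree(taxa, seed = 7)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, taxa)
  expect_true(all(tr$edge.length > 0))
  expect_true(ape::is.rooted(tr))
  expect_identical(ape::write.tree(simulate_tree(taxa, seed = 7)),
                   ape::write.tree(tr))
  expect_false(identical(ape::write.tree(simulate_tree(taxa, seed = 8)),
                         ape::write.tree(tr)))
  tr2 <- simulate_tree(c("a", "b"), seed = 1)
  expect_equal(length(tr2$tip.label), 2L)
  expect_gt(sum(tr2$edge.length), 0)
  expect_error(simulate_tree(c("a", "a"), seed = 1), "duplicate")
  expect_error(simulate_tree("a", seed = 1), "at least 2")
})
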