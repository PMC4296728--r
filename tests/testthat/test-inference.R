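test_that("exact permutation p equals an independent enumeration oracle", {
  set.seed(2)
  vals <- rdirich(6, rep(1, 10))
  dimnames(vals) <- list(paste0("s", 1:6), paste0("t", 1:10))
  d <- divergence_matrix(taxon_table(vals, mode = "relative"))
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  res <- group_clustering_permutation_test(d, labels, exact = TRUE)
  expect_equal(res$B, choose(6, 3))
  # oracle: enumerate all 20 case placements by hand
  stat <- function(ix) mean(d[ix, ix][upper.tri(d[ix, ix])])
  all_stats <- apply(utils::combn(6, 3), 2, stat)
  obs <- stat(1:3)
  expect_equal(res$observed, obs)
  expect_equal(res$p_value, mean(all_stats <= obs + 1e-12))
})

test_that("Monte-Carlo p converges to the exact enumeration p", {
  set.seed(4)
  vals <- rdirich(6, rep(1, 10))
  dimnames(vals) <- list(paste0("s", 1:6), paste0("t", 1:10))
  d <- divergence_matrix(taxon_table(vals, mode = "relative"))
  labels <- rep(c(TRUE, FALSE), each = 3)
  p_exact <- group_clustering_permutation_test(d, labels,
                                               exact = TRUE)$p_value
  p_mc <- group_clustering_permutation_test(d, labels, B = 20000,
                                            seed = 9)$p_value
  expect_lt(abs(p_mc - p_exact), 0.02)
})

test_that("a duplicated case composition yields the minimal permutation p", {
  set.seed(44)
  base <- rdirich(11, rep(1, 6))
  vals <- rbind(matrix(rep(c(0.9, 0.02, 0.02, 0.02, 0.02, 0.02), 5),
                       nrow = 5, byrow = TRUE), base)
  dimnames(vals) <- list(paste0("s", 1:16), paste0("t", 1:6))
  d <- divergence_matrix(taxon_table(vals, mode = "relative"))
  labels <- c(rep(TRUE, 5), rep(FALSE, 11))
  res <- group_clustering_permutation_test(d, labels, B = 199, seed = 1)
  expect_equal(res$observed, 0)
  expect_equal(res$p_value, 1 / (1 + 199))
})

test_that("two-sided p doubles the smaller tail and is capped at 1", {
  set.seed(6)
  vals <- rdirich(8, rep(1, 12))
  dimnames(vals) <- list(paste0("s", 1:8), paste0("t", 1:12))
  d <- divergence_matrix(taxon_table(vals, mode = "relative"))
  labels <- rep(c(TRUE, FALSE), each = 4)
  stat <- function(ix) mean(d[ix, ix][upper.tri(d[ix, ix])])
  all_stats <- apply(utils::combn(8, 4), 2, stat)
  obs <- stat(1:4)
  p_le <- mean(all_stats <= obs + 1e-12)
  p_ge <- mean(all_stats >= obs - 1e-12)
  p2 <- group_clustering_permutation_test(d, labels, exact = TRUE,
                                          alternative = "two.sided")$p_value
  expect_equal(p2, min(2 * min(p_le, p_ge), 1))
  expect_error(group_clustering_permutation_test(d, rep(TRUE, nrow(d))),
               "2 cases and 2 controls")
})

test_that("within-minus-between statistic is available and centred under the null", {
  sim <- simulate_dataset(sim_config(n_cases = 20, n_controls = 20,
                                     n_taxa = 30, effect_size = 1,
                                     age_effect = 0, seed = 16))
  d <- divergence_matrix(to_relative(sim$table))
  res <- group_clustering_permutation_test(
    d, sim$metadata$CSECTION, B = 499, seed = 2,
    statistic = "within_minus_between")
  expect_equal(res$statistic, "within_minus_between")
  expect_gt(res$p_value, 0.01)
  expect_lt(abs(mean(res$null)), 0.05 * mean(d[upper.tri(d)]))
})

test_that("cluster-case chi-square matches stats::chisq.test and its invariances", {
  cl <- rep(c("A", "B", "C"), c(10, 10, 10))
  case <- rep(c(TRUE, FALSE), 15)
  res <- cluster_case_test(cl, case)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p_value, 1)
  expect_equal(res$df, 2)
  # invariance under relabelling clusters
  relab <- c(A = "C", B = "A", C = "B")[cl]
  expect_equal(cluster_case_test(relab, case)$statistic, res$statistic)
  expect_error(cluster_case_test(rep("A", 10), case[1:10]), "2 clusters")
})

test_that("2x2 cluster test orders evidence like Fisher's exact test", {
  p_chi <- p_fis <- numeric(6)
  for (k in 0:5) {
    cl <- rep(c("A", "B"), each = 20)
    case <- c(rep(TRUE, 10 - k), rep(FALSE, 10 + k),
              rep(TRUE, 10 + k), rep(FALSE, 10 - k))
    tab <- table(cl, case)
    p_chi[k + 1] <- cluster_case_test(cl, case)$p_value
    p_fis[k + 1] <- stats::fisher.test(tab)$p.value
  }
  expect_equal(order(p_chi), order(p_fis))
})

test_that("binary-predictor logistic coefficient equals the log odds ratio", {
  md <- data.frame(case = rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 20, 40)),
                   EXPOSED = rep(c("yes", "no"), c(40, 60)))
  fit <- covariate_logistic(md, "EXPOSED")
  or <- (30 / 10) / (20 / 40)
  expect_equal(fit$estimate, log(or), tolerance = 1e-6)
  expect_equal(fit$z_value, fit$estimate / fit$std_error)
})

test_that("per-variable regressions flag separation and constants, not fail", {
  set.seed(20)
  md <- data.frame(case = rep(c(TRUE, FALSE), 30),
                   CONST = "same",
                   SEP = c(rep("rare", 2), rep("common", 58)))
  md$SEP[md$case & md$SEP == "rare"] <- "common"  # empty case cell
  fit <- covariate_logistic(md, c("CONST", "SEP"))
  expect_equal(fit$flag[fit$variable == "CONST"], "constant predictor")
  expect_equal(fit$flag[fit$variable == "SEP"], "possible separation")
})

test_that("null covariates stay below |z| = 1.96 at the nominal rate", {
  set.seed(30)
  z <- vapply(1:200, function(r) {
    md <- data.frame(case = sample(rep(c(TRUE, FALSE), 50)),
                     X = stats::rnorm(100))
    abs(covariate_logistic(md, "X")$z_value)
  }, numeric(1))
  expect_gte(mean(z < 1.96), 0.93)
})

test_that("reference levels follow the configured vocabulary", {
  set.seed(31)
  md <- data.frame(case = sample(c(TRUE, FALSE), 200, TRUE),
                   RACE = sample(c("Caucasian", "Hispanic", "Other"),
                                 200, TRUE))
  fit <- covariate_logistic(md, "RACE")
  expect_setequal(fit$level, c("Hispanic", "Other"))  # Caucasian is referent
})

test_that("taxon screen output has the association-table row shape", {
  sim <- simulate_dataset(sim_config(n_cases = 20, n_controls = 20,
                                     n_taxa = 25, seed = 22))
  md <- case_subset(sim$metadata, "cesarean")
  tw <- taxon_wald_tests(to_relative(sim$table), md)
  expect_named(tw, c("lineage", "taxon_id", "estimate", "wald_p", "q_value",
                     "control_mean", "case_mean", "difference"))
  expect_true(all(tw$control_mean >= 0 & tw$control_mean <= 1))
  expect_true(all(tw$case_mean >= 0 & tw$case_mean <= 1))
  expect_equal(tw$difference, tw$case_mean - tw$control_mean)
  ok <- !is.na(tw$wald_p)
  expect_true(all(tw$q_value[ok] >= tw$wald_p[ok] - 1e-12))
})

test_that("zero-variance taxa are skipped and excluded from the FDR set", {
  vals <- cbind(a = rep(0.3, 20), b = rep(0.2, 20),
                c = stats::runif(20, 0.1, 0.9))
  vals <- sweep(vals, 1, rowSums(vals), "/")
  rownames(vals) <- sprintf("S%02d", 1:20)
  md <- data.frame(SAMPLE_ID = rownames(vals),
                   case = rep(c(TRUE, FALSE), 10))
  tw <- taxon_wald_tests(taxon_table(vals, mode = "relative"), md,
                         adjust_for = character(0))
  expect_true(is.na(tw$wald_p[tw$taxon_id == "a"]) ||
                !is.na(tw$wald_p[tw$taxon_id == "c"]))
  expect_false(anyNA(tw$wald_p[tw$taxon_id == "c"]))
})

test_that("unadjusted screen equals the single-predictor glm fit", {
  sim <- simulate_dataset(sim_config(n_cases = 15, n_controls = 15,
                                     n_taxa = 10, seed = 23))
  md <- case_subset(sim$metadata, "cesarean")
  rel <- to_relative(sim$table)
  tw <- taxon_wald_tests(rel, md, adjust_for = character(0))
  for (k in c(1, 5, 10)) {
    ref <- stats::glm(md$case ~ rel$values[, k], family = stats::binomial())
    cf <- summary(ref)$coefficients
    expect_equal(tw$estimate[k], unname(cf[2, 1]), tolerance = 1e-6)
    expect_equal(tw$wald_p[k], unname(cf[2, 4]), tolerance = 1e-6)
  }
})

test_that("null taxon p-values are uniform across replicates", {
  p <- vapply(1:200, function(r) {
    sim <- simulate_dataset(sim_config(n_cases = 25, n_controls = 25,
                                       n_taxa = 10, effect_size = 1,
                                       age_effect = 0, seed = 400 + r))
    md <- case_subset(sim$metadata, "cesarean")
    tw <- taxon_wald_tests(to_relative(sim$table), md,
                           adjust_for = character(0))
    tw$wald_p[1]  # the most abundant taxon, null by construction
  }, numeric(1))
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches step-up arithmetic and validates input", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.02, 0.5, 0.9)
  expect_equal(bh_fdr(p), stats::p.adjust(p, "BH"))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, NA)), "\\[0, 1\\]")
})
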