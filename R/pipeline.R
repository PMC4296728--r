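#' Case-control divergence analysis of a microbiome cohort
#'
#' The package's main fitting function. Runs the full workflow on a counts
#' table and metadata pair: exclusion filters, case subsetting, per-sample
#' alpha diversity, Jensen-Shannon divergence matrices at each taxonomic
#' level with permutation tests for case-group clustering, hierarchical
#' community clusters with a cluster x case chi-square test, per-variable
#' covariate logistic regressions, and the covariate-adjusted per-taxon
#' Wald screen with FDR control over the pooled phylum-to-species set.
#'
#' @param table counts-mode [taxon_table()] at the OTU level.
#' @param metadata per-sample metadata data.frame (see
#'   [default_column_map()] for expected columns).
#' @param case_field `"cesarean"` or `"appendectomy"`.
#' @param tree optional rooted `ape::phylo` over the table's taxa for
#'   Faith's PD.
#' @param levels taxonomic levels analysed, default phylum through species.
#' @param B permutation count for the clustering tests.
#' @param K number of hierarchical clusters.
#' @param cluster_level level at which samples are clustered (genus by
#'   default).
#' @param linkage `"average"` or `"ward"` (see [hierarchical_clusters()]).
#' @param seed integer seed controlling the permutation draws.
#' @param log_base logarithm base for entropies and divergences.
#' @param two_sided report two-sided permutation p-values.
#' @param covariates variables entered in the per-variable logistic
#'   regressions (those present in the metadata are used).
#' @param adjust_for covariates adjusted for in the per-taxon screen.
#' @param column_map metadata column binding, see [default_column_map()].
#' @return Object of class `"cc_analysis"`; see [print.cc_analysis()] and
#'   [summary.cc_analysis()].
#' @export
cc_divergence_analysis <- function(table, metadata,
                                   case_field = c("cesarean", "appendectomy"),
                                   tree = NULL,
                                   levels = c("phylum", "class", "order",
                                              "family", "genus", "species"),
                                   B = 1000, K = 4, cluster_level = "genus",
                                   linkage = c("average", "ward"), seed = 1,
                                   log_base = exp(1), two_sided = FALSE,
                                   covariates = c("AGE", "BMI", "SEX",
                                                  "GLUTEN", "LACTOSE",
                                                  "ASTHMA", "RACE", "REGION",
                                                  "ANTIBIOTIC_SELECT",
                                                  "WEIGHT_CHANGE", "DIET_TYPE",
                                                  "ALCOHOL_FREQUENCY",
                                                  "SMOKING_FREQUENCY"),
                                   adjust_for = c("AGE", "SEX", "RACE"),
                                   column_map = default_column_map()) {
  case_field <- match.arg(case_field)
  linkage <- match.arg(linkage)
  set.seed(seed)

  cleaned <- apply_exclusions(metadata, table, column_map)
  md <- case_subset(cleaned$metadata, case_field, column_map)
  if (sum(md$case) < 2 || sum(!md$case) < 2)
    stop("fewer than 2 definite cases or controls after filtering")
  ids <- if (!is.null(md$SAMPLE_ID)) md$SAMPLE_ID else rownames(md)
  tab <- cleaned$table
  keep <- intersect(tab$sample_ids, ids)
  counts <- taxon_table(tab$values[keep, , drop = FALSE],
                        lineages = tab$lineages, mode = "counts")
  md <- md[match(keep, ids), , drop = FALSE]
  is_case <- md$case

  alpha <- alpha_diversity(counts, tree = tree, base = log_base)
  rel <- to_relative(counts)

  beta <- lapply(levels, function(lv) {
    d <- divergence_matrix(collapse_to_level(rel, lv), base = log_base)
    pt <- group_clustering_permutation_test(
      d, is_case, B = B,
      alternative = if (two_sided) "two.sided" else "less")
    list(level = lv, divergence = d, permutation = pt)
  })
  names(beta) <- levels
  beta_table <- data.frame(
    level = levels,
    observed = vapply(beta, function(b) b$permutation$observed, numeric(1)),
    p_value = vapply(beta, function(b) b$permutation$p_value, numeric(1)),
    row.names = NULL)

  cl_d <- if (cluster_level %in% levels) beta[[cluster_level]]$divergence
          else divergence_matrix(collapse_to_level(rel, cluster_level),
                                 base = log_base)
  clusters <- hierarchical_clusters(cl_d, K = K, method = linkage)
  cluster_test <- cluster_case_test(clusters, is_case)

  covariate_table <- covariate_logistic(md, intersect(covariates, names(md)))

  pooled <- to_relative(pool_levels(counts, levels))
  taxa <- taxon_wald_tests(pooled, md, adjust_for = adjust_for)

  structure(list(
    case_field = case_field, alpha = alpha, beta = beta,
    beta_table = beta_table, clusters = clusters,
    cluster_test = cluster_test, covariates = covariate_table,
    taxa = taxa, attrition = cleaned$attrition, metadata = md,
    n_cases = sum(is_case), n_controls = sum(!is_case),
    config = list(levels = levels, B = B, K = K,
                  cluster_level = cluster_level, linkage = linkage,
                  seed = seed, log_base = log_base, two_sided = two_sided,
                  adjust_for = adjust_for)),
    class = "cc_analysis")
}

#' @rdname cc_divergence_analysis
#' @param x,object a `cc_analysis` object.
#' @param ... unused.
#' @export
print.cc_analysis <- function(x, ...) {
  cat(sprintf("Case-control microbiome divergence analysis (%s)\n",
              x$case_field))
  cat(sprintf("  %d cases, %d controls after exclusions\n",
              x$n_cases, x$n_controls))
  cat(sprintf("  clustering permutation tests (B = %d, %s):\n",
              x$config$B, if (x$config$two_sided) "two-sided" else "one-sided"))
  for (i in seq_len(nrow(x$beta_table)))
    cat(sprintf("    %-8s p = %.4g\n", x$beta_table$level[i],
                x$beta_table$p_value[i]))
  cat(sprintf("  %d clusters at %s level: chi-square p = %.4g\n",
              x$config$K, x$config$cluster_level, x$cluster_test$p_value))
  nsig <- sum(x$taxa$wald_p < 0.05, na.rm = TRUE)
  cat(sprintf("  taxon screen: %d of %d taxa with Wald p < 0.05 (min q = %.3g)\n",
              nsig, sum(!is.na(x$taxa$wald_p)),
              suppressWarnings(min(x$taxa$q_value, na.rm = TRUE))))
  invisible(x)
}

#' @rdname cc_divergence_analysis
#' @export
summary.cc_analysis <- function(object, ...) {
  top <- object$taxa[!is.na(object$taxa$wald_p), ]
  top <- top[order(top$wald_p), ]
  out <- list(case_field = object$case_field,
              n_cases = object$n_cases, n_controls = object$n_controls,
              attrition = object$attrition,
              beta_table = object$beta_table,
              cluster_table = object$cluster_test$table,
              cluster_p = object$cluster_test$p_value,
              top_taxa = utils::head(top, 10))
  class(out) <- "summary.cc_analysis"
  out
}

#' @export
print.summary.cc_analysis <- function(x, ...) {
  cat(sprintf("Case field: %s (%d cases / %d controls)\n\nAttrition:\n",
              x$case_field, x$n_cases, x$n_controls))
  print(x$attrition, row.names = FALSE)
  cat("\nClustering permutation tests:\n")
  print(x$beta_table, row.names = FALSE)
  cat(sprintf("\nCluster x case table (chi-square p = %.4g):\n", x$cluster_p))
  print(x$cluster_table)
  cat("\nTop taxa by Wald p-value:\n")
  print(x$top_taxa[, c("lineage", "wald_p", "q_value", "control_mean",
                       "case_mean", "difference")], row.names = FALSE)
  invisible(x)
}

#' @rdname cc_divergence_analysis
#' @export
plot.cc_analysis <- function(x, ...) {
  plot(x$clusters$hclust,
       labels = FALSE, hang = -1,
       main = sprintf("J-S divergence dendrogram (%s level, %s linkage)",
                      x$config$cluster_level, x$config$linkage),
       xlab = "", sub = "", ...)
  invisible(x)
}

#' Run the full pipeline and write its artifact directory
#'
#' Thin orchestration over [cc_divergence_analysis()]: reads inputs if given
#' as paths, runs the analysis, and writes the attrition report, alpha
#' diversity table, per-level divergence matrices and dendrogram, the three
#' result tables (covariate regressions, per-level permutation tests,
#' per-taxon screen), the cluster x case table, and a JSON manifest
#' sufficient to re-run bit-identically.
#'
#' @param table a [taxon_table()] or path to a classic OTU TSV.
#' @param metadata data.frame or path to a metadata TSV.
#' @param out_dir output directory (created if needed).
#' @param tree optional `ape::phylo` or newick path.
#' @param ... further arguments to [cc_divergence_analysis()].
#' @return The `cc_analysis` object, invisibly; artifacts in `out_dir`.
#' @export
run_pipeline <- function(table, metadata, out_dir, tree = NULL, ...) {
  if (is.character(table)) table <- read_taxon_table(table)
  if (is.character(metadata))
    metadata <- utils::read.delim(metadata, stringsAsFactors = FALSE,
                                  check.names = FALSE)
  if (is.character(tree)) tree <- ape::read.tree(tree)
  fit <- cc_divergence_analysis(table, metadata, tree = tree, ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.table(
    df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  w(fit$attrition, "attrition.tsv")
  w(fit$alpha, "alpha_diversity.tsv")
  w(fit$covariates, "covariate_tests.tsv")
  w(fit$beta_table, "clustering_tests.tsv")
  taxa <- fit$taxa[order(fit$taxa$wald_p), ]
  w(taxa, "taxon_associations.tsv")
  for (lv in fit$config$levels)
    write_divergence_matrix(fit$beta[[lv]]$divergence,
                            file.path(out_dir, paste0("jsd_", lv, ".tsv")))
  write_dendrogram(fit$clusters, file.path(out_dir, "dendrogram.nwk"))
  ct <- as.data.frame(fit$cluster_test$table)
  ct <- cbind(cluster = rownames(fit$cluster_test$table),
              as.data.frame.matrix(fit$cluster_test$table))
  w(ct, "cluster_case_table.tsv")
  manifest <- c(fit$config,
                list(case_field = fit$case_field, n_cases = fit$n_cases,
                     n_controls = fit$n_controls,
                     cluster_chisq_p = fit$cluster_test$p_value))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fit)
}

#' Render a markdown report for a pipeline run directory
#'
#' @param run_dir directory produced by [run_pipeline()].
#' @param path optional output path; default `report.md` inside `run_dir`.
#' @return The report path, invisibly. If artifacts are missing the report
#'   lists them instead of failing.
#' @export
make_report <- function(run_dir, path = file.path(run_dir, "report.md")) {
  need <- c("manifest.json", "attrition.tsv", "clustering_tests.tsv",
            "cluster_case_table.tsv", "taxon_associations.tsv")
  have <- file.exists(file.path(run_dir, need))
  lines <- "# Case-control microbiome analysis report"
  if (!all(have)) {
    lines <- c(lines, "", "Incomplete run; missing artifacts:",
               paste0("- ", need[!have]))
    writeLines(lines, path)
    return(invisible(path))
  }
  man <- jsonlite::read_json(file.path(run_dir, "manifest.json"))
  rd <- function(f) utils::read.delim(file.path(run_dir, f),
                                      check.names = FALSE)
  att <- rd("attrition.tsv"); bt <- rd("clustering_tests.tsv")
  ct <- rd("cluster_case_table.tsv"); tx <- rd("taxon_associations.tsv")
  fmt_tab <- function(df) c(paste(names(df), collapse = " | "),
                            paste(rep("---", ncol(df)), collapse = " | "),
                            apply(df, 1, paste, collapse = " | "))
  prev <- sprintf("- cluster %s: %d of %d cases (%.0f%%)", ct$cluster,
                  ct$case, ct$case + ct$control,
                  100 * ct$case / (ct$case + ct$control))
  lines <- c(lines, "",
             sprintf("Case field: %s; %s cases, %s controls; seed %s; B = %s.",
                     man$case_field, man$n_cases, man$n_controls, man$seed,
                     man$B),
             "", "## Sample attrition", "", fmt_tab(att),
             "", "## Case-group clustering by taxonomic level", "",
             fmt_tab(bt),
             "", "## Community clusters", "",
             sprintf("Cluster x case chi-square p = %.4g; case prevalence:",
                     as.numeric(man$cluster_chisq_p)),
             prev,
             "", "## Top taxa", "",
             fmt_tab(utils::head(tx[, c("lineage", "wald_p", "q_value",
                                        "difference")], 10)))
  writeLines(lines, path)
  invisible(path)
}
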