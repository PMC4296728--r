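# mean pairwise divergence within the case set, or the within-minus-between
# contrast; matrix-block sums keep the permutation loop cheap
.clustering_stat <- function(d, is_case, type) {
  idx <- which(is_case)
  m <- length(idx)
  within <- sum(d[idx, idx]) / 2 / choose(m, 2)
  if (type == "within") return(within)
  between <- sum(d[idx, -idx, drop = FALSE]) / (m * (nrow(d) - m))
  within - between
}

#' Permutation test for case-group clustering on a divergence matrix
#'
#' Tests whether the case samples are more mutually similar (beta-diversity
#' "clustered") than random sets of the same size. The observed statistic is
#' the mean pairwise divergence among case samples (or, with
#' `statistic = "within_minus_between"`, the within-case mean minus the
#' case-control mean). The null distribution is built by permuting the case
#' labels over all samples `B` times; the one-sided p-value for tighter
#' clustering uses the add-one correction
#' `p = (1 + #(null <= observed)) / (1 + B)`. With `exact = TRUE` all
#' distinct label arrangements are enumerated instead and the p-value is the
#' exact proportion of arrangements at or below the observed statistic.
#'
#' @param d a [divergence_matrix()] (or symmetric numeric matrix).
#' @param labels logical case indicator, or a vector coercible to one
#'   (`"yes"`/`"no"` or `TRUE`/`FALSE`), aligned with the rows of `d`.
#' @param B number of label permutations (`>= 99`).
#' @param statistic `"within"` (default) or `"within_minus_between"`.
#' @param alternative `"less"` (cases cluster more tightly; default) or
#'   `"two.sided"`, which reports `min(2 * min(p_less, p_greater), 1)`.
#' @param exact enumerate all `choose(n, n_cases)` arrangements (error if
#'   more than `2e5`).
#' @param seed optional seed for the permutation draws; `NULL` uses the
#'   current RNG stream.
#' @return Object of class `"permutation_test"`: list with `observed`,
#'   `p_value`, `B`, `statistic`, `alternative`, `null` (the null statistic
#'   draws), `seed`, `level`.
#' @export
group_clustering_permutation_test <- function(d, labels, B = 10000,
                                              statistic = c("within", "within_minus_between"),
                                              alternative = c("less", "two.sided"),
                                              exact = FALSE, seed = NULL) {
  statistic <- match.arg(statistic)
  alternative <- match.arg(alternative)
  is_case <- .as_case_logical(labels)
  n <- nrow(d)
  if (length(is_case) != n) stop("labels do not match the matrix dimension")
  if (sum(is_case) < 2 || sum(!is_case) < 2)
    stop("need at least 2 cases and 2 controls")
  if (!exact && B < 99) stop("B must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  dm <- unclass(d)
  obs <- .clustering_stat(dm, is_case, statistic)
  if (exact) {
    m <- sum(is_case)
    if (choose(n, m) > 2e5)
      stop("too many arrangements to enumerate; use Monte Carlo")
    combos <- utils::combn(n, m)
    null <- apply(combos, 2, function(ix) {
      v <- rep(FALSE, n); v[ix] <- TRUE
      .clustering_stat(dm, v, statistic)
    })
    B <- length(null)
    p_less <- mean(null <= obs + 1e-12)
    p_greater <- mean(null >= obs - 1e-12)
  } else {
    null <- vapply(seq_len(B), function(b)
      .clustering_stat(dm, sample(is_case), statistic), numeric(1))
    p_less <- (1 + sum(null <= obs + 1e-12)) / (1 + B)
    p_greater <- (1 + sum(null >= obs - 1e-12)) / (1 + B)
  }
  p <- switch(alternative,
              less = p_less,
              two.sided = min(2 * min(p_less, p_greater), 1))
  structure(list(statistic = statistic, observed = obs, B = B,
                 p_value = p, alternative = alternative, exact = exact,
                 null = null, seed = seed, level = attr(d, "level")),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test for case-group clustering (%s statistic)\n",
              x$statistic))
  if (!is.null(x$level)) cat("  taxonomic level:", x$level, "\n")
  cat(sprintf("  observed = %.5g, %s = %d, p = %.4g (%s)\n", x$observed,
              if (x$exact) "arrangements" else "permutations", x$B,
              x$p_value, x$alternative))
  invisible(x)
}

.as_case_logical <- function(labels) {
  if (is.logical(labels)) return(labels)
  x <- tolower(as.character(labels))
  if (all(x %in% c("yes", "no"))) return(x == "yes")
  if (all(x %in% c("true", "false"))) return(x == "true")
  stop("labels must be logical or yes/no")
}

#' Chi-square test of case status across community clusters
#'
#' Pearson chi-square test of independence on the K x 2 table of case and
#' control counts per cluster (no continuity correction, df = K - 1).
#'
#' @param clusters a [hierarchical_clusters()] result or a vector of cluster
#'   labels.
#' @param labels case indicator aligned with the clustered samples (see
#'   [group_clustering_permutation_test()]).
#' @return List with `statistic`, `df`, `p_value`, and `table` (the K x 2
#'   count matrix), class `"cluster_case_test"`.
#' @export
cluster_case_test <- function(clusters, labels) {
  cl <- if (inherits(clusters, "cluster_assignment")) clusters$assignment
        else as.character(clusters)
  is_case <- .as_case_logical(labels)
  if (length(is_case) != length(cl))
    stop("labels do not match the clustered samples")
  if (length(unique(cl)) < 2) stop("need at least 2 clusters")
  tab <- table(cluster = cl, case = factor(is_case, c(TRUE, FALSE),
                                           c("case", "control")))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  structure(list(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, table = unclass(tab)),
            class = "cluster_case_test")
}

#' @export
print.cluster_case_test <- function(x, ...) {
  cat(sprintf("Cluster x case chi-square: X2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  print(x$table)
  invisible(x)
}

# reference levels matching the conventional presentation of cohort tables
.default_references <- c(RACE = "Caucasian", REGION = "California",
                         ANTIBIOTIC_SELECT = "Not in the last year",
                         WEIGHT_CHANGE = "Remained stable",
                         DIET_TYPE = "Omnivore", ALCOHOL_FREQUENCY = "Never",
                         SMOKING_FREQUENCY = "Never")

#' Per-variable logistic regressions of case status
#'
#' Fits one unadjusted logistic regression of the binary case indicator on
#' each variable in turn (the layout of a cohort characteristics table):
#' numeric variables enter linearly, categorical variables are expanded
#' against a reference level. Quasi-separated levels (huge standard errors
#' from empty cells) are flagged, not fatal; constant predictors are
#' flagged and skipped.
#'
#' @param metadata data.frame containing a logical `case` column (e.g. from
#'   [case_subset()]) and the variables.
#' @param variables character vector of metadata column names to test.
#' @param references named character vector of reference levels for
#'   categorical variables (defaults cover race/region/antibiotic/diet/
#'   alcohol/smoking/weight-change).
#' @return data.frame with one row per coefficient: `variable`, `level`
#'   (`NA` for numeric), `estimate` (log-odds), `std_error`, `z_value`,
#'   `p_value`, `n`, `flag`.
#' @export
covariate_logistic <- function(metadata, variables,
                               references = .default_references) {
  if (is.null(metadata$case) || !is.logical(metadata$case))
    stop("metadata must carry a logical `case` column; see case_subset()")
  refs <- .default_references
  refs[names(references)] <- references
  out <- list()
  for (v in variables) {
    x <- metadata[[v]]
    if (is.null(x)) stop("variable not in metadata: ", v)
    ok <- !.is_missing(x) & !is.na(metadata$case)
    xi <- x[ok]; yi <- metadata$case[ok]
    if (length(unique(xi)) < 2) {
      out[[v]] <- data.frame(variable = v, level = NA, estimate = NA,
                             std_error = NA, z_value = NA, p_value = NA,
                             n = sum(ok), flag = "constant predictor")
      next
    }
    if (!is.numeric(xi)) {
      xi <- factor(xi)
      if (v %in% names(refs) && refs[[v]] %in% levels(xi))
        xi <- stats::relevel(xi, refs[[v]])
    }
    fit <- stats::glm(yi ~ xi, family = stats::binomial())
    cf <- summary(fit)$coefficients
    cf <- cf[-1, , drop = FALSE]
    lev <- if (is.factor(xi)) sub("^xi", "", rownames(cf)) else NA_character_
    out[[v]] <- data.frame(
      variable = v, level = lev, estimate = cf[, 1], std_error = cf[, 2],
      z_value = cf[, 3], p_value = cf[, 4], n = sum(ok),
      flag = ifelse(cf[, 2] > 50, "possible separation", ""),
      row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Covariate-adjusted per-taxon association screen
#'
#' For each taxon, fits a logistic regression of the case indicator on the
#' taxon's relative abundance plus adjustment covariates (age, sex and
#' race by default) and reports the Wald p-value for the abundance
#' coefficient, group mean abundances, their difference, and the
#' Benjamini-Hochberg q-value across all tested taxa. Abundances enter the
#' model untransformed by default; `transform = "arcsinsqrt"` applies the
#' arcsine-square-root variance stabiliser.
#'
#' @param table relative-mode [taxon_table()]; to screen the full
#'   phylum-to-species testing set, pass `to_relative()` of
#'   [pool_levels()].
#' @param metadata data.frame with a logical `case` column and the
#'   adjustment covariates, aligned by sample id with the table.
#' @param adjust_for metadata column names to adjust for.
#' @param transform `"none"` or `"arcsinsqrt"`.
#' @return data.frame of class `"taxon_association"`: `lineage`, `estimate`,
#'   `wald_p`, `q_value`, `control_mean`, `case_mean`, `difference`,
#'   ordered as in the input table; skipped zero-variance taxa carry `NA`
#'   p-values and are excluded from the FDR adjustment.
#' @export
taxon_wald_tests <- function(table, metadata,
                             adjust_for = c("AGE", "SEX", "RACE"),
                             transform = c("none", "arcsinsqrt")) {
  stopifnot(inherits(table, "taxon_table"))
  transform <- match.arg(transform)
  if (table$mode != "relative")
    stop("taxon screening requires relative abundances")
  if (is.null(metadata$case) || !is.logical(metadata$case))
    stop("metadata must carry a logical `case` column; see case_subset()")
  id_col <- if (!is.null(metadata$SAMPLE_ID)) metadata$SAMPLE_ID
            else rownames(metadata)
  keep <- intersect(table$sample_ids, id_col)
  if (!length(keep)) stop("no overlapping samples between table and metadata")
  md <- metadata[match(keep, id_col), , drop = FALSE]
  x <- table$values[keep, , drop = FALSE]
  y <- md$case
  if (length(adjust_for)) {
    covs <- md[, adjust_for, drop = FALSE]
    for (j in seq_along(covs))
      if (!is.numeric(covs[[j]])) covs[[j]] <- factor(covs[[j]])
    mm <- stats::model.matrix(~ ., data = covs)
  } else {
    mm <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  }

  ctrl_mean <- colMeans(x[!y, , drop = FALSE])
  case_mean <- colMeans(x[y, , drop = FALSE])
  p <- est <- rep(NA_real_, ncol(x))
  for (k in seq_len(ncol(x))) {
    a <- x[, k]
    if (stats::var(a) == 0) next  # zero-variance taxon: skipped
    if (transform == "arcsinsqrt") a <- asin(sqrt(pmin(a, 1)))
    fit <- suppressWarnings(
      stats::glm.fit(cbind(abund = a, mm), y,
                     family = stats::binomial()))
    cf <- .wald_from_fit(fit)
    est[k] <- cf[1]; p[k] <- cf[2]
  }
  q <- rep(NA_real_, length(p))
  q[!is.na(p)] <- bh_fdr(p[!is.na(p)])
  res <- data.frame(lineage = table$lineages, taxon_id = table$taxon_ids,
                    estimate = est, wald_p = p, q_value = q,
                    control_mean = unname(ctrl_mean),
                    case_mean = unname(case_mean),
                    difference = unname(case_mean - ctrl_mean),
                    stringsAsFactors = FALSE)
  class(res) <- c("taxon_association", "data.frame")
  res
}

# Wald estimate and p-value of the first coefficient of a glm.fit object,
# mirroring summary.glm's unscaled covariance from the pivoted QR
.wald_from_fit <- function(fit) {
  rank <- fit$rank
  b <- fit$coefficients[1]
  if (rank < 1 || is.na(b)) return(c(NA_real_, NA_real_))
  p1 <- seq_len(rank)
  covu <- tryCatch(chol2inv(fit$qr$qr[p1, p1, drop = FALSE]),
                   error = function(e) NULL)
  if (is.null(covu)) return(c(NA_real_, NA_real_))
  pos <- match(1L, fit$qr$pivot[p1])
  if (is.na(pos)) return(c(NA_real_, NA_real_))  # abundance aliased out
  se <- sqrt(covu[pos, pos])
  c(b, 2 * stats::pnorm(-abs(b / se)))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (q-values), monotone in rank.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return q-values of the same length, each `>=` its p-value.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
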