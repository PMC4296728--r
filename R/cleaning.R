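# values treated as "missing/uncertain" in categorical metadata fields
.missing_codes <- c(NA, "", "NA", "no_data", "Unknown", "unknown",
                    "Unspecified", "unspecified")

.is_missing <- function(x) is.na(x) | as.character(x) %in% .missing_codes

#' Default metadata column mapping
#'
#' Maps the canonical field names used by the cleaning and inference stages
#' to the column names of an American-Gut-style metadata file. Override
#' entries to bind differently named columns.
#'
#' @return Named character vector `canonical -> column name`.
#' @export
default_column_map <- function() {
  c(sample_id = "SAMPLE_ID", subject_id = "HOST_SUBJECT_ID", age = "AGE",
    sex = "SEX", race = "RACE", body_site = "BODY_SITE",
    antibiotic = "ANTIBIOTIC_SELECT", diabetes = "DIABETES", ibd = "IBD",
    cesarean = "CSECTION", appendectomy = "APPENDIX_REMOVED")
}

#' Apply the study exclusion filters
#'
#' Removes samples in a fixed order — age below 4 years; missing sex;
#' missing race; specimen not feces; antibiotic use within the past month;
#' diabetes; inflammatory bowel disease; then duplicate samples per
#' participant (keeping the lexicographically first sample id) — and
#' reports per-filter attrition. Filters are sequential: each sample is
#' counted against the first rule it violates, so removal counts sum to the
#' total removed.
#'
#' @param metadata data.frame of per-sample metadata.
#' @param table optional [taxon_table()] filtered alongside the metadata;
#'   its samples must all be present in the metadata.
#' @param column_map named vector as from [default_column_map()].
#' @return List with `metadata`, `table` (or `NULL`), and `attrition`, a
#'   data.frame of (filter, n_removed, n_remaining) rows.
#' @export
apply_exclusions <- function(metadata, table = NULL,
                             column_map = default_column_map()) {
  cm <- default_column_map()
  cm[names(column_map)] <- column_map
  ids <- metadata[[cm[["sample_id"]]]]
  if (is.null(ids)) stop("metadata lacks sample-id column ", cm[["sample_id"]])
  if (anyDuplicated(ids)) stop("duplicate sample ids in metadata")
  if (!is.null(table)) {
    orphans <- setdiff(table$sample_ids, ids)
    if (length(orphans))
      stop("table samples missing from metadata: ",
           paste(orphans, collapse = ", "))
  }
  col <- function(field) metadata[[cm[[field]]]]

  rules <- list(
    `age < 4 years` = !is.na(suppressWarnings(as.numeric(col("age")))) &
      suppressWarnings(as.numeric(col("age"))) < 4,
    `sex missing` = .is_missing(col("sex")),
    `race missing` = .is_missing(col("race")),
    `specimen not feces` = tolower(as.character(col("body_site"))) !=
      "feces" & !grepl("feces", tolower(as.character(col("body_site")))),
    `antibiotic in past month` = grepl(
      "past month|last month|week|today", tolower(as.character(col("antibiotic")))),
    `diabetes` = tolower(as.character(col("diabetes"))) == "yes",
    `inflammatory bowel disease` = tolower(as.character(col("ibd"))) == "yes")

  keep <- rep(TRUE, nrow(metadata))
  att <- data.frame(filter = character(0), n_removed = integer(0),
                    n_remaining = integer(0))
  for (nm in names(rules)) {
    hit <- keep & rules[[nm]] & !is.na(rules[[nm]])
    keep <- keep & !hit
    att <- rbind(att, data.frame(filter = nm, n_removed = sum(hit),
                                 n_remaining = sum(keep)))
  }
  # duplicates: keep first sample id per participant among survivors
  subj <- as.character(col("subject_id"))
  surv <- which(keep)[order(ids[keep])]
  dup <- duplicated(subj[surv]) & !.is_missing(subj[surv])
  hit <- rep(FALSE, nrow(metadata))
  hit[surv[dup]] <- TRUE
  keep <- keep & !hit
  att <- rbind(att, data.frame(filter = "duplicate participant",
                               n_removed = sum(hit), n_remaining = sum(keep)))

  md <- metadata[keep, , drop = FALSE]
  tb <- table
  if (!is.null(table)) {
    keep_s <- intersect(table$sample_ids, ids[keep])
    tb <- taxon_table(table$values[keep_s, , drop = FALSE],
                      lineages = table$lineages, mode = "counts")
    tb$mode <- table$mode
  }
  list(metadata = md, table = tb, attrition = att)
}

#' Restrict to samples with a definite case status
#'
#' Drops samples whose case field (cesarean or appendectomy status) is
#' missing or uncertain, and appends a logical `case` column.
#'
#' @inheritParams apply_exclusions
#' @param case_field `"cesarean"` or `"appendectomy"` (canonical name,
#'   resolved through `column_map`), or a literal column name.
#' @return Filtered metadata with a logical `case` column.
#' @export
case_subset <- function(metadata, case_field = c("cesarean", "appendectomy"),
                        column_map = default_column_map()) {
  cm <- default_column_map()
  cm[names(column_map)] <- column_map
  field <- if (case_field[1] %in% names(cm)) cm[[case_field[1]]] else case_field[1]
  x <- metadata[[field]]
  if (is.null(x)) stop("metadata lacks case column ", field)
  x <- tolower(as.character(x))
  keep <- x %in% c("yes", "no")
  out <- metadata[keep, , drop = FALSE]
  out$case <- x[keep] == "yes"
  out
}
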