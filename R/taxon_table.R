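#' Construct a taxon composition table
#'
#' The central container of the package: a samples x taxa matrix of
#' non-negative counts or relative abundances together with a
#' greengenes-style lineage string per taxon (e.g.
#' `"k__Bacteria;p__Firmicutes;c__Clostridia;..."`).
#'
#' @param values numeric matrix, samples in rows and taxa in columns, with
#'   unique row (sample) and column (taxon) names.
#' @param lineages character vector of lineage strings, one per taxon.
#'   Defaults to the column names. Lineages may repeat (several OTUs can map
#'   to the same taxonomy string); taxon ids may not.
#' @param mode `"counts"` for read counts, `"relative"` for proportions
#'   (each sample row must then sum to 1 within `1e-9`).
#' @return An object of class `"taxon_table"`.
#' @export
taxon_table <- function(values, lineages = colnames(values),
                        mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample row names and taxon column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate taxon ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (anyNA(values) || any(values < 0))
    stop("negative or missing abundances are not allowed")
  if (length(lineages) != ncol(values))
    stop("`lineages` must have one entry per taxon")
  if (mode == "relative") {
    bad <- abs(rowSums(values) - 1) > 1e-9
    if (any(bad))
      stop("relative-mode rows must sum to 1; offending samples: ",
           paste(rownames(values)[bad], collapse = ", "))
  }
  structure(
    list(values = values,
         sample_ids = rownames(values),
         taxon_ids = colnames(values),
         lineages = as.character(lineages),
         mode = mode),
    class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table: %d samples x %d taxa (%s mode)\n",
              nrow(x$values), ncol(x$values), x$mode))
  cat("samples:", paste(utils::head(x$sample_ids, 5), collapse = ", "),
      if (length(x$sample_ids) > 5) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$values)

# canonical rank order and prefixes used in greengenes lineages
.rank_prefixes <- c(kingdom = "k", phylum = "p", class = "c", order = "o",
                    family = "f", genus = "g", species = "s")

#' Parse a greengenes lineage string into named rank components
#'
#' Splits on `";"` (optionally followed by whitespace) and maps the
#' `k__`/`p__`/.../`s__` prefixes to rank names. Empty names (`"g__"`) are
#' retained as empty strings; ranks absent from the string are `NA`.
#'
#' @param lineage a single lineage string.
#' @return Named character vector over kingdom..species.
#' @export
parse_lineage <- function(lineage) {
  out <- stats::setNames(rep(NA_character_, 7L), names(.rank_prefixes))
  parts <- trimws(strsplit(lineage, ";")[[1]])
  parts <- parts[nzchar(parts)]
  for (p in parts) {
    if (!grepl("^[kpcofgs]__", p))
      stop("malformed lineage component '", p, "' in '", lineage, "'")
    rk <- names(.rank_prefixes)[match(substr(p, 1, 1), .rank_prefixes)]
    out[rk] <- substring(p, 4)
  }
  out
}

#' Truncate a lineage string at a taxonomic level
#'
#' Returns the lineage prefix down to `level`, padding intermediate absent
#' ranks with empty names so that e.g. a phylum-only lineage truncated at
#' class yields `"p__X;c__"`. The kingdom component is kept only when present
#' in the input.
#'
#' @param lineages character vector of lineage strings.
#' @param level one of `"phylum"`, `"class"`, `"order"`, `"family"`,
#'   `"genus"`, `"species"`.
#' @return Character vector of truncated lineage strings.
#' @export
truncate_lineage <- function(lineages, level) {
  level <- match.arg(level, names(.rank_prefixes)[-1])
  stop_at <- match(level, names(.rank_prefixes))
  vapply(lineages, function(lin) {
    ranks <- parse_lineage(lin)
    keep <- seq_len(stop_at)
    if (is.na(ranks[["kingdom"]])) keep <- keep[-1]
    comp <- ranks[keep]
    comp[is.na(comp)] <- ""
    paste0(.rank_prefixes[names(comp)], "__", comp, collapse = ";")
  }, character(1), USE.NAMES = FALSE)
}

#' Convert a table to relative abundances
#'
#' Divides each sample row by its total so rows sum to 1. Already-relative
#' tables are renormalised (a no-op up to rounding), making the operation
#' idempotent.
#'
#' @param table a [taxon_table()].
#' @return A `taxon_table` in `"relative"` mode.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  tot <- rowSums(table$values)
  if (any(tot <= 0))
    stop("samples with zero total abundance: ",
         paste(table$sample_ids[tot <= 0], collapse = ", "))
  taxon_table(sweep(table$values, 1, tot, "/"), table$lineages,
              mode = "relative")
}

#' Collapse taxa to a taxonomic level
#'
#' Taxa whose lineages share the prefix truncated at `level` are summed; the
#' collapsed taxon ids are the truncated lineage strings. Per-sample totals
#' are conserved exactly. Taxa with an empty name at the target rank (e.g.
#' `"g__"`) form their own group keyed by the full truncated prefix; they are
#' not merged into their parent.
#'
#' @inheritParams to_relative
#' @param level target level, `"phylum"` through `"species"`.
#' @return A `taxon_table` at the requested level, same mode as the input.
#' @export
collapse_to_level <- function(table, level) {
  stopifnot(inherits(table, "taxon_table"))
  keys <- truncate_lineage(table$lineages, level)
  uk <- unique(keys)
  idx <- split(seq_along(keys), factor(keys, levels = uk))
  out <- vapply(idx, function(i) rowSums(table$values[, i, drop = FALSE]),
                numeric(nrow(table$values)))
  if (nrow(table$values) == 1L) out <- matrix(out, nrow = 1)
  dimnames(out) <- list(table$sample_ids, uk)
  tab <- taxon_table(out, lineages = uk, mode = "counts")
  tab$mode <- table$mode  # collapse conserves row sums, so mode carries over
  tab$level <- level
  tab
}

#' Pool collapsed tables across taxonomic levels
#'
#' Builds the combined testing set used for taxon-wise screening: the table
#' is collapsed at each requested level and the per-level taxa are
#' concatenated, each level contributing its taxa once.
#'
#' @inheritParams to_relative
#' @param levels character vector of levels, default phylum through species.
#' @return A `taxon_table` whose taxa are all collapsed lineages, pooled.
#' @export
pool_levels <- function(table,
                        levels = c("phylum", "class", "order", "family",
                                   "genus", "species")) {
  pieces <- lapply(levels, function(l) collapse_to_level(table, l))
  vals <- do.call(cbind, lapply(pieces, function(p) p$values))
  lins <- unlist(lapply(pieces, function(p) p$lineages), use.names = FALSE)
  dup <- duplicated(colnames(vals))
  vals <- vals[, !dup, drop = FALSE]
  lins <- lins[!dup]
  tab <- taxon_table(vals, lineages = lins, mode = "counts")
  tab$mode <- table$mode
  tab
}

#' Read a classic OTU-table TSV
#'
#' Reads the classic tab-separated OTU-table layout: optional leading `#`
#' comment lines, a header line starting `#OTU ID` followed by sample ids
#' and (optionally) a final `taxonomy` column, then one row per taxon.
#' Lineage separators `";"` and `"; "` are both accepted.
#'
#' @param path file path.
#' @param mode `"auto"` (counts if all values are whole numbers), `"counts"`
#'   or `"relative"`.
#' @return A [taxon_table()] (samples in rows; the on-disk layout is
#'   transposed).
#' @export
read_taxon_table <- function(path, mode = c("auto", "counts", "relative")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  hdr_i <- grep("^#OTU ID\t", lines)
  if (!length(hdr_i)) stop("no '#OTU ID' header line in ", path)
  hdr_i <- hdr_i[1]
  header <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  has_tax <- tolower(header[length(header)]) == "taxonomy"
  sample_ids <- header[-c(1L, if (has_tax) length(header))]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  cells <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(cells)
  if (any(nf != length(header)))
    stop("ragged row(s) at line(s) ",
         paste(hdr_i + which(nf != length(header)), collapse = ", "),
         " of ", path)
  taxon_ids <- vapply(cells, `[[`, character(1), 1L)
  lineages <- if (has_tax)
    gsub(";[ ]+", ";", vapply(cells, function(x) x[[length(x)]], character(1)))
  else taxon_ids
  num <- vapply(cells, function(x)
    as.numeric(x[seq(2L, 1L + length(sample_ids))]), numeric(length(sample_ids)))
  num <- matrix(num, nrow = length(sample_ids))  # samples x taxa
  if (anyNA(num))
    stop("non-numeric abundance value(s) in ", path)
  neg <- which(colSums(num < 0) > 0)
  if (length(neg))
    stop("negative abundance in row(s) for taxon ",
         paste(taxon_ids[neg], collapse = ", "))
  dimnames(num) <- list(sample_ids, taxon_ids)
  if (mode == "auto")
    mode <- if (max(abs(num - round(num))) < 1e-9) "counts" else "relative"
  if (mode == "relative")  # tolerate rounding on disk
    num <- sweep(num, 1, rowSums(num), "/")
  taxon_table(num, lineages = lineages, mode = mode)
}

#' Write a classic OTU-table TSV
#'
#' Inverse of [read_taxon_table()]: emits the taxa x samples layout with a
#' `#OTU ID` header and a trailing `taxonomy` column.
#'
#' @inheritParams to_relative
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_taxon_table <- function(table, path) {
  stopifnot(inherits(table, "taxon_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# Constructed from biom file", con)
  writeLines(paste(c("#OTU ID", table$sample_ids, "taxonomy"),
                   collapse = "\t"), con)
  vals <- t(table$values)
  rows <- vapply(seq_len(nrow(vals)), function(i)
    paste(c(table$taxon_ids[i],
            format(vals[i, ], scientific = FALSE, trim = TRUE, digits = 15),
            table$lineages[i]), collapse = "\t"), character(1))
  writeLines(rows, con)
  invisible(path)
}
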