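#' Construct a feature table
#'
#' A `feature_table` bundles a taxon-by-sample matrix of read counts with
#' per-sample metadata. It is the substrate of all community-level analyses
#' in the package: relative abundance, prevalence/core-taxon screens,
#' Shannon diversity and neutral-model fitting all start from one.
#'
#' @param counts Integer matrix, taxa as rows and samples as columns. Row
#'   names are taxon identifiers, column names sample identifiers; both must
#'   be unique. Counts must be non-negative whole numbers.
#' @param metadata A data frame with one row per sample. Must contain a
#'   `sample_id` column covering every column of `counts`. Typical further
#'   columns are `sub_line` (e.g. CF, WILC, WIL1--WIL4), `generation`
#'   (G1--G4), `day` (D0/D5/D10) and `replicate`.
#'
#' @return An object of class `feature_table` with elements `counts`
#'   (integer matrix), `taxon_ids`, `sample_ids` and `metadata` (a tibble
#'   ordered as the count columns).
#'
#' @examples
#' m <- matrix(c(5L, 0L, 2L, 7L), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("s1", "s2")))
#' ft <- feature_table(m, data.frame(sample_id = c("s1", "s2")))
#' ft
#' @export
feature_table <- function(counts, metadata) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have taxon row names and sample column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate taxon_ids in `counts`", call. = FALSE)
  if (anyDuplicated(colnames(counts))) stop("duplicate sample_ids in `counts`", call. = FALSE)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers", call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  metadata <- tibble::as_tibble(metadata)
  if (!"sample_id" %in% names(metadata)) {
    stop("`metadata` must have a `sample_id` column", call. = FALSE)
  }
  missing <- setdiff(colnames(counts), metadata$sample_id)
  if (length(missing) > 0) {
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  metadata <- metadata[match(colnames(counts), metadata$sample_id), , drop = FALSE]
  structure(
    list(counts = counts,
         taxon_ids = rownames(counts),
         sample_ids = colnames(counts),
         metadata = metadata),
    class = "feature_table"
  )
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$counts), " taxa x ", ncol(x$counts),
      " samples\n", sep = "")
  cat("total reads: ", sum(x$counts),
      "; metadata fields: ", paste(setdiff(names(x$metadata), "sample_id"),
                                   collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

#' Read a feature table from delimited files
#'
#' Reads a taxon-by-sample count table (first column `taxon_id`, remaining
#' columns one per sample) together with a sample metadata table keyed by
#' `sample_id`. Comma- and tab-separated files are both accepted.
#'
#' @param counts_path Path to the count table (TSV or CSV).
#' @param metadata_path Path to the per-sample metadata table.
#' @return A [feature_table].
#' @export
read_feature_table <- function(counts_path, metadata_path) {
  cts <- .read_delim_auto(counts_path)
  if (names(cts)[1] != "taxon_id") names(cts)[1] <- "taxon_id"
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$taxon_id
  md <- .read_delim_auto(metadata_path)
  feature_table(m, md)
}

.read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Write a feature table to delimited files
#'
#' @param table A [feature_table].
#' @param counts_path,metadata_path Output paths (written tab-separated).
#' @return `table`, invisibly.
#' @export
write_feature_table <- function(table, counts_path, metadata_path) {
  stopifnot(inherits(table, "feature_table"))
  out <- tibble::as_tibble(table$counts, rownames = "taxon_id")
  readr::write_tsv(out, counts_path, progress = FALSE)
  readr::write_tsv(table$metadata, metadata_path, progress = FALSE)
  invisible(table)
}

#' Subset the samples of a feature table by metadata
#'
#' Keeps the samples whose metadata rows satisfy the given predicates, e.g.
#' `ft_filter_samples(ft, sub_line == "WIL1")`. Taxa are left untouched;
#' combine with [filter_zero_taxa()] to drop taxa absent from the subset.
#'
#' @param table A [feature_table].
#' @param ... Logical predicates evaluated in the metadata, as in
#'   [dplyr::filter()].
#' @return A [feature_table] restricted to the matching samples.
#' @export
ft_filter_samples <- function(table, ...) {
  stopifnot(inherits(table, "feature_table"))
  md <- dplyr::filter(table$metadata, ...)
  if (nrow(md) == 0) stop("no samples match the filter", call. = FALSE)
  feature_table(table$counts[, md$sample_id, drop = FALSE], md)
}

#' Drop taxa with zero counts across all samples
#'
#' Removes every taxon whose total count over the samples of the table is
#' zero. Applied per group before neutral-model fitting, so that a taxon
#' absent from an entire sub-line does not enter that sub-line's fit.
#'
#' @param table A [feature_table].
#' @return A [feature_table] with the all-zero taxa removed; the sample set
#'   is unchanged.
#' @export
filter_zero_taxa <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  keep <- rowSums(table$counts) > 0
  feature_table(table$counts[keep, , drop = FALSE], table$metadata)
}

#' Per-sample relative abundances
#'
#' Divides each sample's counts by its total, so each column sums to one.
#'
#' @param table A [feature_table], or a numeric taxon-by-sample matrix.
#' @return A numeric matrix of fractions with the same dimnames.
#' @export
relative_abundance <- function(table) {
  m <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  totals <- colSums(m)
  if (any(totals == 0)) {
    bad <- colnames(m)[totals == 0]
    stop("sample(s) with zero total count: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sweep(m, 2, totals, "/")
}
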