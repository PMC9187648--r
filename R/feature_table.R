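#' Construct a feature table
#'
#' A feature table is the backbone container of the package: a samples x taxa
#' matrix of non-negative integer read counts (ASV abundances), tagged with the
#' primer set that generated it. Two primer sets are distinguished because
#' archaea-specific and prokaryote-universal libraries drawn from the same
#' community have very different archaeal capture rates.
#'
#' @param counts integer matrix, samples in rows, taxa in columns. Must carry
#'   unique row and column names.
#' @param primer_set `"archaea_specific"` or `"universal"`.
#' @return An object of class `feature_table`: the validated count matrix with
#'   attributes `primer_set` and per-sample `totals`.
#' @export
feature_table <- function(counts, primer_set = c("archaea_specific", "universal")) {
  primer_set <- match.arg(primer_set)
  counts <- as.matrix(counts)
  if (nrow(counts) > 0L && ncol(counts) > 0L) {
    storage.mode(counts) <- "double"
    if (anyNA(counts)) stop("counts contain NA")
    if (any(counts < 0)) stop("counts must be non-negative")
    if (any(counts != round(counts))) stop("counts must be integers")
  }
  if (is.null(rownames(counts))) rownames(counts) <- character(nrow(counts))
  if (is.null(colnames(counts))) colnames(counts) <- character(ncol(counts))
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate taxon ids")
  structure(counts, class = c("feature_table", "matrix"),
            primer_set = primer_set)
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d taxa (%s primers), %s reads\n",
              nrow(x), ncol(x), attr(x, "primer_set"),
              format(sum(x), big.mark = ",")))
  invisible(x)
}

#' Sample identifiers, taxon identifiers and read totals
#'
#' @param table a [feature_table()].
#' @return character vector of ids, or named numeric vector of per-sample
#'   read totals.
#' @export
sample_ids <- function(table) rownames(table)

#' @rdname sample_ids
#' @export
taxon_ids <- function(table) colnames(table)

#' @rdname sample_ids
#' @export
sample_totals <- function(table) {
  if (ncol(table) == 0L) stats::setNames(numeric(nrow(table)), rownames(table))
  else rowSums(unclass(table))
}

#' Read / write a feature table as TSV
#'
#' The on-disk dialect is a UTF-8 tab-delimited table with a header row of
#' taxon ids and sample ids in the first column; cells are integer counts.
#' `write_feature_table()` followed by `read_feature_table()` reproduces the
#' counts bit-exactly.
#'
#' @param path TSV file path.
#' @param primer_set primer set tag recorded on the returned table.
#' @return [read_feature_table()] returns a `feature_table`;
#'   `write_feature_table()` returns `path` invisibly.
#' @export
read_feature_table <- function(path, primer_set = c("archaea_specific", "universal")) {
  primer_set <- match.arg(primer_set)
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           row.names = NULL)
  if (ncol(raw) < 1L) stop("malformed feature table: no columns")
  ids <- raw[[1L]]
  m <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(m), nrow = nrow(m),
                                 dimnames = dimnames(m)))
  if (length(num) > 0L && anyNA(num)) {
    bad <- m[which(is.na(num))[1L]]
    stop(sprintf("non-numeric cell in feature table: '%s'", bad))
  }
  if (length(num) > 0L && any(num != round(num)))
    stop("non-integer cell in feature table")
  rownames(num) <- ids
  feature_table(num, primer_set)
}

#' @rdname read_feature_table
#' @param table a `feature_table` to serialize.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = rownames(table),
                   unclass(table)[, , drop = FALSE], check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Zero out minor ASVs per sample
#'
#' Within each sample, counts of taxa making up less than `threshold` of that
#' sample's reads are set to zero; taxa left with zero reads everywhere are
#' dropped. The comparison is inclusive: a taxon at exactly the threshold
#' fraction is retained. The canonical use is the per-sample >= 1% abundance
#' filter applied before phylogenetic placement of ASVs.
#'
#' @param table a [feature_table()].
#' @param threshold proportion in (0, 1); default 0.01.
#' @return filtered `feature_table`.
#' @export
filter_major_asvs <- function(table, threshold = 0.01) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("threshold must be a single number in (0, 1)")
  m <- unclass(table)
  tot <- sample_totals(table)
  keepable <- m >= threshold * tot  # recycles tot down columns
  m[!keepable] <- 0
  nonzero <- colSums(m) > 0
  feature_table(m[, nonzero, drop = FALSE], attr(table, "primer_set"))
}

#' Merge replicate samples by host species
#'
#' Samples from the same species are merged by summing ASV abundances, giving
#' one row per species. The global read total is conserved.
#'
#' @param table a [feature_table()].
#' @param species named character vector mapping every sample id to a species
#'   id.
#' @return `feature_table` with one row per species.
#' @export
merge_replicates_by_species <- function(table, species) {
  missing <- setdiff(rownames(table), names(species))
  if (length(missing) > 0L)
    stop("unmapped samples: ", paste(missing, collapse = ", "))
  sp <- species[rownames(table)]
  m <- rowsum(unclass(table), group = sp, reorder = TRUE)
  feature_table(m, attr(table, "primer_set"))
}
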