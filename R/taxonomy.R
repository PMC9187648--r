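#' Parse Silva-style semicolon-delimited lineages
#'
#' Lineage strings of the form
#' `"Archaea; Euryarchaeota; Methanobacteria; Methanobacteriales;
#' Methanobacteriaceae; Methanobrevibacter"` are split on `";"` with
#' whitespace stripped; common Silva rank prefixes (`d__`, `p__`, ...) are
#' removed. Missing trailing ranks are padded with `"unknown"` so every
#' lineage has the six ranks domain through genus, ordered coarse to fine.
#'
#' @param strings character vector of semicolon-delimited lineages.
#' @return character matrix with one row per input and columns
#'   `domain, phylum, class, order, family, genus`.
#' @export
parse_lineage <- function(strings) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  out <- matrix("unknown", nrow = length(strings), ncol = length(ranks),
                dimnames = list(NULL, ranks))
  parts <- strsplit(strings, ";", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- trimws(parts[[i]])
    p <- sub("^[dpcofgs]__", "", p)
    p <- p[nzchar(p)]
    n <- min(length(p), length(ranks))
    if (n > 0L) out[i, seq_len(n)] <- p[seq_len(n)]
  }
  out
}

#' Read a taxonomy table
#'
#' Expects a TSV with columns `taxon_id` and `taxonomy` (the raw
#' semicolon-delimited string). The source string is retained alongside the
#' parsed ranks.
#'
#' @param path TSV file path.
#' @return `taxonomy_table`: a data.frame with columns `taxon_id`, the six
#'   ranks, and `taxonomy` (the source string).
#' @export
read_taxonomy <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (!all(c("taxon_id", "taxonomy") %in% names(raw)))
    stop("taxonomy TSV needs columns 'taxon_id' and 'taxonomy'")
  taxonomy_table(raw$taxon_id, raw$taxonomy)
}

#' @rdname read_taxonomy
#' @param taxon_id character vector of taxon identifiers.
#' @param taxonomy character vector of semicolon-delimited lineage strings.
#' @export
taxonomy_table <- function(taxon_id, taxonomy) {
  if (anyDuplicated(taxon_id)) stop("duplicate taxon_id in taxonomy")
  out <- data.frame(taxon_id = taxon_id, parse_lineage(taxonomy),
                    taxonomy = taxonomy, stringsAsFactors = FALSE)
  class(out) <- c("taxonomy_table", "data.frame")
  out
}

#' Look up lineages for a feature table, padding unknowns
#'
#' Taxa absent from the taxonomy are returned as all-"unknown" lineages so a
#' partially annotated table can still be profiled.
#'
#' @param taxonomy a [taxonomy_table()].
#' @param taxa character vector of taxon ids.
#' @return character matrix of ranks, rownames = `taxa`.
#' @keywords internal
lineage_matrix <- function(taxonomy, taxa) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus")
  out <- matrix("unknown", nrow = length(taxa), ncol = length(ranks),
                dimnames = list(taxa, ranks))
  hit <- match(taxa, taxonomy$taxon_id)
  ok <- !is.na(hit)
  out[ok, ] <- as.matrix(taxonomy[hit[ok], ranks])
  out
}
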