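#' Read host metadata
#'
#' Per-species covariates used throughout the association analyses: diet type,
#' crude-fibre content of the diet (g per kg dry matter), digesta mean
#' retention time (hours), body mass (kg), coefficient of gut differentiation
#' (relative size of stomach + large intestine versus small intestine) and
#' gastrointestinal-tract type. Missing values stay `NA`; nothing is imputed.
#'
#' @param path CSV with at least a `species_id` column; recognised optional
#'   columns: `class`, `order`, `diet_type`, `primary_diet_fraction`,
#'   `fibre_content`, `mrt`, `body_mass`, `gut_diff_coeff`, `git_type`,
#'   `origin`.
#' @return `host_metadata`: a validated data.frame keyed by `species_id`.
#' @export
read_host_metadata <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  host_metadata(raw)
}

#' @rdname read_host_metadata
#' @param df data.frame of covariates, one row per species.
#' @export
host_metadata <- function(df) {
  if (!"species_id" %in% names(df)) stop("host metadata needs 'species_id'")
  if (anyDuplicated(df$species_id)) stop("duplicate species_id")
  num_cols <- intersect(c("primary_diet_fraction", "fibre_content", "mrt",
                          "body_mass", "gut_diff_coeff"), names(df))
  for (cl in num_cols) df[[cl]] <- as.numeric(df[[cl]])
  if ("fibre_content" %in% names(df) &&
      any(df$fibre_content < 0, na.rm = TRUE))
    stop("fibre_content must be >= 0")
  if ("mrt" %in% names(df) && any(df$mrt <= 0, na.rm = TRUE))
    stop("mrt must be > 0 where present")
  if ("git_type" %in% names(df)) {
    bad <- setdiff(stats::na.omit(unique(df$git_type)),
                   c("foregut", "hindgut", "caecum", "simple"))
    if (length(bad) > 0L)
      stop("unknown git_type: ", paste(bad, collapse = ", "))
  }
  class(df) <- c("host_metadata", "data.frame")
  df
}

#' Read a host or taxon phylogeny
#'
#' Thin wrapper over [ape::read.tree()] that enforces the invariants the
#' downstream statistics rely on: unique leaf names and non-negative branch
#' lengths.
#'
#' @param path newick file.
#' @return an [ape::read.tree()] `phylo` object.
#' @export
read_phylo <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse newick tree: ", path)
  validate_phylo(tree)
}

#' @keywords internal
validate_phylo <- function(tree) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf names in tree")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths in tree")
  tree
}
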