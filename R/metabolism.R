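METABOLISM_CLASSES <- c("co2_reducing", "methyl_reducing",
                        "methylotroph_dismutation", "acetoclastic",
                        "mixed", "non_methanogen", "unknown")

RANK_DEPTH <- c(domain = 1L, phylum = 2L, class = 3L, order = 4L,
                family = 5L, genus = 6L)

#' Taxon-to-methane-metabolism rule map
#'
#' Almost all methanogen genera/families have a single dominant methane
#' metabolism, so a taxonomy-based lookup assigns each ASV to a class:
#' hydrogenotrophic CO2 reduction, hydrogenotrophic methyl reduction,
#' methylotrophic dismutation, acetoclastic, `mixed` (Methanosarcina, whose
#' species span several pathways) or `non_methanogen`. The default map ships
#' as an editable CSV covering the lineages that dominate animal-gut
#' archaeomes (Methanobrevibacter, Methanosphaera, Methanomethylophilaceae,
#' Methanocorpusculum, Methanimicrococcus, Nitrososphaeraceae, ...); rules at
#' a more specific rank override coarser ones, so e.g. the methanol-reducing
#' genus Methanosphaera overrides its otherwise CO2-reducing order
#' Methanobacteriales.
#'
#' @param path CSV with columns `rank` (domain..genus), `taxon`, `class`.
#' @return `metabolism_map` data.frame.
#' @export
read_metabolism_map <- function(path = system.file("extdata",
                                                   "metabolism_map.csv",
                                                   package = "gutarchaeome")) {
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("rank", "taxon", "class") %in% names(map)))
    stop("metabolism map needs columns rank, taxon, class")
  bad_rank <- setdiff(map$rank, names(RANK_DEPTH))
  if (length(bad_rank) > 0L)
    stop("unknown ranks in metabolism map: ", paste(bad_rank, collapse = ", "))
  bad_cls <- setdiff(map$class, METABOLISM_CLASSES)
  if (length(bad_cls) > 0L)
    stop("unknown classes in metabolism map: ", paste(bad_cls, collapse = ", "))
  class(map) <- c("metabolism_map", "data.frame")
  map
}

#' Assign a lineage to a methane-metabolism class
#'
#' Scans the rule map for entries whose taxon name matches the lineage at the
#' rule's rank; the match at the most specific (deepest) rank wins. Lineages
#' matching no rule are `unknown`. Deterministic and independent of rule
#' order except among duplicate same-rank rules, which are rejected upstream.
#'
#' @param lineage named character vector with entries `domain` .. `genus`
#'   (one row of [parse_lineage()]), or a character matrix of such rows.
#' @param map a [read_metabolism_map()].
#' @return class string (vector when `lineage` is a matrix).
#' @export
assign_metabolism <- function(lineage, map = read_metabolism_map()) {
  if (is.matrix(lineage)) {
    return(apply(lineage, 1L, assign_metabolism, map = map))
  }
  depth <- RANK_DEPTH[map$rank]
  hit <- map$taxon == unname(lineage[map$rank]) & !is.na(lineage[map$rank])
  if (!any(hit)) return("unknown")
  map$class[hit][which.max(depth[hit])]
}

#' Per-sample methane-metabolism profile
#'
#' For each sample, the proportion of reads in each metabolism class and the
#' methyl-reducing to CO2-reducing ratio (reads of methyl reducers / reads of
#' CO2 reducers). `mixed` reads count toward neither side of the ratio. The
#' ratio is flagged undefined when a sample has no CO2-reducer reads; samples
#' with zero total reads get an all-`NA` row.
#'
#' @param table a [feature_table()] (raw or rarefied; recorded in the output
#'   attribute `rarefied`).
#' @param taxonomy a [taxonomy_table()] covering the table's taxa (missing
#'   taxa are treated as unknown).
#' @param map a [read_metabolism_map()].
#' @param rarefied logical flag recorded on the output.
#' @return `pathway_profile` data.frame: one row per sample with the class
#'   proportions, `methyl_co2_ratio` and `ratio_undefined`.
#' @export
pathway_profile <- function(table, taxonomy, map = read_metabolism_map(),
                            rarefied = FALSE) {
  lin <- lineage_matrix(taxonomy, taxon_ids(table))
  cls <- assign_metabolism(lin, map)
  m <- unclass(table)
  by_class <- vapply(METABOLISM_CLASSES,
                     function(k) rowSums(m[, cls == k, drop = FALSE]),
                     numeric(nrow(m)))
  if (nrow(m) == 1L) by_class <- matrix(by_class, nrow = 1L,
                                        dimnames = list(rownames(m),
                                                        METABOLISM_CLASSES))
  tot <- rowSums(by_class)
  prop <- by_class / ifelse(tot > 0, tot, NA_real_)
  ratio <- by_class[, "methyl_reducing"] / by_class[, "co2_reducing"]
  undefined <- by_class[, "co2_reducing"] == 0
  ratio[undefined] <- NA_real_
  out <- data.frame(sample_id = rownames(m), prop,
                    methyl_co2_ratio = ratio,
                    ratio_undefined = undefined | tot == 0,
                    row.names = NULL, check.names = FALSE)
  attr(out, "rarefied") <- rarefied
  class(out) <- c("pathway_profile", "data.frame")
  out
}

#' Classify sequence source environments from annotation text
#'
#' Free-text isolation-source annotations are binned into `Gut` (animal
#' digestive tract), `Engineered` (built environments such as digesters) or
#' `Environment` (open natural environments), with an exclusion list for
#' ambiguous sources (e.g. sponge tissue, nests, polluted sites). Keyword
#' lists are configuration, not code; the bundled defaults cover the common
#' cases. Precedence: excluded > Gut > Engineered > Environment; text
#' matching nothing falls back to `Environment`. Matching is case-insensitive
#' substring search.
#'
#' @param annotations character vector of free-text annotations.
#' @param rules data.frame with columns `category`
#'   (`excluded`/`Gut`/`Engineered`) and `keyword`; default the bundled CSV.
#' @return character vector of categories (`Gut`, `Environment`,
#'   `Engineered`, `excluded`).
#' @export
classify_source <- function(annotations, rules = read_source_rules()) {
  matches <- function(text, kws) any(vapply(kws, grepl, logical(1), x = text,
                                            fixed = TRUE))
  vapply(tolower(annotations), function(txt) {
    if (is.na(txt) || !nzchar(trimws(txt))) {
      warning("empty annotation classified as excluded")
      return("excluded")
    }
    for (cat in c("excluded", "Gut", "Engineered")) {
      if (matches(txt, tolower(rules$keyword[rules$category == cat])))
        return(cat)
    }
    "Environment"
  }, character(1), USE.NAMES = FALSE)
}

#' @rdname classify_source
#' @param path CSV of keyword rules.
#' @export
read_source_rules <- function(path = system.file("extdata", "source_rules.csv",
                                                 package = "gutarchaeome")) {
  rules <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("category", "keyword") %in% names(rules)))
    stop("source rules need columns category, keyword")
  rules
}
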