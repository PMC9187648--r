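#' Rarefy a feature table to even depth
#'
#' Single-draw subsampling without replacement (multivariate hypergeometric)
#' to exactly `depth` reads per sample; samples with fewer than `depth`
#' total reads are dropped. Canonical depths: 3,000 reads for archaeal
#' libraries, 12,000 for bacterial.
#'
#' @param table a [feature_table()].
#' @param depth target reads per sample (>= 1).
#' @param seed RNG seed for the draw.
#' @return rarefied `feature_table` (taxa left with zero reads everywhere
#'   are retained so tables stay comparable).
#' @export
rarefy <- function(table, depth = 3000, seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  m <- unclass(table)
  keep <- rowSums(m) >= depth
  m <- m[keep, , drop = FALSE]
  out <- matrix(0, nrow = nrow(m), ncol = ncol(m), dimnames = dimnames(m))
  withr_seed(seed, {
    for (i in seq_len(nrow(m))) {
      pool <- rep.int(seq_len(ncol(m)), m[i, ])
      drawn <- sample(pool, depth, replace = FALSE)
      out[i, ] <- tabulate(drawn, nbins = ncol(m))
    }
  })
  feature_table(out, attr(table, "primer_set"))
}

#' Observed richness per sample
#'
#' @param table a [feature_table()].
#' @return named integer vector: number of taxa with nonzero counts.
#' @export
observed_richness <- function(table) {
  m <- unclass(table)
  stats::setNames(as.integer(rowSums(m > 0)), rownames(m))
}

#' Beta-diversity distance matrix
#'
#' Standard community dissimilarities between all sample pairs:
#' * `bray_curtis`: sum |x - y| / sum (x + y) on counts;
#' * `jaccard`: 1 - |shared taxa| / |union taxa| on presence/absence;
#' * `unifrac_unweighted`: unshared / total branch length over the taxon
#'   tree, on presence/absence;
#' * `unifrac_weighted`: branch lengths weighted by the difference in
#'   relative abundance flowing through them, normalised so the distance
#'   lies in `[0, 1]`.
#'
#' @param table a [feature_table()].
#' @param metric distance to compute.
#' @param tree `phylo` covering every taxon in the table (UniFrac only).
#' @return symmetric `dist`-like matrix with sample ids.
#' @export
beta_distance <- function(table,
                          metric = c("bray_curtis", "jaccard",
                                     "unifrac_unweighted", "unifrac_weighted"),
                          tree = NULL) {
  metric <- match.arg(metric)
  m <- unclass(table)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (startsWith(metric, "unifrac")) {
    if (is.null(tree)) stop("UniFrac metrics require a tree")
    missing <- setdiff(colnames(m), tree$tip.label)
    if (length(missing) > 0L)
      stop("taxa missing from tree: ", paste(missing, collapse = ", "))
    bp <- branch_profiles(tree, m)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- unifrac_pair(bp$len, bp$mass[, i], bp$mass[, j],
                                         weighted = metric == "unifrac_weighted")
    }
    return(d)
  }
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    x <- m[i, ]; y <- m[j, ]
    d[i, j] <- d[j, i] <- switch(metric,
      bray_curtis = {
        tot <- sum(x + y)
        if (tot == 0) 0 else sum(abs(x - y)) / tot
      },
      jaccard = {
        un <- sum(x > 0 | y > 0)
        if (un == 0) 0 else 1 - sum(x > 0 & y > 0) / un
      })
  }
  d
}

# per-branch lengths and per-sample relative read mass flowing through each
# branch; column order of `mass` follows the table's sample order
#' @keywords internal
branch_profiles <- function(tree, m) {
  ntip <- length(tree$tip.label)
  tot <- rowSums(m)
  rel <- m / ifelse(tot > 0, tot, 1)
  # postorder accumulation of subtree mass per node
  nodes <- max(tree$edge)
  mass <- matrix(0, nrow = nodes, ncol = nrow(m))
  tip_idx <- match(tree$tip.label, colnames(m))
  present <- !is.na(tip_idx)
  mass[seq_len(ntip)[present], ] <- t(rel[, tip_idx[present], drop = FALSE])
  po <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(po$edge))) {
    parent <- po$edge[k, 1L]; child <- po$edge[k, 2L]
    mass[parent, ] <- mass[parent, ] + mass[child, ]
  }
  child_of_edge <- tree$edge[, 2L]
  list(len = tree$edge.length,
       mass = mass[child_of_edge, , drop = FALSE])
}

#' @keywords internal
unifrac_pair <- function(len, a, b, weighted) {
  if (weighted) {
    denom <- sum(len * (a + b))
    if (denom == 0) return(0)
    sum(len * abs(a - b)) / denom
  } else {
    pa <- a > 0; pb <- b > 0
    denom <- sum(len[pa | pb])
    if (denom == 0) return(0)
    sum(len[xor(pa, pb)]) / denom
  }
}

#' Cophenetic distance matrix from a tree
#'
#' Pairwise path-length (patristic) distances between leaves, used to turn a
#' host phylogeny into the distance matrix consumed by Mantel tests and the
#' phylogenetic weights of Moran's I.
#'
#' @param tree `phylo` with branch lengths.
#' @return symmetric matrix of leaf-to-leaf path lengths.
#' @export
cophenetic_from_tree <- function(tree) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  stats::cophenetic(tree)
}
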