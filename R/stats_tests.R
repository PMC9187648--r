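#' @keywords internal
lower_tri <- function(m) m[lower.tri(m)]

#' @keywords internal
perm_pvalue <- function(obs, perms, alternative) {
  switch(alternative,
         greater = (1 + sum(perms >= obs)) / (length(perms) + 1),
         less = (1 + sum(perms <= obs)) / (length(perms) + 1),
         two.sided = (1 + sum(abs(perms) >= abs(obs))) / (length(perms) + 1))
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance in the McArdle-Anderson
#' formulation: the squared distance matrix is Gower-centred and partitioned
#' by the hat matrix of a single predictor (grouping factor or numeric
#' covariate). Reports the pseudo-F, R2 = SS_model / SS_total and a
#' one-sided permutation p-value from unrestricted label permutations.
#'
#' @param dist symmetric distance matrix with sample ids.
#' @param rhs grouping factor/character (>= 2 groups) or numeric covariate,
#'   in the same sample order.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return `test_result` list: `statistic` (pseudo-F), `r_squared`, `df`,
#'   `p_value`, `n_perm`.
#' @export
permanova <- function(dist, rhs, n_perm = 999, seed = 1) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (length(rhs) != n) stop("rhs length must match distance matrix")
  if (!is.numeric(rhs)) {
    rhs <- factor(rhs)
    if (nlevels(rhs) < 2L) stop("need at least 2 groups")
    if (nlevels(rhs) >= n) stop("need replication within groups")
  }
  X <- stats::model.matrix(~rhs)
  hat_of <- function(X) X %*% solve(crossprod(X), t(X))
  G <- gower_center(d)
  df_m <- qr(X)$rank - 1L
  df_r <- n - df_m - 1L
  fstat <- function(G) {
    H <- hat_of(X)
    ss_m <- sum(H * G)  # tr(HG), H symmetric idempotent
    ss_t <- sum(diag(G))
    c(f = (ss_m / df_m) / ((ss_t - ss_m) / df_r), r2 = ss_m / ss_t)
  }
  obs <- fstat(G)
  perms <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n)
      fstat(G[idx, idx])[1L]
    }, numeric(1))
  })
  test_result("PERMANOVA pseudo-F", unname(obs["f"]),
              df = c(df_m, df_r),
              p_value = perm_pvalue(obs["f"], perms, "greater"),
              n_perm = n_perm, r_squared = unname(obs["r2"]))
}

#' @keywords internal
gower_center <- function(d) {
  A <- -0.5 * d^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation between the off-diagonal entries of two distance
#' matrices over the same samples, with significance from permuting the
#' rows/columns of the second matrix (999 permutations by default,
#' two-sided).
#'
#' @param d1,d2 symmetric matrices with matching ids (matched by name when
#'   both are named).
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return `test_result` with `statistic` = Mantel r.
#' @export
mantel_test <- function(d1, d2, n_perm = 999, seed = 1,
                        alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  if (!all(dim(d1) == dim(d2))) stop("distance matrices differ in size")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2))) {
    if (!setequal(rownames(d1), rownames(d2)))
      stop("distance matrices have different sample ids")
    d2 <- d2[rownames(d1), rownames(d1)]
  }
  r_obs <- stats::cor(lower_tri(d1), lower_tri(d2))
  n <- nrow(d1)
  perms <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      idx <- sample.int(n)
      stats::cor(lower_tri(d1), lower_tri(d2[idx, idx]))
    }, numeric(1))
  })
  test_result("Mantel r", r_obs, df = NA_integer_,
              p_value = perm_pvalue(r_obs, perms, alternative),
              n_perm = n_perm)
}

#' Phylogenetic Moran's I
#'
#' Autocorrelation of a per-species trait (e.g. archaeal richness) on a host
#' phylogeny. Weights default to inverse cophenetic distance with zero
#' diagonal, row-standardised; under the null the expected value is
#' -1/(n-1). Significance by permuting trait values across tips.
#'
#' @param values named numeric per species (>= 3, non-constant).
#' @param tree host `phylo`; or pass `weights` directly.
#' @param weights optional n x n weight matrix overriding the tree.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @param alternative as in [mantel_test()].
#' @return `test_result` with `statistic` = I and `expectation` = -1/(n-1).
#' @export
morans_i <- function(values, tree = NULL, weights = NULL, n_perm = 999,
                     seed = 1,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.null(weights)) {
    if (is.null(tree)) stop("provide a tree or a weight matrix")
    d <- cophenetic_from_tree(tree)
    ids <- intersect(rownames(d), names(values))
    values <- values[ids]
    d <- d[ids, ids]
    weights <- 1 / d
    diag(weights) <- 0
  } else {
    weights <- as.matrix(weights)
    if (!is.null(rownames(weights)) && !is.null(names(values)))
      values <- values[rownames(weights)]
  }
  n <- length(values)
  if (n < 3L) stop("need at least 3 species")
  if (stats::var(values) == 0) stop("values are constant")
  w <- weights / rowSums(weights)  # row-standardized; S0 = n
  istat <- function(v) {
    z <- v - mean(v)
    sum(w * outer(z, z)) / sum(z^2)
  }
  i_obs <- istat(values)
  perms <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(k) istat(sample(values)), numeric(1))
  })
  p_gr <- (1 + sum(perms >= i_obs)) / (n_perm + 1)
  p_ls <- (1 + sum(perms <= i_obs)) / (n_perm + 1)
  p <- switch(alternative, greater = p_gr, less = p_ls,
              two.sided = min(1, 2 * min(p_gr, p_ls)))
  out <- test_result("Moran's I", i_obs, df = NA_integer_, p_value = p,
                     n_perm = n_perm)
  out$expectation <- -1 / (n - 1)
  out
}

#' Kruskal-Wallis rank-sum test
#'
#' Midrank-based H statistic with the tie correction
#' 1 - sum(t^3 - t) / (N^3 - N), referred to a chi-square distribution with
#' k - 1 degrees of freedom.
#'
#' @param values numeric vector of observations.
#' @param groups group labels, same length.
#' @return `test_result` with `statistic` = H.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  N <- length(values)
  r <- rank(values)
  ss <- tapply(r, groups, function(x) sum(x)^2 / length(x))
  H <- 12 / (N * (N + 1)) * sum(ss) - 3 * (N + 1)
  ties <- table(values)
  correction <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (correction == 0) {  # all values identical
    return(test_result("Kruskal-Wallis H", 0,
                       df = nlevels(groups) - 1L, p_value = 1))
  }
  H <- H / correction
  df <- nlevels(groups) - 1L
  test_result("Kruskal-Wallis H", H, df = df,
              p_value = stats::pchisq(H, df, lower.tail = FALSE))
}

# two-sided two-sample Wilcoxon rank-sum p-value: exact (via the null
# Mann-Whitney distribution) for small untied samples, otherwise normal
# approximation with continuity correction and tie-adjusted variance
#' @keywords internal
rank_sum_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  if (!has_ties && n1 <= 20 && n2 <= 20) {
    if (U > n1 * n2 / 2) {
      p <- 2 * stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE)
    } else {
      p <- 2 * stats::pwilcox(U, n1, n2)
    }
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  N <- n1 + n2
  sigma2 <- n1 * n2 / 12 * (N + 1 - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 == 0) return(1)
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Pairwise Wilcoxon rank-sum tests with BH correction
#'
#' All pairwise two-sided rank-sum comparisons between groups, with
#' continuity-corrected normal approximation for larger or tied samples and
#' the exact null distribution otherwise. P-values are adjusted with the
#' Benjamini-Hochberg step-up procedure across the family of pairs.
#'
#' @param values numeric observations.
#' @param groups group labels.
#' @return data.frame `group1`, `group2`, `p_value`, `p_adjusted`.
#' @export
pairwise_wilcoxon_bh <- function(values, groups) {
  if (!is.factor(groups)) groups <- factor(groups)
  lev <- levels(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  counts <- table(groups)
  empty <- names(counts)[counts == 0]
  if (length(empty) > 0L) {
    warning("empty groups skipped: ", paste(empty, collapse = ", "))
    lev <- setdiff(lev, empty)
  }
  pairs <- utils::combn(lev, 2L)
  p <- apply(pairs, 2L, function(pr) {
    rank_sum_p(values[groups == pr[1L]], values[groups == pr[2L]])
  })
  data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ], p_value = p,
             p_adjusted = stats::p.adjust(p, method = "BH"))
}

#' Regression of log10 abundance on a covariate
#'
#' Ordinary least squares of log10(abundance) on a covariate such as dietary
#' crude-fibre content or mean retention time. Zero or negative abundances
#' cannot be log-transformed and are excluded, with the count reported.
#'
#' @param x covariate.
#' @param y abundance (copies/g); must be positive to enter the fit.
#' @return `test_result` with `statistic` = slope, plus `r_squared`,
#'   `conf_int` (95% for the slope), `intercept`, `n_used`, `n_excluded`.
#' @export
log_abundance_regression <- function(x, y) {
  ok <- !is.na(x) & !is.na(y) & y > 0
  n_excluded <- sum(!ok)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 usable observations")
  fit <- stats::lm(log10(y) ~ x)
  sm <- suppressWarnings(summary(fit))  # exact fits trip summary.lm's alarm
  out <- test_result("OLS slope (log10 abundance)",
                     unname(stats::coef(fit)[2L]),
                     df = fit$df.residual,
                     p_value = sm$coefficients[2L, 4L])
  out$r_squared <- sm$r.squared
  out$intercept <- unname(stats::coef(fit)[1L])
  out$conf_int <- unname(suppressWarnings(stats::confint(fit))[2L, ])
  out$n_used <- length(x)
  out$n_excluded <- n_excluded
  out
}

#' Moving average over an ordered series
#'
#' Centred arithmetic mean over a window of `window` points; at the edges
#' the window truncates (shrinks) rather than padding. `mode = "trailing"`
#' averages the current point and the `window - 1` before it instead.
#'
#' @param values numeric series, already ordered by the key of interest.
#' @param window window size in points (>= 1, <= length of series).
#' @param mode `"centered"` (default) or `"trailing"`.
#' @return numeric vector of smoothed values, same length.
#' @export
moving_average <- function(values, window = 25,
                           mode = c("centered", "trailing")) {
  mode <- match.arg(mode)
  n <- length(values)
  if (n == 0L) return(numeric(0))
  if (window < 1 || window > n) stop("window must be in [1, length(values)]")
  half <- (window - 1) %/% 2
  vapply(seq_len(n), function(i) {
    rng <- if (mode == "centered") {
      max(1L, i - half):min(n, i + (window - 1L - half))
    } else {
      max(1L, i - window + 1L):i
    }
    mean(values[rng])
  }, numeric(1))
}

#' Detection table across the three survey methods
#'
#' Per species, whether archaea were detected by qPCR with archaea-specific
#' primers, by sequencing with archaea-specific primers, and by sequencing
#' with prokaryote-universal primers; plus per-class detection rates per
#' method. Presence = any positive signal; a species missing a method is NA
#' for that cell.
#'
#' @param qpcr,archaea_seq,universal_seq named logical (or 0/1) vectors per
#'   species; `NA` = not assayed.
#' @param class optional named character of host classes for rate summaries.
#' @return list with `detections` (per-species data.frame) and `rates`
#'   (method x class proportion detected).
#' @export
detection_table <- function(qpcr, archaea_seq, universal_seq, class = NULL) {
  species <- sort(unique(c(names(qpcr), names(archaea_seq),
                           names(universal_seq))))
  get <- function(v) {
    out <- as.logical(v[species]); names(out) <- species; out
  }
  det <- data.frame(species = species,
                    qpcr = get(qpcr),
                    archaea_seq = get(archaea_seq),
                    universal_seq = get(universal_seq),
                    row.names = NULL)
  det$detected_any <- apply(det[, c("qpcr", "archaea_seq", "universal_seq")],
                            1L, function(v) any(v, na.rm = TRUE) &&
                              !all(is.na(v)))
  rates <- NULL
  grp <- if (is.null(class)) rep("all", length(species)) else class[species]
  rates <- sapply(split(seq_along(species), grp), function(idx) {
    colMeans(det[idx, c("qpcr", "archaea_seq", "universal_seq")],
             na.rm = TRUE)
  })
  list(detections = det, rates = as.matrix(rates))
}
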