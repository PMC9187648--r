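test_that("PERMANOVA separates clusters and matches vegan's statistic", {
  set.seed(2)
  x <- rbind(matrix(rnorm(40, 0), ncol = 4),
             matrix(rnorm(40, 5), ncol = 4))
  rownames(x) <- paste0("s", 1:20)
  grp <- rep(c("a", "b"), each = 10)
  d <- as.matrix(dist(x))
  res <- permanova(d, grp, n_perm = 199, seed = 1)
  expect_gt(res$r_squared, 0.8)
  expect_equal(res$p_value, 1 / 200)
  expect_true(res$r_squared >= 0 && res$r_squared <= 1)
  skip_if_not_installed("vegan")
  ref <- vegan::adonis2(as.dist(d) ~ grp, permutations = 29)
  expect_equal(res$statistic, ref$F[1], tolerance = 1e-9)
  expect_equal(res$r_squared, ref$R2[1], tolerance = 1e-9)
})

test_that("PERMANOVA handles covariates and rejects degenerate input", {
  set.seed(4)
  cov <- rnorm(12)
  x <- cbind(cov * 2 + rnorm(12, 0, 0.1), rnorm(12))
  d <- as.matrix(dist(x))
  res <- permanova(d, cov, n_perm = 199, seed = 2)
  expect_lt(res$p_value, 0.05)
  expect_error(permanova(d, rep("a", 12)), "2 groups")
  expect_error(permanova(d, rep("a", 5)), "length")
})

test_that("Mantel statistic is the off-diagonal Pearson r", {
  set.seed(6)
  x <- matrix(rnorm(20), ncol = 2)
  d1 <- as.matrix(dist(x))
  rownames(d1) <- colnames(d1) <- paste0("s", 1:10)
  d2 <- 2 * d1
  res <- mantel_test(d1, d2, n_perm = 99, seed = 1)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_true(abs(res$statistic) <= 1)
  expect_error(mantel_test(d1, d1[1:5, 1:5]), "size")
  skip_if_not_installed("vegan")
  d3 <- as.matrix(dist(matrix(rnorm(20), ncol = 2)))
  rownames(d3) <- colnames(d3) <- paste0("s", 1:10)
  ref <- vegan::mantel(d1, d3, permutations = 29)
  got <- mantel_test(d1, d3, n_perm = 99, seed = 1)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-9)
})

test_that("Moran's I finds phylogenetic signal and matches ape", {
  # six-leaf tree with two deep clades; a clade indicator trait maximises I
  tree <- ape::read.tree(
    text = "((A:1,(B:0.5,C:0.5):0.5):3,((D:0.5,E:0.5):0.5,F:1):3);")
  vals <- c(A = 10, B = 11, C = 10.5, D = 0, E = 0.5, F = 0.2)
  res <- morans_i(vals, tree = tree, n_perm = 199, seed = 1)
  expect_gt(res$statistic, 0.5)
  expect_lt(res$p_value, 0.1)
  expect_equal(res$expectation, -1 / 5)
  expect_error(morans_i(c(A = 1, B = 1, C = 1), tree = tree), "constant")
  # same weights, same statistic as ape's implementation
  d <- cophenetic_from_tree(tree)
  w <- 1 / d; diag(w) <- 0
  w_std <- w / rowSums(w)
  ref <- ape::Moran.I(vals[rownames(d)], w_std, scaled = FALSE)
  got <- morans_i(vals, weights = w_std, n_perm = 99, seed = 1)
  expect_equal(got$statistic, ref$observed, tolerance = 1e-9)
})

test_that("Kruskal-Wallis reproduces classical and tie-corrected values", {
  # no ties: {1,2,3} vs {4,5,6} gives H = 3.857
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-9)
  # heavy ties: must agree with the reference implementation exactly
  vals <- c(rep(1, 192), rep(0, 58), rep(1, 175), rep(0, 75),
            rep(1, 115), rep(0, 135))
  grp <- rep(1:3, each = 250)
  res2 <- kruskal_wallis(vals, grp)
  ref <- kruskal.test(vals, grp)
  expect_equal(res2$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res2$p_value, ref$p.value, tolerance = 1e-12)
  # identical observations: H = 0, p = 1
  res3 <- kruskal_wallis(rep(5, 10), rep(c("a", "b"), 5))
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
})

test_that("pairwise Wilcoxon p-values match stats and BH never lowers them", {
  set.seed(12)
  x <- rnorm(10); y <- rnorm(10) + 3; z <- rnorm(10)
  vals <- c(x, y, z); grp <- rep(c("x", "y", "z"), each = 10)
  out <- pairwise_wilcoxon_bh(vals, grp)
  expect_true(all(out$p_adjusted >= out$p_value - 1e-15))
  # exact small-sample branch agrees with wilcox.test
  ref <- wilcox.test(x, y)$p.value
  expect_equal(out$p_value[out$group1 == "x" & out$group2 == "y"], ref,
               tolerance = 1e-12)
  # tied / large-sample branch agrees with the continuity-corrected normal
  set.seed(13)
  a <- round(rnorm(30), 1); b <- round(rnorm(30, 0.5), 1)
  ref2 <- suppressWarnings(wilcox.test(a, b)$p.value)
  got2 <- pairwise_wilcoxon_bh(c(a, b), rep(c("a", "b"), each = 30))
  expect_equal(got2$p_value, ref2, tolerance = 1e-12)
  # identical groups: adjusted p = 1
  same <- pairwise_wilcoxon_bh(rep(c(1, 2, 3), 2), rep(c("g", "h"), each = 3))
  expect_equal(same$p_adjusted, 1)
  # shifted normals at delta = 2 sd, n = 30/30: clearly detected
  set.seed(14)
  p <- pairwise_wilcoxon_bh(c(rnorm(30), rnorm(30, 2)),
                            rep(c("lo", "hi"), each = 30))
  expect_lt(p$p_adjusted, 0.05)
  expect_warning(
    pairwise_wilcoxon_bh(c(1, 2, 3), factor(c("a", "a", "b"),
                                            levels = c("a", "b", "c"))),
    "empty groups")
})

test_that("log-abundance regression recovers exact lines and excludes zeros", {
  x <- 1:10
  y <- 10^(2 + 0.3 * x)
  res <- log_abundance_regression(x, y)
  expect_equal(res$statistic, 0.3, tolerance = 1e-12)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_equal(res$intercept, 2, tolerance = 1e-12)
  y2 <- c(y[1:8], 0, -5)
  res2 <- log_abundance_regression(x, y2)
  expect_equal(res2$n_excluded, 2)
  expect_equal(res2$n_used, 8)
  expect_error(log_abundance_regression(1:3, c(0, 0, 1)), "3 usable")
})

test_that("moving averages smooth with truncated or trailing windows", {
  expect_equal(moving_average(rep(4, 10), 5), rep(4, 10))
  lin <- moving_average(1:10, 5)
  expect_equal(lin[3:8], 3:8)  # symmetric window on a line is unchanged
  # with the window spanning the whole series, the centre point sees all of it
  expect_equal(moving_average(1:7, 7)[4], mean(1:7))
  expect_equal(moving_average(numeric(0), 1), numeric(0))
  trail <- moving_average(c(1, 2, 3, 4), 2, mode = "trailing")
  expect_equal(trail, c(1, 1.5, 2.5, 3.5))
  expect_error(moving_average(1:3, 4), "window")
})

test_that("detection tables combine methods and summarise by class", {
  qpcr <- c(sp1 = TRUE, sp2 = TRUE, sp3 = FALSE)
  aseq <- c(sp1 = TRUE, sp2 = TRUE, sp3 = FALSE)
  useq <- c(sp1 = FALSE, sp2 = TRUE)
  out <- detection_table(qpcr, aseq, useq,
                         class = c(sp1 = "Mammalia", sp2 = "Mammalia",
                                   sp3 = "Aves"))
  det <- out$detections
  expect_true(det$detected_any[det$species == "sp1"])   # universal missed it
  expect_false(det$universal_seq[det$species == "sp1"])
  expect_false(det$detected_any[det$species == "sp3"])
  expect_true(is.na(det$universal_seq[det$species == "sp3"]))
  expect_equal(out$rates["qpcr", "Mammalia"], 1)
  expect_equal(out$rates["qpcr", "Aves"], 0)
})

test_that("universal primers under-detect archaea in the default scenario", {
  sc <- synthetic_scenario(n_species = 60, seed = 31)
  ds <- generate_dataset(sc)
  arch_cols <- grepl("^ASV", taxon_ids(ds$tables$universal))
  uni_det <- rowSums(unclass(ds$tables$universal)[, arch_cols]) > 0
  arch_det <- sample_totals(ds$tables$archaea_specific) > 0
  out <- detection_table(qpcr = arch_det, archaea_seq = arch_det,
                         universal_seq = uni_det)
  rates <- out$rates[, "all"]
  expect_lt(rates[["universal_seq"]], rates[["archaea_seq"]])
})
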