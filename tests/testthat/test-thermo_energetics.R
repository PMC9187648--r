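# independent oracle: hand-summed nu * dG0f straight from the bundled CSV,
# bypassing the pathway machinery
oracle_dg0 <- function() {
  tab <- read.csv(system.file("extdata", "formation_energies.csv",
                              package = "gutarchaeome"))
  g <- setNames(tab$dg0f_kj_mol, paste(tab$species, tab$phase, sep = "."))
  c(methyl_dismutation = unname(g["CH4.g"] + g["CO2.g"] / 3 +
                                  2 * g["H2O.l"] / 3 - 4 * g["methanol.aq"] / 3),
    methyl_reduction = unname(g["CH4.g"] + g["H2O.l"] - g["methanol.aq"] -
                                g["H2.g"]),
    co2_reduction = unname(g["CH4.g"] + 2 * g["H2O.l"] - g["CO2.g"] -
                             4 * g["H2.g"]))
}

test_that("standard Gibbs energies match the hand-summed oracle", {
  ora <- oracle_dg0()
  pw <- methanogenesis_pathways()
  for (nm in names(pw)) {
    expect_equal(delta_g_standard(pw[[nm]]), ora[[nm]], tolerance = 1e-12)
  }
  # magnitude anchors for the bundled Thauer-style table
  expect_equal(ora[["co2_reduction"]], -130.75, tolerance = 1e-9)
  expect_equal(ora[["methyl_reduction"]], -112.53, tolerance = 1e-9)
  # stoichiometric identity 3x(1) = 4x(2) - (3), exactly
  expect_equal(3 * ora[["methyl_dismutation"]],
               4 * ora[["methyl_reduction"]] - ora[["co2_reduction"]],
               tolerance = 1e-12)
})

test_that("pathways are elementally balanced and normalised per mole CH4", {
  for (pw in methanogenesis_pathways()) {
    expect_true(all(gutarchaeome:::elemental_balance(pw) == 0))
    st <- pw$stoich
    expect_equal(st$num[st$species == "CH4"] / st$den[st$species == "CH4"], 1)
  }
  err_tab <- read_formation_energies()
  err_tab <- err_tab[err_tab$species != "CH4", ]
  class(err_tab) <- c("formation_energy_table", "data.frame")
  expect_error(delta_g_standard(methanogenesis_pathway("co2_reduction"),
                                err_tab),
               "CH4")
})

test_that("dG reduces to dG0 at unit activities and follows RT ln Q", {
  pw <- methanogenesis_pathways()
  unit <- thermo_state(1, 1, p_co2 = 1, p_ch4 = 1)
  for (nm in names(pw)) {
    expect_equal(delta_g(pw[[nm]], unit), delta_g_standard(pw[[nm]]),
                 tolerance = 1e-12)
  }
  # CO2 reduction at p(H2) = 1e-4, p(CO2) = p(CH4) = 0.1:
  # Q = p_ch4 / (p_co2 * p_h2^4) = 10^16, so dG = dG0 + RT ln 10^16
  st <- thermo_state(1e-4, 1e-4)
  expect_equal(delta_g(pw$co2_reduction, st),
               delta_g_standard(pw$co2_reduction) +
                 8.314e-3 * 298.15 * log(10^16),
               tolerance = 1e-9)
})

test_that("dG is blind to H2 for dismutation and to pH for all pathways", {
  pw <- methanogenesis_pathways()
  a <- thermo_state(1e-5, 1e-7)
  b <- thermo_state(1e-5, 1)
  expect_equal(delta_g(pw$methyl_dismutation, a),
               delta_g(pw$methyl_dismutation, b), tolerance = 1e-12)
  ph_a <- thermo_state(1e-5, 1e-3, pH = 2)
  ph_b <- thermo_state(1e-5, 1e-3, pH = 12)
  for (nm in names(pw)) {
    expect_equal(delta_g(pw[[nm]], ph_a), delta_g(pw[[nm]], ph_b),
                 tolerance = 1e-12)
  }
})

test_that("log-derivatives of dG match the analytic quotient slopes", {
  pw <- methanogenesis_pathways()
  RT <- 8.314e-3 * 298.15
  h <- 1e-6
  base <- list(c = 1e-5, p = 1e-3)
  fd <- function(pathway, var) {
    up <- base; dn <- base
    up[[var]] <- up[[var]] * exp(h); dn[[var]] <- dn[[var]] * exp(-h)
    (delta_g(pathway, thermo_state(up$c, up$p)) -
       delta_g(pathway, thermo_state(dn$c, dn$p))) / (2 * h)
  }
  # d dG / d ln p(H2): 0, -RT, -4RT
  expect_equal(fd(pw$methyl_dismutation, "p"), 0, tolerance = 1e-9)
  expect_equal(fd(pw$methyl_reduction, "p"), -RT, tolerance = 1e-6 * RT)
  expect_equal(fd(pw$co2_reduction, "p"), -4 * RT, tolerance = 1e-6 * RT)
  # d dG / d ln C(methanol): -4/3 RT, -RT, 0
  expect_equal(fd(pw$methyl_dismutation, "c"), -4 / 3 * RT,
               tolerance = 1e-6 * RT)
  expect_equal(fd(pw$methyl_reduction, "c"), -RT, tolerance = 1e-6 * RT)
  expect_equal(fd(pw$co2_reduction, "c"), 0, tolerance = 1e-9)
})

test_that("state classification finds the documented dominance corners", {
  # high methanol, very low H2: dismutation wins
  expect_equal(classify_state(thermo_state(1e-3, 1e-7))$dominant,
               "methyl_dismutation")
  # low methanol, H2 at 1 bar: CO2 reduction wins (brute-force argmin)
  cl <- classify_state(thermo_state(1e-7, 1))
  expect_equal(cl$dominant, "co2_reduction")
  expect_equal(cl$dominant, names(cl$dg)[which.min(cl$dg)])
  expect_error(classify_state(thermo_state(1e-5, 1e-3), threshold = -1),
               "threshold")
})

test_that("dominance map labels are consistent and threshold-monotone", {
  map <- build_dominance_map(n_c = 41, n_p = 41)
  expect_lte(max(abs(3 * map$dg1 - (4 * map$dg2 - map$dg3))), 1e-9)
  # corner labels at the default window
  expect_equal(map$label[41, 1], "methyl_dismutation")  # high MeOH, low H2
  expect_equal(map$label[1, 41], "co2_reduction")       # low MeOH, 1 bar H2
  # every cell's label equals the threshold rule applied to its dG triple
  dg <- cbind(methyl_dismutation = as.vector(map$dg1),
              methyl_reduction = as.vector(map$dg2),
              co2_reduction = as.vector(map$dg3))
  relab <- apply(dg, 1, function(v)
    paste(colnames(dg)[v <= min(v) + map$threshold], collapse = "+"))
  expect_identical(as.vector(map$label), relab)
  # shrinking the threshold shrinks comparable sets
  small <- build_dominance_map(n_c = 41, n_p = 41, threshold = 2)
  multi_small <- grepl("+", small$label, fixed = TRUE)
  multi_big <- grepl("+", map$label, fixed = TRUE)
  expect_true(all(multi_big[multi_small]))
  expect_error(build_dominance_map(n_c = 1), "resolution")
  expect_error(build_dominance_map(log10_c_range = c(-5, -5)), "degenerate")
})

test_that("the equal-dG contour is a +3-slope line where all dG agree", {
  map <- build_dominance_map(n_c = 81, n_p = 81)
  ct <- equal_dg_contour(map)
  expect_gt(nrow(ct), 5)
  # on the contour all three pathways agree to interpolation tolerance
  pw <- methanogenesis_pathways()
  for (k in seq_len(min(nrow(ct), 10))) {
    st <- thermo_state(10^ct$log10_c_methanol[k], 10^ct$log10_p_h2[k])
    dg <- vapply(pw, delta_g, numeric(1), state = st)
    expect_lt(max(dg) - min(dg), 0.05)
  }
  fit <- lm(log10_c_methanol ~ log10_p_h2, data = ct)
  expect_equal(unname(coef(fit)[2]), 3, tolerance = 1e-6)
  # widening the window keeps existing contour points (locality)
  wide <- equal_dg_contour(build_dominance_map(log10_c_range = c(-8, -2),
                                               log10_p_range = c(-8, 1),
                                               n_c = 101, n_p = 91))
  shared_p <- intersect(round(ct$log10_p_h2, 9), round(wide$log10_p_h2, 9))
  expect_gt(length(shared_p), 0)
  # a contour entirely outside the window is empty
  off <- build_dominance_map(log10_c_range = c(-3.2, -3),
                             log10_p_range = c(-7, -6.8),
                             n_c = 5, n_p = 5)
  expect_equal(nrow(equal_dg_contour(off)), 0)
})

test_that("environment observations are placed, clipped and classified", {
  map <- build_dominance_map(n_c = 21, n_p = 21)
  obs <- data.frame(label = c("rumen", "marine_sediment"),
                    c_methanol = c(1e-5, 1e-3),
                    p_h2 = c(1e-3, 1e-7))
  pts <- map_environment_points(map, obs)
  # a point at a grid node keeps node coordinates
  expect_equal(pts$log10_c_methanol[1], -5)
  expect_equal(pts$log10_p_h2[1], -3)
  # the high-methanol/low-H2 observation is dismutation-favoured
  expect_equal(pts$dominant[2], "methyl_dismutation")
  obs_bad <- data.frame(label = "x", c_methanol = 1e-5, p_h2 = 1e-3,
                        p_h2_min = 1e-2, p_h2_max = 1e-3)
  expect_error(map_environment_points(map, obs_bad), "min exceeds max")
  obs_out <- data.frame(label = "y", c_methanol = 1e-2, p_h2 = 1e-3)
  expect_warning(map_environment_points(map, obs_out), "clipped")
})
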