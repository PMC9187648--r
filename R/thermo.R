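#' Methanogenesis pathway specifications
#'
#' The three catabolisms compared on the dominance map, written per mole of
#' CH4 produced (reactant coefficients negative):
#'
#' * `methyl_dismutation`: 4/3 CH3OH -> CH4 + 1/3 CO2 + 2/3 H2O
#' * `methyl_reduction`:   CH3OH + H2 -> CH4 + H2O
#' * `co2_reduction`:      CO2 + 4 H2 -> CH4 + 2 H2O
#'
#' Stoichiometric coefficients are stored as exact integer ratios
#' (numerator, denominator) so the elemental balance and the linear identity
#' 3 x (dismutation) = 4 x (methyl reduction) - (CO2 reduction) are exact;
#' they are evaluated in floating point.
#'
#' @param name one of `"methyl_dismutation"`, `"methyl_reduction"`,
#'   `"co2_reduction"`; `methanogenesis_pathways()` returns all three.
#' @return a `pathway_spec`: list with `name` and a data.frame `stoich`
#'   (columns `species`, `phase`, `num`, `den`).
#' @export
methanogenesis_pathway <- function(name = c("methyl_dismutation",
                                            "methyl_reduction",
                                            "co2_reduction")) {
  name <- match.arg(name)
  st <- switch(name,
    methyl_dismutation = data.frame(
      species = c("methanol", "CH4", "CO2", "H2O"),
      phase   = c("aq", "g", "g", "l"),
      num     = c(-4L, 1L, 1L, 2L),
      den     = c(3L, 1L, 3L, 3L)),
    methyl_reduction = data.frame(
      species = c("methanol", "H2", "CH4", "H2O"),
      phase   = c("aq", "g", "g", "l"),
      num     = c(-1L, -1L, 1L, 1L),
      den     = c(1L, 1L, 1L, 1L)),
    co2_reduction = data.frame(
      species = c("CO2", "H2", "CH4", "H2O"),
      phase   = c("g", "g", "g", "l"),
      num     = c(-1L, -4L, 1L, 2L),
      den     = c(1L, 1L, 1L, 1L)))
  spec <- structure(list(name = name, stoich = st), class = "pathway_spec")
  stopifnot(all(elemental_balance(spec) == 0))
  spec
}

#' @rdname methanogenesis_pathway
#' @export
methanogenesis_pathways <- function() {
  nm <- c("methyl_dismutation", "methyl_reduction", "co2_reduction")
  stats::setNames(lapply(nm, methanogenesis_pathway), nm)
}

# exact integer element balance (per 3 moles CH4 so thirds clear); a balanced
# reaction returns c(C = 0, H = 0, O = 0)
#' @keywords internal
elemental_balance <- function(pathway) {
  comp <- list(methanol = c(C = 1L, H = 4L, O = 1L),
               H2  = c(C = 0L, H = 2L, O = 0L),
               CO2 = c(C = 1L, H = 0L, O = 2L),
               CH4 = c(C = 1L, H = 4L, O = 0L),
               H2O = c(C = 0L, H = 2L, O = 1L))
  st <- pathway$stoich
  scaled <- st$num * (3L %/% st$den)  # dens are 1 or 3: exact
  bal <- c(C = 0L, H = 0L, O = 0L)
  for (i in seq_len(nrow(st))) bal <- bal + scaled[i] * comp[[st$species[i]]]
  bal
}

#' Read a standard Gibbs formation-energy table
#'
#' CSV with columns `species`, `phase`, `dg0f_kj_mol` and `source`, giving
#' standard Gibbs energies of formation at 298.15 K (kJ/mol; aqueous species
#' at 1 mol/l, gases at 1 bar, water as pure liquid). A curated table with
#' the five species needed by the methanogenesis pathways ships with the
#' package and is the default.
#'
#' @param path CSV path; default the bundled table.
#' @return `formation_energy_table` data.frame.
#' @export
read_formation_energies <- function(path = system.file("extdata",
                                                       "formation_energies.csv",
                                                       package = "gutarchaeome")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "phase", "dg0f_kj_mol", "source")
  if (!all(need %in% names(tab)))
    stop("formation-energy CSV needs columns: ", paste(need, collapse = ", "))
  required <- c("methanol.aq", "H2.g", "CO2.g", "CH4.g", "H2O.l")
  have <- paste(tab$species, tab$phase, sep = ".")
  if (anyDuplicated(have)) stop("duplicate species+phase in table")
  missing <- setdiff(required, have)
  if (length(missing) > 0L)
    stop("formation-energy table missing: ", paste(missing, collapse = ", "))
  class(tab) <- c("formation_energy_table", "data.frame")
  tab
}

#' A point in thermodynamic state space
#'
#' Defaults follow the gut-relevant reference conditions: T = 298.15 K,
#' p(CO2) = p(CH4) = 0.1 bar, pH 7, unit water activity. The reactions as
#' written contain no protons, so pH does not enter the reaction quotient;
#' it is carried for provenance only.
#'
#' @param c_methanol methanol concentration, mol/l.
#' @param p_h2 hydrogen partial pressure, bar.
#' @param T_K temperature, K.
#' @param p_co2,p_ch4 partial pressures, bar.
#' @param pH dimensionless (inert here).
#' @return `thermo_state` list.
#' @export
thermo_state <- function(c_methanol, p_h2, T_K = 298.15,
                         p_co2 = 0.1, p_ch4 = 0.1, pH = 7) {
  vals <- c(c_methanol = c_methanol, p_h2 = p_h2, T_K = T_K,
            p_co2 = p_co2, p_ch4 = p_ch4)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("temperature, concentrations and pressures must be positive")
  structure(list(c_methanol = c_methanol, p_h2 = p_h2, T_K = T_K,
                 p_co2 = p_co2, p_ch4 = p_ch4, pH = pH, a_h2o = 1),
            class = "thermo_state")
}

R_GAS_KJ <- 8.314e-3  # kJ / (mol K)

#' Standard-state Gibbs energy of a pathway
#'
#' Sum of nu * dG0f over the reaction, per mole CH4. State-independent.
#'
#' @param pathway a [methanogenesis_pathway()].
#' @param table a [read_formation_energies()] table.
#' @return kJ per mol CH4.
#' @export
delta_g_standard <- function(pathway, table = read_formation_energies()) {
  st <- pathway$stoich
  key <- paste(st$species, st$phase, sep = ".")
  idx <- match(key, paste(table$species, table$phase, sep = "."))
  if (anyNA(idx))
    stop("species missing from formation-energy table: ",
         paste(key[is.na(idx)], collapse = ", "))
  sum((st$num / st$den) * table$dg0f_kj_mol[idx])
}

# activity of one reaction participant under the ideal (unit activity
# coefficient) convention: aqueous vs 1 mol/l, gas vs 1 bar, liquid water 1
#' @keywords internal
species_activity <- function(species, phase, state) {
  if (phase == "l") return(state$a_h2o)
  switch(species,
         methanol = state$c_methanol,
         H2  = state$p_h2,
         CO2 = state$p_co2,
         CH4 = state$p_ch4,
         stop("no activity rule for species ", species))
}

#' Gibbs energy of a pathway at a state
#'
#' dG = dG0 + R T ln Q with Q the activity quotient of the reaction as
#' written (per mole CH4).
#'
#' @inheritParams delta_g_standard
#' @param state a [thermo_state()]. `c_methanol` and `p_h2` may be vectors of
#'   equal length for vectorised grid evaluation.
#' @return kJ per mol CH4 (vectorised over the state's methanol/H2 entries).
#' @export
delta_g <- function(pathway, state, table = read_formation_energies()) {
  dg0 <- delta_g_standard(pathway, table)
  st <- pathway$stoich
  lnQ <- 0
  for (i in seq_len(nrow(st))) {
    a <- species_activity(st$species[i], st$phase[i], state)
    if (any(a <= 0)) stop("nonpositive activity for ", st$species[i])
    lnQ <- lnQ + (st$num[i] / st$den[i]) * log(a)
  }
  dg0 + R_GAS_KJ * state$T_K * lnQ
}

#' Rank pathways by energy yield at one state
#'
#' The dominant pathway is the one with the lowest (most negative) dG per
#' mole CH4; every pathway within `threshold` kJ of that minimum is reported
#' as comparable to it.
#'
#' @param state a [thermo_state()].
#' @param table formation energies.
#' @param threshold comparability band, kJ/mol CH4 (default 10).
#' @return list with `dg` (named numeric, all three pathways), `dominant`
#'   (name of the argmin) and `comparable` (names within the band, always
#'   including the dominant one).
#' @export
classify_state <- function(state, table = read_formation_energies(),
                           threshold = 10) {
  if (threshold <= 0) stop("threshold must be > 0")
  dg <- vapply(methanogenesis_pathways(), delta_g, numeric(1),
               state = state, table = table)
  dominant <- names(dg)[which.min(dg)]
  list(dg = dg, dominant = dominant,
       comparable = names(dg)[dg <= min(dg) + threshold])
}

#' Build the pathway-dominance map
#'
#' Evaluates all three pathway dG values over a log10-spaced grid of methanol
#' concentration and hydrogen partial pressure (all other state variables at
#' their defaults) and labels each cell with the dominant pathway, or with
#' the `+`-joined comparable set when competitors fall within `threshold`
#' kJ/mol CH4 of the minimum. The default grid covers the gut-to-sediment
#' range C(methanol) 1e-7..1e-3 mol/l and p(H2) 1e-7..1 bar at 141 x 141
#' resolution.
#'
#' @param log10_c_range,log10_p_range numeric length-2, log10 axis limits.
#' @param n_c,n_p grid resolution per axis (>= 2).
#' @param state_defaults a [thermo_state()] providing T, p(CO2), p(CH4), pH.
#' @param table formation energies.
#' @param threshold comparability band, kJ/mol CH4.
#' @return `dominance_map`: list with axes `log10_c`, `log10_p`, matrices
#'   `dg1`, `dg2`, `dg3` (dismutation, methyl reduction, CO2 reduction;
#'   methanol on rows, H2 on columns), character matrix `label`, and the
#'   threshold.
#' @export
build_dominance_map <- function(log10_c_range = c(-7, -3),
                                log10_p_range = c(-7, 0),
                                n_c = 141, n_p = 141,
                                state_defaults = thermo_state(1e-4, 1e-4),
                                table = read_formation_energies(),
                                threshold = 10) {
  if (n_c < 2 || n_p < 2) stop("grid resolution must be at least 2 x 2")
  if (diff(log10_c_range) == 0 || diff(log10_p_range) == 0)
    stop("degenerate grid axis")
  log10_c <- seq(log10_c_range[1], log10_c_range[2], length.out = n_c)
  log10_p <- seq(log10_p_range[1], log10_p_range[2], length.out = n_p)
  grid <- expand.grid(c = 10^log10_c, p = 10^log10_p)
  st <- state_defaults
  st$c_methanol <- grid$c
  st$p_h2 <- grid$p
  pw <- methanogenesis_pathways()
  dg <- vapply(pw, delta_g, numeric(nrow(grid)), state = st, table = table)
  lab <- apply(dg, 1L, function(v) {
    comp <- colnames(dg)[v <= min(v) + threshold]
    paste(comp, collapse = "+")
  })
  dim_nm <- list(NULL, NULL)
  shape <- function(x) matrix(x, nrow = n_c, ncol = n_p, dimnames = dim_nm)
  structure(list(log10_c = log10_c, log10_p = log10_p,
                 dg1 = shape(dg[, "methyl_dismutation"]),
                 dg2 = shape(dg[, "methyl_reduction"]),
                 dg3 = shape(dg[, "co2_reduction"]),
                 label = shape(lab), threshold = threshold,
                 state_defaults = state_defaults),
            class = "dominance_map")
}

#' Equal-energy contour of the dominance map
#'
#' The locus where all three pathways yield exactly the same dG per mole of
#' CH4. Because 3 x (dismutation) = 4 x (methyl reduction) - (CO2 reduction)
#' stoichiometrically, dG2 = dG3 implies dG1 equals both, so the contour is
#' the zero set of dG2 - dG3, located by linear interpolation along the
#' methanol axis for each H2 grid line. In these log-log coordinates it is a
#' straight line of slope dlog10(C)/dlog10(p(H2)) = +3: each extra decade of
#' hydrogen pressure needs three more decades of methanol to keep methyl
#' reduction and CO2 reduction equally favourable.
#'
#' @param map a [build_dominance_map()].
#' @return data.frame `log10_c_methanol`, `log10_p_h2`; zero rows when the
#'   contour does not cross the grid window.
#' @export
equal_dg_contour <- function(map) {
  f <- map$dg2 - map$dg3  # rows: methanol, cols: H2
  pts_c <- numeric(0); pts_p <- numeric(0)
  for (j in seq_along(map$log10_p)) {
    col <- f[, j]
    s <- which(col[-length(col)] * col[-1L] <= 0 &
               (col[-length(col)] != 0 | col[-1L] != 0))
    for (i in s) {
      frac <- col[i] / (col[i] - col[i + 1L])
      pts_c <- c(pts_c, map$log10_c[i] +
                   frac * (map$log10_c[i + 1L] - map$log10_c[i]))
      pts_p <- c(pts_p, map$log10_p[j])
    }
    if (any(col == 0)) {
      k <- which(col == 0)
      pts_c <- c(pts_c, map$log10_c[k])
      pts_p <- c(pts_p, rep(map$log10_p[j], length(k)))
    }
  }
  out <- unique(data.frame(log10_c_methanol = pts_c, log10_p_h2 = pts_p))
  out[order(out$log10_p_h2), , drop = FALSE]
}

#' Place literature environment observations on the map
#'
#' Each observation carries a methanol concentration and hydrogen partial
#' pressure (mean plus min/max range), e.g. rumen, human colon, cockroach
#' hindgut or marine sediment measurements. Observations are located in the
#' map's log10 coordinates (clipped to the grid window with a warning) and
#' classified by dominant pathway at their mean state.
#'
#' @param map a [build_dominance_map()].
#' @param observations data.frame with columns `label`, `c_methanol`,
#'   `p_h2` and optional `c_methanol_min`, `c_methanol_max`, `p_h2_min`,
#'   `p_h2_max` (linear units).
#' @param table formation energies.
#' @return data.frame of log10 coordinates, range bars and the dominant
#'   pathway at the mean.
#' @export
map_environment_points <- function(map, observations,
                                   table = read_formation_energies()) {
  obs <- observations
  need <- c("label", "c_methanol", "p_h2")
  if (!all(need %in% names(obs)))
    stop("observations need columns: ", paste(need, collapse = ", "))
  for (v in c("c_methanol", "p_h2")) {
    lo <- paste0(v, "_min"); hi <- paste0(v, "_max")
    if (!lo %in% names(obs)) obs[[lo]] <- obs[[v]]
    if (!hi %in% names(obs)) obs[[hi]] <- obs[[v]]
    if (any(obs[[lo]] > obs[[hi]]))
      stop("min exceeds max in observation ranges for ", v)
    if (any(obs[[v]] <= 0 | obs[[lo]] <= 0)) stop("observations must be positive")
  }
  clip <- function(x, rng) pmin(pmax(x, rng[1]), rng[2])
  crng <- range(map$log10_c); prng <- range(map$log10_p)
  lc <- log10(obs$c_methanol); lp <- log10(obs$p_h2)
  if (any(lc < crng[1] | lc > crng[2] | lp < prng[1] | lp > prng[2]))
    warning("observations outside the grid window were clipped")
  dominant <- vapply(seq_len(nrow(obs)), function(i) {
    st <- map$state_defaults
    st$c_methanol <- obs$c_methanol[i]; st$p_h2 <- obs$p_h2[i]
    classify_state(st, table, map$threshold)$dominant
  }, character(1))
  data.frame(label = obs$label,
             log10_c_methanol = clip(lc, crng),
             log10_p_h2 = clip(lp, prng),
             log10_c_min = clip(log10(obs$c_methanol_min), crng),
             log10_c_max = clip(log10(obs$c_methanol_max), crng),
             log10_p_min = clip(log10(obs$p_h2_min), prng),
             log10_p_max = clip(log10(obs$p_h2_max), prng),
             dominant = dominant)
}
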