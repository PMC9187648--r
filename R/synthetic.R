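DIET_TYPES <- c("herbivore", "frugivore", "carnivore", "insectivore",
                "omnivore")

# archaeal lineage pool the generator draws communities from: baseline share
# of the methanogen community, metabolism class, and how many ASVs the
# lineage is split into in the amplicon tables
ARCHAEAL_LINEAGES <- data.frame(
  lineage = c("Methanobrevibacter", "Methanosphaera",
              "Methanomethylophilaceae", "Methanocorpusculum",
              "Methanimicrococcus", "Methanosarcina"),
  qpcr_target = c("Methanobacteriales", "Methanobacteriales",
                  "Methanomassiliicoccales", "Methanomicrobiales",
                  "Methanimicrococcus", NA),
  metabolism = c("co2_reducing", "methyl_reducing", "methyl_reducing",
                 "co2_reducing", "methyl_reducing", "mixed"),
  base_share = c(0.45, 0.10, 0.20, 0.15, 0.08, 0.02),
  n_asv = c(8L, 3L, 6L, 4L, 3L, 2L),
  taxonomy = c(
    "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobrevibacter",
    "Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanosphaera",
    "Archaea;Thermoplasmatota;Thermoplasmata;Methanomassiliicoccales;Methanomethylophilaceae;unknown",
    "Archaea;Euryarchaeota;Methanomicrobia;Methanomicrobiales;Methanocorpusculaceae;Methanocorpusculum",
    "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;Methanosarcinaceae;Methanimicrococcus",
    "Archaea;Euryarchaeota;Methanomicrobia;Methanosarcinales;Methanosarcinaceae;Methanosarcina"),
  stringsAsFactors = FALSE)

THAUM_TAXONOMY <- "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrososphaerales;Nitrososphaeraceae;unknown"

#' Define a synthetic gut-archaeome scenario
#'
#' A scenario fixes the study conditions the generator emulates: a host
#' cohort spanning diet types, a latent archaeal community whose methanogen
#' load rises with dietary fibre and saturates near 200 g crude fibre per kg
#' dry matter, an elevated methyl-reducer to CO2-reducer ratio in
#' frugivores, low and diet-independent Thaumarchaeota, paired
#' archaea-specific and universal amplicon libraries drawn from the same
#' community (the universal primers capturing archaea poorly), and
#' duplicate-run qPCR panels calibrated against 10-fold plasmid dilution
#' series.
#'
#' @param n_species number of host species (>= 2).
#' @param seed integer seed; all stages derive deterministic substreams.
#' @param depth_archaea,depth_universal reads per sample for the two
#'   libraries.
#' @param diet_mix named proportions over
#'   herbivore/frugivore/carnivore/insectivore/omnivore, summing to 1.
#' @param fibre_effect list `slope` (log10 copies per g/kg crude fibre) and
#'   `saturation` (g/kg at which the fibre response plateaus).
#' @param mrt_effect slope of log10 copies on log(mean retention time, h).
#' @param frugivore_methyl_boost multiplier on the methyl-reducer share of
#'   the methanogen community in frugivores (renormalised).
#' @param archaea_fraction_universal relative capture efficiency of archaeal
#'   templates by the universal primer set: the archaeal read mass in the
#'   universal library is this factor times the true archaea:bacteria copy
#'   ratio.
#' @param truth_sd biological scatter (sd of log10 copies) around the
#'   fibre/MRT model in the ground truth.
#' @param qpcr_noise_sd measurement noise (sd of log10 copies) per qPCR run;
#'   standard-curve points get Cq noise of `0.25 * qpcr_noise_sd` cycles.
#' @param efficiency qPCR amplification efficiency in (0.7, 1.1], recycled
#'   over targets.
#' @param baseline_log10_methanogens intercept of the fibre model (log10
#'   copies/g at zero fibre, log(MRT) centered at log(10) h).
#' @return `synthetic_scenario` list.
#' @export
synthetic_scenario <- function(n_species = 200,
                               seed = 1,
                               depth_archaea = 3000,
                               depth_universal = 10000,
                               diet_mix = c(herbivore = 0.30,
                                            frugivore = 0.20,
                                            carnivore = 0.20,
                                            insectivore = 0.10,
                                            omnivore = 0.20),
                               fibre_effect = list(slope = 0.005,
                                                   saturation = 200),
                               mrt_effect = 0.3,
                               frugivore_methyl_boost = 3,
                               archaea_fraction_universal = 0.5,
                               truth_sd = 0.4,
                               qpcr_noise_sd = 0.2,
                               efficiency = 0.95,
                               baseline_log10_methanogens = 6.5) {
  if (n_species < 2) stop("n_species must be >= 2")
  if (abs(sum(diet_mix) - 1) > 1e-9) stop("diet_mix must sum to 1")
  if (!all(names(diet_mix) %in% DIET_TYPES))
    stop("diet_mix names must be diet types")
  if (depth_archaea < 1 || depth_universal < 1) stop("depths must be >= 1")
  if (truth_sd < 0 || qpcr_noise_sd < 0) stop("sd must be >= 0")
  if (fibre_effect$saturation <= 0) stop("saturation point must be > 0")
  if (any(efficiency <= 0.7 | efficiency > 1.1))
    stop("efficiency must be in (0.7, 1.1]")
  structure(list(n_species = n_species, seed = seed,
                 depth_archaea = depth_archaea,
                 depth_universal = depth_universal,
                 diet_mix = diet_mix, fibre_effect = fibre_effect,
                 mrt_effect = mrt_effect,
                 frugivore_methyl_boost = frugivore_methyl_boost,
                 archaea_fraction_universal = archaea_fraction_universal,
                 truth_sd = truth_sd, qpcr_noise_sd = qpcr_noise_sd,
                 efficiency = efficiency,
                 baseline_log10_methanogens = baseline_log10_methanogens),
            class = "synthetic_scenario")
}

#' Generate a host cohort and phylogeny
#'
#' Hosts get a pure-birth (Yule, unit-rate) phylogeny, diet types drawn from
#' the scenario's diet mix, crude-fibre contents high for herbivores and low
#' for carnivores, mean retention times positively correlated with fibre,
#' log-normal body masses and a gut-differentiation coefficient rising with
#' fibre. Deterministic under the scenario seed.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list `metadata` ([host_metadata()]) and `tree` (`phylo`).
#' @export
generate_hosts <- function(scenario) {
  n <- scenario$n_species
  if (n < 2) stop("n_species must be >= 2")
  withr_seed(stage_seed(scenario$seed, 1), {
    tree <- ape::rphylo(n, birth = 1, death = 0)
    tree$tip.label <- sprintf("sp%03d", seq_len(n))
    diet <- sample(names(scenario$diet_mix), n, replace = TRUE,
                   prob = scenario$diet_mix)
    fibre_mean <- c(herbivore = 250, frugivore = 90, omnivore = 110,
                    insectivore = 40, carnivore = 15)[diet]
    fibre_sd <- c(herbivore = 60, frugivore = 30, omnivore = 40,
                  insectivore = 15, carnivore = 8)[diet]
    fibre <- pmax(1, stats::rnorm(n, fibre_mean, fibre_sd))
    mrt <- exp(1.5 + 0.003 * fibre + stats::rnorm(n, 0, 0.25))
    body_mass <- exp(stats::rnorm(n, 2, 1.5))
    gut_diff <- pmax(0.1, 0.5 + 0.004 * fibre + stats::rnorm(n, 0, 0.15))
    git <- ifelse(diet == "herbivore",
                  sample(c("foregut", "hindgut"), n, replace = TRUE),
                  sample(c("simple", "caecum"), n, replace = TRUE,
                         prob = c(0.7, 0.3)))
    host_class <- sample(c("Mammalia", "Aves", "Reptilia", "Actinopterygii"),
                         n, replace = TRUE, prob = c(0.5, 0.2, 0.15, 0.15))
    md <- host_metadata(data.frame(
      species_id = tree$tip.label, class = host_class, diet_type = diet,
      primary_diet_fraction = stats::runif(n, 0.7, 1),
      fibre_content = fibre, mrt = mrt, body_mass = body_mass,
      gut_diff_coeff = gut_diff, git_type = git,
      origin = "synthetic", stringsAsFactors = FALSE))
    list(metadata = md, tree = tree)
  })
}

#' Generate the latent ground truth for a host cohort
#'
#' Total methanogen load per species follows
#' `log10(copies/g) = baseline + slope * min(fibre, saturation) +
#' mrt_effect * (log(MRT) - log(10)) + Normal(0, truth_sd)`. The methanogen
#' community is apportioned over six lineages whose methyl-reducing share is
#' multiplied by `frugivore_methyl_boost` in frugivores and renormalised.
#' Thaumarchaeota copies are drawn low and diet-independent; bacterial loads
#' are diet-independent log-normals. Each lineage is split into several ASVs
#' with species-specific within-lineage composition, alongside an
#' unstructured pool of bacterial ASVs for the universal library.
#'
#' @param hosts output of [generate_hosts()].
#' @param scenario a [synthetic_scenario()].
#' @return `ground_truth` list: `species` data.frame (covariates, per-lineage
#'   and total copies/g, true class proportions), `arch_composition` and
#'   `bact_composition` (species x ASV relative abundances), `taxonomy`
#'   ([taxonomy_table()] for all ASVs).
#' @export
generate_truth <- function(hosts, scenario) {
  md <- hosts$metadata
  n <- nrow(md)
  if (n == 0L) stop("hosts must be nonempty")
  lin <- ARCHAEAL_LINEAGES
  withr_seed(stage_seed(scenario$seed, 2), {
    fib <- pmin(md$fibre_content, scenario$fibre_effect$saturation)
    log10_meth <- scenario$baseline_log10_methanogens +
      scenario$fibre_effect$slope * fib +
      scenario$mrt_effect * (log(md$mrt) - log(10)) +
      stats::rnorm(n, 0, scenario$truth_sd)
    meth_copies <- 10^log10_meth
    thaum_copies <- 10^stats::rnorm(n, 4.5, 0.3)
    bact_copies <- 10^stats::rnorm(n, 10.5, 0.4)

    # lineage shares of the methanogen community: Dirichlet jitter around the
    # pool's baseline shares, then the frugivore methyl boost
    jitter <- matrix(stats::rgamma(n * nrow(lin),
                                   shape = 50 * rep(lin$base_share, each = n)),
                     nrow = n)
    shares <- jitter / rowSums(jitter)
    colnames(shares) <- lin$lineage
    methyl_cols <- lin$lineage[lin$metabolism == "methyl_reducing"]
    boost <- ifelse(md$diet_type == "frugivore",
                    scenario$frugivore_methyl_boost, 1)
    shares[, methyl_cols] <- shares[, methyl_cols] * boost
    shares <- shares / rowSums(shares)

    lineage_copies <- shares * meth_copies
    arch_total <- meth_copies + thaum_copies

    # split lineages (and Thaumarchaeota) into ASVs
    asv_lineage <- c(rep(lin$lineage, lin$n_asv), rep("Nitrososphaeraceae", 3))
    asv_id <- sprintf("ASV%03d", seq_along(asv_lineage))
    arch_comp <- matrix(0, nrow = n, ncol = length(asv_id),
                        dimnames = list(md$species_id, asv_id))
    lineage_rel <- cbind(lineage_copies, Nitrososphaeraceae = thaum_copies) /
      arch_total
    for (lg in unique(asv_lineage)) {
      cols <- which(asv_lineage == lg)
      w <- matrix(stats::rgamma(n * length(cols), shape = 1), nrow = n)
      w <- w / rowSums(w)
      arch_comp[, cols] <- w * lineage_rel[, lg]
    }

    n_bact <- 300L
    bact_id <- sprintf("bASV%04d", seq_len(n_bact))
    bw <- matrix(stats::rgamma(n * n_bact, shape = 0.3), nrow = n,
                 dimnames = list(md$species_id, bact_id))
    bact_comp <- bw / rowSums(bw)

    cls <- c(stats::setNames(lin$metabolism, lin$lineage),
             Nitrososphaeraceae = "non_methanogen")
    class_prop <- vapply(unique(cls), function(k) {
      rowSums(lineage_rel[, names(cls)[cls == k], drop = FALSE])
    }, numeric(n))

    lineage_tax <- c(stats::setNames(lin$taxonomy, lin$lineage),
                     Nitrososphaeraceae = THAUM_TAXONOMY)
    tax <- taxonomy_table(c(asv_id, bact_id),
                          c(unname(lineage_tax[asv_lineage]),
                            rep("Bacteria;unknown", n_bact)))

    species <- data.frame(md, check.names = FALSE,
                          methanogen_copies = meth_copies,
                          thaumarchaeota_copies = thaum_copies,
                          total_archaea_copies = arch_total,
                          total_bacteria_copies = bact_copies,
                          class_prop,
                          stringsAsFactors = FALSE)
    qpcr_lin <- lin[!is.na(lin$qpcr_target), ]
    for (tg in unique(qpcr_lin$qpcr_target)) {
      cols <- qpcr_lin$lineage[qpcr_lin$qpcr_target == tg]
      species[[paste0("copies_", tg)]] <-
        rowSums(lineage_copies[, cols, drop = FALSE])
    }
    structure(list(species = species, arch_composition = arch_comp,
                   bact_composition = bact_comp, taxonomy = tax,
                   lineages = lin),
              class = "ground_truth")
  })
}

#' Draw the two primer-set amplicon tables
#'
#' The archaea-specific table is a multinomial draw of `depth_archaea` reads
#' per species from the true archaeal ASV composition. The universal table
#' draws `depth_universal` reads from the combined community in which the
#' archaeal mass is `archaea_fraction_universal` times the true
#' archaea:bacteria copy ratio — the mechanism by which universal primers
#' under-detect archaea. Species whose archaeal community is empty get a row
#' of zeros in the archaea-specific table.
#'
#' @param truth a [generate_truth()].
#' @param scenario a [synthetic_scenario()].
#' @return list of two [feature_table()]s: `archaea_specific`, `universal`.
#' @export
generate_tables <- function(truth, scenario) {
  sp <- truth$species$species_id
  withr_seed(stage_seed(scenario$seed, 3), {
    arch <- t(vapply(sp, function(s) {
      p <- truth$arch_composition[s, ]
      if (sum(p) == 0) return(numeric(length(p)))
      stats::rmultinom(1, scenario$depth_archaea, p)[, 1L]
    }, numeric(ncol(truth$arch_composition))))
    dimnames(arch) <- list(sp, colnames(truth$arch_composition))

    r <- truth$species$total_archaea_copies /
      truth$species$total_bacteria_copies
    arch_mass <- scenario$archaea_fraction_universal * r
    uni <- t(vapply(seq_along(sp), function(i) {
      w <- c(truth$arch_composition[i, ] * arch_mass[i],
             truth$bact_composition[i, ])
      stats::rmultinom(1, scenario$depth_universal, w)[, 1L]
    }, numeric(ncol(truth$arch_composition) +
                 ncol(truth$bact_composition))))
    dimnames(uni) <- list(sp, c(colnames(truth$arch_composition),
                                colnames(truth$bact_composition)))
    list(archaea_specific = feature_table(arch, "archaea_specific"),
         universal = feature_table(uni, "universal"))
  })
}

#' Simulate qPCR panels with standard curves
#'
#' For each target (total archaea, total bacteria, the four methanogen
#' lineages, Thaumarchaeota) a 10-fold plasmid dilution series from 1e9 to
#' 1e1 copies/ul is "measured" with
#' `Cq = intercept - log10(copies) / log10(1 + efficiency)` plus
#' standard-curve Cq noise, and every sample is measured in two independent
#' runs with log10-copy noise `qpcr_noise_sd` per run. True copies/g are
#' converted to template copies/ul through the dilution and per-gram
#' factors; nonpositive template gives no amplification (`NA` Cq).
#'
#' @param truth a [generate_truth()].
#' @param scenario a [synthetic_scenario()].
#' @param dilution template dilution factor (default 10).
#' @param per_gram_factor elution volume per extracted mass, ul/g (default
#'   400 ul / 0.25 g = 1600).
#' @param intercept Cq at 1 copy/ul (default 38).
#' @return list `standards` (data.frame target/copies_per_ul/cq), `runs`
#'   (data.frame target/sample/run/cq/dilution), `per_gram_factor`,
#'   `dilution`.
#' @export
generate_qpcr <- function(truth, scenario, dilution = 10,
                          per_gram_factor = 1600, intercept = 38) {
  eff <- rep_len(scenario$efficiency, length(QPCR_TARGETS))
  names(eff) <- QPCR_TARGETS
  if (any(eff <= 0.7 | eff > 1.1)) stop("efficiency must be in (0.7, 1.1]")
  slope <- -1 / log10(1 + eff)
  true_copies <- list(
    total_archaea = truth$species$total_archaea_copies,
    total_bacteria = truth$species$total_bacteria_copies,
    Methanobacteriales = truth$species$copies_Methanobacteriales,
    Methanomassiliicoccales = truth$species$copies_Methanomassiliicoccales,
    Methanomicrobiales = truth$species$copies_Methanomicrobiales,
    Methanimicrococcus = truth$species$copies_Methanimicrococcus,
    Thaumarchaeota = truth$species$thaumarchaeota_copies)
  sp <- truth$species$species_id
  withr_seed(stage_seed(scenario$seed, 4), {
    std_copies <- 10^(9:1)
    standards <- do.call(rbind, lapply(QPCR_TARGETS, function(tg) {
      data.frame(target = tg, copies_per_ul = std_copies,
                 cq = intercept + slope[tg] * log10(std_copies) +
                   stats::rnorm(length(std_copies),
                                0, 0.25 * scenario$qpcr_noise_sd))
    }))
    runs <- do.call(rbind, lapply(QPCR_TARGETS, function(tg) {
      tmpl <- true_copies[[tg]] / (dilution * per_gram_factor)
      do.call(rbind, lapply(1:2, function(run) {
        lg <- ifelse(tmpl > 0,
                     log10(tmpl) + stats::rnorm(length(tmpl),
                                                0, scenario$qpcr_noise_sd),
                     NA_real_)
        data.frame(target = tg, sample = sp, run = run,
                   cq = intercept + slope[tg] * lg, dilution = dilution)
      }))
    }))
    list(standards = standards, runs = runs,
         per_gram_factor = per_gram_factor, dilution = dilution)
  })
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper running all four generation stages.
#'
#' @param scenario a [synthetic_scenario()].
#' @return list `hosts`, `truth`, `tables`, `qpcr`.
#' @export
generate_dataset <- function(scenario = synthetic_scenario()) {
  hosts <- generate_hosts(scenario)
  truth <- generate_truth(hosts, scenario)
  list(hosts = hosts, truth = truth,
       tables = generate_tables(truth, scenario),
       qpcr = generate_qpcr(truth, scenario))
}
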