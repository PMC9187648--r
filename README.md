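# gutarchaeome

Quantitative analysis of archaea in animal gut microbiomes, for researchers
working with paired 16S rRNA amplicon and qPCR surveys across host species.
The package covers the four quantitative stages such studies need:

1. **Thermodynamic dominance mapping** of the three methanogenesis
   pathways. For each pathway, ΔG = ΔG° + RT ln Q per mole CH₄, with
   ΔG° = Σ ν·ΔG°f from a bundled formation-energy table, evaluated over a
   log-spaced grid of methanol concentration C(CH₃OH) and hydrogen partial
   pressure p(H₂) at 298.15 K, p(CO₂) = p(CH₄) = 0.1 bar:

   * methyl dismutation: 4/3 CH₃OH → CH₄ + 1/3 CO₂ + 2/3 H₂O (ΔG° = −106.46 kJ/mol CH₄)
   * methyl reduction: CH₃OH + H₂ → CH₄ + H₂O (ΔG° = −112.53)
   * CO₂ reduction: CO₂ + 4 H₂ → CH₄ + 2 H₂O (ΔG° = −130.75)

   Each grid cell is labelled with the lowest-ΔG pathway (or the set within
   a 10 kJ/mol CH₄ comparability band), and the exact equal-energy contour
   — a line of slope +3 in (log₁₀ p(H₂), log₁₀ C) — is extracted.
   Literature observations (rumen, colon, sediments) can be placed on the
   map and classified.

2. **Taxonomy → methane metabolism classification** of ASVs
   (CO₂-reducing, methyl-reducing, methylotrophic dismutation,
   acetoclastic, mixed, non-methanogen), per-sample pathway proportions
   and the methyl:CO₂ reducer ratio, plus Gut/Environment/Engineered
   source classification of sequence annotations.

3. **qPCR-calibrated absolute abundance**: standard-curve fitting
   (efficiency = 10^(−1/slope) − 1), duplicate-run quantification to 16S
   copies per gram, copies-to-DNA QC filtering, methanogen totals (sum of
   the four methanogen lineage assays), rescaling of relative amplicon
   compositions to copies/g, and qPCR-ratio-calibrated merging of
   archaeal and bacterial count tables.

4. **Community statistics**, implemented in-package and cross-checked
   against independent references: rarefaction, observed richness,
   Bray–Curtis / Jaccard / UniFrac distances, PERMANOVA, Mantel tests,
   phylogenetic Moran's I, Kruskal–Wallis, pairwise Wilcoxon with BH
   correction, log-abundance regressions, moving averages and
   detection-rate tables.

A seeded **synthetic-data generator** produces host metadata, a host tree,
paired primer-set count tables and duplicate-run qPCR panels from a latent
community with known ground truth (fibre-dependent methanogen load
saturating at 200 g crude fibre/kg dry matter, elevated methyl:CO₂ ratio in
frugivores, low diet-independent Thaumarchaeota, universal primers
under-capturing archaea), so every estimator can be validated end-to-end.

## Worked example

```r
library(gutarchaeome)

sc <- synthetic_scenario(n_species = 60, seed = 7)
ds <- generate_dataset(sc)
ds$tables$archaea_specific
#> feature_table: 60 samples x 29 taxa (archaea_specific primers), 180,000 reads

## thermodynamics: standard-state energies and a state classification
vapply(methanogenesis_pathways(), delta_g_standard, numeric(1))
#> methyl_dismutation   methyl_reduction      co2_reduction
#>            -106.46            -112.53            -130.75
classify_state(thermo_state(c_methanol = 1e-3, p_h2 = 1e-7))$dominant
#> [1] "methyl_dismutation"

## qPCR: fit curves, quantify, sum the methanogen lineages
curves <- lapply(split(ds$qpcr$standards, ds$qpcr$standards$target),
                 function(d) fit_standard_curve(d$copies_per_ul, d$cq))
curves$total_archaea
#> standard_curve: slope -3.4377 Cq/decade, E = 0.954, R2 = 1.0000
panels <- lapply(split(ds$qpcr$runs, ds$qpcr$runs$target), function(d)
  qpcr_panel(d$target[1], d[c("sample", "run", "cq")],
             dilution = ds$qpcr$dilution,
             per_gram_factor = ds$qpcr$per_gram_factor))
meth <- total_methanogens(Map(quantify, panels, curves[names(panels)]))

## methanogen load rises with dietary fibre
md <- ds$hosts$metadata
log_abundance_regression(
  pmin(md$fibre_content, 200)[match(meth$sample, md$species_id)],
  meth$methanogen_copies_per_g)
#> OLS slope (log10 abundance) = 0.005819, R2 = 0.435, df = 58, p = 9.92e-09

## frugivores carry relatively more methyl reducers
prof <- pathway_profile(ds$tables$archaea_specific, ds$truth$taxonomy)
diet <- md$diet_type[match(prof$sample_id, md$species_id)]
tapply(prof$methyl_co2_ratio, diet, median)
#>   carnivore   frugivore   herbivore insectivore    omnivore
#>   0.6958462   1.5566436   0.5816521   0.5848861   0.5826893

## community structure: diet is a significant factor
rar <- rarefy(ds$tables$archaea_specific, depth = 3000, seed = 1)
bc <- beta_distance(rar, "bray_curtis")
permanova(bc, diet, n_perm = 999, seed = 1)
#> PERMANOVA pseudo-F = 1.394, R2 = 0.092, df = 4,55, p = 0.016 (999 permutations)
```

The regression slope (0.0058 log₁₀ copies per g/kg fibre) recovers the
generator's true slope of 0.005; the frugivore median methyl:CO₂ ratio is
roughly three times that of the other diets, matching the scenario's 3×
boost; and the diet PERMANOVA detects the composition shift the boost
induces.

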