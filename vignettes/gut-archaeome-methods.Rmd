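---
title: "Methods: quantitative gut-archaeome analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative gut-archaeome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutarchaeome)
```

This vignette is the package's own account of the models and procedures it
implements: what is being computed, under which assumptions, with which
defaults, and what the synthetic-data validation does and does not
demonstrate.

## The scientific setting

Archaea in animal guts are dominated by a handful of methanogen lineages
plus the ammonia-oxidising *Nitrososphaeraceae* (Thaumarchaeota). Three
questions recur when profiling them across host species:

1. **Energetics.** Which methanogenesis pathway yields the most energy under
   gut conditions, and does that explain which pathways are found there?
2. **Quantity.** How many archaea are present per gram of gut content —
   absolute abundance, not just relative composition — and how does that
   covary with host diet and physiology?
3. **Structure.** How do community composition and richness relate to host
   phylogeny and covariates (phylosymbiosis), assessed with
   distance-based statistics?

## Thermodynamic dominance mapping

Three catabolisms are compared, written per mole of CH₄ produced:

* methyl dismutation: 4/3 CH₃OH → CH₄ + 1/3 CO₂ + 2/3 H₂O
* hydrogenotrophic methyl reduction: CH₃OH + H₂ → CH₄ + H₂O
* hydrogenotrophic CO₂ reduction: CO₂ + 4 H₂ → CH₄ + 2 H₂O

For each, ΔG = ΔG° + RT ln Q with R = 8.314 J mol⁻¹ K⁻¹ and Q the activity
quotient: aqueous methanol against a 1 mol/l standard state, gases against
1 bar, water at unit activity. ΔG° is assembled as Σ ν·ΔG°f from a bundled,
versioned CSV of standard Gibbs formation energies at 298.15 K
(Thauer-style values: CH₃OH(aq) −175.4, CH₄(g) −50.75, CO₂(g) −394.36,
H₂O(l) −237.18 kJ/mol), giving −106.46, −112.53 and −130.75 kJ/mol CH₄ for
the three pathways at standard state.

Numerical and design choices:

* **Temperature.** The reference condition is quoted as 298 K; we evaluate
  at 298.15 K. The difference is below 0.1 kJ/mol CH₄ across the grid.
* **Ideality.** All activity coefficients are 1; no ionic-strength model is
  applied.
* **pH.** The reactions as written contain no protons, so pH cannot enter
  Q; it is carried in the state object for provenance only. Had the CO₂
  pool been speciated into bicarbonate at pH 7 this would change; we do not
  speciate.
* **Exact stoichiometry.** Coefficients are stored as integer ratios
  (thirds) and evaluated in floating point, so 3×(dismutation) =
  4×(methyl reduction) − (CO₂ reduction) holds to machine precision at
  every state — a property the test suite asserts at ≤ 1e−9 kJ over the
  full grid.
* **Grid.** The default dominance map is 141 × 141, log10-spaced, over
  C(methanol) 10⁻⁷–10⁻³ mol/l and p(H₂) 10⁻⁷–1 bar, with
  p(CO₂) = p(CH₄) = 0.1 bar. Cells are labelled with the lowest-ΔG
  pathway, or with the `+`-joined set of pathways within a 10 kJ/mol CH₄
  comparability band of the minimum.
* **Equal-energy contour.** Because of the stoichiometric identity, the
  locus where any two pathways tie is where all three tie. The contour is
  found as the zero set of ΔG₂ − ΔG₃ by linear interpolation along the
  methanol axis. Analytically its slope is dlog₁₀C/dlog₁₀p(H₂) = +3
  (∂(ΔG₂−ΔG₃)/∂ln p = +3RT, ∂(ΔG₂−ΔG₃)/∂ln C = −RT): each decade of extra
  hydrogen pressure requires three decades more methanol for methyl
  reduction and CO₂ reduction to stay equally favourable. The tests verify
  the fitted contour slope against this analytic value.

## Taxonomy-based metabolism classification

Almost all methanogen genera/families have one dominant methane metabolism,
so ASVs are classed by their deepest matching taxonomy rule
(`co2_reducing`, `methyl_reducing`, `methylotroph_dismutation`,
`acetoclastic`, `mixed`, `non_methanogen`, `unknown`). The rule map is an
editable CSV, not code; the bundled default covers the lineages that
dominate gut archaeomes. *Methanosphaera* (obligate methanol reducer)
overrides its otherwise CO₂-reducing order Methanobacteriales — the
most-specific-rank rule exists for exactly this case. *Methanosarcina* is
`mixed` because its species span several pathways; mixed reads count toward
neither side of the methyl:CO₂ ratio. The ratio is flagged undefined when a
sample has no CO₂-reducer reads rather than reported as infinity.

Source-environment classification (`Gut` / `Environment` / `Engineered`)
is keyword matching over free-text isolation-source annotations with
precedence excluded > Gut > Engineered > Environment; keyword lists are
configuration because no complete rulebook exists — only exemplars.

## qPCR quantification

Standard curves are least-squares fits of Cq on log10(copies/µl) over a
10-fold dilution series (validity requires ≥ 3 points spanning ≥ 3
decades); efficiency = 10^(−1/slope) − 1, so perfect doubling gives slope
−log₂10 = −3.3219 Cq/decade. Quantification inverts each run through the
curve, then averages duplicates **on the copies scale** (not the Cq scale),
then applies the dilution and per-gram factors. The per-gram factor
(elution volume / extracted mass, e.g. 400 µl / 0.25 g = 1600, times any
template dilution) is configuration, since it depends on the extraction
protocol.

Total methanogens are the sum of exactly four lineage quantifications —
Methanobacteriales, Methanomicrobiales, Methanomassiliicoccales,
Methanimicrococcus — never Thaumarchaeota. The low copies-to-DNA QC rule
removes samples whose bacterial copies per ng DNA fall below the cohort's
2.5th percentile by default (an absolute threshold can be supplied; the
rule's exact cutoff in the source protocol is not published, so it is
configuration).

Relative amplicon compositions are rescaled to absolute copies/g by the
sample's total archaeal qPCR value; row sums then conserve the qPCR totals
exactly. Merging archaeal and bacterial tables onto a common scale rescales
both blocks to a target depth and apportions reads so the block mass ratio
equals the qPCR archaea:bacteria ratio, using largest-remainder rounding so
block totals are exact integers while within-block composition is preserved
to rounding.

## Community statistics

All statistics the analysis needs are implemented in the package and
cross-checked in the tests against independent references (`vegan`,
`ape`, `phyloseq`, base `stats`) on small fixtures:

* **Rarefaction**: one seeded draw without replacement (multivariate
  hypergeometric) to exactly the target depth; shallower samples are
  dropped. Default depths follow common practice for archaeal (3,000
  reads) and bacterial (12,000 reads) libraries.
* **Distances**: Bray–Curtis, Jaccard (presence/absence), unweighted and
  normalised weighted UniFrac computed from per-branch read mass on the
  taxon tree.
* **PERMANOVA**: McArdle–Anderson partition of the Gower-centred squared
  distance matrix; single predictor (factor or covariate) per fit, run
  factor-by-factor; one-sided p by unrestricted permutation. Multi-term
  sequential fits are out of scope.
* **Mantel**: Pearson r over off-diagonal entries, 999 permutations,
  two-sided by default.
* **Moran's I**: phylogenetic weights default to inverse cophenetic
  distance, zero diagonal, row-standardised — the index is standard but the
  weighting is a choice, so it is exposed as an argument. The null
  expectation −1/(n−1) is reported alongside.
* **Kruskal–Wallis**: midranks with the tie correction
  1 − Σ(t³−t)/(N³−N), referred to χ²(k−1).
* **Pairwise Wilcoxon**: exact null distribution for untied samples up to
  n = 20 per group, otherwise normal approximation with continuity
  correction and tie-adjusted variance; Benjamini–Hochberg adjustment
  across the pair family.
* **Log-abundance regression**: OLS of log10(copies/g) on a covariate;
  non-positive abundances are excluded with the count reported, never
  silently.
* **Moving average**: centred windows that truncate (shrink) at the series
  edges; a trailing mode is available. With the window equal to the series
  length only the central point sees the whole series — a consequence of
  truncation that users of full-width windows should note.

Permutation p-values are always (1 + #{extreme}) / (n_perm + 1), so
p ≥ 1/(n_perm + 1) and exact nominal levels are attainable (e.g. 10/200
with 199 permutations at α = 0.05).

## The synthetic-data generator

The generator is first-class, tested code: it draws a host cohort and
everything the pipeline consumes, with the ground truth retained so every
downstream stage can be validated against known parameters.

Stage structure and seeding: one scenario seed expands into fixed per-stage
substreams (hosts, truth, tables, qPCR), so a stage can be regenerated
independently; all stages are bit-reproducible under the scenario.

What the defaults encode, and why:

* **Hosts** (`n_species = 200`): pure-birth unit-rate tree (topology is
  only consumed by the Mantel/Moran stages, so the rate is inert); diet
  types from a mix of 30% herbivores, 20% each frugivores, carnivores and
  omnivores, 10% insectivores; crude fibre high for herbivores
  (≈250 g/kg dry matter) down to ≈15 g/kg for carnivores; mean retention
  time positively correlated with fibre.
* **Truth**: log10(methanogen copies/g) = 6.5 + 0.005·min(fibre, 200)
  + 0.3·(log MRT − log 10) + N(0, 0.4). The 200 g/kg saturation point and
  the fibre response emulate the observed plateau of methanogen abundance
  at high-fibre diets; the slope default of 0.5 log10 units per 100 g/kg
  is a realistic effect magnitude for that plateau to emerge over the
  observed fibre range. The `truth_sd = 0.4` biological scatter is a
  separate parameter from qPCR measurement noise — the generative model
  needs both, though they are never identifiable from a single run.
  The methanogen community is Dirichlet-jittered around baseline lineage
  shares (Methanobrevibacter 0.45, Methanomethylophilaceae 0.20,
  Methanocorpusculum 0.15, Methanosphaera 0.10, Methanimicrococcus 0.08,
  Methanosarcina 0.02), with the methyl-reducing share multiplied by 3 in
  frugivores (renormalised) — the frugivore/pectin/methanol effect.
  Thaumarchaeota are drawn low (≈10^4.5 copies/g) and diet-independent;
  bacteria ≈10^10.5 copies/g, diet-independent.
* **Tables**: archaea-specific libraries are multinomial draws of 3,000
  reads from the true archaeal composition. Universal libraries draw
  10,000 reads from the joint community in which archaeal mass equals
  `archaea_fraction_universal` (default 0.5) times the true
  archaea:bacteria copy ratio — the mechanism that makes universal primers
  miss archaea in low-ratio hosts, reproducing the detection-rate gap
  between primer sets.
* **qPCR**: Cq = intercept − log10(copies)/log10(1+E) per target; two
  independent runs per sample with N(0, `qpcr_noise_sd`) noise on log10
  copies (default 0.2); standard-curve points get 0.25·`qpcr_noise_sd`
  cycles of Cq noise so the zero-noise limit leaves the dilution series
  exact. Default efficiency 0.95 per target.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: sequencing error and chimeras (ASV inference is
upstream of this package), primer-template mismatch biases beyond a single
scalar capture factor, 16S copy-number variation per genome, compositional
correlation structure among bacteria (the bacterial pool is unstructured;
network inference is out of scope), phylogenetic signal in the *community*
composition beyond what diet covariates induce, and PCR inhibition. Recovery
results on synthetic data therefore validate the estimators and their
calibration, not the biology of any particular cohort.

## Validation design and problem sizes

The test-suite and acceptance checks run at sizes chosen to make each
property measurable with comfortable margins while keeping a full run in
minutes on one core: zero-noise round-trips on 30-species cohorts; slope
recovery as 95%-CI coverage over 100 replicate cohorts of 200 species
(expected coverage 95%, required ≥ 93/100); frugivore-effect power over 50
replicate 25-vs-25 comparisons at boost 3× (required ≥ 0.8); and type-I
calibration of PERMANOVA (199 permutations), Mantel (999) and Wilcoxon over
1000 null replicates each, required to sit within the exact binomial 99%
band around 0.05 (0.033–0.069). The fibre-slope recovery fit adjusts for
log(MRT) because the generator correlates retention time with fibre; a
univariate fit would be confounded by construction and its CI would not
cover the generative slope at the nominal rate.

## Known limitations

* The metabolism rule map encodes the well-attested lineage assignments
  only; users profiling unusual communities should extend the CSV.
* PERMANOVA is single-predictor; sequential (Type-I) multi-term
  partitions are deliberately not implemented.
* UniFrac requires every table taxon on the tree; there is no automatic
  pruning or placement.
* Thermodynamics are fixed at 298.15 K; no van't Hoff temperature
  correction or carbonate speciation.
* The ≥1% per-sample ASV filter is applied wherever the user calls it; by
  default the package profiles after species merging (filter order in the
  source protocol is unstated).
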