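Package: gutarchaeome
Title: Quantitative Analysis of the Animal Gut Archaeome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative profiling of archaea in animal gut
    microbiomes from 16S rRNA amplicon data and lineage-specific qPCR.
    Implements thermodynamic dominance mapping of the three methanogenesis
    pathways (methyl dismutation, hydrogenotrophic methyl reduction and
    CO2 reduction) over methanol concentration and hydrogen partial
    pressure, taxonomy-based assignment of amplicon sequence variants to
    methane-metabolism classes, qPCR standard-curve quantification with
    conversion to 16S rRNA gene copies per gram, rescaling of relative
    amplicon abundances to absolute abundances, and the community
    statistics used on such data: rarefaction, observed richness,
    Bray-Curtis, Jaccard and UniFrac distances, PERMANOVA, Mantel tests,
    phylogenetic Moran's I, Kruskal-Wallis and pairwise Wilcoxon tests
    with Benjamini-Hochberg correction, and log-abundance regressions.
    A seeded synthetic-data generator produces host metadata, host trees,
    paired primer-set count tables and qPCR panels with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    jsonlite,
    phyloseq,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
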