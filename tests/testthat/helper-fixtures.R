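# small in-code fixtures shared across test files

tiny_table <- function(counts = rbind(s1 = c(3, 0, 7), s2 = c(2, 5, 1)),
                       taxa = c("ASV1", "ASV2", "ASV3"),
                       primer = "archaea_specific") {
  colnames(counts) <- taxa
  feature_table(counts, primer)
}

# four-leaf caterpillar tree with known path lengths
tiny_tree <- function() {
  ape::read.tree(text = "((A:1,B:2):0.5,(C:1.5,D:0.5):1):0;")
}

tiny_taxonomy <- function() {
  taxonomy_table(
    c("ASV1", "ASV2", "ASV3"),
    c("Archaea;Euryarchaeota;Methanobacteria;Methanobacteriales;Methanobacteriaceae;Methanobrevibacter",
      "Archaea;Thermoplasmatota;Thermoplasmata;Methanomassiliicoccales;Methanomethylophilaceae",
      "Archaea;Thaumarchaeota;Nitrososphaeria;Nitrososphaerales;Nitrososphaeraceae"))
}

# noise-free dilution-series Cq at a given efficiency
ideal_standards <- function(efficiency = 1, intercept = 38,
                            copies = 10^(9:1)) {
  slope <- -1 / log10(1 + efficiency)
  data.frame(copies_per_ul = copies, cq = intercept + slope * log10(copies))
}
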