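rank,taxon,class
order,Methanobacteriales,co2_reducing
genus,Methanobrevibacter,co2_reducing
genus,Methanobacterium,co2_reducing
genus,Methanothermobacter,co2_reducing
genus,Methanosphaera,methyl_reducing
order,Methanomicrobiales,co2_reducing
genus,Methanocorpusculum,co2_reducing
family,Methanoregulaceae,co2_reducing
family,Methanospirillaceae,co2_reducing
order,Methanocellales,co2_reducing
order,Methanomassiliicoccales,methyl_reducing
family,Methanomethylophilaceae,methyl_reducing
family,Methanomassiliicoccaceae,methyl_reducing
genus,Methanimicrococcus,methyl_reducing
genus,Methanosarcina,mixed
genus,Methanosaeta,acetoclastic
genus,Methanothrix,acetoclastic
family,Methanosarcinaceae,mixed
class,Thaumarchaeota,non_methanogen
order,Nitrososphaerales,non_methanogen
family,Nitrososphaeraceae,non_methanogen
family,Nitrosopumilaceae,non_methanogen
family,Nitrosotaleaceae,non_methanogen
phylum,Bathyarchaeota,non_methanogen
order,Halobacteriales,non_methanogen
domain,Bacteria,non_methanogen
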