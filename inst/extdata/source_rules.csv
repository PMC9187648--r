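category,keyword
excluded,sponge
excluded,nest
excluded,dump
excluded,polluted
Gut,gut
Gut,rumen
Gut,faeces
Gut,feces
Gut,fecal
Gut,faecal
Gut,intestin
Gut,colon
Gut,caecum
Gut,cecum
Gut,stomach
Gut,hindgut
Gut,foregut
Gut,digestive
Gut,manure
Engineered,digester
Engineered,bioreactor
Engineered,reactor
Engineered,sludge
Engineered,wastewater
Engineered,landfill
Engineered,biogas
Engineered,compost
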