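name,formula,exact_mass,source,class
indole diketopiperazine,C22H22N2O4,,marine-derived actinomycete,diketopiperazine
triphenyl hydroxypiperidine,C37H33N3O3,,synthetic antimicrobial,piperidine
deoxyguanosine congener,C21H24N6O5,,synthetic antimicrobial,nucleoside
oxoindoline benzofuran,C17H11N3O4,,synthetic antimicrobial,benzofuran
diazaspirodecenone,C35H31N3O6,,synthetic antimicrobial,spiro heterocycle
benzimidazole dihydrazide,C13H18N6O3,,synthetic antimicrobial,benzimidazole
nitrobiphenyl carboxamide,C33H33N3O6,,synthetic antimicrobial,biphenyl
aminoacetamido benzofuran,C18H23N3O3,,synthetic antimicrobial,benzofuran
talathermophilin E,C18H21N3O2,,Talaromyces thermophilus,prenylated indole
lankacyclinol,C24H35NO5,,Streptomyces rochei,polyene
borrelidin,C28H43NO6,,Streptomyces rochei,macrolide
lankacyclinol A,C26H37NO6,,Streptomyces rochei,polyene
"8,15-dideoxylankamycin",C42H72O14,,Streptomyces rochei,macrolide
antibiotic T 2636K,C34H43NO12,,Streptomyces rochei,polyketide
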