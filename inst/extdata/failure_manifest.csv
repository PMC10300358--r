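"run_id","failure","contaminant_species"
"S016_r2","hybridization_bs1",""
"S017_r1","hybridization_bs1",""
"S021_r3","hybridization_bs1",""
"S022_r2","hybridization_bs1",""
"S031_r1","hybridization_bs1",""
"S032_r3","hybridization_bs1",""
"S064_r1","hybridization_bs1",""
"S078_r2","hybridization_bs1",""
"S079_r1","hybridization_bs1",""
"S093_r3","hybridization_bs1",""
"S094_r2","hybridization_bs1",""
"S103_r1","hybridization_bs1",""
"S013_r2","hybridization_bs2",""
"S046_r1","hybridization_bs2",""
"S047_r3","hybridization_bs2",""
"S056_r3","hybridization_bs2",""
"S065_r2","hybridization_bs2",""
"S104_r3","hybridization_bs2",""
"S001_r1","inconsistent","Telatrygon zugei"
"S007_r2","inconsistent","Neotrygon orientalis"
"S018_r3","inconsistent","Himantura imbricata"
"S026_r1","inconsistent","Gymnura poecilura"
"S036_r2","inconsistent","Rhina ancylostoma"
"S041_r3","inconsistent","Anoxypristis cuspidata"
"S051_r1","inconsistent","Mobula tarapacana"
"S059_r2","inconsistent","Sphyrna lewini"
"S073_r3","inconsistent","Carcharhinus sorrah"
"S083_r1","inconsistent","Stegostoma fasciatum"
"S088_r2","inconsistent","Lamna nasus"
"S098_r3","inconsistent","Alopias pelagicus"
"S106_r1","inconsistent","Rhynchobatus australiae"
"S111_r2","inconsistent","Isurus paucus"
"S116_r3","inconsistent","Alopias superciliosus"
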