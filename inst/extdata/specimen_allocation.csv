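"species_name","n_specimens","n_test"
"Alopias pelagicus",6,3
"Alopias superciliosus",6,3
"Carcharhinus falciformis",3,2
"Carcharhinus longimanus",5,3
"Isurus oxyrinchus",5,3
"Isurus paucus",5,3
"Lamna nasus",5,3
"Sphyrna lewini",5,3
"Sphyrna mokarran",5,3
"Carcharhinus brevipinna",5,3
"Carcharhinus sorrah",5,3
"Prionace glauca",3,2
"Anoxypristis cuspidata",5,3
"Glaucostegus typus",3,2
"Mobula birostris",3,2
"Mobula mobular",3,2
"Mobula tarapacana",5,3
"Pristis pristis",5,2
"Rhina ancylostoma",5,2
"Rhynchobatus australiae",5,2
"Rhynchobatus laevis",5,2
"Rhynchobatus springeri",5,2
"Galeocerdo cuvier",3,2
"Stegostoma fasciatum",5,2
"Gymnura poecilura",5,2
"Himantura imbricata",5,2
"Neotrygon orientalis",5,2
"Telatrygon zugei",5,2
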