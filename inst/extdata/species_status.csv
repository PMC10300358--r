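"no","species_name","english_name","group","cites_listed","amplifies_bs1","amplifies_bs2","visual_distinguishable","dl_distinguishable","dl_misassignment_risk"
1,"Alopias pelagicus","Pelagic thresher","shark","Yes","Yes","Yes","Yes","Yes","No"
2,"Alopias superciliosus","Bigeye thresher","shark","Yes","Yes","Yes","Yes","Yes","No"
3,"Carcharhinus falciformis","Silky shark","shark","Yes","Yes","No","No","Yes","No"
4,"Carcharhinus longimanus","Oceanic whitetip shark","shark","Yes","No","Yes","Yes","No","No"
5,"Isurus oxyrinchus","Shortfin mako shark","shark","Yes","No","Yes","Yes","Yes","Yes"
6,"Isurus paucus","Longfin mako shark","shark","Yes","Yes","Yes","Yes","Yes","Yes"
7,"Lamna nasus","Porbeagle shark","shark","Yes","No","Yes","Yes","Yes","No"
8,"Sphyrna lewini","Scalloped hammerhead","shark","Yes","Yes","Yes","Yes","Yes","No"
9,"Sphyrna mokarran","Great hammerhead","shark","Yes","Yes","Yes","Yes","Yes","No"
10,"Carcharhinus brevipinna","Spinner shark","shark","Yes","Yes","No","Yes","Yes","No"
11,"Carcharhinus sorrah","Spot-tail shark","shark","Yes","Yes","Yes","Yes","No","No"
12,"Prionace glauca","Blue shark","shark","Yes","Yes","No","No","Yes","Yes"
13,"Anoxypristis cuspidata","Knifetooth sawfish","ray","Yes","Yes","Yes","Yes","Yes","No"
14,"Glaucostegus typus","Giant shovelnose ray","ray","Yes","No","No","No","No","No"
15,"Mobula birostris","Giant oceanic manta ray","ray","Yes","Yes","Yes","No","Yes","No"
16,"Mobula mobular","Giant devil ray","ray","Yes","Yes","Yes","No","Yes","No"
17,"Mobula tarapacana","Sicklefin devil ray","ray","Yes","Yes","Yes","Yes","Yes","No"
18,"Pristis pristis","Largetooth sawfish","ray","Yes","No","Yes","Yes","Yes","No"
19,"Rhina ancylostoma","Bowmouth guitarfish","ray","Yes","Yes","Yes","Yes","Yes","No"
20,"Rhynchobatus australiae","Whitespotted guitarfish","ray","Yes","Yes","Yes","Yes","Yes","No"
21,"Rhynchobatus laevis","Smoothnose wedgefish","ray","Yes","No","Yes","Yes","Yes","Yes"
22,"Rhynchobatus springeri","Broadnose wedgefish","ray","Yes","Yes","Yes","Yes","Yes","Yes"
23,"Galeocerdo cuvier","Tiger shark","shark","No","No","No","No","No","No"
24,"Stegostoma fasciatum","Zebra shark","shark","No","Yes","Yes","Yes","No","No"
25,"Gymnura poecilura","Longtail butterfly ray","ray","No","Yes","Yes","Yes","Yes","No"
26,"Himantura imbricata","Bengal whipray","ray","No","Yes","Yes","Yes","Yes","No"
27,"Neotrygon orientalis","Oriental bluespotted maskray","ray","No","Yes","Yes","Yes","Yes","No"
28,"Telatrygon zugei","Pale-edged stingray","ray","No","Yes","Yes","Yes","Yes","No"
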