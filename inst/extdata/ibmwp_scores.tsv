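taxon	rank	score
Siphlonuridae	family	10
Heptageniidae	family	10
Leptophlebiidae	family	10
Potamanthidae	family	10
Ephemeridae	family	10
Taeniopterygidae	family	10
Leuctridae	family	10
Capniidae	family	10
Perlodidae	family	10
Perlidae	family	10
Chloroperlidae	family	10
Aphelocheiridae	family	10
Phryganeidae	family	10
Molannidae	family	10
Beraeidae	family	10
Odontoceridae	family	10
Leptoceridae	family	10
Goeridae	family	10
Lepidostomatidae	family	10
Brachycentridae	family	10
Sericostomatidae	family	10
Athericidae	family	10
Blephariceridae	family	10
Astacidae	family	8
Lestidae	family	8
Calopterygidae	family	8
Gomphidae	family	8
Cordulegastridae	family	8
Aeshnidae	family	8
Corduliidae	family	8
Libellulidae	family	8
Psychomyiidae	family	8
Philopotamidae	family	8
Glossosomatidae	family	8
Ephemerellidae	family	7
Nemouridae	family	7
Rhyacophilidae	family	7
Polycentropodidae	family	7
Limnephilidae	family	7
Neritidae	family	6
Viviparidae	family	6
Ancylidae	family	6
Thiaridae	family	6
Unionidae	family	6
Corophiidae	family	6
Gammaridae	family	6
Atyidae	family	6
Platycnemididae	family	6
Coenagrionidae	family	6
Hydroptilidae	family	6
Oligoneuriidae	family	5
Polymitarcidae	family	5
Dryopidae	family	5
Elmidae	family	5
Helophoridae	family	5
Hydrochidae	family	5
Hydraenidae	family	5
Clambidae	family	5
Hydropsychidae	family	5
Tipulidae	family	5
Simuliidae	family	5
Planariidae	family	5
Dendrocoelidae	family	5
Dugesiidae	family	5
Baetidae	family	4
Caenidae	family	4
Haliplidae	family	4
Curculionidae	family	4
Chrysomelidae	family	4
Tabanidae	family	4
Stratiomyidae	family	4
Empididae	family	4
Dolichopodidae	family	4
Dixidae	family	4
Ceratopogonidae	family	4
Anthomyiidae	family	4
Limoniidae	family	4
Psychodidae	family	4
Sialidae	family	4
Piscicolidae	family	4
Hydracarina	order	4
Mesoveliidae	family	3
Hydrometridae	family	3
Gerridae	family	3
Nepidae	family	3
Naucoridae	family	3
Notonectidae	family	3
Pleidae	family	3
Corixidae	family	3
Helodidae	family	3
Hydrophilidae	family	3
Hygrobiidae	family	3
Dytiscidae	family	3
Gyrinidae	family	3
Valvatidae	family	3
Hydrobiidae	family	3
Lymnaeidae	family	3
Physidae	family	3
Planorbidae	family	3
Bithyniidae	family	3
Sphaeriidae	family	3
Glossiphoniidae	family	3
Hirudidae	family	3
Erpobdellidae	family	3
Asellidae	family	3
Ostracoda	class	3
Chironomidae	family	2
Culicidae	family	2
Muscidae	family	2
Thaumaleidae	family	2
Ephydridae	family	2
Oligochaeta	class	1
Syrphidae	family	1
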