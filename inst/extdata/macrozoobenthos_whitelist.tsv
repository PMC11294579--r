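taxon	rank
Annelida	phylum
Mollusca	phylum
Platyhelminthes	phylum
Ephemeroptera	order
Plecoptera	order
Trichoptera	order
Odonata	order
Coleoptera	order
Diptera	order
Hemiptera	order
Megaloptera	order
Hydracarina	order
Amphipoda	order
Isopoda	order
Decapoda	order
Ostracoda	class
Oligochaeta	class
Clitellata	class
Hydrozoa	class
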