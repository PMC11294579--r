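species_name	category	source
Pacifastacus leniusculus	invasive	Spanish Catalogue of Invasive Alien Species
Vespa velutina	invasive	Spanish Catalogue of Invasive Alien Species
Potamopyrgus antipodarum	invasive	regional invasive list
Physella acuta	invasive	regional invasive list
Craspedacusta sowerbii	invasive	regional invasive list
Drosophila suzukii	invasive	regional invasive list
Acanthocyclops americanus	NIS	literature record
Chydorus brevilabris	NIS	literature record
Ceratophysella communis	NIS	literature record
Girardia sinensis	NIS	literature record
Oncorhynchus mykiss	invasive	regional invasive list
Rana iberica	protected	Spanish List of Wildlife Species under Special Protection Regime
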