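# Packaged data files

- `ibmwp_scores.tsv` — editable copy of the IBMWP scoring-taxon table
  following the published index (family-level sensitivity scores 1–10 plus
  the coarser scored groups Hydracarina, Ostracoda and Oligochaeta). Check
  against the current official version before regulatory use.
- `reference_example.yaml` — example reference IBMWP value and EQR class
  boundaries for a synthetic river type. These are jurisdiction-specific
  intercalibration products; the package deliberately ships no defaults that
  could be mistaken for official values.
- `checklist_example.tsv` — example screening checklist of non-indigenous /
  invasive and protected species known from NW-Iberian rivers (public
  catalogue and literature records).
- `macrozoobenthos_whitelist.tsv` — example group whitelist used to restrict
  taxa lists to benthic macroinvertebrates (mixed ranks).
- `synthetic_species_pool.tsv` — fully synthetic species pool used by the
  simulation module (invented epithets; five real checklist species included
  so screening has true positives). Generated by
  `rivermetrix::synthetic_species_pool()`.
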