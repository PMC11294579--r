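# Example reference configuration for tests and demonstrations.
#
# Reference IBMWP values and EQR class boundaries are river-type-specific
# intercalibration products set by the competent authority; this file is a
# plausible example for a small siliceous mountain river, NOT an official
# set. Boundaries are EQR cut-points High/Good, Good/Moderate,
# Moderate/Poor, Poor/Bad; a boundary value belongs to the better class.
river_type: synthetic-siliceous-mountain-river
reference_ibmwp: 160
boundaries:
  - 0.93
  - 0.70
  - 0.50
  - 0.25
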