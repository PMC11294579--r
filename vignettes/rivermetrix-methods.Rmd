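---
title: "Methods: from OTU tables to ecological status, and how the pipeline is validated"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from OTU tables to ecological status, and how the pipeline is validated}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rivermetrix)
```

# Scope and assumptions

`rivermetrix` implements the post-assignment half of a molecular river
biomonitoring workflow. It assumes that reads have already been trimmed,
denoised, clustered into OTUs and taxonomically assigned; its unit of input
is an OTU × replicate count table plus a ranked lineage per OTU. Everything
downstream of that point — replicate quality control, contamination
handling, taxa-list construction, species screening, biotic-index
computation and method-comparison statistics — is in scope. Everything
upstream (primers, PCR conditions, clustering radii, reference databases)
is not, and no parameter here can compensate for problems there.

Two survey designs are modelled. *Bulk samples* are homogenized
multi-organism net samples: DNA is abundant and fresh, so detections are
expected to be robust across replicates, and the stricter consistency rule
(all 3 PCR replicates) is used. *eDNA samples* are filtered river water:
template is dilute and degraded, so requiring 2 of 3 replicates trades a
small false-positive risk for much better sensitivity. Both rules operate
at OTU level by default; a taxon-level variant (presence pooled over OTUs
sharing a best-rank name before the rule is applied) is available via
`filter_replicate_consistency(level = "taxon")`, which is the natural
reading when one taxon fragments into several OTUs.

# The filtering stage

Order of operations, fixed by `filter_pipeline()`:

1. **Merge** extraction/filtration replicates into PCR replicates by
   summation (totals conserved; a group of one passes through unchanged).
2. **Replicate consistency**: per sample, zero out any OTU present (count
   at or above `presence_threshold`, default 1 read) in fewer than the
   policy's minimum number of PCR replicates. Decisions are per sample —
   an OTU can be genuine at one site and noise at another.
3. **Blank subtraction**: per OTU, aggregate its reads over all negative
   controls and subtract that value from every sample column, floored at
   zero; control columns are then dropped.
4. **Condense** to per-sample presence/absence taxa lists at each OTU's
   deepest assigned rank, collapsing OTUs that resolve to the same
   (name, rank).

Running consistency before subtraction is a genuine design choice: the two
operations do not commute (a read present in 3 of 3 replicates can be
wiped by subtraction, which is different from being wiped first and then
failing the replicate rule). We default to consistency-first and expose
`subtract_first = TRUE` for the other order; a unit test pins the default
by constructing a case the two orders classify differently.

Aggregating multiple blanks with `max` rather than `sum` is the
conservative choice for the common case of 2–3 blanks sharing one
contamination source: `sum` double-counts the same contaminant and
over-subtracts. `sum` remains available for labs that prefer it.

Both filters are idempotent and can only reduce counts — properties the
test suite asserts on randomly generated matrices, because they are what
makes re-running a pipeline on its own output safe.

# Screening and resolution

Checklist screening matches **species-level entries only**, by exact
binomial comparison after whitespace/case normalization. No fuzzy matching
is attempted: a false invasive-species alert triggers management action,
so the matcher prefers missing a misspelled record over inventing one. A
detection is counted once per sample regardless of how many OTUs carry the
species. Screening runs before the macrozoobenthos/IBMWP group filters so
that terrestrial or planktonic checklist hits (a hornet, a jellyfish) are
not silently discarded.

Resolution tallies count **OTUs**, not collapsed taxa, because the
question they answer — how much of the OTU inventory reaches species
level — is about assignment quality, not ecology. Diversity and index
computations use collapsed taxa. The two denominators are deliberately
different and reported separately.

# Index computation

Each taxa-list entry is walked up its lineage (species → genus → family →
order → class → phylum) and attached to the first name present in the
score table; the resulting scoring taxa form a set, so three species of
one scored family contribute that family once. IBMWP is the sum of scores,
IASPT the mean score per scoring taxon, EQR the ratio of observed to
reference IBMWP, and status the class of the EQR under four decreasing
cut-points, with a boundary value belonging to the better class (an EQR
exactly at the High/Good cut-point is High). The boundary rule is stated
here and in the docs because conventions differ between jurisdictions.

Mixed-rank morphological lists (family-level mostly) and species-level
molecular lists funnel through the same mapping, which is what makes their
index values comparable.

Two things are deliberately **not** defaulted: the reference IBMWP and the
class boundaries. They are intercalibration products that vary by river
type and jurisdiction; shipping plausible-looking defaults would invite
regulatory misuse. The packaged `reference_example.yaml` (reference 160,
boundaries 0.93/0.70/0.50/0.25 — values typical in scale for small
siliceous mountain rivers) exists for tests and demonstrations and says so
in its header. EQR is not capped at 1 by default because molecular
inventories can legitimately exceed a morphology-calibrated reference;
`eqr(cap = TRUE)` is available.

Where a site yields no scoring taxa, IASPT is reported as 0 with a warning
rather than NaN: downstream tabulation code handles 0 gracefully and the
warning preserves the information that the value is a placeholder.

The published IASPT can be pooled two ways — mean of per-sample IASPT
values, or the IASPT of the pooled taxon set — and survey reports are not
always explicit about which. `compute_index()` returns per-sample values
so either aggregate can be formed; the acceptance script reports the
per-sample mean.

# Comparison statistics

- **Spearman, Mann–Whitney**: wrapped from base R with the conventions
  pinned by tests (exact p for small tie-free samples, tie-corrected
  normal approximation otherwise; `W` is the Mann–Whitney U of the first
  sample, with the rank-sum also returned).
- **Exact binomial on paired statuses**: ties excluded, two-sided p by
  doubling the smaller tail, capped at 1. Under the symmetric null
  (p = 1/2) this equals the standard exact binomial two-sided p, which a
  test verifies.
- **Friedman on paired statuses**: statuses coded Bad = 1 … High = 5,
  ranked within samples with average ranks and the tie-corrected
  chi-square statistic. The statistic is implemented in-package (checked
  against `stats::friedman.test`) so that an exact within-block
  permutation p (`p_method = "permutation"`, all 2^n sign flips for two
  methods) is available alongside the chi-square approximation; with
  heavily tied ordinal data and modest n the approximation alone is
  hard to trust.
- **Bisector test**: OLS of molecular on morphological EQR with two-sided
  t-tests of slope = 1 and intercept = 0. The regression direction
  (molecular on morphological) treats the regulatory method as the
  baseline; it is switchable by exchanging the arguments. Zero-residual
  fits (possible on synthetic data) are handled explicitly: p is 1 when
  the estimate equals its null value and 0 otherwise.
- **PERMANOVA**: written from scratch. The distance matrix is squared,
  Gower-centred (G), and each term's marginal sum of squares is
  trace(H·G) of the full model minus the model without that term, with
  hat matrices built by QR on dummy-coded factors. Pseudo-F uses the
  full-model residual. Significance comes from free permutation of
  observation labels — rows and columns of the distance matrix permuted
  jointly — with the observed statistic included in the reference set
  (p ≥ 1/(n_perm+1) by construction). Free permutation is the simplest
  defensible scheme; restricted/residual-permutation variants can differ
  slightly for unbalanced designs. The implementation reproduces
  `vegan::adonis2(by = "margin")` sums of squares, R² and F exactly on
  test designs, and its p-value matches exhaustive enumeration at n = 6,
  but vegan is never used as the implementation — only as an independent
  cross-check.

Jaccard dissimilarity (1 − |A∩B|/|A∪B|) is used both as the paired
set-comparison summary and, row-pairwise, as the default distance for the
community PERMANOVA, matching the presence/absence character of the data.

# What the synthetic generator emulates — and what it does not

`generate_communities()` + `generate_otu_table()` produce surveys with
known truth. Defaults mirror the sampling frame the package targets:
27 sites with bulk + morphological surveys, eDNA at 16 of them; 3 PCR
replicates per sample over 2 extraction replicates (bulk) or 3 filters
(eDNA); 2–3 negative controls per method; a method-pool overlap of 0.25,
i.e. a between-method Jaccard dissimilarity of 0.75 by construction; and
detection probabilities (bulk 0.95, eDNA 0.80, morphology 0.75) chosen to
reproduce the qualitative ordering bulk > eDNA > morphology in richness,
with a bulk:eDNA richness ratio near 1.2. Per-site communities of 60
species are drawn from a 199-species pool with site-specific gamma
weights, so a location effect exists for PERMANOVA. Richness is scaled
down relative to real surveys (tens rather than hundreds of species per
site) to keep the pool, and with it every test, desk-sized; ratios and
overlap, not absolute richness, are the emulated quantities.

Noise model: read depths are shifted negative binomial per species and
PCR replicate (`1 + NB(mu, size)`, so a non-dropped replicate always has
at least one read and the dropout probability `q` is exactly the
per-replicate absence probability); whole PCR replicates drop out with
probability `q = 0.1`; contaminant OTUs carry Poisson(λ = 0.5) reads in
every column, blanks included, sharing OTU identity between samples and
controls so that blank subtraction is exercised genuinely; spurious OTUs
(10% of true OTUs) get coarse-rank-only taxonomy and reads in a single
PCR replicate, so the consistency filter — not the taxonomy — must remove
them.

What the generator does **not** emulate: sequence-level artifacts
(chimeras, NUMTs, index hopping), abundance structure beyond
overdispersion, eDNA transport from upstream, and taxonomic mis-assignment
(as opposed to coarse assignment). Passing the recovery tests therefore
shows the *bookkeeping* is lossless and the *filters* behave as specified
under the stated noise model; it does not certify performance on real
surveys, where the dominant error sources are upstream of this package.

Key closed-form anchors used by the tests: a species survives the bulk
3-of-3 rule with probability (1−q)³; a contaminant OTU appears in a merged
PCR replicate with probability 1 − exp(−n_ext·λ) and survives the 3-of-3
rule with that quantity cubed; the intended bulk/eDNA pools at a site have
Jaccard dissimilarity 1 − s exactly.

# Numerical and degenerate-input choices

- Counts must be whole and non-negative; violations are errors, never
  coerced.
- Samples with the wrong number of PCR replicates are rejected by name,
  not rescaled.
- Blank subtraction with no control columns warns and returns the input
  unchanged (the caller asked for something that cannot be done, but the
  data are not wrong).
- `iaspt(0, 0)` returns 0 with a warning; `eqr` requires a positive
  reference; `classify_status` rejects negative EQR.
- Permutation p-values use the +1/+1 correction throughout, so p = 0 is
  impossible and p ≥ 1/(n_perm+1).
- Readers sort rows and columns lexicographically so that written outputs
  are byte-stable across runs; `run_pipeline()` under a fixed config and
  seed is checksum-reproducible, which the suite asserts.
- Ties in all rank statistics use average ranks; tie corrections are
  applied where the classical statistic defines them.

# Problem sizes used in validation

The test suite and acceptance script size their simulations for a
single-CPU desk run: the full suite completes in well under a minute, the
acceptance script in a few minutes. The heaviest checks are the PERMANOVA
type-I calibration (500 null simulations of n = 12 observations at 199
permutations each, rejection rate required within 2 binomial standard
errors of α = 0.05), the exhaustive n = 6 permutation oracle (720
permutations against a classical one-way ANOVA F oracle), and the
synthetic PERMANOVA in the acceptance script (32 observations, 9,999
permutations). These sizes are the package's validation conditions, chosen
once; enlarging them tightens nothing conceptually.

# Known limitations

- The IBMWP score table ships as editable data following the published
  index; users must verify it against the current official version before
  regulatory use.
- Reference values and class boundaries are user configuration by design;
  results are only as intercalibrated as that configuration.
- Name matching is exact; synonymy must be resolved upstream (a synonym
  table hook exists in the checklist format via additional rows).
- Free permutation is the only PERMANOVA scheme implemented; designs
  needing restricted permutation (nested or repeated-measures structures)
  are out of scope.
- Presence/absence only: read counts are used solely for filtering, never
  for weighting.
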