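---
title: "Methods: phosphoproteomic and high-content analysis of GSK3-pathway screens"
author: "crmp2screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphoproteomic and high-content analysis of GSK3-pathway screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmp2screen)
```

# Scope and model

crmp2screen implements the two computational arms of a lithium-mimetic
discovery workflow built on GSK3 signaling in human neurons:

1. a **SILAC phosphoproteomics arm** that takes a searched phosphopeptide
   quantification table (one row per quantified phosphopeptide, with
   treated/control abundance ratios for CHIR-99021 at 1 and 10 µM in two
   replicate SILAC experiments) and produces the filtered peptide set,
   regulation calls, per-protein summaries, a GSK3 phospho-motif position
   frequency matrix, and a protein–protein interaction component summary;
2. a **high-content imaging arm** that segments nuclei in three-channel
   fluorescence images (nuclear / MAP2 / p-CRMP2^T514^), classifies cells
   with four collar-ring criteria, traces neurites from the MAP2 channel,
   and reports per-well percent p-CRMP2/MAP2 and MAP2⁺ neuron counts, which
   plate-level analytics turn into normalized percentages, Z′ quality
   control, banded hit calls and a toxicity counter-screen.

Both arms are exercised end to end by seeded synthetic generators, because
the raw mass-spectrometry output and the raw plate images of the original
study are not redistributable. The generators define the study conditions
the tests assume; their defaults are documented here and are not tuned
against test outcomes.

# The phosphoproteomics arm

## Filter cascade

Four conjunctive retention rules are applied to the loaded table:
identification in both SILAC experiments; not a decoy; at least one fully
localized phosphosite; and quantification in both replicates for at least
one treatment condition. Because the rules are conjunctive, their
application order cannot change the result, and the test suite checks the
retained set against a brute-force per-record oracle applied in several
permuted orders. "Observed in both experiments" is deliberately distinct
from the replicate-quantification rule: a peptide may be identified in an
experiment without yielding a usable ratio, so records carry the set of
experiment identifiers in which the peptide was seen.

## Normalization and the regulation test

Ratios are log2-transformed and each condition × replicate channel is
centered so its median over quantified peptides is exactly zero (verified
to 1e−9 in tests). Missing cells stay missing; an entirely unquantified
channel is skipped with a typed warning.

The default per-peptide test is a two-sided one-sample *t*-test of the
replicate log2 ratios against zero, with Benjamini–Hochberg control over
all scored peptides and significance at adjusted p < 0.05. Two conventions
cover the degenerate cases: replicates that are all exactly zero give
p = 1 (zero effect), and zero spread around a nonzero mean gives p = 0.
Peptides with fewer than two replicate values in the tested condition are
flagged unscored (p = NA) rather than dropped — a one-sample *t*-test has
zero degrees of freedom at n = 1.

With only two replicates this default test has a single degree of freedom,
so two-sided p < 0.05 requires |t| > 12.7; at a planted effect of −1.5
log2 units against replicate noise of 0.3 its power is only ≈ 0.42, and
the empirical false discovery proportion of nominal calls is high. This is
a faithful property of 1-df testing (it is why corrected-significant sets
in such data are small relative to nominal ones), not an implementation
artifact. For recovery of planted signal the package therefore exposes
`test_regulation(method = "moderated")`, an empirical-Bayes moderated
one-sample test (limma `lmFit`/`eBayes`) that borrows variance information
across peptides. The recovery properties in the tests and the acceptance
script (sensitivity ≥ 0.8 at FDR ≤ 0.1 under the generator's default
conditions) use the moderated test; the plain *t*-test remains the default
for descriptive volcano statistics.

## Protein summaries, motif matrix, network

Per-protein counts of regulated peptides default to the nominal p < 0.05
set (the convention behind published per-protein summaries at this
replicate depth), with adjusted-significance counting available. Peptides
mapping to a configured accession group — by default GSK3A/GSK3B, whose
tryptic phosphopeptides are shared — are counted once under the merged
key; otherwise the first accession wins. Ties in the ranking are broken
lexicographically for reproducible output.

The motif matrix takes a 13-residue window (site ± 6) around every fully
localized down-regulated S/T site, pads past protein termini with a gap
symbol, and computes per-column frequencies excluding gaps. The canonical
GSK3 substrate consensus S/T-X-X-X-pS/pT appears as S/T modal columns at
offsets 0 and +4. The window length is a package choice; 13 comfortably
contains the +4 priming position with symmetric context. No enrichment
test against a background proteome is performed — the matrix is
descriptive.

The interaction network restricts an input edge list (two-column TSV or
SIF) to the protein set of interest, drops foreign edges with a count, and
reports connected components over nodes of degree ≥ 1, singletons, and
the connected fraction of the full set.

## The phosphopeptide generator

`phospho_spec()` defaults: 1000 peptides, 20% true substrates with mean
log2 shifts of −1.5 (10 µM) and −0.8 (1 µM), replicate noise 0.3, decoy
rate 5%, unlocalized rate 10%, per-channel missingness 10%,
single-experiment rate 5%, and the consensus context planted at 90% of
true substrate sites (an S/T at +4; non-substrates get an explicit
non-S/T at +4 so the background motif stays flat). Roughly three peptides
share each synthetic 60-residue protein so per-protein counting is
non-trivial. Everything is a pure function of the seed.

# The imaging arm

## Segmentation and the four criteria

Nuclei are segmented by Otsu global threshold, hole filling, and watershed
on the distance map (EBImage), which splits touching nuclei with distinct
peaks. Areas are reported in µm²; the default calibration is 0.65 µm/px,
a plausible ×20-objective value, and every size threshold is applied in
micron units so the calibration is the single point of unit truth.

Classification applies, in order: (1) nuclear size inside [50, 160] µm²
(inclusive ends; smaller is debris, larger is clumps) — the published
unit for this band is ambiguous, so an equivalent-diameter mode is
available behind `size_unit`; (2) mean nuclear intensity ≥ 2197 counts
(the printed unit "pixels" for this threshold is treated as a typo for
camera counts, and the value is configurable); (3) collar-ring MAP2 mean
above a floor, estimated per image as background mean + 3 sd from
sub-Otsu pixels unless overridden; (4) collar-ring MAP2 coefficient of
variation > 1 for neurons. The CV direction is implemented exactly as
printed: a neuron's 2-µm collar ring mixes bright MAP2 puncta and neurite
roots with dark background, so its CV is high, whereas a MAP2-negative
cell's ring is uniformly dim. An inverted mode exists behind a flag. Each
rejection is labelled by its first failing criterion in the numbered
order. Rings are clipped at image borders and always exclude every
nucleus, not only their own.

## Neurite tracing and the well statistic

The MAP2 channel is thresholded (per-image Otsu, fixed override
available), soma regions (nuclei dilated by 2 µm) are removed, and the
remaining mask is reduced to a one-pixel skeleton by Zhang–Suen thinning
(implemented in the package; tests pin a straight 100-px, 3-px-wide
neurite to a 98–102-px skeleton). Only skeleton components adjacent to a
soma are retained, and both MAP2 and p-CRMP2 intensities are measured on
the retained pixels.

The well readout in high-content mode averages the field-level neurite
means (restricted to fields containing MAP2⁺ neurons), subtracts the
per-channel median as a background estimate by default, and reports
100 × p-CRMP2 / MAP2. Field-level averaging is the default aggregation;
a whole-field mode with no per-cell gating (total above-background
intensity) emulates a laser-scanning-cytometer readout. A well with no
neurons reports a typed missing percent and a count of zero. The
statistic is scale-invariant under common gain changes and linear in a
p-CRMP2-only gain, which the tests verify in the noise-free case.

## The plate generator

`plate_spec()` defaults: 192 × 192-px fields at 0.65 µm/px; per field 8
neurons, 5 MAP2-negative cells, 3 debris (< 50 µm² by construction), 1
clump (> 160 µm²); nuclear mean 12000 ± 1500 counts, MAP2 signal 9000
over a constant background of 600 with additive Gaussian camera noise of
sd 150 — the simplest intensity model that stresses the thresholds.
Neurons extend three smoothed random-walk neurites (30–60 steps, 3 px
wide) whose p-CRMP2 signal is the well's suppression factor *f* times the
MAP2 signal; walks stop before entering another cell's collar zone so
ring statistics stay attributable. Placement is collision-free with
bounded retries and explicit failure. Four fields per well by default
(the protocol range is 4–6).

The dose–response helper `hill_suppression()` is a Hill curve with top 1
and coefficient 2 whose bottom (0.5612562) and EC50 (1.5581033 mM) were
solved once so that 1 mM maps to 87.2% and 2.5 mM to 68.4% of control —
the published lithium magnitudes the synthetic assay emulates. The real
plate statistics themselves (Z′ = 0.6, the 23.2% positive control) are
properties of unavailable raw images; the generator reproduces their
magnitudes, not their noise structure, so synthetic Z′ values are higher
than the published one.

What the generator does *not* emulate: optics (PSF, shading,
bleed-through), intensity gradients, touching cells across class
boundaries, or realistic neuronal morphology. Passing tests therefore
demonstrate correctness of the measurement pipeline under a controlled
model, not performance on real micrographs.

# Screen analytics

Normalization expresses each well as a percentage of a reference mean:
DMSO wells, the all-well average (the primary-screen convention), or
lithium reference wells (re-test convention, lithium at 1 mM = 100%).
Z′ uses sample (n−1) standard deviations, `1 − 3(σ₊+σ₋)/|μ₊−μ₋|`, and
returns a typed NA when the arm means coincide.

Hit banding resolves the overlap between the published "<80%"
(GSK3-inhibitor-like) and "75–90%" (candidate) brackets by partitioning at
80: strong < 80 ≤ candidate < 90 ≤ inactive, with edges configurable. A
compound whose MAP2⁺ neuron-count ratio against reference falls below 0.5
(configurable; no published cutoff exists) is called toxic, overriding any
activity band. The unpaired *t*-test is equal-variance by default (Welch
behind a flag) with stars at the printed bands, lower edges inclusive:
`*` 0.01 ≤ p < 0.05, `**` 0.001 ≤ p < 0.01, `***` 0.0001 ≤ p < 0.001,
`****` p < 0.0001.

# Problem sizes, determinism, limitations

The test suite and `scripts/acceptance.R` run entirely on synthetic data.
Chosen problem sizes: 1000-peptide tables for filter/recovery properties;
300–500-peptide tables for motif and protein summaries; 20 seeds for
motif and classification accuracy properties; a 96-well screen at 144-px
fields with 6 neurons per field, 4 fields per well, over 10 seeds for the
end-to-end recovery property. These sizes keep the full suite in the
minutes range while leaving every statistical margin comfortable; they
are package choices, stated here so they can be scaled up.

All randomness flows through explicit seeds; per-field and per-object
streams are derived deterministically so any field can be regenerated in
isolation, and plate regeneration is byte-identical on disk (verified by
checksum in the tests).

Known limitations: the published supplementary phosphopeptide export is
not redistributable with the package, so the reproduction of its printed
counts (2829 retained peptides and downstream summaries) requires placing
that export at `inst/extdata/spectrum_mill_export.tsv`; the corrected-
significant count depends on the unstated correction method behind the
published value and is reported as computed, never tuned. Skeleton length
is a pixel count and slightly underestimates curved path length; per-
neuron morphometrics (branching, Sholl) are out of scope, as the pooled
per-field neurite intensity is what the well statistic needs.
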