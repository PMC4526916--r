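---
title: "capemine: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{capemine: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capemine)
```

# The problem

CAP-superfamily proteins (cysteine-rich secretory proteins, antigen 5 and
pathogenesis-related 1) can be proteolytically processed at their C
terminus into an 11-residue peptide hormone, the CAP-derived peptide
(CAPE). The mature peptide matches the positional pattern `PxGNxxxxxPY`
and is released at the bond following a four-residue `CNYx` cleavage
signal; substituting the signal's tyrosine abolishes processing, so
candidates carrying the peptide motif behind a mutated signal are reported
as motif hits flagged *cleavage incompetent* rather than silently
dropped. `capemine` turns the full desk workflow around this biology —
candidate mining, targeted-assay design, label-free quantification,
expression screening and phenotype summaries — into a tested R package,
with seeded synthetic-data generators standing in for instrument and array
data.

# Mining model

A candidate is the C-terminal-most window of 15 residues (4-residue
signal + 11-residue peptide) whose peptide positions match the pattern
and whose last residue lies within `terminal_slack` residues of the
protein end (default 0: all catalogued CAPEs end their precursor, so the
motif is anchored to the C terminus). Competence is decided solely by the
critical signal position (default position 3, tyrosine); the other signal
positions are recorded but not required, which is what lets the
CNAD-style mutant appear as an incompetent hit.

The homology prefilter is an optimal local alignment (Smith–Waterman)
score under affine gaps, where a gap of length $L$ costs
$\text{gap\_open} + L \cdot \text{gap\_extend}$ (defaults 10 and 1,
BLOSUM62). A raw score threshold replaces a database E-value: E-values are
a function of database size and composition, which a desk-scale fixture
does not meaningfully have, and the motif rule — not the homology step —
determines the candidate set. The threshold therefore defaults to 0
(disabled). The scorer is compiled (Rcpp) and is checked in the test suite
against an independent plain-R dynamic-programming oracle; during
development it was also verified to agree exactly with
`Biostrings::pairwiseAlignment(type = "local")` under the same gap
convention.

Nomenclature ranking uses ungapped positional percent identity,
$100 \cdot \text{matches}/11$, against a reference peptide; all in-scope
peptides are 11-mers and unequal lengths are rejected rather than
aligned. Ties are broken by ascending precursor id so the ordering is
total and reproducible.

# Mass model

Residue masses are standard monoisotopic and average tables to at least
four decimals, with water 18.010565 Da and proton 1.007276 Da. Precursor
m/z is $(M + z\,m_{H^+})/z$; fragment ions are singly charged b/y series
($b_i$ = N-terminal running sum + proton; $y_i$ = C-terminal running sum +
water + proton), the appropriate model for ion-trap CID of a small
peptide. Two identities serve as property tests: additivity
$M(AB) = M(A) + M(B) - M(H_2O)$ and complementarity
$b_i + y_{n-i} = M + 2\,m_{H^+}$, both to $10^{-9}$ Da.

With these constants the AtCAPE1 worked example reproduces every printed
assay value: 589.80 for the doubly protonated analyte, 563.29 / 676.38 /
900.47 for its y5/y6/b9 transitions, and 537.28 / 650.36 / 813.43 for the
internal standard's y5/y6/y7 — all within the ±0.15 Th band we allow when
comparing theory to values printed from an ion-trap method section. The
printed IS precursor (562.4) sits between the theoretical monoisotopic
(562.30) and average (562.65) values; since the convention behind the
printed number is unknowable, `design_internal_standard()` reports both.

The default transition-selection rule (descending m/z among in-range
ions) is a deterministic stand-in for "most intense fragments", which
cannot be predicted without a spectrum; the published ion sets are
supplied explicitly in `atcape1_assay()`, and any curated set can be
passed to `build_assay()` the same way.

An external-calculator oracle is frozen as a fixture: 100 random peptides
with masses from an independent reference implementation. Monoisotopic
masses agree to better than $10^{-4}$ Da. Average masses agree to 0.06 Da
over peptides up to 30 residues — average residue tables legitimately
differ between references in the third decimal, so that assertion is
looser by design, not because of a defect.

# Quantification model

The canonical input is a long trace table (sample, transition, retention
time, intensity); a raw-spectra route (per-scan m/z lists) is reduced to a
trace by summing intensity within ±tolerance (default ±0.5 Th, ion-trap
resolution) of the target m/z. Integration is trapezoidal over a window
centred on the apex (default half-width 30 s), after subtracting the
median of the window's first and last three points (`edge_median`), which
maps a constant offset to zero area; `none` is available for closed-form
oracle tests. Areas are clamped at zero. The published protocol states
neither window, baseline nor smoothing, so these defaults are declared
choices, not inferences.

Per sample, the analyte readout is the *sum* of its transition areas
divided by the sum of the internal-standard transition areas; missing
transitions contribute zero with a warning, and a zero IS sum flags the
sample out of ratio computation. Relative ratios divide each sample's
normalized value by a designated control sample's, with the control
pinned at exactly 1. Because the IS is co-extracted and co-measured, any
per-sample global intensity scale cancels exactly — a metamorphic test in
the suite.

# Expression screen

QC keeps a gene if there **exists** a time point (condition) at which the
replicate mean raw intensity exceeds 100 and the CV (sd/mean) is below
50% — the "at any time point" rule, tested on constructed cases.
Normalization is per-sample median scaling to the control condition's
median; the original analysis named its control but not its algorithm, so
this is a declared substitute. Differential expression uses the ratio of
condition means (linear scale) with a Welch t-test on log2 intensities,
calling a gene at FC ≥ 1.5 (or ≤ 1/1.5) and P ≤ 0.05 with no multiplicity
correction — faithfully reproducing a raw-p screen; a Benjamini–Hochberg
flag is available in `screen_config()`. Two identical zero-variance
groups get p = 1 by convention.

Specificity: a gene is `salt_specific` when DE under salt and DE in at
most `specificity_stress_limit` non-salt stress categories (default 1 —
the source text says both "regulated mainly by salt" and "more than two
abiotic stresses", so the boundary is exposed as configuration);
`multi_stress` when DE in more non-salt categories than the limit;
`non_responsive` otherwise. The classification is invariant to the order
of panel rows.

# What the generators emulate — and what they do not

**Proteomes.** True precursors are uniform-random sequences ending in
`CNYx` + a random pattern instance; four decoy families probe one mining
rule each (no motif, internal motif vs the terminal-slack rule, mutated
critical tyrosine vs the competence flag, one broken pattern position vs
the matcher). Bodies are resampled until they carry no accidental
terminal match, so mining sensitivity and specificity are exactly 1 by
construction. Real proteomes bring homologous families, low-complexity
regions and non-canonical residues; a green mining test here establishes
the rules, not real-proteome FDR.

**Chromatograms.** One Gaussian peak per transition per sample on a
shared grid (default σ = 8 s sampled at σ/8, apex jittered per sample,
additive truncated-Gaussian noise with sd 20 against a base amplitude of
1000, i.e. 2%), with fixed per-transition response factors. The closed
form $A\sigma\sqrt{2\pi}$ provides an analytic area oracle. Tailing,
isotope envelopes, interference and saturation are deliberately absent:
recovery tests validate the integration/normalization arithmetic, not
chromatographic robustness.

**Expression matrices.** Log-normal intensities: per-gene baseline log2
level from N(10, 1.5) truncated below at log2(180) so every
non-QC-failure gene sits unambiguously above the raw-intensity floor and
the planted QC truth is exact; replicate noise N(0, 0.25) on log2 (about
18% CV); planted responses are additive log2 fold changes; three
replicates per condition over a control + salt/osmotic/drought/cold/
oxidative panel. Planted QC failures are deterministic: dim genes around
raw intensity 16, and high-CV genes carrying a fixed 0.05/1/3 replicate
pattern (CV ≈ 112% at every time point). Probe effects, batch structure
and intensity-dependent variance are not modelled.

# Numerical and degenerate-input choices

- Unknown residues are rejected with their position, everywhere.
- Proteins shorter than 15 residues yield no candidate (not an error);
  empty proteomes return an empty table with a warning; malformed FASTA
  is rejected by the reader.
- `severity_class` generalizes the six-leaf diagram to leaf fractions
  (I: dead or no green leaves; IV: green ≥ 5/6; III: green ≥ 4/6;
  II: pale-or-green ≥ 4/6 with green < 4/6; else I), with the dead/no-green
  rule taking precedence; exact six-leaf cases reproduce the published
  assignments.
- Spectrum annotation assigns ion/peak pairs greedily by ascending m/z
  error, so one peak satisfies at most one ion and the closest pair wins.
- All generator randomness flows through one seeded RNG scope per call
  (the caller's RNG state is restored), making every artifact
  byte-reproducible from its spec.

# Known limitations

- No mzML reader: the raw-spectra route accepts in-memory scan tables;
  vendor/mzML conversion must happen upstream.
- No post-translational modifications, multiply charged fragments or
  isotope envelopes in the mass model.
- The homology prefilter reports raw scores only; there is no E-value
  statistics layer, by design.
- The screen's normalization and test are declared substitutes for an
  unpublished commercial pipeline; absolute DE counts from real array
  series are therefore out of scope, and only planted-truth recovery is
  asserted.
- The 172-residue example precursor is a synthetic architectural stand-in
  (`synthetic_proatcape1()`), not the database sequence.
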