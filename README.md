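# capemine

Discovery and targeted quantification of CAP-derived peptides (CAPEs) in R.

CAPEs are 11-residue peptides released from the C terminus of
CAP-superfamily precursor proteins (cysteine-rich secretory proteins,
antigen 5, and pathogenesis-related 1). The mature peptide matches the
conserved positional pattern `PxGNxxxxxPY` and sits immediately behind a
four-residue `CNYx` cleavage signal whose tyrosine is required for
proteolytic release; in *Arabidopsis*, the salt-regulated member AtCAPE1
(`PAGNYIGARPY`, from the AT4G33730 precursor) is quantified by a targeted
LC-MS/MS assay against a sequence-substituted internal standard. `capemine`
implements that entire desk workflow as tested, reusable functions:

- **Proteome mining** — Smith–Waterman homology prefilter (affine gaps,
  BLOSUM62, compiled in C++), C-terminal motif matching with a
  cleavage-competence flag (`CNYx` position 3 must be Y), percent-identity
  nomenclature ranking.
- **Mass assay design** — monoisotopic/average masses, precursor m/z
  `(M + z·H⁺)/z`, b/y fragment ladders
  (`b_i = Σresidues(1..i) + H⁺`, `y_i = Σresidues(n−i+1..n) + H₂O + H⁺`),
  substituted internal standards with collision checks, transition
  selection, spectrum annotation with y/b series coverage.
- **Label-free quantification** — XIC extraction, baseline-subtracted
  trapezoidal peak integration, summing of the three transitions per
  peptide, internal-standard normalization, relative ratios against a
  control sample.
- **Expression screening** — raw-intensity floor (>100) and CV ceiling
  (<50%) QC at *any* time point, Welch-t differential expression at
  FC ≥ 1.5 and P ≤ 0.05, salt-specificity classification across a stress
  panel, and the qPCR `scale · 2^−ΔCt` transform.
- **Phenotype summaries** — seedling severity classes I–IV from leaf
  counts/colour and germination-rate tables.
- **Synthetic data** — seeded generators for planted-motif proteomes with
  four decoy families, Gaussian transition chromatograms with closed-form
  true areas, and expression matrices with planted fold changes and QC
  failures, so every stage can be validated against known ground truth.

## Worked example

```r
library(capemine)

# The published assay: analyte + triply substituted internal standard
assay <- atcape1_assay()
assay
#> Targeted assay: PAGNYIGARPY (m/z 589.80, z=2) with IS PAAAYIGARAY (m/z 562.30)
#>   analyte transitions: y5 563.29, y6 676.38, b9 900.47
#>   IS transitions:      y5 537.28, y6 650.36, y7 813.43

# Mine a synthetic proteome with planted precursors and decoys
sim <- generate_proteome(proteome_spec(5, 95,
  decoy_modes = c("no_motif", "internal_motif",
                  "mutated_cleavage_Y", "broken_motif"), seed = 7))
cands <- mine_proteome(sim$sequences, reference_peptide = "PAGNYIGARPY")
nrow(cands)                       #> 29  (5 true + 24 Y-mutated decoy hits)
sum(cands$cleavage_competent)     #> 5   (exactly the true precursors)

# Quantify a simulated salt-treatment run (designed 4-fold induction)
run <- generate_run(run_spec(c("control", "treated"),
                             designed_abundance = c(1, 4), seed = 11),
                    assay)
quantify_run(run$traces, assay, "control")
#>   sample_id analyte_area  is_area normalized flagged relative_ratio
#> 1   control     47779.47 46797.14   1.020991   FALSE       1.000000
#> 2   treated    190052.42 47217.40   4.025050   FALSE       3.942296
```

The `relative_ratio` column is the IS-normalized analyte area divided by
the control sample's value — the label-free readout the assay reports
(here recovering the designed 4-fold induction within ~1.5%).

## Command line

```sh
Rscript inst/cli/capemine.R mine --fasta proteome.fasta \
    --reference PAGNYIGARPY --out candidates.tsv
Rscript inst/cli/capemine.R assay --peptide PAGNYIGARPY --out assay.tsv
Rscript inst/cli/capemine.R simulate run --seed 1 --ratio 4 --out sim/
Rscript inst/cli/capemine.R quant --traces sim/traces.tsv \
    --control control --out quant.csv
```

See `vignettes/capemine-methods.Rmd` for the model, parameter choices,
what the synthetic generators do and do not emulate, and known
limitations.
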