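# mixsplice

Tools for deciding whether an apparent condition-dependent change in
alternative splicing measured in bulk RNA-seq of a mixed cell population is
real splicing regulation or an artefact of cell-type composition change.

## The problem

Bulk RNA-seq of a mixed culture — say 85% neurons and 15% astrocytes —
averages over cell types. If a treatment kills one cell type (a strongly
depolarising high-K⁺ stimulus kills neurons via NMDA-receptor
excitotoxicity while sparing astrocytes), every cell-type-dependent readout
shifts with no change inside any cell. Splicing is especially exposed: at
splice-site 4 of *Nrxn1* the inclusion:exclusion isoform ratio is ~0.28 in
neurons but ~36 in astrocytes, so a falling neuron fraction alone drives the
bulk SS4⁺/SS4⁻ ratio up.

For an event with per-type inclusion fraction ψ_t (PSI), gene expression
g_t and mRNA-mass weight w_t, the pooled sample shows the
expression-weighted mean

    ψ_mix = Σ_t w_t g_t ψ_t / Σ_t w_t g_t

A composition shift w → w′ with no within-cell change produces an apparent
Δψ = ψ_mix(w′) − ψ_mix(w) at *every* divergent event. Plotting the
condition-wise Δψ (y) against the cell-type difference ψ_a − ψ_n (x) then
gives a strong correlation with a slope strictly between 0 and 1 — the
fingerprint `mixsplice` detects.

The package provides:

* **Marker curation** — cell-type-specific gene sets from pure reference
  transcriptomes (`curateMarkers`: mean > 10 FPKM and ≥ 10-fold higher;
  `restrictToExpressed`).
* **Composition audit** — `fractionOfPure`, `signCountEnrichment`,
  `pairedT`, `meanFoldChange`, and NNLS mRNA-fraction estimation
  (`estimateWeights`, `auditComposition`).
* **Splicing quantification** — length-normalised PSI (`computePsi`), a
  likelihood-ratio test of |Δψ| ≤ c (`deltaPsiTest`), BH filtering
  (`filterEvents`), rMATS-style table I/O (`readRmatsTable`,
  `writeRmatsTable`).
* **Confound diagnostic** — `deltaDeltaCorrelation` (Pearson r with
  Fisher-z CI, OLS slope with CI, permutation p), mixture-model predictions
  (`predictMixtureDeltaPsi`, `compositionShiftRegression`).
* **qPCR isoform arithmetic** — efficiency-corrected ΔΔCt
  (`relativeQuantity`), within-sample isoform ratios (`isoformRatio`), and
  pooled-RNA net ratios (`netMixtureRatio`).
* **Synthetic data** — `generateReference`, `mixBulkSample`,
  `simulateExperiment`: a two-cell-type generator whose defaults emulate
  the neuron/astrocyte co-culture and its neurotoxic composition shift.
* **Orchestration** — `runFullAudit` runs the whole chain and writes
  reproducible TSV/JSON reports; `convertSupplementary` turns a source-data
  workbook into per-panel TSVs for `panelAnova`.

## Worked example

```r
library(mixsplice)

## the flagship mixing arithmetic
psi <- psiFromRatio(c(0.28, 36))        # 0.21875  0.97297
mixturePsi(c(0.85, 0.15), c(2, 1), psi) # 0.2799032
netMixtureRatio(0.28, 36, 2 * 0.85, 1 * 0.15)
# [1] 0.3887022  -- the pooled SS4+/SS4- ratio of an 85/15 RNA mix

## the full synthetic audit: composition shift, no within-cell change
res <- runFullAudit(defaultAuditConfig(seed = 1))
res$confound
# ConfoundReport on 222 matched events
#   Pearson r = 0.9255 (95% CI 0.9040 to 0.9423), p = 1.03e-94
#   OLS slope = 0.2678 (95% CI 0.2533 to 0.2824)
#   permutation p = 0.001
#   unmatched events dropped: condition=0, cellType=378
res$composition
# CompositionReport
#   fraction of pure neuron: 86.3 +/- 1.1% (n = 99 genes)
#   fraction of pure astrocyte: 19.1 +/- 0.4% (n = 55 genes)
#   neuron markers: 0/99 up (sign test p = 3.16e-30)
#   astrocyte markers: 55/55 up (sign test p = 5.55e-17)
#   estimated mRNA-mass weights:
#           control treated
# neuron      0.846  0.4999
# astrocyte   0.154  0.5001
```

Reading: every filtered "treatment-responsive" splicing event lines up
with the astrocyte−neuron splicing difference (r = 0.93) at a slope well
inside (0, 1), astrocyte markers rise unanimously while neuron markers
fall, and the NNLS weights recover the planted 0.85 → 0.50 neuronal mRNA
loss — the treatment "effect" is pure composition.

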