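---
title: "Auditing cell-type composition confounds in alternative splicing analyses"
author: "mixsplice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing cell-type composition confounds in alternative splicing analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixsplice)
```

# The problem

Bulk RNA-seq of a mixed cell population measures a weighted average over its
constituent cell types. When a treatment changes the *proportions* of those
cell types — for example, a strongly depolarising high-K⁺ stimulus that
kills neurons through NMDA-receptor-dependent excitotoxicity while sparing
astrocytes — every cell-type-dependent molecular readout shifts, even if
nothing changes inside any cell. Alternative splicing is especially
vulnerable: neurons and astrocytes make systematically different splicing
choices, so a change in the neuron:astrocyte ratio masquerades as
condition-dependent splicing regulation. The canonical example is
splice-site 4 (SS4) of *Nrxn1*, where the inclusion-to-exclusion isoform
ratio is roughly 0.28 in cortical neurons but about 36 in astrocytes — two
orders of magnitude apart. A mixed culture losing neurons therefore shows a
rising bulk SS4⁺/SS4⁻ ratio with no change in either cell type.

`mixsplice` packages the audit that exposes this artefact: marker-gene
composition proxies, PSI estimation and interval-null testing, an explicit
two-cell-type mRNA mixture model, and the Δ–Δ correlation diagnostic that
relates condition-wise splicing changes to cell-type splicing differences.

# The mixture model

Let cell type $t$ contribute a fraction $w_t$ of the total mRNA mass
($\sum_t w_t = 1$), express gene $g$ at level $g_t$ (FPKM-like units per
unit of mRNA), and include a given alternative exon in a fraction
$\psi_t \in [0,1]$ of that gene's transcripts (the percent spliced in,
PSI). The pooled sample then shows

$$\psi_{mix} = \frac{\sum_t w_t\, g_t\, \psi_t}{\sum_t w_t\, g_t},$$

the *expression-weighted* mean of the per-type PSI values. Two properties
drive everything else:

* $\psi_{mix}$ is bounded by the per-type PSIs and moves monotonically
  toward the PSI of whichever type gains weight;
* the influence of a cell type is damped by low expression of the event's
  gene — astrocytes dominate the culture's SS4⁺ signal despite expressing
  *Nrxn1* at only half the neuronal level, but less than they would
  otherwise.

For a shift $w \to w'$ with *no within-cell-type change*, the apparent
condition effect is $\Delta\psi = \psi_{mix}(w') - \psi_{mix}(w)$. In the
equal-expression limit this is exactly $\Delta w \cdot (\psi_a - \psi_n)$:
a straight line through the origin with slope $\Delta w$ when plotted
against the cell-type difference. Heterogeneous expression perturbs each
event's attenuation factor, which lowers the correlation below 1 but keeps
the slope strictly inside $(0, 1)$ for a partial shift. That is the
signature the Δ–Δ diagnostic looks for: `deltaDeltaCorrelation()` puts the
condition contrast on y, the cell-type contrast on x, and reports Pearson
r with a Fisher-z interval, the OLS slope with its interval, and a
permutation p. A strong r with slope below 1 says the "treatment effect"
is an attenuated image of the cell-type difference.

The same arithmetic expressed in isoform-ratio units
($R = \psi/(1-\psi)$, so $\psi = R/(1+R)$) gives the pooled ratio of a
physical RNA-mixing experiment, `netMixtureRatio()`: mixing neuronal RNA
($R = 0.28$, relative amount $2 \times 0.85$) with astrocytic RNA
($R = 36$, $1 \times 0.15$) yields $\psi_{mix} = 0.280$ and a net ratio of
0.389.

# Composition proxies

`curateMarkers()` implements the dual-threshold rule: a gene is cell-type
specific if its replicate-mean expression exceeds 10 FPKM in the high type
(*strictly* greater, matching the wording ">10 FPKM") and is at least
10-fold its mean in the other type (ties at exactly 10-fold included). No
pseudocount is added — a thresholding rule should not depend on an
arbitrary offset — and a zero mean in the low type counts as infinite fold
but still requires the expression floor. `restrictToExpressed()` applies
the ">10 FPKM in the target data" condition; its default scope is the
*control* samples only, because the treated samples' marker expression is
precisely the quantity under test (this scope is a genuine ambiguity; both
scopes are one argument away).

Four proxies quantify composition and its change:

* `fractionOfPure()` — marker FPKM in the mixed sample as a percent of the
  pure culture, summarised as mean ± SEM across genes (the per-gene mean
  is the headline; the ratio-of-means pooled variant is also reported,
  since either reading is defensible);
* `signCountEnrichment()` — how many markers moved up vs down, with an
  exact two-sided binomial sign test (ties excluded);
* `pairedT()` — the classic paired t on per-gene condition means;
* `estimateWeights()` — non-negative least squares of the mixed profile on
  the pure profiles over the marker genes, normalised to sum to 1
  (`pracma::lsqnonneg` is the solver; near-collinear references are
  flagged).

# PSI estimation and the interval-null test

From inclusion reads $I$ and skipping reads $S$ with effective form
lengths $l_I, l_S$ (defaults 2 and 1 junction equivalents for skipped-exon
topology), $\hat\psi = (I/l_I)\,/\,(I/l_I + S/l_S)$. `deltaPsiTest()`
pools replicates within group and tests $H_0: |\psi_1 - \psi_2| \le c$
(default $c = 0.05$) with a likelihood-ratio statistic against a binomial
read-allocation model; the constrained optimum is found by 1-D search on
the boundary $\psi_2 = \psi_1 \pm c$ (both signs scanned, tolerance 1e-9),
and p comes from $\chi^2_1$. When the unconstrained estimates already
satisfy the null, $\Lambda = 0$ and $p = 1$. Events with no reads in a
group propagate as flagged `NA`, never as silent zeros.
`filterEvents()` applies Benjamini–Hochberg across events and keeps
$p_{adj} < 0.05$ with mean per-sample $I + S$ strictly above 100 — the
printed thresholds of the analysis this package audits.

Two deliberate simplifications, and what they cost: replicates are pooled
(no overdispersion term), so on real data the p-values are
anti-conservative relative to tools with a hierarchical replicate model,
and event lists are expected to *approximate*, not match, rMATS output
(the published 612-event list is tied to that tool's internals). The
interval null at the boundary makes the test conservative — simulated
type-I error at $\alpha = 0.05$ runs near 0.01–0.02, comfortably below
the 0.07 ceiling the calibration check enforces — because the worst case
$|\Delta\psi| = c$ contributes roughly half-tail rejections and interior
nulls contribute almost none.

# The synthetic-data generator

`generateReference()` and `simulateExperiment()` emulate the study design
the audit targets, and their defaults *are* those conditions:

* two cell types; one flagship event (`Nrxn1_SS4`) fixed at the hallmark
  values $R_n = 0.28$, $R_a = 36$, on a gene expressed 2:1
  neuron:astrocyte, so the published mixing arithmetic is reproduced
  exactly;
* a planted fraction of genes (default 20%) exactly satisfying the
  >10 FPKM & ≥10-fold marker rule — `curateMarkers()` must recover them
  verbatim, which the tests assert by brute-force re-scanning the emitted
  tables;
* a planted fraction of events (default 50%) with $|\psi_a - \psi_n| \ge
  0.5$, the strong cell-type splicing divergence the Δ–Δ diagnostic needs
  as its x-axis;
* control weights (0.85, 0.15) — the mixed culture of 85% NeuN⁺ neurons /
  15% GFAP⁺ astrocytes — and treated weights (0.50, 0.50), emulating
  substantial excitotoxic neuronal death. The treated value reproduces the
  *direction and approximate magnitude* of the published mixing
  experiment; the true per-cell RNA-yield conversion is not published, so
  weights are defined on mRNA mass, with `cellCountsToWeights()` as the
  documented converter;
* junction reads per event drawn as
  $n \sim \text{Poisson}(\text{depth} \times g_{mix}/\bar g_{mix})$, so
  `depth` reads as "expected junction reads for an average-expression
  event" (default 2000, a modest bulk coverage) and lowly expressed genes
  are read-poor — reproducing the read-support filter's real behaviour;
* reads split $I \sim \text{Binomial}(n, \psi l_I/(\psi l_I + (1-\psi)
  l_S))$: binomial counting noise only by default, with optional
  multiplicative log-normal expression noise (`exprNoiseSd`, 0 by default;
  0.2 in the bundled audit config, a typical between-replicate spread);
* a single master seed, with per-sample substreams derived
  deterministically from (seed, condition, replicate), so regenerating any
  sample is independent of how many others are drawn and identical
  configurations give byte-identical outputs.

What the generator does **not** emulate: read-level artefacts (fragment
length, GC, mapping bias), overdispersion beyond the log-normal expression
term, more than two cell types in the tested workflows, and any
within-cell-type splicing response. Passing tests therefore demonstrate
that the *pipeline* behaves correctly under a pure composition shift —
they cannot certify that any particular real dataset contains no genuine
within-cell splicing change; on real data the diagnostic quantifies how
much of the observed pattern composition alone explains.

# The end-to-end audit

`runFullAudit()` chains the stages on a synthetic experiment: references →
mixed and pure simulated RNA-seq → marker curation → composition report →
differential inclusion (condition contrast, filtered; cell-type contrast,
unfiltered) → Δ–Δ correlation with permutation p. At the bundled scale
(1000 genes, 600 events, 3 replicates per condition) the audit finds
r above 0.9 with slope near 0.27 — comfortably inside $(0,1)$, smaller
than the weight change of 0.35 because expression heterogeneity and
estimation noise both attenuate — and the NNLS weights recover the planted
shift to within about 0.01. With identical control and treated weights the
summary flags "no composition shift detected" and the Δ–Δ correlation is
flat. These problem sizes (600 events; 50-seed sweeps for the null and for
weight recovery; 2000 events for test calibration) were chosen as the
smallest at which the qualitative claims are stable across seeds.

# Numerical and design choices

* Weight sums are validated to 1e-12; mixture-PSI closed form is tested
  against brute-force transcript counting at 1e-12.
* The constrained MLE search tolerance is 1e-9, and the grid oracle in the
  tests agrees to 1e-6 in $\Lambda$; `optimize()` never evaluates interval
  endpoints, so both endpoints are checked explicitly.
* Degenerate inputs are flagged, not guessed: zero-read events give `NA`
  PSI; zero-variance vectors give undefined r; all-tie sign tests report
  `NA`; zero-variance paired differences with non-zero mean report
  infinite t with p = 0.
* Event matching between contrasts is by event identifier in synthetic
  mode; for real tables, match on exon coordinates (0-based, half-open,
  strand explicit) before constructing the two `delta_psi` tables —
  unmatched events are dropped and counted, never imputed.
* qPCR: efficiency is a fraction $e$ with amplification base $E = 1 + e$
  (99% → 1.99); technical replicates average on the Ct scale before
  exponentiation; with $e = 1$ the classic $2^{-\Delta\Delta Ct}$ is
  recovered exactly. Within a sample the reference gene and the calibrator
  cancel algebraically from the isoform ratio, so
  `isoformRatio()` computes $R = E_+^{-Ct_+}/E_-^{-Ct_-}$ directly and is
  exactly calibrator-independent, while the per-isoform *relative
  quantities* it also reports do depend on the calibrator.
* Thresholds (10 FPKM, 10-fold, $\alpha = 0.05$, $c = 0.05$, count > 100)
  default to the printed analysis settings; `readAuditConfig()` warns on
  any override, because unexamined analysis settings are what this audit
  exists to catch.

# Reproducing published statistics

The desk-scale pipeline ships with everything it needs. Two reproductions
require inputs that cannot be redistributed here: recomputing the
figure-legend one-way ANOVAs needs the article's source-data workbook
(drop `source_data.xlsx` into the package's `extdata/`, then
`convertSupplementary()` + `panelAnova()`), and the composition statistics
for the deposited RNA-seq (fraction-of-pure ≈ 30%, near-unanimous marker
sign counts, the large paired t values, and the Δ–Δ r ≈ 0.956 with slope
≈ 0.463) need FPKM tables derived from the deposited accessions
(E-MTAB-8058 pure cultures; GSE93682 ±KCl cultures) via alignment-scale
processing. The README documents the expected file layouts; the
acceptance tests for these reproductions activate when the files are
present.

# Known limitations

The two-component NNLS assumes the pure references span the mixture; a
third cell type biases both weights. Pooled-replicate likelihoods
understate uncertainty on real data. The Δ–Δ diagnostic is correlational:
it cannot decompose a mixture of genuine within-cell regulation plus a
composition shift (no Deming/orthogonal regression is attempted), it can
only show that composition alone suffices to produce the observed
pattern.
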