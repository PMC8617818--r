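---
title: "Quantifying cell-surface recycling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cell-surface recycling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recyclequant)
```

This vignette documents the models behind each quantification stage, the
parameters that matter, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## The imaging model: % PM by erosion

A recycling-competent cell shows its reporter at the plasma membrane; a
defective one accumulates it in endosomes. We measure this as the
fraction of a cell's background-corrected fluorescence that lies in a
*shell*: the set difference between the cell's segmentation mask and its
morphological erosion by a disc structuring element.

Assumptions worth stating:

* **The shell width is a free parameter.** The erosion radius
  (`width_px`, default **3 px**) should roughly match the apparent PM
  thickness at the acquisition's pixel size; % PM is monotonically
  non-decreasing in it (a wider shell can only capture more signal), so
  cross-strain comparisons must use one fixed width. The default suits
  the simulated geometry (cell radii ~12 px); real data at other
  magnifications will need a different value, which every function
  accepts.
* **The structuring element is the Euclidean disc** `dx² + dy² ≤ r²`
  (the 3×3 cross at r = 1). The generator paints its rim with the same
  element, so ground-truth recovery is exact up to pixelation and noise
  — a deliberate commensurability choice, not a claim that this is the
  only reasonable element.
* **Sum-based fractions.** % PM uses intensity *sums* (shell sum over
  cell sum), not means; with uniform intensity the fraction reduces to
  the shell/cell area ratio. The per-cell conservation identity
  `shell + interior = total` is exact because the total is defined as
  the sum of the two partial sums over the disjoint partition.
* **Background is one scalar per field.** Autofluorescence is taken as
  uniform and estimated as the mean pixel value of the quantified
  channel over cells that demonstrably lack the reporter — a co-imaged
  population carrying only a red marker, classified by 2-means splitting
  of per-cell channel means (`find_negative_cells`). Subtracting a
  constant is exactly undone by passing the same constant, which the
  tests exploit. Shading or per-pixel background maps are out of scope.
* **Clamping and flags.** `pm_percent` is clamped to [0, 100] (noise can
  push raw ratios outside); cells with non-positive corrected totals or
  an empty eroded interior are flagged and excluded from strain
  summaries rather than imputed.
* **Student's, not Welch's.** Strain comparisons default to the pooled
  two-sample *t*-test; Welch is available via `welch = TRUE`. Zero
  pooled variance is reported as a flagged degenerate case instead of
  NaN.

Bundled segmentation (relative Otsu threshold on the min–max-normalised
image, hole filling, connected components, minimum area 20 px) is a
stand-in adequate for well-separated synthetic cells; for real
micrographs an externally produced label-mask TIFF can be supplied
directly.

## The efflux model

Events from a kinetic flow-cytometry acquisition are `(time, fluorescence)`
pairs. The trace is anchored to the **unweighted mean over all events in
the first 10 s** — not over bins — and each bin's mean is reported as a
percentage of that anchor. Consequences:

* the event-weighted mean of the trace over bins tiling the initial
  window is exactly 100 (a test invariant), and
* the trace is invariant to any global rescaling of fluorescence
  (loading, gain).

Binning defaults to **5 s** over the full acquisition (the window must
be a multiple of the bin width for the anchor identity to hold exactly);
bins with fewer than **20 events** are masked from fitting — at the
instrument's 1000–3000 events/s this masks only pathological bins.

Decay fitting is a convenience quantification. Two models:

* `exponential` — log-linear least squares on positive bins; the right
  model when efflux is a single first-order process, and the model used
  in the recovery benchmarks because it matches the generator.
* `exponential_plus_plateau` (default for real data) —
  `p(t) = c + (A − c)·e^(−kt)`, since dye efflux saturates above zero.
  For fixed *k* the model is linear in `(c, A − c)`, so those are
  profiled out and *k* is found by 1-D minimisation on [1e−6, 1] s⁻¹
  with a refinement pass; this avoids the poor conditioning of a joint
  3-parameter search. On data with no true plateau the two extra degrees
  of freedom trade off against *k*, which is why rate *recovery* is
  benchmarked with the matched exponential model.

## Cross-mutant expression averaging

Because every subunit mutant of the deacetylase complex phenocopies the
recycling defect, shared transcriptional targets should shift coherently
across mutants; averaging the per-gene log2 fold change across mutants
is therefore the prioritisation statistic. Conventions:

* means are over non-missing entries; genes missing everywhere are
  excluded, never imputed as zero;
* ranking is stable (ties broken by input order) and invariant to mutant
  column order;
* "significantly reduced" is operationalised as mean log2FC < 0 **and**
  Fisher's combined *p* over the per-mutant p-values < α (default 0.05).
  No universal rule exists for combining per-mutant significance; Fisher
  is the documented, configurable choice.
* the candidate list is the significant set in rank order plus the next
  `extension_n` (default 10) genes by mean regardless of significance —
  insurance against targets repressed strongly in only some mutants;
* `threshold_repressed` interprets its threshold as a *fold reduction*:
  mean log2FC ≤ −log2(threshold), default 5-fold;
* clustering of mutant columns uses Euclidean distance (pairwise
  complete over missing values) with complete linkage — the common
  default of base-R heatmap tooling — and exports the dendrogram as
  newick;
* enrichment is a generic hypergeometric upper tail
  `P(X ≥ k), X ~ Hypergeom(N, K, n)` on user-supplied flat term→gene
  maps with BH adjustment; no GO DAG propagation.

## Growth scoring

A strain's score is the plain sum of its spot densities across the
dilution series (a trapezoid weighting over log-dilution is available),
and the reported value is the ratio to the same-plate wild-type — which
cancels plate-wide exposure and pinning effects exactly. Replicate
plates are compared with a one-sample *t*-test of the per-plate ratios
against 1 (the reference's own ratio is identically 1, so a two-sample
test would always be degenerate) plus a two-sample test between
conditions.

## What the generator emulates — and what it does not

* **Fields**: non-overlapping disc cells, radius ~N(12, 1.5²) px by
  default; a rim ring of width 3 px receives exactly `pm_fraction` of
  the cell's signal and the interior the rest (optional puncta reallocate
  interior signal without moving the fraction); uniform background;
  additive Gaussian noise added *last*, with truth recorded pre-noise.
  Not modelled: point-spread blur, budding/cell-cycle shapes, z-stacks,
  uneven illumination, touching cells. Passing tests therefore
  demonstrate correctness of the *measurement*, not robustness of
  segmentation to realistic optics.
* **Efflux**: Poisson event times; per-event initial fluorescence
  lognormal with CV 0.25 around 1000 a.u.; single-exponential decay;
  multiplicative Gaussian noise (CV 0.05) — detector noise scales with
  signal, unlike the additive camera-noise convention used for images.
  Instrument noise models are not published for either assay; both
  defaults are conventions, kept small and configurable.
* **Expression**: 89 genes × 9 mutants by default, 24 genes planted at
  δ = −1.5 with σ = 0.3 — the scale at which cross-mutant averaging is
  expected to operate; p-values are two-sided normal on the standardised
  drawn effect (with σ = 0 they degenerate to 0/1), a convention rather
  than a microarray model.
* **Growth**: spot density = plate scale × fitness × a shared
  dilution-response `g(d) = f^−(d−1)` × multiplicative noise; spotting
  artefacts and colony morphology are not modelled.

Determinism: every generator takes an explicit seed and identical
spec + seed gives bit-identical output; the pipeline report records the
seed so runs are exactly repeatable.

## Benchmark problem sizes

The packaged checks run the imaging benchmarks at 20 cells per
256×256-px field, the pixel-level oracle comparisons on one hundred
≤64×64 fields, efflux recovery at 1500 events/s × 600 s for
k ∈ {0.002, 0.004, 0.01} s⁻¹ over 20 seeds, expression recovery at
89 × 9 over 20 seeds, and growth recovery over 20 seeds — sizes chosen
to match the assays' own scales while keeping a full verification run in
the order of a minute or two on one core.

## Known limitations

* Bundled segmentation is not a reproduction of any particular ImageJ
  protocol and is validated only on synthetic fields; real DIC
  segmentation should come from dedicated tooling and be passed in as a
  label mask.
* FCS files are not parsed; events are exchanged as CSV
  (`time_s,fluorescence`), which any cytometry package can export.
* The compendium emulated by `simulate_expression` is a statistical
  caricature (independent Gaussian noise, fixed planted effects);
  conclusions about real microarray data require the real compendium.
* % PM from sums is sensitive to segmentation quality at the boundary:
  a mask one pixel too wide moves background pixels into the shell. The
  background-correction step removes the mean effect but not its
  variance.
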