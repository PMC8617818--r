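# recyclequant

Quantification tools for cell-surface **recycling** assays in budding
yeast. When endosomal recycling works, reporters such as a GFP-tagged
surface receptor sit at the plasma membrane (PM); when recycling fails
they accumulate in endosomes. This package turns four complementary raw
readouts into numbers:

1. **Imaging — % PM by morphological erosion.** Each segmented cell is
   split into a PM *shell* (the ring between the cell boundary and its
   erosion by a disc of radius *w*) and an interior. The per-cell
   statistic is

   `pm_percent = 100 · Σ shell (I − b) / Σ cell (I − b)`,

   where *b* is a scalar autofluorescence background estimated from a
   co-imaged reporter-negative population (cells carrying only a red
   marker: their green signal is pure background). Strains are compared
   with Student's *t*-tests.
2. **Flow-cytometry dye efflux.** Time-stamped events from lipid-dye
   (FM4-64) loaded cells are binned, and each bin's mean fluorescence is
   expressed as a percentage of the mean over all events in the first
   10 s. A decay model (exponential, optionally with a plateau) fitted
   to the trace gives a per-strain efflux rate *k* (s⁻¹).
3. **Cross-mutant expression averaging.** Given a genes × deletion-mutant
   log2 fold-change matrix, genes are ranked by their mean log2FC across
   mutants (shared targets change coherently; noise averages out),
   significantly repressed candidates are selected (negative mean and
   Fisher's combined *p* < α) plus a fixed-size extension, with
   essential-gene subsetting, hierarchical clustering of mutant profiles,
   and hypergeometric annotation enrichment with BH correction.
4. **Spot-assay growth.** Serial-dilution spot densities are summed per
   strain and expressed as a ratio to wild-type *from the same plate*,
   making scores invariant to plate-wide intensity scale.

A synthetic-data generator (`make_field`, `make_mixed_field`,
`simulate_efflux`, `simulate_expression`, `simulate_growth`) produces
inputs with exact, pre-noise ground truth for every stage, so the whole
pipeline is verifiable without any external data.

## Worked example

Quantify % PM on a mixed field (reporter cells + red-only cells for
background estimation), then compare against a recycling-defective
strain:

```r
library(recyclequant)

spec_g <- field_spec(n_cells = 10, pm_fraction = 0.85,
                     background_level = 50, noise_sd = 2, seed = 7)
spec_r <- field_spec(n_cells = 10, pm_fraction = 0.85,
                     background_level = 50, noise_sd = 2, seed = 7,
                     channel_tag = "redonly")
field <- make_mixed_field(spec_g, spec_r)

neg <- find_negative_cells(field$channels$green, field$channels$red,
                           field$truth_labels)
bg  <- estimate_background(field$channels$green, field$truth_labels, neg)
#> bg = 50  (true background was 50)

rec <- quantify_pm(field$channels$green, field$truth_labels,
                   width_px = 3, background = bg)
head(rec[, c("cell_id", "area_px", "shell_area_px", "pm_percent")], 4)
#>   cell_id area_px shell_area_px pm_percent
#> 1       1     748           251      84.94
#> 2       2     381           172      85.18
#> 3       3     348           164      84.97
#> 4       4     542           212      85.03
```

The recovered `pm_percent` matches the painted truth (85%). Strain-level
comparison with a simulated mutant painted at 45%:

```r
summarize_strains(records, reference = "wt")
#>   strain  n  mean      sd t_statistic   p_value
#> 1     wt 10 85.02 0.08481          NA        NA
#> 2   rpd3 10 45.00 0.04440       -1322 2.412e-46
```

An efflux run at the instrument's scale (1500 events/s for 600 s,
k = 0.004 s⁻¹) is normalised and refitted to within 0.1%:

```r
tr  <- normalize_trace(simulate_efflux(decay_rate_per_s = 0.004, seed = 7))
fit_decay(tr, model = "exponential")$rate_per_s
#> 0.003998
```

A command-line wrapper covering all stages ships in
`inst/cli/recyclequant.R`
(`simulate | quantify-pm | efflux | rank | select | cluster | enrich |
growth | demo`).

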