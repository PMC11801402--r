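# opticyto

Flow-cytometry-like single-cell analysis of fluorescence microscopy images.

A standard fluorescence microscope can stand in for a flow cytometer when
the question is how a fluorescent readout — glucose uptake reported by a
2-NBDG-like probe, mitochondrial membrane potential reported by a TMRE-like
probe — shifts between experimental groups of cultured cells. `opticyto`
implements that workflow as a reproducible R pipeline for cell biologists
and imaging scientists:

1. **Segmentation** — cells are identified in each grayscale frame by
   *global minimum cross-entropy (Li) thresholding*: intensities are
   quantized to bin centers *g* with counts *h(g)* and the threshold *t*
   minimizes

   −Σ<sub>g&lt;t</sub> g·h(g)·log μ<sub>low</sub>(t) −
   Σ<sub>g≥t</sub> g·h(g)·log μ<sub>high</sub>(t),

   where μ<sub>low</sub>, μ<sub>high</sub> are the intensity-weighted means
   of the two sides. Touching cells are split by seeded watershed on the
   distance transform, and objects are gated to an equivalent diameter
   2·√(area/π)·pitch between 18 and 38 µm (inclusive).
2. **Quantification** — one record per cell: the arithmetic mean intensity
   over the whole cell region (no nuclear compartment, no background
   subtraction), rescaled to an 8-bit axis by multiplying by 255.
3. **Histogram analytics** — per group and modality, a Gaussian-kernel
   density estimate (normal-reference bandwidth *h* = 1.06·s·n<sup>−1/5</sup>)
   yields the four histogram characteristics: **peak** location (KDE
   argmax), **FWHM** (outermost half-maximum crossings around the global
   peak), **mean** and **median** (raw sample). Treatment groups are
   summarized as relative changes, 100·(group − control)/control.
4. **Statistics & concordance** — Student's *t*-test (two groups) or one-way
   ANOVA (three or more) at α = 0.05 on per-image (imaging) or per-tube
   (flow) mean intensities, plus a metric-by-metric concordance report
   between the imaging-derived and flow-cytometry-derived relative changes.
5. **Synthetic data** — a generator renders ground-truth-annotated frames
   (non-overlapping disk cells, lognormal per-cell intensities, Gaussian
   PSF, shot + read noise, channel-calibrated signal-to-background ratios of
   ~20 / ~80 for the glucose-like / MMP-like channels) and matched flow
   event samples (~20,000 events, multiplicative lognormal noise,
   SBR-derived baseline of ~10 / ~1000), so every stage is verifiable by
   parameter recovery.

## Worked example

Simulate a two-group experiment with a +30% shift in the treated group,
segment every frame, and compare the modalities:

```r
library(opticyto)
library(dplyr)

params <- generator_params(
  image_width_px = 500, image_height_px = 375,
  n_images = 10, cells_per_image = 12,
  fold_changes = c(control = 1, treated = 1.3),
  seed = 7)
expt <- generate_experiment(params)
#> <cyto_experiment> 2 group(s) x 10 image(s), 240 cells total, 40000 flow events

cells <- purrr::map_dfr(names(expt$images), function(id) {
  segment_image(expt$images[[id]])$cells |>
    mutate(group = sub("_img[0-9]+$", "", image_id))
})
events <- bind_rows(
  event_table(cells$mean_intensity_8bit, "imaging", cells$group, cells$image_id),
  expt$flow_events |> select(intensity_8bit, modality, group, source_id))

histogram_summaries(events)
#> # A tibble: 4 × 8
#>   modality group   peak_8bit fwhm_8bit mean_8bit median_8bit n_cells bandwidth
#> 1 flow     control      92.8      49.8     101.         98.2   20000      3.41
#> 2 flow     treated     117.       65.3     129.        125.    20000      4.42
#> 3 imaging  control      76.4      51.8      89.3        89.0     117      7.57
#> 4 imaging  treated     110.       48.4     116.        114.      119      7.78

rel <- relative_changes(histogram_summaries(events))
tt  <- compare_groups(filter(replicate_means(events), modality == "imaging"))
tt
#> <cyto_test> student_t: statistic -9.5747, df 18, p = 1.736e-08 (significant at alpha = 0.05)

tidy(build_concordance(filter(rel, modality == "imaging"),
                       filter(rel, modality == "flow"), test_imaging = tt))
#> # A tibble: 4 × 7
#>   metric group   control rel_change_imaging_pct rel_change_flow_pct sign_agree
#> 1 peak   treated control                  43.7                 26.1 TRUE
#> 2 fwhm   treated control                  -6.50                31.2 FALSE
#> 3 mean   treated control                  29.9                 27.0 TRUE
#> 4 median treated control                  27.5                 26.9 TRUE
```

The segmentation recovered 117 and 119 of the 120 simulated cells per
group. Both modalities report the configured +30% shift in mean intensity
(imaging +29.9%, flow +27.0% — the flow value is compressed slightly by the
instrument baseline), agree in sign for peak, mean and median, and the
per-image *t*-test is strongly significant. FWHM, the most
bandwidth-sensitive metric, is the first to lose sign agreement at imaging
sample sizes of ~120 cells — which is exactly why the concordance report
tracks it.

The same analysis runs end to end from a YAML config, in R
(`run_all(config, out_dir)`) or from the shell:

```sh
inst/cli/opticyto run-all --config config.yaml --out runs/demo --seed 7
```

writing `cells.csv`, `summaries.csv`, `rel_changes.csv`, `tests.csv`,
`concordance.csv` and a `manifest.json` with every seed and count.

## Vignette

`vignettes/opticyto-methods.Rmd` documents the model and its assumptions,
every tunable parameter with units and defaults, what the synthetic
generator does and does not emulate, and the package's numerical choices
and limitations.
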