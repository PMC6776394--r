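# agfret

Spillover-corrected FRET quantification of spindle pole body (SPB) spot
pairs from three-channel fluorescence microscopy, plus the companion image
quantifications used alongside it: radial colony growth area, needle-spore
length morphometry, and counting of nuclei that carry an SPB signal. The
package targets studies of sporulation-plaque assembly in filamentous fungi
(Ashbya-type mycelium with mobile nuclei and ~30 µm × 1 µm needle spores),
where candidate interactions at the SPB are screened with a green/red
(Clover–mRuby2-class) FRET pair.

## The measurement

For each manually selected SPB, three images are analysed — donor, acceptor
and FRET channel. Every channel is independently cropped, background
subtracted (border-frame median), maximum-located on a smoothed image, and
fitted with an isotropic 2D Gaussian; the spot intensity is the fitted
amplitude. The ratiometric FRET index is

```
FRETR = I_fret / (s_green * I_green + s_red * I_red)
```

where the spillover coefficients `s_green`, `s_red` are calibrated from
single-label control strains as the median per-spot ratio of FRET-channel
to labelled-channel amplitude. FRETR ≈ 1 means the FRET channel contains
nothing beyond bleed-through (no detectable transfer); elevated values
indicate sensitized emission, i.e. donor–acceptor proximity. Strain
distributions are summarized boxplot-style (type-7 quantiles, 1.5 IQR
whiskers) and classified against a negative control as
background / weak / high.

No public image data exist for this assay, so the package bundles a seeded
synthetic-microscopy generator (three-cube emission model, Poisson + read
noise, inter-channel spot drift, ground-truth JSON manifests) that produces
every input the pipeline consumes; all tests run end to end against known
truth. See the methods vignette (`vignettes/agfret-methods.Rmd`) for the
model, parameter defaults and design decisions.

## Worked example

Simulate two control strains for calibration, a negative control and a
tandem-fusion positive, then run the full pipeline:

```r
library(agfret)
base <- tempfile("agfret-demo")

make_single_label_dataset("donor", 0.2, 20, sim_config(seed = 11),
                          dir = file.path(base, "donor_only"))
make_single_label_dataset("acceptor", 0.1, 20, sim_config(seed = 12),
                          dir = file.path(base, "acceptor_only"))
make_fret_dataset("negctrl", 25, fret_truth_defaults(0),
                  sim_config(seed = 13), dir = file.path(base, "negctrl"))
make_fret_dataset("tandem", 25, fret_truth_defaults(0.4),
                  sim_config(seed = 14), dir = file.path(base, "tandem"))

conf <- pipeline_config(
  strain_dirs = c(negctrl = file.path(base, "negctrl"),
                  tandem = file.path(base, "tandem")),
  negative_control = "negctrl",
  donor_calibration_dir = file.path(base, "donor_only"),
  acceptor_calibration_dir = file.path(base, "acceptor_only"),
  out_dir = file.path(base, "run"))
res <- run_fret_pipeline(conf)
#> calibrating spillover from single-label datasets
#> spillover: s_green = 0.2006, s_red = 0.0998
#> negctrl: 25 spots, 25 accepted, 0 excluded
#> tandem: 25 spots, 25 accepted, 0 excluded
#> negctrl: median FRETR 0.996 (n = 25), class background
#> tandem: median FRETR 2.838 (n = 25), class high

res$summaries[, c("strain", "n", "median", "q25", "q75",
                  "interaction_class")]
#>    strain  n    median       q25      q75 interaction_class
#> 1 negctrl 25 0.9964324 0.9755598 1.025453        background
#> 2  tandem 25 2.8380916 2.7769938 2.878567              high
```

The calibration recovered the generating spillover (0.2 / 0.1) to well
under a percent; the zero-transfer strain sits at FRETR ≈ 1 (pure
bleed-through) and is classified `background` against itself, while the
tandem-fusion strain (transfer fraction 0.4) is cleanly `high`. The run
directory contains `measurements.csv` (per spot), `summaries.csv`,
`spillover.json`, a boxplot figure and a log that tallies every exclusion.

Relative label-intensity comparisons work from a table of per-strain
median red-channel amplitudes normalized to the weakest strain (the
package ships one such published table as an example dataset):

```r
tab <- read.csv(system.file("extdata", "relative_intensity_table.csv",
                            package = "agfret"))
rel <- setNames(tab$relative_mruby2_intensity, tab$strain)
intensity_ratio(rel, "Cmd1", "Cnm67")
#> [1] "1:1.95"
```

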