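---
title: "Quantifying SPB FRET and companion morphometry with agfret"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying SPB FRET and companion morphometry with agfret}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agfret)
```

## The measurement problem

Protein proximity at the spindle pole body (SPB) — the fungal centrosome
equivalent, a diffraction-limited punctum at the nuclear envelope — can be
probed by Förster resonance energy transfer (FRET) between a green donor
(Clover-class) and a red acceptor (mRuby2-class) fluorophore fused to
candidate partners. Three images are acquired per field: the donor channel,
the acceptor channel, and a FRET channel (donor excitation, acceptor
emission). The FRET channel always contains signal even without energy
transfer, because both fluorophores bleed into it ("spillover"). The
ratiometric index used here is

$$\mathrm{FRETR} \;=\; \frac{I_{fret}}{s_{green}\, I_{green} + s_{red}\,
I_{red}},$$

where $I_{green}, I_{red}, I_{fret}$ are the per-channel spot intensities of
one SPB and $s_{green}, s_{red}$ are the spillover coefficients measured
from control strains carrying only one of the two fusions. With exact
coefficients and no transfer, the FRET channel carries pure spillover and
FRETR equals 1; sensitized emission pushes it above 1.

In mycelium the nuclei are mobile, so the spot moves by a few pixels between
the three exposures; every channel must therefore be re-localized
independently inside the analysis crop.

## Spot quantification

Each channel of a field is processed as:

1. **Crop** a fixed window (default 200 × 200 px) around the user-supplied
   approximate spot position, shifted inward at image borders. All
   coordinates in this package are R-native 1-based (row, column) pixel
   centres.
2. **Background subtraction.** The background is the median of the crop's
   border frame (default 10 px wide) — robust to the central spot. The
   subtraction kept for fitting is *signed*: flooring negative noise
   excursions at zero would clip half the noise distribution and biases
   weak amplitudes low by tens of percent (we measured ≈ −20 % at 25-count
   spots). The floored version is still what `subtract_background()$pixels`
   returns, and is what maximum finding operates on. If an unusually large
   share of border pixels sits far above the median, the spot probably
   overlaps the border and a border-contrast warning is raised.
3. **Maximum identification** on the 3 × 3 mean-smoothed region, which
   attenuates single hot pixels nine-fold; exact ties resolve to the
   smallest row, then the smallest column.
4. **2D Gaussian fit** of
   $\;\mathrm{offset} + A \exp\!\big(-((r - r_0)^2 + (c - c_0)^2) / 2\sigma^2\big)$
   by Levenberg–Marquardt over a window (default 31 × 31) around the
   maximum, started from the window maximum, the window-border median and
   $\sigma = 2$ px; convergence at relative RSS change $< 10^{-8}$ or 200
   iterations. The reported intensity is the fitted amplitude $A$ (not the
   integrated volume); with a channel-stable PSF this differs from the
   volume only by a constant factor that cancels in FRETR.

A fit counts as a *detection* only if it converges, its amplitude clears a
noise floor (3 × the robust border-noise sd, configurable) and its width is
PSF-plausible ($\sigma$ within $[\sigma_0/2,\, 4\sigma_0]$). The plausibility
gate matters on empty channels: pure noise happily "converges" to a
sub-pixel spike ($\sigma \approx 0.3$) whose amplitude can clear the floor.

### The FRET channel is special

The donor and acceptor channels gate spot inclusion, so both must yield a
detection. The FRET channel may legitimately approach zero signal (a
non-interacting pair contributes only spillover), and three asymmetric
choices follow:

* **Search region.** Its maximum is searched only within ± 20 px of the
  reference-channel fitted centres — the spot cannot have drifted further
  than the drift bound, and a whole-crop search at 25-count amplitudes
  locks onto noise peaks elsewhere (we measured ≈ −11 % median bias).
* **Shared PSF width.** Sensitized emission *is* acceptor emission: same
  emission band, same PSF. The FRET fit therefore holds $\sigma$ at the
  acceptor channel's fitted value (donor's, for donor-only calibration
  fields), freeing centre, amplitude and offset. A fully free fit at weak
  amplitudes has roughly four-fold the amplitude scatter with heavy tails.
* **No amplitude floor.** A converged FRET fit is used even below the
  detection floor; replacing sub-floor fits by the smoothed window maximum
  would bias weak-spillover calibration upward. The smoothed-maximum
  fallback applies only when the FRET fit does not converge, and is
  flagged in the output.

## Spillover calibration

For a control strain carrying only one fluorophore, the expected FRET-channel
signal is exactly $s$ times the labelled channel's signal. The estimator is
the **median over spots of $I_{fret} / I_{labelled}$**, with the median
absolute deviation as dispersion; the median is robust to the heavy tails
that amplitude-dependent noise produces in per-spot ratios. Spots whose
labelled amplitude sits at or below the noise floor are excluded and
counted; fewer than 10 usable spots (configurable) is a calibration error.
Under the default camera model (peak SNR ≈ 20) and 100 spots, the estimate
recovers the truth to within about 1–2 % for coefficients between 0.05 and
0.4.

## Distribution summaries and classes

Per-strain FRETR distributions are summarized boxplot-style: median and
hinges by linear-interpolation quantiles (R's default type 7 — stated
because quantile conventions differ), whiskers at the most extreme point
within 1.5 IQR of each hinge, and the number of SPBs printed with each
distribution. Three qualitative interaction classes are assigned relative to
a negative control: *background* (median at or below the control's),
*weak* (above it, below 1.2) and *high* (at or above 1.2). The 1.2 boundary
is a package default, exposed in the configuration and recorded in the
output: medians near 1 mean no detectable transfer, while distributions
whose median clears 1.2 are well separated from calibration noise
(single-spot values of 1.5 and above already suggest interaction).

Relative label intensity across strains is the per-strain median of fitted
red-channel amplitudes, normalized so the weakest strain is exactly 1;
`intensity_ratio()` formats pairwise comparisons as `"1:x"` with two
decimals.

## The synthetic-microscopy generator

No public image data exist for this kind of experiment, so the package
ships a seeded generator that produces every input the pipeline consumes,
together with ground-truth manifests (JSON). It emulates:

* **Spot fields** (200 × 200 px, 16-bit): one isotropic Gaussian spot
  (σ = 2 px) per channel on a constant background (100 counts), with
  per-channel centre offsets drawn i.i.d. Gaussian (sd 3 px, clamped to
  half the drift bound) emulating nuclear movement between exposures. The
  three-cube emission model is: donor $A_d(1-f)$, acceptor $A_a$, FRET
  $s_{green} A_d (1-f) + s_{red} A_a + q f A_d$, where $f \in [0,1]$ is the
  hidden transfer fraction and $q$ (default 1) the sensitized-emission
  detection gain. The defaults $s_{green} = 0.2$, $s_{red} = 0.1$,
  amplitudes ~ N(500, 50) truncated at 100 are generator conventions, not
  instrument claims; at $f = 0$ the model makes FRETR = 1 exact. Noise is
  Poisson shot noise on expected counts followed by additive Gaussian read
  noise (sd 3) — the standard CMOS camera model — giving peak SNR ≈ 20 at
  the default amplitude. Noiseless renders are the analytic surfaces;
  quantization to the 16-bit grid happens on TIFF output (round to
  nearest).
* **Single-label fields** for calibration: the opposite amplitude is zero,
  so the FRET channel carries exactly $s$ times the labelled signal.
* **Colony plates**: a dark quasi-circular colony on a bright plate with a
  rendered calibration bar of known length; boundary roughness is a smooth
  low-order angular perturbation, and the manifest stores the polar-integral
  true area per timepoint (default cadence 3 h).
* **Needle spores**: curved rods (default length ~ N(30, 3) µm, width 1 µm,
  sagitta 5 % of length) placed without overlap; recorded truth is the
  end-to-end arc length *including* the rounded caps, which is why the
  centreline is drawn `width` shorter than the nominal length.
* **Nuclei fields**: bright nuclear disks on a jittered grid, with exactly
  `round(fraction × n)` of them carrying an adjacent red spot at the
  nuclear periphery. Grid spacing is six nuclear radii so a spot can never
  fall within the association distance of the wrong nucleus.

Identical configuration and seed give byte-identical files. What the
generator does **not** emulate: hyphal autofluorescence and structured
background, sub-pixel channel mis-registration, photobleaching across the
acquisition sequence, focus drift, multiple SPBs per crop, and realistic
mycelial morphology. Passing tests therefore validate the estimators under
a clean, known forward model — they bound algorithmic error, not the full
error budget of real micrographs.

## Morphometry choices

* **Colony area**: automatic global (Otsu) threshold, largest connected
  component, hole fill, pixel count × (mm/px)². The scale comes from the
  manifest or from measuring the rendered calibration bar
  (`measure_scale_bar()`, most-elongated dark component). Timelapse series
  flag area decreases beyond 5 % (colonies only grow) and refuse
  non-increasing timestamps.
* **Spore length**: Otsu threshold, connected components, Zhang–Suen
  thinning, then the longest geodesic between skeleton endpoints. The raw
  8-connected chain over- or under-states length depending on orientation,
  so the path coordinates are smoothed with a running mean (half-width 3)
  before summing segment lengths, and each end is extended by the maximal
  projection of nearby object pixels onto the outward path direction
  (thinning erodes rod tips by about half a width). Straight 30 µm rods
  are recovered within ~0.5 %, gently curved ones within a few percent.
  Components touching the border or shorter than 5 µm are excluded and
  counted — both filters are hygiene defaults, exposed as arguments.
* **Nucleus–SPB colocalization**: nuclei are thresholded green components
  above 20 px; red spots are smoothed local maxima above the noise floor
  confirmed by a Gaussian fit; a nucleus is positive if a spot centre lies
  within 1.5 µm of its interior (SPBs sit at the nuclear envelope; the
  distance is configurable since none is canonical).

## Numerical conventions and degenerate inputs

Quantization is round-to-nearest on the 16-bit grid at file output. A flat
(all-zero after subtraction) region is a no-signal error before fitting. An
all-equal FRETR distribution has zero IQR and degenerate whiskers at the
common value; whisker fences use a relative $10^{-8}$ epsilon so that exact
fence hits are kept. Empty plates yield a zero-area result with a warning
rather than an error, because a timelapse may legitimately start before the
inoculum is visible. Exclusions never vanish silently: every excluded spot
carries a machine-readable reason, and the pipeline log tallies them so
that input = accepted + excluded always holds.

## Problem sizes

The shipped tests and the acceptance script run the chain at the scale a
single-workstation analysis would use: 50 spots per simulated strain for
distribution checks, 100 spots per calibration dataset (three replicate
datasets per coefficient, reporting the median estimate), 500 repeats for
fit-recovery statistics, 100 nuclei per colocalization field, 12–30
timepoint growth series, and 6–8 spores per field. These sizes were chosen
to keep Monte-Carlo error comfortably inside the tolerances being checked.

## Known limitations

FRETR is a ratio, not a FRET efficiency: no G-factor or
acceptor-photobleaching calibration is attempted, and no statistical tests
between strains are provided (distributions are reported, not p-values).
Only one spot per crop is modelled; automatic SPB detection across whole
mycelium images is out of scope. The three-cube model assumes spillover
coefficients are channel-global constants; strongly expression-dependent
bleed-through would violate that assumption.
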