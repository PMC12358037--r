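---
title: "Modelling the conspicuousness of green flowers to bee and fly pollinators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the conspicuousness of green flowers to bee and fly pollinators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(florivis)
```

## The question and the modelling chain

Flower detection by insect pollinators depends on the contrast a flower
creates against the vegetation behind it. Flowers that look green to humans
sit spectrally close to that background, so the interesting quantity is not
the spectrum itself but the *perceived* distance between flower and foliage
in the colour space of each pollinator group. `florivis` implements the full
chain:

reflectance spectrum → receptor quantum catches → von Kries adaptation →
colour locus → chromatic/achromatic contrast → threshold flag,

for two standard models: the trichromatic honeybee **colour hexagon** (UV,
blue, green receptors, hyperbolic transduction) and the **tetravariant fly
colour space** (R7p, R7y, R8p, R8y receptor classes, opponent differences of
linearly adapted signals). Around that core sit a spectral *marker-point*
detector with MAD/minAD fit metrics, a simulation-based *phylogenetic
ANOVA*, and a pigment-based *synthetic-spectrum generator* that stands in
for field data.

## Spectral processing

Spectra live on a shared wavelength grid, by default 300–700 nm at 1 nm
(401 points) — the insect-visual range at the resolution the model
sensitivities are defined on. Reflectance is stored in percent (0–100); the
readers auto-detect 0–1 scaled files (maximum ≤ 1.5) and rescale with a
message. Input files sampled on other grids are linearly interpolated;
extrapolation beyond the measured range is refused rather than guessed.

Two processing steps mirror common practice for spectrometer data:

* **Smoothing** (`smooth_spectra()`, span = 0.20). The smoothness parameter
  is interpreted as the *span* of a local-regression smoother — locally
  weighted least squares with tricube weights (`stats::loess`, degree 2) —
  the convention of the colorimetric software this workflow follows. Local
  regression of degree 2 reproduces constant and linear spectra exactly
  (up to numerical precision), which the unit tests pin down; a plain
  centred moving average is available via `method = "movavg"`.
* **Negative-value correction** (`fix_negative()`). Minor calibration
  deviations can produce slightly negative reflectance. We use the
  *additive* reading of "setting the minimum value to zero and scaling
  other values accordingly": |min| is added to every value, so the minimum
  becomes exactly zero and the rank order is preserved. A multiplicative
  rescaling after shifting would change band ratios, so it is deliberately
  not implemented; the choice is flagged here because the phrase is
  ambiguous.

Replicate spectra of one species are aggregated (`aggregate_spectra()`) to
a per-wavelength mean with the sample standard deviation carried alongside.
The pipeline default is smooth-then-aggregate; the order is not critical
for the smooth synthetic spectra, but smoothing first matches how
individual field measurements are usually cleaned before averaging.

## Vision models

**Quantum catches.** `Q_i = Σ_λ R(λ) S_i(λ) I(λ) Δλ` by the rectangle rule
on the grid. An acceptance test checks agreement with a 100×-finer
brute-force integration to 10⁻⁴ relative for smooth inputs, so the 1 nm
grid is not a practical accuracy limit.

**Sensitivities.** Receptor curves are generated from the Govardovskii
visual-pigment nomogram (alpha + beta band), peak-normalized on the grid.
Default peaks: honeybee UV 344, blue 436, green 544 nm; fly R7p 335,
R7y 355, R8p 460, R8y 530 nm. These are literature-style values shipped as
editable arguments — the original analyses rely on curves bundled with
their software, which are not printed anywhere, so absolute EU values are
sensitive to this choice and tabulated curves can be supplied via
`make_receptor(template = "tabulated")` to reproduce any convention.

**Illuminant and background.** CIE D65, tabulated at 10 nm, interpolated
and normalized to unit mean. Von Kries adaptation divides each catch by the
background catch, so the illuminant's absolute scale cancels — an
invariance the tests enforce at 10⁻¹² tightness. The default adaptation
background is the package's deterministic synthetic foliage spectrum (no
published 230-species foliage mean is redistributable); a measured
background can be passed to `viewing_context()` for literature
comparability.

**Bee model.** Hyperbolic transduction `E = q/(q+1)` puts the adapted
background at exactly `E = 0.5` in every receptor, hence at the hexagon
centre. Hue sectors are the six 60° sextants centred on the receptor axes
(blue at 90°, green at −30°, UV at 210°); boundary angles are assigned
counter-clockwise, and loci within 10⁻⁹ EU of the centre are labelled
"achromatic" because their hue angle is numerically meaningless. Achromatic
(green-receptor) contrast is `|E_G − 0.5|`.

**Fly model.** The workflow applies von Kries adaptation in both models but
hyperbolic transduction only for bees, so fly signals stay linear: adapted
catches are normalized to sum to one and the opponent coordinates are the
direct differences `x = s_{7p} − s_{8p}`, `y = s_{7y} − s_{8y}`, each
bounded in [−1, 1]. Whether these axes should be rescaled is not specified
anywhere we could follow, so the direct-difference convention is used and
documented. The four categorical colours (UV, purple, blue, yellow) map to
the sign quadrants through a configurable table; the default places
"yellow" in the quadrant reached by a 580 nm narrowband stimulus under the
default curves and background (a built-in smoke test), with UV opposite on
the long diagonal and blue where blue–violet spectra land.

**Thresholds.** 0.11 EU (bee) and 0.096 EU (fly), inclusive at the
boundary: a contrast exactly at the threshold counts as discriminable. Both
are overridable; they are laboratory values and should be read as rough
guides rather than hard perceptual limits.

## Marker points

The published detector behind the recommended settings (≥ 10 % change over
50 nm, ±10-point smoothing window, 5 points of lookahead) does not print
its internals, so `detect_marker_points()` is a documented reconstruction,
not a bit-exact clone: smooth with a centred ±10-point moving average, take
the slope as a 5-point forward difference (the point is placed at the
centre of that interval), keep local maxima of |slope|, accept a candidate
only if the smoothed reflectance range within the 50 nm window around it
reaches 10 *percentage points* (the absolute reading of "≥ 10 %"; a
relative variant is a settings switch), and merge accepted points closer
than 25 nm to the steepest one. Tests pin the behaviour on logistic
fixtures: one detection within ±3 nm of the true inflection, amplitude
gating at 5 pp, translation consistency, and the no-two-points-closer-than-
25 nm invariant. Near the chlorophyll dip at ~670 nm the merge rule yields
one point per steep flank when both flanks clear the amplitude gate.

MAD is, by default, the mean distance of each marker point to its *nearest*
optimum (the all-pairs mean is available by flag — the verbal definition
admits both readings); minAD is the minimum distance to one specific
optimum. Species without marker points have undefined metrics: they raise
an error individually, are reported as excluded in the summary tables, and
never enter class means.

## Phylogenetic ANOVA

`phyl_anova()` controls for relatedness by simulation: the Brownian rate is
estimated once from the observed traits by maximum likelihood (GLS root
profiled out), `n_sim` trait vectors are simulated under that rate on the
tree with group labels fixed to the tips, and the P-value is the add-one
proportion `(1 + #{F_sim ≥ F_obs})/(n_sim + 1)` — never exactly zero,
unlike implementations that report raw proportions. Post hoc pairwise
pooled-variance t statistics (Welch by flag) are referred to the same
simulated draws — a shared-draw design chosen for efficiency, since nothing
specifies whether the omnibus and post hoc nulls must be simulated
separately — and Holm-adjusted. Degenerate inputs have documented
sentinels: zero within-group variance with unequal means gives `F = Inf`.

Calibration is part of the acceptance suite: under the Brownian null on
30-tip Yule trees with groups of 19 and 11 (the focal design), the
rejection rate at α = 0.05 over 500 replicates of 400 simulations each must
sit inside the binomial 99 % interval around 0.05; and on star trees, where
the Brownian null collapses to iid normals, the simulation P must agree
with the parametric F-test P within Monte-Carlo error. An independent
reference implementation (`phytools::phylANOVA`) is cross-checked in a unit
test; it is never used inside the package.

## The synthetic-data generator

Because the original reflectance measurements are not deposited, the
package ships a generator whose defaults *are* the study conditions:
19 green + 11 green–yellow focal spectra and 38 yellow, 28 blue–violet,
25 pink, 9 white comparison spectra (130 total), a Yule tree over all
species, and Brownian traits for the statistics.

Spectra follow a Beer–Lambert pigment model,
`R(λ) = baseline · exp(−Σ bands) + smooth noise`, with Gaussian absorbance
bands at literature-style positions: chlorophyll *a* ~430/670 nm,
chlorophyll *b* ~455/645 nm, a broad chlorophyll shoulder ~610 nm (the
550–650 nm decline), a carotenoid triplet ~425/450/480 nm, cyanidin-type
anthocyanins ~530/560 nm, and a flavonol-type UV absorber ~330 nm. The
noise is Gaussian-kernel-smoothed white noise (sd 0.8 %, bandwidth 15 nm),
smooth enough not to create spurious marker points at the default detector
settings; its amplitude is a knob for robustness experiments.

Two design ideas make the classes behave like their real counterparts.
Green flowers are drawn with pigment concentrations centred on the foliage
values but a widely varying baseline: a flower that is a brightness-scaled
copy of the background has *zero* chromatic contrast in both models but a
large green-receptor deviation — exactly the low-chromatic/high-achromatic
signature of green flowers. Green–yellow flowers keep less chlorophyll and
much more carotenoid, which suppresses 400–500 nm reflectance and elevates
the long-wavelength plateau, pushing them far from the background in both
colour spaces while their moderate green-band brightness keeps the
achromatic contrast low. Under the defaults the class structure lands close
to the field-reported one (hexagon class means ≈ 0.11 EU green vs
≈ 0.27 EU green–yellow; some green spectra below the 0.11 EU threshold,
no green–yellow ones).

What passing tests on these data do **not** show: agreement with any real
species' EU values (those depend on unpublished receptor curves and the
measured foliage background), realistic within-species measurement
structure (one spectrum per synthetic species), or instrument artefacts
beyond small smooth noise and occasional negative values. The generator
validates the *machinery and the directional structure*, not field numbers.

## Numerical choices and limitations

* Grid 1 nm, 300–700 nm; readers discard wavelengths outside it and refuse
  ranges that do not cover it.
* Quantum catches by the rectangle rule; adequacy enforced by the
  fine-grid oracle test.
* Loess smoothing with `surface = "direct"` for exact (non-interpolated)
  predictions at the grid points.
* Hexagon sector ties go counter-clockwise; near-centre loci are
  "achromatic". Threshold comparisons are inclusive (≥).
* P-values use the add-one estimator, so `p ≥ 1/(n_sim + 1)`.
* Problem sizes in the shipped analyses: 130 spectra, 10 000 phylANOVA
  simulations per test in `analysis/05_phylanova.R` (the acceptance script
  uses 2 000, and the calibration experiment 500 × 400), chosen to keep a
  full desk run in minutes while leaving Monte-Carlo error well below the
  effects of interest.
* Seeds: every stochastic function takes one and restores the caller's RNG
  state; `run_full_analysis()` derives all stage seeds from the single
  master seed, and its written tables are byte-identical across reruns.
* Out of scope by design: receptor-noise (ΔS) models, tetrahedral bird
  colour space, tree inference, instrument calibration, and fly
  discrimination optima (none are established; MAD/minAD for non-bee taxa
  require a user-supplied optima list).
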