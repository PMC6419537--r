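---
title: "Quantifying polarized surface and ciliary arrival: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polarized surface and ciliary arrival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ciliarrival)
```

This vignette is the package's account of its own science: the statistics
it computes, the compartmental and optical models behind the synthetic
generator, the tunable parameters with their defaults and units, the
numerical choices, and what validation on synthetic data does and does not
demonstrate about real microscopy.

## 1. The three statistics

**Ciliary fraction (MCC).**  For a background-subtracted reporter channel
$R$ and a ciliary mask $M$ from the marker channel,
$$\mathrm{MCC} \;=\; \frac{\sum_{i \in M} R_i}{\sum_{j\,:\,R_j > 0} R_j},$$
i.e. the fraction of total above-background reporter that co-localizes
with the ciliary marker.  Because the reporter is a membrane protein and
the mask is the cilium, this *is* the ciliary fraction of the protein.
"Above background" is implemented as: voxels strictly positive after
clipped background subtraction, restricted to the cell mask.  The
subtraction-and-clip convention means noise can leave small positive
residues in empty voxels; the imaging defaults (section 4) keep that
contribution below ~2 % of the denominator.  An optional `min_gfp`
threshold excludes additional dim voxels from the denominator; it defaults
to 0 because no second threshold is part of the definition, but the flag
exposes the alternative reading.

A useful analytic anchor: a reporter distributed uniformly over the cell
volume yields MCC equal to the ciliary volume fraction.  At the most
generous published ciliary-to-cell volume ratio of 1/2700 that is
$3.7\times10^{-4}$ — two orders of magnitude below the measured ciliary
fractions near 0.05, which is why an MCC of that size demonstrates active
enrichment.

**Surface-to-total ratio.**  $\sum$ surface-stain / $\sum$ reporter over
one cell's mask.  The two channels have independent gains, so the ratio is
not bounded by 1 and is comparable only within a series at fixed gains.
Time courses therefore average cells per replicate and time, normalize
each replicate by its own series maximum, and only then average across
replicates (SEM over replicates, not cells).  This order of operations
makes the result exactly invariant to per-replicate gain changes, which is
verified as a property test.

**Slopes and their comparison.**  At a fixed release time, an unweighted
OLS fit of MCC against the side-specific surface ratio across single
cells; the slope is the correlation measure.  Replicate slopes for the two
sides are compared with a two-tailed paired *t*-test, pairing by
replicate.  Whether the original analysis weighted cells or trimmed
outliers is unknown; unweighted OLS is the default and the only fitter —
a robust variant was deliberately left out of scope rather than offered
half-tested.

## 2. QC: which cells contribute

Cells enter MCC statistics only when the segmented cilium (a) exists,
(b) protrudes at least `min_protrusion` = 1 µm above the apical reference
plane and (c) tilts at most `tilt_max` = 60° from the optical axis.  The
rationale is optical, not biological: a cilium lying in the apical plane
occupies the same image plane as the surrounding apical membrane, and at
confocal resolution the two cannot be separated, so co-localization there
is an artifact.  The thresholds are our quantitative reading of "clearly
protruding"; both are settings.  QC-failing cells still contribute their
surface ratios — only the ciliary statistic is undefined for them.

The apical reference plane comes from ground truth for synthetic data, or
from the 95th percentile of the cell-mask voxel z-distribution when only a
manual outline exists (robust to a few bright subapical vesicles).  No
automatic cell segmentation is attempted: the experimental design
quantifies isolated expressing cells surrounded by non-expressing
neighbours, where a manual outline is unambiguous.

## 3. Cilium segmentation

The marker channel is thresholded (Otsu on the full histogram by default,
overridable by an absolute value), 6-connected components are labelled,
components that do not reach above the apical plane are discarded — this
is what removes cytoplasmic acetylated-tubulin signal — and the largest
surviving component wins (ties: greater protrusion, then brightness).
Because a 0.12 µm cilium is below the lateral resolution, the PSF
surrounds it with a dim shell that a global threshold includes; the
selected component is therefore tightened to voxels above half of the
component's peak intensity (the FWHM contour), after which the mask
matches the true cilium with Jaccard overlap ≈ 0.6–0.8 under default
noise.  For the MCC numerator this tight mask is then re-dilated by
`mask_dilate_um` (default 0.3 µm axially, 0.25 µm laterally ≈ 2 lateral
PSF σ) so reporter photons blurred just outside the marker core are still
counted; without this the ciliary fraction is underestimated by ~10 %.

## 4. The synthetic generator

### Trafficking kinetics

Four well-mixed compartments, linear first-order transfer:
ER →(k_release, split φ_bl) → {apical, basolateral};
basolateral →(k_transcytosis)→ apical;
apical →(k_ciliary, saturating)→ cilium, with import slowing as
$1 - C/C_{\max}$ near the ceiling $C_{\max}$ (`cilium_capacity`).  Mass is
conserved exactly (no degradation); a `leak_fraction` places reporter on
the surfaces before release, split by φ_bl, to represent constitutive
leak.  Integration is fixed-step RK4 at dt = 0.001 h (via deSolve), which
conserves mass to machine precision and matches an adaptive reference
integrator to ≤ 1e-6.

Defaults (units 1/h unless noted): `k_release` = 2.0, `phi_bl` = 0.62,
`k_transcytosis` = 0.5, `k_ciliary` = 0.3, `cilium_capacity` = 0.05,
`leak_fraction` = 0.  The rate constants are not measured quantities; they
are calibrated once so the model reproduces the qualitative behaviour the
statistics are meant to detect: the basolateral pool peaks at ~0.92 h,
basolateral arrival exceeds apical roughly 2-fold when the sorting split
alone acts (φ_bl = 2/3 with transcytosis off gives BL/AP = 2 exactly at
all times), the ciliary pool reaches 0.048 of total reporter by 1.5 h
(saturating toward 0.05), and a live trace shows first ciliary signal
(>10 % of plateau) at the 20-min frame with 90 % of plateau near 80 min.
These values were fixed before the validation suite was written and are
not revisited.

One structural limitation is worth stating plainly: with no endocytosis or
degradation, the total apical-domain signal (apical membrane + cilium) is
monotone non-decreasing, so on a 0–2 h grid its maximum sits at the end of
the window rather than declining after ~1.5 h as measured membrane signals
do in cells with membrane turnover.  The basolateral-before-apical peak
ordering, which the statistics actually use, is reproduced.  Adding a
turnover pathway would require a fifth compartment and was rejected to
keep the state space identical to what the measurements see.

The model treats the apical pool as well mixed; whether ciliary import
draws on the whole apical pool or a periciliary subregion is unknown, and
a periciliary model would change single-cell kinetics but not the
population statistics validated here.

### Geometry

A cylindrical cell (footprint ⌀ 10 µm, height 8 µm), membrane shells at
least one voxel thick, a cilium of length 3 µm, radius 0.12 µm, tilt 10°
protruding from the apical face, a ring of non-expressing neighbours, and
a clear margin to the stack boundary.  The resulting ciliary-to-cell
volume ratio is 1/4630, inside the published 1/2700–1/6800 band.  The
cilium is voxelized volume-preservingly: voxels are ranked by supersampled
partial-volume fraction and selected until the analytic cylinder volume is
filled.  A naive "voxel centre inside" or "half inside" rule fails here —
at 0.25 µm sampling a 0.12 µm cylinder can fall entirely between voxel
centres and vanish.

### Image formation

Reporter photons are spread uniformly within each compartment's voxels in
proportion to the compartment fractions; the surface channel carries the
stained side only (apical staining includes the ciliary membrane, which is
continuous with the apical surface); the marker channel covers the cilium
independently of the reporter.  The optical chain is: anisotropic Gaussian
PSF (σ lateral 0.12 µm, axial 0.35 µm — a standard confocal
approximation), applied with truncated, renormalized (unit-sum) separable
kernels so pre-noise intensity is conserved exactly while all signal stays
one kernel radius from the boundary; then Poisson shot noise on signal
plus background, additive Gaussian read noise, clipping and quantization
to 16 bits.  Defaults: 3 × 10⁷ photons per expression unit, background 10
counts, read noise 1.5 counts.  The photon budget is chosen so the
clipped-noise residue that background subtraction leaves in empty voxels
stays ≈ 2 % of the per-cell sums; much dimmer settings would bias the
ratio statistics upward, much brighter ones would clip the ciliary peak at
the detector ceiling.  `seed` fixes all randomness: the same seed
reproduces a stack bit-identically.

### Per-cell variability

Expression is log-normal (median 1, `expression_sdlog` = 0.35 — a
realistic 2–3× spread between dim and bright transfected cells).  The
sorting fraction φ_bl is jittered normally per cell (`phi_sd` = 0.08,
truncated to [0.02, 0.98]).  Because the split partitions a conserved
total, cells with a larger basolateral share automatically have a smaller
apical + ciliary share; this is the ground-truth anticorrelation that the
slope analysis must recover, not an assumption layered on top of it.

### Live imaging

A time lapse renders one frame per time point from the same kinetic
trajectory, by default a single confocal plane through the cilium
mid-height (depth-1 stack, lateral blur only — the thin-object
approximation for single-plane acquisition); full-3D mode shares the code
path.  Live frames use 10 % of the fixed-cell illumination
(`live_photon_fraction`), as live acquisitions do to limit phototoxicity;
this also keeps the concentrated single-plane ciliary signal inside the
16-bit range.  The trace masks the reporter with the per-frame-thresholded
marker channel and sums; the mask is recomputed every frame because cilia
drift, with an optional union-with-previous smoothing (off by default) and
an optional exponential photobleaching correction (off by default — no
correction is applied unless requested).

## 5. Problem sizes and sampling profiles

Single-cell validation uses the default sampling of (0.3, 0.1, 0.1) µm
voxels.  Population studies use `population_profile()`: (0.3, 0.2, 0.2) µm
voxels with a narrower neighbour ring, which leaves MCC recovery within
~8 % of truth while rendering a cell in well under a second; large
sign-structure screens (hundreds of cells where only the relative per-cell
ordering matters) use (0.4, 0.25, 0.25) µm.  The validation suite runs ten
repetitions of three 50-cell replicate populations for the slope-sign
analysis, ten seeded renders for ciliary-fraction recovery, and 40 cells
per side for the sorting-split recovery; these sizes put Monte-Carlo error
comfortably inside the tolerances being tested while a full run stays in
the minutes range.

## 6. What synthetic validation shows — and what it does not

Passing recovery tests shows the pipeline is correct and approximately
unbiased *under the generator's assumptions*: well-mixed compartments,
uniform within-compartment labelling, a Gaussian PSF, stationary
background, isolated cells with cooperative neighbours for background
estimation, and a marker channel that labels exactly the cilium.  Real
microscopy violates each of these to some degree: acetylated tubulin
stains cytoplasmic microtubules (the protrusion filter is the defence, but
a bright tilted bundle touching the apical plane can still fool it),
backgrounds drift, PSFs have non-Gaussian tails, membranes are not
uniformly labelled, and antibody access differs between the apical and
basolateral sides of filter-grown cells — the package treats each side's
ratio as internally comparable and never compares raw apical to
basolateral staining intensities directly; the 2-fold sorting asymmetry is
recovered from simulations where the two channels share gains by
construction.  Numbers produced on real data therefore inherit these
caveats in exactly the places the generator is idealized.

## 7. Numerical and interface choices

* Arrays are `[z, y, x]` (R's 1-based, z first), `voxel_size` is the
  (z, y, x) triple in µm, physical coordinates are voxel centres.  Stated
  once here, used everywhere.
* Stacks are written as plain multi-page TIFF (channel-major pages) with a
  JSON sidecar for voxel size, channel names and acquisition metadata;
  round trips are bit-exact at 8 or 16 bits.  Proprietary microscope
  formats are out of scope.
* Tie-breaks in component selection: size, then protrusion above the
  apical plane, then total brightness — deterministic for reproducibility.
* Degenerate inputs fail loudly and early: empty background regions, zero
  total reporter (MCC and ratio undefined), fewer than two points or zero
  x-variance in a slope fit, unpaired replicate lists, a replicate whose
  series is all zero (named in the error).  A paired test on identical
  lists returns t = 0, p = 1 rather than erroring, because "no difference"
  is a meaningful result.
* An empty cilium mask is not an error but a QC outcome ("no cilium
  detected"): absence of a cilium is data.
* The pipeline entry point is configuration-driven (`run_pipeline()` on a
  YAML config) and writes a manifest with MD5 hashes of every output plus
  the fully resolved configuration, so a run is reproducible from its
  manifest; the same functions back the thin command-line wrapper in
  `inst/cli/ciliarrival.R` (subcommands `simulate`, `quantify`,
  `timecourse`, `slopes`, `trace`, `demo`).

```{r example, eval = FALSE}
# a miniature end-to-end run
pr  <- population_profile(seed = 1)
pop <- generate_population(6, kinetic_params(), variability_spec(),
                           time = 1, seed = 1, geometry = pr$geometry,
                           imaging = pr$imaging,
                           stained_side = c("apical", "basolateral"))
q   <- quantify_population(pop, pr$settings)
fit_mcc_vs_surface(q, "apical")
```
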