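# ciliarrival

Quantification of polarized cell-surface arrival and ciliary arrival of a
membrane reporter in 3D fluorescence microscopy of epithelial cells — with
a ground-truthed synthetic microscopy generator so the whole pipeline can
be validated without raw imaging data.

## The problem

After a synchronized release from the endoplasmic reticulum, a ciliary
membrane protein (e.g. the GPCR SSTR3 carrying a GFP tag) travels through
the secretory pathway and appears at the apical membrane, the basolateral
membrane and the primary cilium of polarized epithelial cells (MDCK
monolayers).  Three single-cell statistics describe this wave:

- **Ciliary fraction (Manders' co-localization coefficient).**  With a
  ciliary-marker channel segmented into a mask *M*, and a reporter channel
  *R* background-subtracted,

  MCC = Σ_{i ∈ M} R_i / Σ_{j : R_j > 0} R_j ,

  the fraction of total reporter signal that sits in the cilium.  A value
  of 0.05 means 5 % of the protein is ciliary.  Because a cilium occupies
  only ~1/2700–1/6800 of the cell volume, random (volume-proportional)
  delivery could explain at most MCC ≈ 3.7 × 10⁻⁴; anything near 0.05 is
  active enrichment.

- **Surface-to-total ratio.**  Side-specific surface-stain signal divided
  by total reporter signal in one cell: the arrival statistic per side
  (apical staining includes the ciliary membrane, which is part of the
  apical surface).  Time courses are averaged per replicate and
  max-normalized before replicates are combined, so channel gains cancel.

- **Slope of MCC vs surface signal.**  Across single cells at a fixed
  release time, an OLS fit of MCC against the apical (or basolateral)
  surface ratio.  Lateral ciliary import from the apical membrane predicts
  a positive apical slope and a negative basolateral slope; the two sides
  are compared with a two-tailed paired t-test over replicates.

Cells only enter the MCC statistics when their cilium passes QC: the
segmented marker component must protrude ≥ 1 µm above the apical plane and
tilt ≤ 60° from the optical axis (sharply tilted cilia cannot be separated
from apical membrane signal at confocal resolution).

## The synthetic generator

No raw data accompany the study conditions, so the package ships a
generator that renders the whole experiment: a four-compartment trafficking
model (ER → apical/basolateral sorting split → transcytosis → saturating
ciliary import, integrated with fixed-step RK4), a parametric polarized
cell (cylindrical body, membrane shells, a 3 µm × 0.12 µm cilium tilted
10°, non-expressing neighbours), and an image-formation model (anisotropic
Gaussian PSF, Poisson shot noise, Gaussian read noise, 16-bit
quantization).  Every stack carries its ground truth, so recovery can be
checked against the known compartment fractions.

## Worked example

```r
library(ciliarrival)

pr  <- population_profile(seed = 42)             # population-scale rendering
pop <- generate_population(n_cells = 10, params = kinetic_params(),
                           variability = variability_spec(), time = 1,
                           seed = 42, geometry = pr$geometry,
                           imaging = pr$imaging,
                           stained_side = c("apical", "basolateral"))
q <- quantify_population(pop, pr$settings)
head(q[, c("cell_id", "side", "surface_ratio", "mcc", "qc_pass")], 4)
#>   cell_id        side surface_ratio    mcc qc_pass
#> 1 r1_c001      apical         0.411 0.0330    TRUE
#> 2 r1_c002 basolateral         0.507 0.0296    TRUE
#> 3 r1_c003      apical         0.547 0.0390    TRUE
#> 4 r1_c004 basolateral         0.378 0.0367    TRUE

fit_mcc_vs_surface(q, "apical")
#> MCC vs apical surface ratio: slope 0.03026, intercept 0.02132 (n = 5 cells, R2 = 0.834)
fit_mcc_vs_surface(q, "basolateral")
#> MCC vs basolateral surface ratio: slope -0.04559, intercept 0.05346 (n = 5 cells, R2 = 0.983)
```

One hour after release each cell carries ~3–4 % of its reporter in the
cilium (`mcc`), and roughly 40–50 % of the reporter has reached the stained
surface (`surface_ratio`, equal channel gains).  Cells with more apical
signal have more ciliary signal (positive apical slope); cells with more
basolateral signal have less (negative basolateral slope) — the signature
of lateral ciliary import via the apical membrane.

The analytic bound is one call:

```r
manders_mcc(array(1, c(2700, 1, 1)),
            array(c(TRUE, rep(FALSE, 2699)), c(2700, 1, 1)))
#> [1] 0.0003703704       # random delivery at a 1/2700 volume ratio
```

An end-to-end demonstration (simulate → quantify → time courses → slopes,
with a manifest of every output and its MD5) runs from the shipped config:

```sh
Rscript inst/cli/ciliarrival.R demo --out demo_out --seed 1
```

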