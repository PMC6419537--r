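#' Render a synthetic multi-channel stack of one polarized cell
#'
#' Produces the three acquisition channels used throughout the package:
#' `gfp` (total reporter, distributed over compartments in proportion to
#' the compartment state), `surface` (side-specific surface stain: apical
#' staining covers the apical membrane *and* the ciliary membrane, since
#' the ciliary membrane is part of the apical surface; basolateral staining
#' covers the lateral walls and base), and `cilium` (ciliary marker,
#' independent of the reporter).  Signal is blurred with a unit-sum
#' anisotropic Gaussian PSF, then Poisson shot noise, Gaussian read noise,
#' clipping and integer quantization are applied.  The returned ground
#' truth carries the voxel label map, the compartment state and every
#' parameter, so recovered statistics can be compared with truth.
#'
#' @param geometry A [cell_geometry()].
#' @param state A [compartment_state()] (fractions of total reporter).
#' @param imaging An [imaging_params()]; `imaging$seed` fixes the noise.
#' @param stained_side Which surface was stained: `"apical"`,
#'   `"basolateral"` or `"none"`.
#' @param expression_level Reporter expression of this cell (unitless);
#'   total pre-noise reporter intensity is
#'   `expression_level * imaging$photons_per_unit`.
#' @param surface_gain Photons collected per reporter unit in the surface
#'   channel relative to the reporter channel (1 = equal gains).
#' @param marker_photons Total pre-noise photons in the ciliary-marker
#'   channel.
#' @param replicate_id Replicate label stored in the stack metadata.
#' @param plane_mode If `TRUE`, render a single confocal plane through the
#'   mid-height of the cilium (depth-1 stack, lateral blur only), as in a
#'   live-imaging acquisition.
#' @param vox Optional precomputed [voxelize_cell()] result (re-used across
#'   renders of the same geometry for speed).
#' @return A list with `stack` (a [voxel_stack()]) and `truth` (class
#'   `ground_truth`: `labels`, `state`, `expression_level`, per-channel
#'   pre-noise totals, geometry and imaging parameters).
#' @examples
#' im <- imaging_params(voxel_size = c(0.3, 0.2, 0.2), seed = 7)
#' st <- compartment_state(fractions = c(er = 0.5, apical = 0.3,
#'                                       basolateral = 0.15, cilium = 0.05))
#' r <- render_stack(cell_geometry(), st, im)
#' r$stack
#' @export
render_stack <- function(geometry, state, imaging,
                         stained_side = c("apical", "basolateral", "none"),
                         expression_level = 1,
                         surface_gain = 1,
                         marker_photons = 2e5,
                         replicate_id = "r1",
                         plane_mode = FALSE,
                         vox = NULL) {
  stained_side <- match.arg(stained_side)
  if (is.null(vox)) vox <- voxelize_cell(geometry, imaging$voxel_size)
  lab <- vox$labels
  d <- dim(lab)

  expr_photons <- expression_level * imaging$photons_per_unit
  idx <- list(
    intracellular = which(lab == LABELS[["intracellular"]]),
    apical = which(lab == LABELS[["apical_membrane"]]),
    basolateral = which(lab == LABELS[["basolateral_membrane"]]),
    cilium = which(lab == LABELS[["cilium"]]))

  gfp <- array(0, dim = d)
  put <- function(a, voxels, total) {
    if (total > 0 && length(voxels)) a[voxels] <- a[voxels] + total / length(voxels)
    a
  }
  gfp <- put(gfp, idx$intracellular, state$er * expr_photons)
  gfp <- put(gfp, idx$apical, state$apical * expr_photons)
  gfp <- put(gfp, idx$basolateral, state$basolateral * expr_photons)
  gfp <- put(gfp, idx$cilium, state$cilium * expr_photons)

  surf <- array(0, dim = d)
  if (stained_side == "apical") {
    surf <- put(surf, idx$apical, state$apical * expr_photons * surface_gain)
    surf <- put(surf, idx$cilium, state$cilium * expr_photons * surface_gain)
  } else if (stained_side == "basolateral") {
    surf <- put(surf, idx$basolateral,
                state$basolateral * expr_photons * surface_gain)
  }

  marker <- put(array(0, dim = d), idx$cilium, marker_photons)

  if (plane_mode) {
    zc <- vox$centers$z
    cil_z <- arrayInd(idx$cilium, d)[, 1]
    iz <- if (length(cil_z)) round(mean(range(cil_z))) else which.min(abs(zc - vox$apical_z))
    slab <- function(a) array(a[iz, , ], dim = c(1L, d[2], d[3]))
    gfp <- slab(gfp); surf <- slab(surf); marker <- slab(marker)
    lab <- slab(lab)
    d <- dim(gfp)
  }

  pre_noise <- list(gfp = gfp, surface = surf, cilium = marker)
  pre_noise <- lapply(pre_noise, apply_psf, psf_sigma = imaging$psf_sigma,
                      voxel_size = imaging$voxel_size,
                      lateral_only = plane_mode)

  set.seed(imaging$seed)
  channels <- lapply(pre_noise, apply_noise, imaging = imaging)

  stack <- voxel_stack(channels, voxel_size = imaging$voxel_size,
                       release_time = state$time,
                       stained_side = stained_side,
                       replicate_id = replicate_id,
                       meta = list(expression_level = expression_level,
                                   surface_gain = surface_gain))
  truth <- structure(list(
    labels = lab,
    state = state,
    expression_level = expression_level,
    stained_side = stained_side,
    pre_noise_totals = vapply(pre_noise, sum, numeric(1)),
    apical_z = vox$apical_z,
    geometry = geometry,
    imaging = imaging,
    plane_mode = plane_mode), class = "ground_truth")
  list(stack = stack, truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth:\n")
  cat(sprintf("  expression %.3g, stained side %s, t = %.3g h\n",
              x$expression_level, x$stained_side, x$state$time))
  cat(sprintf("  fractions: ER %.3f apical %.3f basolateral %.3f cilium %.3f\n",
              x$state$er, x$state$apical, x$state$basolateral,
              x$state$cilium))
  cat(sprintf("  cilium voxels: %d of %d cell voxels\n",
              sum(x$labels == LABELS[["cilium"]]),
              sum(x$labels %in% LABELS[c("intracellular", "apical_membrane",
                                         "basolateral_membrane", "cilium")])))
  invisible(x)
}

#' Masks derived from ground-truth labels
#'
#' `truth_cell_mask()` returns the expressing-cell mask, dilated laterally
#' by `dilate_um` to capture membrane signal spread outside the geometric
#' cell by the PSF (the synthetic analogue of drawing a generous manual
#' outline around an isolated cell).  `truth_background_mask()` returns a
#' region over non-expressing neighbours, eroded away from the cell by
#' `clearance_um` so blurred cell signal does not contaminate the
#' background estimate.
#'
#' @param truth A `ground_truth` from [render_stack()].
#' @param dilate_um Dilation of the cell mask, scalar or `(z, y, x)` µm.
#' @param clearance_um Minimum distance between the background region and
#'   the (undilated) cell (µm).
#' @return A logical array `[z, y, x]`.
#' @export
truth_cell_mask <- function(truth, dilate_um = c(1.0, 0.4, 0.4)) {
  cellish <- truth$labels %in% LABELS[c("intracellular", "apical_membrane",
                                        "basolateral_membrane", "cilium")]
  dim(cellish) <- dim(truth$labels)
  dilate_mask(cellish, dilate_um, truth$imaging$voxel_size)
}

#' @rdname truth_cell_mask
#' @export
truth_background_mask <- function(truth, clearance_um = 2) {
  cellish <- truth$labels %in% LABELS[c("intracellular", "apical_membrane",
                                        "basolateral_membrane", "cilium")]
  dim(cellish) <- dim(truth$labels)
  near_cell <- dilate_mask(cellish, clearance_um, truth$imaging$voxel_size)
  cand <- truth$labels == LABELS[["neighbor_cell"]]
  if (!any(cand)) cand <- truth$labels == LABELS[["outside"]]  # plane mode
  bg <- cand & !near_cell
  dim(bg) <- dim(truth$labels)
  bg
}

# Binary dilation by a physical radius, axis-separable (box structuring
# element) - adequate for guard margins.  `radius_um` is either a scalar
# or a (z, y, x) triple.
dilate_mask <- function(mask, radius_um, voxel_size) {
  radius_um <- rep_len(radius_um, 3L)
  if (all(radius_um <= 0) || !any(mask)) return(mask)
  d <- dim(mask)
  r_vox <- pmin(floor(radius_um / voxel_size), d - 1L)
  # operate on the padded bounding box of the mask only
  ai <- arrayInd(which(mask), d)
  lo <- pmax(apply(ai, 2, min) - r_vox, 1L)
  hi <- pmin(apply(ai, 2, max) + r_vox, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE] * 1
  for (ax in 1:3) {
    r <- r_vox[ax]
    if (r < 1 || dim(sub)[ax] == 1L) next
    sub <- conv_axis(sub, ax, rep(1, 2 * r + 1))
  }
  out <- mask
  out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub > 1e-9
  out
}
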