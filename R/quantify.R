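#' Quantification settings
#'
#' Tunable parameters of the per-cell quantification pipeline.
#'
#' @param channel_map Named character vector mapping the roles `gfp`
#'   (total reporter), `surface` (side stain) and `cilium` (ciliary
#'   marker) to channel names in the stack.
#' @param threshold Ciliary-marker threshold: `"otsu"` (default; Otsu's
#'   method on the background-subtracted marker histogram) or an absolute
#'   intensity value.
#' @param tilt_max Maximum allowed cilium tilt from the z-axis (degrees);
#'   cilia lying flatter than this are excluded as "sharply tilted".
#' @param min_protrusion Minimum axial extent of the cilium above the
#'   apical reference plane (µm) for a cell to pass QC.
#' @param cell_dilate_um Dilation of the ground-truth cell mask, `(z, y,
#'   x)` µm, capturing membrane signal blurred outside the geometric cell
#'   (the synthetic analogue of a generous manual outline).
#' @param bg_clearance_um Clearance between the background region and the
#'   cell (µm) when the region is derived from ground truth.
#' @param mask_dilate_um Dilation of the segmented cilium mask, `(z, y,
#'   x)` µm, applied before the MCC numerator so that ciliary reporter
#'   signal spread by the PSF just outside the half-maximum marker core
#'   is still counted; the default is about two lateral PSF sigma and one
#'   axial voxel at the default sampling.
#' @param min_gfp Optional minimum reporter intensity (counts) a voxel
#'   must exceed, beyond background subtraction, to enter the MCC
#'   denominator.  The default 0 uses every voxel positive after clipped
#'   background subtraction.
#' @return An object of class `quant_settings`.
#' @export
quant_settings <- function(channel_map = c(gfp = "gfp", surface = "surface",
                                           cilium = "cilium"),
                           threshold = "otsu",
                           tilt_max = 60,
                           min_protrusion = 1,
                           cell_dilate_um = c(1.0, 0.4, 0.4),
                           bg_clearance_um = 2,
                           mask_dilate_um = c(0.3, 0.25, 0.25),
                           min_gfp = 0) {
  stopifnot(all(c("gfp", "surface", "cilium") %in% names(channel_map)))
  structure(list(channel_map = channel_map, threshold = threshold,
                 tilt_max = tilt_max, min_protrusion = min_protrusion,
                 cell_dilate_um = cell_dilate_um,
                 bg_clearance_um = bg_clearance_um,
                 mask_dilate_um = mask_dilate_um,
                 min_gfp = min_gfp),
            class = "quant_settings")
}

#' Subtract background estimated from non-expressing regions
#'
#' For each channel the scalar background is the mean intensity over the
#' `background` region (non-expressing neighbour cells); it is subtracted
#' and negative values are clipped to zero.  The estimated backgrounds are
#' recorded in the stack metadata.
#'
#' @param stack A [voxel_stack()].
#' @param regions A [region_set()] with a `background` mask (and
#'   optionally a `cell` mask used to warn about overlap).
#' @return The background-subtracted [voxel_stack()].
#' @export
subtract_background <- function(stack, regions) {
  stopifnot(is_voxel_stack(stack), inherits(regions, "region_set"))
  bg_mask <- regions$masks$background
  if (is.null(bg_mask)) stop("regions must contain a 'background' mask", call. = FALSE)
  if (!is.null(regions$masks$cell) && any(bg_mask & regions$masks$cell)) {
    warning("background region overlaps the cell outline; estimate may be biased")
  }
  bg <- vapply(stack$channels, function(ch) mean(ch[bg_mask]), numeric(1))
  stack$channels <- lapply(seq_along(stack$channels), function(i) {
    pmax(stack$channels[[i]] - bg[i], 0)
  })
  names(stack$channels) <- stack$channel_names
  stack$meta$background <- bg
  stack$meta$background_subtracted <- TRUE
  stack
}

# 6-connected components of a voxel set, via igraph.  `lin` are linear
# indices into an array of dimension `d`.  Returns a membership vector.
components_3d <- function(lin, d) {
  n <- length(lin)
  ai <- arrayInd(lin, d)
  ord <- order(lin)
  lin_sorted <- lin[ord]
  edges <- list()
  strides <- c(1L, d[1], d[1] * d[2])
  for (ax in 1:3) {
    ok <- ai[, ax] < d[ax]
    nb <- lin[ok] + strides[ax]
    hit <- findInterval(nb, lin_sorted)
    hit_ok <- hit > 0 & lin_sorted[pmax(hit, 1L)] == nb
    if (any(hit_ok)) {
      edges[[length(edges) + 1L]] <- cbind(which(ok)[hit_ok],
                                           ord[hit[hit_ok]])
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges)) {
    g <- igraph::add_edges(g, t(do.call(rbind, edges)))
  }
  igraph::components(g)$membership
}

#' Segment the primary cilium from the ciliary-marker channel
#'
#' Thresholds the background-subtracted marker channel (Otsu by default),
#' labels 6-connected components, discards components that do not reach
#' above the apical reference plane (rejecting intracellular acetylated
#' tubulin such as cytoplasmic microtubules), and keeps the largest
#' remaining component.  Ties on size are broken by greater protrusion
#' above the apical plane, then by total brightness.  The selected
#' component is then tightened to its half-maximum contour
#' (`peak_fraction` of the component's peak intensity), which trims the
#' dim shell that the PSF spreads around a sub-resolution cilium.  An
#' empty mask is a valid outcome (no cilium detected), reported
#' downstream via QC.
#'
#' @param channel Background-subtracted marker channel, array `[z, y, x]`.
#' @param voxel_size `(z, y, x)` voxel size (µm).
#' @param apical_z Apical reference plane height (µm).
#' @param threshold `"otsu"` or an absolute intensity.
#' @param peak_fraction Fraction of the selected component's peak
#'   intensity used to tighten the mask; 0 keeps the full suprathreshold
#'   component.
#' @return A logical array `[z, y, x]`: the cilium mask.
#' @export
segment_cilium <- function(channel, voxel_size, apical_z,
                           threshold = "otsu", peak_fraction = 0.5) {
  d <- dim(channel)
  mx <- max(channel)
  if (mx <= 0) return(array(FALSE, dim = d))
  thr <- if (identical(threshold, "otsu")) {
    otsu_threshold(channel)
  } else as.numeric(threshold)
  lin <- which(channel > thr)
  if (!length(lin)) return(array(FALSE, dim = d))
  memb <- components_3d(lin, d)
  zc <- (arrayInd(lin, d)[, 1] - 0.5) * voxel_size[1]
  comp_ids <- unique(memb)
  stats <- vapply(comp_ids, function(cid) {
    sel <- memb == cid
    c(size = sum(sel),
      protrusion = max(zc[sel]) - apical_z,
      brightness = sum(channel[lin[sel]]))
  }, numeric(3))
  protruding <- stats["protrusion", ] > 0
  if (!any(protruding)) return(array(FALSE, dim = d))
  cand <- which(protruding)
  cand <- cand[order(-stats["size", cand], -stats["protrusion", cand],
                     -stats["brightness", cand])]
  best <- comp_ids[cand[1]]
  keep <- lin[memb == best]
  if (peak_fraction > 0) {
    keep <- keep[channel[keep] >= peak_fraction * max(channel[keep])]
  }
  mask <- array(FALSE, dim = d)
  mask[keep] <- TRUE
  mask
}

# Global Otsu threshold on a voxel array; EBImage computes the threshold
# from the intensity histogram, so the array is passed as a single frame.
otsu_threshold <- function(channel) {
  mx <- max(channel)
  v <- as.numeric(channel) / mx
  img <- EBImage::Image(matrix(v, ncol = 1L))
  EBImage::otsu(img, range = c(0, 1), levels = 256L) * mx
}

#' Quality control of a segmented cilium
#'
#' A cell passes only if a cilium was detected, its principal axis is
#' tilted from the z-axis by at most `tilt_max` degrees (cilia lying in
#' the apical plane cannot be separated from apical membrane signal at
#' confocal resolution), and it extends at least `min_protrusion` µm above
#' the apical reference plane.
#'
#' @param mask Logical cilium mask `[z, y, x]` from [segment_cilium()].
#' @param apical_z Apical reference plane (µm).
#' @param voxel_size `(z, y, x)` voxel size (µm).
#' @param tilt_max Maximum tilt (degrees).
#' @param min_protrusion Minimum protrusion above `apical_z` (µm).
#' @return A list with `qc_pass` (logical), `qc_reason` (text, empty on
#'   pass) and `tilt` (degrees, `NA` if undefined).
#' @export
cilium_qc <- function(mask, apical_z, voxel_size, tilt_max = 60,
                      min_protrusion = 1) {
  if (!any(mask)) {
    return(list(qc_pass = FALSE, qc_reason = "no cilium detected", tilt = NA_real_))
  }
  co <- voxel_coords_um(mask, voxel_size)
  tilt <- principal_tilt(co)
  protrusion <- max(co[, "z"]) - apical_z
  if (!is.na(tilt) && tilt > tilt_max) {
    return(list(qc_pass = FALSE, qc_reason = "sharply tilted", tilt = tilt))
  }
  if (protrusion < min_protrusion) {
    return(list(qc_pass = FALSE, qc_reason = "insufficient protrusion",
                tilt = tilt))
  }
  list(qc_pass = TRUE, qc_reason = "", tilt = tilt)
}

voxel_coords_um <- function(mask, voxel_size) {
  ai <- arrayInd(which(mask), dim(mask))
  cbind(z = (ai[, 1] - 0.5) * voxel_size[1],
        y = (ai[, 2] - 0.5) * voxel_size[2],
        x = (ai[, 3] - 0.5) * voxel_size[3])
}

# Tilt of the principal axis of a voxel cloud from the z-axis, degrees.
principal_tilt <- function(co) {
  if (nrow(co) < 3L) return(NA_real_)
  if (all(apply(co, 2, var) < 1e-12)) return(NA_real_)
  pc <- prcomp(co, center = TRUE, scale. = FALSE)
  v <- pc$rotation[, 1]
  acos(min(abs(v[["z"]]) / sqrt(sum(v^2)), 1)) * 180 / pi
}

#' Manders' co-localization coefficient
#'
#' The fraction of total above-background reporter signal found in voxels
#' of the ciliary mask:
#' \deqn{MCC = \frac{\sum_i R_i^{coloc}}{\sum_j R_j}}
#' where the numerator sums the reporter over mask voxels and the
#' denominator over every voxel whose reporter signal is positive after
#' clipped background subtraction (restricted to `cell_mask` when given).
#' Because the reporter is a membrane protein and the mask is the cilium,
#' the MCC is the ciliary fraction of the reporter.
#'
#' @param gfp_channel Background-subtracted reporter channel `[z, y, x]`.
#' @param cilium_mask Logical mask from [segment_cilium()].
#' @param cell_mask Optional logical mask restricting the denominator to
#'   one cell.
#' @param min_gfp Optional extra intensity threshold for the denominator
#'   support (counts); 0 keeps every positive voxel.
#' @return The MCC, in `[0, 1]`.
#' @examples
#' ch <- array(1, dim = c(4, 5, 5))
#' m <- array(FALSE, dim = dim(ch)); m[1, 1, 1:5] <- TRUE
#' manders_mcc(ch, m)   # 5 / 100
#' @export
manders_mcc <- function(gfp_channel, cilium_mask, cell_mask = NULL,
                        min_gfp = 0) {
  support <- gfp_channel > min_gfp
  if (!is.null(cell_mask)) support <- support & cell_mask
  total <- sum(gfp_channel[support])
  if (total <= 0) stop("total reporter signal is zero; MCC undefined", call. = FALSE)
  sum(gfp_channel[support & cilium_mask]) / total
}

#' Side-specific surface-to-total intensity ratio
#'
#' The summed surface-stain intensity divided by the summed total-reporter
#' intensity over one cell.  The two channels have independent gains, so
#' the ratio is not bounded by 1 and is only comparable within a series
#' acquired at fixed gains (time courses are max-normalized downstream).
#'
#' @param surface_channel Background-subtracted surface-stain channel.
#' @param gfp_channel Background-subtracted reporter channel.
#' @param cell_mask Logical mask of the cell.
#' @return The ratio (>= 0).
#' @export
surface_total_ratio <- function(surface_channel, gfp_channel, cell_mask) {
  if (!any(cell_mask)) stop("cell mask is empty", call. = FALSE)
  total <- sum(gfp_channel[cell_mask])
  if (total <= 0) stop("total reporter signal is zero; ratio undefined", call. = FALSE)
  sum(surface_channel[cell_mask]) / total
}

#' Quantify one cell: background, segmentation, QC, MCC and surface ratio
#'
#' Runs the full per-cell pipeline: background subtraction from
#' non-expressing regions, ciliary-marker segmentation, protrusion QC,
#' then the MCC (only for QC-passing cells) and the side-specific
#' surface-to-total ratio (always).  Regions can be supplied manually as a
#' [region_set()] (`background` required, `cell` optional) or derived from
#' the rendering ground truth of a synthetic stack.
#'
#' @param stack A [voxel_stack()] with reporter, surface and marker
#'   channels.
#' @param regions A [region_set()], or `NULL` to derive masks from
#'   `truth`.
#' @param settings A [quant_settings()].
#' @param truth Optional `ground_truth` from [render_stack()]; supplies
#'   the cell mask, background region and apical plane for synthetic data.
#' @param apical_z Apical reference plane (µm); defaults to the ground
#'   truth value or, failing that, to the 95th percentile of the
#'   cell-mask voxel z-distribution.
#' @param cell_id Identifier stored in the record.
#' @return An object of class `cell_quant`: per-cell statistics plus a
#'   `provenance` list recording backgrounds, threshold, mask sizes and
#'   settings.
#' @export
quantify_cell <- function(stack, regions = NULL, settings = quant_settings(),
                          truth = NULL, apical_z = NULL,
                          cell_id = "cell1") {
  cm <- settings$channel_map
  missing_ch <- setdiff(unname(cm), stack$channel_names)
  if (length(missing_ch)) {
    stop("channel map names channels absent from the stack: ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  }
  if (is.null(regions)) {
    if (is.null(truth)) stop("either regions or ground truth must be given", call. = FALSE)
    regions <- region_set(list(
      background = truth_background_mask(truth, settings$bg_clearance_um),
      cell = truth_cell_mask(truth, settings$cell_dilate_um)))
  }
  cell_mask <- regions$masks$cell
  if (is.null(cell_mask)) {
    if (!is.null(truth)) {
      cell_mask <- truth_cell_mask(truth, settings$cell_dilate_um)
    } else stop("no cell mask available", call. = FALSE)
  }
  sub <- subtract_background(stack, regions)
  gfp <- sub$channels[[cm[["gfp"]]]]
  surf <- sub$channels[[cm[["surface"]]]]
  marker <- sub$channels[[cm[["cilium"]]]]

  if (is.null(apical_z)) {
    apical_z <- if (!is.null(truth)) truth$apical_z else {
      zc <- voxel_coords_um(cell_mask, stack$voxel_size)[, "z"]
      quantile(zc, 0.95, names = FALSE)
    }
  }

  mask <- segment_cilium(marker, stack$voxel_size, apical_z,
                         threshold = settings$threshold)
  qc <- cilium_qc(mask, apical_z, stack$voxel_size,
                  tilt_max = settings$tilt_max,
                  min_protrusion = settings$min_protrusion)
  mcc <- if (qc$qc_pass) {
    mcc_mask <- dilate_mask(mask, settings$mask_dilate_um, stack$voxel_size)
    manders_mcc(gfp, mcc_mask, cell_mask = cell_mask,
                min_gfp = settings$min_gfp)
  } else NA_real_
  ratio <- surface_total_ratio(surf, gfp, cell_mask)

  structure(list(
    cell_id = cell_id,
    replicate_id = stack$replicate_id,
    release_time = stack$release_time,
    side = stack$stained_side,
    surface_ratio = ratio,
    mcc = mcc,
    cilium_voxels = sum(mask),
    qc_pass = qc$qc_pass,
    qc_reason = qc$qc_reason,
    provenance = list(
      background = sub$meta$background,
      threshold = settings$threshold,
      apical_z = apical_z,
      tilt = qc$tilt,
      cell_mask_voxels = sum(cell_mask),
      settings = settings)),
    class = "cell_quant")
}

#' @export
print.cell_quant <- function(x, ...) {
  cat(sprintf("Cell %s (replicate %s, t = %s h, %s stain):\n",
              x$cell_id, x$replicate_id, format(x$release_time), x$side))
  cat(sprintf("  surface/total ratio = %.4f\n", x$surface_ratio))
  if (x$qc_pass) {
    cat(sprintf("  MCC = %.4f over %d cilium voxels\n", x$mcc, x$cilium_voxels))
  } else {
    cat(sprintf("  QC failed (%s); MCC not reported\n", x$qc_reason))
  }
  invisible(x)
}

#' Convert a `cell_quant` to a one-row data frame
#' @param x A `cell_quant` object.
#' @param ... Unused.
#' @export
as.data.frame.cell_quant <- function(x, ...) {
  data.frame(cell_id = x$cell_id, replicate_id = x$replicate_id,
             release_time = x$release_time, side = x$side,
             surface_ratio = x$surface_ratio, mcc = x$mcc,
             cilium_voxels = x$cilium_voxels, qc_pass = x$qc_pass,
             qc_reason = x$qc_reason, stringsAsFactors = FALSE)
}

#' Quantify every cell of a synthetic population
#'
#' Applies [quantify_cell()] to each rendered cell of a
#' [generate_population()] result and binds the records.
#'
#' @param population A `cell_population`.
#' @param settings A [quant_settings()].
#' @return A data frame with one row per cell.
#' @export
quantify_population <- function(population, settings = quant_settings()) {
  # all cells share one geometry, so the truth-derived masks are computed once
  tr1 <- population[[1]]$truth
  regions <- region_set(list(
    background = truth_background_mask(tr1, settings$bg_clearance_um),
    cell = truth_cell_mask(tr1, settings$cell_dilate_um)))
  rows <- lapply(population, function(ci) {
    as.data.frame(quantify_cell(ci$stack, regions = regions,
                                settings = settings,
                                apical_z = ci$truth$apical_z,
                                cell_id = ci$cell_id))
  })
  do.call(rbind, rows)
}
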