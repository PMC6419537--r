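#' Trace ciliary reporter intensity through a time lapse
#'
#' The live-imaging quantification: in every frame the ciliary-marker
#' channel is background-subtracted and thresholded, the resulting mask
#' (recomputed per frame, since the cilium drifts) is applied to the
#' background-subtracted reporter channel, and the masked reporter
#' intensity is summed.  Background for both channels comes from a static
#' region over empty/non-expressing area, supplied once and reused for
#' every frame.  Frames whose marker mask is empty are flagged and their
#' intensity recorded as missing.
#'
#' Single-plane time lapses are depth-1 stacks and share this code path
#' with full 3D time lapses.
#'
#' @param timelapse List of [voxel_stack()] frames, time-ordered; frame
#'   times (min) are taken from `times` or from each stack's
#'   `release_time` metadata (converted from h to min when `times` is
#'   `NULL`).
#' @param background_mask Logical array (frame-shaped): the static
#'   background region.
#' @param times Frame times in minutes (optional, overrides metadata).
#' @param settings A [quant_settings()]; supplies the channel map and
#'   marker threshold.
#' @param mask_union_previous If `TRUE`, each frame's mask is unioned
#'   with the previous frame's (smooths flicker for dim markers); off by
#'   default.
#' @param bleach_halflife Optional photobleaching correction: intensities
#'   are divided by `2^(-t / halflife)` (minutes); `NULL` (default)
#'   applies no correction.
#' @return A `ciliary_trace`: data frame with columns `time` (min),
#'   `intensity` (summed masked reporter, counts), `mask_voxels` and
#'   `flagged`.
#' @export
trace_ciliary_intensity <- function(timelapse, background_mask, times = NULL,
                                    settings = quant_settings(),
                                    mask_union_previous = FALSE,
                                    bleach_halflife = NULL) {
  if (!length(timelapse)) stop("empty time lapse", call. = FALSE)
  if (is.null(times)) {
    times <- vapply(timelapse, function(s) s$release_time, numeric(1)) * 60
  }
  if (length(times) != length(timelapse)) {
    stop("times must match the number of frames", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  cm <- settings$channel_map
  prev_mask <- NULL
  rows <- vector("list", length(timelapse))
  for (i in seq_along(timelapse)) {
    fr <- timelapse[[i]]
    need <- c(cm[["gfp"]], cm[["cilium"]])
    if (!all(need %in% fr$channel_names)) {
      stop("frame ", i, " lacks reporter or marker channel", call. = FALSE)
    }
    gfp <- fr$channels[[cm[["gfp"]]]]
    marker <- fr$channels[[cm[["cilium"]]]]
    bg_g <- mean(gfp[background_mask])
    bg_m <- mean(marker[background_mask])
    gfp <- pmax(gfp - bg_g, 0)
    marker <- pmax(marker - bg_m, 0)
    mx <- max(marker)
    mask <- if (mx <= 0) {
      array(FALSE, dim = dim(marker))
    } else {
      thr <- if (identical(settings$threshold, "otsu")) {
        otsu_threshold(marker)
      } else as.numeric(settings$threshold)
      marker > thr
    }
    if (mask_union_previous && !is.null(prev_mask)) mask <- mask | prev_mask
    prev_mask <- mask
    if (!any(mask)) {
      rows[[i]] <- data.frame(time = times[i], intensity = NA_real_,
                              mask_voxels = 0L, flagged = TRUE)
      next
    }
    val <- sum(gfp[mask])
    if (!is.null(bleach_halflife)) {
      val <- val / 2^(-times[i] / bleach_halflife)
    }
    rows[[i]] <- data.frame(time = times[i], intensity = val,
                            mask_voxels = sum(mask), flagged = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ciliary_trace", "data.frame")
  out
}

#' @export
print.ciliary_trace <- function(x, ...) {
  cat(sprintf("Ciliary reporter trace: %d frames, %d flagged\n",
              nrow(x), sum(x$flagged)))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
plot.ciliary_trace <- function(x, ...) {
  graphics::plot(x$time, x$intensity, type = "b", pch = 16,
                 xlab = "time after release (min)",
                 ylab = "masked reporter intensity (counts)", ...)
  invisible(x)
}

#' Simulate a live-imaging time lapse
#'
#' Renders a single-plane (or full 3D) time lapse of one cell following
#' the calibrated trafficking kinetics, as acquired in a live-imaging
#' experiment: reporter and ciliary-marker channels, one frame per time
#' point.  Per-frame noise is seeded independently but reproducibly from
#' `seed`.
#'
#' @param times_min Frame times in minutes after release.
#' @param params [kinetic_params()].
#' @param geometry [cell_geometry()].
#' @param imaging [imaging_params()].
#' @param seed Integer seed.
#' @param plane_mode Single-plane acquisition (default) or full 3D.
#' @param live_photon_fraction Illumination scale relative to fixed-cell
#'   imaging; live acquisitions use reduced laser power to limit
#'   phototoxicity, which also keeps the concentrated single-plane ciliary
#'   signal inside the detector range.
#' @return A list with `frames` (list of [voxel_stack()]), `times_min`,
#'   `truths` (per-frame ground truth) and `background_mask`.
#' @export
simulate_timelapse <- function(times_min = seq(0, 120, by = 10),
                               params = kinetic_params(),
                               geometry = cell_geometry(),
                               imaging = imaging_params(),
                               seed = 1L,
                               plane_mode = TRUE,
                               live_photon_fraction = 0.1) {
  imaging$photons_per_unit <- imaging$photons_per_unit * live_photon_fraction
  vox <- voxelize_cell(geometry, imaging$voxel_size)
  tc <- simulate_trafficking(params, times = times_min / 60)
  frames <- vector("list", length(times_min))
  truths <- vector("list", length(times_min))
  for (i in seq_along(times_min)) {
    st <- compartment_state(fractions = unlist(
      tc[i, c("er", "apical", "basolateral", "cilium")]))
    st$time <- times_min[i] / 60
    im_i <- imaging
    im_i$seed <- (seed + 104729L * i) %% .Machine$integer.max
    r <- render_stack(geometry, st, im_i, stained_side = "none",
                      plane_mode = plane_mode, vox = vox)
    frames[[i]] <- r$stack
    truths[[i]] <- r$truth
  }
  bg <- truth_background_mask(truths[[1]], clearance_um = 2)
  list(frames = frames, times_min = times_min, truths = truths,
       background_mask = bg)
}
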