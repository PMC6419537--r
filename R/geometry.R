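#' Parametric polarized-cell geometry
#'
#' Describes one polarized epithelial cell in a monolayer: a cylindrical
#' cell body (circular footprint, flat apical face), a thin membrane shell
#' split into an apical face and a basolateral shell (lateral walls plus
#' base), a single cilium modelled as a tilted cylinder protruding from the
#' apical face, and a ring of non-expressing neighbour cells used for
#' background estimation.
#'
#' With the defaults (cilium 3 µm long, radius 0.12 µm; cell 10 µm across,
#' 8 µm high) the ciliary-to-cell volume ratio is about 1/4600, inside the
#' 1/6800–1/2700 band expected for epithelial cells.
#'
#' @param footprint_diameter Cell footprint diameter (µm).
#' @param cell_height Cell height from base to apical face (µm).
#' @param apical_z Height of the apical face above the stack origin (µm).
#' @param membrane_thickness Membrane shell thickness used for voxelization
#'   (µm); optical membranes are thinner than a voxel, this is the
#'   rendering support.
#' @param cilium_base_xy Cilium base position on the apical face, `(y, x)`
#'   µm relative to the cell centre.
#' @param cilium_length Cilium length (µm).
#' @param cilium_radius Cilium radius (µm).
#' @param cilium_tilt Cilium tilt from the z-axis (degrees).
#' @param neighbor_count Number of non-expressing neighbour cells in the
#'   surrounding ring.
#' @param neighbor_ring_width Radial extent of the neighbour ring (µm).
#' @param margin Clear margin between the neighbour ring and the stack
#'   boundary (µm); must exceed the PSF support so blur conserves signal.
#' @return An object of class `cell_geometry`.
#' @examples
#' g <- cell_geometry()
#' cilium_volume(g) / cell_volume(g)   # ~ 1/4600
#' @export
cell_geometry <- function(footprint_diameter = 10,
                          cell_height = 8,
                          apical_z = 9.5,
                          membrane_thickness = 0.15,
                          cilium_base_xy = c(0, 0),
                          cilium_length = 3,
                          cilium_radius = 0.12,
                          cilium_tilt = 10,
                          neighbor_count = 6,
                          neighbor_ring_width = 2.5,
                          margin = 1.5) {
  g <- list(footprint_diameter = footprint_diameter,
            cell_height = cell_height,
            apical_z = apical_z,
            membrane_thickness = membrane_thickness,
            cilium_base_xy = cilium_base_xy,
            cilium_length = cilium_length,
            cilium_radius = cilium_radius,
            cilium_tilt = cilium_tilt,
            neighbor_count = as.integer(neighbor_count),
            neighbor_ring_width = neighbor_ring_width,
            margin = margin)
  lens <- c(footprint_diameter, cell_height, membrane_thickness,
            cilium_length, cilium_radius, margin)
  if (any(lens <= 0)) stop("all geometry lengths must be > 0", call. = FALSE)
  if (membrane_thickness >= footprint_diameter / 4) {
    stop("membrane_thickness must be < footprint_diameter/4", call. = FALSE)
  }
  if (apical_z < cell_height) {
    stop("apical_z must leave room for the cell body below the apical face",
         call. = FALSE)
  }
  if (cilium_tilt < 0 || cilium_tilt >= 90) {
    stop("cilium_tilt must be in [0, 90) degrees so the cilium protrudes",
         call. = FALSE)
  }
  structure(g, class = "cell_geometry")
}

#' @rdname cell_geometry
#' @param geometry A `cell_geometry` object.
#' @export
cilium_volume <- function(geometry) {
  pi * geometry$cilium_radius^2 * geometry$cilium_length
}

#' @rdname cell_geometry
#' @export
cell_volume <- function(geometry) {
  pi * (geometry$footprint_diameter / 2)^2 * geometry$cell_height
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf("Polarized cell: footprint %.3g um, height %.3g um, apical face at z = %.3g um\n",
              x$footprint_diameter, x$cell_height, x$apical_z))
  cat(sprintf("Cilium: length %.3g um, radius %.3g um, tilt %.3g deg; volume ratio 1/%.0f\n",
              x$cilium_length, x$cilium_radius, x$cilium_tilt,
              cell_volume(x) / cilium_volume(x)))
  cat(sprintf("%d non-expressing neighbours, %.3g um outer margin\n",
              x$neighbor_count, x$margin))
  invisible(x)
}

# Voxel label codes shared by the renderer and the ground truth.
LABELS <- c(outside = 0L, intracellular = 1L, apical_membrane = 2L,
            basolateral_membrane = 3L, cilium = 4L, neighbor_cell = 5L)

#' Voxelize a cell geometry into a label map
#'
#' Partitions a voxel grid into outside, intracellular, apical membrane,
#' basolateral membrane, cilium and neighbour-cell labels.  Cilium voxels
#' are assigned by volume-preserving voxelization: voxels are ranked by
#' their supersampled partial-volume fraction inside the cilium cylinder
#' and selected until the analytic cylinder volume is filled, so the
#' voxelized cilium volume matches the analytic volume to within half a
#' voxel even when the cilium is thinner than the lateral sampling.  The
#' cilium takes precedence over membrane labels where it meets the apical
#' face.
#'
#' @param geometry A [cell_geometry()] object.
#' @param voxel_size `(z, y, x)` voxel size in µm.
#' @param subsamples Per-axis subsampling factor for the cilium
#'   partial-volume test.
#' @param extent Optional physical stack extent `(z, y, x)` in µm; defaults
#'   to a size that contains the cell, cilium, neighbour ring and margin.
#'   An extent too small for the cilium is a geometry error.
#' @return A list with `labels` (integer array `[z, y, x]`), `dim`,
#'   `voxel_size`, `apical_z` and the voxel coordinates helpers used by the
#'   renderer.
#' @export
voxelize_cell <- function(geometry, voxel_size = c(0.3, 0.1, 0.1),
                          subsamples = 3L, extent = NULL) {
  g <- geometry
  vz <- voxel_size[1]; vy <- voxel_size[2]; vx <- voxel_size[3]
  tilt <- g$cilium_tilt * pi / 180
  ring_width <- g$neighbor_ring_width
  tip_z <- g$apical_z + g$cilium_length * cos(tilt)
  tip_x <- abs(g$cilium_base_xy[2]) + g$cilium_length * sin(tilt)
  if (is.null(extent)) {
    half_xy <- g$footprint_diameter / 2 + ring_width + g$margin
    zmax <- tip_z + max(1.5, g$margin)
  } else {
    zmax <- extent[1]
    half_xy <- min(extent[2], extent[3]) / 2
    if (tip_z + g$cilium_radius > zmax ||
        tip_x + g$cilium_radius > half_xy) {
      stop("cilium extends beyond stack bounds", call. = FALSE)
    }
  }
  nz <- ceiling(zmax / vz); ny <- ceiling(2 * half_xy / vy)
  nx <- ceiling(2 * half_xy / vx)

  zc <- (seq_len(nz) - 0.5) * vz
  yc <- (seq_len(ny) - 0.5) * vy - half_xy
  xc <- (seq_len(nx) - 0.5) * vx - half_xy

  lab <- array(LABELS[["outside"]], dim = c(nz, ny, nx))

  r2 <- outer(yc^2, xc^2, "+")            # [y, x] squared radius from centre
  rad <- sqrt(r2)
  R <- g$footprint_diameter / 2
  base_z <- g$apical_z - g$cell_height
  # membrane shells are at least one voxel thick so they contain voxel centres
  th_xy <- max(g$membrane_thickness, vy, vx)
  th_z <- max(g$membrane_thickness, vz)
  in_fp <- rad <= R
  in_lat_shell <- in_fp & rad > R - th_xy
  in_core <- rad <= R - th_xy
  in_ring <- rad > R & rad <= R + ring_width

  z_in_cell <- zc >= base_z & zc <= g$apical_z
  z_apical <- zc > g$apical_z - th_z & zc <= g$apical_z
  z_basal <- zc >= base_z & zc < base_z + th_z

  for (iz in seq_len(nz)) {
    if (!z_in_cell[iz]) next
    sl <- lab[iz, , ]
    sl[in_ring] <- LABELS[["neighbor_cell"]]
    if (z_basal[iz]) {
      sl[in_fp] <- LABELS[["basolateral_membrane"]]
    } else if (z_apical[iz]) {
      sl[in_core] <- LABELS[["apical_membrane"]]
      sl[in_lat_shell] <- LABELS[["basolateral_membrane"]]
    } else {
      sl[in_core] <- LABELS[["intracellular"]]
      sl[in_lat_shell] <- LABELS[["basolateral_membrane"]]
    }
    lab[iz, , ] <- sl
  }

  # Cilium: tilted cylinder from the apical face, axis in the x-z plane.
  b <- c(z = g$apical_z, y = g$cilium_base_xy[1], x = g$cilium_base_xy[2])
  axis <- c(z = cos(tilt), y = 0, x = sin(tilt))
  cil_idx <- cilium_voxels(b, axis, g$cilium_length, g$cilium_radius,
                           zc, yc, xc, voxel_size, subsamples)
  if (nrow(cil_idx) > 0) lab[cil_idx] <- LABELS[["cilium"]]

  list(labels = lab, dim = c(nz, ny, nx), voxel_size = voxel_size,
       apical_z = g$apical_z, centers = list(z = zc, y = yc, x = xc))
}

# Volume-preserving voxelization of the cilium cylinder: voxels ranked by
# subsampled partial-volume fraction, selected until the analytic cylinder
# volume is filled.  Returns an index matrix [z, y, x].
cilium_voxels <- function(base, axis, len, radius, zc, yc, xc,
                          voxel_size, subsamples = 3L) {
  # bounding box of the cylinder, padded by one radius
  ends <- rbind(base, base + axis * len)
  lo <- apply(ends, 2, min) - radius - voxel_size
  hi <- apply(ends, 2, max) + radius + voxel_size
  iz <- which(zc >= lo["z"] & zc <= hi["z"])
  iy <- which(yc >= lo["y"] & yc <= hi["y"])
  ix <- which(xc >= lo["x"] & xc <= hi["x"])
  if (!length(iz) || !length(iy) || !length(ix)) {
    return(matrix(integer(0), ncol = 3))
  }
  grid <- expand.grid(z = iz, y = iy, x = ix)
  s <- subsamples
  offs <- (seq_len(s) - 0.5) / s - 0.5  # sub-offsets in voxel units
  sub <- expand.grid(dz = offs * voxel_size[1], dy = offs * voxel_size[2],
                     dx = offs * voxel_size[3])
  frac <- numeric(nrow(grid))
  pz <- zc[grid$z]; py <- yc[grid$y]; px <- xc[grid$x]
  for (k in seq_len(nrow(sub))) {
    dz <- pz + sub$dz[k] - base["z"]
    dy <- py + sub$dy[k] - base["y"]
    dx <- px + sub$dx[k] - base["x"]
    t_ax <- dz * axis["z"] + dy * axis["y"] + dx * axis["x"]
    r2 <- (dz - t_ax * axis["z"])^2 + (dy - t_ax * axis["y"])^2 +
      (dx - t_ax * axis["x"])^2
    frac <- frac + (t_ax >= 0 & t_ax <= len & r2 <= radius^2)
  }
  frac <- frac / nrow(sub)
  v_vox <- prod(voxel_size)
  n_target <- max(1L, round(pi * radius^2 * len / v_vox))
  cand <- which(frac > 0)
  if (!length(cand)) return(matrix(integer(0), ncol = 3))
  cand <- cand[order(-frac[cand])]
  keep <- cand[seq_len(min(n_target, length(cand)))]
  as.matrix(grid[keep, c("z", "y", "x"), drop = FALSE])
}
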