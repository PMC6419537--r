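#' Multi-channel voxel stack
#'
#' The image currency of the package: a named list of 3D intensity arrays
#' (one per channel, all `[z, y, x]` with identical dimensions), the voxel
#' size in µm, and acquisition metadata (release time, stained side,
#' replicate ID).
#'
#' @param channels Named list of numeric arrays `[z, y, x]`; names are the
#'   channel names (conventionally `gfp`, `surface`, `cilium`).
#' @param voxel_size `(z, y, x)` voxel size in µm.
#' @param release_time Time since ER release (h), or `NA`.
#' @param stained_side `"apical"`, `"basolateral"` or `"none"`.
#' @param replicate_id Replicate identifier.
#' @param meta Additional metadata list (kept as-is).
#' @return An object of class `voxel_stack`.
#' @export
voxel_stack <- function(channels, voxel_size = c(0.3, 0.1, 0.1),
                        release_time = NA_real_,
                        stained_side = c("none", "apical", "basolateral"),
                        replicate_id = NA_character_, meta = list()) {
  stained_side <- match.arg(stained_side)
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("all channels must be named", call. = FALSE)
  }
  dims <- lapply(channels, dim)
  dims <- lapply(dims, function(d) if (is.null(d)) stop("channels must be arrays") else d)
  d1 <- dims[[1]]
  if (length(d1) == 2L) {  # promote single-plane images to depth-1 stacks
    channels <- lapply(channels, function(ch) array(ch, dim = c(1L, dim(ch))))
    d1 <- c(1L, d1)
  }
  for (d in lapply(channels, dim)) {
    if (!identical(as.integer(d), as.integer(dim(channels[[1]])))) {
      stop("all channels must share dimensions", call. = FALSE)
    }
  }
  if (any(voxel_size <= 0)) stop("voxel_size must be strictly positive", call. = FALSE)
  if (any(vapply(channels, function(ch) any(ch < 0), logical(1)))) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(list(channels = channels,
                 channel_names = names(channels),
                 voxel_size = voxel_size,
                 release_time = release_time,
                 stained_side = stained_side,
                 replicate_id = replicate_id,
                 meta = meta),
            class = "voxel_stack")
}

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("Voxel stack %d x %d x %d (z, y, x), %d channel(s): %s\n",
              d[1], d[2], d[3], length(x$channels),
              paste(x$channel_names, collapse = ", ")))
  cat(sprintf("  voxel size (%.3g, %.3g, %.3g) um | release %s h | stained side %s | replicate %s\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              format(x$release_time), x$stained_side, x$replicate_id))
  invisible(x)
}

#' @rdname voxel_stack
#' @param x Object to test.
#' @export
is_voxel_stack <- function(x) inherits(x, "voxel_stack")

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write a voxel stack to multi-page TIFF
#'
#' Pages are written channel-major (all z planes of channel 1, then
#' channel 2, ...), 16- or 8-bit.  Voxel size, channel names and
#' acquisition metadata go to a JSON sidecar next to the TIFF (same name,
#' `.json` extension), so the round trip [read_stack()] ∘ `write_stack`
#' preserves intensities bit-exactly and all metadata fields.
#'
#' @param stack A [voxel_stack()].
#' @param path Output TIFF path.
#' @param bit_depth 8 or 16; intensities must fit the range.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bit_depth = 16L) {
  stopifnot(is_voxel_stack(stack))
  top <- 2^bit_depth - 1
  pages <- list()
  for (ch in stack$channel_names) {
    a <- stack$channels[[ch]]
    if (max(a) > top) stop("intensities exceed bit depth", call. = FALSE)
    for (iz in seq_len(dim(a)[1])) {
      pages[[length(pages) + 1L]] <- a[iz, , ] / top
    }
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bit_depth,
                  compression = "none", reduce = FALSE)
  side <- list(
    format = "ciliarrival-stack",
    channel_names = as.list(stack$channel_names),
    nz = dim(stack$channels[[1]])[1],
    bit_depth = bit_depth,
    voxel_size = stack$voxel_size,
    release_time = stack$release_time,
    stained_side = stack$stained_side,
    replicate_id = stack$replicate_id,
    meta = stack$meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a voxel stack from TIFF
#'
#' Reads a multi-page TIFF written by [write_stack()] (metadata from the
#' JSON sidecar) or a plain multi-page TIFF (channel order and z-depth
#' given by `channel_names` and `nz`).  Single-plane 2D TIFFs are promoted
#' to depth-1 stacks.  When no voxel size is available a documented default
#' of `(0.3, 0.1, 0.1)` µm is used with a warning.
#'
#' @param path TIFF path.
#' @param channel_names Channel names for plain TIFFs without a sidecar;
#'   the page count must be a multiple of the channel count.
#' @param nz Number of z planes per channel for plain TIFFs; defaults to
#'   `pages / length(channel_names)`.
#' @param voxel_size Override voxel size (µm).
#' @return A [voxel_stack()].
#' @export
read_stack <- function(path, channel_names = NULL, nz = NULL,
                       voxel_size = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, info = FALSE),
                    error = function(e) stop("cannot read TIFF '", path, "': ",
                                             conditionMessage(e), call. = FALSE))
  if (!is.list(pages)) pages <- list(pages)
  side <- NULL
  if (file.exists(sidecar_path(path))) {
    side <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  }
  bit_depth <- if (!is.null(side$bit_depth)) side$bit_depth else 16L
  if (is.null(channel_names)) {
    channel_names <- if (!is.null(side)) side$channel_names else "channel1"
  }
  n_ch <- length(channel_names)
  if (is.null(nz)) {
    nz <- if (!is.null(side$nz)) side$nz else length(pages) / n_ch
  }
  if (n_ch * nz != length(pages)) {
    stop(sprintf("%d TIFF pages cannot hold %d channel(s) x %d plane(s)",
                 length(pages), n_ch, nz), call. = FALSE)
  }
  top <- 2^bit_depth - 1
  channels <- list()
  for (ci in seq_len(n_ch)) {
    d2 <- dim(pages[[1]])[1:2]
    a <- array(0, dim = c(nz, d2))
    for (iz in seq_len(nz)) {
      pg <- pages[[(ci - 1L) * nz + iz]]
      if (length(dim(pg)) > 2L) pg <- pg[, , 1L]  # collapse replicated samples
      a[iz, , ] <- round(pg * top)
    }
    channels[[channel_names[[ci]]]] <- a
  }
  if (is.null(voxel_size)) {
    if (!is.null(side$voxel_size)) {
      voxel_size <- side$voxel_size
    } else {
      warning("no voxel-size metadata; assuming (0.3, 0.1, 0.1) um")
      voxel_size <- c(0.3, 0.1, 0.1)
    }
  }
  voxel_stack(channels, voxel_size = voxel_size,
              release_time = if (!is.null(side$release_time)) side$release_time else NA_real_,
              stained_side = if (!is.null(side$stained_side)) side$stained_side else "none",
              replicate_id = if (!is.null(side$replicate_id)) side$replicate_id else NA_character_,
              meta = if (!is.null(side$meta)) as.list(side$meta) else list())
}

#' Named voxel regions for background estimation
#'
#' @param masks Named list of logical arrays matching the stack dimensions
#'   (e.g. `background` over non-expressing neighbours, optional `cell`
#'   outline).
#' @return An object of class `region_set`.
#' @export
region_set <- function(masks) {
  if (is.null(names(masks))) stop("regions must be named", call. = FALSE)
  for (nm in names(masks)) {
    if (!any(masks[[nm]])) stop("region '", nm, "' is empty", call. = FALSE)
  }
  structure(list(masks = masks), class = "region_set")
}

quant_columns <- c("cell_id", "replicate_id", "release_time", "side",
                   "surface_ratio", "mcc", "cilium_voxels", "qc_pass",
                   "qc_reason")

#' Write per-cell quantification records to CSV
#'
#' One row per cell with a stable column order; statistics that failed QC
#' are written as empty fields.
#'
#' @param records A data frame of per-cell quantifications (rows from
#'   [quantify_cell()], see [as.data.frame.cell_quant()]), or a list of
#'   `cell_quant` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_quant_table <- function(records, path) {
  df <- quant_records(records)
  if (nrow(df) == 0L) stop("no records to write", call. = FALSE)
  write.csv(df[, quant_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a per-cell quantification table written by [write_quant_table()]
#' @param path CSV path.
#' @return A data frame with the standard quantification columns.
#' @export
read_quant_table <- function(path) {
  df <- read.csv(path, na.strings = "", colClasses = list(
    cell_id = "character", replicate_id = "character", side = "character",
    qc_reason = "character"))
  df$qc_pass <- as.logical(df$qc_pass)
  df$qc_reason[is.na(df$qc_reason)] <- ""
  df[, quant_columns]
}

# Coerce quantification input (data frame or list of cell_quant) to a
# data frame with the standard columns.
quant_records <- function(records) {
  if (is.data.frame(records)) {
    missing_cols <- setdiff(quant_columns, names(records))
    if (length(missing_cols)) {
      stop("missing quantification columns: ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    return(records)
  }
  if (inherits(records, "cell_quant")) records <- list(records)
  do.call(rbind, lapply(records, as.data.frame))
}
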