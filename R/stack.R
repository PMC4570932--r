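# Image stacks, ROIs and cropping.
#
# Internal layout: voxels are stored as a 4D numeric array with dimensions
# (channel, z, y, x); single-channel input is promoted. Axial spacing dz may
# differ from the in-plane spacing, which must be isotropic (dy == dx).

#' Multi-channel 3D image stack
#'
#' Container for a fluorescence z-stack with physical voxel spacing. The
#' canonical two-channel layout is a membrane-potential-independent green
#' marker (mitochondrial structure) plus a potential-dependent red marker.
#'
#' @param voxels numeric array, either 3D `(z, y, x)` for a single channel or
#'   4D `(channel, z, y, x)`. All intensities must be finite and >= 0.
#' @param spacing numeric length-3 vector `(dz, dy, dx)` in micrometres, all
#'   strictly positive; `dz` may differ from the (isotropic) in-plane spacing.
#' @param channel_names character vector of channel labels; defaults to
#'   `"gfp"`, `"mcherry"`, `"stain"` for 1-3 channels.
#'
#' @return An object of class `image_stack` with fields `voxels`, `spacing`
#'   and `channel_names`.
#' @export
image_stack <- function(voxels, spacing, channel_names = NULL) {
  if (!is.array(voxels) || !length(dim(voxels)) %in% c(3L, 4L))
    stop("`voxels` must be a 3D (z,y,x) or 4D (channel,z,y,x) array")
  if (length(dim(voxels)) == 3L)
    voxels <- array(voxels, dim = c(1L, dim(voxels)))
  nc <- dim(voxels)[1L]
  if (!nc %in% 1:3)
    stop("channel count must be 1, 2 or 3 (got ", nc, ")")
  if (anyNA(voxels) || any(!is.finite(voxels)))
    stop("all intensities must be finite")
  if (any(voxels < 0))
    stop("all intensities must be non-negative")
  if (is.null(channel_names))
    channel_names <- c("gfp", "mcherry", "stain")[seq_len(nc)]
  if (length(channel_names) != nc)
    stop("length(channel_names) must equal the channel count")
  spacing <- check_spacing(spacing)
  structure(
    list(voxels = voxels, spacing = spacing,
         channel_names = as.character(channel_names)),
    class = "image_stack")
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || anyNA(spacing) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive values (dz, dy, dx) in um")
  if (abs(spacing[2L] - spacing[3L]) > 1e-9 * spacing[2L])
    stop("in-plane spacing must be isotropic (dy == dx)")
  names(spacing) <- c("dz", "dy", "dx")
  spacing
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d channel(s) [%s], %d x %d x %d (z,y,x) voxels\n",
              d[1L], paste(x$channel_names, collapse = ", "),
              d[2L], d[3L], d[4L]))
  cat(sprintf("  spacing (um): dz = %g, dy = %g, dx = %g\n",
              x$spacing[1L], x$spacing[2L], x$spacing[3L]))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$voxels)

#' Extract one channel of a stack as a 3D array
#'
#' @param stack an [image_stack].
#' @param channel channel name or index.
#' @return 3D numeric array `(z, y, x)`.
#' @export
get_channel <- function(stack, channel) {
  stopifnot(inherits(stack, "image_stack"))
  if (is.character(channel)) {
    i <- match(channel, stack$channel_names)
    if (is.na(i)) stop("no channel named '", channel, "'")
  } else i <- as.integer(channel)
  if (i < 1L || i > dim(stack$voxels)[1L]) stop("channel index out of range")
  arr <- stack$voxels[i, , , , drop = FALSE]
  array(arr, dim = dim(stack$voxels)[-1L])
}

#' Rectangular per-cell region of interest
#'
#' Axis-aligned box in voxel indices, 0-based and half-open: voxel index `i`
#' (0-based) belongs to the ROI iff `lo <= i < hi` on every axis. This is the
#' interchange convention of the ROI sidecar files; R's 1-based indexing is
#' applied internally when cropping.
#'
#' @param label cell identifier string.
#' @param lo,hi integer length-3 vectors `(z, y, x)`, `lo < hi` elementwise.
#' @return An object of class `cell_roi`.
#' @export
cell_roi <- function(label, lo, hi) {
  lo <- as.integer(lo); hi <- as.integer(hi)
  if (length(lo) != 3L || length(hi) != 3L || anyNA(lo) || anyNA(hi))
    stop("`lo` and `hi` must be integer (z, y, x) triples")
  if (any(lo < 0L)) stop("ROI bounds must be >= 0")
  if (any(hi <= lo)) stop("ROI must have a non-empty interior (hi > lo)")
  structure(list(label = as.character(label), lo = lo, hi = hi),
            class = "cell_roi")
}

#' Crop a stack to one cell's ROI
#'
#' @param stack an [image_stack].
#' @param roi a [cell_roi]; must lie within the stack extent.
#' @return The sub-stack, with spacing and channel names preserved.
#' @export
crop_cell <- function(stack, roi) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "cell_roi"))
  ext <- dim(stack$voxels)[-1L]
  if (any(roi$hi > ext))
    stop("ROI '", roi$label, "' exceeds the stack extent")
  v <- stack$voxels[, (roi$lo[1L] + 1L):roi$hi[1L],
                      (roi$lo[2L] + 1L):roi$hi[2L],
                      (roi$lo[3L] + 1L):roi$hi[3L], drop = FALSE]
  image_stack(v, stack$spacing, stack$channel_names)
}

#' Read a TIFF z-stack
#'
#' Pages are interpreted channel-fastest (page = (z - 1) * n_channels + c, the
#' ImageJ hyperstack XYCZT order). 8- and 16-bit integer data are read as-is;
#' 32-bit stacks are linearly rescaled so that their maximum maps to 65535
#' before any thresholding.
#'
#' @param path TIFF file path.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres (acquisition
#'   metadata, supplied by the user).
#' @param channel_names channel labels; their number fixes the channel count.
#' @return An [image_stack].
#' @export
read_stack <- function(path, spacing, channel_names = "gfp") {
  if (!file.exists(path)) stop("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) stop("unreadable TIFF '", path, "': ",
                                             conditionMessage(e)))
  if (length(pages) == 0L) stop("TIFF '", path, "' contains no images")
  bits <- attr(tiff::readTIFF(path, info = TRUE), "bits.per.sample")
  if (!is.null(bits) && bits > 16L) {
    pages <- tiff::readTIFF(path, all = TRUE)  # native float values
    mx <- max(vapply(pages, max, numeric(1)))
    if (mx > 0) pages <- lapply(pages, function(p) p * (65535 / mx))
  }
  nc <- length(channel_names)
  if (length(pages) %% nc != 0L)
    stop("page count (", length(pages), ") is not a multiple of the declared ",
         nc, " channel(s)")
  nz <- length(pages) %/% nc
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  v <- array(0, dim = c(nc, nz, ny, nx))
  for (z in seq_len(nz))
    for (ch in seq_len(nc))
      v[ch, z, , ] <- pages[[(z - 1L) * nc + ch]]
  image_stack(v, spacing, channel_names)
}

#' Write a stack as a 16-bit TIFF
#'
#' Pages are written channel-fastest, matching [read_stack()]. Intensities
#' above 65535 are clipped.
#'
#' @param stack an [image_stack].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$voxels)
  pages <- vector("list", d[1L] * d[2L])
  for (z in seq_len(d[2L]))
    for (ch in seq_len(d[1L])) {
      m <- matrix(stack$voxels[ch, z, , ], d[3L], d[4L])
      pages[[(z - 1L) * d[1L] + ch]] <- pmin(pmax(round(m), 0), 65535) / 65535
    }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read / write ROI sidecar files
#'
#' CSV with columns `label, z0, y0, x0, z1, y1, x1`; bounds are 0-based and
#' half-open (see [cell_roi()]).
#'
#' @param path CSV file path.
#' @return `read_rois()`: a list of [cell_roi]; `write_rois()`: `path`,
#'   invisibly.
#' @export
read_rois <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "z0", "y0", "x0", "z1", "y1", "x1")
  if (!all(need %in% names(df)))
    stop("ROI file must have columns: ", paste(need, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i)
    cell_roi(df$label[i],
             lo = c(df$z0[i], df$y0[i], df$x0[i]),
             hi = c(df$z1[i], df$y1[i], df$x1[i])))
}

#' @rdname read_rois
#' @param rois list of [cell_roi] objects.
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(label = r$label, z0 = r$lo[1L], y0 = r$lo[2L], x0 = r$lo[3L],
               z1 = r$hi[1L], y1 = r$hi[2L], x1 = r$hi[3L])))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
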