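# Otsu thresholding, Gaussian smoothing and the per-cell analysis mask.

#' Otsu threshold of an intensity volume
#'
#' Histogram threshold maximising the between-class variance, computed on a
#' 256-bin histogram spanning `[min, max]` of the volume. Ties are broken by
#' the lowest threshold; the foreground mask is `intensity > threshold`.
#'
#' @param volume numeric array or vector with at least two distinct values.
#' @param n_bins number of histogram bins (default 256).
#' @return The threshold intensity (upper edge of the optimal background bin).
#' @export
otsu_threshold <- function(volume, n_bins = 256L) {
  v <- as.numeric(volume)
  if (anyNA(v) || any(!is.finite(v))) stop("volume contains non-finite values")
  rng <- range(v)
  if (rng[1L] == rng[2L])
    stop("constant volume: no separable intensity classes")
  edges <- seq(rng[1L], rng[2L], length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), n_bins)
  cnt <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  w0 <- cumsum(cnt)
  m0 <- cumsum(cnt * mids)
  wtot <- w0[n_bins]; mtot <- m0[n_bins]
  # candidate split after bin k (k = 1 .. n_bins - 1)
  k <- seq_len(n_bins - 1L)
  p0 <- w0[k] / wtot
  p1 <- 1 - p0
  mu0 <- ifelse(w0[k] > 0, m0[k] / w0[k], 0)
  mu1 <- ifelse(wtot - w0[k] > 0, (mtot - m0[k]) / (wtot - w0[k]), 0)
  bcv <- p0 * p1 * (mu0 - mu1)^2
  edges[which.max(bcv) + 1L]  # which.max returns the first (lowest) maximum
}

#' Gaussian blur of a 3D volume
#'
#' Default mode smooths each z-slice with a 2D Gaussian kernel (the in-plane
#' convention of display-based image analysis); `mode = "3d"` additionally
#' convolves along z with sigma scaled by `dx / dz` so the physical smoothing
#' radius is isotropic.
#'
#' @param volume 3D numeric array `(z, y, x)`.
#' @param sigma kernel standard deviation in pixels; `0` is the identity.
#' @param mode `"2d"` (per-slice) or `"3d"`.
#' @param spacing voxel spacing, required for `mode = "3d"`.
#' @return The blurred array, same dimensions.
#' @export
gaussian_blur <- function(volume, sigma, mode = c("2d", "3d"), spacing = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(volume)
  size <- 2L * ceiling(3 * sigma) + 1L
  d <- dim(volume)
  size <- min(size, 2L * (min(d[2L], d[3L]) %/% 2L) - 1L)  # kernel <= image
  brush <- EBImage::makeBrush(size, shape = "gaussian", sigma = sigma)
  img <- aperm(volume, c(3L, 2L, 1L))  # EBImage frames: (x, y, z)
  out <- EBImage::filter2(img, brush, boundary = "replicate")
  out <- aperm(as.array(out), c(3L, 2L, 1L))
  if (mode == "3d") {
    spacing <- check_spacing(spacing)
    out <- convolve_z(out, sigma * spacing[["dx"]] / spacing[["dz"]])
  }
  out
}

# 1D Gaussian convolution along z with replicated borders.
convolve_z <- function(volume, sigma_z) {
  if (sigma_z <= 0) return(volume)
  r <- ceiling(3 * sigma_z)
  k <- stats::dnorm(-r:r, sd = sigma_z)
  k <- k / sum(k)
  nz <- dim(volume)[1L]
  out <- array(0, dim(volume))
  for (i in seq_along(k)) {
    off <- i - r - 1L
    src <- pmin(pmax(seq_len(nz) + off, 1L), nz)  # replicate edges
    out <- out + k[i] * volume[src, , , drop = FALSE]
  }
  out
}

#' Binary volume with provenance
#'
#' @param mask 3D logical array `(z, y, x)`.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres.
#' @param provenance list describing the thresholding that produced the mask
#'   (method, sigma, threshold value, channels).
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(mask, spacing, provenance = list()) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  structure(list(mask = mask, spacing = check_spacing(spacing),
                 provenance = provenance),
            class = "binary_volume")
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("binary_volume: %d x %d x %d (z,y,x), %d foreground voxels\n",
              d[1L], d[2L], d[3L], sum(x$mask)))
  if (!is.null(x$provenance$threshold))
    cat(sprintf("  provenance: %s threshold = %g (sigma = %g)\n",
                x$provenance$method %||% "?", x$provenance$threshold,
                x$provenance$sigma %||% 0))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-cell analysis mask (blurred-sum Otsu)
#'
#' Builds the voxel population over which co-localisation statistics are
#' computed: the fluorescence channels are summed per voxel, smoothed with a
#' Gaussian (sigma = 5 pixels by default, per z-slice), and thresholded by
#' Otsu's method. Summing green + red keeps the mask stable when the red
#' marker is delocalised to the cytosol.
#'
#' @param stack an [image_stack] with >= 1 fluorescence channel.
#' @param sigma blur standard deviation in pixels (default 5; 0 = no blur).
#' @param mode blur mode, `"2d"` per slice (default) or `"3d"`.
#' @param channels channels to sum; defaults to the first two (green + red),
#'   or the single channel of a one-channel stack.
#' @return A [binary_volume] whose provenance records method, sigma and the
#'   threshold value.
#' @export
cell_mask <- function(stack, sigma = 5, mode = c("2d", "3d"), channels = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  mode <- match.arg(mode)
  nc <- dim(stack$voxels)[1L]
  if (is.null(channels))
    channels <- stack$channel_names[seq_len(min(2L, nc))]
  summed <- Reduce(`+`, lapply(channels, function(ch) get_channel(stack, ch)))
  blurred <- gaussian_blur(summed, sigma, mode = mode, spacing = stack$spacing)
  thr <- otsu_threshold(blurred)
  binary_volume(blurred > thr, stack$spacing,
                provenance = list(method = "otsu", sigma = sigma, mode = mode,
                                  channels = channels, threshold = thr))
}

#' Write a binary mask as an 8-bit TIFF
#'
#' @param mask a [binary_volume].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_volume"))
  d <- dim(mask$mask)
  pages <- lapply(seq_len(d[1L]), function(z)
    matrix(as.numeric(mask$mask[z, , ]), d[2L], d[3L]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}
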