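# Membrane-potential readout: per-cell co-localisation of the
# potential-independent (green) and potential-dependent (red) markers.

#' Pearson correlation of two channels over a mask
#'
#' Standard Pearson correlation of the red and green voxel intensities over
#' the masked voxel population. No background subtraction is applied by
#' default: the correlation floor contributed by background present in both
#' channels is part of the measurement's behaviour.
#'
#' @param green,red 3D numeric arrays of identical dimensions.
#' @param mask a [binary_volume] or 3D logical array selecting the voxels;
#'   `NULL` uses all voxels.
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_cc <- function(green, red, mask = NULL) {
  if (inherits(mask, "binary_volume")) mask <- mask$mask
  if (is.null(mask)) mask <- array(TRUE, dim(green))
  stopifnot(all(dim(green) == dim(red)), all(dim(green) == dim(mask)))
  g <- green[mask]; r <- red[mask]
  if (length(g) < 2L) stop("mask selects fewer than 2 voxels")
  if (stats::var(g) == 0 || stats::var(r) == 0)
    stop("zero intensity variance within the mask")
  stats::cor(g, r)
}

#' Coefficient of determination of the red~green fit
#'
#' R-squared of the least-squares linear regression of red on green over the
#' masked voxels; for a single predictor this equals the squared Pearson
#' correlation.
#'
#' @inheritParams pearson_cc
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(green, red, mask = NULL) {
  pearson_cc(green, red, mask)^2
}

saturation_fraction <- function(x) {
  caps <- c(255, 4095, 65535)
  mx <- max(x)
  if (any(abs(mx - caps) < 0.5)) mean(x >= mx) else 0
}

#' Per-cell co-localisation over a set of ROIs
#'
#' Crops each cell, builds the analysis mask (Gaussian-blurred channel sum +
#' Otsu, or the whole cropped cell), and computes the Pearson correlation and
#' R-squared of the two markers. Cells violating preconditions (e.g. constant
#' intensities) are reported with an error flag rather than dropped.
#'
#' @param stack an [image_stack] with green and red channels.
#' @param rois list of [cell_roi].
#' @param sigma mask blur in pixels (default 5).
#' @param mask_mode `"otsu"` (blurred-sum Otsu mask, default) or `"all"`
#'   (every voxel of the cropped cell).
#' @param green,red channel names.
#' @return Data frame with one row per ROI: `cell_label`, `pcc`, `r2`,
#'   `n_voxels`, `mask_sigma`, `mask_threshold`, `saturated`, `error`.
#' @export
batch_coloc <- function(stack, rois, sigma = 5,
                        mask_mode = c("otsu", "all"),
                        green = "gfp", red = "mcherry") {
  stopifnot(inherits(stack, "image_stack"))
  mask_mode <- match.arg(mask_mode)
  if (!all(c(green, red) %in% stack$channel_names))
    stop("stack lacks the '", green, "' and/or '", red, "' channel")
  if (length(rois) == 0L)
    return(data.frame(cell_label = character(), pcc = numeric(),
                      r2 = numeric(), n_voxels = integer(),
                      mask_sigma = numeric(), mask_threshold = numeric(),
                      saturated = logical(), error = character()))
  rows <- lapply(rois, function(roi) {
    out <- data.frame(cell_label = roi$label, pcc = NA_real_, r2 = NA_real_,
                      n_voxels = NA_integer_, mask_sigma = sigma,
                      mask_threshold = NA_real_, saturated = FALSE,
                      error = NA_character_)
    tryCatch({
      cell <- crop_cell(stack, roi)
      g <- get_channel(cell, green)
      r <- get_channel(cell, red)
      if (mask_mode == "otsu") {
        m <- cell_mask(cell, sigma = sigma, channels = c(green, red))
        out$mask_threshold <- m$provenance$threshold
        msk <- m$mask
      } else {
        msk <- array(TRUE, dim(g))
      }
      out$pcc <- pearson_cc(g, r, msk)
      out$r2 <- out$pcc^2
      out$n_voxels <- sum(msk)
      out$saturated <- saturation_fraction(g) > 0.01 ||
        saturation_fraction(r) > 0.01
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  do.call(rbind, rows)
}

#' Group summary of co-localisation results
#'
#' @param coloc data frame from [batch_coloc()].
#' @return List with `mean_pcc`, `sem_pcc` (`NA` below 2 cells), `n` (cells
#'   with a valid PCC) and `n_failed`.
#' @export
coloc_group_summary <- function(coloc) {
  ok <- !is.na(coloc$pcc)
  p <- coloc$pcc[ok]
  list(mean_pcc = if (any(ok)) mean(p) else NA_real_,
       sem_pcc = if (sum(ok) >= 2L) stats::sd(p) / sqrt(length(p)) else NA_real_,
       n = sum(ok),
       n_failed = sum(!ok))
}

#' Minimum cells per group to detect a PCC difference
#'
#' Given per-cell PCC values from two conditions, estimates the smallest
#' per-group sample size at which a two-sample t-test reaches the requested
#' power at the observed effect size (pooled-SD Cohen's d). The default
#' method uses the normal approximation
#' `n = 2 * ((z_{1-alpha/2} + z_{power}) / d)^2`; `method = "exact"` searches
#' the noncentral-t power curve via [stats::power.t.test()].
#'
#' @param pcc_a,pcc_b numeric vectors of per-cell PCCs (>= 2 values each).
#' @param alpha two-sided significance level.
#' @param power requested power.
#' @param method `"normal"` (default) or `"exact"`.
#' @return Smallest per-group n (at least 2); `Inf` for a zero effect size.
#' @export
min_cells_power <- function(pcc_a, pcc_b, alpha = 0.05, power = 0.8,
                            method = c("normal", "exact")) {
  method <- match.arg(method)
  stopifnot(length(pcc_a) >= 2L, length(pcc_b) >= 2L)
  n1 <- length(pcc_a); n2 <- length(pcc_b)
  sp2 <- ((n1 - 1) * stats::var(pcc_a) + (n2 - 1) * stats::var(pcc_b)) /
    (n1 + n2 - 2)
  if (sp2 == 0) stop("zero pooled standard deviation")
  d <- abs(mean(pcc_a) - mean(pcc_b)) / sqrt(sp2)
  if (d == 0) return(Inf)
  if (method == "normal") {
    n <- 2 * ((stats::qnorm(1 - alpha / 2) + stats::qnorm(power)) / d)^2
    max(2L, as.integer(ceiling(n)))
  } else {
    n <- 2L
    while (stats::power.t.test(n = n, delta = d, sd = 1,
                               sig.level = alpha)$power < power &&
           n < 1e6) n <- n + 1L
    n
  }
}
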