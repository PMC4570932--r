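# Per-cell mitochondrial morphology: object extraction, feature table,
# fragmentation index and population summaries.

#' Exclude small objects
#'
#' Objects with a volume strictly smaller than `min_volume` (default
#' 0.1 um^3) are excluded as likely artefacts; an object exactly at the
#' threshold is retained. Order is preserved.
#'
#' @param objects list of voxel sets (integer `(z, y, x)` matrices).
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres.
#' @param min_volume minimum retained volume in um^3.
#' @return The filtered list.
#' @export
filter_small <- function(objects, spacing, min_volume = 0.1) {
  vv <- prod(check_spacing(spacing))
  keep <- vapply(objects, nrow, integer(1)) * vv >= min_volume
  objects[keep]
}

#' Relative object volumes (Vs)
#'
#' Each object's volume as a percentage of the cell's total mitochondrial
#' volume; the values sum to 100.
#'
#' @param volumes numeric vector of object volumes (any common unit).
#' @return Numeric vector of Vs percentages.
#' @export
relative_volumes <- function(volumes) {
  if (length(volumes) == 0L) stop("no objects")
  tot <- sum(volumes)
  if (tot <= 0) stop("total volume must be > 0")
  100 * volumes / tot
}

#' Fragmentation index f
#'
#' The sum of relative fragment volumes Vs that individually make up at most
#' `threshold` percent (default 20) of the cell's total mitochondrial
#' volume: the percentage of mitochondrial volume held in small fragments.
#'
#' @param vs numeric vector of Vs percentages (summing to 100).
#' @param threshold fragment cutoff in percent; objects with
#'   `Vs <= threshold` count as fragmented.
#' @return f in percent, between 0 and 100.
#' @export
fragmentation_index <- function(vs, threshold = 20) {
  sum(vs[vs <= threshold])
}

#' Surface-area-weighted mean features of a cell
#'
#' Small objects are inherently more compact and spherical; weighting each
#' object's features by its surface area before averaging prevents their
#' over-representation in per-cell means.
#'
#' @param objects data frame of per-object features containing a
#'   `surface_um2` column (as produced by [cell_morphology()]).
#' @param features names of the feature columns to average.
#' @return Named numeric vector of weighted means.
#' @export
weighted_cell_features <- function(objects,
                                   features = c("volume_um3", "surface_um2",
                                                "compactness", "isotropy",
                                                "ipq", "sphericity",
                                                "radius_variance")) {
  stopifnot(is.data.frame(objects), "surface_um2" %in% names(objects))
  w <- objects$surface_um2
  if (any(w <= 0)) stop("all surface areas must be > 0")
  vapply(features, function(f) sum(w * objects[[f]]) / sum(w), numeric(1))
}

object_features_row <- function(voxel_set, spacing, table) {
  n <- nrow(voxel_set)
  vol <- n * prod(spacing)
  surf <- surface_voxels(voxel_set)
  area <- surface_area(voxel_set, spacing, table)
  ctr <- centroid(voxel_set, spacing)
  data.frame(
    n_voxels = n,
    volume_um3 = vol,
    surface_um2 = area,
    centroid_z_um = ctr[1L], centroid_y_um = ctr[2L], centroid_x_um = ctr[3L],
    compactness = compactness(voxel_set, spacing),
    isotropy = if (n >= 2L) as.numeric(distribution_isotropy(voxel_set, spacing)) else NA_real_,
    ipq = isoperimetric_quotient(vol, area),
    sphericity = sphericity(vol, area),
    radius_variance = radius_variance(voxel_set, spacing, surf))
}

#' Morphological analysis of one cell
#'
#' Runs the per-cell morphology pipeline on a segmented mitochondrial mask:
#' connected-component labelling, exclusion of sub-`min_volume` objects,
#' per-object shape descriptors, relative volumes Vs, the fragmentation
#' index f, and surface-area-weighted mean features.
#'
#' @param mask a [binary_volume] (e.g. Otsu segmentation of the green
#'   channel) or a 3D logical array.
#' @param spacing voxel spacing; taken from `mask` when it is a
#'   [binary_volume].
#' @param min_volume exclusion threshold in um^3 (default 0.1).
#' @param frag_threshold Vs cutoff (percent) for the fragmentation index
#'   (default 20).
#' @param connectivity 26 (default) or 6.
#' @param cell_label identifier carried into the feature table.
#' @return An object of class `cell_morphology`: a list with `objects` (per-
#'   object feature data frame including `vs`), `f`, `weighted_features`,
#'   `total_volume_um3`, `n_excluded` and `spacing`.
#' @export
cell_morphology <- function(mask, spacing = NULL, min_volume = 0.1,
                            frag_threshold = 20, connectivity = 26L,
                            cell_label = "cell") {
  if (inherits(mask, "binary_volume")) {
    spacing <- mask$spacing
    mask <- mask$mask
  }
  spacing <- check_spacing(spacing)
  objs <- label_objects(mask, connectivity)
  kept <- filter_small(objs, spacing, min_volume)
  if (length(kept) == 0L)
    stop("no mitochondrial objects of at least ", min_volume,
         " um^3 in cell '", cell_label, "'")
  table <- surface_class_table()
  rows <- lapply(kept, object_features_row, spacing = spacing, table = table)
  df <- do.call(rbind, rows)
  df <- cbind(data.frame(cell_label = cell_label,
                         object_id = seq_len(nrow(df))), df)
  df$vs <- relative_volumes(df$volume_um3)
  structure(list(
    objects = df,
    f = fragmentation_index(df$vs, frag_threshold),
    weighted_features = weighted_cell_features(df),
    total_volume_um3 = sum(df$volume_um3),
    n_excluded = length(objs) - length(kept),
    spacing = spacing), class = "cell_morphology")
}

#' @export
print.cell_morphology <- function(x, ...) {
  cat(sprintf("cell_morphology: %d object(s), total volume %.3f um^3, f = %.1f%%\n",
              nrow(x$objects), x$total_volume_um3, x$f))
  invisible(x)
}

#' Population summary over cells
#'
#' Aggregates per-cell fragmentation indices (mean and SEM) and pools all
#' objects' relative volumes into a Vs histogram (the population
#' "footprint"): fragment volume summed per Vs bin of width `bin_width`
#' across cells, bins `[0,10), ..., [90,100]`.
#'
#' @param cells list of [cell_morphology] results.
#' @param bin_width Vs bin width in percent (default 10).
#' @return A list with `per_cell_f`, `mean_f`, `sem_f` (`NA` for fewer than
#'   2 cells), `vs_histogram` (named numeric vector of summed Vs per bin)
#'   and `n_cells`.
#' @export
population_summary <- function(cells, bin_width = 10) {
  stopifnot(length(cells) >= 1L)
  f <- vapply(cells, function(c) c$f, numeric(1))
  vs <- unlist(lapply(cells, function(c) c$objects$vs))
  n_bins <- ceiling(100 / bin_width)
  idx <- pmin(floor(vs / bin_width) + 1L, n_bins)  # top bin closed at 100
  hist <- vapply(seq_len(n_bins), function(b) sum(vs[idx == b]), numeric(1))
  names(hist) <- sprintf("[%g,%g%s", bin_width * (seq_len(n_bins) - 1L),
                         bin_width * seq_len(n_bins),
                         c(rep(")", n_bins - 1L), "]"))
  list(per_cell_f = f,
       mean_f = mean(f),
       sem_f = if (length(f) >= 2L) stats::sd(f) / sqrt(length(f)) else NA_real_,
       vs_histogram = hist,
       n_cells = length(f))
}

#' Segment mitochondria from the structural (green) channel
#'
#' Otsu threshold of the raw channel volume; the mask is
#' `intensity > threshold`.
#'
#' @param stack an [image_stack].
#' @param channel channel to segment (default `"gfp"`).
#' @return A [binary_volume].
#' @export
segment_mitochondria <- function(stack, channel = "gfp") {
  v <- get_channel(stack, channel)
  thr <- otsu_threshold(v)
  binary_volume(v > thr, stack$spacing,
                provenance = list(method = "otsu", sigma = 0,
                                  channels = channel, threshold = thr))
}
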