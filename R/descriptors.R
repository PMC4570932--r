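# Shape descriptors of voxelised objects.
#
# All distances are physical: voxel centres at (index - 0.5) * spacing.
# Variances are population variances (divide by n), matching the descriptor
# definitions, which sum squared deviations over all n voxels and divide
# by n.

voxel_centres <- function(voxel_set, spacing) {
  spacing <- check_spacing(spacing)
  sweep(voxel_set - 0.5, 2L, spacing, `*`)
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Centroid of a voxel object
#'
#' @param voxel_set integer matrix of `(z, y, x)` voxel indices.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres.
#' @return Physical centroid `(z, y, x)` in micrometres (arithmetic mean of
#'   voxel-centre coordinates).
#' @export
centroid <- function(voxel_set, spacing) {
  colMeans(voxel_centres(voxel_set, spacing))
}

#' Compactness (tubularity) of a voxel object
#'
#' Population variance of the distances of all object voxels from the
#' centroid, divided by the object volume. Low for near-spherical objects,
#' high for elongated tubes; units 1/um.
#'
#' @inheritParams centroid
#' @return Compactness in 1/um.
#' @export
compactness <- function(voxel_set, spacing) {
  p <- voxel_centres(voxel_set, spacing)
  d <- sqrt(rowSums(sweep(p, 2L, colMeans(p))^2))
  v <- nrow(voxel_set) * prod(check_spacing(spacing))
  pop_var(d) / v
}

#' Distribution isotropy of a voxel object
#'
#' For each principal grid axis the axial distance of every voxel from the
#' axis through the centroid is computed (e.g. for the x axis, from the y and
#' z coordinates); the descriptor is the sum over the three axis pairs of the
#' ratio `max(M_a, M_b) / min(M_a, M_b)` of the population variances of these
#' axial distances. It is >= 3, equal to 3 exactly when all three moments
#' coincide, and minimal for rotationally symmetric objects.
#'
#' @inheritParams centroid
#' @return Dimensionless isotropy >= 3. If any moment is zero (a perfectly
#'   linear object along one grid axis) `Inf` is returned with attribute
#'   `degenerate = TRUE`.
#' @export
distribution_isotropy <- function(voxel_set, spacing) {
  if (nrow(voxel_set) < 2L) stop("isotropy needs at least 2 voxels")
  p <- voxel_centres(voxel_set, spacing)
  q <- sweep(p, 2L, colMeans(p))                  # columns z, y, x
  dz <- sqrt(q[, 2L]^2 + q[, 3L]^2)               # distance from z axis
  dy <- sqrt(q[, 1L]^2 + q[, 3L]^2)
  dx <- sqrt(q[, 1L]^2 + q[, 2L]^2)
  m <- c(x = pop_var(dx), y = pop_var(dy), z = pop_var(dz))
  if (any(m == 0)) {
    out <- Inf
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  ratio <- function(a, b) max(m[a], m[b]) / min(m[a], m[b])
  ratio("x", "y") + ratio("x", "z") + ratio("y", "z")
}

#' Isoperimetric quotient
#'
#' Ratio of the object volume to the volume of a sphere with the same
#' surface area: `V / ((4/3) * pi * (A / (4 * pi))^(3/2))`. Equals 1 for a
#' perfect sphere and is < 1 for any other exact geometry.
#'
#' @param V object volume (um^3), > 0.
#' @param A object surface area (um^2), > 0.
#' @return Dimensionless quotient.
#' @export
isoperimetric_quotient <- function(V, A) {
  if (any(V <= 0) || any(A <= 0)) stop("V and A must be > 0")
  V / ((4 / 3) * pi * (A / (4 * pi))^1.5)
}

#' Sphericity
#'
#' Ratio of the surface area of a sphere with the object's volume to the
#' object's surface area: `pi^(1/3) * (6 V)^(2/3) / A`. Equals 1 for a
#' perfect sphere; satisfies `sphericity^3 == ipq^2` for any (V, A).
#'
#' @inheritParams isoperimetric_quotient
#' @return Dimensionless sphericity.
#' @export
sphericity <- function(V, A) {
  if (any(V <= 0) || any(A <= 0)) stop("V and A must be > 0")
  pi^(1 / 3) * (6 * V)^(2 / 3) / A
}

#' Radius variance
#'
#' Population variance of the distances of the object's surface voxels from
#' the centroid: a measure of how smooth the radial distance to the surface
#' is, approaching 0 for a sphere.
#'
#' @inheritParams centroid
#' @param surface logical vector marking surface voxels along the rows of
#'   `voxel_set`; computed with [surface_voxels()] when omitted.
#' @return Radius variance in um^2.
#' @export
radius_variance <- function(voxel_set, spacing, surface = NULL) {
  pop_var(surface_radii(voxel_set, spacing, surface))
}

#' Mean surface radius
#'
#' Mean distance of the object's surface voxels from the centroid; the
#' natural scale for normalising [radius_variance()] across object sizes.
#'
#' @inheritParams radius_variance
#' @return Mean surface radius in um.
#' @export
mean_surface_radius <- function(voxel_set, spacing, surface = NULL) {
  mean(surface_radii(voxel_set, spacing, surface))
}

surface_radii <- function(voxel_set, spacing, surface = NULL) {
  if (is.null(surface)) surface <- surface_voxels(voxel_set)
  if (!any(surface)) stop("object has no surface voxels")
  p <- voxel_centres(voxel_set, spacing)
  ctr <- colMeans(p)
  sqrt(rowSums(sweep(p[surface, , drop = FALSE], 2L, ctr)^2))
}
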