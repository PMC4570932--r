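# Ground-truthed synthetic dual-channel scenes.
#
# The generator emulates fixed yeast cells imaged in two channels: tubular
# or spherical mitochondrial objects inside an ellipsoidal cell, a green
# channel marking all objects, a red channel whose fraction phi of the
# mitochondrial signal is delocalised uniformly over the cytosol (the
# collapsed-membrane-potential phenotype), PSF blurring, and Poisson +
# Gaussian read noise. Ground truth (pre-blur object voxel sets) is returned
# alongside every stack.

#' Scene primitives
#'
#' `sphere_obj()` is a ball; `tube_obj()` a capsule swept along a polyline
#' (cylinder with hemispherical caps). Coordinates are physical `(z, y, x)`
#' micrometres.
#'
#' @param centre length-3 centre of the sphere.
#' @param radius radius in micrometres, > 0.
#' @return A primitive description used in [scene_spec()].
#' @export
sphere_obj <- function(centre, radius) {
  stopifnot(length(centre) == 3L, radius > 0)
  list(type = "sphere", centre = as.numeric(centre), radius = radius)
}

#' @rdname sphere_obj
#' @param points matrix of polyline vertices, one `(z, y, x)` row each.
#' @export
tube_obj <- function(points, radius) {
  points <- rbind(points)
  stopifnot(ncol(points) == 3L, nrow(points) >= 2L, radius > 0)
  list(type = "tube", points = unname(points), radius = radius)
}

#' Specify a synthetic scene
#'
#' @param dim grid extent `(nz, ny, nx)` in voxels.
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres; the default
#'   emulates super-resolution sampling with 1.6-fold z anisotropy.
#' @param objects list of [sphere_obj()] / [tube_obj()] primitives; all must
#'   lie within the grid.
#' @param phi fraction of the red marker delocalised to the cytosol, in
#'   `[0, 1]`.
#' @param intensities list with `fg` (mitochondrial foreground) and `bg`
#'   (background) expected photon counts.
#' @param noise list with `poisson` (logical, shot noise on expected counts)
#'   and `read_sd` (Gaussian read noise SD; default 2% of `fg`).
#' @param psf_sigma PSF blur SD in in-plane pixels (applied in 3D with the
#'   z sigma scaled by `dx/dz`); 0 disables blurring.
#' @param seed mandatory RNG seed; identical specs produce identical stacks.
#' @return An object of class `scene_spec`.
#' @export
scene_spec <- function(dim = c(24L, 64L, 64L), spacing = c(0.16, 0.1, 0.1),
                       objects, phi = 0,
                       intensities = list(fg = 200, bg = 10),
                       noise = list(poisson = TRUE, read_sd = 4),
                       psf_sigma = 1, seed) {
  if (missing(seed) || is.null(seed)) stop("a `seed` is mandatory")
  spacing <- check_spacing(spacing)
  if (phi < 0 || phi > 1) stop("`phi` must lie in [0, 1]")
  if (length(objects) == 0L) stop("at least one object is required")
  extent <- dim * spacing
  for (ob in objects) {
    pts <- if (ob$type == "sphere") rbind(ob$centre) else ob$points
    if (ob$radius <= 0) stop("all radii must be > 0")
    if (any(sweep(pts, 2L, ob$radius, `-`) < 0) ||
        any(sweep(pts, 2L, extent - ob$radius, `-`) > 0))
      stop("object extends outside the grid")
  }
  structure(list(dim = as.integer(dim), spacing = spacing, objects = objects,
                 phi = phi, intensities = intensities, noise = noise,
                 psf_sigma = psf_sigma, seed = as.integer(seed)),
            class = "scene_spec")
}

# Physical voxel-centre coordinate grids (as 3 arrays of dim (nz,ny,nx)).
coord_grids <- function(dim, spacing) {
  zc <- (seq_len(dim[1L]) - 0.5) * spacing[1L]
  yc <- (seq_len(dim[2L]) - 0.5) * spacing[2L]
  xc <- (seq_len(dim[3L]) - 0.5) * spacing[3L]
  list(z = array(rep(zc, times = dim[2L] * dim[3L]), dim),
       y = array(rep(rep(yc, each = dim[1L]), times = dim[3L]), dim),
       x = array(rep(xc, each = dim[1L] * dim[2L]), dim))
}

# Squared distance of every grid voxel centre to a segment p0-p1.
segment_dist2 <- function(g, p0, p1) {
  v <- p1 - p0
  L2 <- sum(v^2)
  if (L2 == 0) {
    return((g$z - p0[1L])^2 + (g$y - p0[2L])^2 + (g$x - p0[3L])^2)
  }
  t <- ((g$z - p0[1L]) * v[1L] + (g$y - p0[2L]) * v[2L] +
          (g$x - p0[3L]) * v[3L]) / L2
  t <- pmin(pmax(t, 0), 1)
  (g$z - (p0[1L] + t * v[1L]))^2 + (g$y - (p0[2L] + t * v[2L]))^2 +
    (g$x - (p0[3L] + t * v[3L]))^2
}

rasterise_objects <- function(spec, g) {
  m <- array(FALSE, spec$dim)
  for (ob in spec$objects) {
    if (ob$type == "sphere") {
      m <- m | (segment_dist2(g, ob$centre, ob$centre) <= ob$radius^2)
    } else {
      for (i in seq_len(nrow(ob$points) - 1L))
        m <- m | (segment_dist2(g, ob$points[i, ], ob$points[i + 1L, ]) <=
                    ob$radius^2)
    }
  }
  m
}

# Ellipsoidal cytosol region centred in the grid, spanning 92% of each
# half-extent.
cytosol_mask <- function(dim, spacing, g) {
  ctr <- dim * spacing / 2
  semi <- 0.46 * dim * spacing
  ((g$z - ctr[1L]) / semi[1L])^2 + ((g$y - ctr[2L]) / semi[2L])^2 +
    ((g$x - ctr[3L]) / semi[3L])^2 <= 1
}

#' Rasterise a synthetic scene
#'
#' Builds the two-channel stack: green = foreground on the objects plus
#' background; red = `(1 - phi)` of the mitochondrial signal on the objects
#' plus the delocalised fraction `phi` spread uniformly over the cytosol
#' (total red signal is conserved). Both channels are then PSF-blurred and
#' noise is applied. Overlapping objects merge; the ground truth reflects
#' the merged components.
#'
#' @param spec a [scene_spec].
#' @return List with `stack` (an [image_stack], channels `gfp`, `mcherry`),
#'   `ground_truth` (list of pre-blur object voxel sets, 26-connected
#'   components), `object_mask` and `cytosol` (logical arrays).
#' @export
rasterise_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  g <- coord_grids(spec$dim, spec$spacing)
  obj <- rasterise_objects(spec, g)
  cyt <- cytosol_mask(spec$dim, spec$spacing, g) | obj
  fg <- spec$intensities$fg; bg <- spec$intensities$bg
  green <- bg + fg * obj
  red <- bg + (1 - spec$phi) * fg * obj
  n_obj <- sum(obj)
  if (spec$phi > 0 && n_obj > 0)
    red <- red + spec$phi * fg * (n_obj / sum(cyt)) * cyt
  if (spec$psf_sigma > 0) {
    green <- gaussian_blur(green, spec$psf_sigma, mode = "3d",
                           spacing = spec$spacing)
    red <- gaussian_blur(red, spec$psf_sigma, mode = "3d",
                         spacing = spec$spacing)
  }
  withr::with_seed(spec$seed, {
    if (isTRUE(spec$noise$poisson)) {
      green <- array(stats::rpois(length(green), green), dim(green))
      red <- array(stats::rpois(length(red), red), dim(red))
    }
    sd <- spec$noise$read_sd %||% 0
    if (sd > 0) {
      green <- green + stats::rnorm(length(green), sd = sd)
      red <- red + stats::rnorm(length(red), sd = sd)
    }
  })
  green <- pmax(green, 0); red <- pmax(red, 0)
  v <- array(0, c(2L, spec$dim))
  v[1L, , , ] <- green; v[2L, , , ] <- red
  list(stack = image_stack(v, spec$spacing, c("gfp", "mcherry")),
       ground_truth = label_objects(obj, 26L),
       object_mask = obj, cytosol = cyt)
}

# Minimum distance between two segments (for overlap rejection).
seg_seg_dist <- function(p0, p1, q0, q1) {
  u <- p1 - p0; v <- q1 - q0; w <- p0 - q0
  a <- sum(u * u); b <- sum(u * v); c <- sum(v * v)
  d <- sum(u * w); e <- sum(v * w)
  D <- a * c - b * b
  if (D < 1e-12) { s <- 0 } else s <- min(max((b * e - c * d) / D, 0), 1)
  t <- if (c < 1e-12) 0 else min(max((b * s + e) / c, 0), 1)
  s <- if (a < 1e-12) 0 else min(max((b * t - d) / a, 0), 1)
  sqrt(sum((p0 + s * u - (q0 + t * v))^2))
}

obj_segments <- function(ob) {
  if (ob$type == "sphere") list(rbind(ob$centre, ob$centre))
  else lapply(seq_len(nrow(ob$points) - 1L),
              function(i) ob$points[i:(i + 1L), , drop = FALSE])
}

objects_clear <- function(ob, placed, gap) {
  for (other in placed)
    for (s1 in obj_segments(ob))
      for (s2 in obj_segments(other))
        if (seg_seg_dist(s1[1L, ], s1[2L, ], s2[1L, ], s2[2L, ]) <
            ob$radius + other$radius + gap) return(FALSE)
  TRUE
}

# Sample a point uniformly inside the scaled cytosol ellipsoid, keeping a
# (possibly per-axis) physical margin from its surface.
sample_in_cell <- function(dim, spacing, margin) {
  ctr <- dim * spacing / 2
  semi <- pmax(0.46 * dim * spacing - margin, 0.05)
  repeat {
    u <- stats::runif(3L, -1, 1)
    if (sum(u^2) <= 1) return(ctr + u * semi)
  }
}

# Random tube orientation, mostly in-plane: the z component is capped so
# long tubules fit the flat cell geometry.
tube_direction <- function(max_tilt = 0.3) {
  dir <- stats::rnorm(3L)
  dir <- dir / sqrt(sum(dir^2))
  if (abs(dir[1L]) > max_tilt) {
    lat <- dir[2:3] / sqrt(sum(dir[2:3]^2))
    dir <- c(sign(dir[1L]) * max_tilt, lat * sqrt(1 - max_tilt^2))
  }
  dir
}

# Partition 100% into a Vs design achieving fragmentation index `target_f`
# exactly, with every fragment's Vs kept well below the 20% cutoff and the
# non-fragment remainder well above it.
design_vs <- function(target_f) {
  if (target_f < 0 || target_f > 100) stop("target_f must lie in [0, 100]")
  if (target_f == 0) return(100)
  if (target_f == 100) {
    k <- ceiling(100 / 16)
    return(rep(100 / k, k))
  }
  big <- 100 - target_f
  if (big <= 24)
    stop("infeasible target_f = ", target_f,
         ": the non-fragmented remainder (", big,
         "%) would itself count as a fragment")
  k <- ceiling(target_f / 16)
  if (target_f / k < 4) k <- max(1L, floor(target_f / 8))
  c(big, rep(target_f / k, k))
}

make_cell_objects <- function(vs, style, total_volume, dim, spacing, gap) {
  vols <- vs / 100 * total_volume
  placed <- list()
  for (v in sort(vols, decreasing = TRUE)) {
    ob <- NULL
    for (attempt in 1:400) {
      if (style == "spherical") {
        r <- (3 * v / (4 * pi))^(1 / 3)
        ctr <- sample_in_cell(dim, spacing, r + 0.05)
        cand <- sphere_obj(ctr, r)
      } else {
        # capsule with aspect ratio ~6: v = pi r^2 L + 4/3 pi r^3, L = 12 r;
        # tubes longer than the cell are thickened to fit
        r <- (v / (12 * pi + 4 * pi / 3))^(1 / 3)
        L <- (v - 4 / 3 * pi * r^3) / (pi * r^2)
        L_max <- 1.4 * 0.46 * min((dim * spacing)[2:3])
        if (L > L_max) {
          L <- L_max
          r <- stats::uniroot(function(r) pi * r^2 * L + 4 / 3 * pi * r^3 - v,
                              c(1e-3, 3))$root
        }
        ctr <- sample_in_cell(dim, spacing, r + 0.05)
        dir <- tube_direction(0.3)
        p0 <- ctr - dir * L / 2; p1 <- ctr + dir * L / 2
        # both endpoints must stay inside the cell with a radius margin
        semi <- pmax(0.46 * dim * spacing - (r + 0.05), 0.05)
        cc <- dim * spacing / 2
        inside <- function(p) sum(((p - cc) / semi)^2) <= 1
        if (!inside(p0) || !inside(p1)) next
        cand <- tube_obj(rbind(p0, p1), r)
      }
      if (objects_clear(cand, placed, gap)) { ob <- cand; break }
    }
    if (is.null(ob))
      stop("could not place a ", style, " object of ", signif(v, 3),
           " um^3 without overlap; reduce total_volume or fragment count")
    placed <- c(placed, list(ob))
  }
  placed
}

#' Generate a fragmentation series of synthetic cells
#'
#' Builds `n_cells` ground-truthed scenes whose designed relative-volume
#' lists give a per-cell fragmentation index of exactly `target_f`:
#' fragment volumes are chosen analytically before rasterisation, then
#' realised as non-overlapping spheres (`style = "spherical"`, the oxidative
#' stress-like phenotype) or elongated capsules (`style = "tubular"`, the
#' mtDNA-loss-like phenotype) placed at seeded random positions.
#'
#' @param style fragment shape, `"spherical"` or `"tubular"`.
#' @param target_f designed fragmentation index in percent. Targets whose
#'   non-fragmented remainder would itself fall at or below the 20% cutoff
#'   (e.g. 90) are infeasible and raise an error.
#' @param n_cells number of cells (default 30, the population size used for
#'   footprint estimates).
#' @param seed base RNG seed; cell i uses `seed + i`.
#' @param total_volume total mitochondrial volume per cell in um^3.
#' @param dim,spacing grid geometry passed to [scene_spec()].
#' @param phi red delocalised fraction passed through to the scenes.
#' @return List of length `n_cells`; each element has `spec`, `scene` (the
#'   [rasterise_scene()] output), `expected_f` and `designed_vs`.
#' @export
make_fragmentation_series <- function(style = c("spherical", "tubular"),
                                      target_f, n_cells = 30L, seed,
                                      total_volume = 3,
                                      dim = c(24L, 64L, 64L),
                                      spacing = c(0.16, 0.1, 0.1),
                                      phi = 0) {
  style <- match.arg(style)
  if (missing(seed)) stop("a `seed` is mandatory")
  vs <- design_vs(target_f)
  lapply(seq_len(n_cells), function(i) {
    objs <- withr::with_seed(seed + i, {
      make_cell_objects(vs, style, total_volume, dim, spacing, gap = 0.35)
    })
    spec <- scene_spec(dim = dim, spacing = spacing, objects = objs,
                       phi = phi, seed = seed + i)
    list(spec = spec, scene = rasterise_scene(spec),
         expected_f = target_f, designed_vs = vs)
  })
}

#' Generate a red-marker delocalisation series
#'
#' One fixed cell geometry imaged at a series of delocalised fractions
#' `phi`: the ground truth for the contract that the per-cell Pearson
#' correlation decreases as the membrane potential collapses.
#'
#' @param phis increasing vector of delocalised fractions in `[0, 1]`.
#' @param seed base RNG seed (geometry uses `seed`; the scene at `phis[i]`
#'   uses `seed + i` for noise).
#' @param n_tubes number of mitochondrial tubules in the cell.
#' @param dim,spacing grid geometry.
#' @return List parallel to `phis`; each element has `phi`, `spec` and
#'   `scene`.
#' @export
delocalisation_series <- function(phis = c(0, 0.25, 0.5, 0.75, 1), seed,
                                  n_tubes = 4L,
                                  dim = c(24L, 64L, 64L),
                                  spacing = c(0.16, 0.1, 0.1)) {
  if (missing(seed)) stop("a `seed` is mandatory")
  objs <- withr::with_seed(seed, {
    make_cell_objects(rep(100 / n_tubes, n_tubes), "tubular",
                      total_volume = 2.4, dim, spacing, gap = 0.3)
  })
  lapply(seq_along(phis), function(i) {
    spec <- scene_spec(dim = dim, spacing = spacing, objects = objs,
                       phi = phis[i], seed = seed + i)
    list(phi = phis[i], spec = spec, scene = rasterise_scene(spec))
  })
}
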