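# 3D connected-component labelling of binary volumes.

# The 13 "positive" neighbour offsets of 26-connectivity (each unordered
# voxel pair is visited once); the first 3 rows are the 6-connectivity face
# neighbours.
neighbour_offsets <- function(connectivity) {
  face <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  if (connectivity == 6L) return(face)
  all <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  keep <- all[, 1L] > 0L |
    (all[, 1L] == 0L & all[, 2L] > 0L) |
    (all[, 1L] == 0L & all[, 2L] == 0L & all[, 3L] > 0L)
  unname(all[keep, , drop = FALSE])
}

#' Label connected mitochondrial objects
#'
#' Partitions the foreground of a binary volume into maximal connected
#' components. 26-connectivity is the default: thin tubules sampled at coarse
#' z-spacing stay connected through voxel corners, where 6-connectivity would
#' fragment them.
#'
#' @param mask a [binary_volume] or a 3D logical array `(z, y, x)`.
#' @param connectivity 26 (faces, edges, corners) or 6 (faces only).
#' @return A list of voxel sets, each an integer matrix with columns
#'   `z, y, x` (1-based indices), ordered by first-occurrence in array order.
#'   An empty mask yields an empty list.
#' @export
label_objects <- function(mask, connectivity = 26L) {
  if (inherits(mask, "binary_volume")) mask <- mask$mask
  stopifnot(is.array(mask), length(dim(mask)) == 3L, is.logical(mask))
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(6L, 26L)) stop("connectivity must be 6 or 26")
  d <- dim(mask)
  fg <- which(mask)
  if (length(fg) == 0L) return(list())
  vid <- integer(prod(d))            # linear index -> vertex id
  vid[fg] <- seq_along(fg)
  offs <- neighbour_offsets(connectivity)
  edges <- vector("list", nrow(offs))
  lin <- array(seq_len(prod(d)), d)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    z1 <- seq_len(d[1L] - abs(o[1L])); z2 <- z1 + abs(o[1L])
    if (o[1L] < 0L) { tmp <- z1; z1 <- z2; z2 <- tmp }
    y1 <- seq_len(d[2L] - abs(o[2L])); y2 <- y1 + abs(o[2L])
    if (o[2L] < 0L) { tmp <- y1; y1 <- y2; y2 <- tmp }
    x1 <- seq_len(d[3L] - abs(o[3L])); x2 <- x1 + abs(o[3L])
    if (o[3L] < 0L) { tmp <- x1; x1 <- x2; x2 <- tmp }
    both <- mask[z1, y1, x1, drop = FALSE] & mask[z2, y2, x2, drop = FALSE]
    if (any(both)) {
      from <- lin[z1, y1, x1, drop = FALSE][both]
      to <- lin[z2, y2, x2, drop = FALSE][both]
      edges[[i]] <- cbind(vid[from], vid[to])
    }
  }
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  coords <- arrayInd(fg, d)
  colnames(coords) <- c("z", "y", "x")
  sets <- split.data.frame(coords, memb)
  # deterministic order: by smallest linear index of each component
  firsts <- vapply(split(fg, memb), min, numeric(1))
  sets <- sets[order(firsts)]
  lapply(unname(sets), function(m) {
    m <- as.matrix(m); storage.mode(m) <- "integer"; m
  })
}
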