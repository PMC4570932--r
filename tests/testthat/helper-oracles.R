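# Independent oracles and small fixture builders used across the suite.

# Exhaustive-scan Otsu oracle: same 256-bin histogram contract, but the
# between-class variance is computed from scratch for every candidate split
# (no shared code with otsu_threshold beyond the bin definition).
otsu_oracle <- function(v, n_bins = 256L) {
  v <- as.numeric(v)
  edges <- seq(min(v), max(v), length.out = n_bins + 1L)
  bin <- findInterval(v, edges, rightmost.closed = TRUE)
  bin[bin < 1L] <- 1L; bin[bin > n_bins] <- n_bins
  mids <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  counts <- vapply(seq_len(n_bins), function(k) sum(bin == k), numeric(1))
  best_k <- NA_integer_; best_v <- -Inf
  for (k in seq_len(n_bins - 1L)) {
    n0 <- sum(counts[1:k]); n1 <- sum(counts[(k + 1L):n_bins])
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(counts[1:k] * mids[1:k]) / n0
    mu1 <- sum(counts[(k + 1L):n_bins] * mids[(k + 1L):n_bins]) / n1
    bcv <- (n0 / length(v)) * (n1 / length(v)) * (mu0 - mu1)^2
    if (bcv > best_v + 1e-15) { best_v <- bcv; best_k <- k }
  }
  edges[best_k + 1L]
}

# Queue-based BFS flood fill, the independent connected-components oracle.
flood_fill_oracle <- function(mask, connectivity) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  if (connectivity == 6L) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  labels <- array(0L, d)
  nxt <- 0L
  for (start in which(mask & labels == 0L)) {
    if (labels[start] != 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(start, d)[1, ])
    labels[start] <- nxt
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (i in seq_len(nrow(offs))) {
        q <- p + offs[i, ]
        if (any(q < 1L) || any(q > d)) next
        if (mask[q[1L], q[2L], q[3L]] && labels[q[1L], q[2L], q[3L]] == 0L) {
          labels[q[1L], q[2L], q[3L]] <- nxt
          queue[[length(queue) + 1L]] <- q
        }
      }
    }
  }
  labels
}

# Partition of foreground voxels as a canonical set of sorted index strings,
# for comparing two labellings irrespective of label order.
component_signature <- function(sets) {
  sort(vapply(sets, function(m) {
    m <- m[order(m[, 1L], m[, 2L], m[, 3L]), , drop = FALSE]
    paste(apply(m, 1L, paste, collapse = ","), collapse = ";")
  }, character(1)))
}

labels_to_sets <- function(labels) {
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  lapply(ids, function(i) {
    m <- arrayInd(which(labels == i), dim(labels))
    colnames(m) <- c("z", "y", "x")
    storage.mode(m) <- "integer"
    m
  })
}

# Small voxel-set builders.
voxel_cube <- function(n, origin = c(1L, 1L, 1L)) {
  m <- as.matrix(expand.grid(z = seq_len(n), y = seq_len(n), x = seq_len(n)))
  m <- sweep(m, 2L, as.integer(origin) - 1L, `+`)
  storage.mode(m) <- "integer"
  colnames(m) <- c("z", "y", "x")
  m
}

voxel_rod <- function(n, axis = 3L) {
  m <- matrix(1L, n, 3L)
  m[, axis] <- seq_len(n)
  colnames(m) <- c("z", "y", "x")
  m
}

random_mask <- function(dims, p) {
  array(stats::runif(prod(dims)) < p, dims)
}

# A quiet two-channel test stack: one bright ball on a dark background.
ball_stack <- function(dim = c(10L, 32L, 32L), spacing = c(0.16, 0.1, 0.1),
                      radius = 0.8, fg = 200, bg = 10) {
  ctr <- dim * spacing / 2
  zc <- (seq_len(dim[1L]) - 0.5) * spacing[1L]
  yc <- (seq_len(dim[2L]) - 0.5) * spacing[2L]
  xc <- (seq_len(dim[3L]) - 0.5) * spacing[3L]
  d2 <- outer(outer((zc - ctr[1L])^2, (yc - ctr[2L])^2, `+`),
              (xc - ctr[3L])^2, `+`)
  ball <- d2 <= radius^2
  v <- array(bg, c(2L, dim))
  v[1L, , , ][ball] <- fg
  v[2L, , , ][ball] <- fg
  image_stack(v, spacing, c("gfp", "mcherry"))
}
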