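# Run-level workflows: configuration, report assembly and provenance.

#' Run configuration
#'
#' Bundles the tunable analysis parameters with their standard defaults:
#' mask blur sigma 5 px, minimum object volume 0.1 um^3, fragment cutoff
#' Vs <= 20%, Vs bin width 10, 26-connectivity. The resolved configuration
#' is serialised next to every output for provenance.
#'
#' @param spacing voxel spacing `(dz, dy, dx)` in micrometres.
#' @param channels named channel map (`green`, `red`).
#' @param sigma_mask co-localisation mask blur (pixels).
#' @param min_volume object exclusion threshold (um^3).
#' @param frag_threshold Vs fragmentation cutoff (percent).
#' @param vs_bin_width Vs histogram bin width (percent).
#' @param connectivity 26 or 6.
#' @param seed RNG seed for simulation runs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(spacing = c(0.16, 0.1, 0.1),
                       channels = c(green = "gfp", red = "mcherry"),
                       sigma_mask = 5, min_volume = 0.1, frag_threshold = 20,
                       vs_bin_width = 10, connectivity = 26L, seed = 1L) {
  structure(list(spacing = check_spacing(spacing), channels = channels,
                 sigma_mask = sigma_mask, min_volume = min_volume,
                 frag_threshold = frag_threshold,
                 vs_bin_width = vs_bin_width,
                 connectivity = as.integer(connectivity),
                 seed = as.integer(seed)),
            class = "run_config")
}

write_config <- function(config, dir) {
  jsonlite::write_json(unclass(config), file.path(dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

log_stage <- function(...) message(sprintf(...))

#' Morphology workflow over a set of cells
#'
#' For each ROI of each stack: crop, segment the green channel (Otsu), run
#' [cell_morphology()], and assemble per-object and per-cell tables plus the
#' population summary. Per-cell failures are logged and flagged; the run
#' continues.
#'
#' @param stacks an [image_stack] or list of them (one per field of view).
#' @param rois list of ROI lists parallel to `stacks` (or a single ROI list).
#' @param config a [run_config].
#' @param out_dir output directory; created if needed. `NULL` skips writing.
#' @return List with `objects` and `cells` data frames, `population`
#'   summary, and `failed` (labels of cells that raised errors). CSV/JSON
#'   outputs and the resolved config are written to `out_dir`.
#' @export
run_morphology <- function(stacks, rois, config = run_config(),
                           out_dir = NULL) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  if (length(rois) > 0L && inherits(rois[[1L]], "cell_roi"))
    rois <- list(rois)
  stopifnot(length(stacks) == length(rois))
  green <- config$channels[["green"]]
  cells <- list(); failed <- character()
  for (i in seq_along(stacks)) {
    for (roi in rois[[i]]) {
      res <- tryCatch({
        cell <- crop_cell(stacks[[i]], roi)
        mask <- segment_mitochondria(cell, green)
        cell_morphology(mask, min_volume = config$min_volume,
                        frag_threshold = config$frag_threshold,
                        connectivity = config$connectivity,
                        cell_label = roi$label)
      }, error = function(e) {
        log_stage("morph: cell '%s' failed: %s", roi$label,
                  conditionMessage(e))
        NULL
      })
      if (is.null(res)) failed <- c(failed, roi$label)
      else cells[[roi$label]] <- res
    }
  }
  log_stage("morph: %d cell(s) analysed, %d failed", length(cells),
            length(failed))
  if (length(cells) == 0L) stop("no cell could be analysed")
  objects <- do.call(rbind, c(lapply(cells, function(cm) cm$objects),
                              make.row.names = FALSE))
  cell_rows <- lapply(cells, function(cm) {
    wf <- as.list(cm$weighted_features)
    names(wf) <- paste0("w_", names(wf))
    cbind(data.frame(cell_label = cm$objects$cell_label[1L],
                     n_objects = nrow(cm$objects),
                     total_volume_um3 = cm$total_volume_um3,
                     f = cm$f, n_excluded = cm$n_excluded),
          as.data.frame(wf))
  })
  cell_df <- do.call(rbind, c(cell_rows, make.row.names = FALSE))
  pop <- population_summary(unname(cells), bin_width = config$vs_bin_width)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(objects, file.path(out_dir, "objects.csv"),
                     row.names = FALSE)
    utils::write.csv(cell_df, file.path(out_dir, "cells.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      c(pop[c("mean_f", "sem_f", "n_cells")],
        list(vs_histogram = as.list(pop$vs_histogram),
             per_cell_f = pop$per_cell_f, failed = failed)),
      file.path(out_dir, "population.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
    write_config(config, out_dir)
  }
  list(objects = objects, cells = cell_df, population = pop, failed = failed)
}

#' Co-localisation workflow over a set of cells
#'
#' Runs [batch_coloc()] per stack and assembles the per-cell table and the
#' group summary (mean PCC +/- SEM).
#'
#' @inheritParams run_morphology
#' @return List with `cells` (per-cell data frame) and `summary`. Outputs
#'   and the resolved config are written to `out_dir` when given.
#' @export
run_coloc <- function(stacks, rois, config = run_config(), out_dir = NULL) {
  if (inherits(stacks, "image_stack")) stacks <- list(stacks)
  if (length(rois) > 0L && inherits(rois[[1L]], "cell_roi"))
    rois <- list(rois)
  stopifnot(length(stacks) == length(rois))
  for (s in stacks)
    if (!all(config$channels %in% s$channel_names))
      stop("stack lacks required channels (",
           paste(config$channels, collapse = ", "), ")")
  tabs <- lapply(seq_along(stacks), function(i)
    batch_coloc(stacks[[i]], rois[[i]], sigma = config$sigma_mask,
                green = config$channels[["green"]],
                red = config$channels[["red"]]))
  cells <- do.call(rbind, c(tabs, make.row.names = FALSE))
  smry <- coloc_group_summary(cells)
  log_stage("coloc: %d cell(s), mean PCC = %.3f (%d failed)", smry$n,
            smry$mean_pcc, smry$n_failed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(cells, file.path(out_dir, "coloc_cells.csv"),
                     row.names = FALSE)
    jsonlite::write_json(smry, file.path(out_dir, "coloc_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    write_config(config, out_dir)
  }
  list(cells = cells, summary = smry)
}

#' Simulation workflow
#'
#' Rasterises a scene and writes the stack (16-bit TIFF), the ground truth
#' (run-length-encoded object voxel lists, JSON), a full-extent ROI sidecar
#' and the scene parameters to `out_dir`. Identical specs produce
#' byte-identical outputs.
#'
#' @param spec a [scene_spec] or the path of a scene JSON file (fields as in
#'   [scene_spec()]; objects with `type`, `radius` and `centre`/`points`).
#' @param out_dir output directory.
#' @return The [rasterise_scene()] result, invisibly.
#' @export
run_simulate <- function(spec, out_dir) {
  if (is.character(spec)) spec <- read_scene_spec(spec)
  stopifnot(inherits(spec, "scene_spec"))
  scene <- rasterise_scene(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(scene$stack, file.path(out_dir, "scene.tif"))
  d <- spec$dim
  write_rois(list(cell_roi("cell_1", c(0L, 0L, 0L), d)),
             file.path(out_dir, "rois.csv"))
  gt <- lapply(scene$ground_truth, function(vs)
    rle_encode(sort(vs[, 1L] + d[1L] * (vs[, 2L] - 1L) +
                      d[1L] * d[2L] * (vs[, 3L] - 1L))))
  jsonlite::write_json(
    list(dim = d, spacing = unname(spec$spacing), phi = spec$phi,
         seed = spec$seed, objects_rle = gt),
    file.path(out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(scene_spec_to_list(spec),
                       file.path(out_dir, "scene_spec.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(scene)
}

rle_encode <- function(idx) {
  if (length(idx) == 0L) return(list(start = integer(), length = integer()))
  breaks <- c(TRUE, diff(idx) != 1L)
  start <- idx[breaks]
  len <- diff(c(which(breaks), length(idx) + 1L))
  list(start = start, length = len)
}

scene_spec_to_list <- function(spec) {
  lst <- unclass(spec)
  lst$spacing <- unname(lst$spacing)
  lst$objects <- lapply(lst$objects, function(ob) {
    if (ob$type == "tube") ob$points <- apply(ob$points, 1L, c, simplify = FALSE)
    ob
  })
  lst
}

#' Read a scene specification from JSON
#'
#' @param path JSON file written by [run_simulate()] or hand-authored with
#'   the [scene_spec()] fields.
#' @return A [scene_spec]. Malformed specifications raise an error naming
#'   the offending field.
#' @export
read_scene_spec <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (field in c("dim", "spacing", "objects", "seed"))
    if (is.null(lst[[field]])) stop("scene spec is missing field '", field, "'")
  objects <- lapply(lst$objects, function(ob) {
    if (is.null(ob$type) || !ob$type %in% c("sphere", "tube"))
      stop("scene spec object field 'type' must be \"sphere\" or \"tube\"")
    if (is.null(ob$radius)) stop("scene spec object is missing field 'radius'")
    if (ob$type == "sphere") {
      if (is.null(ob$centre)) stop("sphere object is missing field 'centre'")
      sphere_obj(unlist(ob$centre), ob$radius)
    } else {
      if (is.null(ob$points)) stop("tube object is missing field 'points'")
      pts <- if (is.matrix(ob$points)) ob$points
             else do.call(rbind, lapply(ob$points, unlist))
      tube_obj(pts, ob$radius)
    }
  })
  args <- list(dim = lst$dim, spacing = lst$spacing, objects = objects,
               seed = lst$seed)
  for (opt in c("phi", "intensities", "noise", "psf_sigma"))
    if (!is.null(lst[[opt]])) args[[opt]] <- lst[[opt]]
  do.call(scene_spec, args)
}
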