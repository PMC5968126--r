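# ---- plain-text interchange formats ----

#' Export a voxel grid (with optional LAT map) as legacy VTK structured points
#'
#' Writes tissue labels, conductivities and, if given, the local activation
#' time as point-data arrays of an ASCII `STRUCTURED_POINTS` VTK file.
#'
#' @param grid A [voxel_grid()].
#' @param path Output file.
#' @param lat Optional per-voxel LAT vector.
#' @export
write_grid_vtk <- function(grid, path, lat = NULL) {
  d <- grid$dims
  n <- prod(d)
  lab <- match(grid$region, c("none", "fibroblast",
                              atrial_region_table()$region)) - 2L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "fibrofocal voxel grid", "ASCII",
               "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", grid$spacing, grid$spacing,
                       grid$spacing),
               sprintf("POINT_DATA %d", n),
               "SCALARS label int 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(lab, collapse = " "), con)
  writeLines(c("SCALARS sigma_l float 1", "LOOKUP_TABLE default"), con)
  writeLines(paste(signif(grid$d_l, 6), collapse = " "), con)
  if (!is.null(lat)) {
    writeLines(c("SCALARS lat float 1", "LOOKUP_TABLE default"), con)
    writeLines(paste(signif(ifelse(is.na(lat), -1, lat), 6),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Export the atlas surface as ASCII PLY with named per-vertex scalars
#'
#' @param atlas An `atrial_atlas`.
#' @param path Output file.
#' @param scalars Named list of per-vertex numeric vectors to embed.
#' @export
write_atlas_ply <- function(atlas, path, scalars = list()) {
  nv <- nrow(atlas$verts); nf <- nrow(atlas$faces)
  con <- file(path, "w")
  on.exit(close(con))
  props <- c("property float x", "property float y", "property float z",
             vapply(names(scalars), function(s)
               paste("property float", s), character(1)))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nv), props,
               sprintf("element face %d", nf),
               "property list uchar int vertex_indices", "end_header"), con)
  M <- atlas$verts
  for (s in scalars) M <- cbind(M, s)
  writeLines(apply(signif(M, 7), 1, paste, collapse = " "), con)
  writeLines(apply(atlas$faces - 1L, 1, function(f)
    paste(c(3, f), collapse = " ")), con)
  invisible(path)
}

#' Store a fibrosis model beside its mesh
#'
#' Per-element integer labels as one-column CSV plus a JSON sidecar with
#' case, stage, fraction and seed metadata.
#'
#' @param model A `fibrosis_model`.
#' @param path Base path (`.csv` and `.json` are appended).
#' @export
write_fibrosis_model <- function(model, path) {
  write.csv(data.frame(fibrotic = as.integer(model$element_labels)),
            paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(case_id = model$case_id, stage = model$stage,
         fraction = model$fraction, target = model$target,
         drop_prob = model$drop_prob, rng_seed = model$rng_seed,
         n_seeds = length(model$seeds)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
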