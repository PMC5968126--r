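# cache for stabilized initial states (per region / fibroblast)
.state_cache <- new.env(parent = emptyenv())

#' Stabilized membrane states used to initialize tissue
#'
#' Myocytes are initialized from the single-cell state after 20 paced beats
#' at a 500 ms basic cycle length; fibroblasts from their relaxed resting
#' state.  Results are cached per region for the session.
#'
#' @param region Atrial region label.
#' @return Named state vector (V first).
#' @export
stabilized_myocyte_state <- function(region = "LA") {
  key <- paste0("myo_", region)
  if (is.null(.state_cache[[key]])) {
    tr <- pace_single_cell(myocyte_params(region), bcl = 500, n_beats = 20)
    .state_cache[[key]] <- tr$final_state
  }
  .state_cache[[key]]
}

#' @rdname stabilized_myocyte_state
#' @export
stabilized_fibroblast_state <- function() {
  if (is.null(.state_cache$fb))
    .state_cache$fb <- fibroblast_steady_state()
  .state_cache$fb
}

#' @rdname stabilized_myocyte_state
#' @param bcl Basic cycle length (ms).
#' @param n_beats Stabilization beats.
#' @details `tissue_stabilized_state()` paces a thin tissue strip (plane
#'   waves at the same diffusivity as the slab experiments) for `n_beats`
#'   beats and returns the end-diastolic state of a mid-strip myocyte.
#'   Tissue action potentials differ from the isolated cell's (electrotonic
#'   loading), so their rate adaptation differs too; slab experiments are
#'   initialized from this state.
#' @export
tissue_stabilized_state <- function(region = "LA", bcl = 500, n_beats = 20) {
  key <- paste0("tissue_", region, "_", bcl, "_", n_beats)
  if (is.null(.state_cache[[key]])) {
    cal <- slab_calibration()
    nx <- 5L; ny <- 167L
    n <- nx * ny
    tab <- atrial_region_table()
    i <- match(region, tab$region)
    probe <- (84L - 1L) * nx + 3L   # mid-strip voxel (1-based)
    out <- cpp_solve_monodomain(
      c(nx, ny, 1L), 0.3, rep(1L, n),
      rep(tab$f_gto[i], n), rep(tab$f_gcal[i], n), rep(tab$f_gkr[i], n),
      rep(cal$d_healthy, n), rep(tab$anisotropy[i], n), 1L,
      unname(stabilized_myocyte_state(region)),
      unname(stabilized_fibroblast_state()),
      0:(2L * nx - 1L), 2, 40,
      n_beats * bcl, 0.02, 0, 0.05, bcl, FALSE, integer(0),
      1, FALSE, -40, bcl, probe - 1L)
    st <- out$probe_state
    names(st) <- names(crn_initial_state())
    .state_cache[[key]] <- st
  }
  .state_cache[[key]]
}

#' Labeled voxel tissue grid
#'
#' A regular voxel lattice for the monodomain solver.  Each voxel is
#' non-conducting (`"none"`), a myocyte of a named atrial region, or a
#' fibroblast.  Conductivity is expressed as a monodomain diffusivity
#' (mm^2/ms) along the fiber axis, with a transverse-to-longitudinal
#' anisotropy ratio.
#'
#' @param dims Integer vector `(nx, ny, nz)` of voxel counts.
#' @param spacing Voxel edge length (mm).
#' @param region Character vector (length `prod(dims)`) of per-voxel labels:
#'   `"none"`, `"fibroblast"`, or an atrial region of
#'   [atrial_region_table()].
#' @param d_l Longitudinal diffusivity per voxel (mm^2/ms); scalar or
#'   per-voxel.
#' @param anisotropy Transverse/longitudinal diffusivity ratio; scalar or
#'   per-voxel.
#' @param fiber_axis `"x"`, `"y"` or `"z"` (shared by the grid).
#' @param probes Optional voxel indices of measurement probes.
#' @return Object of class `voxel_grid`.
#' @export
voxel_grid <- function(dims, spacing = 0.3, region, d_l, anisotropy = 1,
                       fiber_axis = "y", probes = integer(0)) {
  n <- prod(dims)
  stopifnot(length(dims) == 3, spacing > 0, length(region) == n)
  d_l <- rep_len(d_l, n)
  anisotropy <- rep_len(anisotropy, n)
  if (any(d_l < 0)) stop("conductivities must be >= 0")
  known <- c("none", "fibroblast", atrial_region_table()$region)
  if (!all(region %in% known))
    stop("unknown region labels: ",
         paste(unique(setdiff(region, known)), collapse = ", "))
  structure(list(dims = as.integer(dims), spacing = spacing,
                 region = region, d_l = d_l, anisotropy = anisotropy,
                 fiber_axis = match.arg(fiber_axis, c("x", "y", "z")),
                 probes = as.integer(probes)),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  d <- x$dims
  cat(sprintf("voxel_grid %d x %d x %d @ %.2g mm (%.1f x %.1f x %.1f mm)\n",
              d[1], d[2], d[3], x$spacing,
              d[1] * x$spacing, d[2] * x$spacing, d[3] * x$spacing))
  tb <- table(ifelse(x$region %in% c("none", "fibroblast"), x$region,
                     "myocyte"))
  cat("  voxels:", paste(names(tb), tb, sep = " = ", collapse = ", "), "\n")
  if (length(x$probes)) cat("  probes:", length(x$probes), "\n")
  invisible(x)
}

# voxel index helpers (1-based)
grid_index <- function(grid, ix, iy, iz = 1) {
  d <- grid$dims
  (as.integer(iz) - 1L) * d[1] * d[2] + (as.integer(iy) - 1L) * d[1] +
    as.integer(ix)
}

slab_dims <- function(size_mm = 50, spacing = 0.3) {
  c(round(size_mm / spacing), round(size_mm / spacing), 1L)
}

#' Slab experiment builders
#'
#' `build_control_slab()` builds a homogeneous 50 x 50 x 0.3 mm left-atrial
#' slab of 0.3 mm voxels.  `build_barrier_slab()` adds a full-width
#' transverse fibroblast band of the given width (voxels) at mid-height.
#' `build_channel_slab()` inverts the tissue: all fibroblast except a
#' centered healthy channel of the given width spanning the propagation
#' axis, with four probes placed evenly along the channel.
#' `build_patchy_slab()` grows patchy fibrosis on the slab to the target
#' fraction of one of the five stages, with six probes across the slab.
#'
#' @param region Atrial region modeled by the healthy tissue.
#' @param size_mm Slab edge length (mm).
#' @param spacing Voxel edge (mm).
#' @return A [voxel_grid()].
#' @export
build_control_slab <- function(region = "LA", size_mm = 50, spacing = 0.3) {
  cal <- slab_calibration()
  d <- slab_dims(size_mm, spacing)
  tab <- atrial_region_table()
  anis <- tab$anisotropy[match(region, tab$region)]
  voxel_grid(d, spacing, rep(region, prod(d)), cal$d_healthy, anis, "y")
}

#' @rdname build_control_slab
#' @param width_voxels Barrier width in voxels (0 = control).
#' @export
build_barrier_slab <- function(width_voxels, region = "LA", size_mm = 50,
                               spacing = 0.3) {
  stopifnot(width_voxels >= 0)
  g <- build_control_slab(region, size_mm, spacing)
  d <- g$dims
  if (width_voxels >= d[2]) stop("barrier band exceeds slab height")
  if (width_voxels > 0) {
    cal <- slab_calibration()
    y0 <- floor(d[2] / 2) - floor((width_voxels - 1) / 2)
    rows <- y0:(y0 + width_voxels - 1)
    idx <- as.vector(outer(seq_len(d[1]), rows,
                           function(ix, iy) grid_index(g, ix, iy)))
    g$region[idx] <- "fibroblast"
    g$d_l[idx] <- cal$d_healthy * cal$d_fibroblast_factor
    g$anisotropy[idx] <- cal$fb_anisotropy
  }
  g
}

#' @rdname build_control_slab
#' @param channel_width_mm Healthy channel width (mm), spanning the y axis.
#' @export
build_channel_slab <- function(channel_width_mm, region = "LA", size_mm = 50,
                               spacing = 0.3) {
  g <- build_control_slab(region, size_mm, spacing)
  d <- g$dims
  wv <- round(channel_width_mm / spacing)
  if (wv > d[1]) stop("channel wider than slab")
  cal <- slab_calibration()
  x0 <- floor(d[1] / 2) - floor((wv - 1) / 2)
  chan_x <- x0:(x0 + wv - 1)
  fib <- !(seq_len(d[1]) %in% chan_x)
  idx_fib <- as.vector(outer(which(fib), seq_len(d[2]),
                             function(ix, iy) grid_index(g, ix, iy)))
  g$region[idx_fib] <- "fibroblast"
  g$d_l[idx_fib] <- cal$d_healthy * cal$d_fibroblast_factor
  g$anisotropy[idx_fib] <- cal$fb_anisotropy
  cx <- chan_x[ceiling(length(chan_x) / 2)]
  py <- round(seq(0.05, 0.95, length.out = 4) * (d[2] - 1)) + 1
  g$probes <- grid_index(g, rep(cx, 4), py)
  g
}

#' @rdname build_control_slab
#' @param stage Utah-style stage 1..5.
#' @param case_seed Integer RNG seed selecting the random distribution.
#' @param drop_prob Contour reversion probability of the fibrosis generator.
#' @export
build_patchy_slab <- function(stage, case_seed = 1, drop_prob = 0.3,
                              region = "LA", size_mm = 50, spacing = 0.3) {
  stopifnot(stage %in% 1:5)
  g <- build_control_slab(region, size_mm, spacing)
  d <- g$dims
  dom <- lattice_domain(d[1], d[2])
  seeds <- place_seeds(dom, n_seeds = 50,
                       region_weights = c(interior = 1), rng_seed = case_seed)
  targets <- utah_stage_targets()
  fib <- NULL
  for (s in seq_len(stage))
    fib <- grow_fibrosis(dom, seeds, targets[s], drop_prob,
                         rng_seed = case_seed + 1000L, init = fib)
  idx <- which(fib$element_labels)
  cal <- slab_calibration()
  g$region[idx] <- "fibroblast"
  g$d_l[idx] <- cal$d_healthy * cal$d_fibroblast_factor
  g$anisotropy[idx] <- cal$fb_anisotropy
  px <- round(seq(0.15, 0.85, length.out = 6) * (d[1] - 1)) + 1
  py <- round(seq(0.2, 0.8, length.out = 6) * (d[2] - 1)) + 1
  g$probes <- grid_index(g, px, py)
  attr(g, "fibrosis") <- fib
  g
}

#' Planar stimulus voxel set
#'
#' Indices of the full bottom voxel row(s) of a grid (a "cross-wise flat
#' impulse").
#'
#' @param grid A [voxel_grid()].
#' @param rows Number of stimulated rows.
#' @param conducting_only Restrict to myocyte/fibroblast voxels.
#' @return Integer voxel indices.
#' @export
stim_plane <- function(grid, rows = 2, conducting_only = TRUE) {
  d <- grid$dims
  idx <- as.vector(outer(seq_len(d[1]), seq_len(rows),
                         function(ix, iy) grid_index(grid, ix, iy)))
  if (conducting_only) idx <- idx[grid$region[idx] != "none"]
  idx
}

#' Solve the monodomain equations on a voxel grid
#'
#' Operator-splitting monodomain solver: membrane reaction (CRN myocytes with
#' regional conductance factors; MacCannell fibroblasts) followed by explicit
#' diffusion through a 7-point anisotropic Laplacian with no-flux boundaries
#' and harmonic-mean face conductivities.  Local activation time (LAT) is the
#' first upward crossing of the threshold after stimulus onset.  Before the
#' stimulus, the tissue equilibrates for `equil_ms` so electrotonic gradients
#' between myocytes and fibroblasts are established.
#'
#' @param grid A [voxel_grid()].
#' @param stimulus List with `indices` (voxel indices), `dur` (ms) and `amp`
#'   (pA/pF, depolarizing positive); see [stim_plane()].
#' @param duration Simulated time after stimulus onset (ms).
#' @param dt Time step (ms), at most 0.05.
#' @param equil_ms Pre-stimulus equilibration (ms).
#' @param dt_equil Equilibration time step (ms).
#' @param sample_dt Output sampling interval (ms).
#' @param record `"probes"` (default) or `"all"` (full voltage movie).
#' @param early_stop Stop shortly after all conducting voxels activated.
#' @param lat_thresh Activation threshold (mV).
#' @param fb_density Fibroblast membrane current density multiplier
#'   (default: the frozen [slab_calibration()] value).
#' @param myo_init Initial myocyte state (default: the tissue-paced
#'   steady state of the dominant region, [tissue_stabilized_state()]).
#' @return Object of class `simulation_result`: `lat` (ms per voxel, `NA` if
#'   never activated), sampled times `t`, probe voltages `probe_V`, optional
#'   movie `V`, and `meta`.
#' @export
solve_monodomain <- function(grid, stimulus, duration, dt = 0.02,
                             equil_ms = 200, dt_equil = 0.05, sample_dt = 1,
                             record = c("probes", "all"), early_stop = FALSE,
                             lat_thresh = -40,
                             fb_density = slab_calibration()$fb_density,
                             myo_init = NULL) {
  record <- match.arg(record)
  stopifnot(inherits(grid, "voxel_grid"), dt <= 0.05, dt > 0)
  n <- prod(grid$dims)
  lab <- integer(n)
  lab[grid$region == "fibroblast"] <- 2L
  myo <- !(grid$region %in% c("none", "fibroblast"))
  lab[myo] <- 1L
  if (!any(lab > 0)) stop("grid has no conducting voxels")
  si <- as.integer(stimulus$indices)
  if (any(si < 1 | si > n)) stop("stimulus outside grid")

  tab <- atrial_region_table()
  fto <- fcal <- fkr <- rep(1, n)
  ri <- match(grid$region, tab$region)
  ok <- !is.na(ri)
  fto[ok] <- tab$f_gto[ri[ok]]
  fcal[ok] <- tab$f_gcal[ri[ok]]
  fkr[ok] <- tab$f_gkr[ri[ok]]

  regions <- unique(grid$region[myo])
  if (length(regions) > 1) {
    # heterogeneous myocardium: initialize all myocytes from the dominant
    # region's paced state (regional differences equilibrate in equil_ms)
    dom_region <- names(sort(table(grid$region[myo]), decreasing = TRUE))[1]
  } else dom_region <- regions
  myo_init <- myo_init %||% tissue_stabilized_state(dom_region)
  fb_init <- stabilized_fibroblast_state()

  out <- cpp_solve_monodomain(
    grid$dims, grid$spacing, lab, fto, fcal, fkr,
    grid$d_l, grid$anisotropy,
    match(grid$fiber_axis, c("x", "y", "z")) - 1L,
    unname(myo_init), unname(fb_init),
    si - 1L, stimulus$dur %||% 2, stimulus$amp %||% 40,
    duration, dt, equil_ms, dt_equil, sample_dt,
    record == "all", grid$probes - 1L,
    fb_density, early_stop, lat_thresh, 0, -1L)

  structure(list(
    lat = out$lat, t = out$t, probe_V = out$probe_V,
    V = out$V %||% NULL, final_V = out$final_V,
    grid = grid,
    meta = list(dt = dt, duration = duration, equil_ms = equil_ms,
                sample_dt = sample_dt, lat_thresh = lat_thresh,
                stimulus = list(n = length(si), dur = stimulus$dur %||% 2,
                                amp = stimulus$amp %||% 40),
                t_end = out$t_end,
                n_activated = out$n_activated,
                n_conducting = out$n_conducting)),
    class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  m <- x$meta
  cat(sprintf("monodomain simulation: %.0f ms (dt %.3g ms), %d/%d voxels activated\n",
              m$t_end, m$dt, m$n_activated, m$n_conducting))
  if (m$n_activated > 0)
    cat(sprintf("  total activation time %.1f ms\n",
                max(x$lat, na.rm = TRUE)))
  invisible(x)
}

#' Total activation time of a simulation
#'
#' Latest defined local activation time.  If `edge` is given, restricted to
#' that boundary row of the grid (useful to test whether a wavefront reached
#' the far edge).
#'
#' @param result A `simulation_result`.
#' @param edge Optional: `"ymax"`, `"ymin"`, `"xmax"`, `"xmin"`.
#' @return List with `time` (ms, `NA` if nothing/edge never activated) and
#'   `complete` (did every conducting voxel of the scope activate?).
#' @export
total_activation_time <- function(result, edge = NULL) {
  g <- result$grid
  lat <- result$lat
  scope <- which(g$region != "none")
  if (!is.null(edge)) {
    d <- g$dims
    sel <- switch(edge,
      ymax = grid_index(g, seq_len(d[1]), d[2]),
      ymin = grid_index(g, seq_len(d[1]), 1L),
      xmax = grid_index(g, d[1], seq_len(d[2])),
      xmin = grid_index(g, 1L, seq_len(d[2])),
      stop("unknown edge"))
    scope <- intersect(scope, sel)
  }
  l <- lat[scope]
  list(time = if (all(is.na(l))) NA_real_ else max(l, na.rm = TRUE),
       complete = !anyNA(l))
}

#' Conduction velocity and inter-probe delays
#'
#' CV is the path length divided by the activation-time difference between
#' the first and last probe; delays are given for consecutive probe pairs.
#' Undefined activation at a probe is reported as conduction block for its
#' segment; identical first/last activation times yield an infinite-CV flag.
#'
#' @param result A `simulation_result`.
#' @param probes Voxel indices (default: the grid's probes).
#' @param path_length_mm Path length between first and last probe (mm).
#' @return List with `cv` (m/s), `delays` (ms, consecutive pairs), `lat`
#'   (per probe) and `blocked` flags.
#' @export
measure_cv_delay <- function(result, probes = NULL,
                             path_length_mm = NULL) {
  probes <- probes %||% result$grid$probes
  if (length(probes) < 2) stop("need at least two probes")
  lat <- result$lat[probes]
  blocked <- is.na(lat)
  delays <- diff(lat)
  if (is.null(path_length_mm)) {
    d <- result$grid$dims
    xyz <- cbind((probes - 1) %% d[1],
                 ((probes - 1) %/% d[1]) %% d[2],
                 (probes - 1) %/% (d[1] * d[2]))
    path_length_mm <- sqrt(sum((xyz[length(probes), ] - xyz[1, ])^2)) *
      result$grid$spacing
  }
  dt_tot <- lat[length(lat)] - lat[1]
  cv <- if (anyNA(dt_tot)) NA_real_
        else if (dt_tot == 0) Inf
        else path_length_mm / dt_tot   # mm/ms == m/s
  list(cv = cv, delays = delays, lat = lat, blocked = blocked,
       path_length_mm = path_length_mm,
       total_delay = dt_tot)
}
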