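# ---- experiment configuration and orchestration ----

#' Default experiment configuration
#'
#' One nested list drives every stage: ionic pacing protocol, slab solver
#' settings, fibrosis generator targets, atlas geometry, forward-model noise
#' and filtering, and machine-learning grids.  All random draws take
#' explicit seeds derived from `seed`.
#'
#' @param seed Base integer seed.
#' @return Named list of parameter blocks (class `experiment_config`).
#' @export
experiment_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    ionic = list(bcl = 500, n_beats = 20, dt = 0.02, stim_dur = 2),
    slab = list(dt = 0.02, equil_ms = 200, dt_equil = 0.05,
                lat_thresh = -40),
    fibrosis = list(n_cases = 5, stage_targets = utah_stage_targets(),
                    drop_prob = 0.3, n_seeds = 50,
                    region_weights = c(PV = 1, CS = 1, FO_ring = 1,
                                       LA_post = 1)),
    atlas = list(subdiv = 4, torso_nodes = 14157),
    forward = list(power_ratio = 3, sg_window = 21, sg_order = 3,
                   electrodes = 256),
    ml = list(k_range = 2:10, n_list = c(2, 4, 8, 16, 32, 64, 128, 256),
              folds = 4)),
    class = "experiment_config")
}

#' Read / write an experiment configuration as YAML
#'
#' @param config An [experiment_config()].
#' @param path YAML file path.
#' @return `read_config` returns the configuration list.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  # named atomic vectors must become YAML maps, not sequences
  cfg$fibrosis$region_weights <- as.list(cfg$fibrosis$region_weights)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- experiment_config()
  missing <- setdiff(names(defaults), names(cfg))
  if (length(missing))
    stop("configuration is missing keys: ", paste(missing, collapse = ", "))
  cfg$fibrosis$region_weights <- unlist(cfg$fibrosis$region_weights)
  cfg$ml$k_range <- as.integer(unlist(cfg$ml$k_range))
  cfg$ml$n_list <- as.integer(unlist(cfg$ml$n_list))
  structure(cfg, class = "experiment_config")
}

#' Run a reproducible experiment
#'
#' `which = "slab-suite"` reproduces the tissue-level experiments (control,
#' fibroblast barriers, conduction channels) and writes activation-time and
#' action-potential tables.  `which = "dataset"` builds the atlas, fibrosis
#' library and the M0..M5 activation datasets with their BSPiM features.
#' `which = "pipeline"` additionally runs clustering, validation and
#' classification, writing a metrics table over models and K.  `"all"` runs
#' everything.  Outputs are plain CSV files plus a manifest; rerunning with
#' the same configuration reproduces them.
#'
#' @param config An [experiment_config()].
#' @param which One of `"slab-suite"`, `"dataset"`, `"pipeline"`, `"all"`.
#' @param out_dir Output directory (created if needed).
#' @param models Model subset for the pipeline stage.
#' @return Invisibly, a manifest data frame of written files.
#' @export
run_experiment <- function(config = experiment_config(),
                           which = c("pipeline", "slab-suite", "dataset",
                                     "all"),
                           out_dir = tempfile("fibrofocal_"),
                           models = c("M0", "M1", "M2", "M3", "M4", "M5")) {
  which <- match.arg(which)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  log <- function(...) message(sprintf(...))

  if (which %in% c("slab-suite", "all")) {
    t0 <- Sys.time()
    rows <- list()
    for (w in 0:3) {
      g <- build_barrier_slab(w)
      r <- solve_monodomain(g, list(indices = stim_plane(g)), 150,
                            dt = config$slab$dt,
                            equil_ms = if (w > 0) config$slab$equil_ms else 0,
                            early_stop = TRUE)
      tat <- total_activation_time(r, "ymax")
      rows[[length(rows) + 1]] <- data.frame(
        experiment = "barrier", width_voxels = w,
        activation_ms = tat$time, complete = tat$complete)
    }
    tab <- do.call(rbind, rows)
    f <- file.path(out_dir, "slab_barriers.csv")
    write.csv(tab, f, row.names = FALSE)
    files <- c(files, f)
    log("slab-suite done in %.1f min",
        as.numeric(difftime(Sys.time(), t0, units = "mins")))
  }

  if (which %in% c("dataset", "pipeline", "all")) {
    t0 <- Sys.time()
    atlas <- build_atlas(atlas_config(subdiv = config$atlas$subdiv,
                                      torso_nodes = config$atlas$torso_nodes),
                         rng_seed = config$seed)
    dom <- surface_domain(atlas, "LA")
    lib <- build_case_library(
      dom, n_cases = config$fibrosis$n_cases,
      stage_targets = config$fibrosis$stage_targets,
      drop_prob = config$fibrosis$drop_prob,
      rng_base = config$seed * 100,
      n_seeds = config$fibrosis$n_seeds,
      region_weights = config$fibrosis$region_weights)
    layout <- reduce_electrodes(atlas, config$forward$electrodes,
                                rng_seed = config$seed)
    lf <- build_lead_field(atlas,
                           atlas$torso$verts[layout$representatives, ])
    tpl <- pace_single_cell(myocyte_params("LA"),
                            bcl = config$ionic$bcl,
                            n_beats = config$ionic$n_beats,
                            dt = config$ionic$dt, sample_dt = 1)
    graph <- ectopic_graph(atlas)
    metrics_all <- NULL; acc_all <- NULL
    for (m in models) {
      ds <- build_dataset(atlas, lib, m)
      X <- bspim_features(ds, lf, tpl, rng_seed = config$seed * 1000,
                          power_ratio = config$forward$power_ratio,
                          window = config$forward$sg_window,
                          order = config$forward$sg_order)
      f <- file.path(out_dir, paste0("features_", m, ".csv"))
      write.csv(cbind(ds$manifest[!ds$manifest$excluded, ], X), f,
                row.names = FALSE)
      files <- c(files, f)
      if (which %in% c("pipeline", "all")) {
        g <- if (m == "M0") ectopic_graph(atlas, atlas$foci$id) else graph
        pr <- run_full_pipeline(X, ds$manifest, g,
                                k_range = config$ml$k_range,
                                n_list = config$ml$n_list,
                                rng_seed = config$seed,
                                folds = config$ml$folds)
        metrics_all <- rbind(metrics_all, cbind(model = m, pr$metrics))
        acc_all <- rbind(acc_all, cbind(model = m, pr$accuracy))
      }
      log("%s: %d samples (%s)", m, ds$counts$samples,
          format(Sys.time() - t0, digits = 3))
    }
    if (!is.null(metrics_all)) {
      f1 <- file.path(out_dir, "cluster_metrics.csv")
      f2 <- file.path(out_dir, "classification_accuracy.csv")
      write.csv(metrics_all, f1, row.names = FALSE)
      write.csv(acc_all, f2, row.names = FALSE)
      files <- c(files, f1, f2)
    }
  }

  manifest <- data.frame(file = files, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
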