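# small grids keep these tests fast; the full 50 mm slab experiments live in
# the acceptance suite

small_slab <- function(nx = 31, ny = 31, region = "LA", anis = 1) {
  cal <- slab_calibration()
  voxel_grid(c(nx, ny, 1), 0.3, rep(region, nx * ny), cal$d_healthy, anis,
             "y")
}

test_that("no-flux boundaries preserve a uniform resting state", {
  g <- small_slab()
  r <- solve_monodomain(g, list(indices = 1L, dur = 0, amp = 0),
                        duration = 100, equil_ms = 0, sample_dt = 10)
  expect_lt(max(r$final_V) - min(r$final_V), 1e-9)  # spatially uniform
  expect_true(r$final_V[1] > -85 && r$final_V[1] < -70)  # still at rest
  expect_true(all(is.na(r$lat)))
})

test_that("centered point stimulus yields a mirror-symmetric activation map", {
  g <- small_slab(31, 31)
  nb <- as.vector(outer(14:18, 14:18, function(ix, iy)
    fibrofocal:::grid_index(g, ix, iy)))
  r <- solve_monodomain(g, list(indices = nb, dur = 2, amp = 60),
                        duration = 40, equil_ms = 0, early_stop = TRUE)
  lat <- matrix(r$lat, 31, 31)
  expect_false(anyNA(lat))   # full capture and activation
  expect_lt(max(abs(lat - lat[31:1, ])), r$meta$dt + 1e-9)
  expect_lt(max(abs(lat - t(lat))), r$meta$dt + 1e-9)
})

test_that("isolated stimulus site cannot excite non-conducting surroundings", {
  g <- small_slab(11, 11)
  g$region[] <- "none"
  ctr <- as.vector(outer(5:7, 5:7, function(ix, iy)
    fibrofocal:::grid_index(g, ix, iy)))
  g$region[ctr] <- "LA"
  r <- solve_monodomain(g, list(indices = ctr, dur = 2, amp = 40),
                        duration = 30, equil_ms = 0)
  expect_true(all(is.na(r$lat[g$region == "none"])))
  expect_true(any(!is.na(r$lat[ctr])))
})

test_that("plane-wave conduction velocity converges under mesh refinement", {
  run_cv <- function(spacing, dt) {
    n <- round(12 / spacing)
    cal <- slab_calibration()
    g <- voxel_grid(c(5, n, 1), spacing, rep("LA", 5 * n), cal$d_healthy,
                    1, "y")
    g$probes <- c(fibrofocal:::grid_index(g, 3, round(n * 0.4)),
                  fibrofocal:::grid_index(g, 3, round(n * 0.9)))
    # stimulate the same 0.6 mm deep band at either resolution
    r <- solve_monodomain(g, list(indices = stim_plane(g,
                                    rows = round(0.6 / spacing)),
                                  dur = 2, amp = 40),
                          duration = 40, dt = dt, equil_ms = 0,
                          early_stop = TRUE)
    measure_cv_delay(r)$cv
  }
  cv_coarse <- run_cv(0.3, 0.02)
  cv_fine <- run_cv(0.15, 0.01)   # halved step keeps diffusion stable
  expect_lt(abs(cv_fine - cv_coarse) / cv_coarse, 0.05)
})

test_that("stimulus outside the grid or on dead tissue is rejected", {
  g <- small_slab(11, 11)
  expect_error(solve_monodomain(g, list(indices = 99999L), 10), "outside")
  g$region[5] <- "none"
  expect_error(solve_monodomain(g, list(indices = 5L), 10),
               "non-conducting")
})

test_that("slab builders validate their geometry", {
  expect_error(build_barrier_slab(400), "exceeds")
  expect_error(build_channel_slab(60), "wider")
  g1 <- build_barrier_slab(2)
  expect_equal(sum(g1$region == "fibroblast"), 2 * 167)
  g2 <- build_channel_slab(1.5)
  expect_equal(sum(g2$region != "fibroblast"), 5 * 167)
  expect_length(g2$probes, 4)
  expect_true(all(g2$region[g2$probes] == "LA"))
})

test_that("patchy slab fraction matches its stage and grows with stage", {
  g1 <- build_patchy_slab(1, case_seed = 3)
  f1 <- attr(g1, "fibrosis")
  expect_lt(f1$fraction, 0.081)  # Utah stage I band
  g3 <- build_patchy_slab(3, case_seed = 3)
  f3 <- attr(g3, "fibrosis")
  expect_gt(f3$fraction, f1$fraction)
  # nesting of the fibrotic sets (same case seed)
  expect_true(all(which(f1$element_labels) %in% which(f3$element_labels)))
  expect_length(g3$probes, 6)
})

test_that("myocytes near patchy fibrosis rest depolarized with smaller APs", {
  g <- build_patchy_slab(1, case_seed = 2, size_mm = 25)
  r <- solve_monodomain(g, list(indices = stim_plane(g), dur = 2, amp = 40),
                        duration = 330, equil_ms = 200, sample_dt = 0.5)
  expect_equal(r$meta$n_activated, r$meta$n_conducting)  # mild stage conducts
  ap <- lapply(seq_along(g$probes), function(p)
    compute_ap_metrics(list(t = r$t, V = r$probe_V[p, ])))
  amp <- vapply(ap, `[[`, 0, "amplitude")
  rmp <- vapply(ap, `[[`, 0, "RMP")
  worst <- which.min(amp)
  expect_lt(amp[worst], max(amp) - 2)    # amplitude reduced near fibrosis
  expect_gt(rmp[worst], min(rmp) + 1)    # resting potential elevated there
})

test_that("conduction velocity and delay bookkeeping", {
  # synthetic result: probes with known activation times
  g <- small_slab(11, 11)
  g$probes <- c(fibrofocal:::grid_index(g, 6, 1),
                fibrofocal:::grid_index(g, 6, 11))
  res <- structure(list(lat = rep(NA_real_, 121), grid = g),
                   class = "simulation_result")
  res$lat[g$probes] <- c(1, 60)  # 59 ms over 3 mm
  out <- measure_cv_delay(res)
  expect_equal(out$cv, 3 / 59)
  expect_equal(out$delays, 59)
  res$lat[g$probes] <- c(5, 5)   # identical -> infinite-CV flag
  expect_equal(measure_cv_delay(res)$cv, Inf)
  res$lat[g$probes[2]] <- NA     # block
  out <- measure_cv_delay(res)
  expect_true(out$blocked[2])
  expect_true(is.na(out$cv))
})

test_that("grid exports to a legacy VTK file", {
  g <- small_slab(5, 5)
  f <- tempfile(fileext = ".vtk")
  write_grid_vtk(g, f, lat = runif(25))
  head <- readLines(f, n = 5)
  expect_match(head[4], "STRUCTURED_POINTS")
  unlink(f)
})
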