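# a minimal source: one triangle in the x-y plane with a voltage gradient,
# i.e. a single current dipole at the origin
dipole_fixture <- function(n_el = 200, R = 10) {
  verts <- rbind(c(-0.5, -0.3, 0), c(0.5, -0.3, 0), c(0, 0.6, 0))
  faces <- matrix(1:3, 1)
  atlas <- list(verts = verts, faces = faces)
  class(atlas) <- "atrial_atlas"
  el <- R * fibrofocal:::fibonacci_sphere(n_el)
  list(atlas = atlas, electrodes = el)
}

test_that("a single dipole produces antipodal extrema and a null equator", {
  fx <- dipole_fixture()
  lf <- build_lead_field(fx$atlas, fx$electrodes)
  v <- c(0, 0, 1)   # gradient along the triangle -> dipole in-plane
  phi <- as.vector(lf$L %*% v)
  i_max <- which.max(phi); i_min <- which.min(phi)
  # extrema on opposite sides
  expect_lt(sum(fx$electrodes[i_max, ] * fx$electrodes[i_min, ]), 0)
  expect_equal(max(phi), -min(phi), tolerance = 0.05)
  # the voltage rises toward the apex vertex, so the dipole axis is -y;
  # electrodes near the orthogonal plane see ~ nothing
  equator <- abs(fx$electrodes[, 2]) < 0.02 * 10
  expect_gt(sum(equator), 0)
  expect_lt(max(abs(phi[equator])), 0.02 * max(abs(phi)))
})

test_that("lead field is linear and vanishes for uniform sources", {
  fx <- dipole_fixture(50)
  lf <- build_lead_field(fx$atlas, fx$electrodes)
  expect_lt(max(abs(lf$L %*% rep(3.7, 3))), 1e-12)   # uniform V -> 0
  v <- c(0.2, -0.4, 1.1)
  expect_equal(as.vector(lf$L %*% (2 * v)),
               2 * as.vector(lf$L %*% v), tolerance = 1e-12)
  expect_error(build_lead_field(fx$atlas, matrix(c(0, 0.0, 0), 1)),
               "coincides")
})

test_that("noise calibration: powers, SNR and reproducibility", {
  nt <- 2500; ne <- 400                      # 1e6 samples
  b <- structure(list(potentials = matrix(sin(seq_len(nt) / 40), ne, nt,
                                          byrow = TRUE),
                      t = seq_len(nt), noise_meta = NULL), class = "bspm")
  nb <- add_noise(b, rng_seed = 42, power_ratio = 3)
  expect_equal(nb$noise_meta$snr_db, 10 * log10(3))
  expect_equal(nb$noise_meta$snr_db, 4.77, tolerance = 0.005)
  emp <- mean((nb$potentials - b$potentials)^2)
  expect_equal(emp, nb$noise_meta$noise_power, tolerance = 0.01)  # 1% at 1e6
  nb2 <- add_noise(b, rng_seed = 42, power_ratio = 3)
  expect_identical(nb$potentials, nb2$potentials)
  z <- b; z$potentials[] <- 0
  expect_error(add_noise(z, 1), "zero signal")
})

test_that("SNR across seeded realizations stays at 4.77 dB", {
  nt <- 400; ne <- 64
  b <- structure(list(potentials = matrix(cos(seq_len(nt) / 25), ne, nt,
                                          byrow = TRUE),
                      t = seq_len(nt), noise_meta = NULL), class = "bspm")
  p_s <- mean(b$potentials^2)
  snr <- vapply(1:100, function(s) {
    nb <- add_noise(b, rng_seed = s, power_ratio = 3)
    10 * log10(p_s / mean((nb$potentials - b$potentials)^2))
  }, numeric(1))
  expect_equal(mean(snr), 4.77, tolerance = 0.1)
})

test_that("Savitzky-Golay smoothing: polynomial exactness and denoising", {
  t <- 0:499
  poly <- 2 + 0.01 * t - 1e-5 * t^2                # degree 2 <= order 3
  b <- structure(list(potentials = rbind(poly, poly), t = t,
                      noise_meta = NULL), class = "bspm")
  sm <- smooth_bspm(b, window = 21, order = 3)
  expect_equal(sm$potentials[1, 30:470], b$potentials[1, 30:470],
               tolerance = 1e-9)
  # pure noise: variance strictly reduced
  nz <- b; nz$potentials <- matrix(rnorm(1000), 2)
  expect_lt(var(as.vector(smooth_bspm(nz, 21, 3)$potentials)),
            var(as.vector(nz$potentials)))
  # noisy sine: filtering beats no filtering
  clean <- sin(2 * pi * t / 100)
  set.seed(7)
  noisy <- clean + rnorm(length(t), sd = 0.4)
  bb <- structure(list(potentials = rbind(noisy), t = t,
                       noise_meta = NULL), class = "bspm")
  rmse_raw <- sqrt(mean((noisy - clean)^2))
  rmse_sg <- sqrt(mean((smooth_bspm(bb, 21, 3)$potentials[1, ] - clean)^2))
  expect_lt(rmse_sg, rmse_raw)
  expect_error(smooth_bspm(b, 20, 3), "odd")
  expect_error(smooth_bspm(b, 501, 3), "longer")
})

test_that("P-wave integration: rectangle, biphasic, refinement invariance", {
  t <- seq(0, 150, by = 1)
  P <- matrix(0, 3, length(t))
  P[1, t >= 20 & t <= 120] <- 2             # 2 mV for 100 ms
  b <- structure(list(potentials = P, t = t, noise_meta = NULL),
                 class = "bspm")
  bi <- integrate_pwave(b, c(0, 150))
  expect_equal(attr(bi, "raw")[1], 200, tolerance = 4)  # mV ms (trapezoid edges)
  expect_equal(as.numeric(bi[1]), 1.0)
  expect_equal(max(abs(bi)), 1)
  # antisymmetric biphasic wave integrates to ~ 0
  P2 <- rbind(sin(2 * pi * t / 150))
  b2 <- structure(list(potentials = P2, t = t, noise_meta = NULL),
                  class = "bspm")
  expect_lt(abs(attr(integrate_pwave(b2), "raw")[1]), 1e-10)
  # trapezoid refinement: x2 resampling of a piecewise-linear signal
  t2 <- seq(0, 150, by = 0.5)
  P3 <- rbind(approx(t, P[1, ], t2)$y, approx(t, t / 50, t2)$y)
  b3 <- structure(list(potentials = P3, t = t2, noise_meta = NULL),
                  class = "bspm")
  b1 <- structure(list(potentials = rbind(P[1, ], t / 50), t = t,
                       noise_meta = NULL), class = "bspm")
  expect_lt(max(abs(attr(integrate_pwave(b3), "raw") -
                    attr(integrate_pwave(b1), "raw"))), 1e-12)
  expect_error(integrate_pwave(b, c(100, 50)), "t0 < t1")
  zz <- b; zz$potentials[] <- 0
  expect_warning(integrate_pwave(zz), "all-zero")
})

test_that("a dipolar activation yields a BSPiM spanning both signs", {
  a <- small_atlas()
  layout <- reduce_electrodes(a, 64, rng_seed = 1)
  lf <- build_lead_field(a, a$torso$verts[layout$representatives, ])
  e <- eikonal_activation(a, "LA1")
  vm <- synthesize_transmembrane(e$lat, study_template(),
                                 c(0, max(e$lat, na.rm = TRUE) + 10))
  bi <- integrate_pwave(compute_bspm(lf, vm))
  expect_equal(max(abs(bi)), 1)
  expect_lt(min(bi), 0)
  expect_gt(max(bi), 0)
})

test_that("decibel bookkeeping: ratio 3 is 4.8 dB and 3 uW is -55.2 dBW", {
  expect_equal(snr_db(3), 4.77, tolerance = 0.005)
  expect_equal(power_dbw(0.003e-3), -55.2, tolerance = 0.05)
  expect_equal(power_dbw(0.001e-3), -60.0, tolerance = 0.05)
})
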