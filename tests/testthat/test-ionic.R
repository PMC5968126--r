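test_that("resting myocyte is at equilibrium (net current ~ 0, tiny drift)", {
  s <- crn_initial_state()
  out <- myocyte_ionic_current(s, myocyte_params("RA"))
  expect_lt(abs(out$I_ion), 0.05)   # pA/pF, near equilibrium
  tr <- fibrofocal:::cpp_pace_single_cell(1, 1, 1, 1000, 1L, 0.02, 0, 0,
                                          1, numeric(0))
  expect_lt(abs(tr$V[length(tr$V)] - tr$V[1]), 0.1)  # < 0.1 mV over 1 s
})

test_that("regional conductance factors scale exactly the three currents", {
  s <- crn_initial_state()
  s[["V"]] <- -20  # activated range so currents are nonzero
  s[["oa"]] <- 0.5; s[["oi"]] <- 0.5; s[["xr"]] <- 0.5
  s[["d"]] <- 0.3; s[["f"]] <- 0.7
  base <- myocyte_ionic_current(s, myocyte_params("RA"))$currents
  raa <- myocyte_ionic_current(s, myocyte_params("RAA"))$currents
  mvr <- myocyte_ionic_current(s, myocyte_params("MVR"))$currents
  expect_equal(raa[["Ito"]], 0.68 * base[["Ito"]])
  expect_equal(mvr[["IKr"]], 2.44 * base[["IKr"]])
  expect_equal(mvr[["ICaL"]], 0.67 * base[["ICaL"]])
  # all other currents untouched
  same <- setdiff(names(base), c("Ito", "ICaL", "IKr"))
  expect_equal(raa[same], base[same])
})

test_that("implementation matches an independently coded oracle at clamped voltages", {
  s <- crn_initial_state()
  s[["oa"]] <- 0.4; s[["xr"]] <- 0.3; s[["d"]] <- 0.2; s[["fca"]] <- 0.5
  for (V in c(-90, -60, -30, 0, 30)) {
    got <- myocyte_ionic_current(
      replace(s, "V", V), myocyte_params("LA"))$currents
    want <- crn_oracle_currents(V, s, f_gto = 1, f_gcal = 1, f_gkr = 1.6)
    for (nm in names(want))
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12,
                   label = sprintf("%s at V=%g", nm, V))
  }
})

test_that("non-finite state is rejected", {
  s <- crn_initial_state()
  s[["Cai"]] <- NaN
  expect_error(myocyte_ionic_current(s), "non-finite")
})

test_that("gates stay in [0,1] during sustained pacing", {
  tr <- pace_single_cell(myocyte_params("LA"), bcl = 500, n_beats = 4)
  g <- tr$final_state[2:16]
  expect_true(all(g >= 0 & g <= 1))
  # and across a grid of paced protocols
  for (region in c("PV", "MVR", "CT_BB")) {
    st <- pace_single_cell(myocyte_params(region), bcl = 400,
                           n_beats = 2)$final_state
    expect_true(all(st[2:16] >= 0 & st[2:16] <= 1), label = region)
  }
})

test_that("doubling the rapid-rectifier factor shortens APD90", {
  p1 <- myocyte_params("LA")
  p2 <- p1; p2$f_gkr <- 2 * p1$f_gkr
  a1 <- compute_ap_metrics(pace_single_cell(p1, n_beats = 3))
  a2 <- compute_ap_metrics(pace_single_cell(p2, n_beats = 3,
                                            stim_amp = NULL))
  expect_lt(a2$APD90, a1$APD90)
})

test_that("accommodation: beat 20 differs from beat 1, both finite", {
  p <- myocyte_params("LA")
  a1 <- compute_ap_metrics(pace_single_cell(p, n_beats = 1))
  a20 <- compute_ap_metrics(pace_single_cell(p, n_beats = 20))
  expect_true(is.finite(a1$APD90) && is.finite(a20$APD90))
  expect_false(isTRUE(all.equal(a1$APD90, a20$APD90)))
})

test_that("subthreshold stimulus raises a no-capture error", {
  expect_error(pace_single_cell(myocyte_params("LA"), n_beats = 1,
                                stim_amp = 1), "no capture")
})

test_that("fibroblast membrane carries exactly four currents", {
  out <- fibroblast_ionic_current(fibroblast_initial_state())
  expect_named(out$currents, c("IKv", "IK1", "INaK", "IbNa"))
  expect_equal(out$I_ion, sum(out$currents))
})

test_that("IKv vanishes at the fibroblast K reversal potential", {
  ek <- fibroblast_params()$E_K
  s <- fibroblast_initial_state()
  s[["V"]] <- ek
  out <- fibroblast_ionic_current(s)
  expect_equal(out$currents[["IKv"]], 0, tolerance = 1e-12)
})

test_that("fibroblast steady state agrees with root finding and sits above myocyte RMP", {
  ss <- fibroblast_steady_state(duration = 20000)
  root <- uniroot(fb_oracle_total_current, c(-80, -20))$root
  expect_equal(ss[["V"]], root, tolerance = 1e-3)
  expect_equal(ss[["V"]], -48.932, tolerance = 0.01)  # frozen regression value
  myo <- compute_ap_metrics(pace_single_cell(myocyte_params("LA"),
                                             n_beats = 3))
  expect_gt(ss[["V"]], myo$RMP)  # fibroblast rests depolarized vs myocyte
})

test_that("AP metrics: square pulse, real trace, degenerate traces", {
  t <- seq(0, 300, by = 0.5)
  v <- ifelse(t >= 10 & t < 110, 0, -80)
  m <- compute_ap_metrics(list(t = t, V = v))
  expect_equal(m$amplitude, 80)
  expect_equal(m$APD90, 100, tolerance = 0.51)
  expect_equal(m$APD50, 100, tolerance = 0.51)
  expect_error(compute_ap_metrics(list(t = t, V = rep(-80, length(t)))),
               "no AP")
  expect_error(compute_ap_metrics(list(t = t, V = seq(-80, -70,
                                                      length.out = length(t)))),
               "no AP")
})

test_that("trace CSV round trip", {
  tr <- list(t = c(0, 1, 2), V = c(-80, -20, -75))
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  back <- read_trace_csv(f)
  expect_equal(back$t, tr$t)
  expect_equal(back$V, tr$V)
  unlink(f)
})

test_that("constants files match the model tables", {
  k <- ionic_constants("crn")
  expect_equal(k$cell$Cm, 100)
  init <- crn_initial_state()
  expect_equal(init[["V"]], k$initial_state$V)
  expect_equal(init[["Nai"]], k$initial_state$Na_i)
  expect_equal(ionic_constants("maccannell")$cell$Cm_fb, 6.3)
  tab <- atrial_region_table()
  expect_equal(nrow(tab), 11)  # all columns of the regional table
  expect_equal(tab$f_gto[tab$region == "RAA"], 0.68)
  expect_equal(tab$f_gkr[tab$region == "MVR"], 2.44)
})
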