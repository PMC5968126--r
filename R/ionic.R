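#' Myocyte parameters for an atrial region
#'
#' Regional heterogeneity is represented by multiplicative factors on the
#' maximum conductances of three currents of the Courtemanche-Ramirez-Nattel
#' (CRN) myocyte model: the transient outward current, the L-type calcium
#' current and the rapid delayed rectifier.
#'
#' @param region One of the 11 region labels of [atrial_region_table()].
#' @return An object of class `myocyte_params`.
#' @export
#' @examples
#' myocyte_params("LA")
myocyte_params <- function(region = "LA") {
  tab <- atrial_region_table()
  i <- match(region, tab$region)
  if (is.na(i)) stop("unknown atrial region: ", region)
  structure(list(region_id = region,
                 f_gto = tab$f_gto[i], f_gcal = tab$f_gcal[i],
                 f_gkr = tab$f_gkr[i],
                 Cm = ionic_constants("crn")$cell$Cm),
            class = "myocyte_params")
}

#' @export
print.myocyte_params <- function(x, ...) {
  cat("CRN myocyte parameters, region", x$region_id, "\n")
  cat(sprintf("  g_to x %.2f, g_CaL x %.2f, g_Kr x %.2f, Cm %.0f pF\n",
              x$f_gto, x$f_gcal, x$f_gkr, x$Cm))
  invisible(x)
}

#' Fibroblast parameters (MacCannell active model)
#'
#' The active fibroblast membrane carries exactly four currents: the time-
#' and voltage-dependent K current `I_Kv`, the inward-rectifier K current
#' `I_K1`, the Na-K pump current `I_NaK`, and the background Na current
#' `I_bNa`.
#'
#' @return An object of class `fibroblast_params` holding conductances,
#'   reversal-relevant concentrations and the fibroblast capacitance.
#' @export
fibroblast_params <- function() {
  k <- ionic_constants("maccannell")
  rtf <- with(ionic_constants("crn")$physical, R * T / F)
  structure(list(
    g_Kv = k$I_Kv$g_Kv, g_K1 = k$I_K1$g_K1,
    I_NaK_max = k$I_NaK$I_NaK_max, g_bNa = k$I_bNa$g_bNa,
    E_K = rtf * log(k$concentrations$K_o / k$concentrations$K_i),
    E_Na = rtf * log(k$concentrations$Na_o / k$concentrations$Na_i),
    Cm_fb = k$cell$Cm_fb),
    class = "fibroblast_params")
}

#' Initial (resting) state of a CRN myocyte
#'
#' Named vector: transmembrane voltage `V` (mV), 15 gating variables, and 5
#' ionic concentrations (mM), at the model's published resting values.
#'
#' @return Named numeric vector of length 21.
#' @export
crn_initial_state <- function() cpp_crn_init_state()

#' Initial state of a MacCannell fibroblast
#' @return Named numeric vector `V`, `r`, `s`.
#' @export
fibroblast_initial_state <- function() cpp_fb_init_state()

check_cell_state <- function(state, n) {
  if (!all(is.finite(state)))
    stop("non-finite cell state: numerical divergence")
  if (length(state) != n)
    stop("state must have ", n, " elements")
  invisible(TRUE)
}

#' Membrane currents of an atrial myocyte
#'
#' Evaluates all CRN membrane currents (pA/pF) at a given state, with the
#' regional conductance factors applied to the transient outward, L-type
#' calcium and rapid delayed rectifier currents, plus gate steady states and
#' time constants at the given voltage.
#'
#' @param state Named state vector as from [crn_initial_state()] (`V` first).
#' @param params A [myocyte_params()] object.
#' @return List with `I_ion` (total, pA/pF), `currents`, `fluxes`,
#'   `gate_inf`, `gate_tau`.
#' @export
myocyte_ionic_current <- function(state, params = myocyte_params("LA")) {
  check_cell_state(state, 21L)
  g <- state[2:16]
  if (any(g < -1e-9 | g > 1 + 1e-9))
    stop("gating variables outside [0, 1]")
  cpp_crn_currents(state[[1]], unname(state[-1]),
                   params$f_gto, params$f_gcal, params$f_gkr)
}

#' Membrane currents of an active fibroblast
#'
#' @param state Named vector `V`, `r`, `s`.
#' @param params A [fibroblast_params()] object (informational; the model
#'   constants are fixed).
#' @return List with `I_ion` (pA/pF), the four `currents`, `gate_inf`,
#'   `gate_tau`.
#' @export
fibroblast_ionic_current <- function(state, params = fibroblast_params()) {
  check_cell_state(state, 3L)
  cpp_fb_currents(state[[1]], unname(state[-1]))
}

#' Resting steady state of an uncoupled fibroblast
#'
#' Relaxes the fibroblast membrane with no stimulus until the state is
#' stationary.
#'
#' @param duration Relaxation time (ms).
#' @param dt Time step (ms).
#' @return Named vector `V`, `r`, `s` at rest.
#' @export
fibroblast_steady_state <- function(duration = 20000, dt = 0.05) {
  cpp_fb_relax(duration, dt)
}

#' Diastolic stimulus threshold of a myocyte
#'
#' Bisection on the amplitude of a rectangular 2 ms stimulus that elicits an
#' action potential (peak above 0 mV) from the resting model.
#'
#' @param params A [myocyte_params()] object.
#' @param stim_dur Stimulus duration (ms).
#' @param dt Time step (ms).
#' @return Threshold current density (pA/pF, depolarizing positive).
#' @export
diastolic_threshold <- function(params = myocyte_params("LA"), stim_dur = 2,
                                dt = 0.02) {
  captures <- function(amp) {
    tr <- cpp_pace_single_cell(params$f_gto, params$f_gcal, params$f_gkr,
                               400, 1L, dt, amp, stim_dur, 1, numeric(0))
    max(tr$V) > 0
  }
  lo <- 0; hi <- 8
  while (!captures(hi)) {
    hi <- hi * 2
    if (hi > 256) stop("no capture even at very large stimulus amplitude")
  }
  for (i in 1:12) {
    mid <- (lo + hi) / 2
    if (captures(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' Pace a single myocyte and return the final beat
#'
#' Paces a CRN myocyte with rectangular stimuli (default 2 ms at twice the
#' diastolic threshold) at a fixed basic cycle length, and returns the
#' uniformly sampled voltage trace of the last beat after stabilization.
#'
#' @param params A [myocyte_params()] object.
#' @param bcl Basic cycle length (ms).
#' @param n_beats Number of beats (the last is recorded).
#' @param dt Integration step (ms); gates advance by Rush-Larsen,
#'   concentrations by forward Euler.
#' @param stim_amp Stimulus amplitude (pA/pF); default 2 x diastolic
#'   threshold.
#' @param stim_dur Stimulus duration (ms).
#' @param sample_dt Output sampling interval (ms).
#' @return Object of class `ap_trace`: `t`, `V`, `final_state`, and the
#'   protocol description.
#' @export
#' @examples
#' \donttest{
#' tr <- pace_single_cell(myocyte_params("LA"), bcl = 500, n_beats = 2)
#' compute_ap_metrics(tr)
#' }
pace_single_cell <- function(params = myocyte_params("LA"), bcl = 500,
                             n_beats = 20, dt = 0.02, stim_amp = NULL,
                             stim_dur = 2, sample_dt = 0.1) {
  stopifnot(n_beats >= 1, bcl > 0, dt > 0, dt <= 0.05)
  if (is.null(stim_amp))
    stim_amp <- 2 * diastolic_threshold(params, stim_dur, dt)
  out <- cpp_pace_single_cell(params$f_gto, params$f_gcal, params$f_gkr,
                              bcl, as.integer(n_beats), dt, stim_amp,
                              stim_dur, sample_dt, numeric(0))
  if (max(out$V) < 0)
    stop("no capture: stimulated beat did not elicit an action potential ",
         "(peak below 0 mV)")
  structure(list(t = out$t, V = out$V, final_state = out$final_state,
                 params = params, bcl = bcl, n_beats = n_beats, dt = dt,
                 stim_amp = stim_amp, stim_dur = stim_dur),
            class = "ap_trace")
}

#' @export
print.ap_trace <- function(x, ...) {
  cat(sprintf("Action potential trace: %.0f ms at %.2g ms sampling (%s)\n",
              max(x$t), diff(x$t[1:2]), x$params$region_id %||% "custom"))
  invisible(x)
}

#' Action potential metrics
#'
#' Resting membrane potential (pre-stimulus value), peak voltage, amplitude,
#' and action-potential durations at 50% and 90% repolarization.  Durations
#' are measured from the time of maximum upstroke velocity to recovery to
#' `RMP + (1 - x/100) * amplitude`, with linear interpolation between
#' samples.
#'
#' @param trace An `ap_trace`, or a list/data frame with `t` (ms) and `V`
#'   (mV) containing exactly one upstroke.
#' @return Object of class `ap_metrics`: `RMP`, `peak`, `amplitude`,
#'   `APD90`, `APD50` plus upstroke time `t_up` and max dV/dt.
#' @export
compute_ap_metrics <- function(trace) {
  t <- trace$t; V <- trace$V
  stopifnot(length(t) == length(V), length(t) > 3)
  rmp <- V[1]
  peak <- max(V)
  amp <- peak - rmp
  dv <- diff(V) / diff(t)
  iu <- which.max(dv)
  if (amp < 10 || dv[iu] <= 0.5)
    stop("no AP: trace contains no upstroke")
  t_up <- t[iu + 1]
  apd <- function(frac) {
    level <- rmp + (1 - frac) * amp
    after <- which(t > t_up)
    below <- after[V[after] <= level]
    if (!length(below)) return(NA_real_)
    i2 <- below[1]; i1 <- i2 - 1
    tc <- if (V[i1] == V[i2]) t[i2] else
      t[i1] + (level - V[i1]) / (V[i2] - V[i1]) * (t[i2] - t[i1])
    tc - t_up
  }
  structure(list(RMP = rmp, peak = peak, amplitude = amp,
                 APD90 = apd(0.9), APD50 = apd(0.5),
                 t_up = t_up, dvdt_max = dv[iu]),
            class = "ap_metrics")
}

#' @export
print.ap_metrics <- function(x, ...) {
  cat(sprintf("RMP %.1f mV  peak %.2f mV  amplitude %.2f mV\n",
              x$RMP, x$peak, x$amplitude))
  cat(sprintf("APD90 %.1f ms  APD50 %.1f ms  (dV/dt max %.0f mV/ms)\n",
              x$APD90, x$APD50, x$dvdt_max))
  invisible(x)
}

#' Write / read an action potential trace as two-column CSV
#'
#' @param trace An `ap_trace` or list with `t`, `V`.
#' @param path File path.
#' @return `read_trace_csv` returns a list with `t` and `V`.
#' @export
write_trace_csv <- function(trace, path) {
  write.csv(data.frame(t_ms = trace$t, V_mV = trace$V), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  d <- read.csv(path)
  list(t = d$t_ms, V = d$V_mV)
}
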