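# ---- forward projection of atrial sources to torso potentials ----

#' Build a lead field from atrial sources to torso electrodes
#'
#' Infinite homogeneous volume-conductor dipole sum: each surface triangle
#' contributes an equivalent current dipole proportional to the in-plane
#' gradient of the transmembrane voltage times its area, and the potential
#' at an electrode is the sum of dipole kernels `p . r / (4 pi sigma |r|^3)`.
#' The result is a linear map (electrodes x vertices) applied to per-vertex
#' voltages; a zero-mean reference across electrodes is folded into the
#' matrix.  This is a deliberate simplification of a torso volume-conductor
#' model: absolute potentials are nominal, but the spatial pattern structure
#' that the downstream pipeline consumes is preserved.
#'
#' @param atlas An `atrial_atlas`.
#' @param electrodes Electrode coordinates (n x 3, cm); default all torso
#'   nodes.
#' @param sigma Medium conductivity (arbitrary scale).
#' @return Object of class `lead_field`: `L` (electrodes x vertices),
#'   `electrodes`, `geometry_hash`.
#' @export
build_lead_field <- function(atlas, electrodes = NULL, sigma = 0.2) {
  el <- electrodes %||% atlas$torso$verts
  v <- atlas$verts
  f <- atlas$faces
  ne <- nrow(el); nv <- nrow(v)
  # electrode too close to a source point is ill-posed
  ctr <- (v[f[, 1], , drop = FALSE] + v[f[, 2], , drop = FALSE] +
            v[f[, 3], , drop = FALSE]) / 3
  L <- matrix(0, ne, nv)
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  for (i in seq_len(nrow(f))) {
    p1 <- v[f[i, 1], ]; p2 <- v[f[i, 2], ]; p3 <- v[f[i, 3], ]
    n <- cross3(p2 - p1, p3 - p1)
    A2 <- sqrt(sum(n^2))           # 2 * area
    if (A2 < 1e-12) next
    nh <- n / A2
    # linear FEM gradient: grad V = sum_k V_k (nh x e_k) / (2A),
    # e_k the edge opposite vertex k
    G <- cbind(cross3(nh, p3 - p2), cross3(nh, p1 - p3),
               cross3(nh, p2 - p1)) / A2            # 3 x 3 (xyz x verts)
    r <- el - matrix(ctr[i, ], ne, 3, byrow = TRUE)  # ne x 3
    d3 <- (rowSums(r^2))^(1.5)
    if (any(d3 < 1e-9))
      stop("electrode coincides with a source point")
    K <- r / d3 / (4 * pi * sigma)                   # ne x 3
    contrib <- K %*% (-(A2 / 2) * G)                 # ne x 3 vertices
    L[, f[i, ]] <- L[, f[i, ]] + contrib
  }
  L <- sweep(L, 2, colMeans(L))   # zero-mean electrode reference
  structure(list(L = L, electrodes = el,
                 geometry_hash = sum(abs(v)) + nrow(f) + ne),
            class = "lead_field")
}

#' Project transmembrane signals to a body-surface potential map
#'
#' @param lead_field A [build_lead_field()] object.
#' @param vm From [synthesize_transmembrane()] (`V` vertex x time, `t`).
#' @return Object of class `bspm`: `potentials` (electrodes x time, mV
#'   nominal), `t` (ms), `noise_meta`.
#' @export
compute_bspm <- function(lead_field, vm) {
  pot <- lead_field$L %*% vm$V
  structure(list(potentials = pot, t = vm$t, noise_meta = NULL),
            class = "bspm")
}

#' @export
print.bspm <- function(x, ...) {
  cat(sprintf("bspm: %d electrodes x %d samples (%.0f ms)%s\n",
              nrow(x$potentials), ncol(x$potentials), max(x$t),
              if (!is.null(x$noise_meta)) sprintf(
                ", noisy (SNR %.2f dB)", x$noise_meta$snr_db) else ""))
  invisible(x)
}

#' Decibel helpers
#'
#' `snr_db(ratio)` converts a signal-to-noise power ratio to dB;
#' `power_dbw(p)` expresses a power (W) in dBW.
#'
#' @param ratio Signal-to-noise power ratio.
#' @param p Power in watts.
#' @export
snr_db <- function(ratio) 10 * log10(ratio)

#' @rdname snr_db
#' @export
power_dbw <- function(p) 10 * log10(p)

#' Add calibrated white Gaussian noise to a BSPM
#'
#' Measures the mean signal power over the map and adds zero-mean white
#' Gaussian noise with power `signal power / power_ratio` (the default ratio
#' of 3 gives an SNR of about 4.8 dB).
#'
#' @param bspm A `bspm`.
#' @param rng_seed Integer seed.
#' @param power_ratio Signal-to-noise power ratio.
#' @return The noisy `bspm`, with `noise_meta` describing powers and seed.
#' @export
add_noise <- function(bspm, rng_seed = 1, power_ratio = 3) {
  p_s <- mean(bspm$potentials^2)
  if (p_s == 0) stop("zero signal: SNR undefined")
  p_n <- p_s / power_ratio
  noisy <- bspm
  noisy$potentials <- bspm$potentials +
    with_seed(rng_seed,
              matrix(rnorm(length(bspm$potentials), sd = sqrt(p_n)),
                     nrow(bspm$potentials)))
  noisy$noise_meta <- list(signal_power = p_s, noise_power = p_n,
                           power_ratio = power_ratio,
                           snr_db = snr_db(power_ratio), rng_seed = rng_seed)
  noisy
}

#' Savitzky-Golay smoothing of a BSPM
#'
#' Per-electrode least-squares polynomial smoothing.
#'
#' @param bspm A `bspm`.
#' @param window Odd window length (samples), greater than `order`.
#' @param order Polynomial order.
#' @return The filtered `bspm`.
#' @export
smooth_bspm <- function(bspm, window = 21, order = 3) {
  nt <- ncol(bspm$potentials)
  if (window %% 2 == 0 || window <= order)
    stop("window must be odd and greater than the polynomial order")
  if (window > nt) stop("window longer than the signal")
  out <- bspm
  out$potentials <- t(apply(bspm$potentials, 1, function(x)
    signal::sgolayfilt(x, p = order, n = window)))
  out
}

#' Integrate the P wave into a normalized BSPiM
#'
#' Trapezoidal time integration per electrode over the window, then global
#' normalization of the map to \[-1, 1\] by its maximum absolute value.
#'
#' @param bspm A `bspm`.
#' @param window `(t0, t1)` ms; default the full signal.
#' @return Object of class `bspim`: normalized numeric vector (one value per
#'   electrode) with attributes `raw` (mV ms) and `norm` (the divisor).
#' @export
integrate_pwave <- function(bspm, window = NULL) {
  t <- bspm$t
  if (is.null(window)) window <- range(t)
  if (window[1] >= window[2]) stop("window must satisfy t0 < t1")
  sel <- which(t >= window[1] & t <= window[2])
  if (length(sel) < 2) stop("window contains fewer than two samples")
  tt <- t[sel]
  P <- bspm$potentials[, sel, drop = FALSE]
  w <- diff(tt)
  raw <- as.vector((P[, -1, drop = FALSE] + P[, -length(tt), drop = FALSE])
                   %*% w) / 2
  m <- max(abs(raw))
  if (m == 0) {
    warning("all-zero integral map: normalization skipped")
    val <- raw
  } else val <- raw / m
  structure(val, class = "bspim", raw = raw, norm = m)
}

#' @export
print.bspim <- function(x, ...) {
  cat(sprintf("bspim: %d electrodes, range [%.3f, %.3f]\n",
              length(x), min(x), max(x)))
  invisible(x)
}

#' Compute the BSPiM feature matrix of an activation dataset
#'
#' For every surviving run of the dataset: synthesize transmembrane signals
#' from the LAT map, project them through the lead field, add calibrated
#' noise, smooth, and integrate the P wave into a normalized BSPiM.  The
#' per-run P-wave window is `[0, max LAT + tail_ms]`.
#'
#' @param dataset An `activation_dataset`.
#' @param lead_field A [build_lead_field()] object (typically at the
#'   reduced electrode set).
#' @param ap_template An `ap_trace` used as the cell-level source waveform.
#' @param rng_seed Base seed; run `i` uses `rng_seed + i`.
#' @param power_ratio Signal-to-noise power ratio (`NULL` for noise-free).
#' @param window,order Savitzky-Golay parameters.
#' @param tail_ms Window tail after the latest activation (ms).  The P-wave
#'   window `[0, max LAT + tail_ms]` covers the depolarization sequence; a
#'   window long enough to contain every vertex's full action potential
#'   would make the integral map independent of the activation sequence
#'   (the time integral of a shifted template is shift-invariant), so the
#'   tail is kept short.
#' @return Matrix runs x electrodes of normalized BSPiM features.
#' @export
bspim_features <- function(dataset, lead_field, ap_template, rng_seed = 1,
                           power_ratio = 3, window = 21, order = 3,
                           tail_ms = 10) {
  n <- ncol(dataset$lat)
  ne <- nrow(lead_field$L)
  X <- matrix(NA_real_, n, ne)
  for (i in seq_len(n)) {
    lat <- dataset$lat[, i]
    vm <- synthesize_transmembrane(
      lat, ap_template,
      window_ms = c(0, max(lat, na.rm = TRUE) + tail_ms),
      attenuation = dataset$attenuation[, i])
    b <- compute_bspm(lead_field, vm)
    if (!is.null(power_ratio))
      b <- smooth_bspm(add_noise(b, rng_seed + i, power_ratio),
                       window, order)
    X[i, ] <- as.numeric(integrate_pwave(b))
  }
  rownames(X) <- dataset$manifest$run[!dataset$manifest$excluded]
  X
}
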