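# Spectral decomposition of swim bouts. Each tail-segment waveform in a
# temporal window around the bout (150 ms free / 300 ms restrained) is
# Bessel band-pass filtered (0.5-100 Hz), transformed with the DFT, and
# converted to a single-sided RMS amplitude spectrum:
#   X_k = sum_n x_n e^{-i 2 pi n k / N},  A_k = X_k / N,
#   B_0 = A_0,  B_k = 2 A_k (k = 1 .. N/2 - 1),  Bmag = |B_k|.
# The five per-segment spectra are summed, spline-interpolated, and the
# low-frequency (turn component) and high-frequency (tail-beat) peaks are
# read off the interpolated sum spectrum. The Direction Index is the mean
# interpolated sum-spectrum amplitude at 3, 4 and 5 Hz, signed by the time
# integral of the mean tail angle.

#' Spectrum analysis configuration
#'
#' @param mode `"free"` (150 ms window) or `"restrained"` (300 ms).
#' @param fs sampling rate of the tail-angle traces, Hz.
#' @param window_ms analysis window length; default set by `mode`.
#' @param band band-pass edges c(low, high), Hz.
#' @param grid_step_hz interpolation grid step.
#' @param lf_band,hf_band search bands for the low- and high-frequency
#'   peaks, Hz.
#' @param di_freqs frequencies averaged for the Direction Index, Hz.
#' @param filter_order Bessel filter order.
#' @return a `spectrum_config` list; `N` is the window length in samples
#'   (`round(window_ms * fs / 1000)`).
#' @export
spectrum_config <- function(mode = c("free", "restrained"), fs = 500,
                            window_ms = NULL, band = c(0.5, 100),
                            grid_step_hz = 0.1, lf_band = c(2, 8),
                            hf_band = c(15, 45), di_freqs = c(3, 4, 5),
                            filter_order = 4) {
  mode <- match.arg(mode)
  if (is.null(window_ms))
    window_ms <- if (mode == "free") 150 else 300
  if (band[2] >= fs / 2) stop("band edge at or above Nyquist")
  cfg <- list(mode = mode, fs = fs, window_ms = window_ms,
              N = as.integer(round(window_ms * fs / 1000)),
              band = band, grid_step_hz = grid_step_hz,
              lf_band = lf_band, hf_band = hf_band, di_freqs = di_freqs,
              filter_order = filter_order)
  class(cfg) <- "spectrum_config"
  cfg
}

# analog Bessel low-pass prototype of the given order, -3 dB at w = 1
bessel_prototype <- function(order = 4) {
  # reversed Bessel polynomial coefficients by the recurrence
  # theta_n(s) = (2n-1) theta_{n-1}(s) + s^2 theta_{n-2}(s)
  th <- list(c(1), c(1, 1))  # ascending powers
  if (order >= 2) for (n in 2:order) {
    a <- (2 * n - 1) * th[[n]]
    b <- c(0, 0, th[[n - 1]])
    len <- max(length(a), length(b))
    th[[n + 1]] <- c(a, numeric(len - length(a))) +
      c(b, numeric(len - length(b)))
  }
  coefs <- th[[order + 1]]
  p <- polyroot(coefs)
  k0 <- coefs[1]
  H <- function(w) abs(k0 / Reduce(`*`, lapply(p, function(pp) 1i * w - pp)))
  w3 <- stats::uniroot(function(w) H(w) - 1 / sqrt(2), c(0.05, 20))$root
  pn <- p / w3
  signal::Zpg(zero = complex(0), pole = pn, gain = Re(prod(-pn)))
}

#' Zero-phase Bessel band-pass filter
#'
#' Designs a digital Bessel band-pass (bilinear transform of the analog
#' prototype with prewarped edges) and applies it forward-backward
#' (zero phase), which preserves the sign of the tail-angle integral and
#' the timing of oscillation cycles.
#'
#' @param x numeric trace.
#' @param cfg a [spectrum_config()].
#' @return filtered trace, same length as `x`.
#' @export
bandpass <- function(x, cfg) {
  if (cfg$band[2] >= cfg$fs / 2) stop("cutoff at or above Nyquist")
  proto <- bessel_prototype(cfg$filter_order)
  T <- 2
  warp <- function(f) 2 / T * tan(pi * f / cfg$fs)
  bp <- signal::sftrans(proto, W = c(warp(cfg$band[1]), warp(cfg$band[2])),
                        stop = FALSE)
  dig <- signal::bilinear(bp, T = T)
  arma <- signal::as.Arma(dig)
  signal::filtfilt(arma, x)
}

#' Detect swim bouts in a uniformly sampled trace
#'
#' Onset at the first |x| threshold crossing; offset when |x| stays below
#' the threshold for `min_gap_ms`; events shorter than `min_duration_ms`
#' are discarded.
#'
#' @param x trace (tail angle or sensor voltage).
#' @param fs sampling rate, Hz.
#' @param threshold detection threshold on |x|.
#' @param min_duration_ms minimum event duration.
#' @param min_gap_ms quiet time required to close an event.
#' @return data.frame with `onset_ms`, `offset_ms` (possibly 0 rows).
#' @export
detect_bouts <- function(x, fs, threshold, min_duration_ms = 20,
                         min_gap_ms = 50) {
  dt <- 1000 / fs
  above <- abs(x) >= threshold
  n <- length(x)
  gap_n <- max(1L, ceiling(min_gap_ms / dt))
  events <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0))
  i <- 1L
  while (i <= n) {
    if (!above[i]) { i <- i + 1L; next }
    onset <- i
    last_above <- i
    j <- i + 1L
    while (j <= n) {
      if (above[j]) {
        last_above <- j
      } else if (j - last_above >= gap_n) break
      j <- j + 1L
    }
    offset <- last_above
    dur <- (offset - onset) * dt
    if (dur >= min_duration_ms)
      events <- rbind(events, data.frame(onset_ms = (onset - 1) * dt,
                                         offset_ms = (offset - 1) * dt))
    i <- j + 1L
  }
  events
}

#' Single-sided RMS amplitude spectrum of one windowed trace
#'
#' Direct implementation of the DFT-based definition:
#' `X_k = sum x_n exp(-i 2 pi n k / N)`, `A_k = X_k / N`, `B_0 = A_0`,
#' `B_k = 2 A_k` for `k = 1 .. N/2 - 1`, returning `|B_k|` on the native
#' bin grid `k fs / N`.
#'
#' @param x windowed trace of length `cfg$N`.
#' @param cfg a [spectrum_config()].
#' @return data.frame with `freq_hz`, `bmag`.
#' @export
rms_spectrum <- function(x, cfg) {
  N <- length(x)
  if (N < 8) stop("window too short")
  if (N != cfg$N) stop("window length does not match cfg$N")
  X <- stats::fft(x)
  A <- X / N
  kmax <- N %/% 2 - 1
  B <- c(A[1], 2 * A[2:(kmax + 1)])
  data.frame(freq_hz = (0:kmax) * cfg$fs / N, bmag = Mod(B))
}

#' Summed, interpolated bout spectrum with LF/HF peaks
#'
#' Band-passes each of the five tail-segment windowed traces, computes the
#' per-segment single-sided RMS amplitude spectra, sums them, interpolates
#' the sum with a cubic spline onto a fine grid, and locates the
#' low-frequency and high-frequency peaks in their search bands.
#'
#' @param gammas N x 5 matrix of windowed tail-segment traces (degrees).
#' @param cfg a [spectrum_config()].
#' @param filter apply the Bessel band-pass before the DFT.
#' @return a `bout_spectrum` list: `freq_hz`, `per_segment` (matrix),
#'   `sum`, interpolated `grid_hz`/`sum_interp`, `lf` and `hf` peaks
#'   (each `c(freq_hz, amp)`), `undefined` flag for all-zero input.
#' @export
summed_spectrum <- function(gammas, cfg, filter = TRUE) {
  stopifnot(ncol(gammas) == 5)
  if (nrow(gammas) != cfg$N) stop("window length does not match cfg$N")
  if (all(gammas == 0)) {
    return(structure(list(undefined = TRUE), class = "bout_spectrum"))
  }
  spec <- NULL
  per <- matrix(0, cfg$N %/% 2, 5)
  for (i in 1:5) {
    tr <- gammas[, i]
    if (filter) tr <- bandpass(tr, cfg)
    sp <- rms_spectrum(tr, cfg)
    per[, i] <- sp$bmag
    spec <- sp$freq_hz
  }
  sum_spec <- rowSums(per)
  grid <- seq(0, min(cfg$band[2], max(spec)), by = cfg$grid_step_hz)
  interp <- stats::spline(spec, sum_spec, xout = grid, method = "natural")$y
  peak_in <- function(band) {
    sel <- grid >= band[1] & grid <= band[2]
    if (!any(sel)) return(c(NA_real_, NA_real_))
    i <- which.max(interp[sel])
    c(freq_hz = grid[sel][i], amp = interp[sel][i])
  }
  structure(list(freq_hz = spec, per_segment = per, sum = sum_spec,
                 grid_hz = grid, sum_interp = interp,
                 lf = peak_in(cfg$lf_band), hf = peak_in(cfg$hf_band),
                 undefined = FALSE),
            class = "bout_spectrum")
}

#' Direction Index of a bout
#'
#' `DI = sign(integral of the across-segment mean tail angle) *
#'  mean(interpolated sum spectrum at the DI frequencies)`. Positive DI:
#' target-directed (rightward for right-positive angles); a pure symmetric
#' oscillation yields DI = 0 up to numerical noise.
#'
#' @param gammas N x 5 matrix of windowed tail-segment traces.
#' @param spectrum a `bout_spectrum` computed from the same window.
#' @param cfg a [spectrum_config()].
#' @return signed DI, degrees.
#' @export
direction_index <- function(gammas, spectrum, cfg) {
  if (isTRUE(spectrum$undefined)) return(0)
  mean_trace <- rowMeans(gammas)
  integral <- sum(mean_trace) / cfg$fs
  s <- sign(integral)
  amps <- stats::approx(spectrum$grid_hz, spectrum$sum_interp,
                        xout = cfg$di_freqs)$y
  s * mean(amps)
}

#' Windowed tail traces around a bout
#'
#' Centers a window of `cfg$N` samples on the bout midpoint, clipping to
#' the series if needed (the window is shifted, not shortened).
#'
#' @param gammas full frames x 5 tail-angle matrix.
#' @param fs sampling rate, Hz.
#' @param onset_ms,offset_ms bout boundaries.
#' @param cfg a [spectrum_config()].
#' @return list with `idx` (row indices) and `gammas` (N x 5).
#' @export
bout_window <- function(gammas, fs, onset_ms, offset_ms, cfg) {
  if (nrow(gammas) < cfg$N)
    stop("series shorter than the analysis window")
  mid <- (onset_ms + offset_ms) / 2
  ctr <- round(mid / 1000 * fs) + 1
  half <- cfg$N %/% 2
  start <- max(1L, min(ctr - half, nrow(gammas) - cfg$N + 1L))
  idx <- start:(start + cfg$N - 1L)
  list(idx = idx, gammas = gammas[idx, , drop = FALSE])
}

#' Per-bout kinematic and spectral metrics
#'
#' Measures the net heading change, pre/post fish-target angles and
#' distances, spectrum, Direction Index, first-cycle duration and cycle
#' count for one detected bout.
#'
#' @param poses data.frame from [track_midline()] or equivalent with
#'   `theta_deg` and `gamma*_deg` columns.
#' @param geometry optional data.frame from [prey_geometry()] aligned with
#'   `poses` (for `phi_pre`, `phi_post`, `dd_mm`).
#' @param onset_ms,offset_ms bout window, ms.
#' @param fs frame rate, Hz.
#' @param cfg a [spectrum_config()].
#' @return a `swim_bout` list of metrics, including the `bout_spectrum`.
#' @export
bout_metrics <- function(poses, geometry = NULL, onset_ms, offset_ms, fs,
                         cfg) {
  n <- nrow(poses)
  i_on <- floor(onset_ms / 1000 * fs) + 1L   # last frame at/before onset
  i_off <- ceiling(offset_ms / 1000 * fs) + 1L
  if (i_on < 2L || i_off >= n) stop("bout at series edge")
  pre <- i_on - 1L
  post <- i_off + 1L
  dtheta <- poses$theta_deg[post] - poses$theta_deg[pre]

  gcols <- paste0("gamma", 1:5, "_deg")
  gam <- as.matrix(poses[, gcols])
  win <- bout_window(gam, fs, onset_ms, offset_ms, cfg)
  spec <- summed_spectrum(win$gammas, cfg)
  di <- direction_index(win$gammas, spec, cfg)

  # cycle metrics from the high-band mean tail angle within the bout
  hp_cfg <- cfg
  hp_cfg$band <- c(15, cfg$band[2])
  mean_tail <- rowMeans(gam)
  hp <- bandpass(mean_tail, hp_cfg)
  in_bout <- which(seq_len(n) >= i_on & seq_len(n) <= i_off)
  hb <- hp[in_bout]
  m <- max(abs(hb))
  cross_t <- numeric(0)
  if (m > 0) {
    sgn <- sign(hb)
    keep <- abs(hb) > 0.02 * m
    sgn2 <- sgn[keep]
    tt <- (in_bout[keep] - 1) * 1000 / fs
    ch <- which(diff(sgn2) != 0)
    cross_t <- tt[ch + 1]
  }
  n_cycles <- length(cross_t) %/% 2
  first_cycle_ms <- if (length(cross_t) >= 2)
    cross_t[2] - onset_ms else NA_real_

  phi_pre <- phi_post <- dd <- NA_real_
  if (!is.null(geometry)) {
    phi_pre <- geometry$phi_deg[pre]
    phi_post <- geometry$phi_deg[post]
    dd <- geometry$d_mm[pre] - geometry$d_mm[post]
  }
  structure(list(onset_ms = onset_ms, offset_ms = offset_ms,
                 dtheta_deg = dtheta, phi_pre_deg = phi_pre,
                 phi_post_deg = phi_post, DI = di,
                 lf_hz = spec$lf[1], lf_amp = spec$lf[2],
                 hf_hz = spec$hf[1], hf_amp = spec$hf[2],
                 first_cycle_ms = first_cycle_ms, n_cycles = n_cycles,
                 dd_mm = dd, spectrum = spec),
            class = "swim_bout")
}
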