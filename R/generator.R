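# Synthetic bout-kinematics generator. A swim bout is modeled as a
# symmetric tail oscillation (~20-35 Hz, ~3 cycles, smoothly enveloped)
# with a superimposed slow asymmetric turn component: a unimodal
# raised-cosine pulse confined to roughly the first tail-beat cycle. The
# heading trajectory is prescribed directly (no hydrodynamics) as the
# normalized integral of the turn pulse, so the net heading change is exact
# ground truth for recovery tests.

#' Parameters of the synthetic bout generator
#'
#' @param delta_theta signed net heading change of the bout, degrees
#'   (right-positive). The tail turn-component amplitude is
#'   `delta_theta * turn_scale`, so the asymmetric bend is graded with the
#'   turn angle.
#' @param f_osc tail-beat oscillation frequency, Hz (20-35 typical).
#' @param n_cycles number of oscillation cycles in the bout; the
#'   oscillation is active for `n_cycles / f_osc` seconds from bout onset
#'   under a raised-cosine envelope.
#' @param bout_ms bout duration in ms; default
#'   `max(150, n_cycles / f_osc * 1000)` (the slow turn deflection spans
#'   the whole bout, which typically outlasts the oscillation).
#' @param fs frame rate, Hz (250 or 500).
#' @param turn_pulse_ms width of the raised-cosine turn pulse, ms; default
#'   the bout duration, so the slow asymmetric deflection spans the bout
#'   and its spectral weight falls in the few-Hz range.
#' @param osc_amp oscillation amplitude at the tail tip, degrees.
#' @param turn_scale unitless gain from `delta_theta` to the tail tip turn
#'   amplitude.
#' @param segment_gains,turn_gains five non-decreasing rostro-caudal
#'   amplitude multipliers for the oscillation and turn components.
#' @param phase_lag_deg rostro-caudal oscillation phase lag per segment.
#' @param noise_sd kinematic noise added to tail angles inside the bout,
#'   degrees (sd).
#' @param theta0 initial heading, degrees.
#' @param body_length_mm,head_fraction body length and the arclength
#'   fraction taken by the head segment (snout to swim bladder proxy).
#' @param seed integer RNG seed.
#' @return a `generator_params` list, validated.
#' @export
generator_params <- function(delta_theta = 0, f_osc = 30, n_cycles = 3,
                             bout_ms = NULL, fs = 500,
                             turn_pulse_ms = NULL,
                             osc_amp = 25, turn_scale = 1,
                             segment_gains = c(0.25, 0.45, 0.65, 0.85, 1),
                             turn_gains = c(0.2, 0.4, 0.6, 0.8, 1),
                             phase_lag_deg = 20, noise_sd = 0,
                             theta0 = 0, body_length_mm = 4,
                             head_fraction = 0.3, seed = 1L) {
  if (is.null(bout_ms)) bout_ms <- max(150, n_cycles / f_osc * 1000)
  if (is.null(turn_pulse_ms)) turn_pulse_ms <- bout_ms
  p <- list(delta_theta = delta_theta, f_osc = f_osc, n_cycles = n_cycles,
            bout_ms = bout_ms, fs = fs, turn_pulse_ms = turn_pulse_ms,
            osc_amp = osc_amp, turn_scale = turn_scale,
            segment_gains = segment_gains, turn_gains = turn_gains,
            phase_lag_deg = phase_lag_deg, noise_sd = noise_sd,
            theta0 = theta0, body_length_mm = body_length_mm,
            head_fraction = head_fraction, seed = as.integer(seed))
  validate_generator_params(p)
  class(p) <- "generator_params"
  p
}

validate_generator_params <- function(p) {
  if (p$fs <= 2 * p$f_osc)
    stop("Nyquist violation: fs must exceed 2 * f_osc")
  if (p$bout_ms <= 0 || p$turn_pulse_ms <= 0)
    stop("durations must be positive")
  if (p$bout_ms < p$n_cycles / p$f_osc * 1000 - 1e-9)
    stop("bout_ms shorter than n_cycles / f_osc")
  if (length(p$segment_gains) != 5 || length(p$turn_gains) != 5)
    stop("segment_gains and turn_gains must have length 5")
  if (is.unsorted(p$segment_gains) || is.unsorted(p$turn_gains))
    stop("gains must be non-decreasing rostro-caudally")
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  invisible(p)
}

# raised-cosine pulse on [0, width], peak 1 at width/2
raised_cosine_pulse <- function(t_ms, width_ms) {
  p <- numeric(length(t_ms))
  inside <- t_ms >= 0 & t_ms <= width_ms
  p[inside] <- 0.5 * (1 - cos(2 * pi * t_ms[inside] / width_ms))
  p
}

# smooth on/off envelope over [0, dur]; cosine ramps of fraction `ramp`
# of the duration on each side. The default (0.5) is a full raised-cosine
# (Hann) envelope: the tail-beat amplitude waxes and wanes smoothly, and
# the C^2-smooth envelope keeps oscillation leakage out of the
# low-frequency bins of the bout spectrum.
bout_envelope <- function(t_ms, dur_ms, ramp = 0.5) {
  tau <- t_ms / dur_ms
  e <- numeric(length(tau))
  inside <- tau >= 0 & tau <= 1
  e[inside] <- 1
  lo <- inside & tau < ramp
  hi <- inside & tau > 1 - ramp
  e[lo] <- 0.5 * (1 - cos(pi * tau[lo] / ramp))
  e[hi] <- 0.5 * (1 - cos(pi * (1 - tau[hi]) / ramp))
  e
}

#' Generate ground-truth tail kinematics for one swim bout
#'
#' Tail segment angles are
#' `gamma_i(t) = turn_gains[i] * A_turn * P(t) +
#'  segment_gains[i] * osc_amp * sin(2 pi f_osc t + phi_i) * E(t) + noise`,
#' with `P` a raised-cosine pulse of width `turn_pulse_ms` starting at bout
#' onset, `E` a smooth on/off envelope over the bout, and `phi_i` a small
#' rostro-caudal phase lag. The heading ramps from `theta0` by
#' `delta_theta`, following the normalized integral of `P`, so
#' `theta(offset) - theta(onset) == delta_theta` exactly.
#'
#' @param params a [generator_params()] object.
#' @param pad_ms length-2 quiescent padding (before, after) in ms.
#' @return a `ground_truth` list: `t_ms`, `gamma` (frames x 5, degrees),
#'   `theta` (degrees per frame), `onset_ms`, `offset_ms`, `head_center_mm`
#'   (frames x 2), `params`.
#' @export
gen_bout_kinematics <- function(params, pad_ms = c(0, 0)) {
  validate_generator_params(params)
  if (any(pad_ms < 0)) stop("negative durations")
  dt <- 1000 / params$fs
  total_ms <- pad_ms[1] + params$bout_ms + pad_ms[2]
  n <- max(2L, floor(total_ms / dt + 1e-9))
  t_ms <- (seq_len(n) - 1) * dt
  tb <- t_ms - pad_ms[1]                     # time since bout onset

  A_turn <- params$delta_theta * params$turn_scale
  P <- raised_cosine_pulse(tb, params$turn_pulse_ms)
  osc_ms <- params$n_cycles / params$f_osc * 1000
  E <- bout_envelope(tb, osc_ms)
  in_bout <- tb >= 0 & tb <= params$bout_ms

  # kinematic noise drawn under the local bout seed so generation is
  # deterministic without disturbing the caller's RNG stream
  noise <- if (params$noise_sd > 0)
    with_seed(params$seed,
              matrix(rnorm(sum(in_bout) * 5, 0, params$noise_sd),
                     sum(in_bout), 5))
  gamma <- matrix(0, n, 5)
  for (i in 1:5) {
    phi_i <- -deg2rad((i - 1) * params$phase_lag_deg)
    osc <- params$segment_gains[i] * params$osc_amp *
      sin(2 * pi * params$f_osc * tb / 1000 + phi_i) * E
    trn <- params$turn_gains[i] * A_turn * P
    g <- trn + osc
    if (params$noise_sd > 0)
      g[in_bout] <- g[in_bout] + noise[, i]
    gamma[, i] <- g
  }

  # heading follows the normalized cumulative integral of the pulse
  ramp <- cumsum(P)
  ramp <- if (max(ramp) > 0) ramp / max(ramp) else ramp
  ramp[tb < 0] <- 0
  theta <- params$theta0 + params$delta_theta * ramp

  truth <- list(t_ms = t_ms, gamma = gamma, theta = theta,
                onset_ms = pad_ms[1], offset_ms = pad_ms[1] + params$bout_ms,
                head_center_mm = matrix(0, n, 2),
                params = params, seed = params$seed)
  class(truth) <- "ground_truth"
  truth
}

#' Synthesize the 1 kHz tail position-sensor trace
#'
#' Projects the lateral displacement of the tail tip (relative to the body
#' axis) implied by the ground-truth tail angles, resamples it to the
#' sensor rate and adds Gaussian noise, emulating the photodetector voltage
#' used for real-time swim detection.
#'
#' @param truth a `ground_truth` object.
#' @param gain volts per mm of tip displacement.
#' @param noise_sd sensor noise sd, volts.
#' @param fs_out sensor sampling rate, Hz.
#' @param seed RNG seed for the sensor noise.
#' @return data.frame with `time_ms`, `voltage`.
#' @export
gen_psd_trace <- function(truth, gain = 1, noise_sd = 0.01, fs_out = 1000,
                          seed = truth$seed + 1L) {
  p <- truth$params
  if (fs_out <= 2 * p$f_osc) stop("fs_out below Nyquist for f_osc")
  seg_mm <- (1 - p$head_fraction) * p$body_length_mm / 5
  tip_mm <- rowSums(sin(deg2rad(truth$gamma))) * seg_mm
  t_out <- seq(0, max(truth$t_ms), by = 1000 / fs_out)
  v <- stats::approx(truth$t_ms, tip_mm, xout = t_out, rule = 2)$y * gain
  if (noise_sd > 0)
    v <- v + with_seed(seed, rnorm(length(v), 0, noise_sd))
  data.frame(time_ms = t_out, voltage = v)
}

#' Generate a full capture-like sequence of swim bouts
#'
#' Chains bouts separated by a scheduled series of inter-bout intervals.
#' Each bout's true heading change is `undershoot * phi_pre` computed from
#' the current simulated fish-prey geometry, so heading and position
#' integrate across bouts exactly. The eye-angle schedule implements the
#' two-step convergence pattern (contralateral eye near-maximal after the
#' first bout, both eyes maximal after the second).
#'
#' @param n_bouts number of bouts (>= 1).
#' @param ibi_ms inter-bout intervals, ms, length `n_bouts - 1`.
#' @param undershoot fraction of the fish-prey angle corrected per bout.
#' @param prey_mm prey position c(x, y) in mm (arena frame; fish starts at
#'   the origin heading along +x), or a frames x 2 matrix for moving prey.
#' @param advance_mm forward advance per bout (scalar or per-bout vector).
#' @param eye_schedule optional data.frame with `contra`, `ipsi` angles
#'   (degrees, nasal-positive) at each bout boundary (length `n_bouts + 1`);
#'   default follows the measured two-step convergence levels.
#' @param params_template [generator_params()] supplying bout shape; its
#'   `delta_theta` is overridden per bout.
#' @param pre_ms,post_ms quiescent time before the first and after the last
#'   bout.
#' @param seed RNG seed.
#' @return a `ground_truth` list as in [gen_bout_kinematics()], plus
#'   `bouts` (data.frame: onset/offset ms, delta_theta_true, phi_pre,
#'   phi_post, advance_mm), `ibi_ms`, `eye_course`, `prey_mm` (frames x 2).
#' @export
gen_capture_sequence <- function(n_bouts, ibi_ms, undershoot = 0.9,
                                 prey_mm = c(4, 3), advance_mm = 0,
                                 eye_schedule = NULL,
                                 params_template = generator_params(),
                                 pre_ms = 100, post_ms = 100, seed = 1L) {
  if (n_bouts < 1) stop("n_bouts must be >= 1")
  if (length(ibi_ms) != max(0, n_bouts - 1))
    stop("ibi_ms must have length n_bouts - 1")
  if (any(ibi_ms <= 0)) stop("IBIs must be positive")
  advance_mm <- rep_len(advance_mm, n_bouts)
  p <- params_template
  dt <- 1000 / p$fs

  if (is.null(eye_schedule)) {
    contra <- c(13.1, rep(30.6, n_bouts))
    ipsi <- c(15.4, if (n_bouts >= 1) 24, rep(32.5, max(0, n_bouts - 1)))
    eye_schedule <- data.frame(contra = contra[seq_len(n_bouts + 1)],
                               ipsi = ipsi[seq_len(n_bouts + 1)])
  }

  head_xy <- c(0, 0)
  theta <- p$theta0
  prey_static <- is.null(dim(prey_mm))

  seg_t <- list(); seg_gamma <- list(); seg_theta <- list()
  seg_head <- list()
  bouts <- data.frame()
  t_cursor <- 0

  add_quiet <- function(dur_ms) {
    nq <- floor(dur_ms / dt + 1e-9)
    if (nq <= 0) return(invisible(NULL))
    seg_t[[length(seg_t) + 1]] <<- t_cursor + (seq_len(nq) - 1) * dt
    seg_gamma[[length(seg_gamma) + 1]] <<- matrix(0, nq, 5)
    seg_theta[[length(seg_theta) + 1]] <<- rep(theta, nq)
    seg_head[[length(seg_head) + 1]] <<-
      matrix(head_xy, nq, 2, byrow = TRUE)
    t_cursor <<- t_cursor + nq * dt
  }

  phi_to_prey <- function() {
    u <- c(cos(deg2rad(theta)), sin(deg2rad(theta)))
    w <- prey_now() - head_xy
    signed_angle(u, w)
  }
  prey_now <- function() if (prey_static) prey_mm else
    prey_mm[min(nrow(prey_mm), floor(t_cursor / dt) + 1), ]

  add_quiet(pre_ms)
  for (b in seq_len(n_bouts)) {
    phi_pre <- phi_to_prey()
    dth <- undershoot * phi_pre
    bp <- p
    bp$delta_theta <- dth
    bp$seed <- as.integer(seed + b)
    bout <- gen_bout_kinematics(bp)
    nb <- length(bout$t_ms)
    onset <- t_cursor
    seg_t[[length(seg_t) + 1]] <- t_cursor + bout$t_ms
    seg_gamma[[length(seg_gamma) + 1]] <- bout$gamma
    seg_theta[[length(seg_theta) + 1]] <- bout$theta
    # advance along the evolving heading during the bout
    u_new <- cbind(cos(deg2rad(bout$theta)), sin(deg2rad(bout$theta)))
    step <- advance_mm[b] / nb
    disp <- apply(u_new * step, 2, cumsum)
    seg_head[[length(seg_head) + 1]] <-
      sweep(disp, 2, head_xy, "+")
    head_xy <- head_xy + disp[nb, ]
    theta <- theta + dth
    t_cursor <- t_cursor + nb * dt
    phi_post <- phi_to_prey()
    bouts <- rbind(bouts, data.frame(
      bout = b, onset_ms = onset, offset_ms = onset + bp$bout_ms,
      delta_theta_true = dth, phi_pre = phi_pre, phi_post = phi_post,
      advance_mm = advance_mm[b]))
    if (b < n_bouts) add_quiet(ibi_ms[b])
  }
  add_quiet(post_ms)

  t_ms <- unlist(seg_t)
  n <- length(t_ms)
  prey_traj <- if (prey_static)
    matrix(prey_mm, n, 2, byrow = TRUE) else prey_mm[seq_len(n), ]

  truth <- list(
    t_ms = t_ms,
    gamma = do.call(rbind, seg_gamma),
    theta = unlist(seg_theta),
    head_center_mm = do.call(rbind, seg_head),
    prey_mm = prey_traj,
    bouts = bouts, ibi_ms = ibi_ms,
    eye_course = eye_schedule,
    onset_ms = bouts$onset_ms[1], offset_ms = bouts$offset_ms[n_bouts],
    params = p, seed = as.integer(seed))
  class(truth) <- "ground_truth"
  truth
}
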