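# Discrete-event simulation of the closed-loop virtual-reality stimulus
# paradigm: a small rectangular target sweeps a peripheral zone; detection
# of a swim (after the intrinsic detection latency) triggers a fast
# translation of target and background to an update location near the
# visual-field center; depending on the paradigm the target is then held
# until the swim ends and resumes motion toward the contralateral
# hemifield (with optional per-bout size/velocity escalation), or it is
# hidden and reappears at the center after a configured delay. Simulated
# time is event-driven at 1 ms resolution. A pluggable responder agent
# closes the loop.

#' Closed-loop stimulus configuration
#'
#' @param paradigm `"open_loop"`, `"sequence"`, `"hold_until_swim_end"`,
#'   or `"delayed_reappearance"`.
#' @param zone_deg peripheral sweep zone, degrees (e.g. c(30, 50)).
#' @param size_deg target width, degrees (height = width / 2).
#' @param velocity_dps target angular velocity, deg/s.
#' @param update_location_deg post-swim update position, in [-10, 10].
#' @param update_velocity_dps translation speed, deg/s (~400).
#' @param update_delay_ms delay of stimulus reappearance after swim onset
#'   (delayed_reappearance paradigm), ms.
#' @param escalation optional data.frame with `size_deg`, `velocity_dps`
#'   applied after each bout (row k after the k-th swim).
#' @param timeout_s no-response trial abort time, s.
#' @param response_window_s open-loop response-probability observation
#'   interval, s (exposed separately from `timeout_s`).
#' @param detection_latency_ms intrinsic swim-detection delay, ms.
#' @param sensor_fs sensor sampling rate, Hz.
#' @param max_bouts stop the trial after this many swims.
#' @return a `stimulus_config` list.
#' @export
stimulus_config <- function(paradigm = c("sequence", "open_loop",
                                         "hold_until_swim_end",
                                         "delayed_reappearance"),
                            zone_deg = c(30, 50), size_deg = 2,
                            velocity_dps = 20, update_location_deg = -10,
                            update_velocity_dps = 400,
                            update_delay_ms = 0, escalation = NULL,
                            timeout_s = 56, response_window_s = 60,
                            detection_latency_ms = 40, sensor_fs = 1000,
                            max_bouts = 6) {
  paradigm <- match.arg(paradigm)
  if (abs(update_location_deg) > 10)
    stop("update location outside +/-10 degrees")
  if (any(zone_deg < 0) || any(zone_deg > 90)) stop("zone outside [0, 90]")
  if (timeout_s <= 0) stop("timeout must be positive")
  cfg <- list(paradigm = paradigm, zone_deg = zone_deg, size_deg = size_deg,
              velocity_dps = velocity_dps,
              update_location_deg = update_location_deg,
              update_velocity_dps = update_velocity_dps,
              update_delay_ms = update_delay_ms, escalation = escalation,
              timeout_s = timeout_s, response_window_s = response_window_s,
              detection_latency_ms = detection_latency_ms,
              sensor_fs = sensor_fs, max_bouts = max_bouts)
  class(cfg) <- "stimulus_config"
  cfg
}

#' Online (causal) swim detection from a sensor stream
#'
#' Onset at the first sample with |V| >= threshold; end when |V| stays
#' below the threshold continuously for `quiet_window_ms` (the end
#' timestamp is the start of that quiet window). Uses no future samples
#' beyond the quiet window.
#'
#' @param voltage sensor samples.
#' @param fs sampling rate, Hz.
#' @param threshold detection threshold, volts.
#' @param quiet_window_ms quiet time closing an event.
#' @return data.frame with `onset_ms`, `end_ms`.
#' @export
detect_swim_online <- function(voltage, fs = 1000, threshold,
                               quiet_window_ms = 50) {
  ev <- detect_bouts(voltage, fs, threshold, min_duration_ms = 0,
                     min_gap_ms = quiet_window_ms)
  if (!nrow(ev)) return(data.frame(onset_ms = numeric(0),
                                   end_ms = numeric(0)))
  data.frame(onset_ms = ev$onset_ms, end_ms = ev$offset_ms)
}

#' Parameterized responder agent
#'
#' Returns a function mapping the current stimulus state to a swim
#' decision, emulating a larva whose reaction time shortens for central
#' update locations, for reappearance timed near the end of the previous
#' swim, and for larger/faster stimuli.
#'
#' @param base_rt_ms baseline reaction time from stimulus onset.
#' @param loc_coef_ms_per_deg RT penalty per degree of |update location|.
#' @param delay_coef_ms_per_ms RT penalty per ms of |delta-t| (timing
#'   mismatch between reappearance and previous swim end).
#' @param size_gain_ms,velocity_gain_ms RT reduction per degree of target
#'   size / per deg/s of velocity above the baseline 2 degrees, 20 deg/s.
#' @param rt_noise_sd_ms Gaussian RT noise.
#' @param swim_duration_ms emitted swim duration.
#' @param p_respond probability of responding at all; may be a function
#'   of (size_deg, velocity_dps).
#' @return a responder closure used by [run_trial()].
#' @export
responder_agent <- function(base_rt_ms = 400, loc_coef_ms_per_deg = 15,
                            delay_coef_ms_per_ms = 0.8,
                            size_gain_ms = 30, velocity_gain_ms = 3,
                            rt_noise_sd_ms = 0, swim_duration_ms = 150,
                            p_respond = 1) {
  function(state) {
    p <- if (is.function(p_respond))
      p_respond(state$size_deg, state$velocity_dps) else p_respond
    if (runif(1) > p) return(NULL)
    rt <- base_rt_ms +
      loc_coef_ms_per_deg * abs(state$update_location_deg) * state$is_update +
      delay_coef_ms_per_ms * abs(state$dt_ms) * state$is_update -
      size_gain_ms * (state$size_deg - 2) -
      velocity_gain_ms * (state$velocity_dps - 20)
    if (rt_noise_sd_ms > 0) rt <- rt + rnorm(1, 0, rt_noise_sd_ms)
    rt <- max(30, rt)
    list(rt_ms = round(rt), duration_ms = swim_duration_ms)
  }
}

log_event <- function(log, t_ms, event, pos = NA, size = NA, vel = NA,
                      reason = NA) {
  rbind(log, data.frame(t_ms = t_ms, event = event, pos_deg = pos,
                        size_deg = size, velocity_dps = vel,
                        reason = reason, stringsAsFactors = FALSE))
}

#' Run one closed-loop trial
#'
#' Simulates the stimulus state machine with a responder agent and
#' returns a time-stamped event log. All transitions are causal: a
#' stimulus update never precedes its triggering swim onset plus the
#' detection latency.
#'
#' @param cfg a [stimulus_config()].
#' @param responder a closure from [responder_agent()].
#' @param seed RNG seed.
#' @return a `trial_log` list: `events` (data.frame), `cfg`, `seed`.
#' @export
run_trial <- function(cfg, responder, seed = 1L) {
  with_seed(seed, run_trial_impl(cfg, responder, seed))
}

run_trial_impl <- function(cfg, responder, seed) {
  side <- if (seed %% 2 == 0) -1 else 1   # interspersed left/right trials
  log <- data.frame()
  t <- 0
  timeout_ms <- cfg$timeout_s * 1000
  n_swims <- 0
  size <- cfg$size_deg; vel <- cfg$velocity_dps
  pos <- side * cfg$zone_deg[1]
  log <- log_event(log, t, "stimulus_on", pos, size, vel)

  escalate <- function(k) {
    if (!is.null(cfg$escalation) && k <= nrow(cfg$escalation)) {
      size <<- cfg$escalation$size_deg[k]
      vel <<- cfg$escalation$velocity_dps[k]
    }
  }

  repeat {
    # WAIT: target sweeps; ask the responder
    state <- list(size_deg = size, velocity_dps = vel,
                  update_location_deg = cfg$update_location_deg,
                  dt_ms = 0, is_update = as.integer(n_swims > 0),
                  pos_deg = pos, n_swims = n_swims)
    dec <- responder(state)
    if (is.null(dec)) {
      log <- log_event(log, timeout_ms, "trial_end", reason = "timeout")
      break
    }
    onset <- t + dec$rt_ms
    if (onset >= timeout_ms) {
      log <- log_event(log, timeout_ms, "trial_end", reason = "timeout")
      break
    }
    # stimulus position at the moment of the swim: bouncing sweep inside
    # the peripheral zone before the first swim, afterwards constant
    # velocity from the update location toward the contralateral periphery
    pos_at <- if (n_swims == 0)
      sweep_position(pos, vel, onset - t, cfg$zone_deg, side)
    else
      pmax(pmin(pos + side * vel * (onset - t) / 1000, 70), -70)
    swim_end <- onset + dec$duration_ms
    n_swims <- n_swims + 1
    log <- log_event(log, onset, "swim_onset", pos_at)
    log <- log_event(log, swim_end, "swim_end")

    if (cfg$paradigm == "open_loop") {
      log <- log_event(log, swim_end, "trial_end", reason = "swim")
      break
    }
    if (n_swims >= cfg$max_bouts) {
      log <- log_event(log, swim_end, "trial_end", reason = "max_bouts")
      break
    }

    trig <- onset + cfg$detection_latency_ms
    if (cfg$paradigm == "delayed_reappearance") {
      # translate to center, hide, reappear at onset + configured delay
      dist <- abs(pos_at - 0)
      tdur <- dist / cfg$update_velocity_dps * 1000
      log <- log_event(log, trig, "translation_start", pos_at)
      log <- log_event(log, trig + tdur, "translation_end", 0)
      log <- log_event(log, trig + tdur, "stimulus_hidden")
      reappear <- onset + cfg$update_delay_ms
      log <- log_event(log, reappear, "stimulus_reappear", 0, size, vel)
      dt_real <- reappear - swim_end
      state2 <- list(size_deg = size, velocity_dps = vel,
                     update_location_deg = 0, dt_ms = dt_real,
                     is_update = 1L, pos_deg = 0, n_swims = n_swims)
      dec2 <- responder(state2)
      if (is.null(dec2)) {
        log <- log_event(log, timeout_ms, "trial_end", reason = "timeout")
        break
      }
      onset2 <- reappear + dec2$rt_ms
      log <- log_event(log, onset2, "swim_onset", 0)
      log <- log_event(log, onset2 + dec2$duration_ms, "swim_end")
      log <- log_event(log, onset2 + dec2$duration_ms, "trial_end",
                       reason = "second_swim")
      break
    }

    # sequence / hold_until_swim_end: translate to the update location,
    # hold until swim end, then resume motion into the contralateral field
    # update-location convention: negative = undershoot (short of the
    # midline, original side), positive = overshoot (beyond the midline)
    target <- -side * cfg$update_location_deg
    dist <- abs(pos_at - target)
    tdur <- dist / cfg$update_velocity_dps * 1000
    log <- log_event(log, trig, "translation_start", pos_at)
    log <- log_event(log, trig + tdur, "translation_end", target)
    hold_until <- max(swim_end, trig + tdur)
    escalate(n_swims)
    log <- log_event(log, hold_until, "stimulus_resume", target, size, vel)
    t <- hold_until
    pos <- target
    side <- -side   # stimulus now moves into the contralateral hemifield
  }
  log <- log[order(log$t_ms), ]
  rownames(log) <- NULL
  structure(list(events = log, cfg = cfg, seed = seed), class = "trial_log")
}

# position of a target sweeping back and forth inside the zone
sweep_position <- function(start_pos, vel, elapsed_ms, zone, side) {
  lo <- min(zone); hi <- max(zone)
  width <- hi - lo
  if (width <= 0 || vel <= 0) return(start_pos)
  x <- abs(start_pos) - lo + vel * elapsed_ms / 1000
  cyc <- x %% (2 * width)
  p <- if (cyc <= width) lo + cyc else hi - (cyc - width)
  sign(start_pos) * p
}

#' Timing measures of a trial log
#'
#' `IBI = onset(2nd swim) - end(1st swim)`; `RT = onset(2nd swim) -
#' stimulus reappearance`; `delta_t = reappearance - end(1st swim)`
#' (negative when the stimulus reappears before the swim ends). The
#' identity `delta_t = IBI - RT` holds whenever all three are defined.
#'
#' @param log a `trial_log`.
#' @return list with `ibi_ms`, `rt_ms`, `dt_ms` (NA where undefined).
#' @export
measure_timing <- function(log) {
  ev <- log$events
  onsets <- ev$t_ms[ev$event == "swim_onset"]
  ends <- ev$t_ms[ev$event == "swim_end"]
  reap <- ev$t_ms[ev$event == "stimulus_reappear"]
  ibi <- if (length(onsets) >= 2 && length(ends) >= 1)
    onsets[2] - ends[1] else NA_real_
  dt <- if (length(reap) >= 1 && length(ends) >= 1)
    reap[1] - ends[1] else NA_real_
  rt <- if (length(reap) >= 1 && length(onsets) >= 2)
    onsets[2] - reap[1] else NA_real_
  list(ibi_ms = ibi, rt_ms = rt, dt_ms = dt)
}

#' Response-probability grid over size and velocity levels
#'
#' Runs open-loop trials for each (size, velocity) condition and tabulates
#' the fraction of trials with at least one swim within the response
#' window.
#'
#' @param sizes_deg,velocities_dps condition levels.
#' @param n_trials trials per condition.
#' @param responder a [responder_agent()] closure.
#' @param cfg base [stimulus_config()] (paradigm forced to open_loop).
#' @param seed RNG seed.
#' @return data.frame: `size_deg`, `velocity_dps`, `n`, `n_resp`, `p`.
#' @export
run_grid <- function(sizes_deg, velocities_dps, n_trials, responder,
                     cfg = stimulus_config("open_loop"), seed = 1L) {
  if (n_trials < 1) stop("need at least one trial")
  cfg$paradigm <- "open_loop"
  cfg$timeout_s <- cfg$response_window_s
  out <- data.frame()
  k <- 0
  for (s in sizes_deg) for (v in velocities_dps) {
    cfg$size_deg <- s; cfg$velocity_dps <- v
    resp <- 0
    for (tr in seq_len(n_trials)) {
      k <- k + 1
      log <- run_trial(cfg, responder, seed = seed + k)
      if (any(log$events$event == "swim_onset")) resp <- resp + 1
    }
    out <- rbind(out, data.frame(size_deg = s, velocity_dps = v,
                                 n = n_trials, n_resp = resp,
                                 p = resp / n_trials))
  }
  out
}

#' Write a trial log as JSON lines
#' @param log a `trial_log`.
#' @param path output file (one event per line).
#' @export
write_trial_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(log$events))) {
    writeLines(jsonlite::toJSON(as.list(log$events[i, ]),
                                auto_unbox = TRUE, na = "null"), con)
  }
  invisible(path)
}
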