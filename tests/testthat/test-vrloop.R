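never <- function(state) NULL

test_that("online swim detection is causal and accurate", {
  expect_identical(nrow(detect_swim_online(rep(0.01, 2000), 1000,
                                           threshold = 0.1)), 0L)
  p <- generator_params(delta_theta = 20, seed = 3)
  tr <- gen_bout_kinematics(p, pad_ms = c(200, 200))
  psd <- gen_psd_trace(tr, gain = 2, noise_sd = 0.001, seed = 13)
  ev <- detect_swim_online(psd$voltage, 1000, threshold = 0.005,
                           quiet_window_ms = 50)
  expect_identical(nrow(ev), 1L)
  expect_lte(abs(ev$onset_ms[1] - tr$onset_ms), 5)
  # two bursts with a 300 ms gap
  t <- 0:1999
  v <- ifelse((t >= 300 & t <= 450) | (t >= 750 & t <= 900),
              sin(2 * pi * 30 * t / 1000), 0)
  ev2 <- detect_swim_online(v, 1000, threshold = 0.05, quiet_window_ms = 50)
  expect_identical(nrow(ev2), 2L)
})

test_that("a non-responding trial times out at the configured abort time", {
  cfg <- stimulus_config("sequence")
  log <- run_trial(cfg, never, seed = 1)
  ev <- log$events
  end <- ev[ev$event == "trial_end", ]
  expect_identical(end$reason, "timeout")
  expect_equal(end$t_ms, 56 * 1000)
})

test_that("translation kinematics follow the update velocity exactly", {
  # stimulus reaches 50 deg after 1 s of 20 deg/s sweep from 30 deg;
  # overshoot update (+10) sends the target to -10: 60 deg at 400 deg/s
  cfg <- stimulus_config("sequence", update_location_deg = 10,
                         update_velocity_dps = 400, max_bouts = 2)
  resp <- responder_agent(base_rt_ms = 1000, loc_coef_ms_per_deg = 0,
                          swim_duration_ms = 150)
  log <- run_trial(cfg, resp, seed = 1)   # odd seed: right-side trial
  ev <- log$events
  ts <- ev[ev$event == "translation_start", ][1, ]
  te <- ev[ev$event == "translation_end", ][1, ]
  expect_equal(ts$pos_deg, 50)
  expect_equal(te$pos_deg, -10)
  expect_equal(te$t_ms - ts$t_ms, 60 / 400 * 1000)   # 150 ms
  # causality: translation starts detection_latency after swim onset
  onset <- ev$t_ms[ev$event == "swim_onset"][1]
  expect_equal(ts$t_ms, onset + cfg$detection_latency_ms)
})

test_that("delayed reappearance occurs exactly at onset plus delay", {
  cfg <- stimulus_config("delayed_reappearance", update_delay_ms = 300)
  resp <- responder_agent(base_rt_ms = 400)
  log <- run_trial(cfg, resp, seed = 2)
  ev <- log$events
  onset1 <- ev$t_ms[ev$event == "swim_onset"][1]
  reap <- ev$t_ms[ev$event == "stimulus_reappear"][1]
  expect_equal(reap, onset1 + 300)
  # no visible target between hide and reappear
  hid <- ev$t_ms[ev$event == "stimulus_hidden"][1]
  expect_lte(hid, reap)
  tm <- measure_timing(log)
  expect_equal(tm$dt_ms, tm$ibi_ms - tm$rt_ms)
})

test_that("timing measures follow the two-swim definitions", {
  log <- structure(list(events = data.frame(
    t_ms = c(0, 800, 1000, 1200, 1500, 1650),
    event = c("stimulus_on", "swim_onset", "swim_end",
              "stimulus_reappear", "swim_onset", "swim_end"),
    stringsAsFactors = FALSE)), class = "trial_log")
  tm <- measure_timing(log)
  expect_equal(tm$ibi_ms, 500)
  expect_equal(tm$rt_ms, 300)
  expect_equal(tm$dt_ms, 200)
  # reappearance before the swim ends: negative delta-t
  log$events$t_ms[4] <- 900
  expect_equal(measure_timing(log)$dt_ms, -100)
  # no second swim: undefined flags
  log$events <- log$events[1:3, ]
  tm2 <- measure_timing(log)
  expect_true(is.na(tm2$ibi_ms) && is.na(tm2$rt_ms))
})

test_that("timing closure and paradigm fidelity hold over random trials", {
  n_ok <- 0
  for (k in 1:60) {
    delay <- sample(c(0, 100, 200, 300, 400, 500), 1)
    cfg <- stimulus_config("delayed_reappearance", update_delay_ms = delay)
    resp <- responder_agent(base_rt_ms = 350, rt_noise_sd_ms = 60)
    log <- run_trial(cfg, resp, seed = 1000 + k)
    ev <- log$events
    expect_false(is.unsorted(ev$t_ms))
    tm <- measure_timing(log)
    if (!is.na(tm$ibi_ms) && !is.na(tm$rt_ms) && !is.na(tm$dt_ms)) {
      expect_equal(tm$dt_ms, tm$ibi_ms - tm$rt_ms, tolerance = 1e-9)
      n_ok <- n_ok + 1
    }
  }
  expect_gt(n_ok, 50)
})

test_that("escalation schedule is applied per bout", {
  esc <- data.frame(size_deg = c(3, 5, 8), velocity_dps = c(25, 35, 50))
  cfg <- stimulus_config("sequence", escalation = esc, max_bouts = 5)
  resp <- responder_agent(base_rt_ms = 300)
  log <- run_trial(cfg, resp, seed = 5)
  res <- log$events[log$events$event == "stimulus_resume", ]
  expect_equal(res$size_deg[1:3], esc$size_deg)
  expect_equal(res$velocity_dps[1:3], esc$velocity_dps)
  # beyond the schedule the last entry persists
  if (nrow(res) > 3) expect_equal(res$size_deg[4], 8)
})

test_that("responder reaction times reflect location, delay and salience", {
  st <- function(loc, dt = 0, size = 2, vel = 20, upd = 1L)
    list(size_deg = size, velocity_dps = vel, update_location_deg = loc,
         dt_ms = dt, is_update = upd, pos_deg = 0, n_swims = upd)
  resp <- responder_agent(rt_noise_sd_ms = 0)
  set.seed(1)
  rt0 <- resp(st(0))$rt_ms
  rt10 <- resp(st(10))$rt_ms
  rtm10 <- resp(st(-10))$rt_ms
  expect_lt(rt0, rt10)
  expect_lt(rt0, rtm10)
  # escalated stimulus shortens the reaction time
  expect_lt(resp(st(0, size = 8, vel = 50))$rt_ms, rt0)
  # deterministic under a fixed seed
  cfg <- stimulus_config("sequence")
  l1 <- run_trial(cfg, responder_agent(rt_noise_sd_ms = 40), seed = 9)
  l2 <- run_trial(cfg, responder_agent(rt_noise_sd_ms = 40), seed = 9)
  expect_identical(l1$events, l2$events)
})

test_that("response-probability grid matches the agent's true rate", {
  pr <- function(size, vel) 0.6
  g <- run_grid(c(2, 4, 6, 8), c(5, 15, 25, 40), n_trials = 25,
                responder_agent(p_respond = pr), seed = 3)
  expect_identical(nrow(g), 16L)
  ci <- stats::binom.test(round(0.6 * 25), 25)$conf.int
  pooled <- sum(g$n_resp) / sum(g$n)
  expect_gt(pooled, 0.5)
  expect_lt(pooled, 0.7)
  g0 <- run_grid(c(2, 4), c(5, 15), n_trials = 5, never, seed = 1)
  expect_true(all(g0$p == 0))
  expect_error(run_grid(2, 5, 0, never), "at least one")
})
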