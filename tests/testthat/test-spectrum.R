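# brute-force evaluation of the printed DFT / single-sided RMS spectrum
dft_oracle <- function(x) {
  N <- length(x)
  ks <- 0:(N %/% 2 - 1)
  vapply(ks, function(k) {
    X <- sum(x * exp(-1i * 2 * pi * (0:(N - 1)) * k / N))
    A <- X / N
    if (k == 0) Mod(A) else Mod(2 * A)
  }, numeric(1))
}

test_that("rms_spectrum matches the direct summation oracle", {
  set.seed(101)
  for (spec in list(c(38, 250), c(75, 500), c(150, 1000))) {
    N <- spec[1]; fs <- spec[2]
    cfg <- spectrum_config("free", fs = fs, window_ms = N / fs * 1000)
    expect_identical(cfg$N, as.integer(N))
    for (rep in 1:25) {
      x <- rnorm(N)
      got <- rms_spectrum(x, cfg)
      expect_lt(max(abs(got$bmag - dft_oracle(x))), 1e-9)
    }
  }
})

test_that("unit cosine at an exact bin has peak amplitude exactly 1", {
  cfg <- spectrum_config("free", fs = 500)
  N <- cfg$N
  k0 <- 9
  x <- cos(2 * pi * k0 * (0:(N - 1)) / N)
  sp <- rms_spectrum(x, cfg)
  expect_equal(sp$bmag[k0 + 1], 1, tolerance = 1e-12)
  expect_lt(max(sp$bmag[-(k0 + 1)]), 1e-9)
  # constant input: undoubled zero bin
  spc <- rms_spectrum(rep(2.5, N), cfg)
  expect_equal(spc$bmag[1], 2.5, tolerance = 1e-12)
  expect_error(rms_spectrum(x[1:50], cfg), "match")
})

test_that("two-sided spectrum is Parseval-consistent", {
  set.seed(7)
  for (N in c(38, 75, 150)) {
    x <- rnorm(N)
    A <- stats::fft(x) / N
    expect_lt(abs(sum(Mod(A)^2) - sum(x^2) / N), 1e-9)
  }
})

test_that("Bessel band-pass rejects DC, passes the tail-beat band, linear", {
  cfg <- spectrum_config("free", fs = 500)
  n <- 3000
  dc <- bandpass(rep(1, n), cfg)
  expect_lt(max(abs(dc[1000:2000])), 0.01
  )
  s30 <- sin(2 * pi * 30 * (0:(n - 1)) / 500)
  expect_gte(max(abs(bandpass(s30, cfg)[1000:2000])), 0.9)
  set.seed(3)
  x <- rnorm(n)
  expect_equal(bandpass(3.7 * x, cfg), 3.7 * bandpass(x, cfg),
               tolerance = 1e-6)
  bad <- spectrum_config("free", fs = 500)
  bad$band <- c(0.5, 300)
  expect_error(bandpass(x, bad), "Nyquist")
})

test_that("bout detection finds onsets, offsets and gaps", {
  expect_identical(nrow(detect_bouts(numeric(500), 500, 1)), 0L)
  # single burst
  fs <- 500
  t <- (0:499) / fs * 1000
  x <- ifelse(t >= 200 & t <= 350, 10 * sin(2 * pi * 30 * t / 1000), 0)
  ev <- detect_bouts(x, fs, threshold = 0.5, min_duration_ms = 50)
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$onset_ms - 200), 4)
  # two bursts separated by a 300 ms quiet gap
  x2 <- ifelse((t >= 100 & t <= 200) | (t >= 500 & t <= 600),
               10 * sin(2 * pi * 30 * t / 1000), 0)
  ev2 <- detect_bouts(x2, fs, threshold = 0.5, min_duration_ms = 50,
                      min_gap_ms = 60)
  expect_identical(nrow(ev2), 2L)
  expect_equal(ev2$onset_ms[2] - ev2$offset_ms[1], 300, tolerance = 4)
  # events shorter than min_duration are discarded
  ev3 <- detect_bouts(x, fs, threshold = 0.5, min_duration_ms = 200)
  expect_identical(nrow(ev3), 0L)
})

test_that("summed spectrum is linear and peaks recover the generator", {
  cfg <- spectrum_config("free", fs = 500)
  set.seed(5)
  one <- bandpass(rnorm(cfg$N), cfg)
  five <- matrix(one, cfg$N, 5)
  sp <- summed_spectrum(five, cfg, filter = FALSE)
  expect_equal(sp$sum, 5 * rms_spectrum(one, cfg)$bmag, tolerance = 1e-9)

  # all-zero traces: peaks undefined
  expect_true(summed_spectrum(matrix(0, cfg$N, 5), cfg)$undefined)

  # HF peak within 1.5 Hz of the generator frequency
  p <- generator_params(delta_theta = 25, f_osc = 28, seed = 5)
  tr <- gen_bout_kinematics(p, pad_ms = c(30, 20))
  win <- bout_window(tr$gamma, 500, tr$onset_ms, tr$offset_ms, cfg)
  sp2 <- summed_spectrum(win$gammas, cfg)
  expect_lt(abs(sp2$hf[1] - 28), 1.5)
  expect_true(sp2$lf[1] >= cfg$lf_band[1] && sp2$lf[1] <= cfg$lf_band[2])

  # doubling the turn amplitude doubles the LF peak within 2 percent
  p2 <- generator_params(delta_theta = 50, f_osc = 28, seed = 5)
  tr2 <- gen_bout_kinematics(p2, pad_ms = c(30, 20))
  win2 <- bout_window(tr2$gamma, 500, tr2$onset_ms, tr2$offset_ms, cfg)
  sp3 <- summed_spectrum(win2$gammas, cfg)
  ratio <- sp3$lf[2] / sp2$lf[2]
  expect_lt(abs(ratio - 2), 0.04)
})

test_that("direction index follows the printed formula and its symmetries", {
  cfg <- spectrum_config("free", fs = 500)
  # rightward turn with known LF average
  p <- generator_params(delta_theta = 30, seed = 5)
  tr <- gen_bout_kinematics(p, pad_ms = c(30, 20))
  win <- bout_window(tr$gamma, 500, tr$onset_ms, tr$offset_ms, cfg)
  sp <- summed_spectrum(win$gammas, cfg)
  di <- direction_index(win$gammas, sp, cfg)
  lf_avg <- mean(stats::approx(sp$grid_hz, sp$sum_interp,
                               xout = cfg$di_freqs)$y)
  expect_equal(di, lf_avg, tolerance = 1e-12)     # positive integral
  expect_gt(di, 0)

  # negating the traces negates the DI exactly
  spn <- summed_spectrum(-win$gammas, cfg)
  expect_equal(direction_index(-win$gammas, spn, cfg), -di,
               tolerance = 1e-9)

  # pure symmetric oscillation: DI at numerical-noise level
  p0 <- generator_params(delta_theta = 0, seed = 5)
  tr0 <- gen_bout_kinematics(p0, pad_ms = c(30, 20))
  win0 <- bout_window(tr0$gamma, 500, tr0$onset_ms, tr0$offset_ms, cfg)
  sp0 <- summed_spectrum(win0$gammas, cfg)
  di0 <- direction_index(win0$gammas, sp0, cfg)
  summed_osc_amp <- sum(p0$segment_gains) * p0$osc_amp
  expect_lt(abs(di0), 0.01 * summed_osc_amp)
})

test_that("bout metrics recover turn angle, cycles and first-cycle timing", {
  cfg <- spectrum_config("free", fs = 500)
  p <- generator_params(delta_theta = 30, f_osc = 20, n_cycles = 3, seed = 9)
  tr <- gen_bout_kinematics(p, pad_ms = c(40, 40))
  poses <- data.frame(frame = seq_along(tr$t_ms), theta_deg = tr$theta)
  poses[paste0("gamma", 1:5, "_deg")] <- tr$gamma
  sb <- bout_metrics(poses, NULL, tr$onset_ms, tr$offset_ms, 500, cfg)
  expect_equal(sb$dtheta_deg, 30, tolerance = 1e-9)  # noise-free kinematics
  expect_identical(sb$n_cycles, 3)
  expect_equal(sb$first_cycle_ms, 1000 / 20, tolerance = 8)
  expect_error(bout_metrics(poses, NULL, 0, tr$offset_ms, 500, cfg), "edge")
})
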