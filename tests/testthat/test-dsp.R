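fs <- 96000

test_that("synaptic low-pass has first-order Butterworth magnitude response", {
  # DC gain 1
  expect_equal(tail(synaptic_lowpass(rep(1, 20000), fs), 1), 1, tolerance = 1e-4)
  gain_at <- function(f) {
    x <- sin(2 * pi * f * (0:(fs / 2)) / fs)
    y <- synaptic_lowpass(x, fs)
    rms(y[20000:40000]) / rms(x[20000:40000])
  }
  expect_equal(gain_at(500), 1 / sqrt(2), tolerance = 0.01)
  expect_equal(gain_at(5000) / gain_at(500), 1 / 10, tolerance = 0.15)
})

test_that("overlap-add analysis/resynthesis is an identity transfer", {
  x <- white_noise(0.3, fs, seed = 51)
  sf <- stft_analyze(x, fs)
  expect_equal(ncol(sf$frames), 1 + (length(x) - 4001) %/% 2000)
  y <- stft_synthesize(sf)
  mid <- 4002:(length(x) - 4001)
  expect_lt(max(abs(y[mid] - x[mid])) / max(abs(x)), 1e-3)

  z <- stft_analyze(numeric(9000), fs)
  expect_true(all(z$frames == 0))
  expect_true(all(stft_synthesize(z) == 0))
  expect_error(stft_analyze(numeric(100), fs), "shorter")
})

test_that("the IC pipeline reduces to R+L for a=0, psi_m=0 and is linear", {
  # hand-built trivial table: a = 0 everywhere, psi_m = 0, psi_c arbitrary
  cfg0 <- optimization_config(bf_channels = seq(100, 1500, 100), psi_m = 0)
  tab0 <- structure(list(bf_hz = cfg0$bf_channels,
                         target_itd = seq(0, 0.7e-3, length.out = 4),
                         a_opt = matrix(0, length(cfg0$bf_channels), 4),
                         psi_c_opt = rep(0.3, length(cfg0$bf_channels)),
                         config = cfg0),
                    class = "optimal_parameter_table")
  src <- white_noise(0.25, fs, seed = 52)
  s <- apply_itd(src, 2e-4, fs)
  pop <- run_ic_model(s, tab0, 0)
  ref <- synaptic_lowpass(s$right, fs) + synaptic_lowpass(s$left, fs)
  mid <- 6000:(length(src) - 6000)
  expect_gt(stats::cor(pop$reconstruction[[1]][mid], ref[mid]), 0.999)

  # linearity of the signal path
  tab <- pipeline_table()
  s2 <- stereo_sound(3 * s$right, 3 * s$left, fs)
  r1 <- run_ic_model(s, tab, 2e-4)$reconstruction[[1]]
  r2 <- run_ic_model(s2, tab, 2e-4)$reconstruction[[1]]
  expect_equal(r2, 3 * r1, tolerance = 1e-9)
})

test_that("pipeline tuning over target ITD matches the closed-form tuning power", {
  tab <- pipeline_table()
  taus <- seq(0, 0.7e-3, length.out = 15)
  s <- apply_itd(pure_tone(400, 0.6, fs, amplitude = 0.2), 0.4e-3, fs)
  pop <- run_ic_model(s, tab, taus, reconstruct = FALSE)
  prof <- icbinaural:::mean_band_powers(pop)
  kbin <- which.min(abs(pop$bf_hz - 400))
  fbin <- pop$bf_hz[kbin]
  jch <- which.min(abs(tab$bf_hz - fbin))
  closed <- vapply(taus, function(tt) {
    jt <- which.min(abs(tab$target_itd - tt))
    tuning_power_grid(tab$bf_hz[jch], tab$psi_c_opt[jch],
                      tab$a_opt[jch, jt], 0.4e-3)[1, 1]
  }, 0)
  expect_gt(stats::cor(prof[kbin, ], closed), 0.99)
  expect_equal(which.max(prof[kbin, ]), which.max(closed))
})

test_that("delay-line pipeline peaks at the stimulus ITD and passes zeros", {
  taus <- seq(0, 0.7e-3, length.out = 15)
  zero <- stereo_sound(numeric(30000), numeric(30000), fs)
  popz <- run_delay_line(zero, taus, reconstruct = TRUE)
  expect_true(all(popz$activity == 0))
  expect_true(all(popz$reconstruction[[1]] == 0))

  s <- apply_itd(pure_tone(400, 0.5, fs), 0.4e-3, fs)
  pop <- run_delay_line(s, taus, reconstruct = FALSE)
  prof <- icbinaural:::mean_band_powers(pop)
  kbin <- which.min(abs(pop$bf_hz - 400))
  expect_equal(taus[which.max(prof[kbin, ])], 0.4e-3, tolerance = 1e-9)
})

test_that("matched-target reconstruction of a clean source is near-perfect", {
  tab <- pipeline_table()
  src <- speech_surrogate(5, 1, fs)
  s <- apply_itd(src, 0.3e-3, fs)
  rec <- run_ic_model(s, tab, 0.3e-3)$reconstruction[[1]]
  ref <- synaptic_lowpass(src, fs)
  mid <- 8000:(length(src) - 8000)
  # allow the circuit's afferent latency: best alignment within +-0.5 ms
  cc <- stats::ccf(rec[mid], ref[mid], lag.max = 48, plot = FALSE)
  expect_gt(max(abs(cc$acf)), 0.95)
})

test_that("gammatone front end has 41 centered unit-gain channels", {
  click <- numeric(20000); click[1000] <- 1
  s <- stereo_sound(click, numeric(20000), fs)
  bank <- gammatone_front_end(s, lowpass_hz = NULL)
  expect_length(bank, 41)
  centers <- vapply(bank, attr, 0, "center_hz")
  expect_equal(centers, seq(24, 984, length.out = 41))
  for (j in c(5, 20, 41)) {
    h <- bank[[j]]$right
    sp <- Mod(stats::fft(h))^2
    f <- icbinaural:::fft_freqs(length(h), fs)
    fpk <- abs(f[which.max(sp)])
    expect_lt(abs(fpk - centers[j]), fs / length(h) + 8)
  }
  z <- gammatone_front_end(stereo_sound(numeric(20000), numeric(20000), fs))
  expect_true(all(vapply(z, function(ch) max(abs(ch$right), abs(ch$left)), 0) == 0))
})
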