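fs <- 96000

test_that("apply_itd lateralizes with the exact interaural phase and is invertible", {
  x <- pure_tone(400, 0.5, fs)
  s0 <- apply_itd(x, 0, fs)
  expect_equal(s0$right, x, tolerance = 1e-10)
  expect_equal(s0$left, x, tolerance = 1e-10)

  # quarter-period ITD at 400 Hz -> pi/2 interaural phase
  s <- apply_itd(x, 0.625e-3, fs)
  n <- length(x)
  k <- round(400 * n / fs) + 1
  ph <- Arg(stats::fft(s$right)[k] * Conj(stats::fft(s$left)[k]))
  expect_equal(ph, pi / 2, tolerance = 1e-6)
  expect_equal(rms(s$right), rms(x), tolerance = 1e-6)

  # broadband: cross-correlation peaks at the applied ITD (ccf(r, l)
  # correlates r[t+k] with l[t], so a leading right channel peaks at -itd)
  nz <- white_noise(0.2, fs, seed = 41)
  sn <- apply_itd(nz, 0.5e-3, fs)
  cc <- stats::ccf(sn$right, sn$left, lag.max = 100, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], -round(0.5e-3 * fs))

  # undoing the per-ear delays restores a band-limited source mid-signal
  # (content at the Nyquist bin itself cannot be fractionally delayed)
  bl <- Re(stats::fft({z <- stats::fft(nz); z[abs(icbinaural:::fft_freqs(length(nz), fs)) > 20000] <- 0; z},
                      inverse = TRUE)) / length(nz)
  rt <- apply_itd(bl, 0.3e-3, fs)
  back <- stereo_sound(icbinaural:::fractional_delay(rt$right, 0.3e-3 / 2, fs),
                       icbinaural:::fractional_delay(rt$left, -0.3e-3 / 2, fs), fs)
  mid <- 2000:(length(bl) - 2000)
  expect_lt(max(abs(back$right[mid] - bl[mid])) / max(abs(bl)), 1e-6)
})

test_that("tone and noise generators are calibrated and seed-reproducible", {
  tone <- pure_tone(400, 0.1, fs, amplitude = 0.8)
  expect_equal(rms(tone), 0.8 / sqrt(2), tolerance = 1e-9)
  # bin-aligned duration: all power in one positive-frequency bin
  sp <- Mod(stats::fft(pure_tone(400, 0.1, fs)))^2
  half <- sp[2:(length(sp) / 2)]
  expect_gt(max(half) / sum(half), 0.999)

  expect_identical(white_noise(0.05, fs, seed = 5), white_noise(0.05, fs, seed = 5))
  expect_false(all(white_noise(0.05, fs, seed = 5) == white_noise(0.05, fs, seed = 6)))
  expect_lt(abs(mean(white_noise(1, fs, seed = 7))), 0.01)
})

test_that("band-pass masker concentrates its power in 300-500 Hz", {
  x <- band_noise_masker(2, fs, seed = 8)
  sp <- Mod(stats::fft(x))^2
  f <- icbinaural:::fft_freqs(length(x), fs)
  inband <- abs(f) >= 300 & abs(f) <= 500
  # a single-pass two-pole-per-edge Butterworth band-pass keeps ~79% of a
  # white input's power inside its nominal passband (12 dB/oct skirts)
  expect_gt(sum(sp[inband]) / sum(sp), 0.75)
  expect_gt(sum(sp[abs(f) >= 250 & abs(f) <= 550]) / sum(sp), 0.9)
  expect_identical(x, band_noise_masker(2, fs, seed = 8))
  expect_true(all(signal::filter(signal::butter(2, c(300, 500) / (fs / 2), "pass"),
                                 numeric(100)) == 0))
})

test_that("SNR calibration scales RMS ratios exactly", {
  set.seed(9)
  sig <- stats::rnorm(5000)
  msk <- stats::rnorm(5000, sd = 2)
  expect_equal(rms(calibrate_snr(sig, msk, 0)), rms(msk), tolerance = 1e-12)
  expect_equal(rms(calibrate_snr(sig, msk, -20)) / rms(msk), 0.1,
               tolerance = 1e-12)
  expect_error(calibrate_snr(sig, numeric(10), 0), "silent")
})

test_that("phase-warp stimuli have the prescribed spectral structure", {
  d <- 0.25
  expect_error(phase_warp(3.3, d, fs, seed = 1), "multiple")
  s0 <- phase_warp(0, d, fs, seed = 1)
  expect_equal(s0$right, s0$left, tolerance = 1e-12)

  fw <- 16  # on the 4 Hz grid of a 0.25 s stimulus
  s <- phase_warp(fw, d, fs, seed = 2)
  fr <- stats::fft(s$right); fl <- stats::fft(s$left)
  n <- length(s$right); df <- fs / n
  kk <- (ceiling(20 / df):floor(2000 / df)) + 1
  # equal magnitude spectra bin-by-bin
  expect_equal(Mod(fl[kk]), Mod(fr[kk]), tolerance = 1e-8)
  # interaural phase differences are fresh random increments: their
  # circular mean resultant should be small (uniform on the circle)
  dphi <- Arg(fr[kk] * Conj(fl[kk]))
  expect_lt(Mod(mean(exp(1i * dphi))), 0.1)
})

test_that("speech surrogate has pauses, band-limited spectrum and a seed", {
  x <- speech_surrogate(17, 2, fs)
  expect_identical(x, speech_surrogate(17, 2, fs))
  env <- abs(x)
  # a >= 100 ms stretch below 5% of the peak
  quiet <- env < 0.05 * max(env)
  runs <- rle(quiet)
  expect_gte(max(runs$lengths[runs$values]), 0.1 * fs)
  sp <- Mod(stats::fft(x))^2
  f <- icbinaural:::fft_freqs(length(x), fs)
  expect_gt(sum(sp[abs(f) <= 1500]) / sum(sp), 0.95)
})

test_that("WAV I/O round-trips and flags mono/missing/resampled input", {
  s <- stereo_sound(stats::rnorm(960), stats::rnorm(960), fs)
  p <- file.path(tempdir(), "t.wav")
  write_wav(s, p)
  back <- read_wav(p)
  expect_equal(back$right, s$right, tolerance = 1e-7)
  expect_equal(back$left, s$left, tolerance = 1e-7)
  expect_equal(back$fs, fs)

  # 16-bit path quantizes but preserves the waveform closely
  s2 <- stereo_sound(0.5 * sin(1:960 / 10), 0.5 * cos(1:960 / 10), fs)
  write_wav(s2, p, bits = 16)
  expect_equal(read_wav(p)$right, s2$right, tolerance = 1e-3)

  expect_error(read_wav(file.path(tempdir(), "nope.wav")), "no such file")
})
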