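#' Two-channel sound container
#'
#' @param right,left waveforms (equal length numeric vectors).
#' @param fs sample rate in Hz (model default 96 kHz).
#' @return a `stereo_sound` object.
#' @export
stereo_sound <- function(right, left, fs = 96000) {
  if (length(right) != length(left)) stop("channel lengths differ")
  stopifnot(fs > 0)
  structure(list(right = as.numeric(right), left = as.numeric(left), fs = fs),
            class = "stereo_sound")
}

#' @export
print.stereo_sound <- function(x, ...) {
  cat(sprintf("stereo_sound: %d samples @ %g Hz (%.3f s), RMS R/L = %.3g/%.3g\n",
              length(x$right), x$fs, length(x$right) / x$fs,
              rms(x$right), rms(x$left)))
  invisible(x)
}

#' Root-mean-square amplitude
#' @param x waveform.
#' @return scalar RMS.
#' @export
rms <- function(x) sqrt(mean(x^2))

# run expr under a fixed RNG seed without disturbing the caller's RNG stream
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Lateralize a mono sound by an interaural time difference
#'
#' Splits the ITD symmetrically: the right channel is advanced by `itd/2`
#' and the left delayed by `itd/2` (`itd > 0` places the source on the
#' right). Delays are realized as frequency-domain phase ramps, so
#' sub-sample ITDs are exact; each channel keeps the RMS of the input away
#' from the (circular) edges. Equal levels at both ears reflect the
#' low-frequency approximation of negligible interaural level differences.
#'
#' @param mono source waveform.
#' @param itd interaural time difference in seconds (|itd| < 5 ms).
#' @param fs sample rate in Hz.
#' @return a [stereo_sound()].
#' @export
apply_itd <- function(mono, itd, fs = 96000) {
  stopifnot(abs(itd) < 5e-3)
  stereo_sound(right = fractional_delay(mono, -itd / 2, fs),
               left  = fractional_delay(mono,  itd / 2, fs),
               fs = fs)
}

#' Pure tone
#' @param freq_hz tone frequency in Hz.
#' @param duration duration in seconds.
#' @param fs sample rate in Hz.
#' @param amplitude peak amplitude.
#' @return waveform.
#' @export
pure_tone <- function(freq_hz, duration, fs = 96000, amplitude = 1) {
  t <- seq(0, duration - 1 / fs, by = 1 / fs)
  amplitude * sin(2 * pi * freq_hz * t)
}

#' Seeded zero-mean white noise
#' @inheritParams pure_tone
#' @param seed RNG seed (mandatory: generators are pure functions of
#'   (spec, seed)).
#' @param sd standard deviation.
#' @return waveform.
#' @export
white_noise <- function(duration, fs = 96000, seed, sd = 1) {
  stopifnot(!missing(seed))
  n <- round(duration * fs)
  with_seed(seed, stats::rnorm(n, sd = sd))
}

#' Band-pass noise masker
#'
#' White noise passed through a 2nd-order Butterworth band-pass with a
#' 200 Hz passband centered at 400 Hz (300-500 Hz), the masker of the
#' tone-in-noise detection experiments.
#'
#' @inheritParams white_noise
#' @param center,width passband center and width in Hz.
#' @return waveform.
#' @export
band_noise_masker <- function(duration, fs = 96000, seed,
                              center = 400, width = 200) {
  x <- white_noise(duration, fs, seed)
  bp <- signal::butter(2, c(center - width / 2, center + width / 2) / (fs / 2),
                       type = "pass")
  as.numeric(signal::filter(bp, x))
}

#' Scale a signal to a target SNR against a masker
#'
#' 0 dB corresponds to equal root-mean-square of signal and masker;
#' the returned signal satisfies `rms(out)/rms(masker) = 10^(snr_db/20)`.
#'
#' @param sig signal waveform.
#' @param masker reference waveform (must be non-silent).
#' @param snr_db target signal-to-noise ratio in dB.
#' @return rescaled signal.
#' @export
calibrate_snr <- function(sig, masker, snr_db) {
  rm_ <- rms(masker)
  if (rm_ == 0) stop("masker is silent: SNR undefined")
  rs <- rms(sig)
  if (rs == 0) stop("signal is silent: cannot be scaled to a target SNR")
  sig * (rm_ / rs) * 10^(snr_db / 20)
}

#' Phase-warp binaural stimulus
#'
#' Broadband binaural-beat generalization evoking acoustic motion (low warp
#' frequencies) or binaural flutter: in frequency space every component of
#' one ear gets equal magnitude and an independent random phase `phi_f`; the
#' other ear carries `phi_f` at the component shifted up by `f_warp`. The
#' interaural phase pattern therefore sweeps through all delays at rate
#' `f_warp`. Synthesized over a single full-duration FFT; `f_warp` must sit
#' on the FFT frequency grid.
#'
#' @param f_warp warp frequency in Hz (>= 0, multiple of `fs/n`).
#' @param duration duration in seconds.
#' @param fs sample rate in Hz.
#' @param seed RNG seed.
#' @param band flat-spectrum band in Hz (default 20-2000, covering the
#'   low-frequency pathway).
#' @param rms_level target RMS per ear.
#' @return a [stereo_sound()] (ear 1 = right).
#' @export
phase_warp <- function(f_warp, duration, fs = 96000, seed,
                       band = c(20, 2000), rms_level = 0.1) {
  stopifnot(f_warp >= 0, !missing(seed))
  n <- round(duration * fs)
  df <- fs / n
  k_warp <- f_warp / df
  if (abs(k_warp - round(k_warp)) > 1e-8)
    stop("f_warp must be an integer multiple of the FFT resolution fs/n = ",
         signif(df, 6), " Hz")
  k_warp <- round(k_warp)
  kmin <- max(1L, ceiling(band[1] / df))
  kmax <- min(floor(band[2] / df), floor((n - 1) / 2))
  kk <- kmin:kmax
  phi <- with_seed(seed, stats::runif(length(kk), 0, 2 * pi))
  # ear 2 phase at bin k equals ear 1 phase at bin k - k_warp (circular
  # within the band, so every in-band component keeps unit magnitude)
  idx <- ((seq_along(kk) - 1 - k_warp) %% length(kk)) + 1
  mk_ear <- function(ph) {
    spec <- complex(n)
    spec[kk + 1] <- exp(1i * ph)
    spec[n + 1 - kk] <- Conj(spec[kk + 1])
    x <- Re(stats::fft(spec, inverse = TRUE)) / n
    x * rms_level / rms(x)
  }
  stereo_sound(right = mk_ear(phi), left = mk_ear(phi[idx]), fs = fs)
}

#' Synthetic speech surrogate
#'
#' Amplitude-modulated harmonic complex standing in for recorded speech in
#' tests and demos: a fundamental between 100 and 220 Hz (seed-dependent)
#' with 1/h harmonic rolloff band-limited below 1.5 kHz, gated by a
#' syllabic envelope of raised-cosine bursts (3-8 /s) separated by pauses,
#' at least one of them longer than 150 ms.
#'
#' @inheritParams white_noise
#' @return waveform (peak-normalized to 1).
#' @export
speech_surrogate <- function(seed, duration = 2, fs = 96000) {
  stopifnot(!missing(seed))
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    f0 <- stats::runif(1, 100, 220)
    nh <- max(1, floor(1400 / f0))
    vib <- 1 + 0.01 * sin(2 * pi * stats::runif(1, 3, 6) * t)
    carrier <- 0
    for (h in seq_len(nh))
      carrier <- carrier + sin(2 * pi * h * f0 * vib * t + stats::runif(1, 0, 2 * pi)) / h
    env <- numeric(n)
    tcur <- 0
    mid_pause_done <- FALSE
    while (tcur < duration) {
      syl <- stats::runif(1, 0.08, 0.25)
      gap <- stats::runif(1, 0.03, 0.25)
      if (!mid_pause_done && tcur > duration / 2) {
        gap <- max(gap, 0.2)
        mid_pause_done <- TRUE
      }
      i0 <- floor(tcur * fs) + 1
      i1 <- min(n, floor((tcur + syl) * fs))
      if (i0 <= n) {
        m <- i1 - i0 + 1
        env[i0:i1] <- stats::runif(1, 0.5, 1) * (0.5 - 0.5 * cos(2 * pi * seq_len(m) / m))
      }
      tcur <- tcur + syl + gap
    }
    x <- carrier * env
    x / max(abs(x))
  })
}

#' Read / write WAV files
#'
#' Minimal RIFF/WAVE I/O for 16-bit integer and 32-bit IEEE-float PCM.
#' `read_wav` duplicates mono files to both ears (with a warning) and
#' resamples to `target_fs` by linear interpolation when the file rate
#' differs (with a warning). `write_wav` stores 32-bit float by default,
#' which round-trips the waveform losslessly.
#'
#' @param path file path.
#' @param target_fs working sample rate files are resampled to on read.
#' @return `read_wav`: a [stereo_sound()]; `write_wav`: `path`, invisibly.
#' @export
read_wav <- function(path, target_fs = 96000) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "raw", sz)
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop("missing fmt/data chunk: ", path)
  u16 <- function(off) sum(as.integer(fmt[off + 1:2]) * c(1, 256))
  u32 <- function(off) sum(as.integer(fmt[off + 1:4]) * 256^(0:3))
  tag <- u16(0); nch <- u16(2); fs <- u32(4); bits <- u16(14)
  x <- if (tag == 3 && bits == 32) {
    readBin(dat, "double", length(dat) / 4, size = 4, endian = "little")
  } else if (tag == 1 && bits == 16) {
    readBin(dat, "integer", length(dat) / 2, size = 2, signed = TRUE,
            endian = "little") / 32768
  } else stop("unsupported WAV format (tag ", tag, ", ", bits, " bit)")
  if (nch == 1) {
    warning("mono file: duplicating to both ears")
    r <- x; l <- x
  } else {
    r <- x[seq(1, length(x), by = nch)]
    l <- x[seq(2, length(x), by = nch)]
  }
  if (fs != target_fs) {
    warning("resampling from ", fs, " Hz to ", target_fs, " Hz")
    tt <- seq(0, (length(r) - 1) / fs, by = 1 / target_fs)
    r <- stats::approx(seq(0, by = 1 / fs, length.out = length(r)), r, tt, rule = 2)$y
    l <- stats::approx(seq(0, by = 1 / fs, length.out = length(l)), l, tt, rule = 2)$y
    fs <- target_fs
  }
  stereo_sound(r, l, fs)
}

#' @rdname read_wav
#' @param s a [stereo_sound()].
#' @param bits 32 (IEEE float) or 16 (integer PCM).
#' @export
write_wav <- function(s, path, bits = 32) {
  stopifnot(inherits(s, "stereo_sound"), bits %in% c(16, 32))
  n <- length(s$right)
  inter <- as.vector(rbind(s$right, s$left))
  bytes_per <- bits / 8
  data_sz <- n * 2 * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  writeChar("RIFF", con, eos = NULL); w32(36 + data_sz)
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL); w32(16)
  w16(if (bits == 32) 3 else 1)          # IEEE float / integer PCM
  w16(2)                                  # channels
  w32(s$fs)
  w32(s$fs * 2 * bytes_per)               # byte rate
  w16(2 * bytes_per)                      # block align
  w16(bits)
  writeChar("data", con, eos = NULL); w32(data_sz)
  if (bits == 32) {
    writeBin(inter, con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(pmax(-32768, pmin(32767, round(inter * 32768)))),
             con, size = 2, endian = "little")
  }
  invisible(path)
}
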