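#' Circuit parameters of one IC frequency channel
#'
#' Bundles the per-channel synaptic parameters of the MSO/LSO-to-IC transfer:
#' the relative LSO weight `a`, the cross-hemispheric phases of the MSO and
#' LSO afferents (`psi_m`, `psi_l`), the commissural LSO-to-IC phase `psi_c`,
#' and the pathway variant. All phases are expressed in cycles (1 cycle =
#' 2*pi radians), the convention in which the canonical values are quoted
#' (`psi_m = 0.125`, `psi_l = 0`, optimal `psi_c` near 0.3).
#'
#' The `contralateral_excitatory` variant is the principal pathway
#' (excitatory contralateral LSO projection, weight `a >= 0`). The
#' `ipsilateral_inhibitory` variant models the smaller inhibitory ipsilateral
#' LSO projection; there the weight enters as a negative `a` and the transfer
#' is independent of `psi_c`.
#'
#' @param a relative LSO synaptic weight (dimensionless, may be negative for
#'   the ipsilateral variant); must be finite.
#' @param psi_m MSO cross-hemispheric phase in cycles (default 0.125).
#' @param psi_l LSO cross-hemispheric phase in cycles (default 0).
#' @param psi_c commissural LSO-to-IC phase in cycles.
#' @param variant `"contralateral_excitatory"` or `"ipsilateral_inhibitory"`.
#' @return an object of class `circuit_params`.
#' @export
circuit_params <- function(a, psi_c, psi_m = 0.125, psi_l = 0,
                           variant = c("contralateral_excitatory",
                                       "ipsilateral_inhibitory")) {
  variant <- match.arg(variant)
  stopifnot(is.finite(a), is.finite(psi_c), is.finite(psi_m), is.finite(psi_l))
  structure(list(a = a, psi_m = psi_m, psi_l = psi_l, psi_c = psi_c,
                 variant = variant),
            class = "circuit_params")
}

#' @export
print.circuit_params <- function(x, ...) {
  cat(sprintf("IC circuit parameters [%s]\n  a = %.4g, psi_m = %.4g cyc, psi_l = %.4g cyc, psi_c = %.4g cyc\n",
              x$variant, x$a, x$psi_m, x$psi_l, x$psi_c))
  invisible(x)
}

#' Frequency channel descriptor
#'
#' @param bf_hz best frequency in Hz (> 0).
#' @return list with `bf_hz` and the angular frequency `omega = 2*pi*bf_hz`.
#' @export
frequency_channel <- function(bf_hz) {
  stopifnot(is.numeric(bf_hz), length(bf_hz) == 1L, bf_hz > 0)
  structure(list(bf_hz = bf_hz, omega = 2 * pi * bf_hz),
            class = "frequency_channel")
}

# phase in cycles -> unit complex factor e^{-2 pi i psi}
cyc <- function(psi) exp(-2i * pi * psi)

#' Moore-Penrose pseudo-inverse of the two-ear mixing matrix
#'
#' A source at interaural time difference `delta_t` plus independent left and
#' right ear noises maps to the ear spectra through the 2x3 mixing matrix
#' `A = [(e^{i w dt/2}, 1, 0), (e^{-i w dt/2}, 0, 1)]`. The minimum-norm
#' least-squares estimate of `(S, N_R, N_L)` from `(R, L)` is its
#' Moore-Penrose pseudo-inverse, available in closed form:
#' rows are the estimates of the source and the two noises.
#'
#' @param delta_t stimulus ITD in seconds (> 0 for right-leading sources).
#' @param omega angular frequency in rad/s (>= 0).
#' @return 3x2 complex matrix `A*` with `A* A A* = A*` and `A A* A = A`.
#' @export
mixing_pseudoinverse <- function(delta_t, omega) {
  stopifnot(omega >= 0)
  p <- exp(1i * omega * delta_t / 2)   # e^{i w dt/2}
  matrix(c(Conj(p),      p,
           2,            -p^2,
           -Conj(p)^2,   2) / 3,
         nrow = 3, ncol = 2, byrow = TRUE)
}

# forward mixing matrix of the two-ear model (2x3)
mixing_matrix <- function(delta_t, omega) {
  p <- exp(1i * omega * delta_t / 2)
  matrix(c(p,       1, 0,
           Conj(p), 0, 1),
         nrow = 2, ncol = 3, byrow = TRUE)
}

# delay a waveform by 'lag' seconds via a frequency-domain phase ramp
# (positive lag shifts the signal later in time); circular.
fractional_delay <- function(x, lag, fs) {
  n <- length(x)
  if (n == 0L || lag == 0) return(x)
  f <- fft_freqs(n, fs)
  ramp <- exp(-2i * pi * f * lag)
  # the Nyquist coefficient of a real signal must stay real
  if (n %% 2 == 0) ramp[n / 2 + 1] <- cos(pi * fs * lag)
  Re(stats::fft(stats::fft(x) * ramp, inverse = TRUE)) / n
}

# signed FFT bin frequencies for length-n transform at rate fs
fft_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k * fs / n
}

#' Jeffress delay-line reconstruction of source and noises
#'
#' Time-domain counterpart of [mixing_pseudoinverse()]: a coincidence-detector
#' neuron whose internal delay compensates the stimulus ITD `delta_t`
#' optimally reconstructs the source,
#' `s_est(t) = (R(t - dt/2) + L(t + dt/2)) / 3`, together with the noise
#' estimates `nr_est = (2R(t) - L(t + dt))/3` and
#' `nl_est = (2L(t) - R(t - dt))/3`. Fractional delays are realized as
#' frequency-domain phase ramps (circular at the edges).
#'
#' @param r,l right/left ear waveforms (equal length).
#' @param delta_t ITD offset of the coincidence detector in seconds.
#' @param fs sample rate in Hz.
#' @return list with waveforms `s_est`, `nr_est`, `nl_est`.
#' @export
delay_line_estimate <- function(r, l, delta_t, fs) {
  if (length(r) != length(l)) stop("`r` and `l` must have the same length")
  s_est  <- (fractional_delay(r,  delta_t / 2, fs) +
             fractional_delay(l, -delta_t / 2, fs)) / 3
  nr_est <- (2 * r - fractional_delay(l, -delta_t, fs)) / 3
  nl_est <- (2 * l - fractional_delay(r,  delta_t, fs)) / 3
  list(s_est = s_est, nr_est = nr_est, nl_est = nl_est)
}

#' Hemispheric transfer coefficients gamma_R, gamma_L
#'
#' The pure-source IC response factorizes as
#' `IC = S (e^{i w dt/2} gamma_R + e^{i w dt/2} gamma_L) / sqrt(1 + a^2)`
#' with, for the contralateral excitatory pathway,
#' `gamma_R = 1 - a e^{-i(psi_l + psi_c)}` and
#' `gamma_L = e^{-i w dt} (e^{-i psi_m} + a e^{-i psi_c})`
#' (phases converted from cycles to radians internally). The ipsilateral
#' inhibitory variant replaces these by `gamma_R = 1 + a` and
#' `gamma_L = e^{-i w dt} (e^{-i psi_m} - a e^{-i psi_l})`, independent of
#' `psi_c`; at `a = -1` the right-ear drive cancels and ITD tuning is flat.
#'
#' @param params [circuit_params()].
#' @param omega angular frequency in rad/s.
#' @param delta_t stimulus ITD in seconds (> 0 right-leading).
#' @return list with complex `gamma_r`, `gamma_l`.
#' @export
gamma_coefficients <- function(params, omega, delta_t) {
  a <- params$a
  stim <- exp(-1i * omega * delta_t)
  if (params$variant == "contralateral_excitatory") {
    gr <- 1 - a * cyc(params$psi_l + params$psi_c)
    gl <- stim * (cyc(params$psi_m) + a * cyc(params$psi_c))
  } else {
    gr <- (1 + a) + 0i
    gl <- stim * (cyc(params$psi_m) - a * cyc(params$psi_l))
  }
  list(gamma_r = gr, gamma_l = gl)
}

#' MSO/LSO-to-IC transfer in one frequency channel
#'
#' Maps the ear spectra of the modeled (right) IC to the complex IC response,
#' `IC = (R (1 - a e^{-i(psi_l+psi_c)}) + L (e^{-i psi_m} + a e^{-i psi_c}))
#' / sqrt(1 + a^2)`. The division normalizes the sum of squared synaptic
#' weights to one, removing rate effects of the total drive. The left-IC
#' model is the mirror image: swap `r_hat` and `l_hat`.
#'
#' @param params [circuit_params()].
#' @param channel [frequency_channel()] (unused by the constant-phase
#'   parameterization, kept for frequency-dependent phase extensions).
#' @param r_hat,l_hat complex ear amplitudes in this channel.
#' @return complex IC amplitude; linear in `(r_hat, l_hat)`.
#' @export
ic_transfer <- function(params, channel, r_hat, l_hat) {
  cf <- ic_transfer_coefficients(params)
  (r_hat * cf$c_r + l_hat * cf$c_l) / sqrt(1 + params$a^2)
}

# unnormalized coefficients on (R, L) of the IC transfer
ic_transfer_coefficients <- function(params) {
  a <- params$a
  if (params$variant == "contralateral_excitatory") {
    list(c_r = 1 - a * cyc(params$psi_l + params$psi_c),
         c_l = cyc(params$psi_m) + a * cyc(params$psi_c))
  } else {
    list(c_r = 1 + a,
         c_l = cyc(params$psi_m) - a * cyc(params$psi_l))
  }
}

#' ITD tuning power of an IC neuron
#'
#' Response power `|IC|^2` to a unit pure-tone source at the channel
#' frequency presented at ITD `delta_t`, i.e.
#' `|S|^2 |gamma_R + gamma_L|^2 / (1 + a^2)`, which expands to the standard
#' interference form `|gamma_R|^2 + |gamma_L|^2 + 2 |gamma_R gamma_L|
#' cos(arg gamma_R - arg gamma_L)`. Periodic in `delta_t` with period
#' `1/BF`; for the ipsilateral variant at `a = -1` the curve is flat.
#'
#' @param params [circuit_params()].
#' @param channel [frequency_channel()].
#' @param delta_t stimulus ITD in seconds (vectorized).
#' @param source_power source power `|S|^2` (>= 0), default 1.
#' @return nonnegative power, same length as `delta_t`.
#' @export
ic_power_tuning <- function(params, channel, delta_t, source_power = 1) {
  stopifnot(all(source_power >= 0))
  g <- gamma_coefficients(params, channel$omega, delta_t)
  source_power * Mod(g$gamma_r + g$gamma_l)^2 / (1 + params$a^2)
}

#' Normalized MSO/LSO weight vector
#'
#' The IC readout direction in the MSO-LSO input plane,
#' `w = (1, a) / sqrt(1 + a^2)`, with unit Euclidean norm.
#'
#' @param a relative LSO weight (finite).
#' @return numeric length-2 vector of norm 1.
#' @export
weight_vector <- function(a) {
  stopifnot(is.finite(a))
  c(1, a) / sqrt(1 + a^2)
}

#' MSO-LSO input-plane trajectory under pure-tone stimulation
#'
#' Time-domain superior-olivary drives for a pure tone at the channel best
#' frequency presented at ITD `delta_t`:
#' `MSO(t) = R(t) + L(t - Lm)` and (commissural branch)
#' `LSO(t - Lc) = L(t - Lc) - R(t - Ll - Lc)` with latencies
#' `Lx = psi_x / BF`. The principal-axis angle of the ellipse traced in the
#' (MSO, LSO) plane encodes the stimulus ITD and is invariant to sound level.
#'
#' @param channel [frequency_channel()].
#' @param delta_t stimulus ITD in seconds (> 0 right-leading).
#' @param psi_c commissural phase in cycles.
#' @param duration trajectory duration in seconds.
#' @param fs sample rate in Hz.
#' @param psi_m,psi_l afferent phases in cycles.
#' @param amplitude source amplitude.
#' @return list with vectors `mso`, `lso` (commissurally delayed LSO drive),
#'   `t` (time axis), and `angle` (principal-axis angle in degrees).
#' @export
mso_lso_trajectory <- function(channel, delta_t, psi_c, duration, fs = 96000,
                               psi_m = 0.125, psi_l = 0, amplitude = 1) {
  bf <- channel$bf_hz
  t <- seq(0, duration, by = 1 / fs)
  s <- function(tt) amplitude * cos(2 * pi * bf * tt)
  r <- function(tt) s(tt + delta_t / 2)
  l <- function(tt) s(tt - delta_t / 2)
  lm <- psi_m / bf; ll <- psi_l / bf; lc <- psi_c / bf
  mso <- r(t) + l(t - lm)
  lso <- l(t - lc) - r(t - ll - lc)
  list(mso = mso, lso = lso, t = t,
       angle = principal_angle(mso, lso))
}

# principal-axis angle (degrees) of a 2D point cloud, from the leading
# eigenvector of its second-moment matrix (no centering: trajectories are
# zero-mean by construction)
principal_angle <- function(x, y) {
  m <- cbind(x, y)
  ev <- eigen(crossprod(m) / nrow(m), symmetric = TRUE)$vectors[, 1]
  if (ev[1] < 0) ev <- -ev
  atan2(ev[2], ev[1]) * 180 / pi
}
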