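#' Recurrent divisive inhibition across target-ITD neurons
#'
#' Within each frequency channel and time frame, every neuron's input rate
#' is divided by one plus the scaled population mean:
#' `out_tau = in_tau / (1 + (J/N) * sum_tau' in_tau')`, with `J` the
#' inhibitory synaptic weight and `N` the number of target-ITD neurons in
#' the channel. The common divisor preserves the rank order (and shape up
#' to scale) along the target-ITD axis while suppressing frames/channels
#' with high total activity, sharpening the population peak relative to the
#' additive baseline. Applied to band powers only; reconstruction-based
#' (correlation) analyses stay linear and bypass it.
#'
#' @param pop a `population_activity` (nonnegative band powers), or a
#'   plain nonnegative matrix/array whose second axis is the target-ITD
#'   neuron.
#' @param j_inh inhibitory weight `J` (default 20).
#' @return same type as `pop`, with normalized activity.
#' @export
inhibitory_normalization <- function(pop, j_inh = 20) {
  if (inherits(pop, "population_activity")) {
    pop$activity <- inhibitory_normalization(pop$activity, j_inh)
    pop$j_inh <- j_inh
    return(pop)
  }
  x <- pop
  if (any(x < 0)) stop("inhibition operates on nonnegative rates")
  d <- dim(x)
  if (is.null(d)) stop("expected a matrix or array with a target-ITD axis")
  n_tau <- d[2]
  if (n_tau == 0) stop("no target-ITD neurons")
  tot <- apply(x, setdiff(seq_along(d), 2), sum)
  div <- 1 + (j_inh / n_tau) * tot
  if (length(d) == 2) {
    x / matrix(div, d[1], d[2])
  } else {
    sweep(x, c(1, 3), div, "/")
  }
}

#' Adaptation state constants of the superior olivary inputs
#'
#' First-order firing-rate adaptation of the MSO and LSO drives: an
#' attenuation variable per pathway relaxes to 1 with time constant
#' `tau_a` and is driven down by the rectified input at rate `c_x`;
#' the adapted drive is `X(t) (b + alpha_X(t)) / (b + 1)`, so `b/(b+1)`
#' is the floor gain of the maximally adapted state.
#'
#' @param tau_a recovery time constant in seconds (default 2).
#' @param c_mso,c_lso adaptation rates in 1/(unit input * s)
#'   (defaults `5/tau_a` and `10/tau_a`).
#' @param b baseline level (default 0.1).
#' @return an `adaptation_state` list.
#' @export
adaptation_state <- function(tau_a = 2, c_mso = 5 / tau_a, c_lso = 10 / tau_a,
                             b = 0.1) {
  stopifnot(tau_a > 0, b >= 0)
  structure(list(tau_a = tau_a, c_mso = c_mso, c_lso = c_lso, b = b),
            class = "adaptation_state")
}

#' Apply firing-rate adaptation to an SOC drive
#'
#' Integrates `d alpha/dt = (1 - alpha)/tau_a - alpha c |x(t)|` by forward
#' Euler at the audio rate from `alpha(0) = 1` and returns the attenuated
#' drive `x(t) (b + alpha(t)) / (b + 1)`. Inputs are expected normalized to
#' maximum amplitude 1; `alpha` stays in (0, 1]. With a constant drive
#' `|x| = x0` the steady state is `1 / (1 + tau_a c x0)`; during silent
#' pauses `alpha` recovers toward 1, so transient onsets are transmitted
#' nearly unadapted.
#'
#' @param x drive waveform (MSO or LSO activity).
#' @param fs sample rate in Hz.
#' @param c_x adaptation rate for this pathway (see [adaptation_state()]).
#' @param state an [adaptation_state()].
#' @param alpha0 initial attenuation in (0, 1].
#' @return list with `adapted` (waveform) and `alpha` (trajectory).
#' @export
adapt_soc <- function(x, fs, c_x, state = adaptation_state(), alpha0 = 1) {
  stopifnot(alpha0 > 0, alpha0 <= 1)
  dt <- 1 / fs
  if (dt > state$tau_a / 100)
    stop("sample period too coarse for stable integration (need fs >= 100/tau_a)")
  alpha <- euler_alpha(abs(x), dt, state$tau_a, c_x, alpha0)
  list(adapted = x * (state$b + alpha) / (state$b + 1), alpha = alpha)
}

# forward Euler for the attenuation ODE; written as an exact per-step
# exponential relaxation toward the instantaneous fixed point would change
# results by <0.1% at audio rates, so the plain Euler step is kept.
euler_alpha <- function(absx, dt, tau_a, c_x, alpha0) {
  n <- length(absx)
  alpha <- numeric(n)
  a <- alpha0
  for (i in seq_len(n)) {
    a <- a + dt * ((1 - a) / tau_a - a * c_x * absx[i])
    if (a < 0) a <- 0
    alpha[i] <- a
  }
  alpha
}

#' Time-domain MSO/LSO drives with optional adaptation
#'
#' Explicit time-domain variant of the superior-olivary stage used for the
#' adaptation experiments: `MSO(t) = R(t) + L(t - Lm)`,
#' `LSO(t) = L(t) - R(t - Ll)`, commissural delay `Lc` on the LSO branch,
#' latencies `Lx = psi_x / BF`. If `state` is given, both drives are first
#' peak-normalized (jointly), adapted with their pathway rates, and the IC
#' output `[MSO(t) + a LSO(t - Lc)] / sqrt(1 + a^2)` is formed from the
#' adapted drives.
#'
#' @param s a [stereo_sound()] (for the left-IC convention pass ears
#'   swapped; see [run_ic_model()]).
#' @param channel [frequency_channel()].
#' @param params [circuit_params()].
#' @param state optional [adaptation_state()]; `NULL` disables adaptation.
#' @return list with `mso`, `lso` (commissurally delayed, weight not yet
#'   applied), `ic`, and (when adapting) `alpha_mso`, `alpha_lso`.
#' @export
soc_drive <- function(s, channel, params, state = NULL) {
  stopifnot(inherits(s, "stereo_sound"))
  bf <- channel$bf_hz
  lm <- params$psi_m / bf; ll <- params$psi_l / bf; lc <- params$psi_c / bf
  r <- s$right; l <- s$left; fs <- s$fs
  mso <- r + fractional_delay(l, lm, fs)
  lso <- fractional_delay(l, lc, fs) - fractional_delay(r, ll + lc, fs)
  out <- list()
  if (!is.null(state)) {
    peak <- max(abs(c(mso, lso)), 1e-12)
    am <- adapt_soc(mso / peak, fs, state$c_mso, state)
    al <- adapt_soc(lso / peak, fs, state$c_lso, state)
    mso <- am$adapted * peak
    lso <- al$adapted * peak
    out$alpha_mso <- am$alpha
    out$alpha_lso <- al$alpha
  }
  out$mso <- mso
  out$lso <- lso
  out$ic <- (mso + params$a * lso) / sqrt(1 + params$a^2)
  out
}
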