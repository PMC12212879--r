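#' Vector strength of a response trace
#'
#' Modulus of the normalized Fourier mode of a nonnegative response at a
#' reference frequency, `VS = |integral r(t) e^{2 pi i f t} dt| /
#' integral r(t) dt`: 0 for an unmodulated trace, 1 for perfect locking.
#' Evaluate over an integer number of periods of `f`.
#'
#' @param power_trace nonnegative response (e.g. `IC(t)^2`).
#' @param f locking frequency in Hz.
#' @param fs sample rate of the trace in Hz.
#' @return vector strength in `[0, 1]`.
#' @export
vector_strength <- function(power_trace, f, fs) {
  if (any(power_trace < 0)) stop("trace must be nonnegative")
  tot <- sum(power_trace)
  if (tot == 0) stop("zero-integral trace: vector strength undefined")
  t <- (seq_along(power_trace) - 1) / fs
  Mod(sum(power_trace * exp(2i * pi * f * t))) / tot
}

#' Best interaural phase difference of a tuning curve
#'
#' Phase (in cycles, wrapped to `(-0.5, 0.5]`) of the Fourier mode at the
#' channel best frequency of an ITD tuning profile sampled on `itd`;
#' a curve `cos(2 pi BF (itd - itd0))` yields `BF * itd0` (mod 1). The
#' corresponding best ITD is `best IPD / BF`. Returns `NaN` for a flat
#' curve (zero mode).
#'
#' @param response tuning-curve values over `itd`.
#' @param itd ITD axis in seconds (sample at least one full `1/bf` cycle
#'   for an unbiased phase).
#' @param bf channel best frequency in Hz.
#' @return best IPD in cycles.
#' @export
best_ipd <- function(response, itd, bf) {
  stopifnot(length(response) == length(itd))
  m <- sum(response * exp(2i * pi * bf * itd))
  if (Mod(m) < 1e-12 * max(sum(abs(response)), 1e-300)) return(NaN)
  wrap_cycles(Arg(m) / (2 * pi))
}

# wrap phase in cycles to (-0.5, 0.5]
wrap_cycles <- function(p) {
  w <- ((p + 0.5) %% 1) - 0.5
  w[w == -0.5] <- 0.5
  w
}

#' Threshold-rectify tuning-curve values
#'
#' Mimics a non-linear spike threshold: subtracts `factor` times the
#' population mean (computed over the physiological ITD range) and clips at
#' zero.
#'
#' @param tuning_power per-neuron (or matrix of) tuning values.
#' @param factor threshold as a fraction of the population mean
#'   (default 0.67).
#' @param reference values over which the population mean is computed
#'   (default: `tuning_power` itself).
#' @return rectified values, same shape.
#' @export
rectify <- function(tuning_power, factor = 0.67, reference = tuning_power) {
  pmax(tuning_power - factor * mean(reference), 0)
}

#' Population best-IPD statistics of an optimized circuit
#'
#' The single-cell consistency check of the model: per frequency channel
#' and target-ITD neuron, the pure-tone ITD tuning curve implied by the
#' optimized parameters is rectified at 0.67 times the channel's population
#' mean within the physiological ITD range, and the best IPD is read off as
#' the phase of the curve's Fourier mode at BF. Positive IPDs are
#' contralateral-leading.
#'
#' With `window = "physiological"` (default) the curves are evaluated, and
#' the Fourier mode taken, over stimulus ITDs in `[-itd_phys, itd_phys]`;
#' `window = "full_cycle"` instead spans one full `1/BF` period (there the
#' mode phase equals the raw peak position of the sinusoidal curve).
#'
#' @param table `optimal_parameter_table` (typically optimized with
#'   `itd_max = itd_phys`).
#' @param itd_phys physiological ITD range in seconds (default 0.3 ms).
#' @param window curve support (see Details).
#' @param rectify_factor threshold fraction (default 0.67); `NULL` skips
#'   rectification.
#' @param n_itd samples of the stimulus-ITD axis.
#' @return list with `ipd` (channels x neurons matrix of best IPDs in
#'   cycles), `by_channel` (per-channel mean/median/10-90 percentiles) and
#'   `mean` (population mean).
#' @export
population_best_ipd <- function(table, itd_phys = 0.3e-3,
                                window = c("physiological", "full_cycle"),
                                rectify_factor = 0.67, n_itd = 121) {
  window <- match.arg(window)
  nbf <- length(table$bf_hz)
  ntau <- length(table$target_itd)
  cfg <- table$config
  psi_m <- if (!is.null(cfg)) cfg$psi_m else 0.125
  psi_l <- if (!is.null(cfg)) cfg$psi_l else 0
  ipd <- matrix(NA_real_, nbf, ntau)
  for (j in seq_len(nbf)) {
    bf <- table$bf_hz[j]
    dt <- if (window == "physiological") {
      seq(-itd_phys, itd_phys, length.out = n_itd)
    } else {
      seq(0, 1 / bf, length.out = n_itd + 1)[-(n_itd + 1)]
    }
    p <- tuning_power_grid(bf, table$psi_c_opt[j], table$a_opt[j, ], dt,
                           psi_m = psi_m, psi_l = psi_l)
    if (!is.null(rectify_factor)) {
      inphys <- if (window == "physiological") rep(TRUE, length(dt))
                else pmin(dt, 1 / bf - dt) <= itd_phys
      p <- pmax(p - rectify_factor * mean(p[, inphys]), 0)
    }
    ipd[j, ] <- apply(p, 1, best_ipd, itd = dt, bf = bf)
  }
  by_channel <- data.frame(
    bf_hz = table$bf_hz,
    mean = rowMeans(ipd, na.rm = TRUE),
    median = apply(ipd, 1, stats::median, na.rm = TRUE),
    p10 = apply(ipd, 1, stats::quantile, probs = 0.1, na.rm = TRUE),
    p90 = apply(ipd, 1, stats::quantile, probs = 0.9, na.rm = TRUE)
  )
  list(ipd = ipd, by_channel = by_channel, mean = mean(ipd, na.rm = TRUE))
}

#' Relative signal-to-noise response difference dmax
#'
#' Per frequency channel, the maximum over target-ITD neurons of the ratio
#' of time-averaged response powers between the "signal plus noise" and the
#' "noise alone" presentation, minus one: zero when the signal leaves no
#' trace, positive where some neuron responds more with the signal present.
#'
#' @param signal_plus_noise_power,noise_power matrices of time-averaged
#'   band powers, channels x target-ITD neurons, on identical grids (use
#'   the same noise realization for both presentations).
#' @param mode `"power"` (ratio of powers, default) or `"magnitude"`
#'   (ratio of root powers).
#' @return per-channel dmax curve.
#' @export
dmax <- function(signal_plus_noise_power, noise_power,
                 mode = c("power", "magnitude")) {
  mode <- match.arg(mode)
  stopifnot(identical(dim(signal_plus_noise_power), dim(noise_power)))
  if (any(noise_power <= 0)) stop("noise reference power must be positive")
  ratio <- signal_plus_noise_power / noise_power
  if (mode == "magnitude") ratio <- sqrt(ratio)
  apply(ratio, 1, max) - 1
}

#' Peak prominences of a curve
#'
#' For each interior local maximum: its height minus the higher of the two
#' flanking (adjacent) local minima; curve boundary values count as local
#' minima. Note this "highest flanking minimum" rule differs from the
#' textbook (contour-line) prominence for nested peaks: in
#' `c(0, 2, 1, 3, 0)` the peak at 3 has prominence 2 here (flanking minima
#' 1 and 0), not 3.
#'
#' @param curve numeric vector (e.g. dmax over frequency channels).
#' @return data.frame with `index`, `value`, `prominence` per local peak
#'   (zero rows if the curve is monotone).
#' @export
peak_prominence <- function(curve) {
  n <- length(curve)
  out <- data.frame(index = integer(0), value = numeric(0),
                    prominence = numeric(0))
  if (n < 3) return(out)
  interior <- 2:(n - 1)
  is_min <- c(TRUE, curve[interior] < curve[interior - 1] &
                curve[interior] <= curve[interior + 1], TRUE)
  min_idx <- which(is_min)
  for (i in interior) {
    if (curve[i] > curve[i - 1] && curve[i] >= curve[i + 1]) {
      left <- curve[max(min_idx[min_idx < i])]
      right <- curve[min(min_idx[min_idx > i])]
      out <- rbind(out, data.frame(index = i, value = curve[i],
                                   prominence = curve[i] - max(left, right)))
    }
  }
  out
}

#' Tone-in-noise detection threshold from dmax curves
#'
#' The lowest probed SNR at which the dmax curve still has a local peak
#' within `bf_tol` of the signal frequency whose prominence reaches the
#' criterion. SNRs are probed in descending order; returns `NA` (not
#' detected) when no probed SNR qualifies.
#'
#' @param dmax_curves list of per-channel dmax curves, one per probed SNR.
#' @param snr_db probed SNRs in dB (same order as `dmax_curves`).
#' @param bf_hz channel frequency axis of the curves.
#' @param criterion prominence criterion (default 0.05).
#' @param signal_bf signal frequency in Hz (default 400).
#' @param bf_tol acceptance window around `signal_bf` in Hz (default 50).
#' @return threshold SNR in dB, or `NA_real_`.
#' @export
detection_threshold <- function(dmax_curves, snr_db, bf_hz,
                                criterion = 0.05, signal_bf = 400,
                                bf_tol = 50) {
  stopifnot(length(dmax_curves) == length(snr_db))
  ord <- order(snr_db, decreasing = TRUE)
  thr <- NA_real_
  for (i in ord) {
    pk <- peak_prominence(dmax_curves[[i]])
    ok <- pk[abs(bf_hz[pk$index] - signal_bf) <= bf_tol &
               pk$prominence >= criterion, ]
    if (nrow(ok) > 0) thr <- snr_db[i] else break
  }
  thr
}

#' Windowed Pearson correlation between reconstruction and source
#'
#' Pearson's r in consecutive non-overlapping windows (default 20 ms);
#' windows in which either trace has zero variance give `NA`.
#'
#' @param reconstruction,source waveforms of equal length and rate.
#' @param fs sample rate in Hz.
#' @param window window length in seconds (default 0.02).
#' @return data.frame with `t0` (window start, s) and `r`.
#' @export
windowed_pearson <- function(reconstruction, source, fs, window = 0.02) {
  stopifnot(length(reconstruction) == length(source))
  wlen <- round(window * fs)
  nw <- length(source) %/% wlen
  r <- t0 <- numeric(nw)
  for (k in seq_len(nw)) {
    i <- (k - 1) * wlen + seq_len(wlen)
    a <- reconstruction[i]; b <- source[i]
    t0[k] <- (i[1] - 1) / fs
    r[k] <- if (stats::sd(a) == 0 || stats::sd(b) == 0) NA_real_
            else stats::cor(a, b)
  }
  data.frame(t0 = t0, r = r)
}

#' Winner histogram over target-ITD neurons
#'
#' In consecutive non-overlapping windows, the neuron with the maximal mean
#' band power (summed over frequency channels) wins; ties go to the
#' smaller target ITD. Counts how often each neuron wins.
#'
#' @param pop a `population_activity`.
#' @param window window length in seconds (default 0.02).
#' @param exclude_edges drop windows overlapping the first/last analysis
#'   window (transients).
#' @return data.frame with `target_itd` and `count` (summing to the number
#'   of counted windows).
#' @export
winner_histogram <- function(pop, window = 0.02, exclude_edges = TRUE) {
  stopifnot(inherits(pop, "population_activity"))
  ft <- pop$frame_time
  tmax <- max(ft)
  edges <- seq(0, tmax, by = window)
  counts <- integer(length(pop$target_itd))
  drive <- apply(pop$activity, c(2, 3), sum)   # tau x frame
  for (k in seq_len(length(edges) - 1)) {
    sel <- ft >= edges[k] & ft < edges[k + 1]
    if (!any(sel)) next
    if (exclude_edges && (k == 1 || k == length(edges) - 1)) next
    m <- rowMeans(drive[, sel, drop = FALSE])
    w <- which.max(m)   # first max = smallest target ITD on an ascending grid
    counts[w] <- counts[w] + 1L
  }
  data.frame(target_itd = pop$target_itd, count = counts)
}
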