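#' Experiment recipes
#'
#' The `exp_*` functions wire the model modules into the package's
#' figure-level experiments: circuit optimization, tuning statistics,
#' phase-warp tracking, binaural unmasking, speech-scene separation and
#' SOC adaptation. Each is deterministic given its arguments (stochastic
#' stimuli take explicit seeds), returns its report as an R object, and
#' optionally writes TSV/JSON (and WAV, where waveforms are produced) into
#' `out`, together with a small JSON run log containing an md5 hash of the
#' effective configuration.
#'
#' @name experiments
NULL

# write the run log (config + md5 hash) next to an experiment's outputs
write_run_log <- function(out, experiment, config) {
  if (is.null(out)) return(invisible(NULL))
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile()
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA, force = TRUE)
  hash <- unname(tools::md5sum(tmp))
  file.copy(tmp, file.path(out, paste0(experiment, "_config.json")),
            overwrite = TRUE)
  unlink(tmp)
  jsonlite::write_json(list(experiment = experiment, config_md5 = hash,
                            timestamp = format(Sys.time(), tz = "UTC")),
                       file.path(out, paste0(experiment, "_runlog.json")),
                       auto_unbox = TRUE)
  invisible(hash)
}

#' Optimize the circuit for a physiological ITD bound
#'
#' Runs the two-step optimization at the given `itd_max` and (optionally)
#' writes the resulting parameter table.
#'
#' @param itd_max largest target ITD in seconds.
#' @param cfg full [optimization_config()] (overrides `itd_max`).
#' @param out output directory or `NULL`.
#' @return the `optimal_parameter_table`.
#' @export
exp_optimize <- function(itd_max = 0.7e-3, cfg = optimization_config(itd_max = itd_max),
                         out = NULL) {
  table <- optimize_circuit(cfg)
  if (!is.null(out)) {
    write_run_log(out, "optimize", unclass(cfg))
    write_parameter_table(table, file.path(out, sprintf("table_itdmax%gms.tsv",
                                                        1e3 * cfg$itd_max)))
  }
  table
}

#' Tuning-curve and best-IPD statistics
#'
#' @param table `optimal_parameter_table` (default: optimized at 0.3 ms).
#' @param itd_phys physiological ITD range in seconds.
#' @param window,rectify_factor see [population_best_ipd()].
#' @param out output directory or `NULL`.
#' @return the [population_best_ipd()] report.
#' @export
exp_tuning <- function(table = NULL, itd_phys = 0.3e-3,
                       window = "physiological", rectify_factor = 0.67,
                       out = NULL) {
  if (is.null(table))
    table <- optimize_circuit(optimization_config(itd_max = itd_phys))
  rep <- population_best_ipd(table, itd_phys = itd_phys, window = window,
                             rectify_factor = rectify_factor)
  if (!is.null(out)) {
    write_run_log(out, "tuning", list(itd_phys = itd_phys, window = window,
                                      rectify_factor = rectify_factor,
                                      opt = unclass(table$config)))
    utils::write.table(rep$by_channel, file.path(out, "best_ipd_by_channel.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(mean_best_ipd_cyc = rep$mean),
                         file.path(out, "best_ipd_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  rep
}

#' Phase-warp (dynamic ITD) experiment
#'
#' Presents phase-warp stimuli at several warp frequencies and measures
#' phase locking of each target-ITD neuron's squared output waveform to the
#' warp frequency by vector strength.
#'
#' @param table `optimal_parameter_table` covering the analysis band.
#' @param f_warps warp frequencies in Hz (0 entries are diotic controls and
#'   get `NA` vector strength).
#' @param target_itds neuron labels in seconds.
#' @param duration stimulus duration in seconds.
#' @param seed stimulus seed.
#' @param out output directory or `NULL`.
#' @return data.frame with `f_warp`, `target_itd`, `vs`.
#' @export
exp_phase_warp <- function(table, f_warps = c(2^(0:9)),
                           target_itds = seq(0, 0.7e-3, length.out = 15),
                           duration = 0.5, seed = 1, out = NULL) {
  fs <- 96000
  res <- list()
  for (fw in f_warps) {
    n <- round(duration * fs)
    fw_grid <- round(fw / (fs / n)) * (fs / n)   # snap to the FFT grid
    s <- phase_warp(fw_grid, duration, fs, seed = seed)
    pop <- run_ic_model(s, table, target_itds, reconstruct = TRUE)
    edge <- 4001
    idx <- (edge + 1):(n - edge)
    # integer number of warp periods within the analysis span
    if (fw_grid > 0) {
      nper <- floor(length(idx) / fs * fw_grid)
      if (nper < 1) next
      idx <- idx[seq_len(round(nper * fs / fw_grid))]
    }
    vs <- vapply(seq_along(target_itds), function(it) {
      tr <- pop$reconstruction[[it]][idx]^2
      if (fw_grid == 0) NA_real_ else vector_strength(tr, fw_grid, fs)
    }, 0)
    res[[length(res) + 1]] <- data.frame(f_warp = fw_grid,
                                         target_itd = target_itds, vs = vs)
  }
  df <- do.call(rbind, res)
  if (!is.null(out)) {
    write_run_log(out, "phase_warp", list(f_warps = f_warps, seed = seed,
                                          duration = duration,
                                          target_itds = target_itds))
    utils::write.table(df, file.path(out, "phase_warp_vs.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  df
}

# multiplicative Gaussian jitter on the optimized parameters
jitter_table <- function(table, sd = 0.2, seed = 1) {
  with_seed(seed, {
    table$a_opt <- table$a_opt * (1 + stats::rnorm(length(table$a_opt), sd = sd))
    table$psi_c_opt <- table$psi_c_opt *
      (1 + stats::rnorm(length(table$psi_c_opt), sd = sd))
  })
  table
}

# time-averaged (edge frames excluded), optionally inhibited band powers
# of one presentation: channels x target-ITD neurons
mean_band_powers <- function(pop, j_inh = 0) {
  if (j_inh > 0) pop <- inhibitory_normalization(pop, j_inh)
  nf <- dim(pop$activity)[3]
  keep <- if (nf > 4) 3:(nf - 2) else seq_len(nf)
  apply(pop$activity[, , keep, drop = FALSE], c(1, 2), mean)
}

#' Binaural unmasking experiment
#'
#' A 400 Hz tone (signal) in a white-noise masker, presented over a
#' descending SNR grid; per SNR the dmax contrast between "tone plus
#' noise" and "noise alone" (same noise realization) is computed over
#' frequency channels and the detection threshold extracted by the peak
#' prominence rule. SNR 0 dB equalizes the tone RMS with the RMS of the
#' masker band-pass filtered to 300-500 Hz.
#'
#' @param table `optimal_parameter_table`.
#' @param signal_phase `"0"` (diotic tone) or `"pi"` (tone sign-inverted at
#'   one ear).
#' @param signal_itd,noise_itd lateralization of tone and masker in
#'   seconds (positive = contralateral-leading).
#' @param j_inh inhibitory weight `J`.
#' @param snr_db probed SNRs in dB (descending; keep below +1 dB).
#' @param target_itds neuron labels in seconds.
#' @param duration stimulus duration in seconds.
#' @param seed masker noise seed.
#' @param criterion prominence criterion for the threshold.
#' @param jitter_sd multiplicative Gaussian jitter applied to the optimal
#'   parameters (0 = none).
#' @param gammatone if `TRUE`, stimuli pass a 41-channel gammatone front
#'   end and the IC stage runs per peripheral channel.
#' @param masker_level presentation level: RMS of the masker's sub-500 Hz
#'   component in stimulus amplitude units.
#' @param out output directory or `NULL`.
#' @return list with `threshold_db`, `dmax` (list of per-SNR curves),
#'   `bf_hz`, `snr_db`, and the call configuration.
#' @export
exp_bmld <- function(table, signal_phase = c("0", "pi"),
                     signal_itd = 0, noise_itd = 0, j_inh = 20,
                     snr_db = seq(0, -30, by = -2),
                     target_itds = seq(0, 0.7e-3, length.out = 29),
                     duration = 2, seed = 1, criterion = 0.05,
                     jitter_sd = 0, gammatone = FALSE, masker_level = 1,
                     out = NULL) {
  signal_phase <- match.arg(signal_phase)
  stopifnot(all(snr_db < 1))
  fs <- 96000
  if (jitter_sd > 0) table <- jitter_table(table, sd = jitter_sd, seed = seed + 1)
  # presentation level: the sub-500 Hz (synaptically filtered) part of the
  # masker is scaled to RMS `masker_level`, which puts the per-bin band
  # powers in the partially saturated regime of the J = 20 inhibition
  raw <- white_noise(duration, fs, seed = seed)
  lev <- masker_level / rms(synaptic_lowpass(raw, fs))
  noise <- raw * lev
  ref_rms <- rms(band_noise_masker(duration, fs, seed = seed)) * lev
  tone <- pure_tone(400, duration, fs)
  s_noise <- apply_itd(noise, noise_itd, fs)
  bf_hz <- NULL
  powers <- function(s) {
    if (gammatone) {
      bf_hz <<- seq(24, 984, length.out = 41)
      gammatone_ic_powers(s, table, target_itds, j_inh = j_inh)
    } else {
      pop <- run_ic_model(s, table, target_itds, reconstruct = FALSE)
      bf_hz <<- pop$bf_hz
      mean_band_powers(pop, j_inh = j_inh)
    }
  }
  p_noise <- powers(s_noise)
  curves <- vector("list", length(snr_db))
  for (i in seq_along(snr_db)) {
    tn <- tone * ref_rms / rms(tone) * 10^(snr_db[i] / 20)
    s_tone <- apply_itd(tn, signal_itd, fs)
    if (signal_phase == "pi") s_tone$left <- -s_tone$left
    mix <- stereo_sound(s_tone$right + s_noise$right,
                        s_tone$left + s_noise$left, fs)
    p_sn <- powers(mix)
    curves[[i]] <- dmax(p_sn, p_noise)
  }
  thr <- detection_threshold(curves, snr_db, bf_hz, criterion = criterion)
  cfgl <- list(signal_phase = signal_phase, signal_itd = signal_itd,
               noise_itd = noise_itd, j_inh = j_inh, snr_db = snr_db,
               duration = duration, seed = seed, criterion = criterion,
               jitter_sd = jitter_sd, gammatone = gammatone)
  if (!is.null(out)) {
    write_run_log(out, "bmld", cfgl)
    df <- data.frame(bf_hz = rep(bf_hz, length(snr_db)),
                     snr_db = rep(snr_db, each = length(bf_hz)),
                     dmax = unlist(curves))
    utils::write.table(df, file.path(out, "dmax_curves.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(c(cfgl, list(threshold_db = thr)),
                         file.path(out, "bmld_summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(threshold_db = thr, dmax = curves, bf_hz = bf_hz, snr_db = snr_db,
       config = cfgl)
}

# IC band powers with a gammatone front end: the binaural transfer of each
# peripheral channel is applied to the full-duration spectra of that
# channel's output (stationary stimuli), yielding channels x neurons powers
gammatone_ic_powers <- function(s, table, target_itds, j_inh = 0,
                                n_channels = 41) {
  chans <- gammatone_front_end(s, n_channels = n_channels)
  centers <- vapply(chans, attr, 0, "center_hz")
  n <- length(s$right)
  p <- matrix(0, n_channels, length(target_itds))
  for (j in seq_len(n_channels)) {
    fr <- stats::fft(chans[[j]]$right) * 2 / n   # amplitude units
    fl <- stats::fft(chans[[j]]$left) * 2 / n
    kpos <- seq_len(n %/% 2 + 1)
    freqs <- (kpos - 1) * s$fs / n
    keep <- freqs <= max(table$bf_hz)
    for (it in seq_along(target_itds)) {
      cf <- bin_coefficients(table, freqs[keep], target_itds[it])
      # left-IC convention: ears swapped into the right-IC transfer
      p[j, it] <- sum(Mod(fl[kpos][keep] * cf$c_r +
                            fr[kpos][keep] * cf$c_l)^2)
    }
  }
  if (j_inh > 0) p <- inhibitory_normalization(p, j_inh)
  p
}

#' Speech-scene separation experiment
#'
#' Mixes two or three talkers at distinct ITDs, runs the IC population and
#' the Jeffress delay-line baseline broadband (no synaptic low-pass), and
#' scores separation by windowed Pearson correlation between each isolated
#' talker and the reconstructions (mean over target-ITD neurons), plus
#' winner histograms of the inhibited band powers.
#'
#' @param table `optimal_parameter_table`.
#' @param itds source ITDs in seconds (first `n_sources` are used).
#' @param n_sources 2 or 3.
#' @param sources optional list of waveforms; default: seeded
#'   [speech_surrogate()] talkers.
#' @param duration surrogate duration in seconds.
#' @param seed base seed for the surrogate talkers.
#' @param target_itds neuron labels in seconds.
#' @param j_inh inhibitory weight for the winner histograms.
#' @param window correlation window in seconds.
#' @param out output directory (writes mixture/reconstruction WAVs and
#'   TSV reports) or `NULL`.
#' @return list with `pearson` (per model: data.frame of windowed mean r
#'   per source), `winners` (per model), `trace_correlation` (IC vs delay
#'   line correlation of the windowed-r traces, per source).
#' @export
exp_speech <- function(table, itds = c(0.2e-3, 0.4e-3, -0.2e-3),
                       n_sources = 2, sources = NULL, duration = 1.5,
                       seed = 1, target_itds = seq(0, 0.7e-3, length.out = 15),
                       j_inh = 20, window = 0.02, out = NULL) {
  stopifnot(n_sources %in% c(2, 3))
  fs <- 96000
  itds <- itds[seq_len(n_sources)]
  if (is.null(sources))
    sources <- lapply(seq_len(n_sources),
                      function(i) speech_surrogate(seed + i, duration, fs))
  lat <- Map(apply_itd, sources, itds, MoreArgs = list(fs = fs))
  mix <- stereo_sound(Reduce(`+`, lapply(lat, `[[`, "right")),
                      Reduce(`+`, lapply(lat, `[[`, "left")), fs)
  pop_ic <- run_ic_model(mix, table, target_itds, lowpass_hz = NULL)
  pop_dl <- run_delay_line(mix, target_itds, lowpass_hz = NULL)
  score <- function(pop) {
    per_src <- lapply(seq_len(min(2, n_sources)), function(i) {
      rs <- sapply(pop$reconstruction, function(rec)
        windowed_pearson(rec, sources[[i]], fs, window)$r)
      data.frame(t0 = windowed_pearson(sources[[i]], sources[[i]], fs, window)$t0,
                 r_mean = rowMeans(rs, na.rm = TRUE), source = i)
    })
    do.call(rbind, per_src)
  }
  pe_ic <- score(pop_ic)
  pe_dl <- score(pop_dl)
  trace_cor <- vapply(unique(pe_ic$source), function(i) {
    a <- pe_ic$r_mean[pe_ic$source == i]
    b <- pe_dl$r_mean[pe_dl$source == i]
    ok <- is.finite(a) & is.finite(b)
    stats::cor(a[ok], b[ok])
  }, 0)
  win_ic <- winner_histogram(inhibitory_normalization(pop_ic, j_inh), window)
  win_dl <- winner_histogram(pop_dl, window)
  if (!is.null(out)) {
    write_run_log(out, "speech", list(itds = itds, n_sources = n_sources,
                                      duration = duration, seed = seed,
                                      j_inh = j_inh, window = window))
    write_wav(mix, file.path(out, "mixture.wav"))
    for (i in seq_len(n_sources))
      write_wav(stereo_sound(sources[[i]], sources[[i]], fs),
                file.path(out, sprintf("source%d.wav", i)))
    best <- vapply(itds[seq_len(min(2, n_sources))], function(x)
      which.min(abs(target_itds - x)), 0L)
    for (i in seq_along(best)) {
      write_wav(stereo_sound(pop_ic$reconstruction[[best[i]]],
                             pop_ic$reconstruction[[best[i]]], fs),
                file.path(out, sprintf("recon_ic_source%d.wav", i)))
      write_wav(stereo_sound(pop_dl$reconstruction[[best[i]]],
                             pop_dl$reconstruction[[best[i]]], fs),
                file.path(out, sprintf("recon_delayline_source%d.wav", i)))
    }
    utils::write.table(rbind(cbind(model = "ic", pe_ic),
                             cbind(model = "delay_line", pe_dl)),
                       file.path(out, "pearson_windows.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(rbind(cbind(model = "ic", win_ic),
                             cbind(model = "delay_line", win_dl)),
                       file.path(out, "winner_histograms.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  list(pearson = list(ic = pe_ic, delay_line = pe_dl),
       winners = list(ic = win_ic, delay_line = win_dl),
       trace_correlation = trace_cor,
       mixture = mix, target_itds = target_itds)
}

#' SOC adaptation experiment
#'
#' Stimulates one frequency channel with a long pure tone (or a
#' speech-surrogate sound) and tracks the adapted MSO-LSO input-plane
#' trajectory: adaptation drives the trajectory angle toward the diagonal
#' over seconds, while pauses in modulated sounds let it recover.
#'
#' @param table `optimal_parameter_table`.
#' @param bf channel best frequency in Hz.
#' @param stim_itd stimulus ITD in seconds (contralateral-leading).
#' @param duration tone duration in seconds.
#' @param stimulus `"tone"` or `"speech"`.
#' @param seed surrogate seed (speech stimulus).
#' @param state [adaptation_state()].
#' @param out output directory or `NULL`.
#' @return list with `alpha_mso`, `alpha_lso`, `angle_t` (trajectory angle
#'   per 100 ms segment, degrees), `drive` (the [soc_drive()] output).
#' @export
exp_adaptation <- function(table, bf = 400, stim_itd = 0.1e-3, duration = 2,
                           stimulus = c("tone", "speech"), seed = 1,
                           state = adaptation_state(), out = NULL) {
  stimulus <- match.arg(stimulus)
  fs <- 96000
  x <- if (stimulus == "tone") pure_tone(bf, duration, fs)
       else speech_surrogate(seed, duration, fs)
  s <- apply_itd(x, stim_itd, fs)
  ch <- frequency_channel(bf)
  j <- which.min(abs(table$bf_hz - bf))
  jt <- which.min(abs(table$target_itd - stim_itd))
  par <- circuit_params(a = max(table$a_opt[j, jt], 0),
                        psi_c = table$psi_c_opt[j])
  # left-IC convention: swap ears into the right-IC drive equations
  drv <- soc_drive(stereo_sound(s$left, s$right, fs), ch, par, state = state)
  seg <- round(0.1 * fs)
  nseg <- length(drv$mso) %/% seg
  angle_t <- vapply(seq_len(nseg), function(k) {
    i <- (k - 1) * seg + seq_len(seg)
    principal_angle(drv$mso[i], drv$lso[i])
  }, 0)
  res <- list(alpha_mso = drv$alpha_mso, alpha_lso = drv$alpha_lso,
              angle_t = angle_t, drive = drv,
              t_seg = (seq_len(nseg) - 0.5) * 0.1)
  if (!is.null(out)) {
    write_run_log(out, "adaptation", list(bf = bf, stim_itd = stim_itd,
                                          duration = duration,
                                          stimulus = stimulus, seed = seed))
    dec <- seq(1, length(drv$alpha_mso), by = 96)   # 1 kHz trace export
    utils::write.table(
      data.frame(t = (dec - 1) / fs, alpha_mso = drv$alpha_mso[dec],
                 alpha_lso = drv$alpha_lso[dec]),
      file.path(out, "alpha_trajectories.tsv"), sep = "\t",
      row.names = FALSE, quote = FALSE)
  }
  res
}
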