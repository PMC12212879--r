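#' Configuration of the two-step circuit optimization
#'
#' Grids and constants for the normative optimization: per (channel, target
#' ITD) the relative LSO weight `a` is chosen to maximize the unit-source
#' tuning power over the search box `a_range`; per channel the commissural
#' phase `psi_c` is then chosen to minimize the integrated weight-parsimony
#' loss with regularization `lambda_reg` over target ITDs in
#' `[0, itd_max]`.
#'
#' Default grid resolutions (a step 0.01, psi_c step 0.01 cyc, 64 target
#' ITDs, 25 Hz channel spacing) resolve the optimum to well inside the
#' 0.05-cycle band in which the optimal commissural phase is reported.
#'
#' @param itd_max largest target ITD in seconds; 0.7e-3 roughly matches
#'   human head diameters, 0.3e-3 cats, 0.15e-3 gerbils.
#' @param bf_channels best frequencies in Hz.
#' @param a_range closed search interval for `a` (must contain 0).
#' @param a_step grid step for `a`.
#' @param psi_c_grid candidate commissural phases in cycles.
#' @param n_itd number of target-ITD grid points over `[0, itd_max]`.
#' @param lambda_reg regularization weight on the sign penalty (default 1).
#' @param psi_m,psi_l fixed afferent phases in cycles.
#' @return an `optimization_config` list.
#' @export
optimization_config <- function(itd_max = 0.7e-3,
                                bf_channels = seq(200, 1500, by = 25),
                                a_range = c(-10, 10),
                                a_step = 0.01,
                                psi_c_grid = seq(0, 1, by = 0.01),
                                n_itd = 64,
                                lambda_reg = 1,
                                psi_m = 0.125,
                                psi_l = 0) {
  stopifnot(itd_max > 0, lambda_reg >= 0, a_range[1] < 0, a_range[2] > 0,
            a_step > 0, n_itd >= 2, all(bf_channels > 0))
  structure(list(itd_max = itd_max, bf_channels = bf_channels,
                 a_range = a_range, a_step = a_step,
                 psi_c_grid = psi_c_grid, n_itd = n_itd,
                 lambda_reg = lambda_reg, psi_m = psi_m, psi_l = psi_l),
            class = "optimization_config")
}

# target-ITD grid of a config
itd_grid <- function(cfg) seq(0, cfg$itd_max, length.out = cfg$n_itd)

# weight grid ordered by |a| ascending (positive before negative), so that
# the first maximum found is the most parsimonious one
a_grid_ordered <- function(cfg) {
  a <- seq(cfg$a_range[1], cfg$a_range[2], by = cfg$a_step)
  a[order(abs(a), -sign(a))]
}

#' Unit-source tuning power over a (weight, target-ITD) grid
#'
#' Vectorized evaluation of the ITD tuning power for every weight in `a`
#' and every target ITD in `target_itd`, at commissural phase `psi_c`.
#' Target ITDs label contralateral-leading sources; nonnegative weights use
#' the contralateral excitatory pathway, negative weights the ipsilateral
#' inhibitory one (which is independent of `psi_c`).
#'
#' @param bf_hz channel best frequency in Hz.
#' @param psi_c commissural phase in cycles.
#' @param a numeric vector of weights.
#' @param target_itd numeric vector of target ITDs in seconds
#'   (contralateral-leading).
#' @param psi_m,psi_l afferent phases in cycles.
#' @return `length(a)` x `length(target_itd)` matrix of powers.
#' @export
tuning_power_grid <- function(bf_hz, psi_c, a, target_itd,
                              psi_m = 0.125, psi_l = 0) {
  # contralateral-leading target: delta_t = -target_itd for the right IC,
  # hence the stimulus factor e^{-i w delta_t} = e^{+i w target_itd}
  w <- exp(1i * 2 * pi * bf_hz * target_itd)
  pos <- a >= 0
  u <- v <- complex(length(a))
  u[pos]  <- 1 - a[pos] * cyc(psi_l + psi_c)
  v[pos]  <- cyc(psi_m) + a[pos] * cyc(psi_c)
  u[!pos] <- 1 + a[!pos]
  v[!pos] <- cyc(psi_m) - a[!pos] * cyc(psi_l)
  p <- outer(Mod(u)^2 + Mod(v)^2, rep(1, length(target_itd))) +
    2 * Re(outer(v * Conj(u), w))
  p / (1 + a^2)
}

#' Rate-maximizing LSO weight for one target ITD
#'
#' Grid argmax of the unit-source tuning power over the weight search box;
#' ties resolve to the smallest `|a|` (positive before negative).
#'
#' @param target_itd target ITD in seconds (>= 0, contralateral-leading).
#' @param psi_c commissural phase in cycles.
#' @param channel [frequency_channel()].
#' @param cfg [optimization_config()].
#' @return the optimal weight (scalar).
#' @export
optimal_weight <- function(target_itd, psi_c, channel, cfg = optimization_config()) {
  stopifnot(target_itd >= 0)
  optimal_weight_profile(target_itd, psi_c, channel, cfg)
}

# vectorized over target_itd
optimal_weight_profile <- function(target_itd, psi_c, channel, cfg) {
  a_ord <- a_grid_ordered(cfg)
  if (length(a_ord) == 0L) stop("empty weight grid")
  p <- tuning_power_grid(channel$bf_hz, psi_c, a_ord, target_itd,
                         psi_m = cfg$psi_m, psi_l = cfg$psi_l)
  a_ord[max.col(t(p), ties.method = "first")]
}

#' Weight-parsimony loss integrand and quadrature
#'
#' The per-ITD integrand is `|a| - ln|a| + lambda * sign(-a)`: it favors
#' small LSO weights, the log barrier keeps `a` away from the pure-MSO
#' solution `a = 0`, and the sign term penalizes recruiting the (anatomically
#' minor) ipsilateral inhibitory pathway. `loss_integral` applies the
#' trapezoidal rule over the target-ITD grid; `|a|` is clamped below at
#' `a_floor` to guard the log at a (grid-)zero weight.
#'
#' @param a_values optimal weights on the target-ITD grid.
#' @param itd target-ITD grid in seconds (equal length).
#' @param lambda regularization weight.
#' @param a_floor lower clamp on `|a|` inside the log (default: the weight
#'   grid step 0.01).
#' @return scalar loss (units: seconds, from the ITD integration).
#' @export
loss_integral <- function(a_values, itd, lambda = 1, a_floor = 0.01) {
  stopifnot(length(a_values) == length(itd), length(itd) >= 2)
  aa <- pmax(abs(a_values), a_floor)
  f <- aa - log(aa) + lambda * sign(-a_values)
  sum((f[-1] + f[-length(f)]) / 2 * diff(itd))
}

#' Commissural loss of one candidate phase
#'
#' Evaluates the rate-maximizing weight on the target-ITD grid at phase
#' `psi_c` and integrates the weight-parsimony integrand over
#' `[0, itd_max]`.
#'
#' @inheritParams optimal_weight
#' @return scalar loss.
#' @export
commissural_loss <- function(psi_c, channel, cfg = optimization_config()) {
  itd <- itd_grid(cfg)
  a_opt <- optimal_weight_profile(itd, psi_c, channel, cfg)
  loss_integral(a_opt, itd, lambda = cfg$lambda_reg, a_floor = cfg$a_step)
}

#' Two-step normative optimization of the IC circuit
#'
#' Independently per frequency channel: (1) for every candidate commissural
#' phase, find the rate-maximizing weight at every target ITD; (2) select
#' the phase minimizing the integrated weight-parsimony loss, and keep the
#' weight table evaluated at that phase. Deterministic given the config.
#'
#' @param cfg [optimization_config()].
#' @return an `optimal_parameter_table`: list with `bf_hz`, `target_itd`,
#'   `a_opt` (channels x target ITDs matrix), `psi_c_opt` (per channel),
#'   `loss` (channels x psi_c grid matrix) and `config`.
#' @export
optimize_circuit <- function(cfg = optimization_config()) {
  itd <- itd_grid(cfg)
  a_ord <- a_grid_ordered(cfg)
  nbf <- length(cfg$bf_channels)
  npc <- length(cfg$psi_c_grid)
  a_opt <- matrix(NA_real_, nbf, cfg$n_itd)
  loss <- matrix(NA_real_, nbf, npc)
  psi_c_opt <- numeric(nbf)
  for (j in seq_len(nbf)) {
    bf <- cfg$bf_channels[j]
    best <- NULL
    for (k in seq_len(npc)) {
      p <- tuning_power_grid(bf, cfg$psi_c_grid[k], a_ord, itd,
                             psi_m = cfg$psi_m, psi_l = cfg$psi_l)
      ak <- a_ord[max.col(t(p), ties.method = "first")]
      loss[j, k] <- loss_integral(ak, itd, lambda = cfg$lambda_reg,
                                  a_floor = cfg$a_step)
      if (is.null(best) || loss[j, k] < best$loss) {
        best <- list(loss = loss[j, k], psi_c = cfg$psi_c_grid[k], a = ak)
      }
    }
    psi_c_opt[j] <- best$psi_c
    a_opt[j, ] <- best$a
  }
  structure(list(bf_hz = cfg$bf_channels, target_itd = itd,
                 a_opt = a_opt, psi_c_opt = psi_c_opt, loss = loss,
                 config = cfg),
            class = "optimal_parameter_table")
}

#' @export
print.optimal_parameter_table <- function(x, ...) {
  cat(sprintf("Optimal IC parameter table: %d channels (%g-%g Hz), %d target ITDs (0-%g ms)\n",
              length(x$bf_hz), min(x$bf_hz), max(x$bf_hz),
              length(x$target_itd), 1e3 * max(x$target_itd)))
  cat(sprintf("  psi_c_opt: mean %.3f cyc, range [%.2f, %.2f]\n",
              mean(x$psi_c_opt), min(x$psi_c_opt), max(x$psi_c_opt)))
  invisible(x)
}

#' Write / read an optimal parameter table
#'
#' The table is serialized as TSV (one row per channel x target ITD:
#' `bf_hz`, `target_itd_s`, `a_opt`, `psi_c_opt`) with a JSON sidecar
#' (`<path>.json`) holding the full configuration.
#'
#' @param table an `optimal_parameter_table`.
#' @param path TSV output path.
#' @return `path`, invisibly (writer); the reconstructed table (reader).
#' @export
write_parameter_table <- function(table, path) {
  df <- data.frame(
    bf_hz = rep(table$bf_hz, times = length(table$target_itd)),
    target_itd_s = rep(table$target_itd, each = length(table$bf_hz)),
    a_opt = as.vector(table$a_opt),
    psi_c_opt = rep(table$psi_c_opt, times = length(table$target_itd))
  )
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(unclass(table$config), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_parameter_table
#' @export
read_parameter_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  cfg_file <- paste0(path, ".json")
  cfg <- if (file.exists(cfg_file)) {
    raw <- jsonlite::read_json(cfg_file, simplifyVector = TRUE)
    do.call(optimization_config, raw[names(raw) %in% names(formals(optimization_config))])
  } else NULL
  bf <- sort(unique(df$bf_hz))
  itd <- sort(unique(df$target_itd_s))
  a_opt <- matrix(NA_real_, length(bf), length(itd))
  a_opt[cbind(match(df$bf_hz, bf), match(df$target_itd_s, itd))] <- df$a_opt
  psi <- df$psi_c_opt[match(bf, df$bf_hz)]
  structure(list(bf_hz = bf, target_itd = itd, a_opt = a_opt,
                 psi_c_opt = psi, loss = NULL, config = cfg),
            class = "optimal_parameter_table")
}
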