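# shared fixtures, built once per test session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# full-resolution tables at the canonical grids (one per ITD bound)
default_table <- function(itd_max) {
  cached(paste0("tab", itd_max),
         optimize_circuit(optimization_config(itd_max = itd_max)))
}

# coarser table used by the signal-path tests: 50 Hz channel spacing and a
# 0.02-cycle commissural grid resolve the same optimum at a fraction of the
# cost, and the pipeline looks parameters up by nearest best frequency
pipeline_table <- function() {
  cached("pipetab", optimize_circuit(optimization_config(
    itd_max = 0.7e-3, bf_channels = seq(100, 1500, by = 50),
    psi_c_grid = seq(0, 1, by = 0.02))))
}

# random circuit parameters for property tests
random_params <- function(variant = NULL) {
  if (is.null(variant))
    variant <- sample(c("contralateral_excitatory", "ipsilateral_inhibitory"), 1)
  circuit_params(a = stats::runif(1, -3, 3), psi_c = stats::runif(1),
                 psi_m = stats::runif(1), psi_l = stats::runif(1, 0, 0.5),
                 variant = variant)
}

# delta-regularized pseudo-inverse (independent oracle for the closed form)
regularized_pinv <- function(A, delta = 1e-8) {
  AH <- Conj(t(A))
  solve(AH %*% A + delta * diag(ncol(A))) %*% AH
}
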