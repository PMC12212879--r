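test_that("mixing pseudo-inverse matches the closed form and the Moore-Penrose identities", {
  # zero-ITD closed form: rows (1,1)/3, (2,-1)/3, (-1,2)/3
  As0 <- mixing_pseudoinverse(0, 2 * pi * 500)
  expect_equal(As0, matrix(c(1, 1, 2, -1, -1, 2) / 3, 3, 2, byrow = TRUE) + 0i,
               tolerance = 1e-12)
  # half-cycle phase: first row (e^{-i pi/2}, e^{i pi/2})/3
  As <- mixing_pseudoinverse(0.5 / 400, 2 * pi * 400)
  expect_equal(As[1, ], c(-1i, 1i) / 3, tolerance = 1e-12)

  set.seed(11)
  for (i in 1:25) {
    dt <- stats::runif(1, -1e-3, 1e-3)
    om <- 2 * pi * stats::runif(1, 50, 1500)
    A <- icbinaural:::mixing_matrix(dt, om)
    As <- mixing_pseudoinverse(dt, om)
    expect_lt(max(Mod(As %*% A %*% As - As)), 1e-10)
    expect_lt(max(Mod(A %*% As %*% A - A)), 1e-10)
    # against the delta-regularized oracle
    expect_lt(max(Mod(As - regularized_pinv(A))), 1e-6)
  }
})

test_that("delay-line estimate reduces correctly and recovers 2/3 of a matched source", {
  fs <- 96000
  z <- numeric(4800)
  est <- delay_line_estimate(z, z, 3e-4, fs)
  expect_true(all(est$s_est == 0) && all(est$nr_est == 0) && all(est$nl_est == 0))

  r <- sin(2 * pi * 300 * (0:4799) / fs)
  l <- cos(2 * pi * 200 * (0:4799) / fs)
  e0 <- delay_line_estimate(r, l, 0, fs)
  expect_equal(e0$s_est, (r + l) / 3, tolerance = 1e-9)
  expect_equal(e0$nr_est, (2 * r - l) / 3, tolerance = 1e-9)

  expect_error(delay_line_estimate(r, l[-1], 0, fs), "length")

  # noise-free band-limited source at matched ITD: minimum-norm estimate
  # carries 2/3 of the source
  src <- synaptic_lowpass(white_noise(0.4, fs, seed = 21), fs, 400)
  st <- apply_itd(src, 0.35e-3, fs)
  est <- delay_line_estimate(st$right, st$left, 0.35e-3, fs)
  mid <- 6000:(length(src) - 6000)
  gain <- sum(est$s_est[mid] * src[mid]) / sum(src[mid]^2)
  expect_equal(gain, 2 / 3, tolerance = 1e-3)
})

test_that("gamma coefficients obey their closed forms and the transfer factorization", {
  ch <- frequency_channel(700)
  # a = 0: gamma_R = 1, gamma_L = e^{-i w dt} e^{-i psi_m}, both variants
  for (v in c("contralateral_excitatory", "ipsilateral_inhibitory")) {
    p <- circuit_params(0, psi_c = 0.3, variant = v)
    g <- gamma_coefficients(p, ch$omega, 2e-4)
    expect_equal(g$gamma_r, 1 + 0i, tolerance = 1e-12)
    expect_equal(g$gamma_l, exp(-1i * ch$omega * 2e-4) * exp(-2i * pi * 0.125),
                 tolerance = 1e-12)
  }
  # ipsilateral variant at a = -1 cancels the right-ear drive
  pi1 <- circuit_params(-1, psi_c = 0.3, variant = "ipsilateral_inhibitory")
  expect_equal(gamma_coefficients(pi1, ch$omega, 1e-4)$gamma_r, 0 + 0i)

  # e^{i w dt/2} (gamma_R + gamma_L) reproduces the pure-source bracket
  set.seed(12)
  for (i in 1:50) {
    p <- random_params("contralateral_excitatory")
    dt <- stats::runif(1, -1e-3, 1e-3)
    g <- gamma_coefficients(p, ch$omega, dt)
    bracket <- exp(1i * ch$omega * dt / 2) *
      (1 - p$a * exp(-2i * pi * (p$psi_l + p$psi_c))) +
      exp(-1i * ch$omega * dt / 2) *
      (exp(-2i * pi * p$psi_m) + p$a * exp(-2i * pi * p$psi_c))
    expect_equal(exp(1i * ch$omega * dt / 2) * (g$gamma_r + g$gamma_l),
                 bracket, tolerance = 1e-12)
  }
})

test_that("ic_transfer is linear and reduces to R+L for a=0, psi_m=0", {
  ch <- frequency_channel(400)
  p0 <- circuit_params(0, psi_c = 0.3, psi_m = 0)
  expect_equal(ic_transfer(p0, ch, 0.4 + 0.1i, -0.2 + 0.5i),
               (0.4 + 0.1i) + (-0.2 + 0.5i), tolerance = 1e-12)
  p <- circuit_params(0.7, psi_c = 0.3)
  z1 <- ic_transfer(p, ch, 1 + 2i, 3 - 1i)
  expect_equal(ic_transfer(p, ch, 5 * (1 + 2i), 5 * (3 - 1i)), 5 * z1,
               tolerance = 1e-12)
  # bounded by the normalization-free worst case
  g <- gamma_coefficients(p, ch$omega, 0)
  expect_lte(Mod(z1), (Mod(1 + 2i) + Mod(3 - 1i)) *
               max(Mod(g$gamma_r), Mod(g$gamma_l)))
})

test_that("tuning power equals |transfer|^2 for pure sources and scales with level", {
  set.seed(13)
  for (i in 1:1000) {
    p <- random_params()
    ch <- frequency_channel(stats::runif(1, 100, 1500))
    dt <- stats::runif(1, -1.5e-3, 1.5e-3)
    rh <- exp(1i * ch$omega * dt / 2)
    lh <- exp(-1i * ch$omega * dt / 2)
    expect_equal(Mod(ic_transfer(p, ch, rh, lh))^2,
                 ic_power_tuning(p, ch, dt), tolerance = 1e-10)
  }
  p <- circuit_params(0.5, psi_c = 0.3)
  ch <- frequency_channel(600)
  expect_equal(ic_power_tuning(p, ch, 2e-4, source_power = 2),
               2 * ic_power_tuning(p, ch, 2e-4), tolerance = 1e-12)
  # periodic in delta_t with period 1/BF
  dts <- seq(-5e-4, 5e-4, length.out = 7)
  expect_equal(ic_power_tuning(p, ch, dts), ic_power_tuning(p, ch, dts + 1 / 600),
               tolerance = 1e-9)
})

test_that("ipsilateral variant with a=-1 yields a flat tuning curve", {
  p <- circuit_params(-1, psi_c = 0.3, variant = "ipsilateral_inhibitory")
  pw <- ic_power_tuning(p, frequency_channel(500), seq(-2e-3, 2e-3, length.out = 41))
  expect_lt(diff(range(pw)), 1e-12)
})

test_that("weight vector is unit-norm with the right direction", {
  expect_equal(weight_vector(0), c(1, 0))
  expect_equal(weight_vector(1), c(1, 1) / sqrt(2))
  for (a in c(-7.3, -0.2, 0.01, 2.5, 9.9))
    expect_equal(sqrt(sum(weight_vector(a)^2)), 1, tolerance = 1e-12)
})

test_that("MSO-LSO trajectories encode ITD in a level-invariant inclination", {
  ch <- frequency_channel(800)
  # diotic, psi_m = 0: MSO = 2 S, LSO = 0 -> trajectory on the MSO axis
  tr0 <- mso_lso_trajectory(ch, 0, psi_c = 0.3, duration = 0.05, psi_m = 0)
  expect_lt(max(abs(tr0$lso)), 1e-8 * max(abs(tr0$mso)))
  expect_equal(tr0$angle, 0, tolerance = 1e-6)

  # level invariance of the angle
  tr1 <- mso_lso_trajectory(ch, 2e-4, psi_c = 0.3, duration = 0.05)
  tr2 <- mso_lso_trajectory(ch, 2e-4, psi_c = 0.3, duration = 0.05, amplitude = 7)
  expect_equal(tr2$mso, 7 * tr1$mso, tolerance = 1e-9)
  expect_equal(tr1$angle, tr2$angle, tolerance = 1e-9)

  # inclination grows monotonically with ITD over the physiological range
  angles <- vapply(seq(0, 0.6e-3, length.out = 7), function(dt)
    mso_lso_trajectory(ch, -dt, psi_c = 0.3, duration = 0.05)$angle, 0)
  expect_true(all(diff(angles) > 0))
})
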