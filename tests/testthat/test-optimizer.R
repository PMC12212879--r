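test_that("optimal_weight stays in the search box and matches a finer grid search", {
  cfg <- optimization_config()
  set.seed(31)
  for (i in 1:12) {
    bf <- stats::runif(1, 200, 1500)
    psi_c <- stats::runif(1)
    itd <- stats::runif(1, 0, 0.7e-3)
    ch <- frequency_channel(bf)
    a_opt <- optimal_weight(itd, psi_c, ch, cfg)
    expect_gte(a_opt, -10)
    expect_lte(a_opt, 10)
    # 10x finer exhaustive search agrees to within one coarse grid step
    cfg_fine <- optimization_config(a_step = 0.001)
    a_fine <- optimal_weight(itd, psi_c, ch, cfg_fine)
    expect_lte(abs(a_opt - a_fine), cfg$a_step + 1e-12)
  }
})

test_that("high commissural phase forces the weight to (near) zero at low IPD", {
  # at psi_c = 0.7 the input-space inclinations are unreachable by the
  # excitatory pathway; except at high IPD the best choice is a ~ 0
  cfg <- optimization_config()
  a <- optimal_weight(0.05e-3, 0.7, frequency_channel(300), cfg)
  expect_lte(abs(a), 0.1)
})

test_that("loss integrand quadrature reproduces closed-form constants", {
  itd <- seq(0, 0.7e-3, length.out = 64)
  # constant a = 1: integrand 1 - 0 - 1 = 0
  expect_equal(loss_integral(rep(1, 64), itd, lambda = 1), 0, tolerance = 1e-15)
  # constant a = -1: integrand 1 - 0 + 1 = 2 over [0, ITDmax]
  expect_equal(loss_integral(rep(-1, 64), itd, lambda = 1), 2 * 0.7e-3,
               tolerance = 1e-12)
  # constant a = e: integrand e - 1 - 1
  expect_equal(loss_integral(rep(exp(1), 64), itd, lambda = 1),
               (exp(1) - 2) * 0.7e-3, tolerance = 1e-12)
  # |a| clamped at the floor keeps the log finite at a grid zero
  expect_true(is.finite(loss_integral(rep(0, 64), itd, a_floor = 0.01)))
})

test_that("optimize_circuit is reproducible and internally consistent", {
  cfg <- optimization_config(itd_max = 0.7e-3, bf_channels = c(400, 900),
                             psi_c_grid = seq(0, 1, by = 0.05))
  t1 <- optimize_circuit(cfg)
  t2 <- optimize_circuit(cfg)
  expect_identical(t1$a_opt, t2$a_opt)
  expect_identical(t1$psi_c_opt, t2$psi_c_opt)
  # loss at the selected phase is the row minimum
  for (j in seq_along(cfg$bf_channels)) {
    k <- match(t1$psi_c_opt[j], cfg$psi_c_grid)
    expect_equal(t1$loss[j, k], min(t1$loss[j, ]))
  }
  # commissural_loss agrees with the stored loss row
  cl <- commissural_loss(cfg$psi_c_grid[3], frequency_channel(400), cfg)
  expect_equal(cl, t1$loss[1, 3], tolerance = 1e-12)
  expect_true(all(abs(t1$a_opt) <= 10))
})

test_that("optimal weights collapse onto a common function of IPD across channels", {
  tab <- default_table(0.7e-3)
  # compare a_opt at matched IPD between a low and a high BF channel
  j1 <- match(500, tab$bf_hz); j2 <- match(1000, tab$bf_hz)
  ipd2 <- tab$target_itd * tab$bf_hz[j2]
  keep <- ipd2 <= max(tab$target_itd * tab$bf_hz[j1])
  a2 <- tab$a_opt[j2, keep]
  a1_interp <- stats::approx(tab$target_itd * tab$bf_hz[j1], tab$a_opt[j1, ],
                             xout = ipd2[keep])$y
  expect_lt(stats::median(abs(a2 - a1_interp)), 0.05)
})

test_that("negative weights appear only at high IPD", {
  tab <- default_table(0.7e-3)
  ipd <- outer(tab$bf_hz, tab$target_itd)
  expect_true(all(tab$a_opt[ipd < 0.25] >= 0))
})

test_that("parameter tables round-trip through TSV", {
  tab <- optimize_circuit(optimization_config(
    itd_max = 0.3e-3, bf_channels = c(300, 600), psi_c_grid = seq(0, 1, 0.1),
    n_itd = 8))
  path <- file.path(tempdir(), "table.tsv")
  write_parameter_table(tab, path)
  back <- read_parameter_table(path)
  expect_equal(back$bf_hz, tab$bf_hz)
  expect_equal(back$a_opt, tab$a_opt, tolerance = 1e-9)
  expect_equal(back$psi_c_opt, tab$psi_c_opt)
  expect_equal(back$config$itd_max, tab$config$itd_max)
})
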