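test_that("Beer-Lambert conversion and its linearities", {
  expect_equal(rate_from_absorbance(0.0286, protein = 0.025), 0.16)
  expect_equal(rate_from_absorbance(0, protein = 1), 0)
  # glutathione-assay coefficient
  expect_equal(rate_from_absorbance(0.0136, epsilon = 13.6, volume = 0.5,
                                    protein = 1), 5e-4)
  expect_error(rate_from_absorbance(0.1, protein = 0), "positive")
  base <- rate_from_absorbance(0.02, protein = 0.05)
  expect_equal(rate_from_absorbance(0.04, protein = 0.05), 2 * base)
  expect_equal(rate_from_absorbance(0.02, volume = 0.8, protein = 0.05),
               2 * base)
  expect_equal(rate_from_absorbance(0.02, protein = 0.1), base / 2)
})

test_that("rate laws obey their defining identities", {
  p <- list(vmax = 0.519, km = 0.092, ki = 6.5)
  expect_equal(mm_rate(p, p$km), p$vmax / 2)
  expect_equal(mm_rate(p, 0), 0)
  expect_equal(mm_rate(p, 0.75), 0.519 * 0.75 / 0.842)
  expect_equal(competitive_rate(p, 0.5, 0), mm_rate(p, 0.5))
  # I = ki doubles the apparent Km
  expect_equal(competitive_rate(p, 0.3, p$ki),
               p$vmax * 0.3 / (2 * p$km + 0.3))
  expect_equal(competitive_rate(p, 0.5, 5),
               0.519 * 0.5 / (0.092 * (1 + 5 / 6.5) + 0.5))
  expect_error(competitive_rate(list(vmax = 1, km = 1), 1, 1), "ki")
  # monotone in S, antitone in I
  s_grid <- seq(0.01, 2, length.out = 20)
  expect_true(all(diff(competitive_rate(p, s_grid, 1)) > 0))
  i_grid <- seq(0, 20, length.out = 20)
  expect_true(all(diff(competitive_rate(p, 0.5, i_grid)) < 0))
})

test_that("Michaelis-Menten fit recovers exact parameters from exact data", {
  # unit parameters on an exact grid
  s <- c(0.2, 0.5, 1, 2, 5)
  d <- kinetics_dataset(s, s / (1 + s))
  fit <- fit_mm(d)
  expect_equal(fit$vmax, 1, tolerance = 1e-8)
  expect_equal(fit$km, 1, tolerance = 1e-8)
  expect_true(fit$converged)
  # property sweep over the parameter plane, design scaled to each Km
  set.seed(51)
  for (i in 1:8) {
    vmax <- stats::runif(1, 0.01, 10)
    km <- stats::runif(1, 0.01, 10)
    s <- km * c(0.2, 0.5, 1, 2, 4, 8)
    fit <- fit_mm(kinetics_dataset(s, vmax * s / (km + s)))
    expect_equal(fit$vmax, vmax, tolerance = 1e-6)
    expect_equal(fit$km, km, tolerance = 1e-6)
  }
  expect_error(fit_mm(kinetics_dataset(rep(1, 3), rep(0.5, 3))), "distinct")
})

test_that("the four linearizations agree with each other and with NLS on exact data", {
  truth <- dwm_glyi_params()
  d <- make_kinetics(truth, mm_design(), noise_sigma = 0, seed = 1)$data
  ests <- lapply(c("lineweaver_burk", "eadie_hofstee", "hanes",
                   "eadie_scatchard"), function(kind) linearize(d, kind))
  for (e in ests) {
    expect_equal(e$vmax, truth$vmax, tolerance = 1e-9, info = e$kind)
    expect_equal(e$km, truth$km, tolerance = 1e-9, info = e$kind)
  }
  # documented parameter interpretation for LB and Hanes
  lb <- ests[[1]]
  expect_equal(lb$intercept, 1 / truth$vmax, tolerance = 1e-9)
  expect_equal(lb$slope, truth$km / truth$vmax, tolerance = 1e-9)
  hanes <- ests[[3]]
  expect_equal(hanes$slope, 1 / truth$vmax, tolerance = 1e-9)
  # zero-rate points are excluded with a warning
  d0 <- kinetics_dataset(c(0, 0.1, 0.5, 1), c(0, 0.3, 0.6, 0.7))
  expect_warning(linearize(d0, "lineweaver_burk"), "excluded")
})

test_that("Dixon analysis recovers the inhibition constant from exact data", {
  truth <- dwm_glyi_params()
  dd <- dixon_design()
  d <- make_kinetics(truth, dd$S, dd$I, noise_sigma = 0, seed = 1)$data
  dx <- dixon_ki(d)
  expect_equal(dx$ki, truth$ki, tolerance = 1e-6)
  expect_equal(dx$ki_global, truth$ki, tolerance = 1e-6)
  expect_equal(nrow(dx$lines), 4L)
  # closed-form two-line case: vmax 1, km 1, ki 2; lines cross at I = -2
  p <- list(vmax = 1, km = 1, ki = 2)
  g <- expand.grid(S = c(0.5, 2), I = c(0, 1, 4))
  d2 <- kinetics_dataset(g$S, competitive_rate(p, g$S, g$I), g$I)
  expect_equal(dixon_ki(d2)$ki, 2, tolerance = 1e-9)
  # degenerate designs fail loudly
  expect_error(dixon_ki(kinetics_dataset(c(0.5, 1), c(0.2, 0.3), I = 5)),
               "degenerate|inhibitor")
  # parallel lines (uncompetitive-like pattern) have no finite intersection
  lines_par <- expand.grid(S = c(0.5, 1), I = c(1, 5, 10))
  v_par <- 1 / (1 + 0.3 * lines_par$I + 1 / lines_par$S)
  expect_error(dixon_ki(kinetics_dataset(lines_par$S, v_par, lines_par$I)),
               "parallel|intersection")
})

test_that("noisy kinetics estimates are unbiased within Monte-Carlo error", {
  truth <- dwm_glyi_params()
  n_rep <- 60
  km_hat <- vmax_hat <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    d <- make_kinetics(truth, mm_design(), noise_sigma = 0.02,
                       seed = 6000 + r, replicates = 3)$data
    f <- suppressWarnings(fit_mm(d))
    km_hat[r] <- f$km; vmax_hat[r] <- f$vmax
  }
  expect_lt(abs(mean(km_hat) - truth$km), 3 * stats::sd(km_hat) / sqrt(n_rep))
  expect_lt(abs(mean(vmax_hat) - truth$vmax),
            3 * stats::sd(vmax_hat) / sqrt(n_rep))
})

test_that("metal-activation line matches the two-point slope and flags misuse", {
  ma <- metal_activation(c(0.125, 1.5), c(5, 75))
  expect_equal(ma$slope, (75 - 5) / (1.5 - 0.125))
  expect_equal(ma$predict(1.5), 75)
  flat <- metal_activation(c(0.1, 0.5, 1), c(20, 20, 20))
  expect_equal(flat$slope, 0)
  expect_equal(flat$intercept, 20)
  expect_error(metal_activation(0.5, 30), "doses")
  expect_warning(metal_activation(c(0.125, 1.5), c(5, 75))$predict(2),
                 "outside")
})
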