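test_that("conductance moments follow Campbell's theorem", {
  ic <- tc_input()
  ic$K_e <- 25; ic$K_i <- 25  # single-synapse-scale oracle values
  g <- conductance_moments(nu_e = 10, nu_i = 0, ic)
  # muGe = nu K tau Q = 10 * 25 * 0.005 * 1 = 1.25 nS
  expect_equal(g$muGe, 1.25)
  expect_equal(g$muGi, 0)
  # sigmaGe = Q sqrt(nu K tau / 2) = sqrt(0.625)
  expect_equal(g$sigmaGe, sqrt(0.625))
  expect_equal(g$muG, 1.25 + 10)  # leak included
  expect_error(conductance_moments(-1, 0, ic), "non-negative")
})

test_that("membrane moments: mean, single-class limit, zero-input convention", {
  ic <- tc_input()
  ic$K_e <- 25; ic$K_i <- 25
  m <- membrane_moments(nu_e = 10, nu_i = 0, w = 0, ic)
  # muV = (muGe Ee + gL EL) / muG = (0 - 650) / 11.25
  expect_equal(m$muV, -650 / 11.25, tolerance = 1e-12)
  # with a single synaptic class the autocorrelation time is tau_m + tau_e
  expect_equal(m$tauV, m$tau_m + 5, tolerance = 1e-9)
  expect_gt(m$sigmaV, 0)
  # adaptation current hyperpolarises the mean
  m_w <- membrane_moments(10, 0, w = 100, ic)
  expect_lt(m_w$muV, m$muV)
  # no input at all: sigmaV = 0, tauV falls back to tau_m + max(tau_e, tau_i)
  m0 <- membrane_moments(0, 0, 0, ic)
  expect_equal(m0$sigmaV, 0)
  expect_equal(m0$muV, ic$EL)
  expect_equal(m0$tauV, ic$cm / ic$gL + 5)
  # static noise conductances shift the mean without adding variance
  mg <- membrane_moments(10, 0, 0, ic, extra_gi = 5)
  expect_lt(mg$muV, m$muV)
  expect_lt(mg$sigmaV, m$sigmaV)  # larger muG shrinks the effective PSP size
})

test_that("effective threshold is the polynomial in normalised moments", {
  co <- tf_preset("TC")
  nrm <- co$norm
  centre <- tibble::tibble(muV = nrm$muV0, sigmaV = nrm$sigmaV0,
                           tauVN = nrm$tauVN0)
  expect_equal(effective_threshold(centre, co), unname(co$P["P0"]))
  # one normalised unit along muV adds Pmu + Pmumu
  off <- tibble::tibble(muV = nrm$muV0 + nrm$dmuV0, sigmaV = nrm$sigmaV0,
                        tauVN = nrm$tauVN0)
  expect_equal(effective_threshold(off, co),
               unname(co$P["P0"] + co$P["Pmu"] + co$P["Pmumu"]))
  expect_error(tf_coefficients(1:5), "10 finite")
})

test_that("transfer rate is bounded, monotone in its drives, erfc-consistent", {
  ic <- tc_input()
  co <- tf_preset("TC")
  nu_e <- seq(0.5, 30, length.out = 12)
  r <- transfer_rate(nu_e, nu_i = 5, w = 0, co, ic)
  tauV <- membrane_moments(nu_e, 5, 0, ic)$tauV
  expect_true(all(r >= 0 & r <= 1e3 / tauV + 1e-9))
  expect_true(all(diff(r) >= -1e-9))          # increasing in excitation
  # decreasing in inhibition within the fluctuation-driven regime; near the
  # saturated regime the rate bound 1/tauV itself grows with total
  # conductance, so monotonicity only holds below saturation
  r_i <- transfer_rate(5, c(10, 20, 30, 40), 0, co, ic)
  expect_true(all(diff(r_i) <= 1e-9))
  # adaptation suppresses the rate
  expect_lt(transfer_rate(10, 5, w = 200, coeffs = co, ic = ic),
            transfer_rate(10, 5, w = 0, coeffs = co, ic = ic))
  # hand-evaluated erfc identity at one point
  m <- membrane_moments(10, 5, 0, ic)
  vt <- effective_threshold(m, co)
  manual <- 0.5 / (m$tauV * 1e-3) *
    (2 * pnorm((vt - m$muV) / m$sigmaV, lower.tail = FALSE))
  expect_equal(transfer_rate(10, 5, 0, co, ic), manual, tolerance = 1e-10)
})

test_that("the prediction matches a direct single-cell simulation", {
  # one moderate-rate grid point: semi-analytic rate vs Monte-Carlo rate
  pars <- awake_tc()
  ic <- tc_input(pars)
  nu_e <- 4; nu_i <- 10
  pred <- transfer_rate(nu_e, nu_i,
                        w = thalamr:::stationary_w(
                          transfer_rate(nu_e, nu_i, 0, tf_preset("TC"), ic),
                          nu_e, nu_i, pars, ic),
                        tf_preset("TC"), ic)
  mc <- sample_single_cell_rates(pars, ic,
                                 data.frame(nu_e = nu_e, nu_i = nu_i),
                                 duration = 4000, reps = 6, seed = 21)
  expect_equal(pred, mc$nu_out, tolerance = 0.35)
})

test_that("two-stage fit recovers known coefficients from clean synthetic rates", {
  # adaptation switched off so the generating model is exactly invertible
  pars <- awake_tc(a = 0, b = 0)
  ic <- tc_input(pars)
  truth <- tf_preset("TC")
  grid <- tf_fit_grid(n_e = 10, e_range = c(0.5, 60),
                      nu_i_values = c(0, 5, 10, 20))
  rt <- grid
  rt$nu_out <- transfer_rate(grid$nu_e, grid$nu_i, 0, truth, ic)
  fit <- fit_transfer_function(rt, pars, ic, min_points = 30)
  expect_s3_class(fit, "tf_fit")
  expect_lt(fit$rmse, 0.05)
  expect_equal(unname(fit$coefficients$P["P0"]), unname(truth$P["P0"]),
               tolerance = 0.01)
  td <- tidy(fit)
  expect_identical(td$term[1], "P0")
  expect_identical(nrow(td), 10L)
  expect_identical(nrow(glance(fit)), 1L)
  expect_error(fit_transfer_function(rt[1:5, ], pars, ic), "active points")
})
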