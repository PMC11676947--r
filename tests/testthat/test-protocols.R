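test_that("autocorrelation_time recovers the timescale of an OU trace", {
  path <- sample_ou(ou_noise(mean = 0, sd = 1, tau_corr = 10), 2e5, dt = 1,
                    seed = 13)
  tau <- autocorrelation_time(path$x, dt = 1)
  expect_equal(tau, 10, tolerance = 0.25)
  expect_warning(flat <- autocorrelation_time(rep(2, 100), dt = 1), "constant")
  expect_true(is.na(flat))
  # tibble input infers dt from the time column
  rt <- tibble::tibble(t = seq(0, by = 2, length.out = length(path$x)),
                       rate = path$x)
  expect_equal(autocorrelation_time(rt), 2 * tau, tolerance = 0.3)
})

test_that("fit_sigmoid recovers a known logistic and falls back gracefully", {
  fs <- thalamr:::fit_sigmoid
  x <- seq(0, 30, by = 1)
  y <- thalamr:::sigmoid4(x, lo = 0, hi = 12, x0 = 14, s = 3)
  fit <- fs(x, y)
  expect_true(fit$fitted)
  expect_equal(fit$max_slope, 12 / (4 * 3), tolerance = 0.01)
  expect_equal(fit$shift, 14, tolerance = 0.1)
  expect_null(fs(x, rep(1, length(x))))  # flat curve
  # noisy curve still yields a finite slope estimate (fit or fallback)
  set.seed(1)
  fit2 <- fs(x, y + rnorm(length(x), sd = 0.2))
  expect_true(is.finite(fit2$max_slope))
})

test_that("response gain is positive and linear in the awake state", {
  cfg <- mf_config("awake")
  g <- response_gain(cfg, P_const = 4, S_amplitudes = c(0, 5, 10))
  expect_gt(g$gain, 0)
  expect_gt(g$r_squared, 0.95)
  expect_identical(nrow(g$curve), 3L)
  expect_true(all(diff(g$curve$rate) > 0))
  expect_gt(g$sigmaV_bar, 0)
  # without time-varying noise the total fluctuation equals the shotnoise one
  expect_equal(g$sigmaV_total, g$sigmaV_bar, tolerance = 1e-6)
})

test_that("conductance-response scan rises with Qe and fits a sigmoid", {
  cfg <- mf_config("awake")
  sc <- conductance_response_scan(seq(2, 30, by = 7), backend = "mean_field",
                                  cfg = cfg, input_rate = 10,
                                  relative = TRUE, seed = 3L)
  expect_true(all(diff(sc$curve$response) >= -1e-6))
  expect_equal(max(sc$curve$response), 1)  # relative normalisation
  expect_true(is.finite(sc$fit$max_slope))
  expect_gt(sc$fit$max_slope, 0)
})

test_that("peak response and ISI probability protocols return sane curves", {
  cfg <- mf_config("awake")
  pr <- peak_response_curve(cfg, sigma_l_values = c(25, 100),
                            backend = "mean_field", P_const = 4, A = 10)
  expect_s3_class(pr, "response_curve")
  expect_identical(nrow(pr), 2L)
  expect_true(all(pr$peak > 0))
  expect_equal(pr$rel_peak, pr$peak / 10)

  isi <- isi_response_probability(awake_tc(Qe = 14), input_rate = 10,
                                  duration = 2e4, seed = 2L)
  expect_true(all(isi$p_response >= 0 & isi$p_response <= 1, na.rm = TRUE))
  expect_true(all(c("isi_mid", "p_response", "n_events",
                    "wide_uncertainty") %in% names(isi)))
  expect_identical(sum(isi$n_events), sum(isi$n_events[!is.na(isi$p_response)]))
})

test_that("adaptation metric is stronger in sleep than awake", {
  ic_a <- tc_input(awake_tc())
  f_a <- firing_adaptation_metric(awake_tc(), tf_preset("TC"), ic_a,
                                  polarization = 0, nu_in = 10)
  p_s <- sleep_tc()
  ic_s <- tc_input(p_s)
  f_s <- firing_adaptation_metric(p_s, tf_preset("TC"), ic_s,
                                  polarization = 0, nu_in = 10)
  expect_true(f_a$F_adapt >= 0 && f_a$F_adapt <= 1)
  expect_true(f_s$F_adapt >= 0 && f_s$F_adapt <= 1)
  expect_gt(f_s$F_adapt, f_a$F_adapt)
})

test_that("awake mean-field relaxes after a kick (no spurious limit cycle)", {
  cfg <- mf_config("awake")
  rep_ <- spindle_run(cfg, "mean_field", duration = 3000)
  expect_s3_class(rep_, "spindle_report")
  expect_false(rep_$limit_cycle)
  expect_lt(rep_$amplitude, 0.5)
})

test_that("cortical drive scan returns converged fixed points", {
  cfg <- mf_config("awake")
  cs <- cortical_drive_scan(cfg, P_values = c(0, 2, 4))
  expect_identical(nrow(cs$scan), 3L)
  expect_true(all(cs$scan$converged))
  expect_true(all(diff(cs$scan$nu_i) > 0))  # inhibition recruits with drive
  expect_true(is.na(cs$turning_point))      # no minimum on this short grid
})
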