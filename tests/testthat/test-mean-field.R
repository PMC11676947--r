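test_that("the undriven mean-field rests at the silent fixed point", {
  cfg <- mf_config("awake")
  d <- mf_derivatives(mf_state(), cfg, P = 0, S = 0)
  expect_true(all(abs(d) < 1e-9))
  tr <- integrate_mf(cfg, 200, P = 0, S = 0)
  expect_true(all(tr$nu_e < 1e-9))
  expect_true(all(tr$nu_i < 1e-9))
})

test_that("integrate_mf produces a well-formed trajectory", {
  cfg <- mf_config("awake")
  tr <- integrate_mf(cfg, 500, P = 4, S = 0, stride = 10)
  expect_s3_class(tr, "mf_trajectory")
  expect_true(all(c("t", "nu_e", "nu_i", "c_ee", "c_ei", "c_ii",
                    "w_e", "w_i", "muV_e", "sigmaV_e") %in% names(tr)))
  expect_equal(tr$t[2] - tr$t[1], cfg$dt * 10)
  expect_true(all(tr$nu_e >= 0 & tr$nu_i >= 0))
  expect_true(all(is.finite(unlist(tr))))
  expect_true(is.numeric(attr(tr, "clips")))
  expect_error(mf_config("awake", dt = 2), "at most")
})

test_that("stationary_state lands on a root of the derivatives", {
  cfg <- mf_config("awake")
  st <- stationary_state(cfg, P = 4)
  expect_true(st$converged)
  s <- mf_state(st$nu_e, st$nu_i, st$c_ee, st$c_ei, st$c_ii, st$w_e, st$w_i)
  d <- mf_derivatives(s, cfg, P = 4)
  expect_lt(max(abs(d)), 1e-3)
  # the cortical drive recruits the inhibitory population much more strongly
  expect_gt(st$nu_i, st$nu_e)
  # adaptation is in self-consistent balance with the rates
  expect_equal(unname(st$w_e),
               unname(cfg$params_e$b * cfg$params_e$tau_w * 1e-3 * st$nu_e +
                        cfg$params_e$a * (st$muV_e - cfg$params_e$EL)),
               tolerance = 0.05)
})

test_that("mean-field stationary rates match the spiking network at P = 4", {
  cfg <- mf_config("awake")
  st <- stationary_state(cfg, P = 4)

  ncfg <- network_config("awake", seed = 11L)
  conn <- build_connectivity(ncfg)
  ras <- simulate_network(conn, ncfg, duration = 11000, P_drive = 4, seed = 8L)
  rate <- function(pop) {
    rt <- bin_population_rate(ras, pop, 5)
    mean(rt$rate[rt$t > 1000])
  }
  nu_e_net <- rate("TC"); nu_i_net <- rate("RE")
  # parity within one mean-field population-rate sd (finite-size scale)
  expect_lt(abs(nu_i_net - st$nu_i), max(st$sd_i, 0.1 * st$nu_i))
  expect_lt(abs(nu_e_net - st$nu_e), max(st$sd_e, 1))
})

test_that("OU conductance noise is block-averaged, clipped and seeded", {
  spec <- ou_noise(mean = 3, sd = 3, tau_corr = 20, target = "conductance_e")
  nz <- ou_conductance_noise(spec, duration = 5000, T_ms = 5, seed = 9)
  expect_s3_class(nz, "noisy_conductances")
  expect_length(nz$ge, 1000)
  expect_true(all(nz$ge >= 0) && all(nz$gi >= 0))
  # block means concentrate near the stationary mean (clipping biases up a bit)
  expect_equal(mean(nz$ge), 3, tolerance = 0.35)
  # e and i classes are independent paths
  expect_false(isTRUE(all.equal(nz$ge, nz$gi)))
  nz2 <- ou_conductance_noise(spec, duration = 5000, T_ms = 5, seed = 9)
  expect_identical(nz$ge, nz2$ge)
  # static noise conductances shift the mean-field operating point
  cfg <- mf_config("awake")
  st0 <- stationary_state(cfg, P = 4)
  st_g <- stationary_state(cfg, P = 4, noise_ge = 2, noise_gi = 6)
  expect_false(isTRUE(all.equal(st0$nu_e, st_g$nu_e)))
})

test_that("mf_state validates and orders its fields", {
  s <- mf_state(1, 2, 3, -1, 5, 10, -20)
  expect_named(s, c("nu_e", "nu_i", "c_ee", "c_ei", "c_ii", "w_e", "w_i"))
  expect_error(mf_state(nu_e = -1), "nu_e")
})
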