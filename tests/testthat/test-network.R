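test_that("connectivity realises the requested Erdos-Renyi statistics", {
  cfg <- network_config("awake", seed = 3L)
  conn <- build_connectivity(cfg)
  deg <- conn$in_degree
  # expected mean in-degree is p * N_src; allow 5 binomial standard errors
  # of the across-target mean
  expected <- c(tc_re = 0.05 * 500, re_tc = 0.05 * 500, re_re = 0.3 * 499,
                p_tc = 0.05 * 8000, p_re = 0.05 * 8000, s_tc = 1 * 500)
  for (nm in names(expected)) {
    row <- deg[deg$projection == nm, ]
    sd_deg <- max(row$sd_in_degree, 1e-9)
    se_mean <- sd_deg / sqrt(500)
    expect_lt(abs(row$mean_in_degree - expected[[nm]]), 5 * se_mean + 1e-9,
              label = paste("in-degree of", nm))
  }
  # the p = 1 sensory projection is all-to-all: every TC cell receives all
  # 500 sensory sources
  s_tc <- conn$proj$s_tc
  expect_identical(length(s_tc$tgt), 500L * 500L)
  expect_identical(deg$sd_in_degree[deg$projection == "s_tc"], 0)
  # no RE->RE self edges
  re_re <- conn$proj$re_re
  for (s in c(1L, 100L, 500L)) {
    tg <- re_re$tgt[(re_re$ptr[s] + 1):re_re$ptr[s + 1]]
    expect_false((s - 1L) %in% tg)
  }
  # reproducible from the config seed
  conn2 <- build_connectivity(cfg)
  expect_identical(conn$proj$tc_re$tgt, conn2$proj$tc_re$tgt)
})

test_that("undriven network stays silent; driven network fires and conserves counts", {
  cfg <- network_config("awake", N_tc = 100, N_re = 100, N_P = 1000,
                        N_S = 100, seed = 5L)
  conn <- build_connectivity(cfg)
  quiet <- simulate_network(conn, cfg, duration = 500, P_drive = 0,
                            S_drive = 0, seed = 2L)
  expect_identical(nrow(quiet$spikes), 0L)

  ras <- simulate_network(conn, cfg, duration = 1000, P_drive = 8,
                          S_drive = 0, seed = 2L)
  expect_gt(nrow(ras$spikes), 0)
  expect_true(all(ras$spikes$t >= 0 & ras$spikes$t <= ras$duration))
  expect_true(all(ras$spikes$population[ras$spikes$id <= 100] == "TC"))
  # rate binning conserves the spike count exactly
  for (pop in c("TC", "RE")) {
    rt <- bin_population_rate(ras, pop, T_bin = 5)
    n_pop <- 100
    total <- sum(rt$rate * n_pop * 5e-3)
    expect_equal(total, sum(ras$spikes$population == pop), tolerance = 1e-9)
  }
  # reproducibility of the dynamical seed
  ras2 <- simulate_network(conn, cfg, duration = 1000, P_drive = 8,
                           S_drive = 0, seed = 2L)
  expect_identical(ras$spikes$t, ras2$spikes$t)
})

test_that("membrane statistics exclude clamped refractory segments", {
  cfg <- network_config("awake", N_tc = 100, N_re = 100, N_P = 1000,
                        N_S = 100, seed = 5L)
  conn <- build_connectivity(cfg)
  ras <- simulate_network(conn, cfg, duration = 1000, P_drive = 8,
                          record_v = 1:10, seed = 4L)
  ms <- membrane_statistics(ras, t_min = 200)
  expect_gt(ms$n_samples, 0)
  expect_true(is.finite(ms$mean) && is.finite(ms$sd))
  # subthreshold mean lies between the inhibitory reversal and the spike
  # detection threshold
  expect_gt(ms$mean, -80)
  expect_lt(ms$mean, -20)
  expect_true(is_tibble(ms$histogram))
  expect_error(membrane_statistics(
    simulate_network(conn, cfg, 100, P_drive = 0, seed = 1L)), "no recorded")
})
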