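test_that("presets encode the state differences and validate overrides", {
  tc_a <- awake_tc()
  tc_s <- sleep_tc()
  re_a <- awake_re()
  re_s <- thalamic_cell_params("RE", "sleep")

  expect_s3_class(tc_a, "cell_params")
  # awake TC: no subthreshold adaptation, weak spike-triggered adaptation
  expect_identical(tc_a$a, 0)
  expect_identical(tc_a$b, 10)
  expect_identical(tc_a$EL, -65)
  # sleep strengthens adaptation and hyperpolarises, everything else inherited
  expect_identical(tc_s$EL, -70)
  expect_identical(tc_s$a, 24)
  expect_identical(tc_s$b, 200)
  expect_identical(tc_s$tau_w, 270)
  expect_identical(tc_s$Qe, tc_a$Qe)
  expect_identical(tc_s$Vt, tc_a$Vt)
  expect_identical(re_s$EL, -85)
  expect_identical(re_a$V_reset, -55)
  # spindle state only raises the reset on top of sleep
  tc_sp <- thalamic_cell_params("TC", "spindle")
  expect_identical(tc_sp$V_reset, -48)
  expect_identical(tc_sp$EL, -70)
  re_sp <- thalamic_cell_params("RE", "spindle")
  expect_identical(re_sp$V_reset, -42)
  # overrides
  expect_identical(awake_tc(EL = -70)$EL, -70)
  expect_error(awake_tc(nonsense = 1), "unknown parameter override")
  expect_error(cell_params(cm = 160, gL = 10, EL = -65, Vt = -50, Delta = 4.5,
                           a = 0, b = 10, tau_w = 200, Qe = 1, Qi = 6,
                           tau_e = 5, tau_i = 5, Ee = -90, Ei = -80),
               "reversal")
})

test_that("passive membrane decays with tau_m = cm / gL", {
  # awake TC has a = 0, so with no input the voltage relaxes exponentially
  # to EL with tau_m = 160 / 10 = 16 ms; push the spike-onset threshold far
  # away so the exponential initiation term is negligible on the path
  p <- awake_tc(Vt = -10)
  tr <- simulate_cell(p, duration = 64, dt = 0.01, v0 = p$EL + 8, seed = 1)
  expect_length(tr$spikes, 0)
  v16 <- tr$trace$v[which.min(abs(tr$trace$t - 16))]
  v32 <- tr$trace$v[which.min(abs(tr$trace$t - 32))]
  expect_equal(v16 - p$EL, 8 * exp(-1), tolerance = 0.02)
  expect_equal(v32 - p$EL, 8 * exp(-2), tolerance = 0.02)
})

test_that("adex_step bookkeeping: spike reset, adaptation jump, refractoriness", {
  p <- awake_tc()
  s0 <- list(v = -21, w = 0, Ge = 2, Gi = 1, refrac_remaining = 0)
  # huge current forces a threshold crossing within one step
  st <- adex_step(s0, p, I_ext = 1e5, dt = 0.1)
  expect_true(st$spiked)
  expect_identical(st$state$v, p$V_reset)
  expect_equal(st$state$w, p$b, tolerance = 1e-6)
  expect_equal(st$state$refrac_remaining, p$t_refrac)
  # conductances decay exponentially and jump by one quantum per spike
  expect_equal(st$state$Ge, 2 * exp(-0.1 / p$tau_e), tolerance = 1e-12)
  st2 <- adex_step(st$state, p, n_exc = 3, n_inh = 2, dt = 0.1)
  expect_false(st2$spiked)
  expect_equal(st2$state$Ge, st$state$Ge * exp(-0.1 / p$tau_e) + 3 * p$Qe)
  expect_equal(st2$state$Gi, st$state$Gi * exp(-0.1 / p$tau_i) + 2 * p$Qi)
  # during the refractory period the voltage stays clamped at the reset
  expect_identical(st2$state$v, p$V_reset)
  expect_equal(st2$state$refrac_remaining, p$t_refrac - 0.1)
})

test_that("rheobase of the awake TC cell separates silence from firing", {
  # with a = 0 the AdEx rheobase is gL (Vt - EL) - gL Delta = 105 pA
  p <- awake_tc()
  silent <- simulate_cell(p, 2000, I_ext = 90, seed = 1, record = FALSE)
  firing <- simulate_cell(p, 2000, I_ext = 200, seed = 1, record = FALSE)
  expect_length(silent$spikes, 0)
  expect_gt(length(firing$spikes), 5)
})

test_that("simulate_cell is reproducible and honours explicit spike times", {
  p <- awake_tc()
  a <- simulate_cell(p, 500, exc_input = 400, K_exc = 10, seed = 7,
                     record = FALSE)
  b <- simulate_cell(p, 500, exc_input = 400, K_exc = 10, seed = 7,
                     record = FALSE)
  expect_identical(a$spikes, b$spikes)
  # a barrage of simultaneous input spikes drives one output spike
  tr <- simulate_cell(p, 100, exc_input = rep(20, 40),
                      exc_spike_times = TRUE, record = FALSE)
  expect_gte(length(tr$spikes), 1)
  expect_true(all(tr$spikes >= 20))
})

test_that("classify_firing distinguishes silent, tonic and burst trains", {
  win <- c(0, 1000)
  expect_identical(classify_firing(numeric(0), win), "silent")
  expect_identical(classify_firing(500, win), "silent")
  # regular firing up to the window end: tonic
  expect_identical(classify_firing(seq(50, 990, by = 50), win), "tonic")
  # one fast cluster followed by long silence: burst
  expect_identical(classify_firing(c(100, 110, 120, 130), win), "burst")
  # two clusters separated by quiescence: still burst
  expect_identical(classify_firing(c(100, 110, 120, 600, 610, 620), win),
                   "burst")
})
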