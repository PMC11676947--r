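test_that("drive_rate reproduces the declarative stimulus shapes", {
  t <- seq(0, 1000, by = 1)
  expect_equal(drive_rate(stimulus("constant", A = 3, baseline = 2), t),
               rep(5, length(t)))
  r <- drive_rate(stimulus("rectangular", A = 10, t0 = 100, width = 200), t)
  expect_equal(r[t < 100], rep(0, sum(t < 100)))
  expect_equal(r[t >= 100 & t < 300], rep(10, sum(t >= 100 & t < 300)))
  expect_equal(r[t >= 300], rep(0, sum(t >= 300)))
  # oscillatory: non-negative raised cosine, peak baseline + A, period 1/f
  o <- stimulus("oscillatory", A = 10, frequency = 2, t0 = 0)
  ro <- drive_rate(o, t)
  expect_true(all(ro >= 0))
  expect_equal(max(ro), 10, tolerance = 1e-6)
  expect_equal(drive_rate(o, 0), 0)
  expect_equal(drive_rate(o, 250), 10)     # half period of 2 Hz
  expect_equal(drive_rate(o, 500), 0, tolerance = 1e-12)
  # split Gaussian: peak-amplitude convention, asymmetric widths
  sg <- stimulus("split_gaussian", A = 10, t0 = 400, sigma_l = 50,
                 sigma_r = 200, baseline = 1)
  expect_equal(drive_rate(sg, 400), 11)
  expect_equal(drive_rate(sg, 400 - 50), 1 + 10 * exp(-0.5))
  expect_equal(drive_rate(sg, 400 + 200), 1 + 10 * exp(-0.5))
  # symmetric case
  sym <- stimulus("split_gaussian", A = 1, t0 = 0, sigma_l = 80, sigma_r = 80)
  expect_equal(drive_rate(sym, -80), drive_rate(sym, 80))
})

test_that("stimulus validation and rate clamping", {
  expect_error(stimulus("rectangular", baseline = -1), "baseline")
  expect_error(stimulus("split_gaussian", sigma_l = 0), "positive")
  neg <- stimulus("rectangular", A = -5, t0 = 0, width = 100, baseline = 2)
  expect_equal(drive_rate(neg, 50), 0)              # clamped rate
  expect_equal(drive_rate(neg, 50, clamp = FALSE), -3)  # raw (current) value
})

test_that("sample_ou matches the stationary OU moments", {
  spec <- ou_noise(mean = 4, sd = 2, tau_corr = 10)
  path <- sample_ou(spec, duration = 2e5, dt = 1, seed = 11)
  x <- path$x
  expect_equal(mean(x), 4, tolerance = 0.1)
  expect_equal(sd(x), 2, tolerance = 0.1)
  # lag-1 autocorrelation of the exact discretisation is exp(-dt/tau)
  r1 <- cor(x[-1], x[-length(x)])
  expect_equal(r1, exp(-1 / 10), tolerance = 0.02)
  # degenerate sd = 0 path is constant at the mean
  flat <- sample_ou(ou_noise(mean = 3, sd = 0, tau_corr = 5), 100, dt = 0.5)
  expect_true(all(flat$x == 3))
  expect_error(sample_ou(spec, 100, dt = 20), "smaller than")
  expect_error(ou_noise(sd = -1), "non-negative")
})

test_that("stimulus_schedule accepts scalars, vectors and stimuli", {
  sched <- thalamr:::stimulus_schedule
  expect_equal(sched(4, 10, 0.1), rep(4, 10))
  expect_equal(sched(c(1, 2, 3), 3, 1), c(1, 2, 3))
  expect_error(sched(c(1, 2), 5, 1), "wrong length")
  s <- stimulus("rectangular", A = 1, t0 = 5, width = 5)
  expect_equal(sched(s, 10, 1), c(rep(0, 5), rep(1, 5)))
})
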