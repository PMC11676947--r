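#' Autocorrelation time of a population rate trace
#'
#' Normalised autocovariance of a stationary rate trace; the reported
#' `tau_ac` is the lag of the first 1/e crossing (linearly interpolated
#' between lags).
#'
#' @param rate numeric rate trace (Hz) sampled at constant `dt`, or a tibble
#'   with columns `t` and `rate`
#' @param dt sampling step (ms); inferred from a tibble input
#' @param max_lag_ms largest lag examined (ms)
#' @return `tau_ac` in ms (`NA` with a warning for a constant trace)
#' @export
autocorrelation_time <- function(rate, dt = NULL, max_lag_ms = 200) {
  if (is.data.frame(rate)) {
    dt <- dt %||% (rate$t[2] - rate$t[1])
    rate <- rate$rate
  }
  if (is.null(dt)) abort("dt must be supplied for a bare numeric trace")
  if (sd(rate) == 0) {
    warn("constant trace: autocorrelation time undefined")
    return(NA_real_)
  }
  n_lag <- min(length(rate) - 1, ceiling(max_lag_ms / dt))
  ac <- acf(rate, lag.max = n_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  thr <- exp(-1)
  below <- which(ac < thr)
  if (length(below) == 0) return(n_lag * dt)
  k <- below[1] # 1-based index into lags 0..n_lag
  if (k == 1) return(0)
  # interpolate between lag k-2 and k-1 (in steps)
  a0 <- ac[k - 1]; a1 <- ac[k]
  frac <- (a0 - thr) / (a0 - a1)
  ((k - 2) + frac) * dt
}

# steady-state window statistics of a mean-field trajectory
mf_window_stats <- function(tr, t_from, t_to) {
  w <- tr[tr$t >= t_from & tr$t <= t_to, ]
  list(rate_e = mean(w$nu_e), rate_i = mean(w$nu_i),
       sd_rate_e = sd(w$nu_e),
       sigmaV_e = sqrt(mean(w$sigmaV_e^2)),
       # total membrane fluctuation: shotnoise variance plus the wander of
       # the mean potential induced by time-varying noise conductances
       sigmaV_total_e = sqrt(mean(w$sigmaV_e^2) + var(w$muV_e)),
       muV_e = mean(w$muV_e))
}

#' Peak response versus stimulus slope
#'
#' Thalamic response to a split-Gaussian sensory stimulus whose left
#' standard deviation (the stimulus "slope") is scanned while amplitude and
#' right standard deviation stay fixed. The response is the peak TC rate
#' above the pre-stimulus baseline, relative to the stimulus amplitude.
#'
#' @param cfg an [mf_config()] (mean-field backend) or a list
#'   `list(conn =, config =)` for the spiking backend
#' @param sigma_l_values left standard deviations (ms)
#' @param backend "mean_field" or "network"
#' @param P_const constant cortical drive (Hz)
#' @param A stimulus amplitude (Hz)
#' @param sigma_r right standard deviation (ms)
#' @param seed seed for the spiking backend
#' @return `response_curve` tibble: `sigma_l`, `peak` (Hz), `rel_peak`
#'   (peak / A), `baseline` (Hz)
#' @export
peak_response_curve <- function(cfg, sigma_l_values,
                                backend = c("mean_field", "network"),
                                P_const = 4, A = 10, sigma_r = 200,
                                seed = 1L) {
  backend <- match.arg(backend)
  rows <- purrr::map(sigma_l_values, function(sl) {
    t0 <- 1000 + 5 * sl
    dur <- t0 + 4 * sigma_r + 500
    stim <- stimulus("split_gaussian", A = A, t0 = t0,
                     sigma_l = sl, sigma_r = sigma_r)
    win <- c(max(t0 - 3 * sl, 0), t0 + 3 * sigma_r)
    if (backend == "mean_field") {
      st <- stationary_state(cfg, P = P_const)
      init <- mf_state(st$nu_e, st$nu_i, st$c_ee, st$c_ei, st$c_ii,
                       st$w_e, st$w_i)
      tr <- integrate_mf(cfg, dur, P = P_const, S = stim, init = init)
      base <- mean(tr$nu_e[tr$t < t0 - 4 * sl])
      pk <- max(tr$nu_e[tr$t >= win[1] & tr$t <= win[2]]) - base
    } else {
      raster <- simulate_network(cfg$conn, cfg$config, dur,
                                 P_drive = P_const, S_drive = stim,
                                 seed = seed)
      rt <- bin_population_rate(raster, "TC", 5)
      rt$rate <- as.numeric(stats::filter(rt$rate, rep(1 / 3, 3))) # light smooth
      base <- mean(rt$rate[rt$t > 500 & rt$t < t0 - 4 * sl], na.rm = TRUE)
      pk <- max(rt$rate[rt$t >= win[1] & rt$t <= win[2]], na.rm = TRUE) - base
    }
    tibble(sigma_l = sl, peak = pk, rel_peak = if (A > 0) pk / A else 0,
           baseline = base)
  })
  out <- bind_rows(rows)
  attr(out, "protocol") <- list(A = A, sigma_r = sigma_r, P = P_const,
                                backend = backend)
  class(out) <- c("response_curve", class(out))
  out
}

#' Sensory response gain
#'
#' Slope of the stationary TC response versus the amplitude of gated
#' (rectangular) sensory stimuli, under a constant cortical drive.
#' The steady state is read from the last half of each pulse.
#'
#' @param cfg an [mf_config()]
#' @param P_const constant cortical drive (Hz)
#' @param S_amplitudes pulse amplitudes (Hz), within the linear regime
#' @param settle,pulse settle time before and duration of the pulse (ms)
#' @param noise_spec optional [ou_noise()]: fresh conductance-noise paths are
#'   drawn per run with this specification (excitatory class)
#' @param noise_spec_i specification for the inhibitory class (defaults to
#'   the excitatory one)
#' @param seed seed for noise paths
#' @return list with `gain` (Hz per Hz), `r_squared`, `curve` (tibble
#'   `amplitude`, `rate`), and fluctuation summaries `sigmaV_bar`
#'   (time-averaged shotnoise sd) and `sigmaV_total` (including
#'   noise-induced wander of the mean potential)
#' @export
response_gain <- function(cfg, P_const = 4, S_amplitudes = c(0, 2.5, 5, 7.5, 10),
                          noise_spec = NULL, noise_spec_i = noise_spec,
                          settle = 1500, pulse = 2500,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dur <- settle + pulse
  win <- c(settle + pulse / 2, dur)
  st0 <- stationary_state(cfg, P = P_const)
  init <- mf_state(st0$nu_e, st0$nu_i, st0$c_ee, st0$c_ei, st0$c_ii,
                   st0$w_e, st0$w_i)
  runs <- purrr::map(S_amplitudes, function(A) {
    stim <- stimulus("rectangular", A = A, t0 = settle, width = pulse)
    noise <- if (is.null(noise_spec)) NULL else
      ou_conductance_noise(noise_spec, dur, T_ms = cfg$T_ms,
                           spec_i = noise_spec_i)
    tr <- integrate_mf(cfg, dur, P = P_const, S = stim, init = init,
                       noise = noise)
    s <- mf_window_stats(tr, win[1], win[2])
    if (is.null(noise_spec) && s$rate_e > 1 && s$sd_rate_e > 0.5 * s$rate_e)
      abort("non-stationary (oscillating) response; use the spindle protocols")
    tibble(amplitude = A, rate = s$rate_e, sigmaV_bar = s$sigmaV_e,
           sigmaV_total = s$sigmaV_total_e)
  })
  curve <- bind_rows(runs)
  fit <- lm(rate ~ amplitude, data = curve)
  list(gain = unname(coef(fit)[2]),
       r_squared = summary(fit)$r.squared,
       curve = curve,
       sigmaV_bar = mean(curve$sigmaV_bar),
       sigmaV_total = mean(curve$sigmaV_total))
}

#' Gain versus cortical drive
#'
#' Recomputes the sensory response gain across a range of constant cortical
#' drives.
#'
#' @inheritParams response_gain
#' @param P_values cortical drives (Hz)
#' @return `response_curve` tibble: `P`, `gain`, `r_squared`
#' @export
gain_vs_cortical_drive <- function(cfg, P_values,
                                   S_amplitudes = c(0, 2.5, 5, 7.5, 10)) {
  out <- bind_rows(purrr::map(P_values, function(P) {
    g <- response_gain(cfg, P_const = P, S_amplitudes = S_amplitudes)
    tibble(P = P, gain = g$gain, r_squared = g$r_squared)
  }))
  class(out) <- c("response_curve", class(out))
  out
}

#' Gain versus synaptic-noise scan
#'
#' Measures the sensory response gain of the mean-field under increasing
#' amplitudes of piecewise-constant OU conductance noise, records the
#' run-averaged membrane fluctuation, and fits the linear decay of gain with
#' fluctuation amplitude.
#'
#' @param cfg an [mf_config()]
#' @param noise_levels excitatory OU standard deviations (nS); at least 3
#' @param P_const cortical drive (Hz)
#' @param S_amplitudes pulse amplitudes (Hz)
#' @param noise_mean_factor OU stationary mean as a multiple of its sd
#' @param gi_ratio inhibitory-class mean and sd as a multiple of the
#'   excitatory ones. The default 3 balances the conductance driving forces
#'   around a typical operating point (about -60 mV with reversals 0/-80 mV),
#'   so increasing noise scales the membrane fluctuations without
#'   systematically depolarising the populations
#' @param tau_noise OU correlation time (ms)
#' @param reps independent noise realisations per level (gain and
#'   fluctuation are averaged across them)
#' @param fluctuation which fluctuation measure drives the fit:
#'   "total" (shotnoise plus noise-induced wander of the mean potential) or
#'   "shotnoise" (Eq-14 output only)
#' @param seed integer seed
#' @return list with `slope` (gain per mV), `slope_se`, `curve` (tibble
#'   `noise_sd`, `gain`, `gain_sd`, `sigmaV_bar`, `sigmaV_total`),
#'   `fluctuation`
#' @export
noise_gain_scan <- function(cfg, noise_levels, P_const = 4,
                            S_amplitudes = c(0, 2.5, 5, 7.5, 10),
                            noise_mean_factor = 1, gi_ratio = 3,
                            tau_noise = 20, reps = 5,
                            fluctuation = c("total", "shotnoise"),
                            seed = 1L) {
  fluctuation <- match.arg(fluctuation)
  if (length(noise_levels) < 3) abort("need at least 3 noise levels")
  set.seed(seed)
  rows <- purrr::map(noise_levels, function(sdv) {
    spec <- spec_i <- NULL
    if (sdv > 0) {
      spec <- ou_noise(mean = noise_mean_factor * sdv, sd = sdv,
                       tau_corr = tau_noise, target = "conductance_e")
      spec_i <- ou_noise(mean = gi_ratio * noise_mean_factor * sdv,
                         sd = gi_ratio * sdv,
                         tau_corr = tau_noise, target = "conductance_i")
    }
    n_rep <- if (sdv > 0) reps else 1L
    g <- purrr::map(seq_len(n_rep), function(r)
      response_gain(cfg, P_const = P_const, S_amplitudes = S_amplitudes,
                    noise_spec = spec, noise_spec_i = spec_i))
    gains <- purrr::map_dbl(g, "gain")
    tibble(noise_sd = sdv, gain = mean(gains),
           gain_sd = if (n_rep > 1) sd(gains) else 0,
           sigmaV_bar = mean(purrr::map_dbl(g, "sigmaV_bar")),
           sigmaV_total = mean(purrr::map_dbl(g, "sigmaV_total")))
  })
  curve <- bind_rows(rows)
  curve$fluct <- if (fluctuation == "total") curve$sigmaV_total else
    curve$sigmaV_bar
  fit <- lm(gain ~ fluct, data = curve)
  list(slope = unname(coef(fit)[2]),
       slope_se = summary(fit)$coefficients[2, 2],
       curve = select(curve, -"fluct"),
       fluctuation = fluctuation)
}

# 4-parameter logistic and its maximum slope
sigmoid4 <- function(x, lo, hi, x0, s) lo + (hi - lo) / (1 + exp(-(x - x0) / s))

fit_sigmoid <- function(x, y) {
  lo0 <- min(y); hi0 <- max(y)
  if (hi0 - lo0 < 1e-6) return(NULL)
  yn <- (y - lo0) / (hi0 - lo0)
  # a tiny-but-nonzero start breaks the solver's relative-step numeric
  # Jacobian (the step underflows); snap it to zero
  if (abs(lo0) < 1e-8 * (hi0 - lo0)) lo0 <- 0
  rng <- max(x) - min(x)
  # grid of starting values: the Jacobian of the logistic is easily singular
  # when the initial midpoint/scale are off, so retry before giving up
  x0_grid <- unique(c(x[which.min(abs(yn - 0.5))],
                      stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)))
  s_grid <- rng / c(20, 10, 5)
  for (x00 in x0_grid) for (s0 in s_grid) {
    fit <- try(minpack.lm::nlsLM(
      y ~ sigmoid4(x, lo, hi, x0, s),
      start = list(lo = lo0, hi = hi0, x0 = x00, s = s0),
      data = tibble(x = x, y = y),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (!inherits(fit, "try-error")) {
      cf <- coef(fit)
      return(list(lo = cf[["lo"]], hi = cf[["hi"]], shift = cf[["x0"]],
                  scale = cf[["s"]],
                  max_slope = (cf[["hi"]] - cf[["lo"]]) / (4 * cf[["s"]]),
                  fitted = TRUE))
    }
  }
  # fallback: central finite differences of the measured curve
  dy <- diff(y) / diff(x)
  k <- which.max(abs(dy))
  list(lo = lo0, hi = hi0, shift = mean(x[k:(k + 1)]), scale = NA_real_,
       max_slope = dy[k], fitted = FALSE)
}

#' Conductance-response function
#'
#' Response to a common Poissonian input of fixed rate while the quantal
#' excitatory conductance of that input is scanned, mimicking dynamic-clamp
#' experiments. Backends: `single_cell` reports output spikes per input
#' spike for one cell; `mean_field` and `network` report the stationary TC
#' population rate with the common source wired to every cell. A
#' four-parameter sigmoid is fitted to the curve and its maximum slope and
#' midpoint (shift) returned.
#'
#' @param Qe_values increasing quantal conductances (nS)
#' @param backend "single_cell", "mean_field" or "network"
#' @param cfg backend input: [cell_params()] (single_cell), [mf_config()]
#'   (mean_field), or `list(conn =, config =)` (network)
#' @param input_rate common source rate (Hz)
#' @param ou optional [ou_noise()] membrane current (single_cell/network)
#' @param noise_spec optional [ou_noise()] conductance noise (mean_field)
#' @param duration run length per point (ms)
#' @param reps repetitions (single_cell)
#' @param relative normalise the curve by its maximum before fitting
#'   (the relative-response convention; use it when comparing slope
#'   steepness across states whose absolute rates differ)
#' @param seed integer seed
#' @return list with `curve` (tibble `Qe`, `response`) and `fit`
#'   (`max_slope`, `shift`, `fitted` flag; NULL for a degenerate flat
#'   response)
#' @export
conductance_response_scan <- function(Qe_values, backend = c("single_cell",
                                                             "mean_field",
                                                             "network"),
                                      cfg, input_rate = NULL, ou = NULL,
                                      noise_spec = NULL, duration = 10000,
                                      reps = 10, relative = FALSE, seed = 1L) {
  backend <- match.arg(backend)
  stopifnot(!is.unsorted(Qe_values))
  input_rate <- input_rate %||%
    switch(backend, single_cell = 5, mean_field = 10, network = 15)
  set.seed(seed)
  response <- purrr::map_dbl(Qe_values, function(q) {
    if (backend == "single_cell") {
      pars <- cfg; pars$Qe <- q
      mean(purrr::map_dbl(seq_len(reps), function(r) {
        tr <- simulate_cell(pars, duration, exc_input = input_rate,
                            K_exc = 1, ou = ou)
        n_in <- input_rate * duration * 1e-3
        length(tr$spikes) / n_in
      }))
    } else if (backend == "mean_field") {
      cfg2 <- cfg
      cfg2$common <- list(K = 1, Q = q)
      if (is.null(noise_spec)) {
        stationary_state(cfg2, P = 0, S = 0, common_rate = input_rate)$nu_e
      } else {
        noise <- ou_conductance_noise(noise_spec, duration, T_ms = cfg2$T_ms)
        tr <- integrate_mf(cfg2, duration, P = 0, S = 0,
                           common_rate = input_rate, noise = noise)
        mf_window_stats(tr, duration / 2, duration)$rate_e
      }
    } else {
      raster <- simulate_network(cfg$conn, cfg$config, duration,
                                 common = list(rate = input_rate, q_tc = q,
                                               q_re = q),
                                 ou = ou, seed = seed + round(q * 100))
      rt <- bin_population_rate(raster, "TC", 5)
      mean(rt$rate[rt$t > duration / 2])
    }
  })
  if (relative && max(response) > 0) response <- response / max(response)
  curve <- tibble(Qe = Qe_values, response = response)
  fit <- fit_sigmoid(curve$Qe, curve$response)
  if (is.null(fit)) inform("flat response curve: sigmoid fit skipped")
  list(curve = curve, fit = fit, backend = backend, input_rate = input_rate,
       relative = relative)
}

#' Spike response probability versus input inter-spike interval
#'
#' Single TC cell driven by one Poissonian input source; every input spike
#' is labelled responded/unresponded depending on whether the cell emitted
#' an output spike before the next input spike, and the response probability
#' is tabulated against the interval between that input spike and its
#' predecessor.
#'
#' @param params a [cell_params()] (apply `EL` and `Qe` overrides via
#'   [thalamic_cell_params()])
#' @param input_rate Poisson input rate (Hz)
#' @param ou optional [ou_noise()] membrane current
#' @param duration simulation length (ms)
#' @param isi_max largest interval tabulated (ms)
#' @param bin_width histogram bin width (ms)
#' @param min_events bins with fewer input events are flagged wide-uncertainty
#' @param seed integer seed
#' @return tibble `isi_mid`, `p_response`, `n_events`, `wide_uncertainty`
#' @export
isi_response_probability <- function(params, input_rate = 10, ou = NULL,
                                     duration = 3e5, isi_max = 550,
                                     bin_width = 25, min_events = 20,
                                     seed = 1L) {
  set.seed(seed)
  # input spike times: homogeneous Poisson process
  n_exp <- ceiling(duration * input_rate * 1e-3 * 1.3) + 50
  times <- cumsum(rexp(n_exp, rate = input_rate * 1e-3))
  times <- times[times < duration]
  tr <- simulate_cell(params, duration, exc_input = times,
                      exc_spike_times = TRUE, ou = ou, record = FALSE)
  out_sp <- tr$spikes
  isi <- diff(times)
  t_this <- times[-1]
  t_next <- c(times[-(1:2)], duration)
  responded <- purrr::map2_lgl(t_this, t_next, function(a, b)
    any(out_sp >= a & out_sp < b))
  keep <- isi <= isi_max
  bins <- seq(0, isi_max, by = bin_width)
  idx <- findInterval(isi[keep], bins, rightmost.closed = TRUE)
  tb <- tibble(idx = idx, responded = responded[keep]) |>
    group_by(.data$idx) |>
    summarise(p_response = mean(.data$responded), n_events = n()) |>
    ungroup()
  full <- tibble(idx = seq_len(length(bins) - 1))
  out <- left_join(full, tb, by = "idx")
  out$p_response[is.na(out$p_response)] <- NA_real_
  out$n_events[is.na(out$n_events)] <- 0L
  mutate(out,
         isi_mid = bins[.data$idx] + bin_width / 2,
         wide_uncertainty = .data$n_events < min_events) |>
    select("isi_mid", "p_response", "n_events", "wide_uncertainty")
}

#' Firing-adaptation metric from the transfer function
#'
#' A dimensionless measure of how strongly adaptation suppresses the
#' stationary response: `F_adapt = 1 - F(nu_in; w = w*) / F(nu_in; w = 0)`,
#' where `w*` is the self-consistent stationary adaptation at the given
#' input. Evaluated against a polarisation offset of the leak reversal and
#' optionally averaged over realisations of static conductance noise.
#'
#' @param params a [cell_params()]
#' @param coeffs a [tf_coefficients()]
#' @param ic an [input_connectivity()] (the `EL` offset is applied on top)
#' @param polarization offsets added to `EL` (mV), vectorised
#' @param nu_in excitatory input rate (Hz)
#' @param nu_i inhibitory input rate (Hz)
#' @param noise_sd static conductance-noise sd (nS); 0 disables
#' @param noise_reps noise realisations averaged over
#' @param seed integer seed
#' @return tibble `polarization`, `F_adapt` (NA where the unadapted rate is 0)
#' @export
firing_adaptation_metric <- function(params, coeffs, ic, polarization = 0,
                                     nu_in = 10, nu_i = 0, noise_sd = 0,
                                     noise_reps = 20, seed = 1L) {
  set.seed(seed)
  one <- function(dEL, ge, gi) {
    ic2 <- ic; ic2$EL <- ic$EL + dEL
    p2 <- params; p2$EL <- params$EL + dEL
    F0 <- transfer_rate(nu_in, nu_i, 0, coeffs, ic2,
                        extra_ge = ge, extra_gi = gi)
    if (F0 < 1e-6) return(NA_real_)
    w <- 0
    for (k in 1:100) {
      Fk <- transfer_rate(nu_in, nu_i, w, coeffs, ic2,
                          extra_ge = ge, extra_gi = gi)
      muV <- membrane_moments(nu_in, nu_i, w, ic2,
                              extra_ge = ge, extra_gi = gi)$muV
      w_new <- p2$b * (p2$tau_w * 1e-3) * Fk + p2$a * (muV - p2$EL)
      if (abs(w_new - w) < 0.01) { w <- w_new; break }
      w <- 0.5 * w + 0.5 * w_new
    }
    Fs <- transfer_rate(nu_in, nu_i, w, coeffs, ic2,
                        extra_ge = ge, extra_gi = gi)
    1 - Fs / F0
  }
  vals <- purrr::map_dbl(polarization, function(dEL) {
    if (noise_sd == 0) return(one(dEL, 0, 0))
    mean(purrr::map_dbl(seq_len(noise_reps), function(r)
      one(dEL, max(rnorm(1, noise_sd, noise_sd), 0),
          max(rnorm(1, noise_sd, noise_sd), 0))), na.rm = TRUE)
  })
  tibble(polarization = polarization, F_adapt = vals)
}

# spectral summary of an oscillation trace (regular sampling)
oscillation_spectrum <- function(x, dt_ms) {
  x <- x - mean(x)
  n <- length(x)
  sp <- Mod(fft(x))^2
  freq <- (seq_len(n) - 1) / (n * dt_ms * 1e-3) # Hz
  keep <- freq > 0.5 & freq <= 1 / (2 * dt_ms * 1e-3)
  tibble(freq = freq[keep], power = sp[keep])
}

#' Spindle oscillation run
#'
#' Kicks the network or mean-field (spindle presets) with a brief sensory
#' pulse and tests for a self-sustained oscillation after the kick: the
#' dominant frequency of the TC rate spectrum over the last half of the run,
#' its prominence (peak power over median power), and a limit-cycle flag
#' requiring a non-decaying amplitude across the last two quarters.
#'
#' @param cfg an [mf_config()] (mean-field) or `list(conn =, config =)`
#'   (network)
#' @param backend "mean_field" or "network"
#' @param duration run length (ms)
#' @param kick a [stimulus()] applied on S (default: 100 ms, 20 Hz pulse)
#' @param P_const constant cortical drive during the run (Hz)
#' @param min_amplitude rate sd (Hz) below which the state counts as decayed
#' @param seed integer seed (network backend)
#' @return a `spindle_report` list: `frequency` (Hz), `prominence`,
#'   `limit_cycle`, `amplitude` (Hz), `trajectory` (tibble `t`, `nu_e`,
#'   `nu_i`)
#' @export
spindle_run <- function(cfg, backend = c("mean_field", "network"),
                        duration = 6000,
                        kick = stimulus("rectangular", A = 20, t0 = 100,
                                        width = 100),
                        P_const = 0, min_amplitude = 0.5, seed = 1L) {
  backend <- match.arg(backend)
  if (backend == "mean_field") {
    tr <- integrate_mf(cfg, duration, P = P_const, S = kick,
                       init = mf_state(), stride = 10)
    traj <- select(tr, "t", "nu_e", "nu_i")
  } else {
    raster <- simulate_network(cfg$conn, cfg$config, duration,
                               P_drive = P_const, S_drive = kick, seed = seed)
    rt_e <- bin_population_rate(raster, "TC", 2)
    rt_i <- bin_population_rate(raster, "RE", 2)
    traj <- tibble(t = rt_e$t, nu_e = rt_e$rate, nu_i = rt_i$rate)
  }
  dt_tr <- traj$t[2] - traj$t[1]
  half <- traj[traj$t >= duration / 2, ]
  q3 <- half$nu_e[half$t < duration * 0.75]
  q4 <- half$nu_e[half$t >= duration * 0.75]
  amp <- sd(half$nu_e)
  sustained <- amp > min_amplitude && sd(q4) > 0.7 * sd(q3)
  freq <- NA_real_; prom <- NA_real_
  if (amp > 0) {
    spec <- oscillation_spectrum(half$nu_e, dt_tr)
    imax <- which.max(spec$power)
    freq <- spec$freq[imax]
    prom <- spec$power[imax] / stats::median(spec$power)
  }
  structure(list(frequency = freq, prominence = prom,
                 limit_cycle = isTRUE(sustained), amplitude = amp,
                 backend = backend, trajectory = traj),
            class = "spindle_report")
}

#' @export
print.spindle_report <- function(x, ...) {
  cat("<spindle_report>", x$backend,
      if (isTRUE(x$limit_cycle)) "limit cycle" else "decaying",
      sprintf("f = %.2f Hz, amplitude = %.2f Hz\n", x$frequency, x$amplitude))
  invisible(x)
}

#' Bifurcation scan over the connectivity scale
#'
#' Interpolates the recurrent wiring between a sparse-weak and the reference
#' dense regime: connection probabilities scale as `gamma / gamma_ref` while
#' quantal strengths scale inversely, holding the total mean synaptic
#' conductance `K * Q` fixed. Per scale the long-run oscillation amplitude of
#' the TC rate is recorded; the onset (Hopf point) is the first scale whose
#' amplitude exceeds `floor_amp`, and near onset the squared amplitude is
#' expected to grow linearly (supercritical scaling).
#'
#' @param gamma_values scan grid (reference regime at `gamma_ref`)
#' @param state parameter state for the populations (default "spindle")
#' @param gamma_ref scale at which the reference wiring is recovered
#' @param coeffs_e,coeffs_i transfer-function coefficients (defaults: shipped
#'   reference fits)
#' @param duration run length per point (ms)
#' @param kick kick stimulus, see [spindle_run()]
#' @param floor_amp detection floor for the oscillation amplitude (Hz, sd)
#' @return list with `curve` (tibble `gamma`, `amplitude`, `frequency`),
#'   `hopf_gamma`, `sqrt_law_r2`
#' @export
bifurcation_scan <- function(gamma_values = seq(1, 10, by = 1),
                             state = "spindle", gamma_ref = 10,
                             coeffs_e = tf_preset("TC"),
                             coeffs_i = tf_preset("RE"),
                             duration = 6000,
                             kick = stimulus("rectangular", A = 20, t0 = 100,
                                             width = 100),
                             floor_amp = 0.5) {
  rows <- purrr::map(gamma_values, function(g) {
    fac <- g / gamma_ref
    pe <- thalamic_cell_params("TC", state)
    pi_ <- thalamic_cell_params("RE", state)
    pe$Qe <- pe$Qe / fac; pe$Qi <- pe$Qi / fac
    pi_$Qe <- pi_$Qe / fac; pi_$Qi <- pi_$Qi / fac
    cfg <- mf_config(state, params_e = pe, params_i = pi_,
                     coeffs_e = coeffs_e, coeffs_i = coeffs_i,
                     p_ei = 0.05 * fac, p_ie = 0.05 * fac, p_ii = 0.3 * fac)
    rep <- spindle_run(cfg, "mean_field", duration = duration, kick = kick,
                       min_amplitude = floor_amp)
    tibble(gamma = g, amplitude = rep$amplitude, frequency = rep$frequency,
           limit_cycle = rep$limit_cycle)
  })
  curve <- bind_rows(rows)
  above <- which(curve$amplitude > floor_amp & curve$limit_cycle)
  hopf <- if (length(above)) curve$gamma[above[1]] else NA_real_
  r2 <- NA_real_
  if (length(above) >= 3) {
    near <- curve[above[seq_len(min(4, length(above)))], ]
    fit <- lm(I(amplitude^2) ~ gamma, data = near)
    r2 <- summary(fit)$r.squared
  }
  list(curve = curve, hopf_gamma = hopf, sqrt_law_r2 = r2)
}

#' Stationary fixed-point scan over the cortical drive
#'
#' Computes the mean-field fixed point across a grid of constant cortical
#' drives (warm-started continuation) and locates the turning point at the
#' end of the inhibited regime: the minimum of the stationary TC curve,
#' where its slope changes sign from negative (each extra unit of drive
#' recruits more reticular inhibition than direct excitation) to positive
#' (the RE population saturates and additional drive excites TC directly).
#'
#' @param cfg an [mf_config()]
#' @param P_values drive grid (Hz), increasing
#' @return list with `scan` (tibble `P`, `nu_e`, `nu_i`, `sd_e`, `sd_i`)
#'   and `turning_point` (Hz)
#' @export
cortical_drive_scan <- function(cfg, P_values = seq(0, 40, by = 1)) {
  stopifnot(!is.unsorted(P_values))
  init <- mf_state(nu_e = 2, nu_i = 10)
  rows <- vector("list", length(P_values))
  for (k in seq_along(P_values)) {
    st <- stationary_state(cfg, P = P_values[k], init = init)
    rows[[k]] <- mutate(st, P = P_values[k])
    init <- mf_state(max(st$nu_e, 0.1), max(st$nu_i, 0.5),
                     st$c_ee, st$c_ei, st$c_ii, st$w_e, st$w_i)
  }
  scan <- select(bind_rows(rows), "P", "nu_e", "nu_i", "sd_e", "sd_i",
                 "converged")
  # turning point: the minimum of the stationary TC curve inside the
  # inhibited regime -- the drive at which the TC slope changes sign from
  # negative (inhibition-dominated) to positive (the RE population is
  # saturating and additional drive excites TC directly)
  tp <- NA_real_
  slope <- diff(scan$nu_e)
  turn <- which(slope[-length(slope)] < 0 & slope[-1] > 0)
  turn <- turn[scan$nu_e[turn + 1] > 0]
  if (length(turn) > 0) tp <- scan$P[turn[length(turn)] + 1]
  list(scan = scan, turning_point = tp)
}
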