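#' Declarative time-dependent rate drives
#'
#' A stimulus is a declarative description of the firing rate (Hz) of an
#' external drive population as a function of time. Supported kinds:
#'
#' * `constant`: `baseline + A` for all t.
#' * `rectangular`: `baseline + A` on `[t0, t0 + width)`, baseline elsewhere.
#' * `oscillatory`: raised cosine `baseline + A (1 - cos(2 pi f (t - t0))) / 2`
#'   starting at `t0` (stays non-negative, oscillating up from zero as a
#'   graded stimulus does).
#' * `split_gaussian`: two-sided Gaussian bump peaking at `t0` with left
#'   standard deviation `sigma_l` (the stimulus "slope") and right standard
#'   deviation `sigma_r`; peak-amplitude convention (the peak is `baseline + A`).
#' * `poisson_fixed_rate`: alias of `constant` (a fixed-rate Poisson source).
#'
#' @param kind one of the kinds above
#' @param A amplitude (Hz), added on top of `baseline`
#' @param t0 onset / peak time (ms)
#' @param width duration of a rectangular pulse (ms)
#' @param frequency oscillation frequency (Hz)
#' @param sigma_l,sigma_r left/right standard deviations (ms)
#' @param baseline baseline rate (Hz)
#' @return a `stimulus_spec` object
#' @export
stimulus <- function(kind = c("constant", "rectangular", "oscillatory",
                              "split_gaussian", "poisson_fixed_rate"),
                     A = 0, t0 = 0, width = Inf, frequency = 1,
                     sigma_l = 100, sigma_r = 200, baseline = 0) {
  kind <- match.arg(kind)
  # negative amplitudes are allowed for current injections; when a stimulus
  # is evaluated as a rate drive the result is clamped at zero
  if (baseline < 0) abort("stimulus baseline must be non-negative")
  if (kind == "split_gaussian" && (sigma_l <= 0 || sigma_r <= 0))
    abort("split-Gaussian standard deviations must be positive")
  structure(list(kind = kind, A = A, t0 = t0, width = width,
                 frequency = frequency, sigma_l = sigma_l, sigma_r = sigma_r,
                 baseline = baseline),
            class = "stimulus_spec")
}

#' Evaluate a stimulus drive rate
#'
#' @param spec a [stimulus()] specification
#' @param t time or vector of times (ms)
#' @param clamp clamp the result at zero (TRUE for rate drives; set FALSE
#'   when the stimulus describes an injected current)
#' @return drive rate(s) in Hz (non-negative when `clamp` is TRUE)
#' @export
drive_rate <- function(spec, t, clamp = TRUE) {
  if (!inherits(spec, "stimulus_spec")) abort("spec must be a stimulus()")
  r <- switch(spec$kind,
    constant = ,
    poisson_fixed_rate = rep(spec$baseline + spec$A, length(t)),
    rectangular = spec$baseline +
      spec$A * (t >= spec$t0 & t < spec$t0 + spec$width),
    oscillatory = spec$baseline + ifelse(t >= spec$t0,
      spec$A * (1 - cos(2 * pi * spec$frequency * (t - spec$t0) * 1e-3)) / 2, 0),
    split_gaussian = {
      s <- ifelse(t < spec$t0, spec$sigma_l, spec$sigma_r)
      spec$baseline + spec$A * exp(-(t - spec$t0)^2 / (2 * s^2))
    },
    abort(paste("unknown stimulus kind:", spec$kind))
  )
  if (clamp) pmax(r, 0) else r
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec>", x$kind, "A =", x$A, "Hz, baseline =", x$baseline,
      "Hz\n")
  invisible(x)
}

#' Ornstein-Uhlenbeck noise specification
#'
#' Mean-reverting Gaussian noise used either as a membrane current (pA) at
#' the single-cell/network scale or as extra static synaptic conductances
#' (nS) in the mean-field.
#'
#' @param mean stationary mean (pA or nS depending on `target`)
#' @param sd stationary standard deviation
#' @param tau_corr correlation time (ms)
#' @param target "current", "conductance_e" or "conductance_i"
#' @return an `ou_noise_spec` object
#' @export
ou_noise <- function(mean = 0, sd = 0, tau_corr = 10,
                     target = c("current", "conductance_e", "conductance_i")) {
  target <- match.arg(target)
  if (sd < 0) abort("OU standard deviation must be non-negative")
  if (tau_corr <= 0) abort("OU correlation time must be positive")
  structure(list(mean = mean, sd = sd, tau_corr = tau_corr, target = target),
            class = "ou_noise_spec")
}

#' Sample an Ornstein-Uhlenbeck path
#'
#' Exact discretisation with a stationary start: given step `dt` the update
#' is `x[k+1] = m + (x[k] - m) exp(-dt/tau) + s sqrt(1 - exp(-2 dt/tau)) z`.
#'
#' @param spec an [ou_noise()] specification
#' @param duration path length (ms)
#' @param dt sampling step (ms), must be smaller than the correlation time
#' @param seed optional integer seed
#' @return tibble with columns `t` (ms) and `x`
#' @export
sample_ou <- function(spec, duration, dt = 0.1, seed = NULL) {
  if (!inherits(spec, "ou_noise_spec")) abort("spec must be an ou_noise()")
  if (dt >= spec$tau_corr) abort("dt must be smaller than the correlation time")
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(duration / dt)
  al <- exp(-dt / spec$tau_corr)
  x <- numeric(n + 1)
  x[1] <- spec$mean + spec$sd * rnorm(1)
  if (spec$sd > 0) {
    z <- rnorm(n) * spec$sd * sqrt(1 - al^2)
    for (k in seq_len(n)) x[k + 1] <- spec$mean + (x[k] - spec$mean) * al + z[k]
  } else {
    x[] <- spec$mean
  }
  tibble(t = seq(0, by = dt, length.out = n + 1), x = x)
}

# Sample a stimulus on a regular grid of n steps (rate at the start of each
# step), used to build per-step drive schedules for the simulators.
stimulus_schedule <- function(spec, n_steps, dt, clamp = TRUE) {
  if (is.numeric(spec)) {
    if (length(spec) == 1) return(rep(spec, n_steps))
    if (length(spec) == n_steps) return(if (clamp) pmax(spec, 0) else spec)
    abort("numeric drive schedule has the wrong length")
  }
  drive_rate(spec, (seq_len(n_steps) - 1) * dt, clamp = clamp)
}
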