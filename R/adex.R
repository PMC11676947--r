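#' One forward-Euler step of a conductance-based AdEx neuron
#'
#' Advances membrane potential, adaptation current and synaptic conductances
#' by one step `dt`. Synaptic conductances first decay exponentially and are
#' incremented by one quantum per incoming spike; during the refractory
#' period the voltage is clamped at the reset value while adaptation and
#' conductances keep evolving; when the voltage crosses the spike-detection
#' threshold it is reset, the adaptation current is incremented by `b` and
#' the refractory clock is armed. The exponential spike term is clipped at
#' the detection threshold to avoid overflow.
#'
#' @param state list with `v` (mV), `w` (pA), `Ge`, `Gi` (nS),
#'   `refrac_remaining` (ms)
#' @param params a [cell_params()] object
#' @param I_ext external current (pA)
#' @param n_exc,n_inh number of excitatory/inhibitory spikes arriving this step
#' @param dt time step (ms)
#' @return list with the updated `state` and logical `spiked`
#' @export
adex_step <- function(state, params, I_ext = 0, n_exc = 0, n_inh = 0,
                      dt = 0.1) {
  stopifnot(dt > 0, state$Ge >= 0, state$Gi >= 0, state$refrac_remaining >= 0)
  p <- params
  v <- state$v; w <- state$w
  Ge <- state$Ge * exp(-dt / p$tau_e) + p$Qe * n_exc
  Gi <- state$Gi * exp(-dt / p$tau_i) + p$Qi * n_inh
  refrac <- state$refrac_remaining
  spiked <- FALSE
  if (refrac > 0) {
    w <- w + dt * ((p$a * (v - p$EL) - w) / p$tau_w)
    refrac <- refrac - dt
  } else {
    Isyn <- Ge * (p$Ee - v) + Gi * (p$Ei - v)
    veff <- min(v, p$V_spike)
    dv <- (p$gL * (p$EL - v) + p$gL * p$Delta * exp((veff - p$Vt) / p$Delta) -
             w + Isyn + I_ext) / p$cm
    w_new <- w + dt * ((p$a * (v - p$EL) - w) / p$tau_w)
    v <- v + dt * dv
    w <- w_new
    if (v > p$V_spike) {
      spiked <- TRUE
      v <- p$V_reset
      w <- w + p$b
      refrac <- p$t_refrac
    }
  }
  if (!is.finite(v) || !is.finite(w)) {
    bad <- if (!is.finite(v)) "v" else "w"
    abort(paste0("non-finite state variable '", bad, "' after step"))
  }
  list(state = list(v = v, w = w, Ge = Ge, Gi = Gi,
                    refrac_remaining = max(refrac, 0)),
       spiked = spiked)
}

#' Simulate a single AdEx cell
#'
#' Integrates one cell for `duration` ms under Poissonian synaptic input
#' and/or an injected current. Synaptic input is specified as per-source
#' rates (a number in Hz, a [stimulus()], or an explicit vector of spike
#' times in ms) together with in-degrees `K_exc`/`K_inh`; the cell then
#' receives a Poisson event stream of total rate `K * rate`. The injected
#' current can be a constant (pA), a per-step vector, or a [stimulus()]
#' whose rate values are read as pA. An optional [ou_noise()] with target
#' `"current"` adds a fluctuating membrane current.
#'
#' @param params a [cell_params()] object
#' @param duration simulation length (ms)
#' @param dt integration step (ms)
#' @param exc_input,inh_input per-source input rate (Hz, scalar or
#'   [stimulus()]) or a numeric vector of explicit spike times (ms) when
#'   `exc_spike_times`/`inh_spike_times` is `TRUE`
#' @param K_exc,K_inh synaptic in-degrees multiplying the input rates
#' @param exc_spike_times,inh_spike_times interpret the corresponding input
#'   as explicit spike times rather than a rate
#' @param I_ext injected current (pA): scalar, per-step vector or [stimulus()]
#' @param ou optional [ou_noise()] (target "current") added to `I_ext`
#' @param v0,w0 initial conditions (default: rest at `EL`, no adaptation)
#' @param seed optional integer seed (input realisation)
#' @param record keep the full voltage/adaptation trace
#' @return a `trace_record`: list with `trace` (tibble `t`, `v`, `w`),
#'   `spikes` (vector of spike times, ms), `duration`, `dt` and `params`
#' @export
simulate_cell <- function(params, duration, dt = 0.1,
                          exc_input = 0, inh_input = 0,
                          K_exc = 1, K_inh = 1,
                          exc_spike_times = FALSE, inh_spike_times = FALSE,
                          I_ext = 0, ou = NULL,
                          v0 = params$EL, w0 = 0,
                          seed = NULL, record = TRUE) {
  stopifnot(duration > 0, dt > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(duration / dt)

  count_schedule <- function(input, K, as_times) {
    if (as_times) {
      if (!is.numeric(input)) abort("explicit spike times must be numeric")
      return(tabulate(pmin(pmax(ceiling(input / dt), 1), n), nbins = n))
    }
    rate <- stimulus_schedule(input, n, dt)
    lam <- K * rate * dt * 1e-3
    if (all(lam == 0)) integer(n) else rpois(n, lam)
  }
  exc <- count_schedule(exc_input, K_exc, exc_spike_times)
  inh <- count_schedule(inh_input, K_inh, inh_spike_times)

  Iv <- if (inherits(I_ext, "stimulus_spec")) {
    stimulus_schedule(I_ext, n, dt, clamp = FALSE)
  } else if (length(I_ext) == 1) rep(I_ext, n) else {
    if (length(I_ext) != n) abort("I_ext vector must have one value per step")
    I_ext
  }
  if (!is.null(ou)) {
    if (!inherits(ou, "ou_noise_spec") || ou$target != "current")
      abort("ou must be an ou_noise() with target 'current'")
    Iv <- Iv + sample_ou(ou, duration, dt)$x[seq_len(n)]
  }

  res <- adex_cell_sim_cpp(par_vec(params), as.integer(exc), as.integer(inh),
                           Iv, dt, v0, w0, record)
  out <- list(spikes = res$spikes, duration = n * dt, dt = dt,
              params = params)
  if (record)
    out$trace <- tibble(t = seq(0, by = dt, length.out = n + 1),
                        v = res$v, w = res$w)
  structure(out, class = "trace_record")
}

#' @export
print.trace_record <- function(x, ...) {
  cat("<trace_record>", x$params$label, ":", x$duration, "ms,",
      length(x$spikes), "spikes\n")
  invisible(x)
}

#' Classify a spike train as silent, tonic or burst firing
#'
#' Operationalises the visual classification of step-response traces:
#' silent if fewer than two spikes fall in the stimulus window; burst if the
#' spikes form one or more clusters (intra-cluster inter-spike interval
#' below `burst_isi_max`) each followed by a quiescent period of at least
#' `quiescence_min` before the window ends or the next cluster starts; tonic
#' otherwise (sustained regular firing).
#'
#' The defaults reflect how adaptation terminates firing in this model
#' family: a burst is a spike cluster whose internal intervals stay below
#' the quiescent-gap scale (100 ms), while tonic firing persists to the end
#' of the stimulus. Tighten `burst_isi_max` (e.g. to 15 ms) to isolate only
#' high-frequency reset-driven bursts, as seen in network traces.
#'
#' @param spikes numeric vector of spike times (ms) or a `trace_record`
#' @param window length-2 numeric, the stimulus window (ms)
#' @param burst_isi_max maximal intra-burst inter-spike interval (ms)
#' @param quiescence_min minimal silence after a cluster to call it a burst (ms)
#' @return one of "silent", "tonic", "burst"
#' @export
classify_firing <- function(spikes, window,
                            burst_isi_max = 100, quiescence_min = 100) {
  if (inherits(spikes, "trace_record")) spikes <- spikes$spikes
  s <- sort(spikes[spikes >= window[1] & spikes <= window[2]])
  if (length(s) < 2) return("silent")
  isi <- diff(s)
  # split into clusters at gaps larger than burst_isi_max
  brk <- which(isi > burst_isi_max)
  starts <- c(1, brk + 1)
  ends <- c(brk, length(s))
  cluster_end_t <- s[ends]
  next_start_t <- c(s[starts][-1], window[2])
  gaps <- next_start_t - cluster_end_t
  multi <- (ends - starts + 1) >= 2
  if (any(multi & gaps >= quiescence_min)) "burst" else "tonic"
}
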