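#' Mean-field configuration for the two-population thalamic model
#'
#' Bundles everything the second-order mean-field needs: cell parameters and
#' transfer-function coefficients for the excitatory (TC) and inhibitory
#' (RE) populations, the synaptic in-degrees of the recurrent loop and of
#' the external cortical (P) and sensory (S) drives, the adiabatic time
#' constant `T`, and numerical settings.
#'
#' Default wiring mirrors the thalamic circuit: no TC->TC connections, a
#' sparse TC<->RE loop (p = 5%), dense RE->RE self-inhibition (p = 30%), a
#' cortical drive pool of 8000 sources projecting diffusely (p = 5%) to both
#' populations and a sensory pool of 500 sources projecting in full
#' (p = 1, a relay-driver pathway) to TC only.
#'
#' @param state "awake", "sleep" or "spindle" (selects cell presets)
#' @param params_e,params_i [cell_params()] for TC and RE (default: presets
#'   for `state`)
#' @param coeffs_e,coeffs_i [tf_coefficients()] per population (default:
#'   the shipped TC/RE reference fits)
#' @param N_e,N_i population sizes
#' @param N_P,N_S drive pool sizes
#' @param p_ei,p_ie,p_ii,p_drive,p_sensory connection probabilities (TC->RE,
#'   RE->TC, RE->RE, cortical drive, sensory drive)
#' @param T_ms adiabatic time constant (ms)
#' @param dt integration step (ms), must be at most `T_ms / 10`
#' @param fd_min,fd_rel finite-difference step for the transfer-function
#'   derivatives: `h = max(fd_min, fd_rel * nu)` (Hz)
#' @param c_clamp validity clamp on the rate covariances, as a multiple of
#'   their Poissonian finite-size scale `nu (1/T - nu) / N`; the second-order
#'   expansion is only meaningful for covariances of that order, and strong
#'   onset transients can otherwise push the system onto a spurious
#'   large-covariance attractor. Set to 0 to disable.
#' @param common optional common-source drive, a list `list(K =, Q =)`
#'   describing a single Poisson source of quantal strength `Q` (nS)
#'   projecting to every cell (rate supplied per run)
#' @return an `mf_config` object
#' @export
mf_config <- function(state = c("awake", "sleep", "spindle"),
                      params_e = NULL, params_i = NULL,
                      coeffs_e = tf_preset("TC"), coeffs_i = tf_preset("RE"),
                      N_e = 500, N_i = 500, N_P = 8000, N_S = 500,
                      p_ei = 0.05, p_ie = 0.05, p_ii = 0.3, p_drive = 0.05,
                      p_sensory = 1,
                      T_ms = 5, dt = 0.1, fd_min = 0.05, fd_rel = 1e-3,
                      c_clamp = 10, common = NULL) {
  state <- match.arg(state)
  params_e <- params_e %||% thalamic_cell_params("TC", state)
  params_i <- params_i %||% thalamic_cell_params("RE", state)
  if (dt > T_ms / 10) abort("integration step dt must be at most T_ms / 10")
  structure(list(
    state = state, params_e = params_e, params_i = params_i,
    coeffs_e = coeffs_e, coeffs_i = coeffs_i,
    N_e = N_e, N_i = N_i, N_P = N_P, N_S = N_S,
    K_ei = p_ei * N_e, K_ie = p_ie * N_i, K_ii = p_ii * N_i,
    K_pe = p_drive * N_P, K_pi = p_drive * N_P, K_se = p_sensory * N_S,
    T_ms = T_ms, dt = dt, fd_min = fd_min, fd_rel = fd_rel,
    c_clamp = c_clamp, common = common), class = "mf_config")
}

#' @export
print.mf_config <- function(x, ...) {
  cat("<mf_config>", x$state, ": N =", x$N_e, "+", x$N_i,
      ", T =", x$T_ms, "ms\n")
  invisible(x)
}

# list handed to the C++ core
cfg_cpp <- function(cfg) {
  nrm <- cfg$coeffs_e$norm
  list(par_e = par_vec(cfg$params_e), par_i = par_vec(cfg$params_i),
       coef_e = unname(cfg$coeffs_e$P), coef_i = unname(cfg$coeffs_i$P),
       norm = c(nrm$muV0, nrm$dmuV0, nrm$sigmaV0, nrm$dsigmaV0,
                nrm$tauVN0, nrm$dtauVN0),
       K_ie = cfg$K_ie, K_ei = cfg$K_ei, K_ii = cfg$K_ii,
       K_pe = cfg$K_pe, K_pi = cfg$K_pi, K_se = cfg$K_se,
       N_e = cfg$N_e, N_i = cfg$N_i, T_ms = cfg$T_ms,
       fd_min = cfg$fd_min, fd_rel = cfg$fd_rel, c_clamp = cfg$c_clamp,
       com_K = if (is.null(cfg$common)) 0 else cfg$common$K,
       com_Q = if (is.null(cfg$common)) 0 else cfg$common$Q)
}

#' Mean-field state vector
#'
#' @param nu_e,nu_i population rates (Hz)
#' @param c_ee,c_ei,c_ii rate covariances (Hz^2)
#' @param w_e,w_i population adaptation currents (pA)
#' @return named numeric state vector
#' @export
mf_state <- function(nu_e = 0, nu_i = 0, c_ee = 0, c_ei = 0, c_ii = 0,
                     w_e = 0, w_i = 0) {
  stopifnot(nu_e >= 0, nu_i >= 0, c_ee >= 0, c_ii >= 0)
  c(nu_e = nu_e, nu_i = nu_i, c_ee = c_ee, c_ei = c_ei, c_ii = c_ii,
    w_e = w_e, w_i = w_i)
}

#' Time derivatives of the second-order mean-field
#'
#' Master-equation right-hand side for the mean rates, rate covariances and
#' population adaptation currents, with transfer-function derivatives by
#' finite differences and the finite-size source term
#' `A_mumu = F_mu (1/T - F_mu) / N_mu`.
#'
#' @param state an [mf_state()]
#' @param cfg an [mf_config()]
#' @param P,S constant cortical/sensory drive rates (Hz)
#' @param common_rate rate of the optional common source (Hz)
#' @param noise_ge,noise_gi static noise conductances (nS)
#' @return named vector of derivatives (per ms) with attributes `F`, `muV`,
#'   `sigmaV` (per population)
#' @export
mf_derivatives <- function(state, cfg, P = 0, S = 0, common_rate = 0,
                           noise_ge = 0, noise_gi = 0) {
  stopifnot(P >= 0, S >= 0)
  d <- mf_derivs_cpp(cfg_cpp(cfg), as.numeric(state), P, S, common_rate,
                     noise_ge, noise_gi)
  if (any(!is.finite(d)))
    abort(paste("non-finite mean-field derivative; state:",
                paste(signif(state, 4), collapse = ", ")))
  d
}

#' Integrate the mean-field equations
#'
#' Forward-Euler trajectory of the two-population mean-field under
#' time-dependent drives and optional piecewise-constant conductance noise.
#' Rates and covariance diagonals are clipped at zero (clip events counted).
#'
#' @param cfg an [mf_config()]
#' @param duration run length (ms)
#' @param P,S drives: a rate (Hz), a [stimulus()], or a per-step vector
#' @param init initial [mf_state()]
#' @param noise optional `noisy_conductances` from [ou_conductance_noise()]
#' @param common_rate rate of the common source (Hz; scalar or [stimulus()])
#' @param stride record every `stride`-th step
#' @return tibble trajectory: `t`, `nu_e`, `nu_i`, covariances, adaptation,
#'   `muV_*`, `sigmaV_*`; attribute `clips`
#' @export
integrate_mf <- function(cfg, duration, P = 0, S = 0,
                         init = mf_state(), noise = NULL,
                         common_rate = 0, stride = 10) {
  stopifnot(duration > 0)
  n <- ceiling(duration / cfg$dt)
  Pv <- stimulus_schedule(P, n, cfg$dt)
  Sv <- stimulus_schedule(S, n, cfg$dt)
  comv <- if (is.null(cfg$common)) numeric(0) else
    stimulus_schedule(common_rate, n, cfg$dt)
  if (is.null(noise)) {
    nge <- numeric(0); ngi <- numeric(0); nbin <- cfg$T_ms
  } else {
    stopifnot(inherits(noise, "noisy_conductances"))
    nbin <- noise$T_ms
    nb <- ceiling(duration / nbin) + 1
    nge <- rep_len(noise$ge, nb)
    ngi <- rep_len(noise$gi, nb)
  }
  res <- mf_integrate_cpp(cfg_cpp(cfg), as.numeric(init), Pv, Sv, comv,
                          nge, ngi, nbin, cfg$dt, stride)
  out <- as_tibble(as.data.frame(res$trajectory))
  attr(out, "clips") <- res$clips
  class(out) <- c("mf_trajectory", class(out))
  out
}

#' Stationary mean-field state under constant drives
#'
#' Long-time integration until the relative change of every rate over one
#' second falls below `tol`, optionally refined by Levenberg-Marquardt
#' root-finding on the full 7-dimensional derivative vector. Flags the
#' oscillatory (no stable fixed point) case.
#'
#' @inheritParams mf_derivatives
#' @param cfg an [mf_config()]
#' @param init initial state (default: a weakly active seed)
#' @param max_time integration cap (ms)
#' @param tol relative convergence tolerance per second
#' @param refine polish the endpoint by root-finding
#' @return a one-row tibble: rates `nu_e`, `nu_i`, their standard deviations
#'   `sd_e`, `sd_i` (`sqrt` of the covariance diagonal), covariances,
#'   adaptation, `muV`/`sigmaV` per population, and `converged`
#' @export
stationary_state <- function(cfg, P = 0, S = 0, common_rate = 0,
                             noise_ge = 0, noise_gi = 0,
                             init = mf_state(nu_e = 2, nu_i = 10),
                             max_time = 30000, tol = 1e-6, refine = TRUE) {
  chunk <- 1000 # ms
  state <- init
  elapsed <- 0
  converged <- FALSE
  noise <- NULL
  if (noise_ge > 0 || noise_gi > 0)
    noise <- structure(list(ge = noise_ge, gi = noise_gi, T_ms = cfg$T_ms),
                       class = "noisy_conductances")
  while (elapsed < max_time) {
    tr <- integrate_mf(cfg, chunk, P = P, S = S, init = state, noise = noise,
                       common_rate = common_rate, stride = 10)
    new <- unlist(tr[nrow(tr), c("nu_e", "nu_i", "c_ee", "c_ei", "c_ii",
                                 "w_e", "w_i")])
    rel <- abs(new[1:2] - state[1:2]) / pmax(abs(new[1:2]), 0.01)
    state <- mf_state(new[1], new[2], max(new[3], 0), new[4], max(new[5], 0),
                      new[6], new[7])
    elapsed <- elapsed + chunk
    if (elapsed >= 2 * chunk && all(rel < tol)) { converged <- TRUE; break }
  }
  if (!converged)
    warn("no stable fixed point reached (oscillatory regime?)")
  if (refine && converged) {
    fit <- try(minpack.lm::nls.lm(
      par = as.numeric(state),
      fn = function(s) {
        s[c(1, 2, 3, 5)] <- pmax(s[c(1, 2, 3, 5)], 0)
        as.numeric(mf_derivs_cpp(cfg_cpp(cfg), s, P, S, common_rate,
                                 noise_ge, noise_gi))
      },
      control = minpack.lm::nls.lm.control(maxiter = 100)), silent = TRUE)
    if (!inherits(fit, "try-error") && fit$deviance < 1e-8) {
      s <- fit$par
      s[c(1, 2, 3, 5)] <- pmax(s[c(1, 2, 3, 5)], 0)
      state <- mf_state(s[1], s[2], s[3], s[4], s[5], s[6], s[7])
    }
  }
  d <- mf_derivatives(state, cfg, P = P, S = S, common_rate = common_rate,
                      noise_ge = noise_ge, noise_gi = noise_gi)
  muV <- attr(d, "muV"); sigV <- attr(d, "sigmaV")
  tibble(nu_e = state["nu_e"], nu_i = state["nu_i"],
         sd_e = sqrt(max(state["c_ee"], 0)), sd_i = sqrt(max(state["c_ii"], 0)),
         c_ee = state["c_ee"], c_ei = state["c_ei"], c_ii = state["c_ii"],
         w_e = state["w_e"], w_i = state["w_i"],
         muV_e = muV[1], muV_i = muV[2],
         sigmaV_e = sigV[1], sigmaV_i = sigV[2],
         converged = converged)
}

#' Piecewise-constant OU conductance noise for the mean-field
#'
#' Samples one OU path per conductance class at fine resolution, block
#' averages it over bins of the mean-field time constant `T`, and clips
#' negative values to zero. The two classes (excitatory/inhibitory static
#' conductances) use independent paths with the same specification unless
#' `spec_i` is given.
#'
#' @param spec an [ou_noise()] (nS) for the excitatory class
#' @param duration path length (ms)
#' @param T_ms bin width (mean-field adiabatic time constant, ms)
#' @param spec_i optional separate specification for the inhibitory class
#' @param dt fine sampling step (ms)
#' @param seed optional integer seed
#' @return a `noisy_conductances` object: per-bin vectors `ge`, `gi` (nS)
#' @export
ou_conductance_noise <- function(spec, duration, T_ms = 5, spec_i = spec,
                                 dt = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  block_avg <- function(s) {
    x <- sample_ou(s, duration, dt)$x
    nb <- ceiling(duration / T_ms)
    per <- T_ms / dt
    idx <- pmin(floor((seq_along(x) - 1) / per) + 1, nb)
    pmax(as.numeric(tapply(x, idx, mean)), 0)
  }
  structure(list(ge = block_avg(spec), gi = block_avg(spec_i), T_ms = T_ms),
            class = "noisy_conductances")
}
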