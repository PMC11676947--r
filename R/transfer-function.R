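#' Synaptic input connectivity seen by one cell
#'
#' Mean in-degrees and synaptic parameters that map population input rates
#' onto the shotnoise statistics of a single cell's membrane. `K = p * N`
#' for an Erdos-Renyi projection with connection probability `p` from a
#' population of size `N`.
#'
#' @param params a [cell_params()] supplying Qe/Qi, tau_e/tau_i, Ee/Ei, gL,
#'   EL, cm
#' @param K_e,K_i mean excitatory/inhibitory synaptic in-degrees
#' @return an `input_connectivity` object
#' @export
input_connectivity <- function(params, K_e, K_i) {
  stopifnot(K_e >= 0, K_i >= 0)
  structure(list(K_e = K_e, K_i = K_i, Qe = params$Qe, Qi = params$Qi,
                 tau_e = params$tau_e, tau_i = params$tau_i,
                 Ee = params$Ee, Ei = params$Ei, gL = params$gL,
                 EL = params$EL, cm = params$cm, label = params$label),
            class = "input_connectivity")
}

#' Mean and standard deviation of the synaptic conductances
#'
#' Campbell's theorem for Poissonian shotnoise with exponential synapses:
#' `muG_x = nu_x K_x tau_x Q_x` and `sigmaG_x = Q_x sqrt(nu_x K_x tau_x / 2)`
#' (rates in Hz, synaptic times converted to seconds). The total input
#' conductance adds the leak: `muG = muGe + muGi + gL`.
#'
#' @param nu_e,nu_i per-source excitatory/inhibitory input rates (Hz),
#'   vectorised
#' @param ic an [input_connectivity()]
#' @return tibble with `muGe`, `muGi`, `sigmaGe`, `sigmaGi`, `muG` (nS)
#' @export
conductance_moments <- function(nu_e, nu_i, ic) {
  if (any(nu_e < 0) || any(nu_i < 0)) abort("input rates must be non-negative")
  muGe <- nu_e * ic$K_e * (ic$tau_e * 1e-3) * ic$Qe
  muGi <- nu_i * ic$K_i * (ic$tau_i * 1e-3) * ic$Qi
  tibble(muGe = muGe, muGi = muGi,
         sigmaGe = ic$Qe * sqrt(nu_e * ic$K_e * (ic$tau_e * 1e-3) / 2),
         sigmaGi = ic$Qi * sqrt(nu_i * ic$K_i * (ic$tau_i * 1e-3) / 2),
         muG = muGe + muGi + ic$gL)
}

#' Subthreshold membrane fluctuation moments
#'
#' Mean, standard deviation and autocorrelation time of the membrane
#' potential of a conductance-based cell under Poissonian input, in the
#' first-order (effective-leak) approximation. The mean includes the
#' adaptation current `w`; the variance and autocorrelation time follow from
#' the shotnoise power spectrum of single post-synaptic potentials with
#' effective drive `U_x = Q_x/muG (E_x - muV)`:
#' `sigmaV^2 = sum_x K_x nu_x (U_x tau_x)^2 / (2 (tau_m + tau_x))` and
#' `tauV = sum_x K_x nu_x (U_x tau_x)^2 / sum_x [K_x nu_x (U_x tau_x)^2 /
#' (tau_m + tau_x)]`, which reduces to `tau_m + tau_x` for a single synaptic
#' class. With no input at all, `sigmaV = 0` and `tauV` is set to
#' `tau_m + max(tau_e, tau_i)` by convention.
#'
#' Optional static conductances `extra_ge`/`extra_gi` (nS, at the synaptic
#' reversal potentials) shift `muG` and `muV` without contributing shotnoise
#' variance; they implement the piecewise-constant noise conductances of the
#' mean-field noise experiments.
#'
#' @inheritParams conductance_moments
#' @param w adaptation current (pA), vectorised
#' @param extra_ge,extra_gi static excitatory/inhibitory conductances (nS)
#' @return tibble with `muV` (mV), `sigmaV` (mV), `tauV` (ms), `tauVN`
#'   (dimensionless `tauV gL / cm`), `muG` (nS), `tau_m` (ms), `U_e`, `U_i`
#'   (mV)
#' @export
membrane_moments <- function(nu_e, nu_i, w = 0, ic,
                             extra_ge = 0, extra_gi = 0) {
  g <- conductance_moments(nu_e, nu_i, ic)
  muG <- g$muG + extra_ge + extra_gi
  muV <- (g$muGe * ic$Ee + g$muGi * ic$Ei + extra_ge * ic$Ee +
            extra_gi * ic$Ei + ic$gL * ic$EL - w) / muG
  tau_m <- ic$cm / muG # ms (pF / nS)
  U_e <- ic$Qe / muG * (ic$Ee - muV)
  U_i <- ic$Qi / muG * (ic$Ei - muV)
  ce <- ic$K_e * nu_e * (U_e * ic$tau_e * 1e-3)^2
  ci <- ic$K_i * nu_i * (U_i * ic$tau_i * 1e-3)^2
  tm_s <- tau_m * 1e-3
  num <- ce + ci
  den <- ce / (tm_s + ic$tau_e * 1e-3) + ci / (tm_s + ic$tau_i * 1e-3)
  sigmaV <- sqrt(pmax(den, 0) / 2)
  tauV <- ifelse(num > 0, num / den * 1e3,
                 tau_m + max(ic$tau_e, ic$tau_i))
  tibble(muV = muV, sigmaV = sigmaV, tauV = tauV,
         tauVN = tauV * ic$gL / ic$cm, muG = muG, tau_m = tau_m,
         U_e = U_e, U_i = U_i)
}

#' Effective-threshold polynomial coefficients
#'
#' The ten amplitudes of the second-order polynomial expressing the
#' effective firing threshold as a function of the normalised fluctuation
#' moments (muV, sigmaV, tauVN), plus the normalisation constants of the
#' fluctuation-driven regime.
#'
#' @param P numeric vector of 10 coefficients (mV), in the order P0, Pmu,
#'   Psigma, Ptau, Pmumu, Pmusigma, Pmutau, Psigmasigma, Psigmatau, Ptautau
#' @param norm normalisation constants (means and spans of muV, sigmaV,
#'   tauVN); the defaults delimit the fluctuation-driven regime
#' @return a `tf_coefficients` object
#' @export
tf_coefficients <- function(P, norm = tf_norm()) {
  P <- as.numeric(P)
  if (length(P) != 10 || any(!is.finite(P)))
    abort("tf_coefficients needs 10 finite values")
  names(P) <- tf_coef_names()
  structure(list(P = P, norm = norm), class = "tf_coefficients")
}

tf_coef_names <- function() {
  c("P0", "Pmu", "Psigma", "Ptau", "Pmumu", "Pmusigma", "Pmutau",
    "Psigmasigma", "Psigmatau", "Ptautau")
}

#' @rdname tf_coefficients
#' @export
tf_norm <- function() {
  list(muV0 = -60, dmuV0 = 10, sigmaV0 = 4, dsigmaV0 = 6,
       tauVN0 = 0.5, dtauVN0 = 1)
}

#' Reference transfer-function coefficients for TC and RE cells
#'
#' Fitted effective-threshold amplitudes (mV) for the thalamocortical relay
#' and reticular cell types, obtained from single-cell simulations in the
#' awake state; one fit per cell type is shared across awake/sleep states.
#'
#' @param cell "TC" or "RE"
#' @return a [tf_coefficients()] object
#' @export
tf_preset <- function(cell = c("TC", "RE")) {
  cell <- match.arg(cell)
  P <- switch(cell,
    TC = c(-47.31, 1.68, 0.97, -3.46, 0.47, -1.68, -6.46, 3.43, -1.14, 0.19),
    RE = c(-40.77, -1.98, -3.12, 3.57, 1.39, -0.38, -0.33, 0.16, 0.26, -0.53))
  tf_coefficients(P)
}

#' @export
print.tf_coefficients <- function(x, ...) {
  cat("<tf_coefficients> (mV)\n")
  print(round(x$P, 3))
  invisible(x)
}

# polynomial basis in normalised moment space (n x 10 matrix)
tf_basis <- function(muV, sigmaV, tauVN, norm) {
  x <- (muV - norm$muV0) / norm$dmuV0
  y <- (sigmaV - norm$sigmaV0) / norm$dsigmaV0
  z <- (tauVN - norm$tauVN0) / norm$dtauVN0
  cbind(1, x, y, z, x * x, x * y, x * z, y * y, y * z, z * z)
}

#' Effective firing threshold
#'
#' Evaluates the second-order effective-threshold polynomial at the given
#' fluctuation moments.
#'
#' @param m tibble from [membrane_moments()] (needs `muV`, `sigmaV`, `tauVN`)
#' @param coeffs a [tf_coefficients()]
#' @return effective threshold(s) in mV
#' @export
effective_threshold <- function(m, coeffs) {
  drop(tf_basis(m$muV, m$sigmaV, m$tauVN, coeffs$norm) %*% coeffs$P)
}

#' Semi-analytic transfer function
#'
#' Output firing rate of a cell given its excitatory and inhibitory input
#' rates and adaptation current:
#' `nu_out = 1/(2 tauV) erfc((Vthr_eff - muV) / (sqrt(2) sigmaV))`.
#' In the degenerate noiseless limit `sigmaV = 0` the rate is 0 below the
#' effective threshold and `1/tauV` above it.
#'
#' @inheritParams membrane_moments
#' @param coeffs a [tf_coefficients()]
#' @return output rate(s) in Hz, bounded by `[0, 1/tauV]`
#' @export
transfer_rate <- function(nu_e, nu_i, w = 0, coeffs, ic,
                          extra_ge = 0, extra_gi = 0) {
  m <- membrane_moments(nu_e, nu_i, w, ic, extra_ge, extra_gi)
  vthr <- effective_threshold(m, coeffs)
  tauV_s <- m$tauV * 1e-3
  out <- ifelse(m$sigmaV < 1e-9,
                ifelse(m$muV > vthr, 1 / tauV_s, 0),
                0.5 / tauV_s * erfc((vthr - m$muV) / (sqrt(2) * m$sigmaV)))
  as.numeric(out)
}

#' Monte-Carlo sampling of single-cell output rates
#'
#' Drives one AdEx cell with stationary Poisson input at every point of a
#' rate grid and records its mean output rate, averaged over repetitions.
#' The cell receives an event stream of rate `K_e * nu_e` (excitatory) and
#' `K_i * nu_i` (inhibitory).
#'
#' @param params a [cell_params()]
#' @param ic an [input_connectivity()]
#' @param grid data frame with columns `nu_e`, `nu_i` (Hz)
#' @param duration run length per repetition (ms)
#' @param reps repetitions per grid point
#' @param dt integration step (ms)
#' @param seed integer seed
#' @return tibble `nu_e`, `nu_i`, `nu_out` (Hz), `sd_out` (across-rep sd),
#'   `se_out` (Monte-Carlo standard error), `reps`
#' @export
sample_single_cell_rates <- function(params, ic, grid, duration = 5000,
                                     reps = 10, dt = 0.1, seed = NULL) {
  if (nrow(grid) == 0) abort("rate grid is empty")
  if (!is.null(seed)) set.seed(seed)
  n <- ceiling(duration / dt)
  Iv <- rep(0, n)
  pv <- par_vec(params)
  res <- purrr::pmap(grid[, c("nu_e", "nu_i")], function(nu_e, nu_i) {
    lam_e <- ic$K_e * nu_e * dt * 1e-3
    lam_i <- ic$K_i * nu_i * dt * 1e-3
    rates <- vapply(seq_len(reps), function(r) {
      exc <- if (lam_e > 0) rpois(n, lam_e) else integer(n)
      inh <- if (lam_i > 0) rpois(n, lam_i) else integer(n)
      sim <- adex_cell_sim_cpp(pv, as.integer(exc), as.integer(inh), Iv, dt,
                               params$EL, 0, FALSE)
      length(sim$spikes) / (duration * 1e-3)
    }, numeric(1))
    c(mean(rates), sd(rates))
  })
  out <- tibble(nu_e = grid$nu_e, nu_i = grid$nu_i,
                nu_out = map_dbl(res, 1), sd_out = map_dbl(res, 2),
                reps = reps)
  out$se_out <- out$sd_out / sqrt(reps)
  out
}

#' Default rate grid for transfer-function fitting
#'
#' Excitatory rates log-spaced over the fluctuation-driven regime crossed
#' with a small set of inhibitory rates.
#'
#' @param n_e number of excitatory rates, log-spaced over `e_range`
#' @param e_range range of excitatory rates (Hz)
#' @param nu_i_values inhibitory rates (Hz)
#' @return tibble with columns `nu_e`, `nu_i`
#' @export
tf_fit_grid <- function(n_e = 12, e_range = c(0.1, 200),
                        nu_i_values = c(0, 5, 10, 20, 40)) {
  tidyr::expand_grid(
    nu_e = exp(seq(log(e_range[1]), log(e_range[2]), length.out = n_e)),
    nu_i = nu_i_values)
}

# stationary adaptation from a measured output rate, solved by damped
# fixed-point iteration of w = b tau_w nu + a (muV(w) - EL)
stationary_w <- function(nu_out, nu_e, nu_i, params, ic,
                         tol = 0.01, max_iter = 100, damp = 0.5) {
  w <- 0
  for (k in seq_len(max_iter)) {
    muV <- membrane_moments(nu_e, nu_i, w, ic)$muV
    w_new <- params$b * (params$tau_w * 1e-3) * nu_out +
      params$a * (muV - params$EL)
    if (abs(w_new - w) < tol) return(w_new)
    w <- damp * w + (1 - damp) * w_new
  }
  w
}

#' Two-stage transfer-function fit
#'
#' Fits the ten effective-threshold amplitudes to a measured single-cell
#' rate table. Stage 1 computes, for every grid point with
#' `0 < nu_out < 1/tauV`, the stationary adaptation current implied by the
#' measured rate, inverts the erfc rate equation for the effective
#' threshold, and solves the linear least-squares problem in threshold
#' space. Stage 2 refines all ten amplitudes by nonlinear least squares of
#' the predicted rates against the measured rates (Levenberg-Marquardt),
#' initialised at the Stage-1 solution.
#'
#' @param rate_table tibble from [sample_single_cell_rates()] (columns
#'   `nu_e`, `nu_i`, `nu_out`; optional `se_out` used when `weighted`)
#' @param params a [cell_params()]
#' @param ic an [input_connectivity()]
#' @param norm normalisation constants, see [tf_norm()]
#' @param weighted weight Stage-2 residuals by 1/se_out
#' @param min_points minimal number of active (nu_out > 0) points required
#' @return a `tf_fit` object: the fitted [tf_coefficients()] plus
#'   diagnostics (`rmse` in Hz, stage-1 coefficients, residuals)
#' @export
fit_transfer_function <- function(rate_table, params, ic, norm = tf_norm(),
                                  weighted = FALSE, min_points = 30) {
  rt <- as_tibble(rate_table)
  stopifnot(all(c("nu_e", "nu_i", "nu_out") %in% names(rt)))
  active <- sum(rt$nu_out > 0)
  if (active < min_points)
    abort(sprintf("rate table has only %d active points (need >= %d)",
                  active, min_points))
  rt$w_star <- purrr::pmap_dbl(rt[, c("nu_out", "nu_e", "nu_i")],
                               function(nu_out, nu_e, nu_i)
                                 stationary_w(nu_out, nu_e, nu_i, params, ic))
  mom <- membrane_moments(rt$nu_e, rt$nu_i, rt$w_star, ic)

  # stage 1: invert the rate equation where defined, linear fit in
  # threshold space
  tauV_s <- mom$tauV * 1e-3
  invertible <- rt$nu_out > 0 & rt$nu_out < 1 / tauV_s & mom$sigmaV > 0
  n_excl <- sum(!invertible)
  if (n_excl > 0)
    inform(sprintf("stage 1: excluding %d non-invertible points (rate 0 or saturated)",
                   n_excl))
  vthr_emp <- mom$muV + sqrt(2) * mom$sigmaV *
    erfcinv(2 * tauV_s * pmin(rt$nu_out, 1 / tauV_s))
  X <- tf_basis(mom$muV, mom$sigmaV, mom$tauVN, norm)
  fit1 <- lm.fit(X[invertible, , drop = FALSE], vthr_emp[invertible])
  P1 <- fit1$coefficients
  P1[is.na(P1)] <- 0

  # stage 2: nonlinear least squares in rate space
  wts <- if (weighted && "se_out" %in% names(rt)) 1 / pmax(rt$se_out, 0.1) else
    rep(1, nrow(rt))
  resid_fun <- function(P) {
    vthr <- drop(X %*% P)
    pred <- ifelse(mom$sigmaV < 1e-9,
                   ifelse(mom$muV > vthr, 1 / tauV_s, 0),
                   0.5 / tauV_s * erfc((vthr - mom$muV) / (sqrt(2) * mom$sigmaV)))
    (pred - rt$nu_out) * wts
  }
  fit2 <- minpack.lm::nls.lm(par = P1, fn = resid_fun,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  if (fit2$info == 0)
    abort(paste("stage 2 did not converge; residual norm",
                signif(sqrt(fit2$deviance), 4)))
  P2 <- fit2$par
  res <- resid_fun(P2) / wts
  structure(list(coefficients = tf_coefficients(P2, norm),
                 stage1 = tf_coefficients(P1, norm),
                 rmse = sqrt(mean(res^2)),
                 residuals = res, n_points = nrow(rt),
                 n_excluded = n_excl, cell = params$label,
                 table = rt),
            class = "tf_fit")
}

#' @export
print.tf_fit <- function(x, ...) {
  cat("<tf_fit>", x$cell, ":", x$n_points, "grid points, RMSE",
      signif(x$rmse, 3), "Hz\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.tf_fit <- function(x, ...) {
  tibble(term = tf_coef_names(), estimate = unname(x$coefficients$P),
         stage1 = unname(x$stage1$P))
}

#' @export
glance.tf_fit <- function(x, ...) {
  tibble(rmse = x$rmse, n_points = x$n_points, n_excluded = x$n_excluded,
         cell = x$cell)
}
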