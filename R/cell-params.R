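#' AdEx cell and synapse parameters
#'
#' Construct the full parameter set of one adaptive exponential
#' integrate-and-fire (AdEx) cell with conductance-based synapses. The
#' internal unit system is mV, ms, nS, pA, pF (self-consistent: pA/nS = mV,
#' pF/nS = ms). Rates are in Hz everywhere at the user surface.
#'
#' @param cm membrane capacitance (pF)
#' @param gL leak conductance (nS)
#' @param EL resting (leak reversal) potential (mV)
#' @param Vt spike-onset threshold of the exponential term (mV)
#' @param Delta spike-onset sharpness (mV)
#' @param a subthreshold adaptation conductance (nS)
#' @param b spike-triggered adaptation increment (pA)
#' @param tau_w adaptation time constant (ms)
#' @param Qe,Qi excitatory/inhibitory quantal conductance increments (nS)
#' @param tau_e,tau_i synaptic decay time constants (ms)
#' @param Ee,Ei excitatory/inhibitory reversal potentials (mV)
#' @param V_spike numerical spike-detection threshold (mV)
#' @param V_reset post-spike reset potential (mV)
#' @param t_refrac refractory period (ms)
#' @param label cell-type and state tag, e.g. "TC_awake"
#' @return an object of class `cell_params` (a named list)
#' @export
cell_params <- function(cm, gL, EL, Vt, Delta, a, b, tau_w,
                        Qe, Qi, tau_e, tau_i, Ee, Ei,
                        V_spike = -20, V_reset = -50, t_refrac = 5,
                        label = "cell") {
  p <- list(cm = cm, gL = gL, EL = EL, Vt = Vt, Delta = Delta, a = a, b = b,
            tau_w = tau_w, Qe = Qe, Qi = Qi, tau_e = tau_e, tau_i = tau_i,
            Ee = Ee, Ei = Ei, V_spike = V_spike, V_reset = V_reset,
            t_refrac = t_refrac, label = label)
  validate_cell_params(p)
  structure(p, class = "cell_params")
}

validate_cell_params <- function(p) {
  stopifnot(p$cm > 0, p$gL > 0, p$tau_w > 0, p$tau_e > 0, p$tau_i > 0,
            p$Delta > 0, p$t_refrac >= 0)
  # note: EL may sit below Ei (e.g. strongly hyperpolarised sleep states)
  if (!(p$Ei < p$Ee && p$EL < p$Ee))
    abort("reversal potentials must satisfy Ei < Ee and EL < Ee")
  if (!(p$V_reset < p$V_spike))
    abort("V_reset must lie below the spike-detection threshold V_spike")
  invisible(p)
}

# numeric vector in the fixed layout shared with the C++ simulators
par_vec <- function(p) {
  c(p$cm, p$gL, p$EL, p$Vt, p$Delta, p$a, p$b, p$tau_w,
    p$Qe, p$Qi, p$tau_e, p$tau_i, p$Ee, p$Ei,
    p$V_spike, p$V_reset, p$t_refrac)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("<cell_params>", x$label, "\n")
  flds <- setdiff(names(x), "label")
  cat(paste0("  ", flds, " = ", unlist(x[flds]), collapse = "\n"), "\n")
  invisible(x)
}

# Preset tables. The sleep column inherits every value not explicitly
# changed by the loss of acetylcholine (depolarising drive withdrawn,
# adaptation strengthened); the spindle presets additionally raise the reset
# potential above the spike-onset threshold to evoke rebound bursting.
preset_table <- function() {
  list(
    TC_awake = list(cm = 160, gL = 10, EL = -65, Vt = -50, Delta = 4.5,
                    a = 0, b = 10, tau_w = 200, Qe = 1, Qi = 6,
                    tau_e = 5, tau_i = 5, Ee = 0, Ei = -80,
                    V_spike = -20, V_reset = -50, t_refrac = 5),
    RE_awake = list(cm = 200, gL = 10, EL = -75, Vt = -45, Delta = 2.5,
                    a = 8, b = 10, tau_w = 200, Qe = 4, Qi = 1,
                    tau_e = 5, tau_i = 5, Ee = 0, Ei = -80,
                    V_spike = -20, V_reset = -55, t_refrac = 5),
    TC_sleep = list(EL = -70, gL = 9.5, tau_w = 270, a = 24, b = 200),
    RE_sleep = list(EL = -85, gL = 13, tau_w = 230, a = 28, b = 20),
    TC_spindle = list(V_reset = -48),
    RE_spindle = list(V_reset = -42)
  )
}

#' Thalamic cell parameter presets
#'
#' Named AdEx parameter sets for thalamocortical relay (TC) and reticular
#' (RE) cells in the awake (acetylcholine present), sleep (acetylcholine
#' absent) and spindle (sleep with rebound-burst reset) states.
#'
#' @param cell "TC" or "RE"
#' @param state "awake", "sleep" or "spindle"
#' @param ... named parameter overrides (e.g. `EL = -70`, `Qe = 14`)
#' @return a [cell_params()] object
#' @examples
#' thalamic_cell_params("TC", "awake")
#' @export
thalamic_cell_params <- function(cell = c("TC", "RE"),
                                 state = c("awake", "sleep", "spindle"),
                                 ...) {
  cell <- match.arg(cell)
  state <- match.arg(state)
  tab <- preset_table()
  p <- tab[[paste0(cell, "_awake")]]
  if (state %in% c("sleep", "spindle"))
    p <- modifyList(p, tab[[paste0(cell, "_sleep")]])
  if (state == "spindle")
    p <- modifyList(p, tab[[paste0(cell, "_spindle")]])
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) abort(paste("unknown parameter override:", bad[1]))
    p <- modifyList(p, dots)
  }
  p$label <- paste0(cell, "_", state)
  do.call(cell_params, p)
}
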