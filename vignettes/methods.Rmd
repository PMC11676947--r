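---
title: "Methods: from single AdEx cells to a thalamic mean-field"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single AdEx cells to a thalamic mean-field}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(thalamr)
library(ggplot2)
```

`thalamr` implements a multi-scale model of the thalamic relay circuit:
conductance-based adaptive exponential integrate-and-fire (AdEx) neurons, an
Erdős–Rényi spiking network of thalamocortical relay (TC) and reticular (RE)
cells, and a second-order mean-field whose ingredient is a semi-analytic
transfer function. This vignette walks through the mathematical layers in the
order they build on each other. The internal unit system is mV, ms, nS, pA,
pF; rates are in Hz at every user-facing surface.

## 1. The AdEx neuron

Each cell obeys

$$
c_m \frac{dv}{dt} = g_L (E_L - v) + g_L \Delta
  e^{(v - V_t)/\Delta} - w + G_e (E_e - v) + G_i (E_i - v) + I_{\mathrm{ext}},
\qquad
\frac{dw}{dt} = \frac{a (v - E_L) - w}{\tau_w},
$$

with exponential synaptic conductances ($G_x \to G_x + Q_x$ per incoming
spike, decay time $\tau_x$). When $v$ crosses the detection threshold the
cell spikes: $v \to V_{\mathrm{reset}}$, $w \to w + b$, and the voltage is
clamped for a 5 ms refractory period. Two cell types (TC, RE) in three
neuromodulatory states (awake, sleep, spindle) are shipped as presets;
sleep withdraws the depolarising drive (lower $E_L$) and strengthens
adaptation ($a$, $b$), while the spindle presets additionally raise
$V_{\mathrm{reset}}$ above the spike-onset threshold to promote
reset-driven bursting.

```{r fig1}
p_awake <- thalamic_cell_params("TC", "awake")
p_sleep <- thalamic_cell_params("TC", "sleep")
stim <- stimulus("rectangular", A = 600, t0 = 200, width = 1000)
tr_a <- simulate_cell(p_awake, 1500, I_ext = stim, seed = 1)
tr_s <- simulate_cell(p_sleep, 1500, I_ext = stim, seed = 1)
classify_firing(tr_a, c(200, 1200))  # tonic
classify_firing(tr_s, c(200, 1200))  # burst
autoplot(tr_a)
```

## 2. The spiking network

`network_config()` describes 500 TC and 500 RE cells wired at random: TC
excites RE (p = 5%), RE inhibits TC (5%) and itself (30%), and TC cells never
contact each other. Two external Poissonian pools drive the circuit: a
cortical pool (8000 sources, 5% connectivity, both populations) and a sensory
pool (500 sources, p = 1, TC only — a strong relay-driver pathway).

```{r fig2}
ncfg <- network_config("awake", seed = 1L)
conn <- build_connectivity(ncfg)
ras <- simulate_network(conn, ncfg, duration = 2000, P_drive = 4, seed = 1L)
rate <- bin_population_rate(ras, "RE", T_bin = 5)
autoplot(ras)
```

## 3. Subthreshold moments and the semi-analytic transfer function

For stationary Poissonian input at per-source rates $\nu_e, \nu_i$ through
$K_e, K_i$ synapses, Campbell's theorem gives the conductance moments
$\mu_{G_x} = \nu_x K_x \tau_x Q_x$ and
$\sigma_{G_x} = Q_x \sqrt{\nu_x K_x \tau_x / 2}$. In the effective-leak
approximation the membrane then fluctuates around

$$
\mu_V = \frac{\mu_{G_e} E_e + \mu_{G_i} E_i + g_L E_L - w}{\mu_G},
$$

with standard deviation $\sigma_V$ and autocorrelation time $\tau_V$ obtained
from the shotnoise power spectrum of single post-synaptic potentials
(`membrane_moments()`). The output rate follows the fluctuation-driven
expression

$$
\nu_{\mathrm{out}} = \frac{1}{2 \tau_V}
  \operatorname{erfc}\!\left(\frac{V^{\mathrm{eff}}_{\mathrm{thre}} - \mu_V}
  {\sqrt{2}\,\sigma_V}\right),
$$

where the effective threshold $V^{\mathrm{eff}}_{\mathrm{thre}}$ is a
second-order polynomial in the normalised moments
$(\mu_V, \sigma_V, \tau_V g_L / c_m)$ with ten amplitudes. The amplitudes are
fitted per cell type from single-cell simulations by a two-stage pipeline
(`fit_transfer_function()`): stage 1 inverts the erfc equation point-wise and
solves a linear least-squares problem in threshold space; stage 2 refines all
ten amplitudes by Levenberg–Marquardt in rate space. Adaptation enters
through its stationary value $w^* = b \tau_w \nu + a (\mu_V - E_L)$, solved
self-consistently. Reference fits for TC and RE are shipped
(`tf_preset()`).

```{r fig3}
ic <- input_connectivity(p_awake, K_e = 400, K_i = 25)
membrane_moments(nu_e = 4, nu_i = 10, w = 0, ic)
nu_e <- seq(0.5, 20, length.out = 40)
plot_df <- data.frame(nu_e = nu_e,
                      rate = transfer_rate(nu_e, 10, 0, tf_preset("TC"), ic))
ggplot(plot_df, aes(nu_e, rate)) + geom_line() + theme_minimal() +
  labs(x = "excitatory input rate (Hz)", y = "TC output rate (Hz)")
```

## 4. The second-order mean-field

On an adiabatic timescale $T = 5$ ms the two population rates
$\nu_e, \nu_i$, their covariances $c_{\alpha\beta}$ and the population
adaptation currents $w_e, w_i$ obey a master-equation expansion to second
order:

$$
T \frac{d\nu_\alpha}{dt} = (F_\alpha - \nu_\alpha)
  + \tfrac{1}{2} c_{\beta\gamma}
    \frac{\partial^2 F_\alpha}{\partial \nu_\beta \partial \nu_\gamma},
\qquad
T \frac{dc_{\alpha\beta}}{dt} = A_{\alpha\beta}
  + (F_\alpha - \nu_\alpha)(F_\beta - \nu_\beta)
  + c_{\alpha\gamma} \frac{\partial F_\beta}{\partial \nu_\gamma}
  + c_{\beta\gamma} \frac{\partial F_\alpha}{\partial \nu_\gamma}
  - 2 c_{\alpha\beta},
$$

with the finite-size source $A_{\alpha\alpha} = F_\alpha (1/T -
F_\alpha)/N_\alpha$ and the adaptation dynamics
$\tau_w \dot w = a(\mu_V - E_L) - w + b \tau_w \nu$. The transfer-function
derivatives are evaluated by finite differences. Synaptic noise experiments
add piecewise-constant excitatory/inhibitory conductances sampled from an
Ornstein–Uhlenbeck process and block-averaged over $T$
(`ou_conductance_noise()`).

```{r fig4}
cfg <- mf_config("awake")
st <- stationary_state(cfg, P = 4)
st[, c("nu_e", "nu_i", "sd_e", "sd_i", "converged")]
tr <- integrate_mf(cfg, 1500, P = 4,
                   S = stimulus("rectangular", A = 10, t0 = 800, width = 400))
autoplot(tr)
```

## 5. Protocols

The protocol layer reproduces the standard responsiveness experiments:

- `peak_response_curve()`: response to split-Gaussian stimuli whose left
  width (the stimulus "slope") is scanned;
- `response_gain()` / `gain_vs_cortical_drive()`: linear gain of the
  stationary response to gated sensory pulses, as a function of the cortical
  operating point;
- `cortical_drive_scan()`: stationary fixed points against cortical drive and
  the turning point where reticular recruitment saturates;
- `noise_gain_scan()`: gain decay under increasing OU conductance noise,
  reported against the total membrane fluctuation;
- `conductance_response_scan()`: dynamic-clamp-style response versus quantal
  conductance, with sigmoid maximum-slope extraction;
- `isi_response_probability()`, `firing_adaptation_metric()`: single-cell
  responsiveness measures;
- `spindle_run()` and `bifurcation_scan()`: oscillation detection in the
  spindle state and the amplitude-onset scan over a connectivity scale.

```{r fig5}
g <- response_gain(cfg, P_const = 4, S_amplitudes = c(0, 5, 10))
g$gain
g$r_squared
```

## 6. Command-line interface

Every simulation layer is reachable from the installed script
`inst/cli/thalamr` (`Rscript <path> <command> ...`), exchanging plain
tab-separated text so runs can be scripted and diffed without R:

```
thalamr simulate-network --state awake --duration 1000 --p-drive 4 --out raster.tsv
thalamr stationary --state awake --p-drive 4 --out fp.tsv
thalamr sample-rates --cell TC --out rates.tsv
thalamr fit-tf --cell TC --rates rates.tsv --out coefficients.tsv
```
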