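#' Spiking-network configuration
#'
#' Describes the Erdos-Renyi TC-RE network and its external Poissonian
#' drives: a cortical pool P projecting to both populations and a sensory
#' pool S projecting to TC only. TC cells never excite other TC cells.
#' The cortical drive connects sparsely (5%, a diffuse modulator); the
#' sensory drive connects in full (p = 1: every sensory source reaches every
#' TC cell, a relay-driver pathway matching the strong sensory gain of the
#' circuit). Drive synapses use the target cell's
#' excitatory quantal increment, so the stronger cortico-reticular amplitude
#' is carried by the RE cells' larger Qe.
#'
#' @param state "awake", "sleep" or "spindle"
#' @param params_tc,params_re [cell_params()] (default: presets for `state`)
#' @param N_tc,N_re,N_P,N_S population/pool sizes
#' @param p list of connection probabilities with elements `tc_re`, `re_tc`,
#'   `re_re`, `p_tc`, `p_re`, `s_tc`
#' @param Q optional list of per-projection quantal increments (nS) with the
#'   same element names; defaults derived from the target cell parameters
#' @param seed integer seed used for the connectivity realisation
#' @return a `network_config` object
#' @export
network_config <- function(state = c("awake", "sleep", "spindle"),
                           params_tc = NULL, params_re = NULL,
                           N_tc = 500, N_re = 500, N_P = 8000, N_S = 500,
                           p = list(tc_re = 0.05, re_tc = 0.05, re_re = 0.3,
                                    p_tc = 0.05, p_re = 0.05, s_tc = 1),
                           Q = NULL, seed = 1L) {
  state <- match.arg(state)
  params_tc <- params_tc %||% thalamic_cell_params("TC", state)
  params_re <- params_re %||% thalamic_cell_params("RE", state)
  stopifnot(all(unlist(p) >= 0), all(unlist(p) <= 1),
            N_tc >= 1, N_re >= 1, N_P >= 1, N_S >= 1)
  Qdef <- list(tc_re = params_re$Qe, re_tc = params_tc$Qi,
               re_re = params_re$Qi, p_tc = params_tc$Qe,
               p_re = params_re$Qe, s_tc = params_tc$Qe)
  if (!is.null(Q)) Qdef <- modifyList(Qdef, Q)
  structure(list(state = state, params_tc = params_tc, params_re = params_re,
                 N_tc = N_tc, N_re = N_re, N_P = N_P, N_S = N_S,
                 p = p, Q = Qdef, seed = as.integer(seed)),
            class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat("<network_config>", x$state, ": TC", x$N_tc, "+ RE", x$N_re,
      ", drives P", x$N_P, "/ S", x$N_S, "\n")
  invisible(x)
}

# sample one Erdos-Renyi projection as a CSR adjacency (0-based targets);
# self-edges excluded when src and tgt index the same population
er_projection <- function(n_src, n_tgt, p, exclude_self = FALSE) {
  tgt <- vector("list", n_src)
  if (p > 0) {
    for (s in seq_len(n_src)) {
      hits <- which(runif(n_tgt) < p)
      if (exclude_self) hits <- hits[hits != s]
      tgt[[s]] <- hits - 1L
    }
  } else tgt <- rep(list(integer(0)), n_src)
  lens <- lengths(tgt)
  list(ptr = c(0L, cumsum(lens)), tgt = unlist(tgt) %||% integer(0),
       n_src = n_src, n_tgt = n_tgt, p = p)
}

#' Realise the random connectivity of a thalamic network
#'
#' Independent Bernoulli(p) draws per ordered source-target pair for each of
#' the six projections; reproducible from the config seed. RE->RE self-edges
#' are excluded.
#'
#' @param config a [network_config()]
#' @return a `connectivity` object holding per-projection adjacency lists
#'   and realised in-degree summaries
#' @export
build_connectivity <- function(config) {
  set.seed(config$seed)
  proj <- list(
    tc_re = er_projection(config$N_tc, config$N_re, config$p$tc_re),
    re_tc = er_projection(config$N_re, config$N_tc, config$p$re_tc),
    re_re = er_projection(config$N_re, config$N_re, config$p$re_re,
                          exclude_self = TRUE),
    p_tc = er_projection(config$N_P, config$N_tc, config$p$p_tc),
    p_re = er_projection(config$N_P, config$N_re, config$p$p_re),
    s_tc = er_projection(config$N_S, config$N_tc, config$p$s_tc))
  indeg <- purrr::imap(proj, function(pr, nm) {
    deg <- tabulate(pr$tgt + 1L, nbins = pr$n_tgt)
    tibble(projection = nm, mean_in_degree = mean(deg),
           sd_in_degree = sd(deg), edges = length(pr$tgt))
  })
  structure(list(proj = proj, in_degree = bind_rows(indeg),
                 config_seed = config$seed),
            class = "connectivity")
}

#' @export
print.connectivity <- function(x, ...) {
  cat("<connectivity>\n")
  print(as.data.frame(x$in_degree))
  invisible(x)
}

#' Simulate the spiking thalamic network
#'
#' Advances every AdEx cell with forward-Euler steps; drive pools emit
#' inhomogeneous Poisson spikes at the scheduled rates; spikes are delivered
#' to their targets without axonal delay. Initial membrane potentials are
#' drawn uniformly in `EL +- 5 mV` to de-synchronise the startup transient.
#'
#' @param conn a [build_connectivity()] result
#' @param config the matching [network_config()]
#' @param duration run length (ms)
#' @param P_drive,S_drive drive rates: number (Hz), [stimulus()] or
#'   per-step vector
#' @param dt integration step (ms)
#' @param seed integer seed for the dynamical noise (drive spikes, initial
#'   conditions, OU currents)
#' @param record_v integer vector of cell indices (1..N_tc+N_re) whose
#'   membrane potential is recorded
#' @param record_stride sampling stride for recorded voltages
#' @param common optional common Poisson source: list with `rate` (Hz,
#'   scalar or [stimulus()]), `q_tc`, `q_re` (nS)
#' @param ou optional [ou_noise()] (target "current") applied independently
#'   to every cell
#' @return a `raster_record`: tibble of spikes (`id`, `t`, `population`)
#'   plus metadata and optional voltage traces
#' @export
simulate_network <- function(conn, config, duration, P_drive = 0, S_drive = 0,
                             dt = 0.1, seed = 1L, record_v = integer(0),
                             record_stride = 5L, common = NULL, ou = NULL) {
  stopifnot(inherits(conn, "connectivity"), duration > 0)
  set.seed(seed)
  n <- ceiling(duration / dt)
  Pv <- stimulus_schedule(P_drive, n, dt)
  Sv <- stimulus_schedule(S_drive, n, dt)
  N <- config$N_tc + config$N_re
  v0 <- c(runif(config$N_tc, config$params_tc$EL - 5, config$params_tc$EL + 5),
          runif(config$N_re, config$params_re$EL - 5, config$params_re$EL + 5))
  comv <- numeric(0); cq_tc <- 0; cq_re <- 0
  if (!is.null(common)) {
    comv <- stimulus_schedule(common$rate, n, dt)
    cq_tc <- common$q_tc %||% config$params_tc$Qe
    cq_re <- common$q_re %||% config$params_re$Qe
  }
  ou_mean <- c(0, 0); ou_sigma <- c(0, 0); ou_tau <- c(10, 10)
  if (!is.null(ou)) {
    stopifnot(inherits(ou, "ou_noise_spec"), ou$target == "current")
    ou_mean <- rep(ou$mean, 2); ou_sigma <- rep(ou$sd, 2)
    ou_tau <- rep(ou$tau_corr, 2)
  }
  pr <- conn$proj
  res <- adex_network_sim_cpp(
    par_vec(config$params_tc), par_vec(config$params_re),
    config$N_tc, config$N_re,
    pr$tc_re$ptr, pr$tc_re$tgt, pr$re_tc$ptr, pr$re_tc$tgt,
    pr$re_re$ptr, pr$re_re$tgt, pr$p_tc$ptr, pr$p_tc$tgt,
    pr$p_re$ptr, pr$p_re$tgt, pr$s_tc$ptr, pr$s_tc$tgt,
    config$N_P, config$N_S, Pv, Sv,
    c(config$Q$tc_re, config$Q$re_tc, config$Q$re_re,
      config$Q$p_tc, config$Q$p_re, config$Q$s_tc),
    comv, cq_tc, cq_re, ou_mean, ou_sigma, ou_tau,
    dt, v0, as.integer(record_v - 1L), as.integer(record_stride))
  spikes <- tibble(id = res$spike_id, t = res$spike_t,
                   population = ifelse(res$spike_id <= config$N_tc, "TC", "RE"))
  out <- list(spikes = spikes, duration = n * dt, dt = dt,
              N_tc = config$N_tc, N_re = config$N_re, seed = seed,
              state = config$state)
  if (length(record_v) > 0) {
    out$v_rec <- res$v_rec
    out$record_v <- record_v
    out$record_dt <- dt * record_stride
    out$t_refrac <- c(TC = config$params_tc$t_refrac,
                      RE = config$params_re$t_refrac)
  }
  structure(out, class = "raster_record")
}

#' @export
print.raster_record <- function(x, ...) {
  cat("<raster_record>", x$duration, "ms,", nrow(x$spikes), "spikes",
      sprintf("(TC %.2f Hz, RE %.2f Hz)\n",
              sum(x$spikes$population == "TC") / x$N_tc / (x$duration * 1e-3),
              sum(x$spikes$population == "RE") / x$N_re / (x$duration * 1e-3)))
  invisible(x)
}

#' Population firing rate of a raster
#'
#' Bins spike counts of one population into windows of `T_bin` ms:
#' `rate(t) = count / (N_pop * T_bin)`, in Hz. The sum of `rate * N * T_bin`
#' over bins recovers the total spike count exactly.
#'
#' @param raster a `raster_record`
#' @param population "TC" or "RE"
#' @param T_bin bin width (ms), at least the integration step
#' @return tibble `t` (bin centre, ms) and `rate` (Hz)
#' @export
bin_population_rate <- function(raster, population = "TC", T_bin = 5) {
  stopifnot(T_bin >= raster$dt)
  n_pop <- if (population == "TC") raster$N_tc else raster$N_re
  edges <- seq(0, raster$duration + T_bin - 1e-9, by = T_bin)
  s <- raster$spikes$t[raster$spikes$population == population]
  counts <- tabulate(findInterval(s, edges, left.open = TRUE),
                     nbins = length(edges) - 1)
  tibble(t = edges[-length(edges)] + T_bin / 2,
         rate = counts / (n_pop * T_bin * 1e-3))
}

#' Subthreshold membrane-potential statistics of recorded cells
#'
#' Pools the recorded membrane samples of a network run, removing every
#' sample falling within the refractory period after a spike of the same
#' neuron (the clamped reset segments), and summarises the remaining
#' subthreshold distribution.
#'
#' @param raster a `raster_record` from [simulate_network()] with recorded
#'   voltages
#' @param t_min discard samples before this time (ms)
#' @param breaks histogram breaks (mV), passed to [hist()]
#' @return list with `mean`, `sd`, `n_samples`, `histogram` (tibble `v`,
#'   `density`) and `samples_removed`
#' @export
membrane_statistics <- function(raster, t_min = 0, breaks = 60) {
  if (is.null(raster$v_rec)) abort("no recorded voltages in this run")
  tgrid <- seq(0, by = raster$record_dt, length.out = nrow(raster$v_rec))
  keep_all <- c()
  vals <- c()
  for (j in seq_along(raster$record_v)) {
    id <- raster$record_v[j]
    refrac <- unname(raster$t_refrac[if (id <= raster$N_tc) "TC" else "RE"])
    sp <- raster$spikes$t[raster$spikes$id == id]
    keep <- tgrid >= t_min
    for (ts in sp) keep <- keep & !(tgrid >= ts & tgrid < ts + refrac)
    vals <- c(vals, raster$v_rec[keep, j])
    keep_all <- c(keep_all, sum(!keep & tgrid >= t_min))
  }
  if (length(vals) == 0) {
    warn("all recorded samples fell in spike/refractory segments")
    return(list(mean = NA_real_, sd = NA_real_, n_samples = 0,
                histogram = tibble(v = numeric(0), density = numeric(0)),
                samples_removed = sum(keep_all)))
  }
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  list(mean = mean(vals), sd = sd(vals), n_samples = length(vals),
       histogram = tibble(v = h$mids, density = h$density),
       samples_removed = sum(keep_all))
}
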