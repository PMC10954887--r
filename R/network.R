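#' Izhikevich neuron parameters
#'
#' Parameter quadruples (a, b, c, d) for the two cell types used throughout:
#' regular-spiking pyramidal cells (0.02, 0.2, -65, 8) and fast-spiking
#' interneurons (0.1, 0.2, -65, 2). `a` sets the recovery time scale, `b` the
#' sensitivity of the recovery variable to subthreshold voltage, `c` the reset
#' potential (mV) and `d` the after-spike recovery increment.
#'
#' @param type `"pyramidal"` or `"fast_spiking"`.
#' @return list with elements `a`, `b`, `c`, `d`.
#' @export
izhikevich_params <- function(type = c("pyramidal", "fast_spiking")) {
  type <- match.arg(type)
  p <- switch(type,
    pyramidal    = list(a = 0.02, b = 0.2, c = -65, d = 8),
    fast_spiking = list(a = 0.1,  b = 0.2, c = -65, d = 2)
  )
  validate_neuron_params(p)
  p
}

validate_neuron_params <- function(p) {
  stopifnot(is.list(p), all(c("a", "b", "c", "d") %in% names(p)))
  vals <- unlist(p[c("a", "b", "c", "d")])
  if (!all(is.finite(vals))) stop("neuron parameters must all be finite")
  if (p$c >= 30) stop("reset potential c must lie below the 30 mV spike threshold")
  invisible(p)
}

#' Construct a network configuration
#'
#' Declarative description of one two-population pulse-coupled network:
#' `n_pyramidal` excitatory Izhikevich cells driving `n_fast_spiking`
#' inhibitory fast-spiking cells. Connections are drawn independently per
#' ordered pair with the given probabilities (self-connections excluded);
#' pyramidal-to-interneuron (`p_ei`) and interneuron-to-interneuron (`p_ii`)
#' coupling are the core architecture, with `p_ee` and `p_ie` available but
#' zero by default. Each presynaptic spike delivers an instantaneous pulse of
#' weight `w_excitatory` or `w_inhibitory` to its targets on the next
#' integration step.
#'
#' All randomness is controlled by two recorded seeds: `seed_topology` (which
#' edges are realized) and `seed_init` (initial-condition jitter). Initial
#' conditions are `v0 = c + U(0, v_init_jitter)` mV per neuron and
#' `u0 = b * v0`.
#'
#' @param n_pyramidal,n_fast_spiking population sizes.
#' @param p_ei,p_ii,p_ee,p_ie connection probabilities in `[0, 1]`.
#' @param w_excitatory,w_inhibitory pulse weights (mV per spike in
#'   `voltage_kick` mode); excitatory must be positive, inhibitory negative.
#' @param i_ext_pyramidal constant external drive to every pyramidal neuron
#'   (model units). The interneurons receive no external drive.
#' @param dt integration step, ms.
#' @param duration simulated time, ms.
#' @param seed_topology,seed_init integer seeds.
#' @param coupling_mode `"voltage_kick"` (default; per-spike increment of v) or
#'   `"current_pulse"` (one-step current of summed weight / dt) -- numerically
#'   equivalent under forward Euler.
#' @param v_init_jitter amplitude (mV) of the uniform initial-voltage jitter;
#'   0 gives fully symmetric initial conditions.
#' @param burn_in initial transient (ms) excluded from all downstream
#'   frequency and phase metrics.
#' @param params_pyramidal,params_fast_spiking Izhikevich parameter lists;
#'   defaults are the standard quadruples for each type.
#' @return object of class `network_config`.
#' @export
network_config <- function(n_pyramidal = 100, n_fast_spiking = 50,
                           p_ei = 0.7, p_ii = 0.4, p_ee = 0, p_ie = 0,
                           w_excitatory = 0.3, w_inhibitory = -0.3,
                           i_ext_pyramidal = 5,
                           dt = 0.1, duration = 10000,
                           seed_topology = 1L, seed_init = 1L,
                           coupling_mode = c("voltage_kick", "current_pulse"),
                           v_init_jitter = 1, burn_in = 500,
                           params_pyramidal = izhikevich_params("pyramidal"),
                           params_fast_spiking = izhikevich_params("fast_spiking")) {
  coupling_mode <- match.arg(coupling_mode)
  cfg <- list(
    n_pyramidal = as.integer(n_pyramidal),
    n_fast_spiking = as.integer(n_fast_spiking),
    p_ei = p_ei, p_ii = p_ii, p_ee = p_ee, p_ie = p_ie,
    w_excitatory = w_excitatory, w_inhibitory = w_inhibitory,
    i_ext_pyramidal = i_ext_pyramidal,
    dt = dt, duration = duration,
    seed_topology = as.integer(seed_topology),
    seed_init = as.integer(seed_init),
    coupling_mode = coupling_mode,
    v_init_jitter = v_init_jitter, burn_in = burn_in,
    params_pyramidal = params_pyramidal,
    params_fast_spiking = params_fast_spiking
  )
  class(cfg) <- "network_config"
  validate_network_config(cfg)
}

validate_network_config <- function(cfg) {
  for (f in c("p_ei", "p_ii", "p_ee", "p_ie")) {
    p <- cfg[[f]]
    if (!is.numeric(p) || length(p) != 1 || is.na(p) || p < 0 || p > 1) {
      stop(sprintf("configuration error: %s = %s is not a probability in [0, 1]",
                   f, format(cfg[[f]])), call. = FALSE)
    }
  }
  if (cfg$n_pyramidal < 1 || cfg$n_fast_spiking < 1) {
    stop("configuration error: population sizes must be >= 1", call. = FALSE)
  }
  if (cfg$w_excitatory <= 0) stop("configuration error: w_excitatory must be > 0", call. = FALSE)
  if (cfg$w_inhibitory >= 0) stop("configuration error: w_inhibitory must be < 0", call. = FALSE)
  if (cfg$dt <= 0) stop("configuration error: dt must be > 0", call. = FALSE)
  if (cfg$duration < cfg$dt) stop("configuration error: duration must be >= dt", call. = FALSE)
  if (cfg$v_init_jitter < 0) stop("configuration error: v_init_jitter must be >= 0", call. = FALSE)
  validate_neuron_params(cfg$params_pyramidal)
  validate_neuron_params(cfg$params_fast_spiking)
  invisible(cfg)
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> %d pyramidal + %d fast-spiking\n",
              x$n_pyramidal, x$n_fast_spiking))
  cat(sprintf("  p_EI=%.2f p_II=%.2f p_EE=%.2f p_IE=%.2f  w=%+.2f/%+.2f (%s)\n",
              x$p_ei, x$p_ii, x$p_ee, x$p_ie,
              x$w_excitatory, x$w_inhibitory, x$coupling_mode))
  cat(sprintf("  I_ext(pyr)=%.3f  dt=%.3f ms  duration=%.0f ms  seeds: topo=%d init=%d\n",
              x$i_ext_pyramidal, x$dt, x$duration, x$seed_topology, x$seed_init))
  invisible(x)
}

# Global neuron indexing: pyramidal 0..(nE-1), fast-spiking nE..(nE+nI-1),
# 0-based to match the C++ core and CSV output.
neuron_index <- function(cfg) {
  list(pyr = seq_len(cfg$n_pyramidal) - 1L,
       fs  = cfg$n_pyramidal + seq_len(cfg$n_fast_spiking) - 1L)
}

sample_edges <- function(src, tgt, p, exclude_self = FALSE) {
  if (p <= 0) return(matrix(integer(0), ncol = 2))
  pairs <- cbind(rep(src, each = length(tgt)), rep(tgt, times = length(src)))
  if (exclude_self) pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (p >= 1) return(pairs)
  keep <- runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}

#' Realize the random connectivity of a network
#'
#' Draws every ordered (source, target) pair independently with the
#' configured probability, using `seed_topology` so the edge set is exactly
#' reproducible. Self-connections are excluded within a population. Edges are
#' drawn in a fixed projection order (E-E, E-I, I-E, I-I).
#'
#' @param config a [network_config()].
#' @return object of class `network_adjacency`: list with `edges`
#'   (data.frame `source`, `target`, `weight`, `projection`; 0-based ids),
#'   per-projection `counts`, and the CSR representation used by the
#'   integrator.
#' @export
build_network <- function(config) {
  validate_network_config(config)
  idx <- neuron_index(config)
  set.seed(config$seed_topology)
  projs <- list(
    ee = list(sample_edges(idx$pyr, idx$pyr, config$p_ee, TRUE), config$w_excitatory),
    ei = list(sample_edges(idx$pyr, idx$fs,  config$p_ei),       config$w_excitatory),
    ie = list(sample_edges(idx$fs,  idx$pyr, config$p_ie),       config$w_inhibitory),
    ii = list(sample_edges(idx$fs,  idx$fs,  config$p_ii, TRUE), config$w_inhibitory)
  )
  edges <- do.call(rbind, lapply(names(projs), function(nm) {
    m <- projs[[nm]][[1]]
    if (nrow(m) == 0) return(NULL)
    data.frame(source = m[, 1], target = m[, 2],
               weight = projs[[nm]][[2]], projection = nm)
  }))
  if (is.null(edges)) {
    edges <- data.frame(source = integer(0), target = integer(0),
                        weight = numeric(0), projection = character(0))
  }
  n <- config$n_pyramidal + config$n_fast_spiking
  ord <- order(edges$source, edges$target)
  edges_sorted <- edges[ord, , drop = FALSE]
  counts_per_src <- tabulate(edges_sorted$source + 1L, nbins = n)
  csr <- list(ptr = c(0L, cumsum(counts_per_src)),
              tgt = as.integer(edges_sorted$target),
              w = as.numeric(edges_sorted$weight))
  structure(list(edges = edges, csr = csr, n_neurons = n,
                 counts = vapply(projs, function(x) nrow(x[[1]]), integer(1)),
                 config = config),
            class = "network_adjacency")
}

#' @export
print.network_adjacency <- function(x, ...) {
  cat(sprintf("<network_adjacency> %d neurons, %d edges (ee=%d ei=%d ie=%d ii=%d)\n",
              x$n_neurons, nrow(x$edges),
              x$counts[["ee"]], x$counts[["ei"]], x$counts[["ie"]], x$counts[["ii"]]))
  invisible(x)
}

initial_state <- function(cfg) {
  set.seed(cfg$seed_init)
  n <- cfg$n_pyramidal + cfg$n_fast_spiking
  cvec <- c(rep(cfg$params_pyramidal$c, cfg$n_pyramidal),
            rep(cfg$params_fast_spiking$c, cfg$n_fast_spiking))
  bvec <- c(rep(cfg$params_pyramidal$b, cfg$n_pyramidal),
            rep(cfg$params_fast_spiking$b, cfg$n_fast_spiking))
  v0 <- cvec + runif(n, 0, cfg$v_init_jitter)
  list(v0 = v0, u0 = bvec * v0)
}

#' Simulate a configured network
#'
#' Integrates the network with forward Euler at step `dt` for `duration` ms.
#' Deterministic given (`seed_topology`, `seed_init`): repeated runs are
#' bit-identical. Optionally delivers a one-off perturbation: at time
#' `perturbation$t_p` (ms) each interneuron in `perturbation$targets`
#' (0-based interneuron indices, i.e. 0..n_fast_spiking-1) receives a single
#' extra excitatory pulse of `perturbation$weight`, exactly as if one external
#' pyramidal spike arrived.
#'
#' @param config a [network_config()].
#' @param adjacency optional pre-built [build_network()] result (rebuilt from
#'   the config when omitted).
#' @param perturbation `NULL` or list with `t_p`, `targets`, `weight`.
#' @param record_decimation keep every k-th voltage sample (default 1: every
#'   step).
#' @return object of class `sim_result`: `raster` (data.frame `neuron_id`,
#'   `population`, `time_ms`), `traces` (class `voltage_traces`: `time_ms`,
#'   matrix `v` samples x interneurons), the config, adjacency counts and a
#'   config hash.
#' @export
simulate_network <- function(config, adjacency = NULL, perturbation = NULL,
                             record_decimation = 1L) {
  validate_network_config(config)
  if (is.null(adjacency)) adjacency <- build_network(config)
  idx <- neuron_index(config)
  st <- initial_state(config)
  n_steps <- as.integer(round(config$duration / config$dt))
  pstep <- 0L
  ptargets <- integer(0)
  pweight <- 0
  if (!is.null(perturbation)) {
    stopifnot(is.numeric(perturbation$t_p), perturbation$weight >= 0)
    if (perturbation$t_p <= 0 || perturbation$t_p > config$duration) {
      stop("perturbation time t_p must lie within the simulation")
    }
    pstep <- as.integer(round(perturbation$t_p / config$dt))
    ptargets <- as.integer(config$n_pyramidal + perturbation$targets)
    if (any(perturbation$targets < 0 | perturbation$targets >= config$n_fast_spiking)) {
      stop("perturbation targets must be interneuron indices in [0, n_fast_spiking)")
    }
    pweight <- perturbation$weight
  }
  avec <- c(rep(config$params_pyramidal$a, config$n_pyramidal),
            rep(config$params_fast_spiking$a, config$n_fast_spiking))
  bvec <- c(rep(config$params_pyramidal$b, config$n_pyramidal),
            rep(config$params_fast_spiking$b, config$n_fast_spiking))
  cvec <- c(rep(config$params_pyramidal$c, config$n_pyramidal),
            rep(config$params_fast_spiking$c, config$n_fast_spiking))
  dvec <- c(rep(config$params_pyramidal$d, config$n_pyramidal),
            rep(config$params_fast_spiking$d, config$n_fast_spiking))
  ivec <- c(rep(config$i_ext_pyramidal, config$n_pyramidal),
            rep(0, config$n_fast_spiking))
  out <- simulate_izhikevich_cpp(
    st$v0, st$u0, avec, bvec, cvec, dvec, ivec,
    adjacency$csr$ptr, adjacency$csr$tgt, adjacency$csr$w,
    config$dt, n_steps, idx$fs, as.integer(record_decimation),
    config$coupling_mode == "current_pulse",
    pstep, ptargets, pweight)
  pop <- ifelse(out$spike_id < config$n_pyramidal, "pyramidal", "fast_spiking")
  raster <- data.frame(neuron_id = out$spike_id, population = pop,
                       time_ms = out$spike_time)
  traces <- structure(list(time_ms = out$time_ms, v = out$v,
                           neuron_ids = idx$fs,
                           dt = config$dt * record_decimation,
                           sampling_rate_hz = 1000 / (config$dt * record_decimation)),
                      class = "voltage_traces")
  hash <- config_hash(unclass(config))
  log_run(event = "simulate", hash = hash,
          seed_topology = config$seed_topology, seed_init = config$seed_init,
          edges = sum(adjacency$counts), n_spikes = nrow(raster))
  structure(list(raster = raster, traces = traces, config = config,
                 edge_counts = adjacency$counts, config_hash = hash,
                 perturbation = perturbation),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("<sim_result> %.0f ms, %d spikes (%d pyramidal, %d fast-spiking)\n",
              x$config$duration, nrow(x$raster),
              sum(x$raster$population == "pyramidal"),
              sum(x$raster$population == "fast_spiking")))
  invisible(x)
}

#' Population firing frequency from a spike raster
#'
#' Pooled inverse mean interspike interval: collects the ISIs of every neuron
#' in the population (after discarding spikes before `burn_in`) and returns
#' `1000 / mean(ISI in ms)` in Hz.
#'
#' @param raster data.frame with `neuron_id`, `population`, `time_ms` (as in
#'   [simulate_network()]).
#' @param population `"pyramidal"` or `"fast_spiking"`.
#' @param burn_in transient (ms) to discard.
#' @return frequency in Hz.
#' @export
population_frequency <- function(raster, population = "pyramidal", burn_in = 500) {
  r <- raster[raster$population == population & raster$time_ms >= burn_in, ,
              drop = FALSE]
  if (nrow(r) == 0) stop("undefined frequency: no spikes in population after burn-in")
  isis <- unlist(lapply(split(r$time_ms, r$neuron_id), function(t) diff(sort(t))),
                 use.names = FALSE)
  if (length(isis) == 0) stop("undefined frequency: fewer than 2 spikes on every neuron")
  1000 / mean(isis)
}

#' Interneuron population burst rate
#'
#' Mean per-interneuron rate of burst events, where a burst groups all spikes
#' a neuron fires within the same drive cycle (spikes separated by less than
#' half the pyramidal period). When interneurons respond on every drive cycle
#' the burst rate equals the driving frequency; in subharmonic regimes it
#' falls to f/2, f/3, ... -- the rhythm whose phase defines the cluster
#' states. Silent interneurons contribute zero.
#'
#' @param raster raster data.frame from [simulate_network()].
#' @param driving_frequency_hz realized pyramidal frequency (Hz).
#' @param n_interneurons interneuron population size.
#' @param burn_in transient (ms) to discard.
#' @return mean burst rate (Hz).
#' @export
population_burst_rate <- function(raster, driving_frequency_hz, n_interneurons,
                                  burn_in = 500) {
  fs <- raster[raster$population == "fast_spiking" & raster$time_ms >= burn_in, ,
               drop = FALSE]
  if (nrow(fs) == 0) return(0)
  t_cycle <- 1000 / driving_frequency_hz
  dur_s <- (max(raster$time_ms) - burn_in) / 1000
  n_bursts <- vapply(split(fs$time_ms, fs$neuron_id), function(tt) {
    1 + sum(diff(sort(tt)) > 0.5 * t_cycle)
  }, numeric(1))
  sum(n_bursts) / dur_s / n_interneurons
}

#' Frequency-current (f-I) curve of an isolated neuron
#'
#' Simulates a single unconnected Izhikevich neuron at each input current and
#' returns its steady-state firing frequency (transient discarded; fewer than
#' two post-transient spikes gives 0 Hz).
#'
#' @param params Izhikevich parameter list (see [izhikevich_params()]).
#' @param i_values numeric vector of input currents.
#' @param duration,dt,burn_in simulation settings (ms).
#' @return data.frame with `i_ext` and `frequency_hz`.
#' @export
fi_curve <- function(params, i_values, duration = 2000, dt = 0.1, burn_in = 500) {
  validate_neuron_params(params)
  n_steps <- as.integer(round(duration / dt))
  freq <- vapply(i_values, function(I) {
    out <- simulate_izhikevich_cpp(
      params$c, params$b * params$c, params$a, params$b, params$c, params$d,
      I, c(0L, 0L), integer(0), numeric(0),
      dt, n_steps, 0L, n_steps, FALSE, 0L, integer(0), 0)
    st <- out$spike_time[out$spike_time >= burn_in]
    if (length(st) < 2) return(0)
    1000 / mean(diff(st))
  }, numeric(1))
  data.frame(i_ext = i_values, frequency_hz = freq)
}

#' Map target pyramidal frequencies to external currents
#'
#' Inverts the pyramidal f-I curve by monotone interpolation so that sweeps
#' can be indexed by realized frequency rather than by current. Because the
#' pyramidal population receives no recurrent input in the core architecture,
#' the isolated-neuron curve predicts the population frequency directly.
#'
#' @param f_targets desired pyramidal frequencies (Hz).
#' @param params pyramidal parameter list.
#' @param i_range current range to probe.
#' @param n_probe number of probe currents.
#' @param ... passed to [fi_curve()].
#' @return data.frame `f_target_hz`, `i_ext` (NA where unreachable).
#' @export
calibrate_drive <- function(f_targets, params = izhikevich_params("pyramidal"),
                            i_range = c(0, 100), n_probe = 80, ...) {
  probe <- fi_curve(params, seq(i_range[1], i_range[2], length.out = n_probe), ...)
  probe <- probe[probe$frequency_hz > 0, , drop = FALSE]
  probe <- probe[!duplicated(probe$frequency_hz), , drop = FALSE]
  if (nrow(probe) < 2) stop("f-I probe produced too few firing points")
  i_ext <- stats::approx(probe$frequency_hz, probe$i_ext, xout = f_targets,
                         ties = "ordered")$y
  data.frame(f_target_hz = f_targets, i_ext = i_ext)
}
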