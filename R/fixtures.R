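#' Generate synthetic test data with planted structure
#'
#' Deterministic (seeded) generators used by the test tiers that exercise the
#' metric stack without running the simulator:
#'
#' * `planted_cluster_phases`: a `phase_series` whose channels sit in
#'   `n_clusters` equally spaced phase clusters (angular SD `sd`) around a
#'   common drifting mean (frequency `drift_hz`).
#' * `burst_envelope_traces`: `voltage_traces` of gated fast oscillations --
#'   a carrier at `spike_hz` switched on/off by a square envelope at
#'   `envelope_hz` (per-channel envelope offsets in radians via `offsets`),
#'   emulating intra-burst spikes riding on a burst rhythm.
#' * `random_partitions`: a list of label vectors, each item assigned
#'   uniformly to one of `n_clusters`.
#' * `itinerant_switching_phases`: two phase clusters with one designated
#'   channel hopping from cluster 1 to cluster 2 at `t_switch_ms`.
#'
#' @param kind one of the four kinds above.
#' @param seed RNG seed; identical seeds give identical fixtures.
#' @param n_clusters,n_channels,sd,drift_hz,duration_ms,fs_hz planted-phase
#'   settings.
#' @param envelope_hz,spike_hz,offsets,noise_sd burst-trace settings.
#' @param n_items,n_partitions random-partition settings.
#' @param t_switch_ms,switch_channel itinerant-switch settings.
#' @return fixture object; class depends on `kind`.
#' @export
make_fixture <- function(kind = c("planted_cluster_phases", "burst_envelope_traces",
                                  "random_partitions", "itinerant_switching_phases"),
                         seed = 1L,
                         n_clusters = 2, n_channels = 50, sd = 0.1,
                         drift_hz = 1, duration_ms = 2000, fs_hz = 1000,
                         envelope_hz = 50, spike_hz = 400, offsets = NULL,
                         noise_sd = 0.05,
                         n_items = 50, n_partitions = 2,
                         t_switch_ms = 1000, switch_channel = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  t_ms <- seq(0, duration_ms - 1000 / fs_hz, by = 1000 / fs_hz)
  switch(kind,
    planted_cluster_phases = {
      centers <- 2 * pi * (seq_len(n_clusters) - 1) / n_clusters
      member <- rep_len(seq_len(n_clusters), n_channels)
      jitter <- rnorm(n_channels, 0, sd)
      drift <- 2 * pi * drift_hz * t_ms / 1000
      phi <- wrap_phase(outer(drift, centers[member] + jitter, "+"))
      structure(list(time_ms = t_ms, phi = phi,
                     neuron_ids = seq_len(n_channels) - 1L, edge_ms = 0,
                     planted = list(members = member, centers = centers, sd = sd)),
                class = "phase_series")
    },
    burst_envelope_traces = {
      if (is.null(offsets)) offsets <- rep(0, n_channels)
      stopifnot(length(offsets) == n_channels)
      ts <- t_ms / 1000
      v <- vapply(seq_len(n_channels), function(j) {
        env <- as.numeric(sin(2 * pi * envelope_hz * ts + offsets[j]) > 0)
        env * sin(2 * pi * spike_hz * ts) + noise_sd * rnorm(length(ts))
      }, numeric(length(ts)))
      structure(list(time_ms = t_ms, v = v,
                     neuron_ids = seq_len(n_channels) - 1L,
                     dt = 1000 / fs_hz, sampling_rate_hz = fs_hz,
                     planted = list(envelope_hz = envelope_hz,
                                    offsets = offsets)),
                class = "voltage_traces")
    },
    random_partitions = {
      lapply(seq_len(n_partitions), function(i) {
        sample.int(n_clusters, n_items, replace = TRUE)
      })
    },
    itinerant_switching_phases = {
      centers <- c(0, pi)
      member <- rep_len(1:2, n_channels)
      phi <- matrix(0, length(t_ms), n_channels)
      for (j in seq_len(n_channels)) {
        phi[, j] <- centers[member[j]] + rnorm(length(t_ms), 0, sd)
      }
      hop <- t_ms >= t_switch_ms
      phi[hop, switch_channel] <- centers[2] + rnorm(sum(hop), 0, sd)
      structure(list(time_ms = t_ms, phi = wrap_phase(phi),
                     neuron_ids = seq_len(n_channels) - 1L, edge_ms = 0,
                     planted = list(members = member, t_switch_ms = t_switch_ms,
                                    switch_channel = switch_channel)),
                class = "phase_series")
    })
}
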