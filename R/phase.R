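#' Filter specification for burst extraction
#'
#' A fifth-order low-pass Butterworth filter that removes the fast individual
#' spikes from interneuron voltage traces while preserving the slower burst
#' oscillation. With `zero_phase = TRUE` (default) the filter is applied
#' forward and backward, which squares the magnitude response and leaves the
#' phase of every frequency component untouched -- important because all
#' downstream metrics are phase relationships between neurons.
#'
#' @param cutoff_hz -3 dB cutoff (single pass), Hz.
#' @param sampling_rate_hz sampling rate of the traces, Hz.
#' @param order filter order (default 5).
#' @param zero_phase forward-backward application.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(cutoff_hz, sampling_rate_hz, order = 5, zero_phase = TRUE) {
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= sampling_rate_hz / 2) {
    stop(sprintf("configuration error: cutoff_hz = %s must lie in (0, Nyquist = %s)",
                 format(cutoff_hz), format(sampling_rate_hz / 2)), call. = FALSE)
  }
  structure(list(cutoff_hz = cutoff_hz, sampling_rate_hz = sampling_rate_hz,
                 order = order, zero_phase = isTRUE(zero_phase),
                 type = "lowpass_butterworth"),
            class = "filter_spec")
}

#' Low-pass filter voltage traces to isolate burst oscillations
#'
#' @param traces a `voltage_traces` object (see [simulate_network()]) or a
#'   numeric matrix (samples x channels) with attribute-free columns, in which
#'   case `spec$sampling_rate_hz` is trusted.
#' @param spec a [filter_spec()].
#' @return traces of the same shape, filtered per channel.
#' @export
lowpass_burst_filter <- function(traces, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  v <- if (inherits(traces, "voltage_traces")) traces$v else as.matrix(traces)
  if (inherits(traces, "voltage_traces") &&
      abs(traces$sampling_rate_hz - spec$sampling_rate_hz) > 1e-9) {
    stop("filter_spec sampling rate does not match the traces")
  }
  bf <- signal::butter(spec$order, spec$cutoff_hz / (spec$sampling_rate_hz / 2),
                       type = "low")
  apply_fn <- if (spec$zero_phase) {
    function(x) signal::filtfilt(bf, x)
  } else {
    function(x) as.numeric(signal::filter(bf, x))
  }
  out <- vapply(seq_len(ncol(v)), function(j) apply_fn(v[, j]),
                numeric(nrow(v)))
  if (inherits(traces, "voltage_traces")) {
    traces$v <- out
    traces$filter <- spec
    traces
  } else {
    out
  }
}

#' Standardize traces to zero mean and unit standard deviation
#'
#' Uses the population (1/N) standard deviation per channel. A constant
#' channel cannot be standardized and raises an error naming the neuron.
#'
#' @param traces `voltage_traces` or numeric matrix (samples x channels).
#' @return same shape, each channel with mean 0 and population SD 1.
#' @export
standardize_traces <- function(traces) {
  v <- if (inherits(traces, "voltage_traces")) traces$v else as.matrix(traces)
  mu <- colMeans(v)
  centered <- sweep(v, 2, mu)
  s <- sqrt(colMeans(centered^2))
  if (any(s == 0)) {
    ids <- if (inherits(traces, "voltage_traces")) traces$neuron_ids else seq_len(ncol(v)) - 1L
    stop(sprintf("degenerate channel: neuron(s) %s constant, cannot standardize",
                 paste(ids[s == 0], collapse = ", ")), call. = FALSE)
  }
  out <- sweep(centered, 2, s, "/")
  if (inherits(traces, "voltage_traces")) {
    traces$v <- out
    traces
  } else {
    out
  }
}

# Analytic signal via FFT: zero the negative-frequency half, double the
# positive half, keep DC (and Nyquist for even n) untouched. The input is
# zero-padded to a 2-3-5-smooth length (awkward prime factors make R's FFT
# quadratic); padding artifacts sit at the series end, inside the trimmed
# edge window.
analytic_signal <- function(x) {
  n0 <- length(x)
  n <- stats::nextn(n0, c(2, 3, 5))
  if (n > n0) x <- c(x, numeric(n - n0))
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  (fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

#' Instantaneous phase via the Hilbert transform
#'
#' Computes the analytic signal of each (filtered, standardized) channel and
#' returns its argument, wrapped to `(-pi, pi]`. The first and last
#' `edge_ms` of the series are flagged as edge-affected (Hilbert endpoint
#' artifacts) and excluded by [phase_window()].
#'
#' @param traces `voltage_traces` (filtered + standardized) or matrix.
#' @param time_ms time axis, required when `traces` is a bare matrix.
#' @param edge_ms width of the edge-artifact flag window at each end.
#' @return object of class `phase_series`: `time_ms`, `phi` (samples x
#'   channels, radians), `neuron_ids`, `edge_ms`, and filter provenance if
#'   available.
#' @export
hilbert_phase <- function(traces, time_ms = NULL, edge_ms = 100) {
  v <- if (inherits(traces, "voltage_traces")) traces$v else as.matrix(traces)
  if (inherits(traces, "voltage_traces")) time_ms <- traces$time_ms
  if (is.null(time_ms)) stop("time_ms required for matrix input")
  if (nrow(v) == 0) stop("zero-length trace")
  if (any(colSums(abs(v)) == 0)) stop("all-zero channel: phase undefined")
  phi <- vapply(seq_len(ncol(v)), function(j) {
    z <- analytic_signal(v[, j])
    wrap_phase(atan2(Im(z), Re(z)))
  }, numeric(nrow(v)))
  structure(list(time_ms = time_ms, phi = phi,
                 neuron_ids = if (inherits(traces, "voltage_traces")) traces$neuron_ids
                              else seq_len(ncol(v)) - 1L,
                 edge_ms = edge_ms,
                 filter = if (inherits(traces, "voltage_traces")) traces$filter else NULL),
            class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series> %d channels x %d samples, t = [%.1f, %.1f] ms (edge flag %g ms)\n",
              ncol(x$phi), nrow(x$phi), min(x$time_ms), max(x$time_ms), x$edge_ms))
  invisible(x)
}

#' Retained analysis window of a phase series
#'
#' Drops the edge-affected `edge_ms` at both ends (and optionally decimates)
#' and returns the matrix of phases with its time axis.
#'
#' @param phases a `phase_series`.
#' @param decimation keep every k-th retained sample.
#' @return list `time_ms`, `phi`.
#' @export
phase_window <- function(phases, decimation = 1L) {
  stopifnot(inherits(phases, "phase_series"))
  t <- phases$time_ms
  keep <- which(t >= min(t) + phases$edge_ms & t <= max(t) - phases$edge_ms)
  keep <- keep[seq(1, length(keep), by = as.integer(decimation))]
  list(time_ms = t[keep], phi = phases$phi[keep, , drop = FALSE])
}

#' Full burst-phase extraction pipeline
#'
#' Trims the burn-in, low-pass filters each interneuron voltage trace at an
#' adaptive cutoff, standardizes, and assigns instantaneous phases via the
#' Hilbert transform. The default cutoff is `1.5 x` the realized pyramidal
#' driving frequency (bursts recur at the drive rhythm while intra-burst
#' spikes sit far above it), clipped to `[5 Hz, 0.45 x sampling rate]`.
#'
#' @param traces `voltage_traces` from [simulate_network()].
#' @param driving_frequency_hz realized pyramidal population frequency (from
#'   [population_frequency()]); required unless `cutoff_hz` is given.
#' @param burst_rate_hz measured interneuron burst rate (from
#'   [population_burst_rate()]). When supplied and positive, the adaptive
#'   cutoff is `1.5 x` the burst rate instead of `1.5 x` the driving
#'   frequency: in subharmonic regimes the burst rhythm sits at `f/2, f/3,
#'   ...`, and a cutoff below `f` is required to remove the per-cycle volley
#'   response that is common to all neurons and would otherwise mask the
#'   cluster structure.
#' @param cutoff_hz explicit cutoff override.
#' @param zero_phase forward-backward filtering (default TRUE).
#' @param burn_in initial transient to drop (ms).
#' @param edge_ms Hilbert edge-artifact flag window (ms).
#' @return a `phase_series`.
#' @export
extract_phases <- function(traces, driving_frequency_hz = NULL,
                           burst_rate_hz = NULL, cutoff_hz = NULL,
                           zero_phase = TRUE, burn_in = 500, edge_ms = 100) {
  stopifnot(inherits(traces, "voltage_traces"))
  if (length(traces$time_ms) == 0) stop("zero-length trace")
  if (is.null(cutoff_hz)) {
    base_hz <- if (!is.null(burst_rate_hz) && is.finite(burst_rate_hz) &&
                   burst_rate_hz > 0) burst_rate_hz else driving_frequency_hz
    if (is.null(base_hz)) {
      stop("either driving_frequency_hz or cutoff_hz must be supplied")
    }
    cutoff_hz <- min(max(1.5 * base_hz, 5), 0.45 * traces$sampling_rate_hz)
  }
  keep <- traces$time_ms >= burn_in
  if (!any(keep)) stop("burn-in removes the entire trace")
  traces$v <- traces$v[keep, , drop = FALSE]
  traces$time_ms <- traces$time_ms[keep]
  spec <- filter_spec(cutoff_hz, traces$sampling_rate_hz, zero_phase = zero_phase)
  hilbert_phase(standardize_traces(lowpass_burst_filter(traces, spec)),
                edge_ms = edge_ms)
}
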