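#' Kuramoto-Daido order parameter Z_n
#'
#' `Z_n = mean(exp(i * n * phi))` over an ensemble of angles. `|Z_1|` is the
#' usual Kuramoto order parameter; for an ideal arrangement of `c` equally
#' populated, uniformly spaced clusters, `|Z_n| = 1` exactly when `n` is a
#' multiple of `c` and vanishes otherwise.
#'
#' @param phi numeric vector of angles (radians).
#' @param n positive integer harmonic.
#' @return complex `Z_n` (take `Mod()` for the magnitude).
#' @export
kuramoto_daido_z <- function(phi, n) {
  if (length(phi) == 0) stop("empty phase sample")
  stopifnot(n >= 1, n == round(n))
  mean(exp(1i * n * phi))
}

#' Cluster-stability metric G_n
#'
#' Redundancy-corrected, real-valued cluster-stability score:
#' `G_n = |Z_n| * prod_{k<n} (1 - |Z_k|)`. Because an ideal n-cluster state
#' also makes every `|Z_{jn}|` equal to one, the correction factor suppresses
#' harmonics of simpler arrangements, so `G_n` approaches 1 only when the
#' ensemble approximates an ideal n-cluster state.
#'
#' @inheritParams kuramoto_daido_z
#' @return `G_n` in `[0, 1]`.
#' @export
stability_g <- function(phi, n) {
  zmag <- vapply(seq_len(n), function(k) Mod(kuramoto_daido_z(phi, k)), numeric(1))
  zmag[n] * prod(1 - zmag[seq_len(n - 1)])
}

#' Sample pairwise phase differences
#'
#' Draws `n_sets` independent sets of `n_pairs` distinct unordered interneuron
#' pairs and collects the wrapped instantaneous phase differences of each pair
#' at every retained time sample (edge windows excluded, optional
#' decimation). Pooling differences over time cancels the common drift of the
#' cluster phases, so the resulting angle ensemble reflects the cluster
#' structure alone.
#'
#' @param phases a `phase_series` (see [extract_phases()]).
#' @param n_pairs pairs per set (default 100).
#' @param n_sets number of independent sets (default 10).
#' @param decimation keep every k-th time sample.
#' @param seed RNG seed for the pair draw.
#' @return list of class `phase_diff_samples`: one numeric vector of wrapped
#'   differences per set, with the sampled pair indices as attributes.
#' @export
pairwise_phase_differences <- function(phases, n_pairs = 100, n_sets = 10,
                                       decimation = 1L, seed = 1L) {
  win <- phase_window(phases, decimation = decimation)
  n_neuron <- ncol(win$phi)
  if (n_neuron < 2) stop("need at least 2 neurons for phase differences")
  all_pairs <- utils::combn(n_neuron, 2)
  if (n_pairs > ncol(all_pairs)) {
    stop(sprintf("n_pairs = %d exceeds the %d distinct pairs available",
                 n_pairs, ncol(all_pairs)))
  }
  set.seed(seed)
  out <- lapply(seq_len(n_sets), function(s) {
    sel <- all_pairs[, sample.int(ncol(all_pairs), n_pairs), drop = FALSE]
    d <- wrap_phase(win$phi[, sel[1, ], drop = FALSE] -
                    win$phi[, sel[2, ], drop = FALSE])
    structure(as.numeric(d), pairs = sel)
  })
  class(out) <- "phase_diff_samples"
  out
}

#' Order-parameter profile over n = 1..n_max
#'
#' Computes `|Z_n|` and `G_n` per phase-difference set and summarizes them as
#' mean and SD across sets, mirroring the resampling used for the
#' frequency-sweep curves.
#'
#' @param samples a `phase_diff_samples` list (or plain list of numeric angle
#'   vectors).
#' @param n_max largest cluster number scored (default 7).
#' @return data.frame of class `order_parameter_profile` with columns `n`,
#'   `z_mean`, `z_sd`, `g_mean`, `g_sd`.
#' @export
order_parameter_profile <- function(samples, n_max = 7) {
  stopifnot(length(samples) >= 1)
  per_set <- lapply(samples, function(phi) {
    if (length(phi) == 0) stop("empty phase sample")
    # |Z_k| for k = 1..n_max by iterated multiplication of e^{i phi}
    e1 <- exp(1i * as.numeric(phi))
    ek <- e1
    zmag <- numeric(n_max)
    for (k in seq_len(n_max)) {
      zmag[k] <- Mod(mean(ek))
      if (k < n_max) ek <- ek * e1
    }
    g <- vapply(seq_len(n_max), function(k) {
      zmag[k] * prod(1 - zmag[seq_len(k - 1)])
    }, numeric(1))
    cbind(z = zmag, g = g)
  })
  zs <- vapply(per_set, function(m) m[, "z"], numeric(n_max))
  gs <- vapply(per_set, function(m) m[, "g"], numeric(n_max))
  zs <- matrix(zs, nrow = n_max); gs <- matrix(gs, nrow = n_max)
  prof <- data.frame(
    n = seq_len(n_max),
    z_mean = rowMeans(zs),
    z_sd = apply(zs, 1, sd),
    g_mean = rowMeans(gs),
    g_sd = apply(gs, 1, sd)
  )
  class(prof) <- c("order_parameter_profile", "data.frame")
  prof
}

#' Dominant cluster count
#'
#' The `n` maximizing mean `G_n`, with ties broken toward smaller `n` (the
#' simpler partition). If even the best `G_n` falls below the stability floor
#' the profile is flagged as showing no clustering; the flag never alters the
#' reported `n`.
#'
#' @param profile an [order_parameter_profile()].
#' @param floor stability floor below which clustering is not declared
#'   (default 0.2, calibrated so a uniform-phase null stays well under it).
#' @return list `n`, `g` (achieved mean G), `clustered` (logical).
#' @export
dominant_cluster_count <- function(profile, floor = 0.2) {
  stopifnot(inherits(profile, "order_parameter_profile"))
  i <- which.max(profile$g_mean)  # which.max takes the first, i.e. smallest n
  list(n = profile$n[i], g = profile$g_mean[i],
       clustered = profile$g_mean[i] >= floor)
}

#' Polar histogram of phase differences
#'
#' Counts over equal-width angular bins spanning `(-180, 180]` degrees.
#'
#' @param phi numeric vector of wrapped angles (radians).
#' @param n_bins number of bins (>= 4).
#' @return data.frame `bin_start_deg`, `bin_end_deg`, `count`; counts sum to
#'   `length(phi)`.
#' @export
polar_histogram <- function(phi, n_bins = 36) {
  stopifnot(n_bins >= 4)
  deg <- wrap_phase(phi) * 180 / pi
  edges <- seq(-180, 180, length.out = n_bins + 1)
  idx <- pmin(pmax(ceiling((deg + 180) / (360 / n_bins)), 1L), n_bins)
  data.frame(bin_start_deg = edges[-(n_bins + 1)],
             bin_end_deg = edges[-1],
             count = tabulate(idx, nbins = n_bins))
}
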