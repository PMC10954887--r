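#' Frequency sweep of cluster-stability curves
#'
#' Sweeps the external pyramidal drive so the realized population frequency
#' covers `f_targets`, simulating one network per (drive, topology seed) and
#' computing the order-parameter profile of the interneuron burst phases.
#' Runs whose interneurons stay silent are flagged (`silent = TRUE`, metrics
#' NA), never dropped silently; if every run is silent the sweep aborts with
#' a diagnostic.
#'
#' @param config base [network_config()] (its `i_ext_pyramidal` is replaced
#'   per sweep point).
#' @param f_targets target pyramidal frequencies (Hz).
#' @param seeds_topology topology seeds (one sweep per seed).
#' @param n_max largest cluster number scored.
#' @param n_pairs,n_sets phase-difference resampling scheme.
#' @param decimation time decimation for the metric computation.
#' @return data.frame of class `freq_sweep`: one row per (seed, f target, n)
#'   with `f_hz` (realized), `g_mean`, `g_sd`, `z_mean`, `z_sd`, `silent`.
#' @export
sweep_frequency <- function(config, f_targets = seq(10, 200, by = 5),
                            seeds_topology = config$seed_topology,
                            n_max = 7, n_pairs = 100, n_sets = 10,
                            decimation = 10L) {
  cal <- calibrate_drive(f_targets, params = config$params_pyramidal,
                         dt = config$dt)
  cal <- cal[!is.na(cal$i_ext), , drop = FALSE]
  if (nrow(cal) == 0) stop("no target frequency is reachable by the f-I curve")
  rows <- list()
  n_silent <- 0L
  for (seed in seeds_topology) {
    for (r in seq_len(nrow(cal))) {
      cfg <- config
      cfg$i_ext_pyramidal <- cal$i_ext[r]
      cfg$seed_topology <- as.integer(seed)
      res <- simulate_network(cfg)
      f <- tryCatch(population_frequency(res$raster, "pyramidal",
                                         burn_in = cfg$burn_in),
                    error = function(e) NA_real_)
      fs_active <- any(res$raster$population == "fast_spiking" &
                       res$raster$time_ms >= cfg$burn_in)
      if (!fs_active || is.na(f)) {
        n_silent <- n_silent + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          seed_topology = seed, f_target_hz = cal$f_target_hz[r],
          i_ext = cal$i_ext[r], f_hz = f, n = seq_len(n_max),
          g_mean = NA_real_, g_sd = NA_real_, z_mean = NA_real_,
          z_sd = NA_real_, silent = TRUE)
        next
      }
      br <- population_burst_rate(res$raster, f, cfg$n_fast_spiking,
                                  burn_in = cfg$burn_in)
      phases <- extract_phases(res$traces, driving_frequency_hz = f,
                               burst_rate_hz = br, burn_in = cfg$burn_in)
      prof <- order_parameter_profile(
        pairwise_phase_differences(phases, n_pairs = n_pairs, n_sets = n_sets,
                                   decimation = decimation,
                                   seed = seed * 131L + r),
        n_max = n_max)
      rows[[length(rows) + 1L]] <- data.frame(
        seed_topology = seed, f_target_hz = cal$f_target_hz[r],
        i_ext = cal$i_ext[r], f_hz = f, n = prof$n,
        g_mean = prof$g_mean, g_sd = prof$g_sd,
        z_mean = prof$z_mean, z_sd = prof$z_sd, silent = FALSE)
      log_run(event = "sweep_point", seed_topology = seed,
              f_target = cal$f_target_hz[r], f_realized = f)
    }
  }
  out <- do.call(rbind, rows)
  if (all(out$silent)) {
    stop("sweep aborted: interneurons silent at every operating point ",
         "(no excitatory drive reaches them; check coupling weights and p_ei)")
  }
  class(out) <- c("freq_sweep", "data.frame")
  out
}

# Mean Gn curves vs frequency, averaged across topology seeds at matched
# sweep points, 3-point moving-average smoothed.
sweep_curves <- function(sweep, smooth = TRUE) {
  ok <- sweep[!sweep$silent, , drop = FALSE]
  agg <- stats::aggregate(cbind(f_hz, g_mean) ~ f_target_hz + n, data = ok, FUN = mean)
  agg <- agg[order(agg$n, agg$f_target_hz), ]
  if (smooth) {
    agg$g_smooth <- stats::ave(agg$g_mean, agg$n, FUN = function(g) {
      if (length(g) < 3) return(g)
      gs <- stats::filter(g, rep(1 / 3, 3), sides = 2)
      gs[1] <- g[1]; gs[length(g)] <- g[length(g)]
      as.numeric(gs)
    })
  } else {
    agg$g_smooth <- agg$g_mean
  }
  agg
}

local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
}

#' Locate the characteristic cluster-state peaks of a frequency sweep
#'
#' Identifies, on the seed-averaged and 3-point-smoothed `G_n` curves: the
#' first and second well-defined local maxima of `G_2`, the global maximum of
#' `G_3`, the multi-cluster onset (lowest frequency where some
#' `G_n, n >= 2` exceeds `G_1`), and the washout frequency (highest frequency
#' at which any `G_n` still exceeds the stability floor). "Well-defined"
#' means exceeding the floor.
#'
#' @param sweep a [sweep_frequency()] result.
#' @param floor stability floor (default 0.2).
#' @return list `f_g2_first`, `f_g3_max`, `f_g2_second`, `f_onset`,
#'   `f_washout` (NA where undefined) plus the smoothed `curves`.
#' @export
find_cluster_peaks <- function(sweep, floor = 0.2) {
  curves <- sweep_curves(sweep)
  g2 <- curves[curves$n == 2, ]
  g3 <- curves[curves$n == 3, ]
  pk2 <- local_maxima(g2$g_smooth)
  pk2 <- pk2[g2$g_smooth[pk2] >= floor]
  f_g2_first <- if (length(pk2) >= 1) g2$f_hz[pk2[1]] else NA_real_
  f_g3_max <- if (nrow(g3) && max(g3$g_smooth) >= floor) {
    g3$f_hz[which.max(g3$g_smooth)]
  } else NA_real_
  f_g2_second <- NA_real_
  if (!is.na(f_g3_max)) {
    later <- pk2[g2$f_hz[pk2] > f_g3_max]
    if (length(later) >= 1) {
      f_g2_second <- g2$f_hz[later[which.max(g2$g_smooth[later])]]
    }
  }
  # onset / washout from unsmoothed per-frequency means
  byf <- split(curves, curves$f_target_hz)
  f_axis <- vapply(byf, function(d) d$f_hz[1], numeric(1))
  ord <- order(f_axis)
  multi_beats_g1 <- vapply(byf, function(d) {
    max(d$g_mean[d$n >= 2]) > d$g_mean[d$n == 1]
  }, logical(1))[ord]
  any_above <- vapply(byf, function(d) max(d$g_mean) >= floor, logical(1))[ord]
  f_sorted <- unname(f_axis[ord])
  f_onset <- if (any(multi_beats_g1)) f_sorted[which(multi_beats_g1)[1]] else NA_real_
  f_washout <- if (any(any_above)) f_sorted[max(which(any_above))] else NA_real_
  list(f_g2_first = f_g2_first, f_g3_max = f_g3_max, f_g2_second = f_g2_second,
       f_onset = f_onset, f_washout = f_washout, curves = curves)
}

#' Connectivity-grid sweep of maximal cluster stability
#'
#' For every cell of a (p_EI, p_II) grid, runs a frequency sweep and records
#' the maximum of `G_2` and `G_3` over frequency together with the
#' frequencies at which those maxima occur.
#'
#' @param config base [network_config()].
#' @param p_ei_values,p_ii_values grid axes.
#' @param f_targets frequencies swept per cell.
#' @param seed_topology topology seed used in every cell.
#' @param ... passed to [sweep_frequency()].
#' @return data.frame of class `connectivity_grid`: per cell `p_ei`, `p_ii`,
#'   `g2_max`, `f_at_g2_max`, `g3_max`, `f_at_g3_max`, `silent`.
#' @export
sweep_connectivity <- function(config, p_ei_values = seq(0.2, 1, length.out = 5),
                               p_ii_values = seq(0.2, 1, length.out = 5),
                               f_targets = seq(20, 200, by = 10),
                               seed_topology = config$seed_topology, ...) {
  rows <- list()
  for (pei in p_ei_values) {
    for (pii in p_ii_values) {
      cfg <- config
      cfg$p_ei <- pei
      cfg$p_ii <- pii
      cfg$seed_topology <- as.integer(seed_topology)
      sw <- tryCatch(
        sweep_frequency(cfg, f_targets = f_targets,
                        seeds_topology = seed_topology, ...),
        error = function(e) NULL)
      if (is.null(sw) || all(sw$silent)) {
        rows[[length(rows) + 1L]] <- data.frame(
          p_ei = pei, p_ii = pii, g2_max = NA_real_, f_at_g2_max = NA_real_,
          g3_max = NA_real_, f_at_g3_max = NA_real_, silent = TRUE)
        next
      }
      curves <- sweep_curves(sw, smooth = FALSE)
      g2 <- curves[curves$n == 2, ]
      g3 <- curves[curves$n == 3, ]
      rows[[length(rows) + 1L]] <- data.frame(
        p_ei = pei, p_ii = pii,
        g2_max = max(g2$g_mean), f_at_g2_max = g2$f_hz[which.max(g2$g_mean)],
        g3_max = max(g3$g_mean), f_at_g3_max = g3$f_hz[which.max(g3$g_mean)],
        silent = FALSE)
      log_run(event = "grid_cell", p_ei = pei, p_ii = pii)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("connectivity_grid", "data.frame")
  out
}

#' Collective-response curves
#'
#' Runs the paired perturbation protocol at each combination of operating
#' point (external drive), perturbed-neuron count and perturbation weight,
#' with `m` trials per condition. Each trial uses a fresh topology seed, a
#' fresh random target set and a random perturbation time (> 500 ms, leaving
#' room for the averaging window).
#'
#' @param config base [network_config()].
#' @param i_ext_values external drives defining the operating points.
#' @param k_values perturbed-neuron counts.
#' @param weight_values perturbation weights.
#' @param m trials per condition.
#' @param seed master seed; trial seeds are derived from it.
#' @param window post-perturbation ARI averaging window (ms).
#' @param ... passed to [paired_perturbation_trial()].
#' @return data.frame of class `cr_curves`: per condition `i_ext`, `f_hz`
#'   (mean realized), `k`, `weight`, `cr`, `m_accepted`, `m_rejected`.
#' @export
cr_curves <- function(config, i_ext_values, k_values = c(1, 2, 5, 10, 20),
                      weight_values = 0.3, m = 10, seed = 1L, window = 2000,
                      ...) {
  rows <- list()
  cond <- 0L
  for (i_ext in i_ext_values) {
    for (k in k_values) {
      for (w in weight_values) {
        cond <- cond + 1L
        trials <- list()
        set.seed(seed * 7919L + cond)
        t_lo <- config$burn_in + 200
        t_hi <- config$duration - window - 200
        if (t_hi <= max(t_lo, 500)) {
          stop("duration too short for the perturbation protocol window")
        }
        tps <- runif(m, max(t_lo, 501), t_hi)
        for (i in seq_len(m)) {
          cfg <- config
          cfg$i_ext_pyramidal <- i_ext
          cfg$seed_topology <- as.integer(seed * 1000L + cond * 100L + i)
          cfg$seed_init <- as.integer(seed * 555L + i)
          spec <- perturbation_spec(k = k, weight = w, t_p = tps[i],
                                    seed_targets = seed * 100L + cond * 10L + i)
          trials[[i]] <- paired_perturbation_trial(cfg, spec, ...)
        }
        cr <- tryCatch(collective_response(trials, window = window),
                       error = function(e) NULL)
        f_mean <- mean(vapply(trials, function(tr) tr$f_hz, numeric(1)),
                       na.rm = TRUE)
        rows[[length(rows) + 1L]] <- data.frame(
          i_ext = i_ext, f_hz = f_mean, k = k, weight = w,
          cr = if (is.null(cr)) NA_real_ else cr$cr,
          m_accepted = if (is.null(cr)) 0L else cr$m,
          m_rejected = if (is.null(cr)) length(trials) else cr$n_rejected)
        log_run(event = "cr_condition", i_ext = i_ext, k = k, weight = w)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cr_curves", "data.frame")
  out
}

#' Saturation point of a CR-vs-k curve
#'
#' Smallest perturbed-neuron count `k*` such that the collective response at
#' every larger measured count stays within `rel_tol` relative of CR at `k*`.
#'
#' @param k,cr measured counts and responses (same length, k increasing).
#' @param rel_tol relative tolerance (default 0.1).
#' @return k*.
#' @export
cr_saturation_k <- function(k, cr, rel_tol = 0.1) {
  ord <- order(k)
  k <- k[ord]; cr <- cr[ord]
  for (i in seq_along(k)) {
    ref <- cr[i]
    later <- cr[k > k[i]]
    if (length(later) == 0 || all(abs(later - ref) <= rel_tol * max(abs(ref), 1e-12))) {
      return(k[i])
    }
  }
  k[length(k)]
}
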