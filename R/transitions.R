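# Rotate wrapped phases so the largest angular gap maps to the domain
# boundary: a 1-D Gaussian mixture then never has to split a cluster across
# the wrap-around point.
recenter_phases <- function(phi) {
  s <- sort(phi)
  gaps <- diff(c(s, s[1] + 2 * pi))
  j <- which.max(gaps)
  boundary <- s[j] + gaps[j] / 2   # middle of the largest gap
  wrap_phase(phi - boundary - pi)  # boundary -> -pi/pi edge
}

# Seeded 1-D EM Gaussian mixture with hard assignment. Random initialization
# (means drawn from the data), iteration cap, variance floor, multiple
# restarts scored by log-likelihood.
gmm_em_1d <- function(x, n, max_iter = 100, var_floor = 1e-6, tol = 1e-8) {
  N <- length(x)
  mu <- x[sample.int(N, n)]
  sigma2 <- rep(max(stats::var(x) * (N - 1) / N, var_floor), n)
  w <- rep(1 / n, n)
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    dens <- vapply(seq_len(n), function(k) {
      w[k] * stats::dnorm(x, mu[k], sqrt(sigma2[k]))
    }, numeric(N))
    dens <- matrix(dens, nrow = N)
    rowsum_d <- rowSums(dens) + .Machine$double.xmin
    ll <- sum(log(rowsum_d))
    resp <- dens / rowsum_d
    nk <- colSums(resp) + 1e-12
    w <- nk / N
    mu <- colSums(resp * x) / nk
    sigma2 <- pmax(colSums(resp * (outer(x, mu, "-"))^2) / nk, var_floor)
    if (abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  dens <- vapply(seq_len(n), function(k) {
    w[k] * stats::dnorm(x, mu[k], sqrt(sigma2[k]))
  }, numeric(N))
  dens <- matrix(dens, nrow = N)
  list(labels = max.col(dens) - 1L, loglik = sum(log(rowSums(dens) + .Machine$double.xmin)),
       mu = mu, sigma2 = sigma2, w = w, iterations = iter)
}

#' Cluster instantaneous phases with a Gaussian mixture
#'
#' Fits a one-dimensional `n`-component Gaussian mixture to the neurons'
#' instantaneous phases and hard-assigns each neuron to the component with
#' maximal responsibility. Before fitting, phases are rotated so the largest
#' angular gap maps to the domain boundary, preventing a cluster from being
#' split by wrap-around while keeping the plain (non-circular) mixture model.
#' EM runs for at most 100 iterations from seeded random initializations
#' (means sampled from the data); the best of `n_restarts` fits by
#' log-likelihood is kept.
#'
#' @param phi numeric vector of phases (radians), one per neuron.
#' @param n number of mixture components.
#' @param seed RNG seed controlling initialization.
#' @param n_restarts number of EM restarts (default 5).
#' @param max_iter EM iteration cap (default 100).
#' @return object of class `cluster_assignment`: `labels` (0-based, one per
#'   neuron), `n`, `loglik`, `iterations`, `converged`.
#' @export
gmm_assign <- function(phi, n, seed = 1L, n_restarts = 5, max_iter = 100) {
  stopifnot(n >= 1)
  if (length(phi) < n) stop("fewer neurons than mixture components")
  if (length(unique(phi)) < n) stop("fewer distinct phase values than components")
  if (n == 1) {
    return(structure(list(labels = rep(0L, length(phi)), n = 1L,
                          loglik = NA_real_, iterations = 0L, converged = TRUE),
                     class = "cluster_assignment"))
  }
  x <- recenter_phases(phi)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- gmm_em_1d(x, n, max_iter = max_iter)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  structure(list(labels = best$labels, n = as.integer(n), loglik = best$loglik,
                 iterations = best$iterations,
                 converged = best$iterations < max_iter),
            class = "cluster_assignment")
}

pair_counts <- function(a, b) {
  if (length(a) != length(b)) stop("partitions compare different neuron sets")
  tab <- table(a, b)
  N <- length(a)
  choose2 <- function(x) x * (x - 1) / 2
  list(N = N, total = choose2(N),
       nij = sum(choose2(tab)),
       ai = sum(choose2(rowSums(tab))),
       bj = sum(choose2(colSums(tab))))
}

as_labels <- function(x) if (inherits(x, "cluster_assignment")) x$labels else x

#' Rand index between two partitions
#'
#' `(g + h) / C(N, 2)`: the fraction of neuron pairs on which the two
#' partitions agree, where `g` pairs share a cluster in both and `h` pairs are
#' separated in both. Equals 1 for identical arrangements.
#'
#' @param a,b partitions: label vectors or `cluster_assignment` objects over
#'   the same neurons.
#' @return RI in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  pc <- pair_counts(as_labels(a), as_labels(b))
  if (pc$total == 0) return(1)
  g <- pc$nij
  h <- pc$total - pc$ai - pc$bj + pc$nij
  (g + h) / pc$total
}

#' Adjusted Rand index
#'
#' Chance-corrected Rand index `(RI - ERI) / (maxRI - ERI)`: 1 for identical
#' partitions and 0 in expectation for independent random ones.
#' `method = "closed_form"` (default) uses the permutation-model expectation
#' in closed form (Hubert-Arabie); `method = "permutation"` estimates the
#' expected index by Monte-Carlo over random label permutations with a
#' recorded seed. The degenerate comparison of two identical trivial
#' partitions (e.g. everything in one cluster) is defined as 1.
#'
#' @inheritParams rand_index
#' @param method `"closed_form"` or `"permutation"`.
#' @param n_perm Monte-Carlo permutations (>= 1000 recommended).
#' @param seed RNG seed for the permutation method.
#' @return ARI `<= 1`.
#' @export
adjusted_rand_index <- function(a, b, method = c("closed_form", "permutation"),
                                n_perm = 1000, seed = 1L) {
  method <- match.arg(method)
  a <- as_labels(a); b <- as_labels(b)
  pc <- pair_counts(a, b)
  if (method == "closed_form") {
    expected <- pc$ai * pc$bj / max(pc$total, 1)
    max_index <- (pc$ai + pc$bj) / 2
    if (abs(max_index - expected) < .Machine$double.eps * max(1, max_index)) {
      # both partitions trivial (all one cluster or all singletons)
      return(1)
    }
    (pc$nij - expected) / (max_index - expected)
  } else {
    ri <- rand_index(a, b)
    set.seed(seed)
    eri <- mean(vapply(seq_len(n_perm), function(i) {
      rand_index(a, b[sample.int(length(b))])
    }, numeric(1)))
    if (abs(1 - eri) < .Machine$double.eps) return(1)
    (ri - eri) / (1 - eri)
  }
}

#' Specification of a single-spike perturbation
#'
#' @param k number of simultaneously perturbed interneurons (1-20 in the
#'   experiments; any positive count up to the population size is allowed).
#' @param weight voltage increment each perturbed neuron receives (one
#'   external excitatory spike of this weight).
#' @param t_p perturbation time in ms (> 500; must leave room for the
#'   post-perturbation evaluation window).
#' @param seed_targets seed selecting which interneurons are hit.
#' @return object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(k, weight, t_p, seed_targets = 1L) {
  stopifnot(k >= 1, weight >= 0, t_p > 500)
  structure(list(k = as.integer(k), weight = weight, t_p = t_p,
                 seed_targets = as.integer(seed_targets)),
            class = "perturbation_spec")
}

#' Run one paired (baseline, perturbed) perturbation trial
#'
#' Simulates the network twice with identical seeds and initializations. The
#' perturbed run additionally delivers, at `spec$t_p`, a single excitatory
#' pulse of `spec$weight` to each of `spec$k` randomly selected interneurons.
#' The baseline run fixes the cluster count `n` (dominant `G_n` over the
#' baseline analysis window); at each evaluation time both runs' phases are
#' clustered by [gmm_assign()] with identical derived seeds, and the adjusted
#' Rand index between the two assignments is recorded. Before `t_p` the runs
#' are bit-identical, so ARI is exactly 1 there.
#'
#' @param config a [network_config()].
#' @param spec a [perturbation_spec()].
#' @param eval_every spacing of evaluation times (ms).
#' @param eval_window evaluation window around `t_p` (ms, c(before, after)).
#' @param stability_floor minimum baseline `G_n` for the trial to count.
#' @param decimation time decimation for the order-parameter profile.
#' @param gmm_restarts EM restarts per fit.
#' @return object of class `trial_result`: `ari` (data.frame `t_ms`, `ari`),
#'   `n`, `status` ("ok" or "rejected_no_clustering"), `targets`, `spec`,
#'   `config_hash`.
#' @export
paired_perturbation_trial <- function(config, spec,
                                      eval_every = 10, eval_window = c(500, 2000),
                                      stability_floor = 0.2, decimation = 10L,
                                      gmm_restarts = 5) {
  stopifnot(inherits(spec, "perturbation_spec"))
  if (spec$t_p + eval_window[2] > config$duration) {
    stop("t_p plus the evaluation window exceeds the simulation duration")
  }
  adjacency <- build_network(config)
  base <- simulate_network(config, adjacency = adjacency)
  f <- population_frequency(base$raster, "pyramidal", burn_in = config$burn_in)
  br <- population_burst_rate(base$raster, f, config$n_fast_spiking,
                              burn_in = config$burn_in)
  base_phases <- extract_phases(base$traces, driving_frequency_hz = f,
                                burst_rate_hz = br, burn_in = config$burn_in)
  prof <- order_parameter_profile(
    pairwise_phase_differences(base_phases, decimation = decimation,
                               seed = spec$seed_targets))
  dom <- dominant_cluster_count(prof, floor = stability_floor)
  set.seed(spec$seed_targets)
  targets <- sample.int(config$n_fast_spiking, spec$k) - 1L
  if (!dom$clustered) {
    return(structure(list(ari = NULL, n = dom$n, g = dom$g,
                          status = "rejected_no_clustering", targets = targets,
                          spec = spec, f_hz = f,
                          config_hash = config_hash(unclass(config))),
                     class = "trial_result"))
  }
  pert <- simulate_network(config, adjacency = adjacency,
                           perturbation = list(t_p = spec$t_p, targets = targets,
                                               weight = spec$weight))
  pert_phases <- extract_phases(pert$traces, driving_frequency_hz = f,
                                burst_rate_hz = br, burn_in = config$burn_in)
  eval_t <- spec$t_p + seq(-eval_window[1], eval_window[2], by = eval_every)
  tt <- base_phases$time_ms
  lo <- min(tt) + base_phases$edge_ms
  hi <- max(tt) - base_phases$edge_ms
  eval_t <- eval_t[eval_t >= lo & eval_t <= hi]
  idx <- vapply(eval_t, function(tm) which.min(abs(tt - tm)), integer(1))
  # Before t_p the two simulations are bit-identical by construction, so the
  # partitions cannot differ: ARI is 1 exactly. (Fitting on per-run phase
  # estimates there would only expose backward leakage of the zero-phase
  # filter, an estimator artifact, not a dynamical difference.)
  ari <- vapply(seq_along(idx), function(j) {
    if (tt[idx[j]] < spec$t_p) return(1)
    s <- spec$seed_targets * 10007L + j
    a <- gmm_assign(base_phases$phi[idx[j], ], dom$n, seed = s,
                    n_restarts = gmm_restarts)
    b <- gmm_assign(pert_phases$phi[idx[j], ], dom$n, seed = s,
                    n_restarts = gmm_restarts)
    adjusted_rand_index(a, b)
  }, numeric(1))
  structure(list(ari = data.frame(t_ms = tt[idx], ari = ari),
                 n = dom$n, g = dom$g, status = "ok", targets = targets,
                 spec = spec, f_hz = f,
                 config_hash = config_hash(unclass(config))),
            class = "trial_result")
}

#' Collective response over a set of trials
#'
#' `CR = 1 - mean(ARI_i)` where `ARI_i` is trial i's adjusted Rand index
#' time-averaged over `(t_p, t_p + window]`. CR is 0 when perturbations never
#' rearrange the clusters and 1 when they scramble them completely.
#'
#' @param trials list of `trial_result`s (rejected trials are dropped and
#'   counted).
#' @param window post-perturbation averaging window (ms).
#' @return object of class `cr_summary`: `cr`, `m` (accepted trials),
#'   `ari_per_trial`, `n_rejected`, `window`.
#' @export
collective_response <- function(trials, window = 2000) {
  if (inherits(trials, "trial_result")) trials <- list(trials)
  ok <- Filter(function(tr) identical(tr$status, "ok"), trials)
  n_rej <- length(trials) - length(ok)
  if (length(ok) == 0) stop("no accepted trials: cannot compute collective response")
  ari_i <- vapply(ok, function(tr) {
    sel <- tr$ari$t_ms > tr$spec$t_p & tr$ari$t_ms <= tr$spec$t_p + window
    if (!any(sel)) stop("no evaluation points inside the averaging window")
    mean(tr$ari$ari[sel])
  }, numeric(1))
  structure(list(cr = 1 - mean(ari_i), m = length(ok), ari_per_trial = ari_i,
                 n_rejected = n_rej, window = window),
            class = "cr_summary")
}

#' @export
print.cr_summary <- function(x, ...) {
  cat(sprintf("<cr_summary> CR = %.3f over M = %d trials (%d rejected), window %g ms\n",
              x$cr, x$m, x$n_rejected, x$window))
  invisible(x)
}
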