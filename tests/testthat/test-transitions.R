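test_that("GMM assignment recovers planted phase partitions", {
  set.seed(10)
  phi2 <- c(rnorm(25, 0, 0.1), rnorm(25, pi, 0.1))
  truth2 <- rep(0:1, each = 25)
  asg <- gmm_assign(wrap_phase(phi2), 2, seed = 1)
  expect_equal(adjusted_rand_index(asg$labels, truth2), 1)
  # n = 1: everything in one cluster
  one <- gmm_assign(phi2, 1)
  expect_true(all(one$labels == 0))
  # wrap-sensitive 3-cluster case at -2pi/3, 0, 2pi/3 across 20 seeded fits
  phi3 <- wrap_phase(c(rnorm(20, -2 * pi / 3, 0.1), rnorm(20, 0, 0.1),
                       rnorm(20, 2 * pi / 3, 0.1)))
  truth3 <- rep(0:2, each = 20)
  aris <- vapply(1:20, function(s) {
    adjusted_rand_index(gmm_assign(phi3, 3, seed = s)$labels, truth3)
  }, numeric(1))
  expect_gte(mean(aris >= 0.95), 0.95)
  expect_error(gmm_assign(c(0, 1), 3), "fewer")
})

test_that("GMM assignment is deterministic given the seed and robust to wrap", {
  set.seed(11)
  # clusters straddling the +/-pi boundary: rotation must keep them whole
  phi <- wrap_phase(c(rnorm(25, pi, 0.15), rnorm(25, 0, 0.15)))
  a1 <- gmm_assign(phi, 2, seed = 7)
  a2 <- gmm_assign(phi, 2, seed = 7)
  expect_identical(a1$labels, a2$labels)
  truth <- rep(0:1, each = 25)
  expect_gte(adjusted_rand_index(a1$labels, truth), 0.95)
})

test_that("GMM agrees with an independent mixture fit on well-separated data", {
  skip_if_not_installed("mclust")
  suppressMessages(library(mclust))  # Mclust needs its namespace attached
  set.seed(12)
  phi <- wrap_phase(c(rnorm(30, -1.5, 0.12), rnorm(30, 1.2, 0.12)))
  ours <- gmm_assign(phi, 2, seed = 3)
  mc <- mclust::Mclust(phi, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(adjusted_rand_index(ours$labels, mc$classification), 1)
})

test_that("Rand index matches enumeration over all pairs", {
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), 1 / 3)
  expect_equal(rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(rand_index(c(1, 2), c(2, 1)), 1)  # both split into singletons
  set.seed(13)
  for (i in 1:10) {
    a <- sample.int(3, 12, replace = TRUE)
    b <- sample.int(4, 12, replace = TRUE)
    expect_equal(rand_index(a, b), enumerate_rand_index(a, b))
  }
  expect_error(rand_index(1:3, 1:4), "different neuron sets")
})

test_that("adjusted Rand index reproduces worked examples and endpoints", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2)), -0.5)
  # degenerate identical trivial partitions
  expect_equal(adjusted_rand_index(rep(1, 6), rep(2, 6)), 1)
  # random independent partitions average to ~0
  set.seed(14)
  m <- mean(vapply(1:1000, function(i) {
    adjusted_rand_index(sample.int(3, 50, TRUE), sample.int(3, 50, TRUE))
  }, numeric(1)))
  expect_lt(abs(m), 0.02)
})

test_that("ARI is symmetric, label-permutation invariant, and matches mclust", {
  skip_if_not_installed("mclust")
  set.seed(15)
  for (i in 1:20) {
    a <- sample.int(4, 30, TRUE)
    b <- sample.int(3, 30, TRUE)
    ari <- adjusted_rand_index(a, b)
    expect_equal(ari, adjusted_rand_index(b, a))
    perm <- sample.int(4)
    expect_equal(adjusted_rand_index(perm[a], b), ari)
    expect_equal(ari, mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
})

test_that("closed-form and Monte-Carlo ARI agree on random partition pairs", {
  set.seed(16)
  diffs <- vapply(1:100, function(i) {
    a <- sample.int(3, 40, TRUE)
    b <- sample.int(3, 40, TRUE)
    abs(adjusted_rand_index(a, b) -
        adjusted_rand_index(a, b, method = "permutation", n_perm = 1000,
                            seed = i))
  }, numeric(1))
  expect_lt(max(diffs), 0.02)
})

test_that("collective response evaluates the defining endpoints", {
  mk_trial <- function(aris, t_p = 1000) {
    structure(list(ari = data.frame(t_ms = t_p + seq_along(aris) * 10,
                                    ari = aris),
                   spec = perturbation_spec(1, 0.3, t_p), status = "ok"),
              class = "trial_result")
  }
  expect_equal(collective_response(list(mk_trial(rep(1, 5)),
                                        mk_trial(rep(1, 5))))$cr, 0)
  expect_equal(collective_response(list(mk_trial(rep(0, 5))))$cr, 1)
  # M = 2 with time-averaged ARIs {1.0, 0.5} -> CR = 0.25
  expect_equal(collective_response(list(mk_trial(rep(1, 4)),
                                        mk_trial(rep(0.5, 4))))$cr, 0.25)
  expect_error(collective_response(list()), "no accepted trials")
})

perturb_cfg <- function(...) {
  network_config(duration = 2200, seed_topology = 31, seed_init = 5,
                 v_init_jitter = 95, i_ext_pyramidal = 22, burn_in = 400, ...)
}

test_that("paired runs are bit-identical before the perturbation", {
  cfg <- perturb_cfg()
  adj <- build_network(cfg)
  base <- simulate_network(cfg, adjacency = adj)
  pert <- simulate_network(cfg, adjacency = adj,
                           perturbation = list(t_p = 1200, targets = 0:4,
                                               weight = 0.5))
  cut <- 1200
  rb <- base$raster[base$raster$time_ms < cut, ]
  rp <- pert$raster[pert$raster$time_ms < cut, ]
  expect_identical(rb, rp)
  pre <- base$traces$time_ms < cut
  expect_identical(base$traces$v[pre, ], pert$traces$v[pre, ])
  # and the baseline run never sees the perturbed neurons' identities
  expect_identical(base$config_hash, pert$config_hash)
})

test_that("a zero-weight perturbation trial yields ARI 1 and CR 0", {
  cfg <- perturb_cfg()
  spec <- perturbation_spec(k = 5, weight = 1e-9, t_p = 900,
                            seed_targets = 2)
  spec$weight <- 0  # exact null control
  tr <- paired_perturbation_trial(cfg, spec, eval_every = 50,
                                  eval_window = c(200, 800),
                                  stability_floor = 0, gmm_restarts = 2)
  expect_identical(tr$status, "ok")
  expect_true(all(tr$ari$ari == 1))
  expect_equal(collective_response(list(tr), window = 800)$cr, 0)
})

test_that("trials without baseline clustering are rejected explicitly", {
  cfg <- perturb_cfg()
  spec <- perturbation_spec(k = 3, weight = 0.3, t_p = 900, seed_targets = 3)
  tr <- paired_perturbation_trial(cfg, spec, eval_every = 100,
                                  eval_window = c(100, 500),
                                  stability_floor = 1.01)  # unattainable floor
  expect_identical(tr$status, "rejected_no_clustering")
  expect_error(collective_response(list(tr)), "no accepted trials")
})
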