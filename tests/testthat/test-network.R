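small_cfg <- function(...) {
  network_config(n_pyramidal = 20, n_fast_spiking = 10, duration = 1000,
                 i_ext_pyramidal = 10, ...)
}

test_that("edge realization matches the probability model and the seed", {
  # complete bipartite case
  cfg <- network_config(p_ei = 1, p_ii = 0)
  adj <- build_network(cfg)
  expect_equal(unname(adj$counts[["ei"]]), 100 * 50)
  expect_equal(unname(adj$counts[["ii"]]), 0)

  # p = 0 everywhere except ii; self-edges excluded; count inside the exact
  # binomial 99.9% interval for Binomial(2450, 0.4)
  cfg2 <- network_config(n_pyramidal = 50, n_fast_spiking = 50,
                         p_ei = 0, p_ii = 0.4, seed_topology = 42)
  expect_equal(unname(build_network(cfg2)$counts[["ei"]]), 0)
  cnt <- unname(build_network(cfg2)$counts[["ii"]])
  bounds <- qbinom(c(0.0005, 0.9995), 50 * 49, 0.4)
  expect_gte(cnt, bounds[1])
  expect_lte(cnt, bounds[2])
  expect_false(any(with(build_network(cfg2)$edges, source == target)))

  # determinism: identical seed -> identical edge set
  expect_identical(build_network(cfg2)$edges, build_network(cfg2)$edges)
  cfg3 <- cfg2
  cfg3$seed_topology <- 43L
  expect_false(identical(build_network(cfg3)$edges, build_network(cfg2)$edges))
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(network_config(p_ei = 1.5), "p_ei")
  expect_error(network_config(p_ii = -0.1), "p_ii")
  expect_error(network_config(w_excitatory = -1), "w_excitatory")
  expect_error(network_config(w_inhibitory = 0.3), "w_inhibitory")
  expect_error(network_config(dt = 0), "dt")
})

test_that("the pyramidal resting fixed point (-70, -14) is stationary", {
  # root of 0.04 v^2 + 4.8 v + 140 = 0 with u = b v: derivatives vanish there
  p <- izhikevich_params("pyramidal")
  v <- -70; u <- -14
  expect_equal(0.04 * v^2 + 5 * v + 140 - u, 0)
  expect_equal(p$a * (p$b * v - u), 0)
  # a full second of integration from the fixed point stays put
  fi <- fi_curve(p, 0, duration = 1000)
  expect_equal(fi$frequency_hz, 0)
})

test_that("one Euler step reproduces direct substitution into the equations", {
  # v=-65, u=-13, I=0, dt=0.1: dv = 0.04*65^2 - 325 + 140 + 13 = -3
  v <- -65; u <- -13; dt <- 0.1
  p <- izhikevich_params("pyramidal")
  dv <- 0.04 * v^2 + 5 * v + 140 - u
  du <- p$a * (p$b * v - u)
  expect_equal(v + dt * dv, -65.3)
  expect_equal(u + dt * du, -13)
})

test_that("threshold crossing resets v to c and increments u by d", {
  # a strongly driven isolated neuron spikes; recorded v never exceeds 30
  p <- izhikevich_params("pyramidal")
  cfg <- network_config(n_pyramidal = 1, n_fast_spiking = 1,
                        p_ei = 0, p_ii = 0, i_ext_pyramidal = 20,
                        duration = 500, v_init_jitter = 0)
  res <- simulate_network(cfg)
  expect_gt(sum(res$raster$population == "pyramidal"), 5)
  expect_true(all(res$traces$v <= 30))
})

test_that("spike delivery sums per-spike kicks onto the target", {
  # 3 excitatory sources firing together, p = 1, w = +0.3 -> +0.9 mV on the
  # target at the step after their spike
  cfg <- network_config(n_pyramidal = 3, n_fast_spiking = 1, p_ei = 1,
                        p_ii = 0, i_ext_pyramidal = 10, duration = 100,
                        v_init_jitter = 0)
  res <- simulate_network(cfg)
  t_first <- min(res$raster$time_ms[res$raster$population == "pyramidal"])
  # all three pyramidal cells are identical -> they spike simultaneously
  expect_equal(sum(res$raster$time_ms == t_first), 3)
  v <- res$traces$v[, 1]
  i_spk <- round(t_first / cfg$dt)
  jump <- (v[i_spk + 1] - v[i_spk]) - (v[i_spk] - v[i_spk - 1])
  expect_equal(jump, 3 * 0.3, tolerance = 0.02)

  # a one-off pulse of weight w lands as a Delta-v of exactly w on a
  # quiescent interneuron (same delivery path as synaptic spikes)
  cfgQ <- network_config(n_pyramidal = 1, n_fast_spiking = 1, p_ei = 0,
                         p_ii = 0, i_ext_pyramidal = 0, duration = 300,
                         v_init_jitter = 0)
  base <- simulate_network(cfgQ)
  pert <- simulate_network(cfgQ, perturbation = list(t_p = 200, targets = 0L,
                                                     weight = 0.45))
  i_p <- round(200 / cfgQ$dt)
  dv <- pert$traces$v[i_p, 1] - base$traces$v[i_p, 1]
  expect_equal(dv, 0.45, tolerance = 1e-9)
})

test_that("voltage_kick and current_pulse coupling modes agree numerically", {
  cfg_k <- small_cfg(coupling_mode = "voltage_kick")
  cfg_c <- small_cfg(coupling_mode = "current_pulse")
  rk <- simulate_network(cfg_k)
  rc <- simulate_network(cfg_c)
  expect_equal(rk$raster$time_ms, rc$raster$time_ms, tolerance = 1e-8)
  expect_equal(rk$traces$v, rc$traces$v, tolerance = 1e-6)
})

test_that("simulation is bit-identical under fixed seeds", {
  cfg <- small_cfg()
  r1 <- simulate_network(cfg)
  r2 <- simulate_network(cfg)
  expect_identical(r1$raster, r2$raster)
  expect_identical(r1$traces$v, r2$traces$v)
})

test_that("a zero-coupling network leaves the interneurons silent", {
  cfg <- small_cfg(p_ei = 0, p_ii = 0)
  res <- simulate_network(cfg)
  expect_equal(sum(res$raster$population == "fast_spiking"), 0)
  # pyramidal frequency equals the isolated-neuron prediction
  f_pop <- population_frequency(res$raster, "pyramidal", burn_in = 200)
  f_iso <- fi_curve(izhikevich_params("pyramidal"), 10, duration = 1000,
                    burn_in = 200)$frequency_hz
  expect_equal(f_pop, f_iso, tolerance = 0.05)
})

test_that("population_frequency pools interspike intervals correctly", {
  # every neuron spiking every 10 ms -> 100 Hz
  r <- data.frame(neuron_id = rep(0:4, each = 10), population = "pyramidal",
                  time_ms = rep(seq(0, 90, 10), 5) + 1000)
  expect_equal(population_frequency(r, "pyramidal"), 100)
  # ISIs {10,10} and {20,20} pooled -> 1000/15
  r2 <- data.frame(neuron_id = c(0, 0, 0, 1, 1, 1), population = "pyramidal",
                   time_ms = c(0, 10, 20, 0, 20, 40) + 600)
  expect_equal(population_frequency(r2, "pyramidal"), 1000 / 15)
  expect_error(population_frequency(r2[0, ], "pyramidal"), "undefined")
})

test_that("f-I curves are monotone and fast-spiking cells outpace pyramidal", {
  iv <- c(0, 2, 5, 10, 20, 40)
  fp <- fi_curve(izhikevich_params("pyramidal"), iv, duration = 1500)
  ff <- fi_curve(izhikevich_params("fast_spiking"), iv, duration = 1500)
  expect_equal(fp$frequency_hz[1], 0)  # resting fixed point at I = 0
  expect_true(all(diff(fp$frequency_hz) >= -1e-9))
  expect_true(all(diff(ff$frequency_hz) >= -1e-9))
  supra <- iv >= 10
  expect_true(all(ff$frequency_hz[supra] > fp$frequency_hz[supra]))
})
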