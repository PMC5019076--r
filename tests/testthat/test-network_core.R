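test_that("lattice construction initializes neurons at rest", {
  p <- izh_params(a = 0.1, b = 0.2, c = -65, d = 2)
  lat <- build_lattice("GPi", 2, p)
  expect_equal(dim(lat$v), c(2, 2))
  expect_true(all(lat$v == -65))
  expect_true(all(lat$u == 0.2 * -65))
  expect_false(any(lat$spiked))

  big <- build_lattice("STN", 50, izh_params(0.005, 0.265, -65, 2))
  expect_equal(length(big$v), 2500)

  expect_error(build_lattice("STN", 0, p), "shape")
  expect_error(izh_params(a = -1, b = 0.2, c = -65, d = 2), "positive")
  expect_error(izh_params(a = 0.1, b = 0.2, c = 40, d = 2), "below v_peak")
})

test_that("spike reset contract: crossing v_peak iff spiked, then v = c", {
  p <- izh_params(a = 0.1, b = 0.2, c = -65, d = 2)
  res <- izhikevich_step(v = 35, u = 0, I = 0, params = p, dt = 0.5)
  expect_true(res$spiked)
  expect_equal(res$v, -65)

  # property: over random states the reset fires exactly when the Euler
  # update reaches v_peak, and post-step v never exceeds v_peak
  set.seed(11)
  for (k in 1:200) {
    v <- runif(1, -80, 40)
    u <- runif(1, -20, 20)
    I <- runif(1, -10, 30)
    vn_raw <- v + 0.5 * (0.04 * v^2 + 5 * v + 140 - u + I)
    res <- izhikevich_step(v, u, I, p, 0.5)
    expect_identical(res$spiked, vn_raw >= p$v_peak)
    expect_lt(res$v, p$v_peak)
    if (res$spiked) expect_equal(res$v, p$c)
  }
})

test_that("resting neuron stays subthreshold with no input", {
  p <- izh_params(a = 0.1, b = 0.2, c = -65, d = 2)
  v <- p$c
  u <- p$b * p$c
  for (k in 1:1000) {
    res <- izhikevich_step(v, u, 0, p, 0.5)
    v <- res$v
    u <- res$u
    expect_false(res$spiked)
  }
  expect_true(is.finite(v) && is.finite(u))
})

test_that("vectorized lattice step reproduces scalar reference integration", {
  p <- izh_params(a = 0.1, b = 0.2, c = -65, d = 2)
  steps <- 2000  # 1000 ms at dt = 0.5
  ref <- ref_izh(p, I = 10, dt = 0.5, steps = steps)
  v <- matrix(p$c, 2, 2)
  u <- p$b * v
  count <- 0L
  vtr <- numeric(steps)
  for (k in seq_len(steps)) {
    res <- izhikevich_step(v, u, 10, p, 0.5)
    v <- res$v
    u <- res$u
    count <- count + sum(res$spiked) / 4
    vtr[k] <- v[1, 1]
  }
  expect_identical(vtr, ref$v)        # bitwise: same arithmetic, same order
  expect_equal(count, ref$n_spikes)
})

test_that("tonic-input spike count is stable under step refinement", {
  # forward Euler at dt = 0.5 ms carries a known step error for a
  # fast-spiking neuron under strong tonic drive; the rate must stay
  # within 20% of the dt/10 reference integration
  p <- izh_params(a = 0.1, b = 0.2, c = -65, d = 2)
  coarse <- ref_izh(p, I = 10, dt = 0.5, steps = 2000)$n_spikes
  fine <- ref_izh(p, I = 10, dt = 0.05, steps = 20000)$n_spikes
  expect_lt(abs(coarse - fine) / fine, 0.2)
})

test_that("lateral connectivity matches brute-force disc enumeration", {
  expect_true(all(build_connectivity(5, 0)$counts == 0))

  for (r in c(1.4, 1.6, 2, 3.3)) {
    cn <- build_connectivity(9, r)
    centre <- (5 - 1) * 9 + 5  # interior neuron (5, 5) of 9 x 9
    expect_equal(cn$counts[centre], ref_disc_count(r),
                 label = sprintf("radius %s", r))
  }
  # radius 1.4 excludes the diagonals (sqrt(2) > 1.4): 4 neighbours;
  # radius 1.6 takes the full 8-neighbour ring
  expect_equal(build_connectivity(9, 1.4)$counts[(5 - 1) * 9 + 5], 4L)
  expect_equal(build_connectivity(9, 1.6)$counts[(5 - 1) * 9 + 5], 8L)

  # no wraparound: the corner neuron sees only the in-lattice part
  cn <- build_connectivity(9, 1.6)
  expect_equal(cn$counts[1], 3L)

  # neighbour lists never include the neuron itself
  expect_false(any(vapply(seq_along(cn$neighbors),
                          function(i) i %in% cn$neighbors[[i]], logical(1))))

  expect_error(build_connectivity(5, -1), "radius")
})

test_that("connectivity counts are symmetric under lattice rotations", {
  for (r in c(1.6, 3.3)) {
    counts <- matrix(build_connectivity(8, r)$counts, 8, 8)
    rot <- counts
    for (k in 1:3) {
      rot <- t(apply(rot, 2, rev))  # rotate 90 degrees
      expect_equal(rot, counts)
    }
  }
})

test_that("decoupled network equals independent single-neuron integration", {
  cond <- tiny_condition(shape = 4L,
                         weights = list(w_sg = 0, w_gs = 0, w_strd1_gpi = 0,
                                        w_strd2_gpe = 0, w_stn_gpi = 0,
                                        w_lat_stn = 0, w_lat_gpe = 0))
  steps <- 600
  st <- network_state(cond)
  zero <- matrix(0, 4, 4)
  vtr <- matrix(NA_real_, steps, 3)
  for (k in seq_len(steps)) {
    st <- step_network(st, cond, zero, zero)
    vtr[k, ] <- c(st$stn$v[2, 3], st$gpe$v[2, 3], st$gpi$v[2, 3])
  }
  for (j in 1:3) {
    nuc <- c("stn", "gpe", "gpi")[j]
    ref <- ref_izh(cond$params[[nuc]], I = cond$baseline[[nuc]], dt = cond$dt,
                   steps = steps)
    expect_identical(vtr[, j], ref$v)
  }
})

test_that("compiled trial core and R reference step agree bitwise", {
  cond <- tiny_condition(shape = 4L)
  steps <- 300
  N <- 16
  set.seed(7)
  msn_d1 <- matrix(rbinom(steps * N, 1, 0.02), steps, N)
  msn_d2 <- matrix(rbinom(steps * N, 1, 0.02), steps, N)
  core <- bgspike:::.core_config(cond, race_enabled = FALSE, n_steps = steps)
  raw <- bgspike:::cpp_run_trial(core, c(0, 0, 0, 0), msn_d1, msn_d2,
                                 list(rasters = TRUE, stn_pop = TRUE,
                                      gpi_half_steps = FALSE, vtrace = TRUE,
                                      ztrace = FALSE))
  st <- network_state(cond)
  ras <- array(0L, c(steps, N, 3))
  vtr <- matrix(0, steps, 3)
  for (k in seq_len(steps)) {
    st <- step_network(st, cond, matrix(msn_d1[k, ], 4, 4),
                       matrix(msn_d2[k, ], 4, 4))
    ras[k, , 1] <- as.integer(st$stn$spiked)
    ras[k, , 2] <- as.integer(st$gpe$spiked)
    ras[k, , 3] <- as.integer(st$gpi$spiked)
    vtr[k, ] <- c(st$stn$v[1, 1], st$gpe$v[1, 1], st$gpi$v[1, 1])
  }
  expect_identical(matrix(raw$stn_raster, steps, N), ras[, , 1])
  expect_identical(matrix(raw$gpe_raster, steps, N), ras[, , 2])
  expect_identical(matrix(raw$gpi_raster, steps, N), ras[, , 3])
  expect_identical(matrix(raw$vtrace, steps, 3), vtr)
  expect_gt(sum(ras), 0)  # the comparison exercised real spiking
})

test_that("a GPe volley drives the STN current negative on the next step", {
  cond <- tiny_condition(shape = 4L)
  st <- network_state(cond)
  st$gpe$spiked <- matrix(TRUE, 4, 4)
  zero <- matrix(0, 4, 4)
  st <- step_network(st, cond, zero, zero)
  expect_true(all(st$traces$stn_gaba > 0))
  # inhibitory entry carries negative sign in the current sum
  I_stn <- cond$baseline$stn + st$traces$stn_lat - st$traces$stn_gaba
  expect_true(all(I_stn < 0))  # w_gs = 18 dominates the baseline
})

test_that("hand-computed synaptic currents on a 2x2 network", {
  cond <- tiny_condition(shape = 2L)
  w <- cond$weights
  dec_glut <- exp(-cond$dt / cond$tau_syn$glut)
  dec_gaba <- exp(-cond$dt / cond$tau_syn$gaba)
  st <- network_state(cond)

  # step 1: D1 spike at (1, 1); STN neuron (2, 2) spiked on the previous step
  st$stn$spiked <- matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2)
  d1 <- matrix(c(1, 0, 0, 0), 2, 2)
  zero <- matrix(0, 2, 2)
  st <- step_network(st, cond, d1, zero)
  expect_equal(st$traces$gpi_d1, matrix(c(w$w_strd1_gpi, 0, 0, 0), 2, 2))
  # convergent STN -> GPi disc (radius 1.6) covers the whole 2x2 lattice
  expect_equal(st$traces$gpi_glut, matrix(w$w_stn_gpi, 2, 2))

  # step 2: traces decay exponentially, a second D1 spike accumulates
  st$stn$spiked <- matrix(FALSE, 2, 2)
  st <- step_network(st, cond, d1, zero)
  expect_equal(st$traces$gpi_d1[1, 1], w$w_strd1_gpi * dec_gaba + w$w_strd1_gpi)
  expect_equal(st$traces$gpi_glut[2, 2], w$w_stn_gpi * dec_glut)
})

test_that("increasing GABAergic drive never increases target firing", {
  # statistical sign-correctness check: stronger D2 (inhibitory) input to
  # GPe lowers the GPe spike count
  cond <- tiny_condition(shape = 6L)
  core <- bgspike:::.core_config(cond, race_enabled = FALSE, n_steps = 800)
  counts <- sapply(1:5, function(s) {
    set.seed(s)
    lo <- bgspike:::cpp_run_trial(core, c(0, 0, 2, 2), NULL, NULL,
                                  list(rasters = FALSE, stn_pop = FALSE,
                                       gpi_half_steps = FALSE,
                                       vtrace = FALSE, ztrace = FALSE))
    set.seed(s)
    hi <- bgspike:::cpp_run_trial(core, c(0, 0, 40, 40), NULL, NULL,
                                  list(rasters = FALSE, stn_pop = FALSE,
                                       gpi_half_steps = FALSE,
                                       vtrace = FALSE, ztrace = FALSE))
    c(lo = lo$spikes$gpe, hi = hi$spikes$gpe)
  })
  expect_lt(mean(counts["hi", ]), mean(counts["lo", ]))
})

test_that("windowed population activity matches manual counting", {
  # silent raster
  silent <- matrix(0L, 100, 4)
  pa <- population_activity(silent, window_ms = 10, dt = 0.5)
  expect_true(all(pa$activity == 0))

  # one neuron spiking every step: constant 1 after normalization
  ras <- matrix(0L, 100, 4)
  ras[, 2] <- 1L
  pa <- population_activity(ras, window_ms = 10, dt = 0.5)
  expect_true(all(pa$activity == 1))

  # known counts: 3 spikes in window 1, 6 in window 2 -> 0.5, 1
  ras <- matrix(0L, 40, 2)
  ras[c(1, 5, 9), 1] <- 1L
  ras[21:26, 2] <- 1L
  pa <- population_activity(ras, window_ms = 10, dt = 0.5)
  expect_equal(pa$activity, c(0.5, 1))

  expect_equal(nrow(population_activity(matrix(0L, 0, 4), 10)), 0)
  expect_error(population_activity(silent, window_ms = 0), "positive")
})

test_that("numerical divergence is reported with the nucleus name", {
  p <- izh_params(a = 0.1, b = 0.2, c = -65, d = 2)
  expect_error(izhikevich_step(1e308, 0, 1e308, p, 0.5, name = "GPe"),
               "divergence in GPe")
})
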