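test_that("correlation detection thresholds the lagged output product", {
  # silent network: product 0 crosses neither threshold
  ev <- detect_correlations(numeric(3), numeric(3), pre = 1:2, post = 2:3,
                            theta_hi = 0.1, theta_lo = -0.1)
  expect_length(ev$idx, 0L)
  expect_identical(ev$n_corr + ev$n_decorr, 0L)

  # high pre followed by high post: 0.9 * 0.9 = 0.81 > 0.1 emits +alpha
  ev <- detect_correlations(c(0.9, 0), c(0, 0.9), pre = 1L, post = 2L,
                            theta_hi = 0.1, theta_lo = -0.1, alpha = 0.1)
  expect_identical(ev$idx, 1L)
  expect_identical(ev$delta, 0.1)

  # boundary: product exactly at theta_hi emits nothing (strict inequality)
  ev <- detect_correlations(c(0.5, 0), c(0, 0.2), pre = 1L, post = 2L,
                            theta_hi = 0.1, theta_lo = -0.1)
  expect_length(ev$idx, 0L)

  # strong anti-correlation emits -beta
  ev <- detect_correlations(c(1, 0), c(0, -0.09), pre = 1L, post = 2L,
                            theta_hi = 0.1, theta_lo = -0.05, beta = 0.1)
  expect_identical(ev$delta, -0.1)
})

test_that("threshold homeostasis follows the windowed rate band", {
  pp <- plasticity_params()   # mu 0.5 %/s, band [0.1, 2.5] %/s, eta 0.002/s
  th0 <- list(theta_hi = 0.1, theta_lo = -0.1,
              corr_queue = numeric(0), decorr_queue = numeric(0))
  n_syn <- 10000L
  dt <- 0.2

  # 3 %/s measured (above 2.5 %/s): theta_hi grows by eta * dt = 0.0004
  th <- update_thresholds(th0, n_corr = 0.03 * n_syn * dt, n_decorr = 0,
                          n_synapses = n_syn, params = pp, dt = dt)
  expect_equal(th$theta_hi, 0.1 + 0.0004)

  # 0.05 %/s (below 0.1 %/s): theta_hi shrinks by the same step
  th <- update_thresholds(th0, n_corr = 0.0005 * n_syn * dt, n_decorr = 0,
                          n_synapses = n_syn, params = pp, dt = dt)
  expect_equal(th$theta_hi, 0.1 - 0.0004)

  # exactly at the target: dead band, no change
  th <- update_thresholds(th0, n_corr = 0.005 * n_syn * dt,
                          n_decorr = 0.005 * n_syn * dt,
                          n_synapses = n_syn, params = pp, dt = dt)
  expect_equal(th$theta_hi, 0.1)
  expect_equal(th$theta_lo, -0.1)

  # theta_hi floors at zero; |theta_lo| adapts symmetrically off its queue
  th <- update_thresholds(list(theta_hi = 0.0002, theta_lo = -0.0002,
                               corr_queue = numeric(0),
                               decorr_queue = numeric(0)),
                          0, 0, n_syn, pp, dt)
  expect_identical(th$theta_hi, 0)
  expect_identical(th$theta_lo, 0)

  # the queue is first-in-first-out over window/dt entries
  th <- th0
  for (k in 1:60) th <- update_thresholds(th, 10, 0, n_syn, pp, dt)
  expect_length(th$corr_queue, round(pp$window / dt))

  expect_error(update_thresholds(th0, 0, 0, 0L, pp, dt), "n_synapses")
})

test_that("traces decay geometrically and integrate events impulsively", {
  none <- list(idx = integer(0), delta = numeric(0))
  # one decay step: factor 1 - 0.2/4 = 0.95
  expect_equal(update_traces(1, none, tau_c = 4, dt = 0.2), 0.95)
  # 20 event-free steps: exact closed form 0.95^20, near e^-1
  c <- 1
  for (k in 1:20) c <- update_traces(c, none, 4, 0.2)
  expect_equal(c, 0.95^20, tolerance = 1e-14)
  expect_equal(c, exp(-1), tolerance = 0.03)
  # a single +alpha event lands at full magnitude
  c <- update_traces(numeric(5), list(idx = 3L, delta = 0.1), 4, 0.2)
  expect_identical(c, c(0, 0, 0.1, 0, 0))
  expect_error(update_traces(1, none, tau_c = 0.1, dt = 0.2), "tau_c")
})

test_that("modulation integrates reward and decays to its fixed point", {
  pp <- plasticity_params(baseline = 0, lambda = 1)
  # pure decay with tau_m = 1 s: factor 0.8 per 0.2-s step
  expect_equal(update_modulation(1, 0, pp, 0.2), 0.8)
  # reward pulse r = 5 for one step from rest: m jumps to lambda * 5 * dt
  expect_equal(update_modulation(0, 5, pp, 0.2), 1)
  # constant baseline: iterated map converges to tau_m * b
  ppb <- plasticity_params(baseline = -0.001)
  m <- 0
  for (k in 1:400) m <- update_modulation(m, 0, ppb, 0.2)
  expect_equal(m, ppb$tau_m * ppb$baseline, tolerance = 1e-9)
})

test_that("weight updates are modulated, plastic-only and clipped", {
  w <- c(0.2, 0.5)
  plastic <- c(TRUE, FALSE)
  # no modulation: bitwise unchanged
  expect_identical(apply_weight_update(w, plastic, 0, c(1, 1), 0.2), w)
  # Euler step m * c * dt on the plastic synapse only
  w2 <- apply_weight_update(w, plastic, 1, c(0.5, 0.5), 0.2)
  expect_equal(w2, c(0.3, 0.5))
  # clipping at the top of the weight interval
  w3 <- apply_weight_update(c(0.9, 0.9), c(TRUE, TRUE), 10, c(1, 1), 0.2)
  expect_identical(w3, c(1, 1))
  # and at the bottom
  w4 <- apply_weight_update(c(0.05, 0), c(TRUE, TRUE), -10, c(1, 1), 0.2)
  expect_identical(w4, c(0, 0))
})
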