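# Spike <-> rate converters and their invariance properties.

test_that("binned conversion normalizes by cell count and bin width", {
  r <- data.frame(gid = c(1, 2, 3), t_ms = c(10.2, 10.5, 10.9))
  tr <- spikes_to_rate_binned(r, N = 10, bin_width = 1, span = c(10, 11))
  expect_equal(tr$nu, 0.3)  # 3 spikes / (10 cells * 1 ms) = 0.3 kHz per cell
  empty <- spikes_to_rate_binned(r[0, ], N = 10, bin_width = 1, span = c(0, 20))
  expect_true(all(empty$nu == 0))
  expect_error(spikes_to_rate_binned(r, 10, 1, span = c(5, 5)), "empty")
})

test_that("converters are invariant under population duplication", {
  set.seed(1)
  base <- data.frame(gid = sample(1:10, 200, TRUE),
                     t_ms = sort(runif(200, 0, 1000)))
  doubled <- rbind(base, transform(base, gid = gid + 10))
  b1 <- spikes_to_rate_binned(base, 10, 5, c(0, 1000))
  b2 <- spikes_to_rate_binned(doubled, 20, 5, c(0, 1000))
  expect_equal(b1$nu, b2$nu)
  c1 <- ca_activity(base, 10, dt = 1, span = c(0, 1000))
  c2 <- ca_activity(doubled, 20, dt = 1, span = c(0, 1000))
  expect_equal(c1$nu, c2$nu)
})

test_that("calcium filter follows the single-spike closed form", {
  r <- data.frame(gid = 1, t_ms = 100)
  tau <- 100
  tr <- ca_activity(r, N = 1, params = ca_filter_params(tau_ca = tau, beta_ca = 0.1),
                    dt = 0.5, span = c(0, 400))
  # C(t0 + tau) = 0.1 * exp(-1)
  v <- tr$nu[tr$t_ms == 100 + tau]
  expect_equal(v, 0.1 * exp(-1), tolerance = 1e-9)
  expect_true(all(tr$nu[tr$t_ms < 100] == 0))
  expect_true(all(tr$nu >= 0))
  # no spikes -> identically zero
  z <- ca_activity(r[0, ], N = 3, dt = 1, span = c(0, 100))
  expect_true(all(z$nu == 0))
})

test_that("calcium trace decays below 1e-6 within 15 tau of the last spike", {
  r <- data.frame(gid = 1, t_ms = c(50, 60, 70))
  tr <- ca_activity(r, N = 1, params = ca_filter_params(100, 0.1),
                    dt = 5, span = c(0, 70 + 15 * 100))
  expect_lt(tail(tr$nu, 1), 1e-6)
})

test_that("stationary calcium mean approximates beta * r * tau", {
  # regular 50 Hz train over 100 s; time-average of the filter is
  # beta * rate * tau for a periodic train
  st <- seq(10, 100e3, by = 20)  # 50 Hz in ms units -> rate 0.05 kHz
  r <- data.frame(gid = 1, t_ms = st)
  tr <- ca_activity(r, N = 1, params = ca_filter_params(100, 0.1),
                    dt = 1, span = c(0, 100e3))
  stationary <- mean(tr$nu[tr$t_ms > 2000])
  expect_equal(stationary, 0.1 * 0.05 * 100, tolerance = 0.02)
})

test_that("binned and calcium converters agree up to the factor beta * tau
           in a stationary regime", {
  st <- seq(5, 60e3, by = 12.5)  # 80 Hz regular
  r <- data.frame(gid = 1, t_ms = st)
  binned <- spikes_to_rate_binned(r, 1, 100, c(2000, 60e3))
  ca <- ca_activity(r, 1, ca_filter_params(100, 0.1), dt = 1, span = c(0, 60e3))
  ratio <- mean(ca$nu[ca$t_ms > 2000]) / mean(binned$nu)
  expect_equal(ratio, 0.1 * 100, tolerance = 0.02)
})

test_that("proxy scaling is linear in G_A and zero activity contributes nothing", {
  a <- data.frame(nu = c(0, 0.002, 0.01))
  expect_equal(proxy_to_tvb(a, 100), c(0, 0.2, 1))
  expect_equal(proxy_to_tvb(a, 200), 2 * proxy_to_tvb(a, 100))
})

test_that("rate-to-event generation follows the Poisson law and is
           reproducible", {
  # zero rate -> no events
  z <- rate_to_events(0, 1, c(0, 10), n_cells = 5, seed = 3)
  expect_equal(nrow(z), 0)
  expect_error(rate_to_events(-1, 1, c(0, 10), 1), "negative")
  # lambda = 5: empirical mean over many epochs within sampling error
  lam_counts <- vapply(1:4000, function(k) {
    ev <- rate_to_events(nu_I = 0.5, c_IP = 1, epoch = c(0, 10), n_cells = 1,
                         gain = 1, seed = k)
    nrow(ev)
  }, numeric(1))
  expect_equal(mean(lam_counts), 5, tolerance = 4 * sqrt(5 / 4000) / 5)
  # determinism: same seed, same raster
  a <- rate_to_events(0.4, 0.7, c(50, 60), n_cells = 3, seed = 11)
  b <- rate_to_events(0.4, 0.7, c(50, 60), n_cells = 3, seed = 11)
  expect_identical(a, b)
  # every event dispatched to all cells with the delay applied
  ev <- rate_to_events(2, 1, c(0, 10), n_cells = 4, delay = 3, seed = 5)
  if (nrow(ev) > 0) {
    expect_equal(sort(unique(ev$gid)), 1:4)
    expect_true(all(ev$t_ms >= 3 & ev$t_ms <= 13))
    k <- nrow(ev) / 4
    expect_equal(unname(table(ev$gid)), rep(k, 4), ignore_attr = TRUE)
  }
})
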