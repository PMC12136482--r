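# Reduced Wong-Wang mass model: transfer function, fixed points, delayed
# network integration and its invariants.

.toy_conn <- function(n = 3, w = 0.05, len = 6) {
  W <- matrix(w, n, n); diag(W) <- 0
  L <- matrix(len, n, n); diag(L) <- 0
  connectome(W, L)  # speed 3 -> delays len/3 ms
}

test_that("H has the removable singularity value 1/d and is monotone", {
  p <- rww_params()
  x_star <- p$b / p$a
  expect_equal(firing_rate(x_star, p), 1 / p$d, tolerance = 1e-9)
  # approach from both sides converges to 1/d
  for (h in 10^(-c(9, 10, 12))) {
    expect_equal(firing_rate(x_star + h, p) * p$d, 1, tolerance = 1e-7)
    expect_equal(firing_rate(x_star - h, p) * p$d, 1, tolerance = 1e-7)
  }
  # direct evaluation at a x - b = 10/d
  x10 <- (p$b + 10 / p$d) / p$a
  expect_equal(firing_rate(x10, p), (10 / p$d) / (1 - exp(-10)), tolerance = 1e-12)
  # monotone and positive over a dense grid spanning the singularity
  g <- firing_rate(seq(-2, 2, length.out = 4001), p)
  expect_true(all(g > 0))
  expect_true(all(diff(g) > 0))
})

test_that("the isolated fixed point from root search matches the simulation", {
  p <- rww_params()
  S_star <- rww_fixed_point(p)
  # independent bisection oracle on the stated balance equation
  f <- function(S) S / p$tau_s -
    (1 - S) * p$gamma_kin * firing_rate(p$omega * p$J_N * S + p$I_0, p)
  lo <- 0; hi <- 1
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  expect_equal(S_star, (lo + hi) / 2, tolerance = 1e-8)

  # G = 0: every region relaxes to S* regardless of the connectome
  cn <- .toy_conn()
  sim <- simulate_rww(cn, rww_params(G = 1e-12), T = 3000, dt = 0.1,
                      record_every = 100)
  expect_equal(unname(sim$state$S), rep(S_star, 3), tolerance = 1e-4)
})

test_that("drive is positive at S = 0 and trajectories stay in [0, 1]", {
  p <- rww_params()
  cn <- .toy_conn()
  r <- rww_rhs(rep(0, 3), cn, p)
  expect_true(all(r$dS > 0))
  expect_equal(unname(r$dS), rep(p$gamma_kin * firing_rate(p$I_0, p), 3))
  sim <- simulate_rww(cn, p, T = 2000, dt = 0.1, record_every = 50)
  expect_true(all(sim$S >= 0 & sim$S <= 1))
})

test_that("symmetric two-region systems stay symmetric", {
  cn <- .toy_conn(n = 2, w = 0.1)
  sim <- simulate_rww(cn, rww_params(), T = 1000, dt = 0.1, record_every = 10)
  expect_equal(sim$S[, 1], sim$S[, 2], ignore_attr = TRUE)
})

test_that("region permutation with equal delays permutes the output", {
  set.seed(3)
  n <- 4
  W <- matrix(runif(n * n, 0, 0.1), n, n); diag(W) <- 0
  L <- matrix(6, n, n); diag(L) <- 0
  cn <- connectome(W, L)
  perm <- c(3, 1, 4, 2)
  cnp <- connectome(W[perm, perm], L[perm, perm])
  S0 <- seq(0.001, 0.004, length.out = n)
  st <- rww_initial_state(cn, 0.1, S0)
  stp <- rww_initial_state(cnp, 0.1, S0[perm])
  a <- simulate_rww(cn, T = 500, dt = 0.1, state = st, record_every = 100)
  b <- simulate_rww(cnp, T = 500, dt = 0.1, state = stp, record_every = 100)
  expect_equal(a$S[, perm], b$S, ignore_attr = TRUE)
})

test_that("epoch-chunked integration equals the monolithic run bitwise", {
  cn <- .toy_conn(n = 3, w = 0.08)
  mono <- simulate_rww(cn, T = 400, dt = 0.1)
  epoch <- cn$tau_min
  st <- NULL
  vals <- list()
  k <- 0
  t_done <- 0
  while (t_done < 400) {
    out <- simulate_rww(cn, T = epoch, dt = 0.1, state = st, check_dt = FALSE)
    st <- out$state
    t_done <- t_done + epoch
    k <- k + 1
    keep <- if (t_done < 400) seq_len(length(out$t_ms) - 1) else seq_along(out$t_ms)
    vals[[k]] <- out$S[keep, , drop = FALSE]
  }
  S_chunked <- do.call(rbind, vals)
  expect_identical(S_chunked, mono$S[seq_len(nrow(S_chunked)), ])
})

test_that("a step that does not divide tau_min is rejected", {
  cn <- .toy_conn(len = 6)  # tau_min = 2 ms
  expect_error(simulate_rww(cn, T = 10, dt = 0.3), "does not evenly divide")
  expect_silent({res <- simulate_rww(cn, T = 10, dt = 0.1)})
})

test_that("halving dt changes S(1 s) below tolerance", {
  cn <- .toy_conn(n = 3, w = 0.08)
  a <- simulate_rww(cn, T = 1000, dt = 0.1, record_every = 10000)
  b <- simulate_rww(cn, T = 1000, dt = 0.05, record_every = 20000)
  expect_equal(a$state$S, b$state$S, tolerance = 1e-4)
})

test_that("missing history is impossible by construction: fresh states carry
           a full constant pre-history", {
  cn <- .toy_conn()
  st <- rww_initial_state(cn, 0.1, 0.007)
  expect_true(all(st$hist == 0.007))
  expect_gte(nrow(st$hist), max(round(cn$delays / 0.1)))
})
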