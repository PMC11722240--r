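test_that("derivatives match the Hill-function forms at hand-checkable states", {
  p <- circuit_params(kn = 0.5, kd = 0.25)

  # at the origin the activation term vanishes and Delta production is maximal
  d0 <- nd_derivatives(c(0, 0), c(0, 0), p)
  expect_equal(d0$dnotch, c(0, 0))
  expect_equal(d0$ddelta, c(p$v, p$v))

  # N = kd is the half-maximal point of the inhibition Hill function
  dh <- nd_derivatives(c(0.25, 0.25), c(0.5, 0.5), p)
  expect_equal(dh$ddelta, c(0, 0), tolerance = 1e-12)

  # independent scalar evaluation of the default-state derivatives
  nn <- c(0.010, 0.011); dd <- c(1, 1)
  dn_expected <- c(1^2 / (0.5^2 + 1^2) - 0.010, 1^2 / (0.5^2 + 1^2) - 0.011)
  dd_expected <- 1 * (1 / (1 + (nn / 0.25)^2) - 1)
  d <- nd_derivatives(nn, dd, p)
  expect_equal(d$dnotch, dn_expected, tolerance = 1e-14)
  expect_equal(d$ddelta, dd_expected, tolerance = 1e-14)
})

test_that("invalid parameters and topologies are rejected", {
  expect_error(circuit_params(kn = 0, kd = 1), "kn")
  expect_error(circuit_params(kn = 1, kd = -1), "kd")
  expect_error(circuit_params(kn = 1, kd = 1, beta = -1), "beta")
  p <- circuit_params(0.5, 0.25)
  expect_error(nd_derivatives(c(0, 0), c(0, 0), p,
                              topology = list(2L, integer(0))), "neighbour")
  expect_error(nd_derivatives(c(-0.1, 0), c(0, 0), p), ">= 0")
  expect_error(simulate_pair(p, t_end = -1), "t_end")
})

test_that("symmetric initial conditions give identical trajectories", {
  p <- circuit_params(kn = 0.5, kd = 0.25)
  tr <- simulate_pair(p, init_notch = c(0.01, 0.01))
  expect_equal(tr$notch[, 1], tr$notch[, 2], tolerance = 1e-7)
  expect_equal(tr$delta[, 1], tr$delta[, 2], tolerance = 1e-7)

  tr3 <- simulate_triplet(p, init_notch = rep(0.01, 3))
  expect_equal(tr3$notch[, 1], tr3$notch[, 3], tolerance = 1e-7)
  expect_equal(tr3$delta[, 2], tr3$delta[, 3], tolerance = 1e-7)
})

test_that("permuting cell labels permutes trajectories", {
  p <- circuit_params(kn = 0.5, kd = 0.25)
  a <- simulate_pair(p, init_notch = c(0.010, 0.011))
  b <- simulate_pair(p, init_notch = c(0.011, 0.010))
  expect_equal(a$notch[, 2], b$notch[, 1], tolerance = 1e-7)
  expect_equal(a$delta[, 2], b$delta[, 1], tolerance = 1e-7)
})

test_that("pair dynamics agree with the fixed-step RK4 oracle at both reference points", {
  # Point 1 (kn=0.5, kd=0.25): healthy-like feedback; Point 2 (kd=1): injury-like
  for (kd in c(0.25, 1)) {
    p <- circuit_params(kn = 0.5, kd = kd)
    tr <- simulate_pair(p)
    orc <- oracle_point(kd)
    idx <- match(round(orc$times, 8), round(tr$times, 8))
    expect_lt(max(abs(tr$notch[idx, ] - orc$notch)), 1e-5)
    expect_lt(max(abs(tr$delta[idx, ] - orc$delta)), 1e-5)
  }

  # frozen oracle values at t=10 (computed with rk4_nd_oracle, dt=1e-4):
  # the slight initial Notch advantage of cell 2 has only begun to amplify
  # by t=10 at Point 1, and at Point 2 the homogeneous high-Notch/high-Delta
  # state is stable
  tr1 <- simulate_pair(circuit_params(0.5, 0.25))
  expect_equal(unname(tr1$notch[nrow(tr1$notch), ]),
               c(0.33368996, 0.33887817), tolerance = 1e-4)
  expect_equal(unname(tr1$delta[nrow(tr1$delta), ]),
               c(0.35866276, 0.35325304), tolerance = 1e-4)
  tr2 <- simulate_pair(circuit_params(0.5, 1))
  expect_equal(unname(tr2$delta[nrow(tr2$delta), ]),
               c(0.69660612, 0.69659629), tolerance = 1e-4)
})

test_that("lateral inhibition amplifies the initial asymmetry and resolves fates over long times", {
  p <- circuit_params(kn = 0.5, kd = 0.25)
  tr <- simulate_pair(p, t_end = 50)
  at <- function(t) which.min(abs(tr$times - t))
  gap <- abs(tr$notch[, 2] - tr$notch[, 1])
  # the 0.001 asymmetry grows monotonically in time...
  expect_gt(gap[at(10)], gap[at(1)])
  expect_gt(gap[at(25)], gap[at(10)])
  # ...and by t=50 the pair has resolved into opposite fates
  expect_gt(tr$notch[at(50), 2], 0.75)
  expect_lt(tr$delta[at(50), 2], 0.1)
  expect_gt(tr$delta[at(50), 1], 0.9)
})

test_that("triplet simulations agree with the RK4 oracle and break symmetry toward the seeded cell", {
  for (kd in c(0.25, 1)) {
    p <- circuit_params(kn = 0.5, kd = kd)
    tr <- simulate_triplet(p)
    orc <- oracle_point(kd, cells = 3L)
    idx <- match(round(orc$times, 8), round(tr$times, 8))
    expect_lt(max(abs(tr$notch[idx, ] - orc$notch)), 1e-5)
    expect_lt(max(abs(tr$delta[idx, ] - orc$delta)), 1e-5)
    # the seeded cell (3) leads in Notch; the injury regime (kd=1) keeps
    # its Delta high while the healthy regime pushes it lower
    last <- nrow(tr$notch)
    expect_gt(tr$notch[last, 3], tr$notch[last, 1])
    expect_lt(tr$delta[last, 3], tr$delta[last, 1])
    if (kd == 1) expect_gt(tr$delta[last, 3], 0.5)
  }
})

test_that("state stays bounded in [0, 1] for defaults and unit-box initial conditions", {
  p <- circuit_params(kn = 0.5, kd = 0.25)
  set.seed(42)
  for (i in 1:5) {
    tr <- simulate_pair(p, init_notch = runif(2), init_delta = runif(2))
    expect_true(all(tr$notch >= -1e-6 & tr$notch <= 1 + 1e-6))
    expect_true(all(tr$delta >= -1e-6 & tr$delta <= 1 + 1e-6))
  }
})

test_that("reporter accumulation integrates Notch with beta scaling", {
  # zero integrand
  tzero <- make_traj(seq(0, 1, by = 0.1), matrix(0, 11, 2))
  expect_true(all(reporter_accumulation(tzero) == 0))

  # unit integrand: reporter(t) = t
  tone <- make_traj(seq(0, 2, by = 0.01), matrix(1, 201, 2))
  expect_equal(reporter_accumulation(tone, beta = 1)[, 1],
               seq(0, 2, by = 0.01), tolerance = 1e-12)
  expect_equal(reporter_accumulation(tone, beta = 2.5)[, 2],
               2.5 * seq(0, 2, by = 0.01), tolerance = 1e-12)

  expect_error(reporter_accumulation(tone, beta = -1), "beta")

  # arbitrary Point-1 trajectory vs the plain-loop trapezoid oracle
  tr <- simulate_pair(circuit_params(0.5, 0.25))
  rep2 <- reporter_accumulation(tr, beta = 1)[, 2]
  orc <- trapz_oracle(tr$times, tr$notch[, 2])
  expect_lt(max(abs(rep2[-1] - orc[-1]) / orc[-1]), 1e-6)
  # monotone non-decreasing
  expect_true(all(diff(rep2) >= 0))
})

test_that("the full reporter ODE reduces to the running integral as alpha -> 0", {
  tr <- simulate_pair(circuit_params(0.5, 0.25))
  r_int <- reporter_accumulation(tr, beta = 1)
  r_ode <- reporter_accumulation(tr, beta = 1, alpha = 1e-6, mode = "ode")
  expect_lt(max(abs(r_int - r_ode)), 1e-4)
  # with substantial degradation the reporter saturates below the integral
  r_deg <- reporter_accumulation(tr, beta = 1, alpha = 1, mode = "ode")
  expect_true(all(r_deg <= r_int + 1e-12))
})

test_that("steady-state Delta selects the high-Notch cell and obeys the Hill limits", {
  # at enormous kd the inhibition term is ~1, so Delta stays at 1
  expect_equal(steady_state_delta(circuit_params(kn = 0.5, kd = 1e6)), 1,
               tolerance = 1e-4)
  # injury regime keeps the winner's Delta high
  expect_gt(steady_state_delta(circuit_params(0.5, 1)), 0.5)
  # frozen oracle value for the healthy point at t=10
  expect_equal(steady_state_delta(circuit_params(0.5, 0.25)), 0.35325304,
               tolerance = 1e-4)
})

test_that("signalling speed is the windowed mean reporter rate and is faster at high kd", {
  # speed computed from a trajectory's own reporter series via the
  # independent trapezoid oracle
  tr <- simulate_pair(circuit_params(0.5, 0.25))
  orc <- trapz_oracle(tr$times, tr$notch[, 2])
  speed_oracle <- (orc[tr$times == 10] - orc[tr$times == 4]) / 6
  expect_equal(signaling_speed(circuit_params(0.5, 0.25)), speed_oracle,
               tolerance = 1e-6)
  # the central model prediction: raising kd accelerates Notch output
  expect_gt(signaling_speed(circuit_params(0.5, 1)),
            signaling_speed(circuit_params(0.5, 0.25)))
})

test_that("phase maps evaluate the metric on the grid and degenerate to the scalar ops", {
  pm1 <- phase_map(kn_values = 0.5, kd_values = 0.25,
                   metric = "steady_state_delta")
  expect_equal(dim(pm1$values), c(1L, 1L))
  expect_equal(pm1$values[1, 1], steady_state_delta(circuit_params(0.5, 0.25)))

  expect_error(phase_map(kn_values = numeric(0), kd_values = 1), "non-empty")
  expect_error(phase_map(kn_values = c(-1, 1), kd_values = 1), "positive")

  pm <- phase_map(kn_values = c(0.5, 2), kd_values = c(0.25, 0.5, 1),
                  metric = "signaling_speed")
  expect_true(all(is.finite(pm$values)))
  # speed non-decreasing along kd within each kn row
  expect_true(all(apply(pm$values, 1, function(row) all(diff(row) >= -1e-9))))
  df <- as.data.frame(pm)
  expect_equal(nrow(df), 6L)
  expect_equal(df$value[df$kn == 2 & df$kd == 1], pm$values[2, 3])
})
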