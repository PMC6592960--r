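test_that("sigmoid is zero-centred, saturating, with correct slope", {
  expect_equal(sigmoid_response(0, 2, 1), 0)
  sat <- 1 - 1 / (1 + exp(2 * 1))
  expect_equal(sigmoid_response(1e3, 2, 1), sat, tolerance = 1e-12)
  expect_true(all(diff(sigmoid_response(seq(-5, 5, 0.1), 2, 1)) > 0))

  h <- 1e-6
  num <- (sigmoid_response(h, 2, 1) - sigmoid_response(-h, 2, 1)) / (2 * h)
  expect_equal(dirspec:::sigmoid_slope(0, 2, 1), num, tolerance = 1e-6)
})

test_that("drift vanishes at the origin and obeys the synaptic kinetics", {
  m <- nmm_model()
  expect_equal(nmm_drift(numeric(20), m, "W", 0), numeric(20))
  expect_equal(nmm_drift(numeric(20), m, "A", 0), numeric(20))

  # isolated pair displaced to v = 1: vdot = 0, idot = -kappa^2
  m0 <- nmm_model(gamma = rep(0, 5), a_fwd = 0, a_bwd = 0)
  x <- numeric(20); x[1] <- 1     # stellate voltage of source 1
  dx <- nmm_drift(x, m0, "W", 0)
  expect_equal(dx[1], 0)
  expect_equal(dx[2], -m0$ke[1]^2)
  expect_true(all(dx[-(1:2)] == 0))
})

test_that("analytic Jacobian matches finite differences of the drift", {
  m <- nmm_model(b_fwd = -0.7, b_self = c(0.3, 0.3))
  for (cond in c("W", "A")) {
    set.seed(8)
    x <- rnorm(20, sd = 0.3)
    J <- dirspec:::nmm_jacobian(x, m, cond)
    Jfd <- matrix(0, 20, 20)
    h <- 1e-6
    for (j in 1:20) {
      e <- numeric(20); e[j] <- h
      Jfd[, j] <- (nmm_drift(x + e, m, cond) - nmm_drift(x - e, m, cond)) /
        (2 * h)
    }
    expect_lt(max(abs(J - Jfd)) / max(abs(J)), 1e-6)
  }
})

test_that("fixed points satisfy closed forms and dual-method agreement", {
  m <- nmm_model()
  expect_equal(find_fixed_point(m, "W", 0), numeric(20))

  # intrinsic couplings off: stellate settles at He * C * u0 / ke
  m0 <- nmm_model(gamma = rep(0, 5), a_fwd = 0, a_bwd = 0)
  u0 <- 0.05
  xs <- find_fixed_point(m0, "W", u0)
  expect_equal(xs[1], m0$He[1] * m0$C[1] * u0 / m0$ke[1], tolerance = 1e-9)
  expect_equal(xs[11], m0$He[2] * m0$C[2] * u0 / m0$ke[2], tolerance = 1e-9)

  # Newton against plain relaxation integration on the default model
  xs2 <- find_fixed_point(m, "W", 0.02)
  traj <- deSolve::lsoda(numeric(20), c(0, 3),
                         function(t, y, p) list(nmm_drift(y, m, "W", 0.02)),
                         NULL, rtol = 1e-11, atol = 1e-13)
  expect_lt(max(abs(xs2 - traj[2, -1])), 1e-8)
  expect_lt(max(abs(nmm_drift(xs2, m, "W", 0.02))), 1e-10)
})

test_that("linearization has damped synaptic blocks and correct structure", {
  # uncoupled pair: eigenvalues of each 2x2 block are {-kappa, -kappa}
  m0 <- nmm_model(gamma = rep(0, 5), a_fwd = 0, a_bwd = 0)
  lin <- nmm_linearize(m0, "W")
  blk <- lin$J[1:2, 1:2]
  expect_equal(sort(Re(eigen(blk)$values)), rep(-m0$ke[1], 2))
  expect_true(all(abs(Im(eigen(blk)$values)) < 1e-9))
  # with all couplings zero J is block-diagonal over pairs
  off <- lin$J
  for (b in seq(1, 19, by = 2)) off[b:(b + 1), b:(b + 1)] <- 0
  expect_equal(max(abs(off)), 0)

  # stability flagged by eigenvalue sign
  hot <- nmm_model(gamma = c(128, 128, 64, 2000, 16))
  expect_error(nmm_linearize(hot, "W"), "unstable")
})

test_that("transfer function matches the resolvent closed form and rolls off", {
  # hand-built single synaptic pair: observation of v, input on the current
  kap <- 250; H <- 4
  lin <- list(J = matrix(c(0, -kap^2, 1, -2 * kap), 2, 2),
              B = matrix(c(0, kap * H), 2, 1),
              Cmat = matrix(c(1, 0), 1, 2))
  Tf <- nmm_transfer(lin, c(1e-6, 200, 2000))
  expect_equal(Mod(Tf[1, 1, 1]), H / kap, tolerance = 1e-6)
  # second-order kernel: >= 40 dB/decade fall-off far above the corner
  expect_lt(Mod(Tf[1, 1, 3]) / Mod(Tf[1, 1, 2]), 1.2e-2)

  # uncoupled sources give a diagonal transfer matrix
  m0 <- nmm_model(a_fwd = 0, a_bwd = 0)
  T0 <- nmm_transfer(nmm_linearize(m0, "W"), seq(1, 80, 1))
  expect_lt(max(Mod(T0[1, 2, ])), 1e-14)
  expect_lt(max(Mod(T0[2, 1, ])), 1e-14)
})

test_that("predicted CSD is Hermitian, noise-floored, and condition-consistent", {
  fr <- seq(1, 80, 1)
  m0 <- quiet_nmm(a_fwd = 0, a_bwd = 0)
  G0 <- predict_csd(m0, "W", fr)
  expect_lt(max(Mod(G0$G[1, 2, ])), 1e-20)

  m <- nmm_model(a_fwd = 384, a_bwd = 64)
  G <- predict_csd(m, "W", fr)
  expect_lt(max(abs(G$G - Conj(aperm(G$G, c(2, 1, 3))))), 1e-12)
  expect_true(all(Re(G$G[1, 1, ]) >= 0 & Re(G$G[2, 2, ]) >= 0))

  # with all condition scalings at zero, W and A give identical spectra
  GA <- predict_csd(m, "A", fr)
  expect_equal(G$G, GA$G)

  expect_error(predict_csd(m, "W", c(0, 10)), "positive")
})

test_that("model-derived DTF is row-stochastic and monotone in forward gain", {
  fr <- seq(1, 80, 1)
  m0 <- nmm_model(a_fwd = 0, a_bwd = 0)
  d0 <- model_derived_dtf(m0, "W", fr)
  expect_lt(max(d0$values[1, 2, ], d0$values[2, 1, ]), 1e-20)

  m <- nmm_model(a_fwd = 384, a_bwd = 64)
  d <- model_derived_dtf(m, "W", fr)
  sums <- apply(d$values, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)

  fwd <- vapply(c(100, 200, 300, 400), function(a) {
    dm <- model_derived_dtf(nmm_model(a_fwd = a, a_bwd = 64), "W", fr)
    band_average_dtf(dm, c(3, 40), c("P", "F"))
  }, numeric(1))
  expect_true(all(diff(fwd) > 0))
})

test_that("simulation is seed-reproducible and quiescent without input", {
  m <- quiet_nmm()
  r1 <- simulate_nmm(m, "W", 2, 1000, seed = 123)
  r2 <- simulate_nmm(m, "W", 2, 1000, seed = 123)
  expect_identical(r1$data, r2$data)

  silent <- nmm_model(a_fwd = 384, a_bwd = 64, alpha_u = -60, beta_u = -60,
                      alpha_n = -60, beta_n = -60)
  r0 <- simulate_nmm(silent, "W", 1, 1000, seed = 1)
  expect_lt(max(abs(r0$data)), 1e-10)
})

test_that("simulated spectra converge to the linear prediction as
           innovations shrink", {
  fr <- seq(3, 40, 1)
  band_err <- function(au) {
    m <- nmm_model(a_fwd = 384, a_bwd = 64, alpha_u = log(au), beta_u = -30,
                   alpha_n = log(1e-12), beta_n = -30)
    sim <- simulate_nmm(m, "W", 60, 1000, seed = 77, obs_noise = FALSE)
    est <- estimate_csd_welch(segment_recording(sim, 2, 30), fr)
    pred <- predict_csd(m, "W", fr)
    mean(vapply(1:2, function(ch)
      abs(sum(Re(est$G[ch, ch, ])) - sum(Re(pred$G[ch, ch, ]))) /
        sum(Re(pred$G[ch, ch, ])), numeric(1)))
  }
  errs <- vapply(c(1, 1e-2, 1e-4), band_err, numeric(1))
  # monotone improvement until the Welch sampling floor is reached
  expect_true(all(diff(errs) < 0.02))
  expect_lt(errs[3], 0.25)
})
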