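test_that("lagged covariances match white-noise and Lyapunov oracles", {
  zeros <- segment_set(list(matrix(0, 100, 2), matrix(0, 100, 2)), fs = 100)
  R0 <- lagged_covariance(zeros, 3)
  expect_true(all(vapply(R0$R, function(M) max(abs(M)), numeric(1)) == 0))

  set.seed(21)
  N <- 50000
  wn <- segment_set(list(matrix(rnorm(N), N, 1)), fs = 1000)
  Rw <- lagged_covariance(wn, 1)
  expect_lt(abs(Rw$R[[1]][1, 1] - 1), 5 / sqrt(N))
  expect_lt(abs(Rw$R[[2]][1, 1]), 5 / sqrt(N))

  # AR(1) with A = 0.5: stationary variance 1/(1 - 0.25) = 4/3
  m <- mvar_model(list(matrix(0.5)), matrix(1), fs = 1000)
  expect_equal(mvar_stationary_cov(m, 0)$R[[1]][1, 1], 4 / 3)
  sim <- gen_mvar(m, duration_s = 60, seed = 5)
  Rs <- lagged_covariance(segment_set(list(sim$data), fs = 1000), 1)
  expect_lt(abs(Rs$R[[1]][1, 1] - 4 / 3), 0.05 * 4 / 3)

  expect_error(lagged_covariance(zeros, 150), "s_max")
})

test_that("Yule-Walker recovers models exactly from analytic covariances", {
  A <- matrix(c(0.5, 0.4, -0.2, 0.6), 2, 2)
  truth <- mvar_model(list(A), diag(c(1, 2)), fs = 1000)
  R <- mvar_stationary_cov(truth, 3)

  fit1 <- fit_yule_walker(R, 1, fs = 1000)
  expect_lt(max(abs(fit1$coeffs[[1]] - A)), 1e-8)
  expect_lt(max(abs(fit1$noise_cov - diag(c(1, 2)))), 1e-8)

  # over-parameterized fit: the spurious second lag vanishes
  fit2 <- fit_yule_walker(R, 2, fs = 1000)
  expect_lt(max(abs(fit2$coeffs[[2]])), 1e-6)
  expect_lt(max(abs(fit2$coeffs[[1]] - A)), 1e-6)

  # white noise: all coefficients zero, noise covariance = R(0)
  white <- structure(list(lags = 0:3,
                          R = c(list(diag(2)),
                                replicate(3, matrix(0, 2, 2),
                                          simplify = FALSE)),
                          k = 2L),
                     class = "cov_sequence")
  fitw <- fit_yule_walker(white, 2)
  expect_lt(max(abs(fitw$coeffs[[1]])), 1e-12)
  expect_lt(max(abs(fitw$coeffs[[2]])), 1e-12)
  expect_equal(fitw$noise_cov, diag(2))
})

test_that("BIC order selection finds the generating order", {
  # strongly identified AR(3)
  m3 <- mvar_model(list(matrix(c(0.6, 0.2, -0.1, 0.5), 2, 2),
                        matrix(c(-0.4, 0, 0.1, -0.3), 2, 2),
                        matrix(c(0.3, -0.2, 0.1, 0.3), 2, 2)),
                   diag(2), fs = 1000)
  expect_lt(check_stability(m3), 1)
  hits <- vapply(1:5, function(s) {
    sim <- gen_mvar(m3, duration_s = 30, seed = 100 + s)
    segs <- segment_recording(sim, 2, 15)
    select_order_bic(segs, 1, 10) == 3L
  }, logical(1))
  expect_true(all(hits))

  set.seed(9)
  wn <- segment_set(list(matrix(rnorm(30000 * 2), 30000, 2)), fs = 1000)
  expect_identical(as.integer(select_order_bic(wn, 1, 5)), 1L)

  segs <- segment_recording(gen_mvar(m3, 10, seed = 1), 2, 5)
  expect_identical(as.integer(select_order_bic(segs, 7, 7)), 7L)
  expect_error(select_order_bic(segs, 5, 4), "empty order range")
})

test_that("companion spectral radius reports stability", {
  expect_equal(check_stability(mvar_model(list(matrix(0.5)), matrix(1), 1)), 0.5)
  expect_equal(check_stability(
    mvar_model(list(matrix(0, 2, 2)), diag(2), 1)), 0)
  expect_equal(check_stability(mvar_model(list(matrix(1.01)), matrix(1), 1)),
               1.01)
  expect_error(gen_mvar(mvar_model(list(matrix(1.01)), matrix(1), 1000), 1),
               "unstable")
})

test_that("spectral transfer matrix inverts the coefficient polynomial", {
  freqs <- seq(1, 100, by = 1)
  noise_only <- mvar_model(list(), diag(2), fs = 1000)
  H0 <- transfer_matrix(noise_only, freqs)
  expect_true(all(apply(H0$H, 3, function(M) max(abs(M - diag(2)))) < 1e-12))

  # scalar AR(1): H(0) = 1 / (1 - a)
  ar1 <- mvar_model(list(matrix(0.5)), matrix(1), fs = 1000)
  Hdc <- transfer_matrix(ar1, 1e-9)
  expect_equal(Mod(Hdc$H[1, 1, 1]), 2, tolerance = 1e-6)

  # lower-triangular system: no transfer from channel 2 into channel 1,
  # and H * Abar = I on the whole grid
  m <- lower_tri_ar1()
  Ht <- transfer_matrix(m, freqs)
  expect_lt(max(Mod(Ht$H[1, 2, ])), 1e-12)
  dt <- 1 / m$fs
  for (fi in c(1L, 50L, 100L)) {
    Abar <- diag(2) - m$coeffs[[1]] * exp(-2i * pi * freqs[fi] * dt)
    expect_lt(max(Mod(Ht$H[, , fi] %*% Abar - diag(2))), 1e-10)
  }
})

test_that("normalized DTF is a row-stochastic inflow decomposition", {
  freqs <- seq(1, 100, by = 0.5)
  eyeH <- array(rep(c(1 + 0i, 0, 0, 1), length(freqs)), c(2, 2, length(freqs)))
  d_eye <- compute_dtf(eyeH, freqs = freqs)
  expect_true(all(abs(d_eye$values[1, 2, ]) < 1e-12))
  expect_true(all(abs(d_eye$values[1, 1, ] - 1) < 1e-12))

  d <- compute_dtf(transfer_matrix(lower_tri_ar1(), freqs))
  expect_true(all(d$values[1, 2, ] < 1e-10))   # flow 2 -> 1 absent
  expect_true(all(d$values[2, 1, ] > 0))       # flow 1 -> 2 present
  sums <- apply(d$values, c(1, 3), sum)
  expect_lt(max(abs(sums - 1)), 1e-10)

  raw <- compute_dtf(transfer_matrix(lower_tri_ar1(), freqs),
                     normalized = FALSE)
  expect_false(raw$normalized)
  expect_true(all(raw$values >= 0))
})

test_that("parametric spectrum matches closed forms and Parseval", {
  flat <- mvar_spectrum(mvar_model(list(), diag(2), fs = 1000),
                        seq(0, 500, 1))
  expect_true(all(abs(Re(flat$S[1, 1, ]) - 1e-3) < 1e-15))

  # scalar AR(1), a = 0.5: S(0)/S(Nyquist) = ((1+a)/(1-a))^2 = 9
  ar1 <- mvar_model(list(matrix(0.5)), matrix(1), fs = 1000)
  S <- mvar_spectrum(ar1, c(0, 500))
  expect_equal(Re(S$S[1, 1, 1]) / Re(S$S[1, 1, 2]), 9, tolerance = 1e-9)

  # band integral recovers the stationary variance
  m <- lower_tri_ar1(0.5, 0.4, 0.7)
  grid <- seq(0, 500, by = 0.1)
  Sm <- mvar_spectrum(m, grid)
  v_spec <- 2 * sum(Re(Sm$S[1, 1, ])) * 0.1 - 0.1 * Re(Sm$S[1, 1, 1])
  v_true <- mvar_stationary_cov(m, 0)$R[[1]][1, 1]
  expect_lt(abs(v_spec - v_true) / v_true, 0.02)

  # Hermitian with nonnegative diagonal everywhere
  herm <- apply(Sm$S, 3, function(M) max(abs(M - Conj(t(M)))))
  expect_lt(max(herm), 1e-12)
  expect_true(all(Re(Sm$S[1, 1, ]) >= 0))
})

test_that("Welch spectrum of simulated data matches the parametric form", {
  m <- lower_tri_ar1(0.5, 0.4, 0.7)
  sim <- gen_mvar(m, duration_s = 60, seed = 31)
  segs <- segment_recording(sim, 2, 30)
  est <- estimate_csd_welch(segs, seq(2, 100, 1))
  theo <- mvar_spectrum(m, seq(2, 100, 1))
  for (ch in 1:2) {
    bi_est <- sum(Re(est$G[ch, ch, ]))
    bi_theo <- sum(Re(theo$S[ch, ch, ]))
    expect_lt(abs(bi_est - bi_theo) / bi_theo, 0.2)
  }
})
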