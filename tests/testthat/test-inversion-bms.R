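test_that("Welch cross-spectra behave on white noise and duplicated channels", {
  set.seed(14)
  fs <- 1000
  X <- matrix(rnorm(30000 * 2), 30000, 2)
  segs <- segment_set(list(X), fs = fs)
  fr <- seq(2, 100, 1)
  est <- estimate_csd_welch(segs, fr)

  # independent channels: mean coherence stays near the estimator floor
  expect_lt(mean(csd_coherence(est)), 0.2)

  # unit-variance white noise: two-sided density integrates back to 1
  full <- estimate_csd_welch(segs, seq(1, 500, 1))
  v1 <- 2 * sum(Re(full$G[1, 1, ]))
  expect_lt(abs(v1 - 1), 0.1)

  dup <- segment_set(list(cbind(X[, 1], X[, 1])), fs = fs)
  est_dup <- estimate_csd_welch(dup, fr)
  expect_lt(max(abs(csd_coherence(est_dup) - 1)), 1e-10)

  expect_error(estimate_csd_welch(segs, seq(10, 600, 10)), "fs/2")
  tiny <- segment_set(list(X[1:1500, ]), fs = fs)
  expect_error(estimate_csd_welch(tiny, fr), "twice the window")
})

test_that("variational Laplace is exact at self-generated truth", {
  fr <- dcm_fit_grid()
  sk <- dcm_skeleton(1)
  obs <- list(W = predict_csd(sk$base, "W", fr),
              A = predict_csd(sk$base, "A", fr))
  fit <- variational_laplace(obs, sk, dcm_priors())
  expect_lt(max(abs(fit$theta)), 0.1 * sqrt(1 / 16))
  expect_gte(fit$F, fit$F_trace[1L])
  expect_true(all(diff(fit$F_trace) >= -1e-9))
  expect_true(all(eigen(fit$Sigma, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
})

test_that("variational Laplace recovers condition effects from noiseless
           spectra with a monotone free-energy ascent", {
  fr <- dcm_fit_grid()
  sk <- dcm_skeleton(1)
  truth <- dirspec:::dcm_make_model(
    sk, c(b_fwd = -0.7, bself.1 = 0.3, bself.2 = 0.3))
  obs <- list(W = predict_csd(truth, "W", fr),
              A = predict_csd(truth, "A", fr))
  fit <- variational_laplace(obs, sk, dcm_priors(dcm_effect_names()))
  expect_lt(abs(fit$theta[["b_fwd"]] + 0.7), 0.3)
  expect_lt(abs(fit$theta[["b_bwd"]]), 0.2)
  expect_true(all(diff(fit$F_trace) >= -1e-9))

  expect_error(
    variational_laplace(obs["W"], sk, dcm_priors("b_fwd")),
    "no 'A' condition")
})

test_that("free energy penalizes redundancy but ignores irrelevant
           parameters", {
  fr <- dcm_fit_grid()
  # skeleton with the 1/f innovation component switched off, so its
  # log-weight has no influence on the predicted spectra
  base <- nmm_model(a_fwd = 384, a_bwd = 64, beta_u = -30,
                    alpha_n = log(1e-8), beta_n = -30)
  sk <- dcm_skeleton(1, base)
  obs <- list(W = predict_csd(sk$base, "W", fr))
  core <- setdiff(dcm_scaling_names(), c("bu.1", "bu.2", "bn.1", "bn.2"))
  f_nested <- variational_laplace(obs, sk, dcm_priors(free_scalings = core))
  f_extra <- variational_laplace(obs, sk,
                                 dcm_priors(free_scalings = c(core, "bu.1")))
  expect_lt(abs(f_extra$F - f_nested$F), 0.5)

  # a redundant but data-sensitive parameter never wins by > 3 nats
  obs2 <- list(W = obs$W, A = predict_csd(sk$base, "A", fr))
  g_nested <- variational_laplace(obs2, sk, dcm_priors(free_scalings = core))
  g_extra <- variational_laplace(obs2, sk,
                                 dcm_priors("b_bwd", free_scalings = core))
  expect_lt(g_extra$F - g_nested$F, 3)
})

test_that("model spaces enumerate the intended hypotheses", {
  arch <- build_architecture_space()
  expect_length(arch, 2L)
  # model 1: forward connection sent by the parietal source
  sk1 <- arch$model1
  recv <- if (sk1$base$arch == 1L) 1L else 2L
  expect_identical(sk1$base$labels[3L - recv], "P")
  expect_identical(arch$model2$base$arch, 2L)

  effects <- build_condition_effect_space(1L)
  expect_length(effects, 16L)
  free_sets <- lapply(effects, attr, "free_effects")
  expect_length(free_sets[[1L]], 4L)                      # all effects free
  expect_identical(sum(lengths(free_sets) == 0L), 1L)     # single null model
  expect_identical(anyDuplicated(vapply(free_sets, function(s)
    paste(sort(s), collapse = "+"), character(1))), 0L)

  small <- build_condition_effect_space(1L, preset = "cond4")
  expect_length(small, 4L)
  expect_setequal(
    vapply(small, function(s) paste(sort(attr(s, "free_effects")),
                                    collapse = "+"), character(1)),
    c("b_bwd+b_fwd", "b_fwd", "b_bwd", ""))
})

test_that("fixed-effects BMS is a shift-invariant softmax of log evidence", {
  eq <- fixed_effects_bms(rep(1.5, 4))
  expect_equal(eq$prob, rep(0.25, 4))

  two <- fixed_effects_bms(c(0, 3))
  expect_equal(two$prob, c(1, exp(3)) / (1 + exp(3)))

  shifted <- fixed_effects_bms(c(0, 3) + 100)
  expect_equal(shifted$prob, two$prob, tolerance = 1e-12)
  expect_equal(sum(two$prob), 1, tolerance = 1e-12)

  expect_error(fixed_effects_bms(1.2), "at least 2")
})
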