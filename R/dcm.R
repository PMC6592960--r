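#' Default frequency grid for cross-spectral model fitting
#'
#' 1 to 80 Hz in 1 Hz steps: the native resolution of 1 s Welch windows,
#' extending beyond the 3-40 Hz statistics band to use the informative
#' part of the spectrum.
#' @return Numeric vector of frequencies (Hz).
#' @export
dcm_fit_grid <- function() seq(1, 80, by = 1)

#' Canonical free-parameter names of the inversion
#'
#' `dcm_scaling_names()` lists the log-scalings of the biophysical and
#' spectral baseline parameters (suffix `.1` = first source, `.2` =
#' second); `dcm_effect_names()` lists the four condition-effect
#' parameters.
#' @return Character vector of parameter names.
#' @export
dcm_scaling_names <- function() {
  c("He.1", "He.2", "Hi.1", "Hi.2", "ke.1", "ke.2", "ki.1", "ki.2",
    "g5.1", "g5.2", "a_fwd", "a_bwd", "g_obs",
    "au.1", "au.2", "bu.1", "bu.2", "an.1", "an.2", "bn.1", "bn.2")
}

#' @rdname dcm_scaling_names
#' @export
dcm_effect_names <- function() c("b_fwd", "b_bwd", "bself.1", "bself.2")

#' Prior specification for model inversion
#'
#' Zero-mean Gaussian priors on the free parameters: variance `v_scaling`
#' (default 1/16, mild shrinkage) on the log-scalings of the biophysical
#' and spectral parameters, and `v_effect` (default 1) on the
#' condition-effect parameters named in `free_effects`. Parameters not
#' listed are pinned at their skeleton value (prior variance 0, excluded
#' from the free vector).
#'
#' @param free_effects character subset of
#'   `c("b_fwd", "b_bwd", "bself.1", "bself.2")` (suffix 1 = first source,
#'   2 = second).
#' @param v_scaling prior variance of log-scalings.
#' @param v_effect prior variance of condition effects.
#' @param free_scalings which scalings are free (default: all).
#' @return An object of class `dcm_priors`: named numeric vector of prior
#'   variances over the free parameters.
#' @export
dcm_priors <- function(free_effects = character(), v_scaling = 1 / 16,
                       v_effect = 1, free_scalings = dcm_scaling_names()) {
  stopifnot(all(free_effects %in% dcm_effect_names()),
            all(free_scalings %in% dcm_scaling_names()))
  v <- c(stats::setNames(rep(v_scaling, length(free_scalings)), free_scalings),
         stats::setNames(rep(v_effect, length(free_effects)), free_effects))
  structure(v, class = "dcm_priors")
}

#' Model skeleton for inversion
#'
#' Fixes the connection architecture and the baseline parameter values
#' around which the free log-scalings act. The default baseline is the
#' package's nominal two-source operating point (the generator defaults of
#' [anaesthesia_scenario()] with all condition effects at zero).
#'
#' @param arch architecture flag (1 or 2), see [nmm_model()].
#' @param base_model optional [nmm_model()] baseline; condition scalings in
#'   it are ignored (they are controlled by the free parameters).
#' @return An object of class `dcm_skeleton`.
#' @export
dcm_skeleton <- function(arch = 1L, base_model = NULL) {
  if (is.null(base_model))
    base_model <- nmm_model(a_fwd = 384, a_bwd = 64,
                            alpha_n = log(1e-8), beta_n = log(1e-8))
  base_model$arch <- as.integer(arch)
  base_model$b_fwd <- 0; base_model$b_bwd <- 0; base_model$b_self <- c(0, 0)
  structure(list(arch = as.integer(arch), base = base_model),
            class = "dcm_skeleton")
}

# instantiate an nmm_model from a free-parameter vector
dcm_make_model <- function(skeleton, theta) {
  m <- skeleton$base
  g <- function(nm) if (nm %in% names(theta)) theta[[nm]] else 0
  sc <- function(nm) exp(g(nm))
  m$He <- m$He * c(sc("He.1"), sc("He.2"))
  m$Hi <- m$Hi * c(sc("Hi.1"), sc("Hi.2"))
  m$ke <- m$ke * c(sc("ke.1"), sc("ke.2"))
  m$ki <- m$ki * c(sc("ki.1"), sc("ki.2"))
  m$gamma[1L, 5L] <- m$gamma[1L, 5L] * sc("g5.1")
  m$gamma[2L, 5L] <- m$gamma[2L, 5L] * sc("g5.2")
  m$a_fwd <- m$a_fwd * sc("a_fwd")
  m$a_bwd <- m$a_bwd * sc("a_bwd")
  m$g_obs <- m$g_obs * sc("g_obs")
  m$alpha_u <- m$alpha_u + c(g("au.1"), g("au.2"))
  m$beta_u <- m$beta_u + c(g("bu.1"), g("bu.2"))
  m$alpha_n <- m$alpha_n + c(g("an.1"), g("an.2"))
  m$beta_n <- m$beta_n + c(g("bn.1"), g("bn.2"))
  m$b_fwd <- g("b_fwd")
  m$b_bwd <- g("b_bwd")
  m$b_self <- c(g("bself.1"), g("bself.2"))
  m
}

# stacked real feature vector of one or more CSDs: per condition and
# frequency, (Re G11, Re G22, Re G12, Im G12)
csd_features <- function(csd_list) {
  unlist(lapply(csd_list, function(cs)
    as.numeric(rbind(Re(cs$G[1L, 1L, ]), Re(cs$G[2L, 2L, ]),
                     Re(cs$G[1L, 2L, ]), Im(cs$G[1L, 2L, ])))),
    use.names = FALSE)
}

# predicted features for the supplied conditions; NULL if the model is
# unstable at theta
dcm_predict_features <- function(skeleton, theta, conditions, freqs) {
  m <- dcm_make_model(skeleton, theta)
  out <- tryCatch(
    lapply(conditions, function(cond) predict_csd(m, cond, freqs)),
    error = function(e) NULL)
  if (is.null(out)) return(NULL)
  csd_features(out)
}

#' Fit the neural-mass CSD model by variational Laplace
#'
#' Gauss-Newton ascent on a free-energy bound `F = accuracy - complexity`
#' under Gaussian prior and posterior assumptions. The data feature vector
#' stacks the real upper-triangular cross-spectral entries (Re of the auto
#' spectra, Re and Im of the cross spectrum) over frequencies and
#' conditions; residual precision is a scalar hyperparameter updated by
#' expectation-maximization in alternation with the parameter step. Steps
#' that do not increase F are rejected with tenfold ridge damping;
#' convergence is declared after three consecutive accepted steps changing
#' F by less than `tol_f`.
#'
#' @param observed named list of observed `csd_spectrum` objects keyed by
#'   condition (`"W"`, optionally `"A"`), e.g. from
#'   [estimate_csd_welch()]. All must share one frequency grid.
#' @param skeleton a [dcm_skeleton()].
#' @param priors a [dcm_priors()]; condition-effect parameters require the
#'   `"A"` condition to be present.
#' @param max_iter iteration cap (default 96).
#' @param tol_f convergence tolerance on F (default 0.01 nats).
#' @return An object of class `dcm_fit`: list with `theta` (posterior
#'   means), `Sigma` (posterior covariance), `F` (free energy, nats),
#'   `F_trace`, `lambda` (residual precision), `predicted` (fitted
#'   `csd_spectrum` per condition), `skeleton`, `priors`.
#' @export
variational_laplace <- function(observed, skeleton, priors,
                                max_iter = 96L, tol_f = 0.01) {
  stopifnot(inherits(skeleton, "dcm_skeleton"), inherits(priors, "dcm_priors"))
  conditions <- names(observed)
  if (is.null(conditions) || !all(conditions %in% c("W", "A")))
    stop("observed must be a named list keyed by condition ('W', 'A')")
  if (any(dcm_effect_names() %in% names(priors)) && !("A" %in% conditions))
    stop("condition-effect parameters are free but no 'A' condition supplied")
  freqs <- observed[[1L]]$freqs
  for (cs in observed)
    if (!isTRUE(all.equal(cs$freqs, freqs)))
      stop("all observed spectra must share one frequency grid")

  y <- csd_features(observed)
  n <- length(y)
  s <- sqrt(mean(y^2))            # fixed feature scale
  pn <- names(priors)
  np <- length(pn)
  Pi0 <- diag(1 / as.numeric(priors), np)
  theta <- stats::setNames(numeric(np), pn)

  predict_e <- function(th) {
    gf <- dcm_predict_features(skeleton, th, conditions, freqs)
    if (is.null(gf)) return(NULL)
    (y - gf) / s
  }
  jacobian <- function(th, e0) {
    J <- matrix(0, n, np)
    for (i in seq_len(np)) {
      h <- 1e-4 * (1 + abs(th[i]))
      tp <- th; tp[i] <- tp[i] + h
      tm <- th; tm[i] <- tm[i] - h
      ep <- predict_e(tp); em <- predict_e(tm)
      if (is.null(ep) || is.null(em)) {
        # one-sided fallback near a stability boundary
        if (is.null(ep)) { ep <- e0; h2 <- h } else h2 <- h
        if (is.null(em)) { em <- e0 }
        J[, i] <- (ep - em) / h2
      } else J[, i] <- (ep - em) / (2 * h)
    }
    J
  }
  free_energy <- function(e, th, lambda, P) {
    dth <- th
    -0.5 * lambda * sum(e^2) + 0.5 * n * (log(lambda) - log(2 * pi)) -
      0.5 * sum(dth * (Pi0 %*% dth)) +
      0.5 * determinant(Pi0, logarithm = TRUE)$modulus[1L] -
      0.5 * determinant(P, logarithm = TRUE)$modulus[1L]
  }

  e <- predict_e(theta)
  if (is.null(e)) stop("model unstable at the prior mean; check the skeleton")
  lambda <- 1
  J <- jacobian(theta, e)
  P <- lambda * crossprod(J) + Pi0
  # e is -d(residual)/d(theta) scaled; J here is d(e)/d(theta) = -dg/s
  Fcur <- free_energy(e, theta, lambda, P)
  trace <- Fcur
  ridge <- 0
  streak <- 0L
  for (it in seq_len(max_iter)) {
    grad <- -lambda * crossprod(J, e) - Pi0 %*% theta
    H <- P + diag(ridge, np)
    step <- tryCatch(solve(H, grad), error = function(er) NULL)
    accepted <- FALSE
    fails <- 0L
    while (!accepted && fails < 6L) {
      if (!is.null(step)) {
        th_new <- theta + as.numeric(step)
        names(th_new) <- pn
        e_new <- predict_e(th_new)
        if (!is.null(e_new)) {
          J_new <- jacobian(th_new, e_new)
          # EM precision update (maximizes F in lambda)
          JtJ <- crossprod(J_new)
          Sg <- tryCatch(solve(lambda * JtJ + Pi0), error = function(er) NULL)
          lam_new <- lambda
          if (!is.null(Sg)) {
            q <- sum(e_new^2) + sum(J_new %*% Sg * J_new)
            lam_new <- min(max(n / q, 1e-6), 1e9)
          }
          # keep whichever precision yields the larger bound (the EM update
          # ignores the log-determinant term, so it can overshoot)
          F_alt <- free_energy(e_new, th_new, lambda, lambda * JtJ + Pi0)
          P_new <- lam_new * JtJ + Pi0
          F_new <- free_energy(e_new, th_new, lam_new, P_new)
          if (is.finite(F_alt) && (!is.finite(F_new) || F_alt > F_new)) {
            lam_new <- lambda
            P_new <- lambda * JtJ + Pi0
            F_new <- F_alt
          }
          if (is.finite(F_new) && F_new >= Fcur - 1e-9) {
            dF <- F_new - Fcur
            theta <- th_new; e <- e_new; J <- J_new
            lambda <- lam_new; P <- P_new; Fcur <- F_new
            trace <- c(trace, Fcur)
            ridge <- ridge / 10
            streak <- if (abs(dF) < tol_f) streak + 1L else 0L
            accepted <- TRUE
            next
          }
        }
      }
      ridge <- max(ridge * 10, 1)
      H <- P + diag(ridge, np)
      step <- tryCatch(solve(H, grad), error = function(er) NULL)
      fails <- fails + 1L
    }
    if (!accepted || streak >= 3L) break
  }
  Sigma <- tryCatch(solve(P), error = function(er) MASS_ginv(P))
  Sigma <- (Sigma + t(Sigma)) / 2
  fitted_model <- dcm_make_model(skeleton, theta)
  predicted <- stats::setNames(
    lapply(conditions, function(cd) predict_csd(fitted_model, cd, freqs)),
    conditions)
  structure(list(theta = theta, Sigma = Sigma, F = Fcur, F_trace = trace,
                 lambda = lambda, predicted = predicted, model = fitted_model,
                 skeleton = skeleton, priors = priors,
                 iterations = length(trace) - 1L),
            class = "dcm_fit")
}

MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  pos <- s$d > tol * s$d[1L]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' @export
print.dcm_fit <- function(x, ...) {
  cat(sprintf("<dcm_fit> F = %.2f nats after %d iterations (lambda = %.3g)\n",
              x$F, x$iterations, x$lambda))
  eff <- intersect(dcm_effect_names(), names(x$theta))
  if (length(eff)) {
    sd <- sqrt(diag(x$Sigma))[match(eff, names(x$theta))]
    for (i in seq_along(eff))
      cat(sprintf("  %-8s %+.3f (sd %.3f) -> %.0f%% of W strength\n",
                  eff[i], x$theta[[eff[i]]], sd[i],
                  100 * exp(x$theta[[eff[i]]])))
  }
  invisible(x)
}

#' Architecture model space
#'
#' The two hypotheses about extrinsic connectivity between the sources:
#' model 1 sends the forward connection from the second source to the
#' first (parietal to frontal under the default `F, P` labels) with the
#' backward connection in return; model 2 is the reverse. The two models
#' free the same parameters and differ only in the architecture flag.
#'
#' @param base_model optional baseline passed to [dcm_skeleton()].
#' @return List of 2 `dcm_skeleton` objects (class `dcm_space`).
#' @export
build_architecture_space <- function(base_model = NULL) {
  structure(list(model1 = dcm_skeleton(1L, base_model),
                 model2 = dcm_skeleton(2L, base_model)),
            class = "dcm_space")
}

#' Condition-effect model space
#'
#' All `2^4 = 16` combinations of condition-specific changes in the
#' forward gain, the backward gain, and the two sources' inhibitory
#' self-connections. Model 1 allows changes in all four; model 16 is the
#' null model (no condition effect). The 4-model preset
#' (`preset = "cond4"`) restricts the space to forward/backward
#' combinations: both, forward only, backward only, neither.
#'
#' @param arch architecture flag for every model (typically the stage-1
#'   winner).
#' @param base_model optional baseline passed to [dcm_skeleton()].
#' @param preset `"cond16"` (default) or `"cond4"`.
#' @return Named list of `dcm_skeleton` objects (class `dcm_space`), each
#'   with attribute `free_effects`.
#' @export
build_condition_effect_space <- function(arch = 1L, base_model = NULL,
                                         preset = c("cond16", "cond4")) {
  preset <- match.arg(preset)
  effects <- dcm_effect_names()
  sets <- if (preset == "cond16") {
    lapply(15:0, function(mask)
      effects[bitwAnd(mask, c(8L, 4L, 2L, 1L)) > 0L])
  } else {
    list(c("b_fwd", "b_bwd"), "b_fwd", "b_bwd", character())
  }
  out <- lapply(sets, function(fe) {
    sk <- dcm_skeleton(arch, base_model)
    attr(sk, "free_effects") <- fe
    sk
  })
  names(out) <- paste0("model", seq_along(out))
  structure(out, class = "dcm_space")
}

#' Fixed-effects Bayesian model selection
#'
#' Converts per-model free energies (log-evidence approximations for the
#' same data) into posterior model probabilities by a softmax:
#' `p(m) = exp(F_m - max F) / sum_k exp(F_k - max F)`.
#'
#' @param fits list of `dcm_fit` objects, or a numeric vector of free
#'   energies.
#' @return A data.frame with `model`, `F`, `prob`, sorted as supplied;
#'   class `bms_result`.
#' @export
fixed_effects_bms <- function(fits) {
  Fv <- if (is.numeric(fits)) fits
        else vapply(fits, function(f) f$F, numeric(1L))
  if (length(Fv) < 2L) stop("model selection requires at least 2 models")
  nm <- names(Fv)
  if (is.null(nm)) nm <- paste0("model", seq_along(Fv))
  w <- exp(Fv - max(Fv))
  out <- data.frame(model = nm, F = as.numeric(Fv), prob = w / sum(w),
                    stringsAsFactors = FALSE)
  class(out) <- c("bms_result", "data.frame")
  out
}

#' Two-stage DCM pipeline for one modality
#'
#' Stage 1 inverts the two architecture models on the wakefulness
#' cross-spectra alone and selects the winner by fixed-effects BMS.
#' Stage 2 inverts the condition-effect space (default: all 16
#' combinations) on both conditions jointly under the winning
#' architecture, selects the winning effect model, and reports posterior
#' condition effects as percentages of wakefulness strength together with
#' model-derived DTFs per condition.
#'
#' @param segments_w,segments_a [segment_set()]s (or [mc_recording()]s)
#'   for conditions W and A.
#' @param freqs fitting grid (default [dcm_fit_grid()]).
#' @param base_model optional skeleton baseline.
#' @param effect_preset `"cond16"` or `"cond4"`.
#' @param dtf_freqs grid for the reported model-derived DTFs.
#' @param verbose print stage progress.
#' @return A list (class `dcm_report`) with elements `arch_bms`,
#'   `arch_winner`, `effect_bms`, `effect_winner`, `winning_fit`,
#'   `effects_percent` (condition effects as % of W strength),
#'   `model_dtf` (list `W`/`A` of `dtf_spectrum`), `observed` (the two
#'   CSDs).
#' @export
run_dcm_pipeline <- function(segments_w, segments_a, freqs = dcm_fit_grid(),
                             base_model = NULL,
                             effect_preset = c("cond16", "cond4"),
                             dtf_freqs = default_freq_grid(),
                             verbose = FALSE) {
  effect_preset <- match.arg(effect_preset)
  csd_w <- estimate_csd_welch(segments_w, freqs)
  csd_a <- estimate_csd_welch(segments_a, freqs)

  arch_space <- build_architecture_space(base_model)
  pri0 <- dcm_priors()
  arch_fits <- lapply(arch_space, function(sk)
    variational_laplace(list(W = csd_w), sk, pri0))
  arch_bms <- fixed_effects_bms(arch_fits)
  arch_winner <- which.max(arch_bms$prob)
  if (verbose)
    message(sprintf("stage 1: architecture %d wins (p = %.3f)",
                    arch_winner, max(arch_bms$prob)))

  eff_space <- build_condition_effect_space(arch_winner, base_model,
                                            effect_preset)
  eff_fits <- lapply(eff_space, function(sk)
    variational_laplace(list(W = csd_w, A = csd_a), sk,
                        dcm_priors(attr(sk, "free_effects"))))
  eff_bms <- fixed_effects_bms(eff_fits)
  eff_winner <- which.max(eff_bms$prob)
  if (verbose)
    message(sprintf("stage 2: effect model %d wins (p = %.3f)",
                    eff_winner, max(eff_bms$prob)))

  win <- eff_fits[[eff_winner]]
  eff <- intersect(dcm_effect_names(), names(win$theta))
  effects_percent <- stats::setNames(100 * exp(win$theta[eff]), eff)
  model_dtf <- list(W = model_derived_dtf(win$model, "W", dtf_freqs),
                    A = model_derived_dtf(win$model, "A", dtf_freqs))
  structure(list(arch_bms = arch_bms, arch_winner = arch_winner,
                 arch_fits = arch_fits,
                 effect_bms = eff_bms, effect_winner = eff_winner,
                 winning_fit = win, effects_percent = effects_percent,
                 model_dtf = model_dtf,
                 observed = list(W = csd_w, A = csd_a)),
            class = "dcm_report")
}

#' @export
print.dcm_report <- function(x, ...) {
  cat(sprintf("<dcm_report> architecture winner: model %d (p = %.3f)\n",
              x$arch_winner, max(x$arch_bms$prob)))
  cat(sprintf("  effect winner: model %d (p = %.3f), effects: %s\n",
              x$effect_winner, max(x$effect_bms$prob),
              paste(sprintf("%s = %.0f%%", names(x$effects_percent),
                            x$effects_percent), collapse = ", ")))
  invisible(x)
}
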