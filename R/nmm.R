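#' Two-source LFP neural-mass model
#'
#' Generative model of a pair of coupled cortical sources. Each source is a
#' mean-field circuit of three subpopulations — spiny stellate cells in the
#' granular layer, pyramidal cells, and inhibitory interneurons — and each
#' subpopulation is driven through second-order synaptic kinetics: for a
#' synaptic pair with voltage `v` and current `i`,
#' \deqn{\dot v = i, \qquad \dot i = \kappa H d - 2\kappa i - \kappa^2 v}
#' where `d` is the presynaptic drive, `H` the maximal postsynaptic
#' potential and `kappa` the rate constant (excitatory or inhibitory
#' kinetics per pair). Firing is a zero-centred sigmoid of depolarization,
#' see [sigmoid_response()].
#'
#' Extrinsic connections follow cortical-hierarchy rules: the forward
#' connection targets the receiving source's stellate (granular) population,
#' the backward connection targets the pyramidal and interneuron
#' populations. `arch = 1` sends the forward connection from the second
#' source to the first (with the default labels `c("F", "P")`: forward
#' parietal to frontal, backward frontal to parietal); `arch = 2` is the
#' reverse.
#'
#' Condition effects are multiplicative log-scalings applied in condition
#' `"A"` only: `a_fwd * exp(b_fwd)`, `a_bwd * exp(b_bwd)` on the extrinsic
#' gains and `gamma5 * exp(b_self)` on each source's inhibitory
#' self-connection. All `b = 0` reproduces condition `"W"` exactly.
#'
#' The per-source innovations driving the stellate populations, and the
#' per-channel observation noise, have white + 1/f spectral densities
#' `exp(alpha) + exp(beta)/f` (two-sided, power per Hz).
#'
#' @param He,Hi excitatory/inhibitory synaptic gains in mV (length 1 or 2,
#'   recycled over sources).
#' @param ke,ki excitatory/inhibitory rate constants in 1/s.
#' @param gamma intrinsic coupling gains `gamma1..gamma5`: length-5 vector
#'   shared by both sources, or a 2 x 5 matrix (rows = sources).
#' @param rho1,rho2 sigmoid slope and offset.
#' @param a_fwd,a_bwd extrinsic forward/backward gains.
#' @param b_fwd,b_bwd,b_self condition log-scalings (scalars; `b_self`
#'   length 1 or 2, one per source).
#' @param C exogenous/innovation input gain per source.
#' @param g_obs observation gain per source.
#' @param alpha_u,beta_u log white and 1/f innovation spectral parameters
#'   per source.
#' @param alpha_n,beta_n log white and 1/f observation-noise spectral
#'   parameters per channel.
#' @param arch architecture flag, 1 or 2 (which source sends the forward
#'   connection, see Details).
#' @param labels source labels, default `c("F", "P")`.
#' @return An object of class `nmm_model`.
#' @export
nmm_model <- function(He = 4, Hi = 32, ke = 250, ki = 62.5,
                      gamma = c(128, 128, 64, 64, 16),
                      rho1 = 2, rho2 = 1,
                      a_fwd = 32, a_bwd = 32,
                      b_fwd = 0, b_bwd = 0, b_self = c(0, 0),
                      C = 1, g_obs = 1,
                      alpha_u = log(1), beta_u = log(0.5),
                      alpha_n = log(1e-4), beta_n = log(1e-4),
                      arch = 1L, labels = c("F", "P")) {
  two <- function(x) {
    x <- as.numeric(x)
    if (length(x) == 1L) rep(x, 2L) else if (length(x) == 2L) x
    else stop("per-source parameters must have length 1 or 2")
  }
  if (is.matrix(gamma)) {
    stopifnot(all(dim(gamma) == c(2L, 5L)))
  } else {
    stopifnot(length(gamma) == 5L)
    gamma <- matrix(rep(as.numeric(gamma), each = 2L), 2L, 5L)
  }
  m <- list(He = two(He), Hi = two(Hi), ke = two(ke), ki = two(ki),
            gamma = gamma, rho1 = rho1, rho2 = rho2,
            a_fwd = a_fwd, a_bwd = a_bwd,
            b_fwd = b_fwd, b_bwd = b_bwd, b_self = two(b_self),
            C = two(C), g_obs = two(g_obs),
            alpha_u = two(alpha_u), beta_u = two(beta_u),
            alpha_n = two(alpha_n), beta_n = two(beta_n),
            arch = as.integer(arch), labels = labels)
  stopifnot(all(m$ke > 0), all(m$ki > 0), m$arch %in% c(1L, 2L),
            all(m$gamma >= 0), m$a_fwd >= 0, m$a_bwd >= 0)
  class(m) <- "nmm_model"
  m
}

#' @export
print.nmm_model <- function(x, ...) {
  dir <- if (x$arch == 1L) sprintf("%s -> %s", x$labels[2L], x$labels[1L])
         else sprintf("%s -> %s", x$labels[1L], x$labels[2L])
  cat(sprintf("<nmm_model> 2 sources (%s), forward %s, a_fwd = %g, a_bwd = %g\n",
              paste(x$labels, collapse = ", "), dir, x$a_fwd, x$a_bwd))
  cat(sprintf("  condition effects: b_fwd = %g, b_bwd = %g, b_self = [%g, %g]\n",
              x$b_fwd, x$b_bwd, x$b_self[1L], x$b_self[2L]))
  invisible(x)
}

#' Zero-centred sigmoid firing-rate function
#'
#' `S(v) = 1/(1 + exp(-rho1 (v - rho2))) - 1/(1 + exp(rho1 rho2))`:
#' a logistic voltage-to-rate transform shifted so that `S(0) = 0`, which
#' makes the origin an equilibrium of the unforced dynamics.
#'
#' @param v membrane depolarization (mV), vectorized.
#' @param rho1 slope parameter.
#' @param rho2 offset parameter.
#' @return Firing rate (dimensionless), same shape as `v`.
#' @export
sigmoid_response <- function(v, rho1 = 2, rho2 = 1) {
  1 / (1 + exp(-rho1 * (v - rho2))) - 1 / (1 + exp(rho1 * rho2))
}

sigmoid_slope <- function(v, rho1, rho2) {
  e <- exp(-rho1 * (v - rho2))
  rho1 * e / (1 + e)^2
}

# effective (condition-scaled) coupling gains; cond "W" leaves everything
# at its baseline, cond "A" applies exp(b)
effective_gains <- function(model, condition) {
  A <- as.numeric(match.arg(condition, c("W", "A")) == "A")
  fwd_recv <- if (model$arch == 1L) 1L else 2L   # receiver of forward conn.
  bwd_recv <- 3L - fwd_recv
  fwd <- numeric(2L); bwd <- numeric(2L)
  fwd[fwd_recv] <- model$a_fwd * exp(model$b_fwd * A)
  bwd[bwd_recv] <- model$a_bwd * exp(model$b_bwd * A)
  g <- model$gamma
  g[, 5L] <- g[, 5L] * exp(model$b_self * A)
  list(fwd_in = fwd, bwd_in = bwd, gamma = g)
}

# state layout per source (10 states, source 1 then source 2):
#  1 v_st  2 i_st   stellate (granular), excitatory kinetics
#  3 v_pe  4 i_pe   pyramidal, excitatory input pair
#  5 v_pi  6 i_pi   pyramidal, inhibitory input pair
#  7 v_ie  8 i_ie   interneuron, excitatory input pair
#  9 v_ii 10 i_ii   interneuron, inhibitory input pair
# pyramidal output depolarization = v_pe - v_pi (the observed LFP source)
nmm_state_index <- function(source, slot) (source - 1L) * 10L + slot

#' Deterministic drift of the neural-mass state
#'
#' Evaluates the vector field of the 20-dimensional two-source model at
#' state `x` under the given condition, with constant exogenous drive `u`
#' entering each source's stellate population (scaled by `C`).
#'
#' @param x numeric length-20 state vector (see package vignette for the
#'   layout).
#' @param model an [nmm_model()].
#' @param condition `"W"` or `"A"`.
#' @param u exogenous input, scalar or length 2 (per source).
#' @return `dx/dt`, numeric length 20.
#' @export
nmm_drift <- function(x, model, condition = "W", u = 0) {
  g <- effective_gains(model, condition)
  u <- rep(as.numeric(u), length.out = 2L)
  S <- function(v) sigmoid_response(v, model$rho1, model$rho2)
  dx <- numeric(20L)
  P <- c(x[3L] - x[5L], x[13L] - x[15L])       # pyramidal outputs
  Iout <- c(x[7L] - x[9L], x[17L] - x[19L])    # interneuron outputs
  for (r in 1:2) {
    o <- 3L - r
    base <- (r - 1L) * 10L
    ke <- model$ke[r]; ki <- model$ki[r]
    He <- model$He[r]; Hi <- model$Hi[r]
    gam <- g$gamma[r, ]
    drive <- c(
      gam[1L] * S(P[r]) + g$fwd_in[r] * S(P[o]) + model$C[r] * u[r],  # stellate
      gam[2L] * S(x[base + 1L]) + g$bwd_in[r] * S(P[o]),              # pyr exc
      gam[4L] * S(Iout[r]),                                           # pyr inh
      gam[3L] * S(P[r]) + g$bwd_in[r] * S(P[o]),                      # int exc
      gam[5L] * S(Iout[r]))                                           # int inh
    kap <- c(ke, ke, ki, ke, ki)
    H <- c(He, He, Hi, He, Hi)
    for (m in 1:5) {
      vi <- base + 2L * m - 1L
      ii <- vi + 1L
      dx[vi] <- x[ii]
      dx[ii] <- kap[m] * H[m] * drive[m] - 2 * kap[m] * x[ii] -
        kap[m]^2 * x[vi]
    }
  }
  dx
}

#' Fixed point of the deterministic dynamics
#'
#' Damped Newton iteration from the origin using the analytic Jacobian,
#' with a long relaxation integration ([deSolve::lsoda()]) as fallback when
#' Newton stalls. With `u0 = 0` the origin is returned immediately (the
#' sigmoid is zero-centred).
#'
#' @param model an [nmm_model()].
#' @param condition `"W"` or `"A"`.
#' @param u0 constant exogenous drive (scalar or per source).
#' @param tol convergence tolerance on `max(abs(drift))`.
#' @return The fixed-point state vector (length 20).
#' @export
find_fixed_point <- function(model, condition = "W", u0 = 0, tol = 1e-10) {
  u0 <- rep(as.numeric(u0), length.out = 2L)
  x <- numeric(20L)
  if (all(u0 == 0)) return(x)   # S(0) = 0 makes the origin an equilibrium
  newton <- function(x) {
    for (it in 1:100) {
      f <- nmm_drift(x, model, condition, u0)
      if (max(abs(f)) <= tol) return(x)
      J <- nmm_jacobian(x, model, condition)
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lam <- 1
      repeat {
        xn <- x + lam * step
        fn <- nmm_drift(xn, model, condition, u0)
        if (max(abs(fn)) < max(abs(f)) || lam < 1e-6) break
        lam <- lam / 2
      }
      if (max(abs(fn)) >= max(abs(f))) return(NULL)
      x <- xn
    }
    if (max(abs(nmm_drift(x, model, condition, u0))) <= tol) x else NULL
  }
  out <- newton(x)
  if (is.null(out)) {
    # relaxation fallback: integrate to (near) equilibrium, then polish
    traj <- deSolve::lsoda(
      y = numeric(20L), times = c(0, 2),
      func = function(t, y, parms) list(nmm_drift(y, model, condition, u0)),
      parms = NULL, rtol = 1e-10, atol = 1e-12)
    out <- newton(as.numeric(traj[nrow(traj), -1L]))
  }
  if (is.null(out))
    stop("fixed-point search failed to converge (condition ", condition,
         ", max |drift| at last iterate above ", tol, ")")
  out
}

# analytic Jacobian of nmm_drift at state x
nmm_jacobian <- function(x, model, condition = "W") {
  g <- effective_gains(model, condition)
  Sp <- function(v) sigmoid_slope(v, model$rho1, model$rho2)
  J <- matrix(0, 20L, 20L)
  P <- c(x[3L] - x[5L], x[13L] - x[15L])
  Iout <- c(x[7L] - x[9L], x[17L] - x[19L])
  # column index sets contributing to each population output
  pyr_cols <- function(s) c(nmm_state_index(s, 3L), nmm_state_index(s, 5L))
  int_cols <- function(s) c(nmm_state_index(s, 7L), nmm_state_index(s, 9L))
  for (r in 1:2) {
    o <- 3L - r
    base <- (r - 1L) * 10L
    ke <- model$ke[r]; ki <- model$ki[r]
    He <- model$He[r]; Hi <- model$Hi[r]
    gam <- g$gamma[r, ]
    kap <- c(ke, ke, ki, ke, ki)
    H <- c(He, He, Hi, He, Hi)
    # derivative of each drive w.r.t. state: list of (cols, weights)
    dr <- list(
      list(cols = c(pyr_cols(r), pyr_cols(o)),
           w = c(gam[1L] * Sp(P[r]) * c(1, -1),
                 g$fwd_in[r] * Sp(P[o]) * c(1, -1))),
      list(cols = c(nmm_state_index(r, 1L), pyr_cols(o)),
           w = c(gam[2L] * Sp(x[base + 1L]),
                 g$bwd_in[r] * Sp(P[o]) * c(1, -1))),
      list(cols = int_cols(r),
           w = gam[4L] * Sp(Iout[r]) * c(1, -1)),
      list(cols = c(pyr_cols(r), pyr_cols(o)),
           w = c(gam[3L] * Sp(P[r]) * c(1, -1),
                 g$bwd_in[r] * Sp(P[o]) * c(1, -1))),
      list(cols = int_cols(r),
           w = gam[5L] * Sp(Iout[r]) * c(1, -1)))
    for (m in 1:5) {
      vi <- base + 2L * m - 1L
      ii <- vi + 1L
      J[vi, ii] <- 1
      J[ii, vi] <- J[ii, vi] - kap[m]^2
      J[ii, ii] <- J[ii, ii] - 2 * kap[m]
      J[ii, dr[[m]]$cols] <- J[ii, dr[[m]]$cols] + kap[m] * H[m] * dr[[m]]$w
    }
  }
  J
}

#' Linearize the neural-mass model around a fixed point
#'
#' Returns the state Jacobian `J`, the innovation input matrix `B` (each
#' source's innovation enters its stellate current equation scaled by
#' `ke * He * C`) and the observation matrix `Cmat` (per-source pyramidal
#' depolarization `v_pe - v_pi` scaled by `g_obs`).
#'
#' @param model an [nmm_model()].
#' @param condition `"W"` or `"A"`.
#' @param x_star fixed-point state (default: computed with `u0 = 0`).
#' @param require_stable error if any eigenvalue of `J` has non-negative
#'   real part (default `TRUE`).
#' @return List with `J` (20 x 20), `B` (20 x 2), `Cmat` (2 x 20),
#'   `eigenvalues`.
#' @export
nmm_linearize <- function(model, condition = "W", x_star = NULL,
                          require_stable = TRUE) {
  if (is.null(x_star)) x_star <- find_fixed_point(model, condition, 0)
  J <- nmm_jacobian(x_star, model, condition)
  B <- matrix(0, 20L, 2L)
  Cmat <- matrix(0, 2L, 20L)
  for (r in 1:2) {
    B[nmm_state_index(r, 2L), r] <- model$ke[r] * model$He[r] * model$C[r]
    Cmat[r, nmm_state_index(r, 3L)] <- model$g_obs[r]
    Cmat[r, nmm_state_index(r, 5L)] <- -model$g_obs[r]
  }
  eg <- eigen(J)
  ev <- eg$values
  if (require_stable && any(Re(ev) >= 0)) {
    worst <- ev[which.max(Re(ev))]
    stop(sprintf(
      "linearization unstable: eigenvalue %.4g %+.4gi has non-negative real part",
      Re(worst), Im(worst)))
  }
  list(J = J, B = B, Cmat = Cmat, eigenvalues = ev, eig = eg)
}

#' Innovation-to-output transfer function of the linearized model
#'
#' `T(f) = Cmat (2 pi i f I - J)^{-1} B`, evaluated on a frequency grid
#' via the eigendecomposition of `J` (with a direct per-frequency solve as
#' fallback for ill-conditioned eigenvector bases).
#'
#' @param lin a linearization from [nmm_linearize()], or a list with
#'   elements `J`, `B`, `Cmat`.
#' @param freqs frequency grid in Hz.
#' @return Complex array `2 x 2 x n_freq`.
#' @export
nmm_transfer <- function(lin, freqs) {
  J <- lin$J; B <- lin$B; Cm <- lin$Cmat
  n <- nrow(J)
  eg <- if (!is.null(lin$eig)) lin$eig else eigen(J)
  Tf <- array(NA_complex_, c(nrow(Cm), ncol(B), length(freqs)))
  W1 <- Cm %*% eg$vectors                         # 2 x n
  W2 <- tryCatch(solve(eg$vectors, B), error = function(e) NULL)
  # accept the eigenbasis route only if it reproduces B accurately
  ok <- !is.null(W2) &&
    max(abs(eg$vectors %*% W2 - B)) <= 1e-8 * max(1, max(abs(B)))
  if (ok) {
    s <- 2i * pi * freqs
    denom <- 1 / (matrix(s, n, length(freqs), byrow = TRUE) - eg$values)
    for (i in seq_len(nrow(Cm)))
      for (j in seq_len(ncol(B)))
        Tf[i, j, ] <- colSums((W1[i, ] * W2[, j]) * denom)
  } else {
    I <- diag(n)
    for (fi in seq_along(freqs)) {
      M <- tryCatch(solve(2i * pi * freqs[fi] * I - J, B),
                    error = function(e)
                      stop("resolvent singular at ", freqs[fi], " Hz"))
      Tf[, , fi] <- Cm %*% M
    }
  }
  Tf
}

innovation_psd <- function(alpha, beta, freqs) {
  # two-sided density, white + 1/f
  outer(freqs, seq_along(alpha),
        function(f, s) exp(alpha[s]) + exp(beta[s]) / f)
}

#' Predicted cross-spectral density of the neural-mass model
#'
#' `G(f) = T(f) diag(g_u(f)) T(f)^H + diag(g_n(f))` where
#' `g_u(f) = exp(alpha_u) + exp(beta_u)/f` is each source's innovation
#' spectrum and `g_n(f)` the observation-noise spectrum. Densities are
#' two-sided (power per Hz). The grid must exclude 0 (1/f term).
#'
#' @param model an [nmm_model()].
#' @param condition `"W"` or `"A"`.
#' @param freqs frequency grid in Hz, all `> 0`.
#' @param lin optional precomputed linearization.
#' @return An object of class `csd_spectrum`: list with `freqs`, `G`
#'   (complex `2 x 2 x n_freq`, Hermitian), `labels`.
#' @export
predict_csd <- function(model, condition = "W", freqs = default_freq_grid(),
                        lin = NULL) {
  if (any(freqs <= 0))
    stop("frequency grid must be strictly positive (1/f innovation term)")
  if (is.null(lin)) lin <- nmm_linearize(model, condition)
  Tf <- nmm_transfer(lin, freqs)
  gu <- innovation_psd(model$alpha_u, model$beta_u, freqs)
  gn <- innovation_psd(model$alpha_n, model$beta_n, freqs)
  G <- array(NA_complex_, dim(Tf))
  for (fi in seq_along(freqs)) {
    Tm <- Tf[, , fi]
    Gf <- Tm %*% diag(gu[fi, ]) %*% Conj(t(Tm)) + diag(gn[fi, ])
    G[, , fi] <- (Gf + Conj(t(Gf))) / 2
  }
  structure(list(freqs = freqs, G = G, labels = model$labels),
            class = "csd_spectrum")
}

#' Model-derived directed transfer function
#'
#' Applies the DTF normalization to the neural-mass transfer matrix with
#' innovation-spectrum weighting:
#' `DTF[i, j](f) = |T_ij(f)|^2 g_uj(f) / sum_m |T_im(f)|^2 g_um(f)`.
#' Rows sum to 1; the value quantifies the model-implied flow `j -> i`.
#'
#' @inheritParams predict_csd
#' @return A `dtf_spectrum` (same structure as [compute_dtf()] output).
#' @export
model_derived_dtf <- function(model, condition = "W",
                              freqs = default_freq_grid(), lin = NULL) {
  if (any(freqs <= 0)) stop("frequency grid must be strictly positive")
  if (is.null(lin)) lin <- nmm_linearize(model, condition)
  Tf <- nmm_transfer(lin, freqs)
  gu <- innovation_psd(model$alpha_u, model$beta_u, freqs)
  vals <- Mod(Tf)^2
  for (fi in seq_along(freqs)) {
    w <- vals[, , fi] * rep(gu[fi, ], each = 2L)
    vals[, , fi] <- w / rowSums(w)
  }
  structure(list(freqs = freqs, values = vals, normalized = TRUE,
                 labels = model$labels),
            class = "dtf_spectrum")
}

#' Stochastic simulation of the neural-mass model
#'
#' Euler-Maruyama integration of the full nonlinear dynamics with white
#' innovations entering each source's stellate current equation (scaled by
#' the white component `exp(alpha_u)` of the innovation spectrum). The
#' integration step is at most `1/(8 * max(kappa))` and an integer divisor
#' of the output sampling interval; fine-grid output is averaged within
#' output bins. White observation noise with density `exp(alpha_n)` is
#' added to the observed pyramidal depolarizations.
#'
#' @param model an [nmm_model()].
#' @param condition `"W"` or `"A"`.
#' @param duration_s simulated duration in seconds.
#' @param fs output sampling rate in Hz.
#' @param seed integer seed (`NULL` leaves RNG state alone).
#' @param obs_noise add observation noise (default `TRUE`); the noiseless
#'   source outputs support shared-trajectory rendering of several
#'   observation channels.
#' @return An [mc_recording()] (modality `"SYNTH"`, condition as given).
#' @export
simulate_nmm <- function(model, condition = "W", duration_s = 30, fs = 1000,
                         seed = NULL, obs_noise = TRUE) {
  stopifnot(inherits(model, "nmm_model"))
  cond <- match.arg(condition, c("W", "A"))
  lin <- nmm_linearize(model, cond)   # also validates stability
  if (!is.null(seed)) set.seed(seed)
  kmax <- max(model$ke, model$ki)
  # step of 1/(16 kmax): comfortably inside the 1/(8 kmax) stability bound,
  # keeping the Euler-Maruyama variance bias at the few-percent level
  factor <- max(1L, as.integer(ceiling(16 * kmax / fs)))
  dt <- 1 / (fs * factor)
  n_out <- round(duration_s * fs)
  g <- effective_gains(model, cond)
  # innovation scale per fine step: kappa_e He C sqrt(g_u_white) sqrt(dt)
  noise_scale <- model$ke * model$He * model$C *
    sqrt(exp(model$alpha_u)) * sqrt(dt)
  Y <- nmm_simulate_cpp(
    ke = model$ke, ki = model$ki, He = model$He, Hi = model$Hi,
    gamma = g$gamma, rho1 = model$rho1, rho2 = model$rho2,
    fwd_in = g$fwd_in, bwd_in = g$bwd_in,
    noise_scale = noise_scale, x0 = numeric(20L),
    dt = dt, n_out = n_out, factor = factor)
  Y <- t(Y) * rep(model$g_obs, each = n_out)
  if (obs_noise)
    Y <- Y + matrix(stats::rnorm(2L * n_out,
                                 sd = rep(sqrt(exp(model$alpha_n) * fs),
                                          each = n_out)),
                    n_out, 2L)
  mc_recording(Y, fs = fs, channel_labels = model$labels,
               condition = cond, modality = "SYNTH")
}
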