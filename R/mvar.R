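#' Multivariate autoregressive model
#'
#' Container for an order-`p` MVAR model in the regression sign convention
#' `x_t = A_1 x_{t-1} + ... + A_p x_{t-p} + e_t` with white innovations
#' `e_t ~ N(0, noise_cov)`. (The equivalent moving-sum form
#' `sum_j Ahat_j x_{t-j} = e_t` with `Ahat_0 = I` has `Ahat_j = -A_j`;
#' the regression form is stored to keep simulation and spectral code free
#' of sign juggling.)
#'
#' @param coeffs list of `p` square coefficient matrices (`k x k`), or an
#'   empty list for a pure-noise model.
#' @param noise_cov innovation covariance (`k x k`, symmetric PSD).
#' @param fs sampling rate in Hz.
#' @param labels optional channel labels.
#' @return An object of class `mvar_model`.
#' @export
mvar_model <- function(coeffs, noise_cov, fs, labels = NULL) {
  coeffs <- lapply(coeffs, as.matrix)
  noise_cov <- as.matrix(noise_cov)
  k <- nrow(noise_cov)
  if (ncol(noise_cov) != k) stop("noise_cov must be square")
  if (max(abs(noise_cov - t(noise_cov))) > 1e-10)
    stop("noise_cov must be symmetric")
  if (min(eigen(noise_cov, symmetric = TRUE, only.values = TRUE)$values) <
      -1e-10 * max(1, max(abs(noise_cov))))
    stop("noise_cov must be positive semidefinite")
  for (A in coeffs)
    if (!all(dim(A) == c(k, k))) stop("all coefficient matrices must be k x k")
  if (is.null(labels)) labels <- paste0("ch", seq_len(k))
  structure(list(order = length(coeffs), coeffs = coeffs,
                 noise_cov = (noise_cov + t(noise_cov)) / 2,
                 fs = fs, labels = labels),
            class = "mvar_model")
}

#' @export
print.mvar_model <- function(x, ...) {
  cat(sprintf("<mvar_model> order %d, %d channels @ %g Hz, spectral radius %.3f\n",
              x$order, nrow(x$noise_cov), x$fs, check_stability(x)))
  invisible(x)
}

#' Companion-matrix spectral radius of an MVAR model
#'
#' The model is stable (stationary, safe to simulate) iff the spectral
#' radius of its `pk x pk` companion matrix is below 1.
#'
#' @param model an [mvar_model()].
#' @return The spectral radius (0 for a pure-noise model).
#' @export
check_stability <- function(model) {
  p <- model$order
  if (p == 0L) return(0)
  k <- nrow(model$noise_cov)
  C <- matrix(0, p * k, p * k)
  C[1:k, ] <- do.call(cbind, model$coeffs)
  if (p > 1L)
    C[(k + 1):(p * k), 1:((p - 1) * k)] <- diag((p - 1) * k)
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Lagged covariance matrices of segmented data
#'
#' Biased (1/N) estimator `R(s) = E[x_t x_{t+s}^T]`, computed with the
#' per-segment mean removed and averaged across segments.
#'
#' @param segments a [segment_set()], or a single numeric matrix.
#' @param s_max largest lag.
#' @return An object of class `cov_sequence`: list with `lags` (0..s_max)
#'   and `R`, a list of `k x k` matrices.
#' @export
lagged_covariance <- function(segments, s_max) {
  if (is.matrix(segments))
    segments <- segment_set(list(segments), fs = 1)
  stopifnot(inherits(segments, "segment_set"))
  segs <- segments$segments
  n <- nrow(segs[[1L]])
  k <- ncol(segs[[1L]])
  if (s_max >= n)
    stop("s_max (", s_max, ") must be smaller than the segment length (", n, ")")
  R <- lapply(0:s_max, function(s) matrix(0, k, k))
  for (X in segs) {
    X <- sweep(X, 2L, colMeans(X))
    for (s in 0:s_max) {
      # R(s) = (1/n) sum_t x_t x_{t+s}'
      R[[s + 1L]] <- R[[s + 1L]] +
        crossprod(X[1:(n - s), , drop = FALSE],
                  X[(1 + s):n, , drop = FALSE]) / n
    }
  }
  R <- lapply(R, function(M) M / length(segs))
  structure(list(lags = 0:s_max, R = R, k = k), class = "cov_sequence")
}

#' Yule-Walker MVAR fit from lagged covariances
#'
#' Solves the multivariate normal equations
#' `Gamma(s) = sum_j A_j Gamma(s - j)`, `s = 1..p`, where
#' `Gamma(s) = E[x_{t+s} x_t^T] = R(s)^T`, and recovers the innovation
#' covariance from `Sigma = Gamma(0) - sum_j A_j Gamma(j)^T`.
#'
#' @param R a `cov_sequence` from [lagged_covariance()] with lags `>= p`.
#' @param p model order (`p >= 0`).
#' @param fs sampling rate stored on the returned model.
#' @param labels optional channel labels.
#' @return An [mvar_model()].
#' @export
fit_yule_walker <- function(R, p, fs = 1, labels = NULL) {
  stopifnot(inherits(R, "cov_sequence"))
  if (p > max(R$lags)) stop("covariance sequence holds lags up to ",
                            max(R$lags), " but p = ", p)
  k <- R$k
  Gam <- function(s) if (s >= 0) t(R$R[[s + 1L]]) else R$R[[-s + 1L]]
  if (p == 0L)
    return(mvar_model(list(), Gam(0), fs = fs, labels = labels))

  # block system: B %*% M = RHS with B = [A_1 ... A_p] (k x pk),
  # M[(j),(s)] block = Gamma(s - j), RHS = [Gamma(1) ... Gamma(p)]
  M <- matrix(0, p * k, p * k)
  RHS <- matrix(0, k, p * k)
  for (s in 1:p) {
    cols <- ((s - 1) * k + 1):(s * k)
    RHS[, cols] <- Gam(s)
    for (j in 1:p)
      M[((j - 1) * k + 1):(j * k), cols] <- Gam(s - j)
  }
  B <- tryCatch(t(solve(t(M), t(RHS))),
                error = function(e)
                  stop("singular Yule-Walker system at order ", p,
                       "; try a lower order (", conditionMessage(e), ")"))
  coeffs <- lapply(1:p, function(j) B[, ((j - 1) * k + 1):(j * k), drop = FALSE])
  Sigma <- Gam(0)
  for (j in 1:p) Sigma <- Sigma - coeffs[[j]] %*% t(Gam(j))
  Sigma <- (Sigma + t(Sigma)) / 2
  mvar_model(coeffs, Sigma, fs = fs, labels = labels)
}

#' BIC model-order selection for MVAR fits
#'
#' Fits Yule-Walker models of orders `p_min..p_max` to the pooled
#' covariances and returns the order minimizing
#' `N log det(Sigma_p) + log(N) p k^2`, with ties broken toward the
#' smaller order. `N` is the total number of samples across segments.
#'
#' @param segments a [segment_set()].
#' @param p_min,p_max inclusive order range.
#' @return The selected order (integer). The full BIC curve is attached as
#'   `attr(, "bic")`.
#' @export
select_order_bic <- function(segments, p_min = 1L, p_max = 20L) {
  stopifnot(inherits(segments, "segment_set"))
  if (p_max < p_min) stop("empty order range: p_min = ", p_min,
                          ", p_max = ", p_max)
  n_seg <- nrow(segments$segments[[1L]])
  if (p_max >= n_seg / 2)
    stop("p_max must be below half the segment length (", n_seg, ")")
  N <- n_seg * length(segments$segments)
  k <- ncol(segments$segments[[1L]])
  R <- lagged_covariance(segments, p_max)
  orders <- p_min:p_max
  bic <- vapply(orders, function(p) {
    m <- fit_yule_walker(R, p, fs = segments$fs)
    ld <- determinant(m$noise_cov, logarithm = TRUE)
    if (ld$sign <= 0) return(Inf)
    N * as.numeric(ld$modulus) + log(N) * p * k^2
  }, numeric(1L))
  best <- orders[which.min(bic)]   # which.min takes the first = smallest order
  attr(best, "bic") <- stats::setNames(bic, orders)
  best
}

#' Simulate an MVAR process
#'
#' Draws Gaussian innovations with the model's covariance and iterates the
#' regression recursion; a burn-in period is discarded so the output is
#' (approximately) stationary. Reproducible given `seed`.
#'
#' @param model a stable [mvar_model()].
#' @param duration_s length of the returned recording in seconds.
#' @param fs sampling rate (defaults to the model's).
#' @param seed integer seed; `NULL` leaves the RNG state alone.
#' @param burn_s burn-in discarded before recording starts (default 2 s).
#' @return An [mc_recording()] with modality `"SYNTH"`.
#' @export
gen_mvar <- function(model, duration_s, fs = model$fs, seed = NULL,
                     burn_s = 2) {
  stopifnot(inherits(model, "mvar_model"))
  sr <- check_stability(model)
  if (sr >= 1)
    stop(sprintf("model is unstable (spectral radius %.4f >= 1)", sr))
  if (!is.null(seed)) set.seed(seed)
  k <- nrow(model$noise_cov)
  n <- round(duration_s * fs)
  burn <- round(burn_s * fs)
  L <- t(chol(model$noise_cov + diag(1e-14, k)))
  E <- matrix(stats::rnorm((n + burn) * k), nrow = k) # k x (n+burn)
  E <- L %*% E
  A <- if (model$order > 0L) do.call(cbind, model$coeffs) else NULL
  X <- mvar_simulate_cpp(if (is.null(A)) matrix(0, k, 0) else A,
                         E, model$order)
  mc_recording(t(X[, (burn + 1):(burn + n), drop = FALSE]), fs = fs,
               channel_labels = model$labels, modality = "SYNTH")
}

#' Stationary covariance of a stable MVAR model
#'
#' Solves the discrete Lyapunov equation of the companion form, returning
#' the exact lag-0..`s_max` covariances implied by the model. Used as an
#' analytic oracle for the sample estimators.
#'
#' @param model a stable [mvar_model()].
#' @param s_max largest lag required.
#' @return A `cov_sequence` (same structure as [lagged_covariance()]).
#' @export
mvar_stationary_cov <- function(model, s_max) {
  p <- max(model$order, 1L)
  k <- nrow(model$noise_cov)
  C <- matrix(0, p * k, p * k)
  if (model$order > 0L) C[1:k, ] <- do.call(cbind, model$coeffs)
  if (p > 1L) C[(k + 1):(p * k), 1:((p - 1) * k)] <- diag((p - 1) * k)
  Q <- matrix(0, p * k, p * k)
  Q[1:k, 1:k] <- model$noise_cov
  # vec(P) = (I - C (x) C)^{-1} vec(Q)
  P <- matrix(solve(diag((p * k)^2) - kronecker(C, C), as.vector(Q)),
              p * k, p * k)
  # P blocks hold Gamma(i-j) = E[x_{t-j+ i? }]: first block row gives
  # Gamma(0), Gamma(1), ..., Gamma(p-1) with Gamma(s) = E[x_{t} x_{t-s}^T]
  Gam <- vector("list", s_max + 1L)
  for (s in 0:min(s_max, p - 1L))
    Gam[[s + 1L]] <- P[1:k, (s * k + 1):((s + 1) * k)]
  if (s_max >= p) {
    for (s in p:s_max) {
      G <- matrix(0, k, k)
      if (model$order > 0L)
        for (j in 1:model$order) {
          Gj <- Gam[[s - j + 1L]]
          G <- G + model$coeffs[[j]] %*% Gj
        }
      Gam[[s + 1L]] <- G
    }
  }
  # convert Gamma(s) = E[x_t x_{t-s}^T] to R(s) = E[x_t x_{t+s}^T] = Gamma(s)^T
  structure(list(lags = 0:s_max, R = lapply(Gam, t), k = k),
            class = "cov_sequence")
}
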