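#' Default analysis frequency grid
#'
#' 0.5 to 100 Hz in steps of 0.25 Hz; band statistics are taken on
#' \[3, 40\] Hz.
#' @param fmin,fmax,step grid limits and spacing in Hz.
#' @return Numeric vector of frequencies.
#' @export
default_freq_grid <- function(fmin = 0.5, fmax = 100, step = 0.25) {
  seq(fmin, fmax, by = step)
}

#' Spectral transfer matrix of an MVAR model
#'
#' Computes `H(f) = Abar(f)^{-1}` with
#' `Abar(f) = I - sum_j A_j exp(-i 2 pi f dt j)`, `dt = 1/fs`: the transfer
#' from the white innovations to the observed process, `X(f) = H(f) E(f)`.
#'
#' @param model a stable [mvar_model()].
#' @param freqs frequency grid in Hz (default [default_freq_grid()]).
#' @return An object of class `spectral_transfer`: list with `freqs` and
#'   `H`, a complex array `k x k x n_freq`.
#' @export
transfer_matrix <- function(model, freqs = default_freq_grid()) {
  stopifnot(inherits(model, "mvar_model"))
  sr <- check_stability(model)
  if (sr >= 1)
    stop(sprintf("model is unstable (spectral radius %.4f)", sr))
  k <- nrow(model$noise_cov)
  dt <- 1 / model$fs
  H <- array(NA_complex_, c(k, k, length(freqs)))
  I <- diag(k)
  for (fi in seq_along(freqs)) {
    Abar <- I + 0i
    if (model$order > 0L)
      for (j in seq_len(model$order))
        Abar <- Abar - model$coeffs[[j]] * exp(-2i * pi * freqs[fi] * dt * j)
    Hf <- tryCatch(solve(Abar),
                   error = function(e)
                     stop(sprintf("coefficient matrix numerically singular at %g Hz",
                                  freqs[fi])))
    H[, , fi] <- Hf
  }
  structure(list(freqs = freqs, H = H, labels = model$labels, fs = model$fs),
            class = "spectral_transfer")
}

#' Directed transfer function from a spectral transfer matrix
#'
#' `values[i, j, f]` quantifies the flow `j -> i` at frequency `f`. The
#' normalized form divides each squared transfer magnitude by the total
#' inflow to channel `i`, so every row sums to 1 and values lie in
#' \[0, 1\]; the unnormalized form is the raw squared magnitude.
#'
#' @param H a `spectral_transfer` (from [transfer_matrix()]) or a complex
#'   `k x k x n_freq` array accompanied by `freqs`.
#' @param normalized normalize rows over inflows (default `TRUE`).
#' @param freqs frequency grid, required when `H` is a bare array.
#' @param labels optional channel labels.
#' @return An object of class `dtf_spectrum`: list with `freqs`, `values`
#'   (real array `k x k x n_freq`), `normalized`, `labels`.
#' @export
compute_dtf <- function(H, normalized = TRUE, freqs = NULL, labels = NULL) {
  if (inherits(H, "spectral_transfer")) {
    freqs <- H$freqs
    if (is.null(labels)) labels <- H$labels
    H <- H$H
  }
  stopifnot(is.array(H), length(dim(H)) == 3L)
  if (is.null(freqs)) stop("freqs must be supplied with a bare array")
  vals <- Mod(H)^2
  if (normalized) {
    for (fi in seq_len(dim(vals)[3L])) {
      rs <- rowSums(vals[, , fi, drop = FALSE][, , 1L, drop = FALSE])
      dim(rs) <- NULL
      if (any(rs <= 0))
        stop("all-zero inflow row in transfer matrix (internal error)")
      vals[, , fi] <- vals[, , fi] / rs
    }
  }
  if (is.null(labels)) labels <- paste0("ch", seq_len(dim(vals)[1L]))
  structure(list(freqs = freqs, values = vals, normalized = normalized,
                 labels = labels),
            class = "dtf_spectrum")
}

#' @export
print.dtf_spectrum <- function(x, ...) {
  cat(sprintf("<dtf_spectrum> %d channels, %d frequencies [%g, %g] Hz, %s\n",
              dim(x$values)[1L], length(x$freqs), min(x$freqs), max(x$freqs),
              if (x$normalized) "normalized" else "unnormalized"))
  invisible(x)
}

#' Parametric power spectral matrix of an MVAR model
#'
#' `S(f) = H(f) Sigma H(f)^H / fs`: the two-sided spectral density matrix
#' implied by the fitted coefficients and innovation covariance, in units
#' of power per Hz (so `2 * integral over [0, fs/2]` of a diagonal entry
#' recovers that channel's process variance).
#'
#' @param model a stable [mvar_model()].
#' @param freqs frequency grid in Hz.
#' @return List with `freqs` and `S`, a complex `k x k x n_freq` array
#'   (Hermitian at every frequency), class `mvar_spectrum`.
#' @export
mvar_spectrum <- function(model, freqs = default_freq_grid()) {
  Ht <- transfer_matrix(model, freqs)
  k <- nrow(model$noise_cov)
  S <- array(NA_complex_, dim(Ht$H))
  for (fi in seq_along(freqs)) {
    Hf <- Ht$H[, , fi]
    Sf <- Hf %*% model$noise_cov %*% Conj(t(Hf)) / model$fs
    S[, , fi] <- (Sf + Conj(t(Sf))) / 2
  }
  structure(list(freqs = freqs, S = S, labels = model$labels),
            class = "mvar_spectrum")
}

#' Fit per-segment DTFs for a segment set
#'
#' Fits one Yule-Walker model of order `p` per segment and returns the
#' corresponding normalized DTF spectra. This per-segment route provides
#' the sampling distribution used by the condition contrasts.
#'
#' @param segments a [segment_set()].
#' @param p model order; `"auto"` selects by [select_order_bic()] on the
#'   pooled segments.
#' @param freqs frequency grid in Hz.
#' @param p_max upper bound for automatic order selection.
#' @return List of `dtf_spectrum`, one per segment; the order used is
#'   attached as `attr(, "order")`.
#' @export
segment_dtfs <- function(segments, p = 7L, freqs = default_freq_grid(),
                         p_max = 20L) {
  stopifnot(inherits(segments, "segment_set"))
  if (identical(p, "auto")) p <- select_order_bic(segments, 1L, p_max)
  out <- lapply(segments$segments, function(X) {
    R <- lagged_covariance(segment_set(list(X), fs = segments$fs), p)
    m <- fit_yule_walker(R, p, fs = segments$fs, labels = segments$labels)
    compute_dtf(transfer_matrix(m, freqs))
  })
  attr(out, "order") <- as.integer(p)
  out
}

#' Data-driven condition contrast for one modality
#'
#' Convenience wrapper over the data-driven track: per-segment Yule-Walker
#' DTFs for both conditions followed by [compare_conditions()].
#'
#' @param segments_w,segments_a [segment_set()]s for conditions W and A.
#' @param p MVAR order (default 7) or `"auto"`.
#' @param freqs frequency grid.
#' @param band statistics band in Hz.
#' @param q FDR level.
#' @return The contrast table from [compare_conditions()].
#' @export
run_dtf_pipeline <- function(segments_w, segments_a, p = 7L,
                             freqs = default_freq_grid(), band = c(3, 40),
                             q = 0.05) {
  compare_conditions(segment_dtfs(segments_w, p, freqs),
                     segment_dtfs(segments_a, p, freqs),
                     band = band, q = q)
}
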