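#' Welch cross-spectral density of segmented data
#'
#' Averages modified cross-periodograms over Hann windows (default 1 s,
#' 50% overlap) within and across segments, then interpolates the Hermitian
#' spectral matrix onto the requested grid. Densities are two-sided
#' (power per Hz): `2 * integral over (0, fs/2]` of a diagonal entry
#' approximates that channel's variance.
#'
#' @param segments a [segment_set()] (or an [mc_recording()], treated as a
#'   single segment).
#' @param freqs target frequency grid in Hz; must lie within
#'   `(0, fs/2]`. Default: the native window resolution up to 100 Hz.
#' @param window_s window length in seconds (default 1).
#' @param overlap fractional overlap between windows (default 0.5).
#' @return A `csd_spectrum`: list with `freqs`, `G` (complex
#'   `k x k x n_freq`), `labels`.
#' @export
estimate_csd_welch <- function(segments, freqs = NULL, window_s = 1,
                               overlap = 0.5) {
  if (inherits(segments, "mc_recording"))
    segments <- segment_set(list(segments$data), fs = segments$fs,
                            labels = segments$channel_labels,
                            condition = segments$condition,
                            modality = segments$modality)
  stopifnot(inherits(segments, "segment_set"))
  fs <- segments$fs
  nw <- round(window_s * fs)
  n_seg <- nrow(segments$segments[[1L]])
  if (n_seg < 2 * nw)
    stop("segments must be at least twice the window length (",
         n_seg, " < ", 2 * nw, " samples)")
  k <- ncol(segments$segments[[1L]])
  step <- max(1L, round(nw * (1 - overlap)))
  win <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))   # Hann
  U <- fs * sum(win^2)
  nf <- nw %/% 2L + 1L
  f_native <- (seq_len(nf) - 1L) * fs / nw
  acc <- array(0 + 0i, c(k, k, nf))
  n_win <- 0L
  for (X in segments$segments) {
    starts <- seq(1L, nrow(X) - nw + 1L, by = step)
    for (s in starts) {
      W <- X[s:(s + nw - 1L), , drop = FALSE]
      W <- sweep(W, 2L, colMeans(W)) * win
      Fm <- stats::mvfft(W)[seq_len(nf), , drop = FALSE]     # nf x k
      for (i in seq_len(k))
        for (j in seq_len(k))
          acc[i, j, ] <- acc[i, j, ] + Fm[, i] * Conj(Fm[, j]) / U
      n_win <- n_win + 1L
    }
  }
  acc <- acc / n_win
  if (is.null(freqs)) freqs <- f_native[f_native > 0 & f_native <= 100]
  if (any(freqs <= 0) || any(freqs > fs / 2))
    stop("requested frequencies must lie in (0, fs/2]")
  G <- array(NA_complex_, c(k, k, length(freqs)))
  for (i in seq_len(k))
    for (j in seq_len(k)) {
      re <- stats::approx(f_native, Re(acc[i, j, ]), xout = freqs)$y
      im <- stats::approx(f_native, Im(acc[i, j, ]), xout = freqs)$y
      G[i, j, ] <- complex(real = re, imaginary = im)
    }
  structure(list(freqs = freqs, G = G, labels = segments$labels),
            class = "csd_spectrum")
}

#' @export
print.csd_spectrum <- function(x, ...) {
  cat(sprintf("<csd_spectrum> %d channels, %d frequencies [%g, %g] Hz\n",
              dim(x$G)[1L], length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Magnitude-squared coherence from a cross-spectral density
#'
#' @param csd a `csd_spectrum`.
#' @param i,j channel indices (default 1, 2).
#' @return Numeric vector of coherence values per frequency.
#' @export
csd_coherence <- function(csd, i = 1L, j = 2L) {
  Mod(csd$G[i, j, ])^2 / (Re(csd$G[i, i, ]) * Re(csd$G[j, j, ]))
}
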