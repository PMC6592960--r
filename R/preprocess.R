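#' Common-average reference
#'
#' Subtracts, at every sample, the instantaneous mean across channels.
#' Idempotent: a re-referenced recording is unchanged by a second pass.
#'
#' @param rec an [mc_recording()] with at least two channels.
#' @return The re-referenced recording.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "mc_recording"))
  if (n_channels(rec) < 2L)
    stop("average reference requires at least 2 channels")
  rec$data <- rec$data - rowMeans(rec$data)
  rec
}

# Zero-phase IIR filtering: forward-backward application with
# odd-reflection padding and step-matched initial conditions, so narrow
# (high-Q) filters do not leak start-up transients into the data. The pad
# length covers several decay times of the slowest pole.
zero_phase_filter <- function(b, a, x) {
  n <- length(x)
  poles <- polyroot(rev(a))
  r <- max(Mod(poles))
  decay <- if (r >= 1 || r == 0) n else ceiling(3 / (1 - r))
  L <- min(n - 1L, max(decay, 3L * length(a)))
  pad_front <- 2 * x[1L] - x[(L + 1L):2L]
  pad_back <- 2 * x[n] - x[(n - 1L):(n - L)]
  xp <- c(pad_front, x, pad_back)
  dc <- sum(b) / sum(a)
  one_pass <- function(y) {
    init_x <- rep(y[1L], length(b) - 1L)
    init_y <- rep(y[1L] * dc, length(a) - 1L)
    as.numeric(signal::filter(b, a, y, init.x = init_x, init.y = init_y))
  }
  yp <- rev(one_pass(rev(one_pass(xp))))
  yp[(L + 1L):(L + n)]
}

# Second-order IIR notch biquad (Audio EQ cookbook form). Unity gain at DC
# and Nyquist by construction: numerator and denominator coincide at z = 1
# and z = -1.
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1L], a = a / a[1L])
}

#' Zero-phase notch filter
#'
#' Removes a narrow band around `f0` (line noise) with a second-order IIR
#' notch applied forward and backward ([signal::filtfilt()]), giving zero
#' phase distortion and squaring the magnitude response.
#'
#' @param rec an [mc_recording()].
#' @param f0 notch centre frequency in Hz (default 50, European mains).
#' @param q quality factor `f0 / bandwidth`; default 35.
#' @return The filtered recording.
#' @export
notch_filter <- function(rec, f0 = 50, q = 35) {
  stopifnot(inherits(rec, "mc_recording"))
  if (f0 <= 0 || f0 >= rec$fs / 2)
    stop("notch frequency must satisfy 0 < f0 < fs/2 (f0 = ", f0,
         ", fs = ", rec$fs, ")")
  coef <- notch_biquad(f0, rec$fs, q)
  rec$data <- apply(rec$data, 2L, function(x)
    zero_phase_filter(coef$b, coef$a, x))
  rec
}

#' Piecewise-linear trend extraction by \eqn{\ell_1} trend filtering
#'
#' Solves `minimize 0.5 * ||x - t||_2^2 + lam * ||D2 t||_1` where `D2` is the
#' second-difference operator, yielding a continuous piecewise-linear trend.
#' Solved by ADMM on the split `z = D2 t`; convergence is declared when the
#' duality gap (primal objective minus the dual objective at the projected
#' dual point) falls below `tol` relative to the objective scale.
#'
#' As `lam -> 0` the trend tends to the signal itself; as `lam -> Inf` it
#' tends to the affine least-squares fit (the second difference of a line
#' is zero).
#'
#' @param signal numeric vector, length >= 3.
#' @param lam positive regularization weight.
#' @param tol duality-gap tolerance (relative); default 1e-8.
#' @param max_iter ADMM iteration cap.
#' @return A list with components `trend` and `residual`
#'   (`residual = signal - trend`).
#' @export
l1_detrend <- function(signal, lam, tol = 1e-8, max_iter = 5000L) {
  x <- as.numeric(signal)
  n <- length(x)
  if (n < 3L) stop("l1_detrend requires at least 3 samples")
  if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam) || lam <= 0)
    stop("lam must be a positive finite scalar")

  D <- second_diff_matrix(n)                       # (n-2) x n, sparse
  DtD <- Matrix::crossprod(D)
  rho <- max(lam, 1)
  ch <- Matrix::Cholesky(DtD * rho + Matrix::Diagonal(n), LDL = FALSE)

  obj <- function(t) {
    0.5 * sum((x - t)^2) + lam * sum(abs(as.numeric(D %*% t)))
  }
  # dual: maximize -0.5*||D' nu||^2 + nu' D x  subject to |nu| <= lam
  dual_obj <- function(nu) {
    Dtnu <- as.numeric(Matrix::crossprod(D, nu))
    -0.5 * sum(Dtnu^2) + sum(nu * as.numeric(D %*% x))
  }

  t <- x
  z <- as.numeric(D %*% t)
  u <- numeric(n - 2L)
  scale <- 0.5 * sum(x^2) + 1
  for (it in seq_len(max_iter)) {
    rhs <- x + rho * as.numeric(Matrix::crossprod(D, z - u))
    t <- as.numeric(Matrix::solve(ch, rhs))
    Dt <- as.numeric(D %*% t)
    z <- soft_threshold(Dt + u, lam / rho)
    u <- u + Dt - z
    if (it %% 10L == 0L || it <= 2L) {
      nu <- pmin(pmax(rho * u, -lam), lam)
      gap <- obj(t) - dual_obj(nu)
      if (gap <= tol * max(scale, abs(obj(t)))) break
    }
  }
  trend <- t
  list(trend = trend, residual = x - trend)
}

second_diff_matrix <- function(n) {
  i <- rep(seq_len(n - 2L), each = 3L)
  j <- as.vector(vapply(seq_len(n - 2L), function(r) r + 0:2, integer(3L)))
  v <- rep(c(1, -2, 1), n - 2L)
  Matrix::sparseMatrix(i = i, j = j, x = v, dims = c(n - 2L, n))
}

soft_threshold <- function(v, k) sign(v) * pmax(abs(v) - k, 0)

#' Apply \eqn{\ell_1} detrending channel-wise in local windows
#'
#' Runs [l1_detrend()] on consecutive windows of each channel (local
#' detrending) and returns the residual (detrended) recording. When `lam` is
#' `NULL` it is set per window to `10 *` the window variance.
#'
#' @param rec an [mc_recording()].
#' @param lam regularization weight, or `NULL` for the variance-scaled default.
#' @param window_s window length in seconds (default 2).
#' @return The detrended recording.
#' @export
detrend_channels <- function(rec, lam = NULL, window_s = 2) {
  stopifnot(inherits(rec, "mc_recording"))
  n <- n_samples(rec)
  wlen <- max(3L, round(window_s * rec$fs))
  starts <- seq(1L, n, by = wlen)
  for (ch in seq_len(n_channels(rec))) {
    for (s in starts) {
      e <- min(s + wlen - 1L, n)
      if (e - s + 1L < 3L) next
      seg <- rec$data[s:e, ch]
      l <- if (is.null(lam)) 10 * max(stats::var(seg), .Machine$double.eps) else lam
      rec$data[s:e, ch] <- l1_detrend(seg, l)$residual
    }
  }
  rec
}

#' Flag high-amplitude artefact samples by robust z-score
#'
#' Computes per-channel robust z-scores (deviation from the channel median
#' scaled by 1.4826 * MAD) and flags samples where any channel exceeds
#' `z_thresh`. A channel with zero MAD (constant) is skipped with a warning.
#' The mask is stored on the recording (`attr(rec, "artifact_mask")`) and
#' honoured by [segment_recording()].
#'
#' @param rec an [mc_recording()].
#' @param z_thresh positive threshold on the robust z-score (default 8).
#' @return The recording with a logical `artifact_mask` attribute
#'   (`TRUE` = flagged).
#' @export
reject_artifacts <- function(rec, z_thresh = 8) {
  stopifnot(inherits(rec, "mc_recording"))
  if (!is.numeric(z_thresh) || z_thresh <= 0) stop("z_thresh must be > 0")
  mask <- rep(FALSE, n_samples(rec))
  for (ch in seq_len(n_channels(rec))) {
    x <- rec$data[, ch]
    med <- stats::median(x)
    s <- stats::mad(x)
    if (s == 0) {
      warning("channel ", rec$channel_labels[ch],
              " has zero MAD; skipped in artefact detection")
      next
    }
    mask <- mask | (abs(x - med) / s > z_thresh)
  }
  attr(rec, "artifact_mask") <- mask
  rec
}

#' Cut a recording into equal non-overlapping segments
#'
#' Takes `n_segments` contiguous, non-overlapping segments of
#' `seg_duration_s` seconds from the start of the (unmasked) data. If an
#' artefact mask is present (see [reject_artifacts()]) segments are drawn
#' from contiguous unmasked runs, in temporal order, without crossing a
#' masked span.
#'
#' @param rec an [mc_recording()].
#' @param seg_duration_s segment length in seconds.
#' @param n_segments number of segments required.
#' @return A [segment_set()].
#' @export
segment_recording <- function(rec, seg_duration_s, n_segments) {
  stopifnot(inherits(rec, "mc_recording"))
  seg_len <- round(seg_duration_s * rec$fs)
  if (seg_len < 1L) stop("segment length must be at least one sample")
  mask <- attr(rec, "artifact_mask")
  if (is.null(mask)) mask <- rep(FALSE, n_samples(rec))

  runs <- rle(!mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  avail <- sum(runs$lengths[runs$values] %/% seg_len)
  if (avail < n_segments)
    stop(sprintf(paste0("insufficient data: %d segments of %d samples ",
                        "requested but only %d whole segments available ",
                        "(%d of %d samples unmasked)"),
                 n_segments, seg_len, avail, sum(!mask), n_samples(rec)))

  segs <- vector("list", n_segments)
  got <- 0L
  for (r in which(runs$values)) {
    pos <- starts[r]
    while (pos + seg_len - 1L <= ends[r] && got < n_segments) {
      got <- got + 1L
      segs[[got]] <- rec$data[pos:(pos + seg_len - 1L), , drop = FALSE]
      pos <- pos + seg_len
    }
    if (got == n_segments) break
  }
  segment_set(segs, fs = rec$fs, labels = rec$channel_labels,
              condition = rec$condition, modality = rec$modality)
}

#' Full preprocessing chain
#'
#' Applies, in order: common-average reference, zero-phase notch filter,
#' local \eqn{\ell_1} detrending per channel, optional robust-z artefact
#' masking, and segmentation.
#'
#' Common-average referencing is meaningful when the recording holds the
#' full electrode array; once the analysis has been restricted to a
#' two-channel source pair it would leave rank-one data (the two channels
#' become exact negatives), so set `average_ref = FALSE` when `rec` already
#' contains only the selected pair.
#'
#' @param rec an [mc_recording()].
#' @param average_ref apply the common-average reference (default `TRUE`;
#'   use `FALSE` for an already-extracted source pair).
#' @param notch_hz notch centre frequency (Hz); `NULL` skips the notch.
#' @param detrend_lam detrending weight passed to [detrend_channels()]
#'   (`NULL` = variance-scaled default); `NA` skips detrending.
#' @param z_thresh artefact threshold; `NULL` disables artefact masking
#'   (the default for synthetic runs).
#' @param seg_duration_s,n_segments segmentation parameters.
#' @return A [segment_set()].
#' @export
preprocess_recording <- function(rec, average_ref = TRUE, notch_hz = 50,
                                 detrend_lam = NULL, z_thresh = NULL,
                                 seg_duration_s = 2, n_segments = 15) {
  if (average_ref) rec <- average_reference(rec)
  if (!is.null(notch_hz)) rec <- notch_filter(rec, notch_hz)
  if (!(length(detrend_lam) == 1L && is.na(detrend_lam)))
    rec <- detrend_channels(rec, detrend_lam)
  if (!is.null(z_thresh)) rec <- reject_artifacts(rec, z_thresh)
  segment_recording(rec, seg_duration_s, n_segments)
}
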