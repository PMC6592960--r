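#' Scenario specification for synthetic condition pairs
#'
#' Bundles a generative model, recording parameters and the degradation
#' channel that emulates source-reconstructed (scalp-derived) observations:
#' linear mixing between the sources, additive white noise at a given SNR,
#' and a zero-phase low-pass at 60 Hz (scalp signals carry no reliable
#' content above that).
#'
#' @param generator `"nmm"` (neural-mass, [simulate_nmm()]) or `"mvar"`
#'   ([gen_mvar()]).
#' @param model the generating [nmm_model()] or [mvar_model()] (with any
#'   condition scalings already set on an nmm model).
#' @param duration_s recording length per condition (default 30 s).
#' @param fs sampling rate (default 1000 Hz).
#' @param seed master seed; per-condition/per-modality substream seeds are
#'   derived deterministically from it.
#' @param mixing 2 x 2 nonsingular mixing matrix for the degraded modality.
#' @param snr_db signal-to-noise ratio of the degraded modality in dB.
#' @param lowpass_hz low-pass cutoff of the degraded modality.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(generator = c("nmm", "mvar"), model,
                          duration_s = 30, fs = 1000, seed = 42L,
                          mixing = matrix(c(1, 0.3, 0.3, 1), 2L, 2L),
                          snr_db = 10, lowpass_hz = 60) {
  generator <- match.arg(generator)
  if (abs(det(mixing)) < 1e-12) stop("mixing matrix must be nonsingular")
  structure(list(generator = generator, model = model,
                 duration_s = duration_s, fs = fs, seed = as.integer(seed),
                 mixing = mixing, snr_db = snr_db, lowpass_hz = lowpass_hz),
            class = "scenario_spec")
}

# deterministic substream seeds: master + slot * large prime, kept within
# 32-bit integer range
derive_seed <- function(master, slot) {
  as.integer((as.numeric(master) + slot * 999983) %% .Machine$integer.max)
}

#' Degrade a clean recording into an emulated reconstructed-source pair
#'
#' `output = lowpass(mixing %*% sources) + noise`: instantaneous linear
#' mixing (volume-conduction-like leakage of the inverse solution), a
#' zero-phase Butterworth low-pass at `lowpass_hz`, and additive white
#' noise with standard deviation `noise_sd` per channel. Sampling rate and
#' temporal order are untouched.
#'
#' @param rec an [mc_recording()] with 2 channels.
#' @param mixing 2 x 2 nonsingular matrix.
#' @param noise_sd additive white-noise SD (same units as the data).
#' @param lowpass_hz cutoff in Hz; a value at or above Nyquist skips the
#'   filter.
#' @param order Butterworth order (default 4).
#' @return The degraded recording, modality `"RS"`.
#' @export
degrade_to_reconstructed <- function(rec, mixing = matrix(c(1, 0.3, 0.3, 1), 2L, 2L),
                                     noise_sd = 0, lowpass_hz = 60,
                                     order = 4L) {
  stopifnot(inherits(rec, "mc_recording"))
  if (abs(det(mixing)) < 1e-12) stop("mixing matrix must be nonsingular")
  Y <- rec$data %*% t(mixing)
  if (lowpass_hz < rec$fs / 2) {
    bf <- signal::butter(order, lowpass_hz / (rec$fs / 2), type = "low")
    Y <- apply(Y, 2L, function(x) zero_phase_filter(bf$b, bf$a, x))
  }
  if (noise_sd > 0)
    Y <- Y + matrix(stats::rnorm(length(Y), sd = noise_sd), nrow(Y), ncol(Y))
  out <- mc_recording(Y, fs = rec$fs, channel_labels = rec$channel_labels,
                      condition = rec$condition, modality = "RS")
  out
}

#' Generate a wakefulness/anaesthesia condition pair in two modalities
#'
#' Simulates the scenario's generative model once per condition (condition
#' `"W"` with all condition scalings inactive, condition `"A"` with the
#' model's scalings applied) and renders each condition twice from the same
#' underlying source trajectories: a clean intracranial-like recording
#' (`"ECOG"`) and a degraded reconstructed-source recording (`"RS"`, see
#' [degrade_to_reconstructed()]). Substream seeds are derived
#' deterministically from the master seed.
#'
#' @param spec a [scenario_spec()].
#' @param seed optional master-seed override.
#' @return Nested list: `$W$ECOG`, `$W$RS`, `$A$ECOG`, `$A$RS`, each an
#'   [mc_recording()].
#' @export
gen_condition_pair <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  master <- if (is.null(seed)) spec$seed else as.integer(seed)
  out <- list()
  for (ci in 1:2) {
    cond <- c("W", "A")[ci]
    if (spec$generator == "nmm") {
      clean <- simulate_nmm(spec$model, cond, spec$duration_s, spec$fs,
                            seed = derive_seed(master, ci))
    } else {
      clean <- gen_mvar(spec$model, spec$duration_s, spec$fs,
                        seed = derive_seed(master, ci))
      clean$condition <- cond
    }
    clean$modality <- "ECOG"
    # degraded rendering shares the source trajectories; only the noise
    # draw uses a fresh substream
    set.seed(derive_seed(master, ci + 10L))
    noise_sd <- mean(apply(clean$data, 2L, stats::sd)) /
      sqrt(10^(spec$snr_db / 10))
    degraded <- degrade_to_reconstructed(clean, spec$mixing, noise_sd,
                                         spec$lowpass_hz)
    out[[cond]] <- list(ECOG = clean, RS = degraded)
  }
  out
}

#' Reference anaesthesia scenario
#'
#' The packaged default scenario: a two-source neural-mass generator under
#' architecture 1 (forward connection from the parietal to the frontal
#' source, backward from frontal to parietal) in which anaesthesia reduces
#' the forward gain (`b_fwd = -0.7`, i.e. to about 50% of its wakefulness
#' strength) and moderately increases both sources' inhibitory
#' self-connections (`b_self = +0.3`). Extrinsic gains are asymmetric
#' (`a_fwd = 384`, `a_bwd = 64`) so that both cross-direction transfer
#' functions are of comparable, clearly measurable magnitude in
#' wakefulness; 30 s per condition at 1000 Hz.
#'
#' @param seed master seed (default 42).
#' @param b_fwd,b_bwd,b_self condition-effect overrides.
#' @return A [scenario_spec()].
#' @export
anaesthesia_scenario <- function(seed = 42L, b_fwd = -0.7, b_bwd = 0,
                                 b_self = c(0.3, 0.3)) {
  m <- nmm_model(a_fwd = 384, a_bwd = 64,
                 b_fwd = b_fwd, b_bwd = b_bwd, b_self = b_self,
                 alpha_n = log(1e-8), beta_n = log(1e-8))
  scenario_spec("nmm", m, duration_s = 30, fs = 1000, seed = seed)
}

#' Null scenario (no condition effect)
#'
#' The [anaesthesia_scenario()] generator with every condition scaling set
#' to zero, so conditions W and A are statistically exchangeable. Used for
#' calibration of the condition contrasts.
#'
#' @param seed master seed.
#' @return A [scenario_spec()].
#' @export
null_scenario <- function(seed = 42L) {
  anaesthesia_scenario(seed = seed, b_fwd = 0, b_bwd = 0, b_self = c(0, 0))
}

#' Random stable MVAR surrogate model
#'
#' Draws coefficient matrices with i.i.d. Gaussian entries (scale decaying
#' with lag) and rescales lag `j` by `c^j` so the companion spectral
#' radius equals `radius`, giving a stable process with known directed
#' structure. Innovations are unit-variance white noise. Optionally zeroes
#' the upper-triangular coupling blocks (`lower_triangular = TRUE`) so one
#' direction of influence is causally absent.
#'
#' @param k number of channels.
#' @param p model order.
#' @param radius target companion spectral radius (default 0.8).
#' @param fs sampling rate stored on the model.
#' @param lower_triangular restrict to lower-triangular coefficients.
#' @param seed optional seed.
#' @return An [mvar_model()].
#' @export
random_stable_mvar <- function(k = 2L, p = 7L, radius = 0.8, fs = 1000,
                               lower_triangular = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(radius > 0, radius < 1)
  coeffs <- lapply(seq_len(p), function(j)
    matrix(stats::rnorm(k * k, sd = 0.5 / j), k, k))
  if (lower_triangular)
    coeffs <- lapply(coeffs, function(A) { A[upper.tri(A)] <- 0; A })
  m <- mvar_model(coeffs, diag(k), fs = fs)
  r <- check_stability(m)
  if (r > 0) {
    c_scale <- radius / r
    m$coeffs <- lapply(seq_len(p), function(j) coeffs[[j]] * c_scale^j)
  }
  # the per-lag rescaling is exact: eigenvalues of the companion matrix
  # scale linearly when A_j -> c^j A_j
  m
}
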