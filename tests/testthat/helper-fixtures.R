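# fixture builders shared across test files

make_recording <- function(n = 100, k = 2, fs = 1000, seed = 1,
                           labels = paste0("ch", seq_len(k))) {
  set.seed(seed)
  mc_recording(matrix(rnorm(n * k), n, k), fs = fs, channel_labels = labels)
}

# bivariate AR(1) with known lower-triangular structure (1 drives 2)
lower_tri_ar1 <- function(a11 = 0.5, a21 = 0.4, a22 = 0.7, fs = 1000) {
  mvar_model(list(matrix(c(a11, a21, 0, a22), 2, 2)), diag(2), fs = fs)
}

# quiet neural-mass model for spectral cross-checks: weak innovations keep
# the dynamics near the linear regime, negligible 1/f and observation noise
quiet_nmm <- function(a_fwd = 384, a_bwd = 64, ...) {
  nmm_model(a_fwd = a_fwd, a_bwd = a_bwd,
            alpha_u = log(1e-4), beta_u = -30,
            alpha_n = log(1e-12), beta_n = -30, ...)
}

band_avg <- function(dtf, from, to, band = c(3, 40))
  band_average_dtf(dtf, band, c(from, to))
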