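make_flat_dtf <- function(val12 = 0.3, val21 = 0.4,
                          freqs = default_freq_grid(),
                          labels = c("F", "P")) {
  nf <- length(freqs)
  vals <- array(0, c(2, 2, nf))
  vals[1, 2, ] <- val12          # flow P -> F
  vals[2, 1, ] <- val21          # flow F -> P
  vals[1, 1, ] <- 1 - val12
  vals[2, 2, ] <- 1 - val21
  structure(list(freqs = freqs, values = vals, normalized = TRUE,
                 labels = labels), class = "dtf_spectrum")
}

test_that("band averaging respects the inclusive band contract", {
  d <- make_flat_dtf(0.3, 0.4)
  expect_equal(band_average_dtf(d, c(3, 40), c("P", "F")), 0.3)
  expect_equal(band_average_dtf(d, c(3, 40), c(1, 2)), 0.4)

  # linear ramp across a symmetric grid averages to its midpoint
  freqs <- seq(3, 40, by = 0.25)
  ramp <- make_flat_dtf(0, 0, freqs = freqs)
  ramp$values[1, 2, ] <- seq(0, 1, length.out = length(freqs))
  expect_equal(band_average_dtf(ramp, c(3, 40), c("P", "F")), 0.5)

  # only grid points inside [f_lo, f_hi] contribute
  d2 <- make_flat_dtf(0, 0, freqs = c(2.75, 3, 20, 40, 40.25))
  d2$values[1, 2, ] <- c(100, 1, 2, 3, 100)
  expect_equal(band_average_dtf(d2, c(3, 40), c("P", "F")), 2)

  expect_error(band_average_dtf(d, c(40, 3), c("P", "F")), "f_lo < f_hi")
  expect_error(band_average_dtf(d2, c(2.8, 2.9), c("P", "F")), "no grid")
})

test_that("rank-sum test reproduces exact and asymptotic references", {
  same <- ranksum_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-9)

  # fully separated 3 vs 3: 2 extreme assignments out of choose(6,3) = 20
  sep <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(sep$p_value, 0.1, tolerance = 1e-12)

  big <- ranksum_test(1:15, 100 + 1:15)
  expect_lt(big$p_value, 1e-5)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  single <- fdr_bh(0.03)
  expect_equal(single$p_adjusted, 0.03)

  two <- fdr_bh(c(0.005, 0.05), q = 0.05)
  expect_equal(two$p_adjusted, c(0.01, 0.05))
  expect_equal(two$reject, c(TRUE, TRUE))

  four <- fdr_bh(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(four$p_adjusted, rep(0.04, 4))

  # monotone in the raw values and permutation-equivariant
  set.seed(2)
  p <- runif(20)
  adj <- fdr_bh(p)$p_adjusted
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  perm <- sample(20)
  expect_equal(fdr_bh(p[perm])$p_adjusted, adj[perm])

  expect_error(fdr_bh(c(0.5, 1.2)), "0, 1")
})

test_that("condition contrasts detect shifts, stay null when exchangeable,
           and are symmetric under condition swap", {
  set.seed(4)
  n_seg <- 15
  base <- lapply(1:n_seg, function(i) make_flat_dtf(0.3 + rnorm(1, 0, 0.02),
                                                    0.4 + rnorm(1, 0, 0.02)))
  same <- compare_conditions(base, base)
  expect_false(any(same$significant))
  expect_equal(attr(same, "family_size"), 2L)

  # P -> F shifted down by 5 segment SDs in condition A
  shifted <- lapply(1:n_seg, function(i)
    make_flat_dtf(0.3 - 0.1 + rnorm(1, 0, 0.02), 0.4 + rnorm(1, 0, 0.02)))
  ct <- compare_conditions(base, shifted)
  hit <- ct[ct$from == "P" & ct$to == "F", ]
  expect_true(hit$significant)
  expect_lt(hit$effect, 0)

  # swapping W and A flips the sign and preserves p-values
  rev <- compare_conditions(shifted, base)
  expect_equal(rev$p_raw, ct$p_raw)
  expect_equal(rev$effect, -ct$effect)

  # two modalities -> family of 4, recorded in the metadata
  both <- compare_conditions(list(ECOG = base, RS = base),
                             list(ECOG = shifted, RS = shifted))
  expect_equal(attr(both, "family_size"), 4L)
  expect_equal(nrow(both), 4L)
  expect_setequal(unique(both$modality), c("ECOG", "RS"))

  expect_error(compare_conditions(base, base[-1]), "segment counts")
})
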