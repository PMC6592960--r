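---
title: "Directed spectral connectivity between two cortical sources: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed spectral connectivity between two cortical sources: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dirspec)
```

## Scope and scientific question

`dirspec` estimates *directed* interactions between a frontal (F) and a
parietal (P) cortical source recorded in two conditions — wakefulness (W)
and anaesthesia (A) — by two complementary routes:

1. **Data-driven track.** A multivariate autoregressive (MVAR) model is
   fitted to short segments of the two-channel recording; its spectral
   transfer matrix yields the normalized directed transfer function (DTF),
   whose band averages are contrasted across conditions with a rank-sum
   test under false-discovery-rate control.
2. **Model-based track.** A biophysical two-source neural-mass model
   generates a predicted cross-spectral density (CSD); it is fitted to the
   observed Welch cross-spectra by variational Laplace, and competing
   hypotheses about the connection architecture and about which couplings
   change under anaesthesia are compared through approximate log evidences
   (fixed-effects Bayesian model selection, BMS).

Because invasive recordings are not shipped with the package, every claim
the test suite makes is grounded in synthetic data whose ground truth is
known; the generator is first-class, tested code.

## The data-driven track

### MVAR model and DTF

Each 2 s segment is modelled as
$x_t = \sum_{j=1}^{p} A_j x_{t-j} + e_t$
with white innovations $e_t \sim \mathcal N(0, \Sigma)$. Coefficients are
estimated by Yule–Walker: the lagged covariances
$R(s) = E[x_t x_{t+s}^\top]$ (biased $1/N$ estimator, per-segment mean
removed, averaged over segments) define a block-Toeplitz linear system
whose solution is exact when the covariances are exact — the unit tests
exploit this by constructing covariances analytically from the discrete
Lyapunov equation. The innovation covariance follows from
$\Sigma = \Gamma(0) - \sum_j A_j \Gamma(j)^\top$.

The spectral transfer matrix is
$H(f) = \left(I - \sum_j A_j e^{-i 2\pi f \Delta t j}\right)^{-1}$ with
$\Delta t = 1/f_s$, and the normalized DTF is
$$\mathrm{DTF}_{ij}(f) = \frac{|H_{ij}(f)|^2}{\sum_{m} |H_{im}(f)|^2},$$
the fraction of inflow to channel $i$ attributable to channel $j$; rows
sum to one and values lie in $[0, 1]$. A coefficient sign convention worth
stating: the moving-sum form $\sum_{j=0}^p \hat A_j x_{t-j} = e_t$ with
$\hat A_0 = I$ has $\hat A_j = -A_j$; the package stores the regression
form and builds the frequency-domain polynomial internally, which removes
a classic double-negation failure mode between estimation, simulation and
spectra.

### Order selection and model checking

The order is chosen by BIC,
$N \ln\det\Sigma_p + \ln(N)\, p k^2$, with ties broken toward the smaller
order; 7 is the package default for the 1000 Hz two-channel setting and is
also what BIC selects on the packaged synthetic data. Stability is
monitored through the spectral radius of the $pk \times pk$ companion
matrix; simulation refuses unstable models. The parametric spectrum
$S(f) = H \Sigma H^{\mathsf H}/f_s$ is reported two-sided (power per Hz),
so twice its integral over $[0, f_s/2]$ recovers the process variance —
a Parseval identity the tests verify against the Lyapunov solution.

### Condition contrasts

One DTF is computed per 2 s segment (15 segments per 30 s condition) and
averaged over the 3–40 Hz band, giving 15 exchangeable values per
direction and condition. Wakefulness and anaesthesia are compared with the
two-sided Wilcoxon rank-sum test (exact enumeration for combined samples
of at most 12 tie-free values, otherwise the normal approximation with tie
and continuity corrections), and Benjamini–Hochberg FDR is applied
*jointly across all contrasts in the call* — with two directions and two
modalities that family has size 4, recorded in the output metadata. The
test is deliberately performed on band summaries rather than per frequency
bin: a per-bin family would multiply the number of tests several
hundredfold without a matching hypothesis. Effects are reported as
`median(A) - median(W)`, so a negative sign is a decrease under
anaesthesia.

## The model-based track

### The two-source neural-mass model

Each source contains spiny stellate cells (granular layer), pyramidal
cells and inhibitory interneurons. Every synaptic stage is a second-order
kernel: a voltage–current pair driven by presynaptic input $d$,
$$\dot v = i, \qquad \dot i = \kappa H d - 2\kappa i - \kappa^2 v,$$
with excitatory kinetics $(\kappa_e, H_e)$ or inhibitory kinetics
$(\kappa_i, H_i)$ per stage. Ten states per source: stellate pair,
pyramidal excitatory and inhibitory pairs, interneuron excitatory and
inhibitory pairs; the observed output is the pyramidal depolarization
$v_{pe} - v_{pi}$ scaled by an observation gain. Firing rates follow the
zero-centred sigmoid
$S(v) = \left(1 + e^{-\rho_1 (v - \rho_2)}\right)^{-1} -
\left(1 + e^{\rho_1\rho_2}\right)^{-1}$, so the origin is always an
equilibrium of the unforced system.

Extrinsic connections follow cortical hierarchy rules: the forward
connection targets the receiving source's stellate population; the
backward connection targets the pyramidal and interneuron populations.
Architecture 1 sends the forward connection P→F (and backward F→P);
architecture 2 is the reverse. Condition effects act multiplicatively in
condition A only: $a_{fwd} e^{b_{fwd}}$, $a_{bwd} e^{b_{bwd}}$ on the
extrinsic gains and $\gamma_5 e^{b_{self}}$ on each source's inhibitory
self-connection; $b = 0$ reproduces W exactly (a tested identity). The
choice of $\gamma_5$ as the seat of the intrinsic condition effect is a
design decision: the intrinsic "self" modulation had to act somewhere
concrete, and the interneuron self-inhibition is the parameter with the
cleanest interpretation as cortical inhibitory tone under propofol.

Default parameters are the standard LFP-variant values:
$H_e = 4$ mV, $H_i = 32$ mV, $\kappa_e = 250\,s^{-1}$,
$\kappa_i = 62.5\,s^{-1}$, intrinsic gains
$\gamma_{1..5} = 128, 128, 64, 64, 16$, $\rho_1 = 2$, $\rho_2 = 1$. These
are literature-derived configuration values, not fitted constants.

### Spectral prediction

Around the fixed point (damped Newton with the analytic Jacobian;
relaxation integration as fallback; the origin exactly, when the exogenous
drive is zero) the linearized system $(J, B, C)$ gives the
innovation-to-output transfer $T(f) = C (2\pi i f I - J)^{-1} B$,
evaluated through the eigendecomposition of $J$ so a full frequency grid
costs one decomposition. Innovations and observation noise carry
white-plus-$1/f$ spectra $g(f) = e^{\alpha} + e^{\beta}/f$, and the
predicted CSD is
$$G(f) = T(f)\,\mathrm{diag}(g_u(f))\,T(f)^{\mathsf H} +
\mathrm{diag}(g_n(f)).$$
The model-implied DTF weights transfer magnitudes by the innovation
spectra, $|T_{ij}|^2 g_{u_j} / \sum_m |T_{im}|^2 g_{u_m}$ — unlike the
MVAR route, whose innovations are white by assumption.

### Stochastic simulation

`simulate_nmm()` integrates the full nonlinear system by Euler–Maruyama.
The step is $1/(16\,\kappa_{max})$ — twice as fine as the
$1/(8\,\kappa_{max})$ stability bound — because at the coarser step the
Euler scheme inflates output variance by 15–20%, while at the finer step
the residual bias sits at the few-percent level, comfortably inside the
25% tolerance used by the simulation-versus-linearization cross-checks.
Fine-grid output is averaged within output bins (a mild anti-alias
filter), and only the white component of the innovation spectrum is
simulated; the convergence tests therefore switch the $1/f$ component off.
As innovation amplitude shrinks over the decades $1, 10^{-2}, 10^{-4}$ the
band-integrated mismatch between simulated Welch spectra and the linear
prediction falls from roughly 23% (genuine sigmoid nonlinearity) to about
6%, the Welch sampling floor of a 60 s recording.

### Inversion

`variational_laplace()` fits free *log-scalings* of the biophysical and
spectral parameters (prior $\mathcal N(0, 1/16)$) and the condition
effects $b$ (prior $\mathcal N(0, 1)$) by Gauss–Newton ascent on the
Laplace free energy; parameters a model pins are simply excluded. The
data vector stacks Re $G_{11}$, Re $G_{22}$, Re $G_{12}$, Im $G_{12}$
over the 1–80 Hz fitting grid (the native 1 Hz resolution of 1 s Hann
windows with 50% overlap) and over conditions, scaled by a single
root-mean-square constant so the scalar residual precision is
dimensionless. The precision hyperparameter is updated by EM in
alternation with the parameter step, keeping whichever precision yields
the larger bound; steps that fail to increase F are rejected with tenfold
ridge damping. Convergence requires three consecutive accepted steps with
$|\Delta F| < 0.01$ nats. The recorded F trace is monotone by
construction, and the suite asserts it on every fit.

Numerical gradients use central differences with step
$10^{-4}(1 + |\theta|)$. A parameter excursion that destabilizes the
linearization is treated as a rejected step, with a one-sided difference
fallback at the stability boundary.

### Model comparison

Stage 1 compares the two architectures on the wakefulness data alone
(architecture is a property of the system, not of the contrast); stage 2
inverts all $2^4 = 16$ on/off combinations of
$\{b_{fwd}, b_{bwd}, b_{self,F}, b_{self,P}\}$ on both conditions jointly
under the winning architecture. The 16-model space is the primary one;
the 4-model forward/backward-only space is available as a preset
(`effect_preset = "cond4"`). Fixed-effects BMS converts free energies to
posterior model probabilities by a shift-invariant softmax. Posterior
condition effects are reported as $100\,e^{\hat b}$ — percent of the
wakefulness strength.

On noiseless self-generated data an extra free parameter whose prior is
widened from zero changes F by less than half a nat when the parameter is
truly irrelevant (zero sensitivity), and a redundant but *sensitive*
parameter never wins by more than 3 nats — the standard Occam behaviour
the tests pin down.

## Synthetic data: what it emulates and what it does not

`anaesthesia_scenario()` fixes the reference conditions: 30 s per condition at
1000 Hz, architecture 1, anaesthesia reducing the forward gain to
$e^{-0.7} \approx 50\%$ of wakefulness with a moderate increase
($e^{+0.3}$) of both inhibitory self-connections. Extrinsic gains are
asymmetric, `a_fwd = 384`, `a_bwd = 64`: forward input (into the stellate
population, relayed through one extra synaptic stage) is intrinsically
weaker per unit gain than backward input (into the pyramidal population
directly), and these values make the two cross-direction DTFs comparable
in wakefulness (band averages ≈ 0.12 and ≈ 0.11) — the regime in which a
directed interaction is clearly measurable, as it is in the recordings the
package emulates. Clean ("ECOG") observation noise sits ~40 dB below the
signal.

The reconstructed-source ("RS") modality is emulated by instantaneous
linear mixing (leakage 0.3), additive white noise at 10 dB SNR, and a
zero-phase 60 Hz low-pass — the two salient consequences of source
reconstruction (mixing and bandwidth loss) without its machinery (lead
fields, inverse operators), which is out of scope. Real reconstruction
error is richer: frequency-dependent, spatially structured, and
nonstationary. Passing tests on this emulation therefore demonstrate
robustness to mixing and bandwidth loss, not fidelity to any particular
inverse method.

Common-average referencing is part of the preprocessing chain but is
meaningful only on a full electrode array; on an already-extracted
two-channel pair it would leave rank-one data (the two channels become
exact negatives, and Yule–Walker systems turn singular). The synthetic
pipelines therefore run with `average_ref = FALSE`, mirroring a study
design where the reference is removed on the full montage before source
selection. Likewise the notch filter and the $\ell_1$ detrend exist for
real recordings (line noise, slow drifts); the synthetic generator
produces neither, so the calibration pipelines go straight to
segmentation.

## Numerical choices

* **$\ell_1$ trend filtering** solves
  $\tfrac12\|x - t\|_2^2 + \lambda \|D_2 t\|_1$ by ADMM with a duality-gap
  stopping rule at $10^{-8}$ relative; the penalty parameter equals
  $\max(\lambda, 1)$. Exactly linear inputs are returned unchanged in one
  iteration, and large $\lambda$ reproduces the affine least-squares fit
  to $10^{-3}$. The method is applied locally, per 2 s window, with
  $\lambda$ defaulting to ten times the window variance — the cited
  technique fixes neither the window nor $\lambda$, so both are exposed
  configuration.
* **Zero-phase filtering** (notch, low-pass) uses forward–backward
  application with odd-reflection padding and step-matched initial
  conditions; plain forward–backward filtering with zero initial state
  leaks start-up transients through narrow (high-Q) notches.
* **Artefact handling** replaces manual inspection with a robust-z rule
  (median/MAD, threshold 8) that can be disabled; masked spans are never
  crossed by analysis segments. Constant channels (zero MAD) are skipped
  with a warning rather than an error.
* **Welch cross-spectra** use 1 s Hann windows at 50% overlap, per-window
  mean removal, and two-sided power-per-Hz normalization; values are
  linearly interpolated (Re and Im separately) onto the model grid.
* **Seeds.** Every generator is a pure function of (specification, seed);
  substream seeds are derived as `master + slot * 999983` modulo
  $2^{31}-1$.

## Problem sizes used by the verification suite

Sampling-based checks run at desk scale, chosen once: 100 random models
for the normalization identity; 20 seeds for the zero-coupling and
recovery checks; 120–150 null replicates and 20 effect replicates for the
calibration/power checks; 10 seeds each for parameter, architecture and
condition-effect recovery; one fixed-seed scenario for the cross-track
concordance check. Thresholds follow the statements in the test names and
are never loosened to fit a particular draw.

## Known limitations

* Two sources only; no thalamic or hidden third source, although the
  discussion of anaesthesia often invokes one.
* The MVAR track assumes white innovations; the model-based track
  estimates innovation spectra, which is one reason the two DTFs are
  compared only qualitatively (rank order and sign of change).
* Fixed-effects BMS applies to repeated measurements of one subject;
  between-subject heterogeneity (random-effects BMS) is out of scope.
* The inversion uses a scalar residual precision across all spectral
  features; heteroscedastic (per-frequency) precision would weight
  high-power peaks less aggressively.
* The degraded-modality observation model is *not* part of the generative
  model used for fitting; the DCM track fits reconstructed-source data
  with the same two-source observation model, exactly as one does with
  real reconstructed sources, and its robustness to that mismatch is an
  empirical finding of the test suite, not a guarantee. One concrete
  consequence the suite documents: instantaneous mixing is mimicked most
  cheaply by the fast (single-synapse) backward pathway, so on mixed data
  the fitted backward flow inflates and the wakefulness *rank order* of
  the two (nearly equal, by design) cross-flows is not reliably
  recovered, even though the *direction of the anaesthesia change* is.
  The cross-track concordance test asserts both and is expected to stay
  red on the rank-order half for the degraded modality.
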