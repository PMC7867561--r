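---
title: "Spectral DCM and parametric empirical Bayes for a frontostriatal network"
author: "fsdcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral DCM and parametric empirical Bayes for a frontostriatal network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsdcm)
```

## The scientific question

Positive symptoms of schizophrenia (delusions, hallucinations, conceptual
disorganization) are thought to reflect excess dopaminergic signalling in the
striatum, which the prefrontal cortex can restrain through an indirect,
GABA-mediated "brake" pathway. If the strength of that frontostriatal circuit
covaries with symptom severity, prefrontal neurostimulation protocols could
be chosen to tighten or release the brake. `fsdcm` implements the full
analysis chain used to test this: per-subject effective connectivity of a
two-region network — left dorsolateral prefrontal cortex (LDLPFC) and left
striatum (LSTR) — estimated from resting-state BOLD cross-spectra, pooled
across subjects by parametric empirical Bayes (PEB) with PANSS-8 symptom
covariates, and nine symptom models compared by free energy.

## The generative model

Each region holds one excitatory (E) and one inhibitory (I) population. The
neural states $x = (E_f, I_f, E_s, I_s)$ evolve linearly,
$\dot x = A x + u$, with band-limited endogenous fluctuations $u$ driving
the excitatory states. Four connections are free, each parameterized as the
log of a scaling factor on a fixed default strength:

* within-region I$\to$E (GABAergic): $-\tfrac18 e^{\theta}$ Hz
  (`dlpfc_self`, `str_self`);
* between-region E$\to$E (glutamatergic): $+\tfrac18 e^{\theta}$ Hz
  (`str_to_dlpfc`, `dlpfc_to_str`).

The exponential map enforces the sign of every connection for any finite
$\theta$, and $e^{\theta}$ reads directly as "how many times the default
strength". The remaining couplings are fixed, never estimated: E$\to$I gain
$0.5$ Hz and self-decays $-0.5$ Hz for both populations. These values are not
dictated by the physiology — they were chosen once as the minimal symmetric
setting that keeps the system stable at the prior mean ($\theta = 0$) with
well-damped oscillatory modes ($\lambda = -0.5 \pm 0.25i$); all downstream
validation is recovery-based, so only the stability and the free/fixed split
matter, not the particular decay constants.

The measured signal reads the excitatory states through a canonical
double-gamma hemodynamic kernel with closed-form transfer
$H(f) = (1+2\pi i f)^{-6} - \tfrac16 (1+2\pi i f)^{-16}$, and the predicted
cross-spectral density at frequency $f$ is

$$S(f) = |H(f)|^2\, T(f)\, G_u(f)\, T(f)^* + g_{obs}(f)\, I_2,$$

with $T(f)$ the transfer function from fluctuation inputs to excitatory
states, $G_u(f) = \alpha_u f^{-1/2} I_2$ the fluctuation spectrum and
$g_{obs}$ white observation noise. $S(f)$ is Hermitian positive semidefinite
by construction. Defaults: $\alpha_u$ normalizes band-integrated fluctuation
power to 1 on the 0.0078–0.1 Hz analysis band; the observation amplitude sets
band-integrated noise power to one tenth of the model's band signal power at
the prior mean (power SNR 10). The analysis grid is 32 evenly spaced
frequencies on the band.

## Per-subject inversion

The observed data feature is a multivariate autoregressive (Yule–Walker,
order 8) cross-spectral estimate on the same grid; order 8 gives smooth
spectra at the study's 360 volumes and is configurable. The inversion is a
variational-Laplace scheme: Gaussian shrinkage priors on
$\theta$ (mean 0, variance $1/16$ — "uninformative" in the sense that the
data feature, not the prior, should decide, while keeping the system in its
stable regime), Gaussian hyperpriors on two log noise amplitudes and on one
residual hyperparameter — the effective degrees of freedom of the
complex-Wishart (Whittle) residual model under the default likelihood, or
the log residual precision under the Gaussian alternative — and
Gauss–Newton / Fisher-scoring ascent on the free energy
$F = \text{accuracy} - \text{complexity}$. Steps that would lower $F$
are halved (up to eight times), so the accepted trajectory is non-decreasing;
convergence is declared after three consecutive accepted steps with
$|\Delta F| < 0.01$ nats, with a cap of 128 iterations. The posterior
covariance is the negative inverse curvature at the mode, symmetrized and
eigenvalue-floored to PSD. Explained variance is the proportion of variance
of the stacked real and imaginary cross-spectral entries captured by the
prediction, in percent.

Numerical guards worth knowing about: the residual hyperparameter is clamped
to $\pm 16$ on its log scale (noise-free synthetic data would otherwise push
the residual precision to infinity);
a Gauss–Newton step that fails to improve $F$ after eight halvings terminates
the iteration; and perfectly collinear region pairs (a degenerate but
contractually supported input) are handled by refitting the AR model after an
infinitesimal reproducible dither.

## What a 360-volume record can and cannot identify

A central, openly documented limitation: the study acquisition (360 volumes,
TR 1 s, band 0.0078–0.1 Hz) supports only ~33 independent Fourier
frequencies. `recovery_ceiling()` computes the exact Whittle/Fisher
information about $\theta$ in such a record under the model's own spectrum.
At 360 volumes the optimal posterior SD is $\approx 0.23$ against a prior SD
of $0.25$: the best possible true-vs-estimate correlation for prior-drawn
parameters is about 0.3–0.37 per connection, for any estimator and even for
noise-free BOLD. Our inversion empirically sits at that ceiling. Two
consequences shape the package's validation design:

* **Parameter-recovery validation uses long records** (32768 volumes, where
  the ceiling is $\approx 0.95$), because its purpose is to test the
  estimator, not the acquisition. At that length the pipeline reaches
  per-connection recovery correlations of roughly 0.80–0.91, using the
  periodogram-binned spectral feature (see below).
* **Group-level validation uses 8192-volume records** at the study's n = 19.
  At 360 volumes the generating covariate effects sit below the
  single-subject information floor and the null model rightly wins the
  comparison by Occam's razor — a behaviour the `analysis/03_run_pipeline.R`
  driver reproduces on purpose. This also explains why small-sample PEB
  inference on real data leans so heavily on the empirical-prior recursion:
  the group level supplies most of the per-subject precision.

## The group level

For each subject the first-level posterior is converted into its Gaussian
likelihood message (posterior precision minus prior precision, floored to
PSD), which is exact under the Laplace assumption and is what makes the
empirical-prior recursion tractable. The second level is then a Bayesian
linear model: subject parameters are design-weighted group effects plus an
isotropic between-subject random effect with precision $\pi_b$. Designs
follow the nine-model space — a constant column, the symptom covariate of
interest, and binary medication plus duration of untreated psychosis (DUP)
as covariates of no interest, all mean-centered so the constant encodes the
group mean. The null design is the constant alone. Group-effect priors are
zero-mean Gaussians: variance 16 on the constant (weakly informative — the
group mean is for the data to decide) and $1/16$ per covariate effect
(matching the first-level scale). $\pi_b$ carries a Gamma hyperprior with
mode 256 (= 16 times the mean first-level prior precision, the standard
expected between-subject shrinkage) and is re-optimized against the group
free energy until $|\Delta F| < 0.01$ (max 16 rounds); given $\pi_b$,
everything else is closed-form Gaussian algebra, so the recursion converges
in a round or two. The group free energy is the exact marginal likelihood of
the subject messages under the model plus the hyperprior term; the
first-level alignment constants are shared by all nine models and cancel in
every comparison.

Model comparison converts free energies to log Bayes factors against the
best model and to posterior model probabilities by normalized
exponentiation under a flat model prior — so probabilities always sum to
one and renormalize as the model space changes, while each model's evidence
does not. Per-connection covariate effects are summarized by Bayesian model
reduction, pruning one effect at a time; for Gaussian posteriors this is the
Savage–Dickey ratio, and the reported posterior probability is the
probability that the effect is nonzero, with its sign taken from the
posterior mean. A null effect yields at most 0.5 by construction.

## The synthetic cohort generator

The generator emulates the study conditions, not generic fMRI: 19 subjects,
360 volumes at TR 1 s by default; PANSS-8 items drawn uniformly within the
per-item ranges observed in the cohort (P1 confined to 4–7, the narrow
high-severity band characteristic of untreated first-episode psychosis);
roughly 40% of subjects without antipsychotic exposure; DUP log-normal on
the observed 1–72 month range with occasional missing entries (mean-imputed
downstream, like the real table). Ground-truth connectivity follows
$\theta_i = X_i \beta + \mathcal N(0, 0.1^2)$ with the design built and
centered exactly as in the analysis. The default $\beta$ mirrors the
published qualitative pattern — positive-symptom load raises within-region
inhibition and lowers between-region excitation, $\pm 0.1$ log units per
symptom point — an effect size chosen so that recovery at n = 19 is possible
but not trivial. Subject series come from Euler integration (0.1 s step,
64 s burn-in) of the stochastic neural system driven by spectrally
synthesized band-limited fluctuations, convolved with the hemodynamic
kernel, decimated to TR and degraded with white observation noise. The
long-run Welch spectra of these simulations agree with the analytic
`predicted_csd()` — that cross-check is part of the acceptance suite.

What the generator does **not** emulate: head motion and physiological
artifacts, scanner drifts beyond what the cosine filter removes, spatial
preprocessing, regional heterogeneity of the hemodynamic response, and any
nonlinearity of the BOLD response. Passing tests therefore demonstrate that
the inference machinery is correct and calibrated under the model's own
assumptions — not that those assumptions hold in real fMRI. Real-data
explained variance (mean 25% in the study) is far below the synthetic
pipeline's (~85%), which is the expected signature of exactly this gap.

## Worked-example fixtures

The published tables are shipped as plain-text fixtures: the 19-subject
PANSS-8 table with medication flags and DUP (including the printed composite
columns, which the package recomputes and checks), the per-subject explained
variance table, the per-subject `exp(posterior mean)` connectivity estimates,
and the group free energies of the nine models. Statistics computable from
those tables are reproduced exactly by the package: the positive-vs-negative
paired contrast (mean difference 5.21, SD 4.44, t(18) = 5.11, 95% CI
[3.07, 7.35]), the diagnostic summary (mean 25.01%, SD 14.22%, two subjects
below the 10% acceptability threshold), composite ranges, and the conversion
of the two best free energies into posterior probabilities (0.9933 / 0.0067).
The subject-level connectivity values and absolute free energies themselves
are not reproduction targets — they require the undeposited raw fMRI.

## Design choices that were genuinely open

* **DUP imputation.** The published table has two non-reliable DUP entries;
  how they entered the original design is not stated. We mean-impute before
  centering, preserving n = 19 while giving the nuisance column zero net
  weight for those subjects, and announce it with a message.
* **Region summary.** "The time series that summarized the activity" of a
  sphere is implemented as the principal eigenvariate (first PC,
  sign-aligned to the mean voxel series, unit variance) rather than the
  sphere mean, matching common volume-of-interest practice.
* **Band restriction.** The cosine filter removes only the drift subspace
  below 0.0078 Hz; energy above 0.1 Hz is excluded at the cross-spectrum
  stage by the analysis grid rather than by a time-domain low-pass.
* **Effect probabilities by model reduction** rather than posterior tail
  mass, matching the free-energy language of the rest of the pipeline.
* **Likelihood of the spectral feature.** The inversion's default residual
  model is a complex-Wishart (Whittle) likelihood with an estimated
  effective-degrees-of-freedom hyperparameter, maximized by Fisher scoring —
  the natural sampling model for spectral estimates, which weights diagonal
  and cross-spectral information by its precision. A Gaussian
  stacked-residual likelihood with an estimated log precision is retained as
  `likelihood = "gaussian"`; at study-length records the two are
  indistinguishable, while on long records the Wishart form recovers
  parameters visibly better.
* **Spectral feature for validation.** The MVAR estimate is the pipeline
  default, but its parametric smoothing can bias the likelihood bimodally
  when within-region inhibition is weak (the resonance sits at the band
  edge); `estimate_csd(method = "welch")` — bin-averaged raw periodograms,
  unbiased and approximately Wishart with known degrees of freedom — is
  therefore used for recovery validation on long records, and the failure
  mode is documented here rather than hidden.
* **Model space.** Nine models (eight symptom covariates plus null) are
  implemented throughout.

## Problem sizes used in tests

The test suite and the acceptance script run, by design, at sizes a single
CPU handles comfortably: the worked-example checks are instantaneous; the
simulation-vs-analytic oracle uses one 65536-volume noise-free run compared
at six band frequencies within 25% per entry; parameter recovery uses 50
subjects at 32768 volumes (per-connection correlation at least 0.7); and the
group-level checks use 20 seeded cohorts of 19 subjects at 8192 volumes
(sign pattern recovered in at least 80% of cohorts; the generating
"total positive" model selected more often than any alternative).

## Known limitations

Two regions and two states per region are a deliberate minimal circuit, not
a model of psychosis; the fixed neural constants are conventions; the
hemodynamic model is shared by both regions; the AR data feature treats
residuals as exchangeable across frequencies, which makes posterior
variances somewhat overconfident at short record lengths (the group level
compensates by re-estimating the between-subject precision); and absolute
group free energies are comparable only within a fixed cohort and first
level, never across datasets.
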