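---
title: "Online activation mapping for fNIRS: model, estimator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Online activation mapping for fNIRS: model, estimator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirstream)
```

nirstream estimates a per-channel brain-activation map from functional
near-infrared spectroscopy (fNIRS) time series *while the record streams in*:
at every new sample the general linear model (GLM) coefficients are updated
by a Kalman filter, a running one-tailed t-statistic is computed for the
task coefficient, and the Bonferroni-corrected activation map is refreshed.
This vignette explains the model, the tunable parameters and their defaults,
the synthetic-data generator used throughout the tests, and the numerical
and design decisions that were genuinely open.

## From light intensity to hemoglobin

A continuous-wave instrument records light intensity per channel at two
wavelengths (760 and 830 nm by default). The optical-density change is taken
relative to a reference time step (the first, by default):

$$\Delta OD_{\lambda,i}(k) = -\log_{10}\frac{I_{\lambda,i}(k)}{I_{\lambda,i}(k_{\mathrm{ref}})}.$$

The base-10 logarithm is the standard optical-densitometry convention; it
pairs with extinction coefficients tabulated on the decadic scale. The
modified Beer–Lambert law relates this to concentration changes of oxy- and
deoxy-hemoglobin,

$$\Delta OD_{\lambda,i} = \big(\alpha_{HbO}(\lambda)\,\Delta C_{HbO}
  + \alpha_{HbR}(\lambda)\,\Delta C_{HbR}\big)\, L\, \mathrm{DPF}_\lambda,$$

a 2×2 linear system per channel and time step. Because intensities are
referenced to the first sample, recovered concentrations are changes
relative to that sample. Defaults: extinction coefficients from the standard
compiled hemoglobin tables (µM⁻¹·mm⁻¹), DPF 6.0 at both wavelengths (a
common adult-head value). The source–detector distance has **no default**:
it is probe geometry and must be supplied. The analysis downstream is
insensitive to an over- or under-scaled DPF because the GLM estimates each
channel's response amplitude with its own statistics — a constant scale
error rescales the coefficient and its standard error together.

Only the HbO series feeds the estimator by default (it carries the higher
task contrast-to-noise in this kind of study); `hemo_channel()` selects HbR
instead if wanted.

## The design matrix

For a block protocol (preparation period, then `n_sessions` repetitions of
task + rest), the design has $L$ columns:

1. **task** — the 0/1 stimulus vector convolved with a double-gamma
   hemodynamic response kernel, causally truncated to the record;
2. **baseline** — constant 1;
3. … — a small set of discrete-cosine (DCT-II) high-pass columns,
   $c_r(k) = \cos\!\big(\pi r (2k+1)/2N\big)$, unit-normalized, absorbing
   very-low-frequency drifts.

Defaults give $L = 5$ (one task, one baseline, three DCT columns), matching
the five explanatory variables of the reference finger-tapping protocol
(42 s preparation, 10 × (21 s task + 30 s rest) at 1.81 Hz — a 552 s,
999-sample record).

```{r}
design <- nirs_design(nirs_protocol())
design
```

Two conventions make the design fully deterministic: block boundaries are
floored to sample indices with half-open `[onset, offset)` coverage, and the
convolution is causal with no padding beyond the record. The DCT columns
need the total record length $N$; $N$ is fixed by the protocol before the
experiment starts, so this does not violate online operation.

**DCT set size.** The set can be given directly (`n_dct`, default 3) or via
a cutoff frequency (`dct_cutoff_hz`), including every basis frequency
$r/2T$ at or below the cutoff. These two modes can disagree: a cutoff of
0.0006 Hz over 552 s admits *no* DCT column under the $r/2T$ convention,
while the reference design clearly uses three. We therefore default to the
explicit count and keep the cutoff as an alternative mode that errors when
it floors to zero rather than guessing; `min_terms` bounds it below when
both are given.

**HRF parameterization.** The double-gamma kernel is a difference of two
gamma densities with the undershoot scaled by 1/6. We parameterize the gamma
shapes so that each component's *mode* equals its nominal delay
(shape = 1 + delay/dispersion, rate = 1/dispersion): with the default peak
delay of 6 s the sampled kernel really does peak at 6 s. Defaults: peak 6 s,
undershoot 16 s, unit dispersions, ratio 6, 32 s truncation, peak-normalized
to 1 so the task coefficient is in µM.

## Prewhitening

Cardiac, respiratory and Mayer-wave activity leave serial correlation in
the regression error; ignoring it inflates t-values and over-declares
activation. The error is modeled as AR(1): both the measurement and the
design row are differenced by $\rho$ before each filter update,

$$y^*(k) = y(k) - \rho\, y(k-1), \qquad H^*(k) = H(k) - \rho\, H(k-1).$$

$\rho$ is estimated online as the running lag-1 autocorrelation of the
regression residuals $y(k) - H(k)\hat\beta(k)$ (the simplest recursive
estimator consistent with an AR(1) error), refreshed every sample, clipped
to $[-0.99, 0.99]$ to keep the transform invertible, and held at 0 for a
burn-in of 30 samples (~17 s at 1.81 Hz) so that early, unstable residuals
do not drive the transform. A fixed $\rho$ from training data can be
supplied instead (`ar_fixed_rho`); whether the original framework
re-estimated per step or froze a training value is not documented, so both
modes exist and the online one is the default. Differencing by a
time-varying coefficient implicitly assumes the coefficients move little
between adjacent samples, which is exactly the random-walk regime the
estimator works in.

## The Kalman coefficient estimator

Per channel, the GLM coefficients follow a random walk with zero drift:
identity transition matrix, process noise $Q = qI$, scalar observation
noise $r$. The standard predict/update recursion applies with the whitened
pair $(y^*, H^*)$; the observation is scalar so the gain is a vector and
no matrix inversion is needed. Defaults $q = 10^{-4}$ and $r = 0.25$ follow
the reference study's printed values ("(1 %/s)²" and "(0.5 µM/s)²"),
treated as plain variances in working units — the percent notation does not
map cleanly onto µM², and the original values came from a
restricted-maximum-likelihood fit to training data that is out of scope
here, so both are configuration inputs. The state starts at zero with
$P(0) = p_0 I$; $p_0$ is not documented in the reference account, so we
default to a weakly informative $10^4$.

Two numerical points. The covariance update uses the simple form
$(I - KH)P^-$ followed by explicit symmetrization each step; with the
scalar-observation gain this is cheap and keeps $P$ symmetric positive
semidefinite over long streams (property-tested over 1000 random steps).
And setting $q = 0$ with diffuse $p_0$ (≈ $10^8$) makes the filter a
recursive least-squares estimator: its per-step trajectory reproduces batch
ordinary least squares to ~$10^{-8}$ in the coefficients. This
OLS-equivalent mode is the calibration reference for all statistical
claims, and `replay_equivalence()` checks it against an independent batch
refit at every step.

## Running t-statistics and the activation map

At step $k$ the one-tailed statistic for contrast $c$ (default: the task
coefficient) is

$$t^i(k) = \frac{c^\top \hat\beta^i(k)}
  {\sqrt{\hat\sigma_i^2(k)\; c^\top \big(\textstyle\sum_1^k H_j^\top H_j\big)^{-1} c}},
\qquad
\hat\sigma_i^2(k) = \frac{1}{k-L}\sum_{j=1}^k \big(y_j - H_j\hat\beta^i(k)\big)^2,$$

with $k - L$ degrees of freedom. $\hat\sigma^2$ is the residual sum of
squares *of the current coefficients over all samples seen so far*. Rather
than re-scanning the record (which would break streaming), it is computed
exactly from running sufficient statistics,
$\mathrm{RSS} = \sum y^2 - 2\hat\beta^\top\!\sum H^\top y +
\hat\beta^\top\big(\sum H^\top H\big)\hat\beta$, clamped at zero against
round-off cancellation. All three accumulators use the whitened pairs, for
consistency with the model the filter actually fits. A channel is testable
once its degrees of freedom are positive *and* the Gram matrix is
invertible — with $L = 5$ that is the 6th sample at the earliest, but the
code derives it from the degrees of freedom rather than hard-coding a step.
Before that, the channel reports `NA` rather than raising an error in the
streaming loop.

Multiplicity is controlled with the corrected per-test threshold

$$p_b = \frac{1 - (1 - p_{in})^j}{j},$$

which equals $p_{in}$ at $j = 1$ and decreases strictly in $j$. Note this
is larger (more permissive) than the classical $p_{in}/j$: at
$p_{in} = 0.05$ and $j = 24$ channels it gives 0.0295 rather than 0.0021.
The number of tests $j$ is a policy choice the original account leaves
open: `per_step` counts channels only, `cumulative` (the default) counts
channels × testable steps so far, reflecting the concern that type-I error
accumulates as the same hypothesis is re-tested at every sample. Both are
available; detection times under `cumulative` are systematically later.
One-tailed testing is for activation only (coefficient greater than zero);
mapping deactivation is out of scope. First-crossing times are recorded
separately for the uncorrected and corrected thresholds and never unset,
since a noisy t trajectory can dip back below threshold after first
crossing it.

## The synthetic-data generator

No public recording exists for this protocol, so `nirs_simulate()` is the
package's data source for tests and demos. Per channel it sums, exactly:

* the true response: amplitude × (stimulus ⊗ double-gamma), default 1 µM
  on the active channels;
* physiological sinusoids — cardiac 1.1 Hz (0.15 µM), respiratory 0.3 Hz
  (0.1 µM), Mayer wave 0.1 Hz (0.2 µM). At 1.81 Hz sampling the cardiac
  line is above Nyquist and aliases; it is kept deliberately, because that
  is what the instrument records too;
* a very-low-frequency drift: a 0.5 µM sinusoid at 0.002 Hz (~1.1 cycles
  over the record, a visible baseline shift) plus a 0.01 µM/step random
  walk standing in for optode-shift drift;
* AR(1) measurement noise $e(k) = \rho e(k-1) + w(k)$, innovation sd
  0.5 µM (so the white-noise default has marginal sd 0.5 µM), stationary
  initialization.

Amplitudes for the nuisance terms are the package's own choices of
realistic magnitudes — the reference account names the noise sources but
prints no numbers. Everything is overridable, the component decomposition
is returned for debugging, and output is bit-reproducible under a seed.
`nirs_simulate_intensity()` maps a simulation through the forward
Beer–Lambert model (with $\Delta HbR = -0.3\,\Delta HbO$, the conventional
inverse coupling) to raw intensities, for end-to-end tests of the full
ingestion path.

What the generator does **not** emulate: motion-artifact spikes, abrupt
optode displacement steps, subject-specific HRF shape variation,
heteroscedastic instrument noise, and spatial correlation between channels
(channels are independent given the shared physiological waves). Tests
passing on this generator therefore certify the estimator's statistical
behavior under its stated noise model, not performance on any particular
instrument's artifacts.

## What the simulation studies show

The packaged studies (the acceptance script and `test-acceptance.R` rerun
all of them from scratch; problem sizes in parentheses) measure:

* **OLS equivalence** (200 samples, L = 5): diffuse q = 0 trajectories
  match batch OLS to ~1e-8 (coefficients) and ~1e-6 (t).
* **Recovery** (50 seeds, 999 samples): mean final $\hat\beta_1$ within a
  few per mil of the true 1 µM at study-default q, r.
* **Type-I calibration** (2000 null channels): uncorrected one-tailed
  rejection at $p_{in} = 0.05$ lands near 0.05 in the OLS-equivalent mode,
  which is the mode in which the t-distribution argument actually applies.
  With process noise $q > 0$ the coefficient deliberately keeps tracking
  instead of converging, so the nominal t-distribution no longer describes
  its final-step variability exactly; calibration claims in this package
  are made for the OLS-equivalent mode only.
* **Whitening** (1000 AR(0.8) null channels): without prewhitening the
  rejection rate inflates to ~0.3; with it, back to ~0.04.
* **Drift** (20 seeds): a 0.5 µM slow sinusoidal drift biases the task
  coefficient by only ~2% even *without* DCT columns under this protocol —
  ten balanced task/rest sessions make the task regressor nearly orthogonal
  to anything that slow, and the random-walk baseline coefficient absorbs
  most of the rest. The DCT set's practical value here is variance
  reduction and t-calibration under drift, not rescue from a large bias;
  a single-session or unbalanced design would be far more drift-sensitive.

## Known limitations

* AR order is fixed at 1; higher-order or long-memory error structure is
  only partially whitened.
* q and r are configuration constants; no online noise-covariance
  estimation (the original framework's ReML step) is provided.
* The cumulative-j Bonferroni threshold shrinks without bound; for records
  much longer than ~10 minutes it will eventually suppress true detections
  (the underlying account makes the same observation). Decimating the test
  schedule is the practical remedy.
* The activation map is per-channel; no spatial smoothing, interpolation or
  anatomical registration is performed (the probe layout is used for
  plotting only).
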