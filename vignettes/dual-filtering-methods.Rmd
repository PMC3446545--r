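---
title: "Dual and joint unscented Kalman filtering for the Balloon model: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual and joint unscented Kalman filtering for the Balloon model: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemodual)
```

## The model

The Balloon model couples a voxel's neuronal input $u(t)$ to the BOLD
signal through four dimensionless states, all normalized to their
resting values: blood flow $f$, the flow-inducing signal $s = \dot f$,
deoxyhemoglobin content $q$, and venous volume $v$:

$$\dot f = s, \qquad
  \dot s = \varepsilon u - s/\tau_s - (f-1)/\tau_f, \qquad
  \dot v = \tfrac{1}{\tau_0}\!\left(f - v^{1/\alpha}\right),$$
$$\dot q = \tfrac{1}{\tau_0}\!\left(
    f\,\frac{1-(1-E_0)^{1/f}}{E_0} - v^{1/\alpha}\frac{q}{v}\right).$$

The venous compartment behaves like a distensible balloon: outflow
$v^{1/\alpha}$ grows superlinearly with volume, which is what makes
the response nonlinear.  The observation is
$y = V_0\,(k_1(1-q) + k_2(1-q/v) + k_3(1-v))$ with
$k_1 = 7E_0$, $k_2 = 2$, $k_3 = 2E_0 - 0.2$, a calibration specific
to 1.5 T scanners; other field strengths would need different
coefficients and are not covered.

At rest ($f = q = v = 1$, $s = 0$, $u = 0$) every derivative and the
observation are exactly zero.  The implementation evaluates the
oxygen-extraction ratio as exactly one at $f = 1$ so that this fixed
point holds to the last bit, not merely to rounding.

### Parameters

The seven parameters, their units, and the independent normal priors
used for simulation truths and filter initialization
(`hemo_prior()`):

| parameter | meaning | prior |
|---|---|---|
| $\varepsilon$ | neuronal efficacy (–) | $N(0.54, 0.10^2)$ |
| $\tau_s$ | signal decay (s) | $N(1.54, 0.25^2)$ |
| $\tau_f$ | autoregulatory feedback (s) | $N(2.46, 0.25^2)$ |
| $\tau_0$ | mean transit time (s) | $N(0.98, 0.25^2)$ |
| $\alpha$ | stiffness exponent (–) | $N(0.33, 0.045^2)$ |
| $E_0$ | resting O$_2$ extraction (–) | $N(0.34, 0.10^2)$ |
| $V_0$ | resting blood volume fraction (–) | $N(0.02, 0.005^2)$ |

Only five parameters are filtered: $V_0$ multiplies every term of the
observation, so it is unidentifiable jointly with the others from a
single output, and $\alpha$ is a nominal factor to the BOLD contrast.
Both are held at their prior means (0.33 and 0.02) during estimation
but remain configurable constants.  $k_1$ and $k_3$ are recomputed
from the *current* $E_0$ estimate at every observation evaluation, so
the observation model tracks the parameter filter.

## Numerical integration

The dynamics are smooth and nonstiff at fMRI time scales, so the
package uses a fixed-step classical 4th-order Runge–Kutta integrator:
deterministic, cheap, and with step-size error $O(\Delta t^4)$ (the
suite verifies a log–log error slope of $4 \pm 0.3$ against a
fine-step reference).  The default substep is `dt_sub = 0.1` s, i.e.
20 substeps per TR = 2 s, which keeps the one-TR integration error
around $10^{-7}$ — far below the observation noise.  The stimulus is
held constant within each acquisition interval (zero-order hold),
matching boxcar block designs.

Because the dynamics involve $v^{1/\alpha}$ and $(1-E_0)^{1/f}$, the
states $f$, $q$, $v$ must stay positive even when sigma points or
process noise push them toward zero.  The implementation floors these
three states at $10^{-6}$ after every substep and after every
sigma-point excursion; each activation is counted in the fit
diagnostics.  This is the smallest intervention that keeps the
fractional powers defined, and it never fires on noise-free
trajectories with parameters within two prior SDs of the means (a
property the suite checks over 100 draws).

## Sigma-point filtering

Both estimators are scaled unscented Kalman filters.  A Gaussian
belief $(\mu, P)$ is represented by $2L+1$ deterministic sigma points
built from the lower-triangular Cholesky factor of $P$; defaults
$\alpha_{\mathrm{UT}} = 1$, $\beta_{\mathrm{UT}} = 2$,
$\kappa_{\mathrm{UT}} = 3 - L$ give the classic spread
$\sqrt{L+\lambda} = \sqrt 3$ that matches Gaussian fourth moments in
the scalar quadratic case.  All three constants are configurable.

Numerical hygiene, applied everywhere: covariances are symmetrized
after every update; if a Cholesky factorization fails, jitter
$10^{-9}\,\mathrm{tr}(P)/L$ is added and escalated tenfold at most
three times before an error is raised (a diverging filter should fail
loudly, not silently); the innovation covariance is inverted through a
Cholesky solve, never an explicit inverse.

Two noise treatments are available.  The plain (additive) form adds
$Q$ after the transform and $R$ to the innovation covariance.  The
augmented form stacks the state with process- and observation-noise
dimensions ($L^\alpha = L_x + L_v + L_n$) and draws sigma points from
the block-diagonal covariance, letting noise ride through the
nonlinearity.  For additive-noise systems the two are algebraically
identical, which the suite verifies against an independently coded
textbook Kalman filter on random stable linear-Gaussian systems — the
UKF core's master oracle.  The plain form is the default (it is the
cheaper accounting); the augmented form sits behind a flag.

## The two estimators

**Joint filter** (`run_joint_ukf`): one UKF over
$[f, s, q, v, \varepsilon, \tau_s, \tau_f, \tau_0, E_0]$.  The
transition integrates the state block under each sigma point's own
parameter block and applies the identity plus random-walk noise $R_r$
to the parameter block.  The full $9\times 9$ covariance, including
the state–parameter cross blocks $P_{xw}$, is propagated;
`extract_blocks()` partitions it.

**Dual filter** (`run_dual_ukf`): a 4-dimensional state filter and a
5-dimensional parameter filter alternate at every acquisition.  The
state filter predicts with the current parameter mean and updates
against $y_k$; the parameter filter applies the random-walk time
update $P_w \mathrel{+}= R_r$ and then a measurement update through a
map $G(w)$ described below.  No joint covariance is ever allocated —
the state–parameter cross-covariance is structurally zero, mirroring
the absence of any biophysical correlation between states and
parameters.  Parameter means and sigma points are projected onto a
validity box ($\varepsilon \in [10^{-3}, 5]$, time constants in
$[0.05, 20]$ s, $E_0 \in [0.01, 0.99]$); the box is generous relative
to the priors and exists only to keep the model evaluable.

Within a step the state filter runs first by default (using the
previous parameter mean), so the freshest state estimate is available
to the parameter filter; the reverse order is available for
comparison and makes no practical difference in our experiments.
Both filters consume the same scalar $y_k$ — the BOLD signal is the
system's only output — with the usual consequence that the data are
used twice per acquisition; this is inherent to dual estimation.

### The parameter filter's measurement map

The natural-looking choice for $G$ is a one-step map: propagate the
latest state estimate over one TR under each candidate parameter
vector and observe.  Implementing it revealed a structural failure:
over a single TR the predicted signal is sensitive almost exclusively
to $E_0$, which enters the observation coefficients directly, while
$\varepsilon$ and the time constants act through integration and
barely register.  Started one prior SD off in *all* parameters, the
one-step filter lets $E_0$ absorb the whole amplitude error, then
compensates with a biased transit time, and settles on a ridge of
parameter space whose output is nearly indistinguishable from the
truth's at the study's noise level — even though a batch least-squares
fit from the same start recovers the truth exactly, so the
information is present in the data.

The package therefore uses a multi-scan horizon: $G(w)$ takes the
state estimate from `horizon` acquisitions back and integrates it to
the present under $w$ with the known input history.  Over a horizon of
about one stimulation block (the default, 8 acquisitions = 16 s) the
integrated effects of $\varepsilon$, $\tau_0$, $\tau_s$, $\tau_f$
become visible and the sensitivities are balanced; `horizon = 1`
recovers the one-step map for comparison.  The horizon is a
measurement-model choice, not a smoother: the filter remains strictly
recursive and causal.

### Noise defaults

The paper-scale magnitudes of $Q$, $R$ and $R_r$ are inherently
application-specific; the defaults are: $Q = 10^{-6} I$ (states are
$O(1)$ and the simulator's reference trajectories are deterministic),
$R = (0.1 \max|y|)^2$ when not supplied (matching the 10%-of-peak
noise convention below; pass the true variance when it is known), and
$R_r$ diagonal at $10^{-4}$ times the prior variances — a random walk
of about 1% of a prior SD per step, enough to keep learning alive
without letting converged estimates wander.  Exponential annealing of
$R_r$ (factor 0.995 per acquisition) and a log-space parameterization
of the strictly positive parameters are available behind flags;
neither changed our study conclusions.

## The synthetic-data generator

`simulate_bold()` emulates a classic auditory block paradigm: 136
acquisitions at TR = 2 s — an 8-scan rest lead-in followed by 16
alternating 16-second blocks of 8 scans, starting with rest (the
lead-in closes the gap between 136 acquisitions and $16 \times 8 =
128$ block scans; a rest lead-in is conventional fMRI practice, and
the generator makes it configurable).  Ground-truth parameters default
to the prior means.  Observation noise is Gaussian per acquisition
with SD equal to 10% of the clean-signal peak by default.  Process
noise, when requested, enters as additive Gaussian perturbations of
the state at every substep scaled by $\sqrt{\Delta t}$ — the
Euler–Maruyama-consistent reading of continuous white process noise.
The generator records the state at acquisition $k+1$ as the state at
$k$ advanced under $u_k$, the same convention the filters use, and a
given seed determines the output byte-for-byte.

What the generator does *not* emulate: scanner drift, motion,
physiological aliasing (cardiac/respiratory), event-related designs,
multi-voxel structure, or model mismatch (the data are generated by
the same Balloon equations the filters invert).  Passing recovery
tests on these data therefore demonstrates the estimators' internal
correctness and conditioning, not robustness to the confounds of real
fMRI sessions.

## Cost accounting

The only $O(L^3)$ operation in a sigma-point filter is the Cholesky
factorization of the $L \times L$ covariance at each cycle, so the
package charges $L^3/6$ per factorization: the joint filter one
factorization per acquisition, the dual filter two (it runs two
cycles — state and parameter — where the joint filter runs one).
Plain mode compares $4^3/6 + 5^3/6 = 31.5$ against $9^3/6 = 121.5$
(excess 285.7%); augmented mode compares $(9^3 + 11^3)/6 \approx
343.3$ against $19^3/6 \approx 1143.2$ (excess 233.0%).  Cubic
superadditivity makes the excess positive for any split of the
dimensions, and it exceeds 56% in both modes.  Wall-clock
benchmarking is deliberately out of scope: it is hardware-bound and
adds nothing to the dimensional argument.

## Study conditions used by the tests

The recovery study (shared by the test suite and
`scripts/acceptance.R`) uses 20 seeded sessions of the default
paradigm, truth at the prior means, 10%-of-peak observation noise,
and the parameter filter initialized at the prior means shifted +1
prior SD with prior variances.  Twenty seeds at 136 scans keep the
full study around two minutes on one core while making the
across-seed means stable to well within the reported tolerances; the
unit tests use a 20-scan variant of the design where only plumbing,
not statistical power, is being exercised.

The dual-versus-joint trace comparison runs both filters on identical
data, seeds, initializations and noise settings (the magnitudes a
practitioner would have to pick are fixed identically for both
schemes so the comparison isolates the architecture).  Parameter
movement is summarized as the total variation of each parameter trace
normalized by its prior SD, summed over parameters, measured from the
first stimulated acquisition onward — before that point the data are
pure rest and both filters are provably inert, so including the
all-rest prefix would only dilute the comparison.  The joint filter's
extra movement is concentrated in its convergence phase, when the
modelled cross-covariance feeds state innovations into the parameter
estimates.

## Known limitations

* The observation calibration is 1.5 T only.
* Single voxel, known stimulus: no deconvolution of $u$, no spatial
  model.
* One-pass recursive estimation: with all parameters simultaneously
  misspecified the posterior can settle within about one prior SD of
  a compensating ridge direction (amplitude trades between
  $\varepsilon$, $E_0$ and $\tau_0$); a batch optimizer started from
  the filter's answer would sharpen it.  The multi-scan horizon
  mitigates, but does not abolish, this geometry.
* The extended Balloon variants (oxygen-metabolism dynamics,
  separate intra/extravascular compartments) are out of scope; the
  four-state model is sufficient for the estimation questions this
  package addresses.
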