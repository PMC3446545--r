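# hemodual

Dual and joint unscented Kalman filtering for the Balloon hemodynamic
model.

## The problem

The BOLD (blood oxygenation level dependent) signal measured by fMRI
is an indirect, nonlinear readout of a voxel's hemodynamics.  The
Balloon model describes those hemodynamics with four coupled states —
normalized cerebral blood flow *f*, its rate-of-change signal
*s = ḟ*, normalized deoxyhemoglobin content *q* and normalized venous
volume *v* — driven by a neuronal input *u(t)*:

    ḟ = s
    ṡ = ε u − s/τs − (f − 1)/τf
    v̇ = (f − v^{1/α}) / τ0
    q̇ = ( f · (1 − (1 − E0)^{1/f}) / E0 − v^{1/α} · q/v ) / τ0

and the observation equation (1.5 T calibration)

    y = V0 ( k1 (1 − q) + k2 (1 − q/v) + k3 (1 − v) ),
    k1 = 7 E0,  k2 = 2,  k3 = 2 E0 − 0.2.

Inverting this model from a single-voxel BOLD series means estimating
the four states *and* the unknown physiological parameters
(ε, τs, τf, τ0, E0; α and V0 are held fixed) at the same time — the
dual estimation problem.  This package implements and compares two
sigma-point (unscented Kalman filter) solutions:

* **dual filtering** — a 4-dimensional state filter and a
  5-dimensional parameter filter run alternately at every
  acquisition, with *no* modelled state–parameter cross-covariance
  (the states and parameters are not biophysically correlated, so
  none is represented); and
* **joint filtering** — the common baseline, a single filter over the
  concatenated 9-dimensional state with the full cross-covariance.

The dual scheme is both statistically decoupled (parameter traces do
not inherit state fluctuations) and cheaper: sigma-point filters are
dominated by one Cholesky factorization of the L×L covariance per
cycle (≈ L³/6 flops), and two small factorizations (4³ + 5³) cost far
less than one large one (9³) — at least 56% less in every mode, even
though the dual scheme runs two cycles per acquisition.

For whom: methods researchers working on hemodynamic model inversion
and anyone needing a compact, fully seeded test bed for dual-vs-joint
nonlinear state/parameter estimation.

## Worked example

Simulate one session of the default block paradigm (136 acquisitions
at TR = 2 s; 16 alternating 16-second blocks starting with rest, after
an 8-scan rest lead-in; observation noise at 10% of the clean-signal
peak), then invert it with the dual filter started one prior SD away
from the generating parameters:

```r
library(hemodual)

sim <- simulate_bold(seed = 1)                # truth = prior means
pr  <- hemo_prior()
i   <- match(c("epsilon","tau_s","tau_f","tau_0","E_0"), pr$parameter)
init <- gaussian_belief(pr$mean[i] + pr$sd[i], diag(pr$sd[i]^2))

fit <- hemofit(sim, init_params = init, R = attr(sim, "obs_noise_sd")^2)
summary(fit)
```

```
Balloon model fit (dual UKF), 136 acquisitions

Parameters (posterior at the final acquisition):
        estimate     sd prior_mean prior_sd
epsilon   0.5464 0.0486       0.54     0.10
tau_s     1.5452 0.0855       1.54     0.25
tau_f     2.3989 0.1484       2.46     0.25
tau_0     1.0378 0.1438       0.98     0.25
E_0       0.3737 0.0571       0.34     0.10

Fixed: alpha = 0.33 , V_0 = 0.02 
Innovation RMSE: 0.003569   log-likelihood: 571.88
```

The generating values were the prior means (ε = 0.54, τ0 = 0.98 s,
…), and every estimate has moved from its shifted start (+1 prior SD)
back toward the truth.  `coef()`, `fitted()`, `residuals()`,
`predict()`, `simulate()` and `plot()` work as usual;
`hemofit(sim, scheme = "joint")` runs the baseline joint filter on the
same data.

The cost comparison:

```r
compare_complexity()
```

```
      mode dual_dims joint_dims dual_flops joint_flops excess_percent
     plain       4+5          9     31.500      121.50        285.714
 augmented      9+11         19    343.333     1143.17        232.961
minimum excess of joint over dual: 233.0%
```

`plain` charges each filter its own covariance factorization per
acquisition; `augmented` uses the noise-augmented sigma-point form,
where state, process-noise and observation-noise dimensions are
stacked (4+4+1 = 9 and 5+5+1 = 11 for the dual pair, 9+9+1 = 19 for
the joint filter).  In both accountings the joint filter costs well
over 56% more per acquisition.

## Command line

A thin front end is installed with the package:

```sh
script=$(Rscript -e 'cat(system.file("exec","hemodual.R", package="hemodual"))')
Rscript "$script" simulate  --config sim.json --out data/
Rscript "$script" fit-dual  --data data/series.tsv --out fit/
Rscript "$script" fit-joint --data data/series.tsv --out fitj/
Rscript "$script" compare   --data data/series.tsv --out cmp/
Rscript "$script" complexity --mode both
```

All commands are seeded and write byte-identical output for identical
configuration.

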