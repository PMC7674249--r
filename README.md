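# jointmarg

Population-averaged (marginal) estimates of the overall treatment
effect on a survival outcome within a shared-random-effects joint model
for longitudinal and time-to-event data.

## The problem

In a joint model, a Gaussian biomarker trajectory

$$y_i(t) = x_i^\top(t)\beta + z_i^\top(t) b_i + \epsilon_i(t),
\qquad b_i \sim N(0, \Sigma_b),\ \epsilon_i(t) \sim N(0,\sigma^2),$$

is linked to a relative-risk survival submodel

$$h_i(t \mid b_i) = h_0(t)\exp\{\gamma^\top w_i +
\alpha f_i(t \mid b_i)\},$$

where $f_i$ is the current value, slope, or cumulative value of the
true trajectory $\eta_i(t)$.  The overall treatment effect on the
hazard — the time-varying hazard ratio
$\mathcal{T}(t) = \exp\{\bar W\gamma + \alpha\bar X(t)\beta\}$
aggregating the direct effect $\gamma$ and the indirect effect through
the trajectory — is *conditional on the random effects*: it describes
the subject with $b_i = 0$, not the population, because the random
effects do not cancel out of the hazard ratio under the exponential
link.  Clinical trials usually need the population-averaged effect.

jointmarg computes it by marginalizing the subject-specific hazards
over the random-effects distribution by Monte Carlo,

$$\log h^M_i(t) = \log\frac{E_b\{h_i(t\mid b)\,S_i(t\mid b)\}}
{E_b\{S_i(t \mid b)\}},$$

with the survival weights evaluated by 15-point Gauss–Kronrod
quadrature, and then projecting the stacked marginal log hazards (all
longitudinal times plus all observed survival times) onto the model
design by least squares:

$$\theta^M = (\tilde X^\top \tilde X)^{-1}\tilde X^\top \log H^M,
\qquad \tilde X = [\,W_{h0} \mid W \mid X\beta\,],$$

yielding marginal coefficients $(\gamma^M_{h0}, \gamma^M, \alpha^M)$,
marginal hazard-ratio curves
$\mathcal{T}^M(t) = \exp\{\bar W\gamma^M + \alpha^M \bar X(t)\beta\}$,
weighted-average effects
$\phi(t_0) = \exp\{\int_0^{t_0} \log\mathcal{T}(t)\,\Omega(t)\,dt\}$,
and simulation-based standard errors (repeat the marginalization for
$L$ draws of the fitted parameters from their approximate sampling
distribution; summarize with sample SDs and percentile intervals).

The package also contains a maximum-likelihood fitter for the joint
model itself (pseudo-adaptive Gauss–Hermite quadrature, analytic
gradients) and a simulator whose presets reproduce a four-scenario
design with association strengths $\alpha = -0.01, -0.5, -1, -2$, so
the entire method is exercisable end to end without external data.

## Worked example

```r
library(jointmarg)

scen <- scenario_preset("II", n_subjects = 300, seed = 7)  # alpha = -0.5
ds   <- simulate_dataset(scen)
fit  <- fit_joint_model(ds, scen$spec)
m    <- marginal_coefs(fit, ds, marg_config(G = 2000, K = 2000, seed = 11))

ctr <- treatment_contrast(scen$spec, ds)
tt  <- c(1, 4, 7)
data.frame(time        = tt,
           hr_ss       = effect_curve_ss(fit, ctr, tt)$hr,
           hr_marginal = effect_curve_marginal(m, fit, ctr, tt)$hr)
```

prints (elided to three decimals)

```
  time hr_ss hr_marginal
1    1 4.099       4.027
2    4 3.734       3.446
3    7 3.401       2.948
```

The fit recovers the generating parameters
(`alpha` $-0.550 \pm 0.242$ against a true $-0.5$; treatment log
hazard ratio $1.442 \pm 0.146$ against $1.48$), and the marginal
hazard-ratio curve is attenuated toward the null relative to the
subject-specific one — the attenuation grows with follow-up time
(3.40 vs 2.95 at $t = 7$) because survivors are increasingly selected
on their random effects.  Uncertainty and a single-number summary:

```r
un  <- marginal_se(fit, ds, marg_config(G = 500, K = 500, seed = 13), L = 50)
phi <- weighted_effect(
  jointmarg:::loghr_function(m$gamma_M, m$alpha_M, fit$params$beta, ctr),
  weight_function("uniform", t0 = 7))
```

gives `SE(alpha_M) = 0.674`, a 95% percentile interval
`[-2.691, -0.358]` for $\alpha^M$, and a uniform-weighted average
effect `phi(7) = 3.537`.

A command-line interface wrapping simulate / fit / marginalize /
effects / study lives at `inst/cli/jointmarg.R`
(`system.file("cli", "jointmarg.R", package = "jointmarg")`).

## Documentation

The methods vignette
(`vignettes/marginal-treatment-effects.Rmd`) describes the model and
its assumptions, every tunable parameter with its default and
rationale, what the synthetic-data generator does and does not
emulate, the numerical conventions, and known limitations.
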