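# fermkin

Kinetic modelling of batch shake-flask fermentation for an oleaginous,
DHA-producing microorganism (*Aurantiochytrium*-type thraustochytrid),
for bioprocess scientists who want the classical growth /
substrate / product triad as tested, reproducible code rather than a
desktop curve-fitting session.

## The model

Three coupled states — biomass dry cell weight $C_X$, glucose $C_S$, DHA
titer $C_P$, all in g/L, time in days:

$$\frac{dC_X}{dt} = \mu C_X,\qquad
  \mu = \mu_{max}\Bigl(1 - \frac{C_X}{C_{Xm}}\Bigr)$$

$$\frac{dC_S}{dt} = -\frac{1}{Y_{X/S}}\frac{dC_X}{dt} - m_S C_X$$

$$\frac{dC_P}{dt} = (\alpha\mu + \beta)\,C_X$$

logistic growth toward a carrying capacity $C_{Xm}$, Pirt-style glucose
consumption with maintenance coefficient $m_S$ and fixed stoichiometric
yield $Y_{X/S} = 0.45$ g/g, and Luedeking–Piret product formation with
growth-associated $\alpha$ and non-growth-associated $\beta$. Glucose is
clamped at zero on exhaustion.

The package provides:

* `simulate_time_course()` — adaptive ODE simulation onto any sampling
  grid, verified against the closed-form logistic solution;
* `builtin_scenario()` / `generate_observations()` — the three fitted
  strain parameter sets (native, BBF001, BBF002) and a synthetic
  triplicate shake-flask data generator with seeded measurement noise;
* `fit_kinetics()` — joint bounded least-squares estimation of
  ($\mu_{max}$, $C_{Xm}$, $m_S$, $\alpha$, $\beta$) with Latin-hypercube
  multistart, plus the per-variable goodness-of-fit statistic
  $R^2 = SSM/(SSM+SSE)$ and `mixed_growth_partition()`;
* `compute_descriptors()` — the endpoint panel $Q_X$, $Q_S$, $Q_P$,
  $\mu$, $Y_{X/S}$, $Y_{P/S}$ over the window from inoculation to peak
  product titer;
* `run_simulate()` / `run_fit()` / `run_describe()` — file-based pipeline
  steps (CSV time courses, JSON metadata sidecars, YAML configs) used by
  the numbered drivers under `analysis/`.

## Worked example

Simulate the BBF002 scenario, refit its parameters from its own noise-free
daily samples, and compute the endpoint descriptors:

```r
library(fermkin)

sc <- builtin_scenario("BBF002")
tc <- simulate_time_course(sc$params, sc$initial, sc$sample_times)
fit <- fit_kinetics(tc)
fit
#> Batch kinetic model fit (18 observations)
#> Batch fermentation kinetic parameters
#>   mu_max = 1.617 1/d   C_Xm = 19.891 g/L
#>   Y_XS   = 0.45 g/g   m_S  = 0.033 g/(g d)
#>   alpha  = 0.055 g/g   beta = 0.02 g/(g d)
#>   R2: biomass 1.0000  glucose 1.0000  product 1.0000
#>   objective 3.613e-30  converged: TRUE
```

The fit recovers the generating constants to ~1e-13 relative error: the
maximum specific growth rate (1.617 1/d), the biomass carrying capacity
(19.891 g/L), the maintenance drain (0.033 g glucose per g biomass per
day) and the two product coefficients. Since $\alpha > \beta$, DHA is a
mixed-growth-associated product dominated by the growth phase
(`mixed_growth_partition(fit, tc)` puts 48.2 % of product formation in the
growth-associated term for this strain).

```r
compute_descriptors(tc)
#>    label t1 t2      Q_X Q_S       Q_P        mu  Y_XS_obs   Y_PS_obs
#> 1 BBF002  0  5 3.819175   8 0.4360895 0.3764699 0.4773969 0.05451119
```

Over the 5-day window this strain produces biomass at 3.82 g/(L d) and
DHA at 0.44 g/(L d), with an endpoint specific growth rate of 0.38 1/d.
(The observed yield 0.477 exceeds the stoichiometric 0.45 here because
glucose is exhausted near day 3.9 and consumption is clamped; see the
vignette.)

The numbered scripts in `analysis/` run the full workflow — noise-free
simulation of all three strains, synthetic triplicate data generation,
parameter recovery, descriptor panels, and a 50-seed noise-robustness
study — writing their tables under `results/`.

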