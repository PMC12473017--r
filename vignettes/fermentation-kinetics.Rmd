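---
title: "Modelling batch growth, glucose consumption and DHA formation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling batch growth, glucose consumption and DHA formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fermkin)
```

## The model

`fermkin` describes a batch shake-flask fermentation of an oleaginous,
DHA-producing microorganism by three coupled state variables: biomass dry
cell weight $C_X$ (g/L), glucose $C_S$ (g/L) and DHA titer $C_P$ (g/L),
with time in days.

Growth is logistic — the specific growth rate declines linearly with
density toward a carrying capacity rather than depending on substrate:

$$\frac{dC_X}{dt} = \mu C_X, \qquad
  \mu = \mu_{max}\left(1 - \frac{C_X}{C_{Xm}}\right).$$

Glucose is consumed stoichiometrically for biomass plus a maintenance
drain (the Pirt decomposition):

$$\frac{dC_S}{dt} = -\frac{1}{Y_{X/S}}\frac{dC_X}{dt} - m_S C_X.$$

DHA forms by the Luedeking–Piret law, a growth-associated term plus a
non-growth-associated term:

$$\frac{dC_P}{dt} = (\alpha\mu + \beta)\,C_X.$$

The logistic equation has the closed form
$C_X(t) = C_{Xm} C_{X0} e^{\mu_{max} t} / (C_{Xm} - C_{X0} + C_{X0}
e^{\mu_{max} t})$, which the package uses as an independent oracle for the
numerical integrator (`logistic_closed_form()`), not as the simulation
path.

### Parameters

| symbol | meaning | unit | built-in values (native / BBF001 / BBF002) |
|---|---|---|---|
| $\mu_{max}$ | maximum specific growth rate | 1/d | 1.568 / 1.585 / 1.617 |
| $C_{Xm}$ | carrying-capacity biomass | g/L | 12.934 / 17.866 / 19.891 |
| $Y_{X/S}$ | stoichiometric biomass yield | g/g | 0.45 (all; from the elemental biomass formula, held fixed) |
| $m_S$ | maintenance coefficient | g/(g d) | 0.005 / 0.024 / 0.033 |
| $\alpha$ | growth-associated product coefficient | g/g | 0.100 / 0.033 / 0.055 |
| $\beta$ | non-growth-associated product coefficient | g/(g d) | 0.001 / 0.029 / 0.020 |

`builtin_scenario()` ships these three fitted strain parameter sets with
the default initial state and daily sampling over the 5-day cultivation.

### Assumptions and the substrate-exhaustion clamp

The growth law saturates through $C_{Xm}$, not through glucose, so the
substrate balance can formally drive $C_S$ negative. The package keeps
states physical by a clamp: once $C_S$ reaches 0, $dC_S/dt$ is forced to 0
while the growth and product equations are left untouched. This preserves
the published equation structure; it is a convention, since the original
fitting software's handling of exhaustion is not documented.

One visible consequence: with the BBF002 constants and 40 g/L initial
glucose, exhaustion occurs near day 3.9. Over any window that crosses it
the *observed* endpoint yield $\Delta C_X/\Delta C_S$ no longer tracks the
stoichiometry — it comes out at 0.477 g/g, above the stoichiometric
0.45 g/g, because biomass keeps accumulating against a frozen substrate
axis. The classical inequality "observed yield below stoichiometric yield
whenever $m_S > 0$" holds on substrate-positive windows (e.g. BBF002 over
days 0–3 gives 0.442 g/g), and that is how the property is tested.

Overshoot ($C_X > C_{Xm}$, giving $\mu < 0$) is admitted rather than
clamped; the logistic equation self-corrects.

## Simulation

`simulate_time_course()` integrates the system with `deSolve`'s adaptive
`lsoda`/`lsodar` at tolerances `rel_tol = 1e-8`, `abs_tol = 1e-10` — tight
enough that integration error is negligible against parameters quoted to
3–4 significant figures. Exhaustion is handled in two phases: the full
dynamics run under root detection on $C_S$; at the root the integration
restarts with the substrate derivative switched off. A naive conditional
in the right-hand side creates a sliding surface at $C_S = 0$ that forces
step-size collapse; the two-phase scheme avoids it and is what lets
noise-free fits recover parameters at machine precision.

Default initial state: $C_{X0} = 0.6$ g/L, $C_{S0} = 40$ g/L,
$C_{P0} = 0.02$ g/L. The glucose matches the production-medium recipe; the
biomass and product carryover are plausible values for a 10 % (v/v)
inoculum of a grown culture and are configuration, not hard-coded model
constants — the raw flask measurements behind the published fits were
never deposited, so these cannot be read off data.

## The synthetic-data generator

`generate_observations()` emulates triplicate shake-flask sampling: it
simulates the noise-free trajectory, then adds independent Gaussian noise
per variable with standard deviation $\max(\mathrm{CV}\cdot value,
floor)$, truncated at zero so concentrations stay physical. Defaults:
5 % CV on all three variables (typical dry-cell-weight / HPLC / GC assay
precision), small absolute floors (0.01, 0.05, 0.002 g/L) representing
instrument resolution near zero, 3 replicates at each of days 0–5. The
true assay error magnitudes are not recoverable from published error bars,
so these defaults are documented assumptions, exposed in `noise_spec()`.

Each variable draws from its own child random stream derived
deterministically from one root seed, so runs are bit-reproducible and
changing one variable's noise setting does not perturb the others'
realizations.

What the generator does *not* emulate: flask-to-flask biological
variability (replicates share one true trajectory), autocorrelated or
heteroscedastic instrument drift, sampling-time jitter, and missing
values. Passing tests therefore demonstrate correctness of the machinery
and estimator behaviour under idealized i.i.d. measurement noise, not
performance on real flask data.

## Parameter estimation

`fit_kinetics()` estimates ($\mu_{max}$, $C_{Xm}$, $m_S$, $\alpha$,
$\beta$) jointly from all three observed variables; $Y_{X/S}$ stays fixed
at 0.45 unless explicitly freed. Design choices, each genuinely open and
settled as follows:

* **Joint, not sequential.** One coherent weighted objective over all
  three equations rather than fitting growth, then substrate, then
  product. Reproducible and uses all cross-variable information.
* **Range weighting.** Residuals of each variable are divided by that
  variable's observed range, so glucose (~40 g/L span) cannot swamp DHA
  (~2.5 g/L). `weight_mode = "none"` gives raw residuals.
* **Initial state from data.** The first observation's replicate mean, not
  an estimated quantity (estimating it is possible but off by default —
  six time points carry little information to spare).
* **Bounded Levenberg–Marquardt with multistart.** `minpack.lm::nls.lm`
  within generous boxes ($\mu_{max} \le 5$/d, $C_{Xm} \le 60$ g/L,
  $m_S \le 0.5$, $\alpha \le 1$, $\beta \le 0.5$), started from 8
  Latin-hypercube points drawn with a fixed seed; best final objective
  wins, ties to the first start. The original work used a desktop
  optimizer whose internals are unknown; deterministic multistart guards
  against local minima without introducing irreproducibility.
* **Tight stopping.** `ftol = ptol = 1e-13`, up to 200 iterations per
  start: noise-free recovery lands at ~1e-13 relative error, so the 1 %
  recovery checks probe the model and objective, not optimizer slack.

### The goodness-of-fit statistic

The fit quality measure is
$$R^2 = \frac{\sum (C_{cal} - \bar C_{exp})^2}
             {\sum (C_{cal} - \bar C_{exp})^2 + \sum (C_{cal} - C_{exp})^2},$$
reported per variable (`r2_X`, `r2_S`, `r2_P`). By construction it lies in
$[0, 1]$ and equals 1 exactly at a perfect fit — but it is **not** the
classical coefficient of determination (it cannot go negative, and a
constant prediction at the observed mean scores 0 rather than undefined).
The property suite asserts only boundedness and the perfect-fit value.

### Identifiability at six daily samples

With 6 time points per variable the growth constants $\mu_{max}$ and
$C_{Xm}$ are well identified (median relative error ~2 % at 5 % CV,
triplicates, over 50 seeds — `analysis/05_noise_robustness.R` computes the
table). $m_S$, $\alpha$ and $\beta$ are weakly identified at this sampling
density: their noisy-data spread is characterized, not asserted against.
Noise-free recovery of all five to well under 1 % is asserted for all
three strain scenarios.

### Mixed-growth partition

`mixed_growth_partition()` splits total product formed into
$\int \alpha\mu C_X\,dt$ (growth-associated) and $\int \beta C_X\,dt$
(non-growth) by trapezoidal quadrature on a 2001-point simulated
trajectory; the shares sum to 1 within quadrature tolerance and the first
integral equals $\alpha\,\Delta C_X$ exactly, which the tests exploit as a
cross-check. For all three built-in scenarios $\alpha > \beta$: DHA is a
mixed-growth-associated product dominated by the growth term.

## Endpoint descriptors

`compute_descriptors()` implements the endpoint panel over a window
$(t_1, t_2)$: volumetric rates $Q_X$, $Q_S$, $Q_P$ (g/(L d)), specific
growth rate $\mu = Q_X / ((C_{X,1}+C_{X,2})/2)$, and observed yields
$Y_{X/S} = \Delta C_X/\Delta C_S$, $Y_{P/S} = \Delta C_P/\Delta C_S$.
Replicates are averaged per time point first; per-replicate panels are
available behind `per_replicate = TRUE` for spread reporting. The default
window (`pick_window()`) runs from the first sample to the time of peak
product titer, earliest time on ties. Both endpoints must be sampled
times — requesting an off-grid time is an error naming the nearest
available times, never a silent interpolation, because the panel is
defined on measured endpoints. Zero substrate consumption makes the
yields undefined (`NA`); the rates are still returned.

## Numerical and degenerate-input conventions

* A single-time grid returns the initial state unchanged.
* Integration failure raises an error carrying the failing time.
* Tolerance-level negative substrate at the clamp crossing is zeroed.
* A constant observed variable (zero range) falls back to weight 1.
* Time-course CSVs are written with 17 significant digits, so
  write-then-read round trips are lossless at full double precision; every
  output carries a JSON sidecar with seed, tool version and a
  configuration hash for exact re-runs.

## Problem sizes

The shipped analyses and tests use the study's own scale: 6 daily samples,
3 replicates, 5-day horizon; 20 random parameter draws for
integrator-vs-closed-form agreement; 1,000 replicates for the
noise-calibration check; 50 seeds for the noisy-recovery characterization.

## Known limitations

* Growth is substrate-independent by construction; the model cannot
  represent starvation arrest of growth, only of consumption.
* Parameters are constants — no temperature or pH dependence, although the
  underlying experiments varied both.
* Lipid-class partitioning (DHA within total fatty acids) is outside the
  state space; $C_P$ is total DHA titer.
* The estimator returns point estimates; no confidence intervals or
  posterior uncertainty.
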