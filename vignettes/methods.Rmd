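---
title: "Model and methods: effect-compartment PK-PD of L-serine in pediatric autism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: effect-compartment PK-PD of L-serine in pediatric autism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`astpkpd` implements a population pharmacokinetic-pharmacodynamic (PK-PD)
analysis of orally administered L-serine (AST-001) in children with autism
spectrum disorder, together with the clinical trial simulator needed to
select weight-tiered phase-III doses. This vignette is the package's own
account of the model, the estimation machinery, the synthetic-data
generator, and the design decisions behind them.

## The structural model

**Pharmacokinetics.** Plasma concentration follows a two-compartment model
with zero-order absorption of duration $D_1$ and linear elimination,
parameterised by apparent clearance $CL/F$, central and peripheral volumes
$V_1/F$ and $V_2/F$, and inter-compartmental clearance $Q/F$. The package
evaluates the model in closed form: the bi-exponential unit response is
convolved analytically with the zero-order input and superposed over dose
events (`plasma_concentration()`). A generic stiff ODE integration serves
only as a test oracle; the analytic route is exact (agreement to relative
1e-6 and better in the tests) and orders of magnitude faster, which is what
makes the estimation loops affordable. There is no endogenous serine
production term: concentrations are exogenous drug only and decay to zero
after the last dose.

Pediatric PK is obtained from the adult reference values by fixed
allometry: clearances scale with $(\mathrm{weight}/70)^{0.75}$, volumes
linearly with weight (`allometric_scale()`, `scale_pk()`). PK parameters
are never estimated here — the estimation layer holds them fixed, as the
pediatric trial collected no PK samples.

**The placeholder PK values.** The adult reference estimates live in a
separate publication and are not embedded in this package. The shipped
defaults (`pk_parameters()`: $CL/F$ 504 L/day, $V_1/F$ 28 L, $Q/F$ 67
L/day, $V_2/F$ 40 L, $D_1$ 0.0625 day at 70 kg) are documented
placeholders chosen once to be qualitatively consistent with rapid
absorption (peak at 1.5 h) and a terminal half-life near 11 h; substitute
published values for any analysis where the absolute exposure scale
matters. Every quantitative claim the package's tests make is either
PK-free (placebo progression, baseline covariate structure) or
self-consistent simulate-then-recover, so none depends on the placeholder
values.

**Pharmacodynamics.** The endpoint is the K-VABS-II-ABC adaptive-behavior
composite score. Drug effect acts through a hypothetical effect
compartment,
$$\frac{dC_e}{dt} = k_{e0}\,(C_p - C_e), \qquad C_e(0) = 0,$$
whose equilibration half-life $\ln 2 / k_{e0}$ is roughly 15 weeks at the
default $k_{e0} = 0.0065$/day — drug effect builds up over the whole trial
rather than tracking plasma. The observed score is
$$y_{ij} = E_{0,i} + K_{prog,i}\, t_{ij} + D_{eff,i}\, C_e(t_{ij})
  + \varepsilon_{ij}, \qquad \varepsilon_{ij} \sim N(0, \sigma^2),$$
a linear natural-progression term plus a linear effect of effect-site
concentration. $C_e$ is evaluated by the exact piecewise-analytic
convolution of the closed-form plasma curve with the $k_{e0}$ kernel
(`effect_site_concentration()`); a numerically integrated convolution on a
user grid is available for sampled plasma profiles.

**Covariates and variability.** The typical baseline follows a power
function of age normalised at 5 years, $E_0 (\mathrm{age}/5)^{\beta_{age}}$
with $\beta_{age} < 0$ (younger children score higher, partly because the
motor-skills domain is only assessed below age 7). Between-subject
variability is log-normal on $k_{e0}$, $E_0$ and $D_{eff}$ and
additive-normal on $K_{prog}$, with a correlation between the $E_0$ and
$K_{prog}$ etas: children with better baseline adaptive behavior also
progress faster naturally. Residual error is additive, and the baseline
score is treated as an observation (it carries residual error and
information about $E_0$), not as a fixed covariate.

**A deliberate unit tension.** $D_{eff}$ is carried in L/µg against plasma
in µg/L, as printed in the source analysis. At the placeholder adult PK the
implied exposures make the absolute drug effect implausibly large; the
internal concentration scale of the original analysis is not recoverable
from what is published. The package treats the units as printed and keeps
everything self-consistent — simulate-then-recover calibration, direction
and monotonicity properties are all invariant to this scale — and flags
rather than guesses. Absolute treated-arm score changes from the default
configuration should not be read as clinical predictions.

## Estimation

`fit_pkpd()` maximises the marginal likelihood over the PD fixed effects
($k_{e0}$, $E_0$, $\beta_{age}$, $D_{eff}$, $K_{prog}$), the four omega
SDs with the $E_0$–$K_{prog}$ correlation, and $\sigma$, holding PK fixed.

**The Gaussian parameter layer.** Internally the subject-level parameters
are $\phi_i = (\log k_{e0,i}, \log E_{0,i}, \log D_{eff,i}, K_{prog,i})$
with mean $M_i \theta$ (the design matrix carries the covariate terms, age
on $E_0$ by default) and structured covariance $\Omega$. Conditional on
$\phi_i$ the model is Gaussian, so the complete-data likelihood is an
exponential family: the SAEM sufficient statistics are the per-subject
$\phi_i$, $\phi_i\phi_i^\top$ and the residual sum of squares, and the
M-step is closed-form — generalised least squares for $\theta$ given
$\Omega$ alternated twice with the moment update of the structured
$\Omega$, plus $\hat\sigma^2 = \mathrm{RSS}/N$.

**SAEM.** The E-step samples each subject's etas by
Metropolis-Hastings. Because plasma kinetics are eta-free, each subject's
$C_e(k_{e0})$ at the observation times reduces to a small analytic
function of $k_{e0}$ over precomputed event sums (the "Ce basis"), so a
full-population E-step sweep is a handful of vectorised operations. Three
kernels are used per iteration: an independence proposal from the prior, a
joint random walk whose per-subject proposal covariance is the local
Laplace covariance at a warm-started conditional mode (refreshed every 25
iterations), and componentwise random walks with acceptance-adapted
scales. The joint kernel matters: the per-subject posteriors couple
baseline with slope and $k_{e0}$ with $D_{eff}$ strongly, and
componentwise walks alone mix too slowly to keep the stochastic
approximation honest.

Three further stabilisers were adopted after observing the estimator on
phase-II-sized synthetic data, where four observations face four etas per
subject and the drug-effect scale makes the likelihood surface violent:

* chains start at the empirical-Bayes modes of the initial model rather
  than at zero etas, so the first sufficient statistics are not dominated
  by unexplained between-subject spread;
* the burn-in stochastic-approximation step is damped ($\gamma = 0.25$)
  and the smoothing phase uses $1/k^{0.7}$; with full $\gamma = 1$
  replacement, a residual-sum-of-squares spike from momentarily stale etas
  inflates $\sigma^2$, flattens the target, and can lock the run onto a
  spurious attractor (runs rejected by the exact Laplace objective);
* at each proposal refresh during burn-in, any chain stranded more than 10
  log-density units above its freshly computed conditional mode is
  re-anchored there.

The default schedule is 300 exploration plus 400 smoothing iterations with
two chains. The smoothing phase is longer than common defaults because the
$\sigma$ component of the EM map contracts slowly (about 0.9 per step) at
this design's observations-per-eta ratio. For the same reason the fit ends
with a profile polish of $\sigma$ (`polish_sigma = TRUE`): a short 1-D
optimisation of the Laplace objective replaces the SAEM $\sigma$ by its
exact conditional maximum-likelihood value given the other estimates,
removing the slowest-converging component deterministically. On one CPU a
full 145-subject fit takes one to two minutes.

**Laplace.** `neg2_loglik()` computes the objective function value
($-2\log$ marginal likelihood) by the Laplace approximation: per-subject
mode finding over the active etas, a finite-difference Hessian, and the
standard determinant correction. It matches brute-force quadrature to well
under 0.1 OFV units on a one-eta toy problem in the tests, collapses to
the closed-form Gaussian likelihood when all omegas are zero, and serves
three roles: a deterministic fallback estimator (`method = "laplace"`,
practical for small data), the comparator for likelihood-ratio tests, and
the referee used while validating SAEM. When all omegas are zero
`fit_pkpd()` reduces to nonlinear least squares on the fixed effects, the
profile MLE in that degenerate case.

**Model comparison and uncertainty.** `lrt_decision()` applies the
chi-square test on OFV differences (critical value 3.84 at one degree of
freedom and $\alpha = 0.05$); `covariate_search()` wraps it in forward
selection at $p < 0.05$ and backward elimination at $p < 0.01$, entering
continuous covariates as power functions normalised to the dataset median
and sex as an indicator, and returns the full decision log.
`bootstrap_fit()` is a case bootstrap: subjects resampled with
replacement, each replicate refitted, medians and 2.5/97.5 percentiles
reported. `fit_standard_errors()` inverts a central-difference Hessian of
the Laplace OFV on the transformed scale (log for positive parameters,
atanh for the correlation) and reports RSE% as $100\,SE/|\hat\theta|$;
it is quadratic in the parameter count and meant for small-to-moderate
datasets.

**Initial values.** For simulation studies the convention is a perturbed
truth (the acceptance script starts at roughly half the drug-effect slope,
1.5-fold $k_{e0}$, and similarly displaced variance components). For user
data `moment_init()` builds starts from the data: log-log regression of
baseline score on age for $E_0$, $\beta_{age}$ and $\Omega_{E0}$;
pre-crossover placebo slopes for $K_{prog}$ and $\Omega_{Kprog}$; moderate
generic values for the exposure-related parameters.

## The synthetic trial generator

No public dataset exists (the clinical data are confidential), so
`simulate_dataset()` generates cohorts with the statistical structure the
analysis assumes, emulating the phase-II design:

* 145 subjects, three arms (placebo / low / high) in a 1:1:1 ratio;
* ages uniform on 2–11 years, 82.8% male; weight log-normal (CV 15%,
  truncated to 10–60 kg) around an embedded sex-by-age median growth
  table, which preserves the monotone age-weight correlation the dose
  simulations need without pulling in an external exposure-toolkit
  dependency; baseline total serine log-normal around 128 µmol/L as an
  optional covariate;
* weight-tiered BID dosing from the phase-II band table (2/4/7/10/14 g for
  10–14 / 15–24 / 25–37 / 38–51 / ≥52 kg); the high arm takes half dose
  for a two-week titration then full dose to week 24; the low arm half
  dose throughout; the placebo arm crosses over at week 12 to titration
  plus high dose;
* scores observed at days 0, 84, 168 and 252 (baseline before the first
  dose, follow-up 12 weeks after the last), with additive residual error
  on every observation and an optional missing-at-random visit-dropout
  probability (default 0 — the real cohort's ~10 missing visits are not
  reproduced by guessing their pattern).

Band boundaries are half-open at the printed lower bounds (13.6 kg falls
in the 10–13 band of the phase-III table because 13.6 < 14); visit times
are exact nominal days, with no visit-window jitter. What the generator
does **not** emulate: real growth-chart (LMS) fidelity, informative
dropout, adherence, visit-window noise, or any misspecification of the
structural model. Passing simulate-then-recover tests therefore
demonstrates estimator correctness under the assumed model, not robustness
of the original clinical conclusions.

## Diagnostics

`gof_table()` returns population predictions (zero etas), individual
predictions (empirical-Bayes modes) and IWRES $=(y - \mathrm{ipred})/
\hat\sigma$ per observation; with $\sigma = 0$ IWRES is flagged undefined.
Note that at the trial design's four observations against four etas,
empirical-Bayes shrinkage keeps the IWRES spread below 1 even for a
perfectly specified model; the package's calibration test therefore uses a
rich-schedule, near-zero-IIV simulation where shrinkage is negligible and
IWRES is standard normal.

`pc_vpc()` is a prediction-corrected visual predictive check: the dataset
is re-simulated `n_sim` times under its own design and demographics, and
observed and simulated scores are prediction-corrected **additively**
($y - \mathrm{pred}_{ij} + \mathrm{median\ bin\ pred}$) — the additive
form matches the model's additive error on a score scale, where the usual
multiplicative correction has no rationale. Bins are the nominal visit
days (observations are scheduled, so adaptive binning would add nothing).
Percentiles 5/50/95 with simulation envelopes are returned as a table;
`autoplot()` draws them, so tests assert on numbers, not pixels.

## Dose-scenario simulation

`run_dose_scenarios()` reproduces the structure of the weight-tiered
dose-selection exercise: per band, a virtual cohort (drawn conditionally
on the band from the population generator) is dosed at the band's BID dose
for 12 weeks alongside a matched placebo cohort; the week-12 score change
(with residual error on both visits, hence variance $2\sigma^2$ from the
noise alone) is summarised by 5/50/95 percentiles and the target
attainment — the percentage of subjects improving by strictly more than 2
points, the minimal clinically significant difference. An optional
uncertainty layer redraws the fixed effects per band from a normal
distribution on the transformed scale using reported relative standard
errors, an approximation of propagating estimation uncertainty.
`compare_fixed_vs_mgkg()` doses the same subjects (identical etas and
residuals) under the band's fixed dose and an exact mg/kg regimen and
summarises the paired differences. `forest_ratios()` bins a population by
weight and age and reports median individual $CL/F$ and $E_0$ ratios
against a reference bin — configurable, defaulting to the heaviest/oldest
bin, since a two-bin allometric comparison depends on which bin anchors
the ratio and the original choice is ambiguous.

Exact reproduction of the published treated-arm simulation table is out of
scope by design: it requires the unpublished adult PK values and an
uncertainty-propagation recipe that is not fully specified. The engine
reproduces the table's structure, its placebo logic, and the
direction/monotonicity properties (treated attainment above placebo,
median change non-decreasing in dose, dose-linearity of the
drug-attributable effect), which is what the tests assert.

## Numerical choices and limitations

* Time unit days, concentrations µg/L, amounts mg; BID means events every
  0.5 day. $D_1$ must be shorter than the dosing interval.
* The analytic $C_e$ kernel guards the removable singularity at
  $k_{e0} = \lambda_j$ with a series limit; in practice the disposition
  rates are two orders of magnitude above $k_{e0}$.
* Ties at band edges: half-open `[lower, upper)` intervals, top band
  unbounded; weights below the lowest band raise an explicit error.
* Attainment uses strict `> 2`; a change of exactly 2 does not count.
* Convergence is reported, not enforced: non-convergent fits return a
  flagged result rather than an exception.
* The estimator's standard-error convention (numerical Fisher information
  on the Laplace objective) is the package's own; reported RSEs elsewhere
  may come from other procedures.
* Problem sizes in the test suite — 145-subject recovery runs over three
  seeds, a 2,500-subject placebo cohort for the progression check,
  200,000 eta draws for the correlation check, bands of 60–200 virtual
  subjects — were chosen as the smallest sizes at which the quantities
  under test are statistically stable.

## Reproducibility

Every stochastic entry point takes an explicit integer seed and restores
the caller's RNG state (`withr::with_seed`). Identical seeds give
bit-identical datasets, fits, bootstrap draws and VPC tables; the
command-line wrapper refuses stochastic subcommands without `--seed`, and
written artifacts carry the package version, the seed and a config hash in
their metadata.
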