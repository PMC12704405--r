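---
title: "Adjusting meta-analyses for outcome reporting bias with selection models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjusting meta-analyses for outcome reporting bias with selection models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orbsel)
```

## The problem

Outcome reporting bias (ORB) arises when a published trial reports some of
its pre-specified outcomes but not others, and the decision to report depends
on the results — typically, non-significant outcomes are dropped. Unlike
publication bias, the affected studies *are* in the literature: we know they
randomised `n_treat` and `n_ctrl` patients, we simply do not see the effect
estimate for the outcome of interest. A standard meta-analysis that pools
only the reported outcomes implicitly assumes the missingness is unrelated to
the results (MCAR) and overestimates benefit when reporting is in fact driven
by significance (MNAR).

`orbsel` treats ORB as a missing-data problem with an explicitly modelled
selection mechanism, and uses the known sample sizes of the unreported
outcomes to give them a likelihood contribution.

## Model

For studies $i = 1, \dots, K$ with observed effects $y_i$ (here log risk
ratios) and standard errors $\sigma_i$, the random-effects model is

$$ y_i \sim \mathcal{N}(\theta_i, \sigma_i^2), \qquad
   \theta_i \sim \mathcal{N}(\mu, \tau^2), $$

so marginally $y_i \sim \mathcal{N}(\mu, \sigma_i^2 + \tau^2)$. A
*selection function* $w(p) \in [0, 1]$ gives the probability that an outcome
with one-sided p-value $p = \Phi(-y/\sigma)$ is reported. Writing
$f(y) = \mathcal{N}(y; \mu, \sigma^2 + \tau^2)$, the adjusted log-likelihood
is

$$ \ell(\mu, \tau^2) = \sum_{i \in \mathrm{Rep}} \log f(y_i)
 + \sum_{i \in \mathrm{Unrep}} \log \int f(y)\,\{1 - w(p(y))\}\, dy . $$

Each unreported outcome contributes the log-probability that a study of its
size would have gone unreported. By default no selection process is assumed
for the reported outcomes (their weight is 1); the fully weighted variant,
which additionally subtracts $\log \int f(y) w(p(y))\,dy$ for every reported
study, is available via `reported_selection = TRUE` in `orb_fit()` and
`orb_loglik()`. We expose it for completeness but make no performance claims
for it; the default form is the one studied by the simulation engine.

The unreported studies' standard errors are unknown and are imputed from the
reported studies' average *design factor* $\hat k = \sum_{\mathrm{Rep}}
\sigma_i^{-2} / \sum_{\mathrm{Rep}} n_i$ (with $n_i$ the total sample size
over both arms), giving $\hat\sigma_i^2 = 1 / (\hat k\, n_i)$. This assumes
the unreported trials have a similar design (arm balance, event rates) to the
reported ones.

## Selection functions

All families are non-increasing functions of the p-value with values in
$[0,1]$, parameterised by the one-sided significance threshold
$\alpha$ (default 0.05):

| family | `wA`/… alias | form |
|---|---|---|
| `piecewise_constant` | `wA` | $1$ if $p \le \alpha$, else $0$ |
| `constant_decreasing` | `wB` | $1$ if $p \le \alpha$, else $(p-\beta)/(\alpha-\beta)$ |
| `decreasing_constant` | `wC` | $1 - p^\gamma/\alpha^\gamma$ if $p \le \alpha$, else $0$ |
| `piecewise_decreasing` | `wD` | $1-(1-\omega_\alpha)p^\gamma/\alpha^\gamma$ if $p \le \alpha$, else $\omega_\alpha(p-\beta)/(\alpha-\beta)$ |
| `dgm_exponential` | `wDGM` | $e^{-4 p^\gamma}$ |

`wA` is the classical threshold function (also implicit in Copas-style ORB
adjustment); `wB` lets non-significant outcomes still be reported with
decreasing probability; `wC` assumes only (strongly) significant outcomes
are reported; `wD` interpolates, with $\omega_\alpha$ the reporting
probability exactly at the threshold (0.5 by default, midway between `wB`'s
implicit 1 and `wC`'s 0). `wDGM` is the exponential law used by the
simulation engine to *generate* selective reporting, so fitting with it is
the correctly specified adjustment.

Two parameter-range decisions are ours:

* **$\beta > 1$ is enforced at construction.** For $\alpha < \beta \le 1$
  the branch $(p-\beta)/(\alpha-\beta)$ leaves $[0,1]$ before $p$ reaches 1,
  so the "weight" would stop being a probability. All values used in the
  literature we follow (1.5, 3, 7) satisfy this. `run_sensitivity()` maps
  requested $\beta \le 1$ (and $\gamma \le 0$) to the closest admissible
  value and flags the row rather than failing the whole grid.
* **The boundary $p = \alpha$ belongs to the significant branch** in every
  family.

### The p-value scale

The one-sided scale is the default: for a beneficial outcome it is the
plausible driver of reporting (a significant effect in the *harmful*
direction is unlikely to be selectively reported as a success). The
two-sided option exists to reproduce the Copas-style closed form; since
$2\{1 - \Phi(y/\sigma)\}$ exceeds 1 for $y < 0$, we evaluate the two-sided
p-value as $2\{1-\Phi(|y|/\sigma)\}$, which is the version consistent with
the two-tailed significance region
$\Phi((z_{\alpha}\sigma-\mu)/s) - \Phi((-z_{\alpha}\sigma-\mu)/s)$
appearing in that closed form.

## Numerics

**Quadrature.** The unreported-study integral is evaluated on the
standardised scale $z = (y-\mu)/\sqrt{\sigma^2+\tau^2}$ over $[-10, 10]$
(the omitted tails carry mass $< 10^{-22}$), split at the images of the
selection function's breakpoints so the integrand is smooth on each piece,
with `stats::integrate` at absolute tolerance $10^{-10}$ per piece. For the
threshold family `wA` the integral reduces to normal CDFs and the closed
form is used. An underflowing integral (all mass in the reported region)
yields `-Inf`; inside optimisation this is replaced by $-10^{10}$ and
counted in the fit diagnostics, keeping the optimiser stable.

**Optimisation.** `orb_fit()` maximises over
$(\mu, \log(\tau^2 + 10^{-10}))$ with Nelder–Mead (objective tolerance
$10^{-8}$, at most 500 iterations, one restart), starting from the
inverse-variance-weighted mean and the DerSimonian–Laird moment estimate of
$\tau^2$ floored at $10^{-4}$. Because ML heterogeneity estimates often sit
at zero, the $\tau^2 = 0$ boundary is additionally profiled explicitly and
the better of the two candidates is reported.

**Profile CIs.** Endpoints solve
$2\{\ell(\hat\theta) - \ell_p(\theta)\} = \chi^2_{1,0.95} = 3.841459$ by
Brent root search, profiling the other parameter by inner 1-d optimisation;
search brackets are $\hat\mu \pm 10\,\mathrm{SE}$ and
$[0,\, 100\hat\tau^2 + 10]$, widened once if the root is not bracketed and
reported as `NA` otherwise. The lower $\tau^2$ endpoint is clamped at 0 when
the profile never drops below the cutoff there.

## The simulation engine

`simulate_complete()` reproduces the study conditions of the simulation
design the package implements: $K \in \{5, 15, 30\}$ two-arm studies with
$n = 50$ per arm; $\theta_i \sim \mathcal{N}(\mu, \tau^2)$ with
$\mu \in \{0, 0.2, 0.4, 0.6, 0.8\}$; $y_i \sim \mathcal{N}(\theta_i, 2/n)$;
and reported squared standard errors drawn from a scaled chi-square law,
$\sigma_i^2 \sim \frac{2}{(n-1)n}\chi^2_{n-2}$, whose mean
$2(n-2)/\{(n-1)n\}$ is essentially the true sampling variance $2/n$. (The
scaling convention is our reading of an ambiguously typeset law; the mean
constraint pins it down.) Heterogeneity is specified as
$I^2 \in \{0, 0.25, 0.5, 0.75, 0.9\}$ and converted by
$\tau^2 = I^2 \sigma^2 / (1 - I^2)$ with $\sigma^2 = 2/n$ — the standard
conversion against a typical within-study variance; the exact convention
used elsewhere is not printed, so this choice is documented rather than
quoted.

`apply_orb()` keeps each outcome with probability $e^{-4 p_i^\gamma}$
($\gamma = 1.5$, or $0.5$ for a steeper law). A replicate ending with fewer
than two reported outcomes is re-simulated from scratch (new complete data,
new removal). The MCAR benchmark pairs each MNAR replicate: the same
complete draws, with the realised number of removed outcomes removed
uniformly at random instead (`apply_mcar()`).

Per-replicate seeds are derived deterministically from the scenario seed by
a fixed linear rule, so scenarios are reproducible and could be parallelised
without changing results.

**Power** is defined as rejection of $H_0{:}\ \mu = 0$ by the 95%
profile-likelihood CI excluding 0 — the design does not pin down a power
test, so this definition (consistent with the reported CIs) is ours and is
stated here prominently. Estimator failures (errors or non-convergence) are
dropped from that estimator's summaries only, with counts reported in
`n_failed`.

Performance measures (bias, empirical SE, MSE, coverage, power) and their
Monte-Carlo standard errors follow the Morris–White–Crowther definitions;
the truth for $\tau^2$ summaries is the scenario's `tau2_from_I2()` value.

### What the generator does and does not emulate

It emulates significance-driven outcome suppression in homogeneous two-arm
trials with equal arms and a common size. It does not emulate unequal or
correlated study sizes, binary-outcome exactness (effects are exactly
normal), multiple correlated outcomes per study, or reporting driven by
anything other than the one-sided p-value. Passing tests therefore show the
estimator recovers the truth *under the assumed mechanism*; they cannot
show robustness to mechanisms outside this family.

### Problem sizes in the shipped tests

The test suite runs scaled-down Monte-Carlo checks (300–1000 replicates per
scenario, chosen as the smallest sizes whose 3-MCSE bands make the
directional claims decisive); the full-scale design uses
$N_{\mathrm{sim}} = 3200$, which `scenario_grid()` sets as its default.

## The epilepsy example

The packaged example is the meta-analysis of twelve randomised trials of
Topiramate as add-on treatment for drug-resistant focal epilepsy, with the
two beneficial outcomes: 50% seizure-frequency reduction (one study,
Coles 1999, does not report it) and seizure freedom (six of twelve studies
do not report it). Effects are log risk ratios from the 2x2 tables.

**Continuity correction.** When any of the four cells is zero, 0.5 is added
to all four cells of that table (so each arm size grows by 1); tables
without zeros are left alone. Double-zero studies (Tassinari 1996,
Zhang 2011 for seizure freedom) are *retained*, entering as $y = 0$ with a
large standard error, so all six reported seizure-freedom studies inform
the fit; `epilepsy_dataset(cc =)` makes the correction configurable. The
convention used in the original analysis is not printed, so plotted values
elsewhere may differ slightly; the directional findings are insensitive to
this in every variant we test.

On these data the naive analyses find significant benefit for both
outcomes. Adjustment shifts the estimates toward the null — slightly for
the 50%-reduction outcome (one unreported study), substantially for seizure
freedom, where the wA-adjusted 95% CI includes the null. Stricter
mechanisms adjust harder: $\hat\mu_{wB(\beta=3)} \le \hat\mu_{wA} \le
\hat\mu_{wC(\gamma=3)}$. The hybrid wD fits land near this range by
construction, though with $\beta = 7, \gamma = 1.5$ the estimate can sit
marginally (about 0.01 on the log-RR scale, far inside the CI width) above
wC's: with $\omega_\alpha = 0.5$ and a nearly flat non-significant branch,
wD's non-reporting probability is roughly half of wC's everywhere, which
weakens the adjustment slightly rather than interpolating it pointwise.

```{r sensitivity, eval = FALSE}
d <- epilepsy_dataset("seizure_freedom")
sens <- run_sensitivity(d, families = c("wB", "wC", "wD"),
                        beta_values = c(1.5, 2, 2.5, 3),
                        gamma_values = c(0.5, 1, 2, 3))
autoplot(sens)
```

## Known limitations

* The normal likelihood is an approximation for sparse binary data; an
  exact binomial contribution is out of scope here.
* Heterogeneity is estimated by ML (joint with the adjustment), which
  underestimates $\tau^2$; REML is not offered because the adjustment is
  defined through the ordinary likelihood.
* Even the correctly specified adjustment retains a small negative residual
  bias (about a tenth of the naive bias it removes, at the simulated scale;
  compare `mnar_wdgm_mu_bias` with `mnar_naive_mu_bias` in the acceptance
  output). Two gaps between the generating mechanism and the fitted model
  drive it: each study's reporting probability is computed from its own
  drawn standard error, which is unobservable for an unreported study and
  must stand in as one number in both the density and the p-value transform;
  and that number is itself imputed from the systematically more precise
  reported studies. "Bias eliminated" should therefore be read at the scale
  of the naive bias, not as exactly zero.
* Only beneficial outcomes (selection favouring small one-sided p-values)
  are supported; harmful-outcome selection would need reversed mechanisms.
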