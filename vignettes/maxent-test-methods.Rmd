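---
title: "Testing for higher-order correlations in spike-count pairs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing for higher-order correlations in spike-count pairs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maxenttest)
```

## The problem

Trial-to-trial covariation of the spike counts of simultaneously recorded
neurons ("noise correlations") is usually summarized by the Pearson
correlation coefficient. Anything beyond that — dependence not determined by
the two marginal count distributions plus the linear correlation — is a
higher-order correlation, and such structure can exist between just two
neurons. Estimating it directly needs far more trials than a typical
electrophysiology design provides (tens of repetitions per condition). This
package implements a hypothesis test that asks a more modest, answerable
question: *are the marginals and the linear correlation alone sufficient to
explain the data, as judged by a divergence measure the analyst actually
cares about?* If the test rejects, higher-order correlations materially
affect that measure and more data (or a richer model) is needed before
information-theoretic conclusions can be trusted.

## The null family: maximum entropy with second-order constraints

For a pair of spike counts $(X, Y)$ the null family consists of the
distributions $P^*$ that maximize the Shannon entropy
$H(P) = -\sum_{x,y} P(x,y)\log_2 P(x,y)$ subject to

* fixed marginal distributions $P_X$, $P_Y$ (here Poisson with rates
  $\lambda_x, \lambda_y$, the expected counts per bin), and
* a fixed Pearson correlation $\rho$, i.e. a fixed product moment $E[XY]$.

This distribution is unique and has the exponential family form
$P^*(i,j) \propto r_i \, c_j \, e^{\theta i j}$, with one factor per row,
one per column, and a single interaction exponent $\theta$. `fit_maxent()`
solves it by alternating iterative proportional fitting (matching the row
and column factors to the marginals for a trial $\theta$) with a
one-dimensional root solve on $\theta$ so that $E[XY]$ matches the value
implied by $\rho$; $E[XY]$ is strictly increasing in $\theta$, so the root
is unique. Convergence is declared when every constraint residual is below
`constraint_tol` ($10^{-9}$ by default) with a cap of $10^4$ inner
iterations. The test suite checks the solution entry-wise (to $10^{-6}$)
against an independently computed constrained-optimization solution of the
same program on small grids.

**Support truncation.** Poisson marginals have unbounded support; all table
computations use the grid $\{0..K_x\}\times\{0..K_y\}$ where each $K$ is the
smallest count whose cumulative marginal mass reaches
$1-\varepsilon$ with $\varepsilon = 10^{-10}$ (configurable). Mass below
$10^{-10}$ cannot influence p-values at realistic sample sizes; the
truncated marginal is renormalized so that the constraints are exact on the
finite grid, and enlarging the grid further moves fitted entries by less
than $10\varepsilon$ (tested).

**Feasible correlations.** Not every $\rho$ is attainable for fixed discrete
marginals; the extremes are the Frechet–Hoeffding bounds, computed by
quantile coupling (`feasible_correlation_range()`, verified against a linear
program). A separate, purely numerical limit also exists: as $\rho$
approaches the bound, $\theta$ diverges and the row/column factors leave
double precision (around $\rho \approx 0.97$ for rate-3 marginals). Requests
beyond the representable range raise an error; inside the nuisance search
(`clip_rho = TRUE`) they return the best-effort boundary member with the
achieved correlation recorded, which keeps the optimizer's domain connected
— any member of the null family is a legitimate evaluation point, so this
cannot invalidate the test.

## The Monte Carlo goodness-of-fit test

Given data $x^{(n)}$ of $n$ count pairs and a candidate parameter triple
$(\lambda_x, \lambda_y, \rho)$, the test

1. fits the maximum entropy reference $P^*$,
2. computes the observed divergence $D_0$ between the empirical
   distribution of the data and $P^*$,
3. draws $N$ Monte Carlo datasets of the same size $n$ from $P^*$ and
   computes their divergences $D_1,\dots,D_N$, and
4. ranks $D_0$ among them:
   $p = \big(\#\{k : (D_k, U_k) \ge (D_0, U_0)\} + 1\big)/(N+1)$,
   where the $U_k$ are i.i.d. Uniform(0,1) tie-breaking marks compared
   lexicographically.

Count statistics are discrete, so ties occur with positive probability; the
uniform marks randomize their order, which keeps the p-value exactly valid
at finite $N$ — every returned p is a multiple of $1/(N+1)$, and under the
null $\Pr(p < \alpha) \le \alpha$.

**Nuisance parameters.** The rates and the correlation are unknown. Instead
of plugging in estimates, the p-value is maximized over them by simulated
annealing from the sample means and sample correlation: Gaussian proposals
scaled by each estimate's standard error ($\sqrt{\hat\lambda/n}$ per rate,
$(1-\hat\rho^2)/\sqrt n$ for the correlation), geometric cooling
$T_{t+1} = 0.95\,T_t$ from $T_0 = 0.1$ in p-value units, 200 proposal steps
by default, and the search confined to the box estimate $\pm\,2.5$ standard
errors. The box matters for more than efficiency. The maximization domain
must be the *statistically plausible* nuisance set, not the whole parameter
space: with three free parameters and a one-dimensional divergence, an
unbounded optimizer can always solve $H(P^*(\lambda_x,\lambda_y,\rho)) =
H(\hat P)$ exactly, driving the observed divergence to zero and the
p-value to one for any data whatsoever — a test with no power. Maximizing
over a confidence set instead is the classical remedy for nuisance
parameters in exact randomized tests. The width is a genuine design
trade-off: a wider box leaves more room for the reference entropy to chase
the empirical entropy (less power), a narrower one risks excluding the true
parameters (level). At $\pm 2.5$ SE — a roughly 99% per-parameter
confidence box — a pilot calibration showed the achieved rejection rate
under the null sitting far *below* the nominal level across sample sizes
(the worst case over the box is intrinsically conservative, which more than
absorbs the box's ~1% per-parameter non-coverage) while power against the
copula mixtures is retained; the level and super-uniformity checks in the
test suite verify this at scale. Reporting the maximum p encountered then
makes the test conservative for every plausible member of the null family. The p-value surface is a step function on the
$1/(N+1)$ lattice, so past a point extra annealing steps buy little; the
budget trades statistical power (a larger maximum lowers rejections) for
runtime and is fully configurable. Evaluations within one search reuse
common Monte Carlo random numbers by default: a single p-value evaluation
is itself noisy (sd $\approx \sqrt{p(1-p)/N}$), and a maximum taken over
many fresh-noise evaluations selects upward noise excursions rather than
genuinely better parameters — measurably inflating borderline p-values and
silently costing power. With common random numbers the annealed maximum
reflects the parameter search alone; fresh draws per evaluation remain
available (`anneal_config(common_rng = FALSE)`). The simulation studies and
the acceptance script in this package run
at a reduced scale — $N = 199$ Monte Carlo samples and 60 annealing steps —
which preserves the level guarantee exactly (it holds for any $N$ and any
optimizer budget) and was chosen as the package's study scale; the
publication-scale $N = 1000$ and 200 steps are the defaults of
`run_test()`.

**Decision rule.** The null is rejected when the worst-case p-value is
*strictly* below $\alpha$ (default 0.05). With $N = 999$, $\alpha = 0.05$
this puts $p = 50/1000$ exactly at the boundary of non-rejection, matching
the conservative reading of the finite-sample correction.

**Initialization edge cases.** If a marginal sample variance is zero the
sample correlation is undefined and $\rho$ initializes at 0; rates
initialize at the sample means floored at $10^{-3}$ so the Poisson family
stays well-defined for all-zero samples.

## Divergence measures

Two statistics ship with the package; both are expressed in bits (base-2
logarithms, the neural-coding convention) and both accept a pluggable
replacement via `divergence_measure(function(...) ...)`.

* **Entropy difference** $|H(\hat P) - H(P^*)|$. The absolute value makes
  the statistic a nonnegative divergence that is symmetric in the sign of
  the discrepancy. Because it is a difference of two plug-in entropies,
  additive small-sample biases shared by both terms cancel under the null;
  no explicit bias correction (Miller–Madow or similar) is applied.
* **Mutual information difference**
  $|I(S;\hat P_{\cdot|S}) - I(S;P^*_{\cdot|S})|$ for a labelled sample:
  one reference table and one nuisance triple per stimulus, a flat stimulus
  prior by default, and Monte Carlo datasets that copy the data's
  per-stimulus allocation exactly. Under the null the true mutual
  information is inside the searched family, so the worst-case p-value
  remains valid even when $n$ is far too small to estimate mutual
  information itself.

The convention $0 \log 0 = 0$ is used throughout.

## Validation generators: copula mixtures with calibrated correlation

Power studies need distributions with *controlled* higher-order structure:
the marginals and the linear correlation must stay fixed while higher-order
dependence is dialed up. The package builds them as a two-component convex
mixture (weight $m$ on the copula part):

* a maximum entropy component at the target correlation (0 for family M1,
  0.2 for M2), and
* a copula component: a mixture of two Gaussian copulas with opposite-sign
  parameters, applied to the same Poisson marginals through the discrete
  rectangle construction
  $P(i,j) = C(F_1(i),F_2(j)) - C(F_1(i{-}1),F_2(j)) - C(F_1(i),F_2(j{-}1))
  + C(F_1(i{-}1),F_2(j{-}1))$.

The first copula parameter is fixed at $\rho_1 = 0.9$ and the second is
calibrated by a root solve so that the copula component's table correlation
hits the same target (to $10^{-4}$). $\rho_1 = 0.9$ is a deliberate,
configurable choice — published power curves depend on how strong the
injected higher-order dependence is, and this value produces the
characteristic cross-shaped mass pattern (mass concentrated on both
diagonals) while leaving the linear correlation at the target; the inner
mixing weight between the two Gaussian copulas defaults to 0.5. By
construction the mixture's marginals and correlation are independent of
$m$: $m = 0$ *is* the maximum entropy distribution, and the entropy deficit
relative to it grows monotonically with $m$ (tested). The default rate of 3
expected counts per bin corresponds to 30 Hz in 100 ms bins. The bivariate
normal CDF is evaluated with `mvtnorm::pmvnorm` at absolute tolerance
$10^{-10}$.

**What the generators do not emulate.** Real spike counts are
non-stationary within a trial, autocorrelated across bins, and not exactly
Poisson. The copula mixtures are i.i.d. across trials with exact Poisson
marginals, so passing power/level checks on them demonstrates correctness
of the *test machinery*, not robustness to real-data violations — that is
what the gamma-process study below probes, and even it covers only marginal
autocorrelation, not cross-correlated non-Poisson structure.

## Baselines and auxiliary tests

**Likelihood ratio test** (`lr_test()`): full model = saturated multinomial
over the count grid (MLE = empirical frequencies), reduced model = maximum
entropy family (MLE over rates and correlation by Nelder–Mead from the
sample estimates); $\Lambda = 2(\ell_{full} - \ell_{ME})$ compared to
chi-square with (cells $-$ 1) $-$ 3 degrees of freedom. The saturated model
is defined on the grid spanned by the observed counts: cells beyond the
data's range carry no likelihood and counting them would inflate the
degrees of freedom by hundreds of never-occupied cells and destroy the
test's power. The chi-square reference is asymptotic and unreliable at
small $n$ — precisely the regime in which the exact Monte Carlo test is
preferable, and the comparison experiments quantify that gap.

**Benjamini–Hochberg** (`bh_procedure()`): the explicit step-up rule, so
the rejection set and threshold index are available; it is cross-checked
against `stats::p.adjust(method = "BH")` in the tests. In multi-pair scans
the correction is applied within each bin size (and condition), never
across bin sizes: whether second-order structure suffices is a separate
hypothesis for every bin size. With the mutual-information divergence the
stimuli are already pooled inside the statistic, so the correction runs
over pairs only.

**Poisson goodness of fit** (`poisson_gof_mc()`): the univariate analogue
of the main test with the rate as the single annealed nuisance parameter.
The statistic is the KL divergence of the empirical histogram from the
Poisson reference rather than an entropy difference: with the rate free, a
rate can always be found whose Poisson entropy equals the empirical
entropy, so an entropy-difference statistic would be blind to even gross
non-Poisson shapes, while KL is location-aware and retains power (e.g.
against bimodal rate mixtures).

**Time-rescaling Kolmogorov–Smirnov test** (`time_rescaling_ks()`):
interspike intervals are rescaled by the integrated (piecewise-constant)
rate; under a Poisson process the rescaled intervals are unit-exponential
and $1-e^{-\tau}$ is uniform, tested by a one-sample KS test. In the
autocorrelation study the rescaled intervals of the two simulated trains
are pooled into a single KS test, which keeps one decision per trial pair
at the nominal level while using all spikes.

## Gamma renewal processes

`simulate_gamma_train()` draws i.i.d. Gamma(shape $\gamma$, mean $1/r$)
interspike intervals, so the mean rate is $r$ for every $\gamma$;
$\gamma = 1$ is a Poisson process and larger $\gamma$ adds a relative
refractory period (interval CV $= 1/\sqrt\gamma$), which induces
autocorrelation in binned counts. The train is an ordinary renewal process
started at $t = 0$ — the equilibrium-start correction is negligible at the
5–10 s durations used and the ordinary start is exactly reproducible. The
two "simultaneous" trains are simulated independently: the study isolates
the effect of marginal autocorrelation on a test whose null assumes Poisson
marginals, not cross-correlation. Counts use left-closed right-open bins
with the trailing partial bin discarded.

## Synthetic experiment fixtures

`generate_fixture()` emulates the design of a multi-electrode adaptation
experiment: 11 neurons (55 pairs), control and adaptation conditions, 8
orientations, 42 repetitions per design cell, bin sizes 10–400 ms, and a
bimodal rate population (high 20–35 Hz, low 2–8 Hz, uniform within each —
the population split is documented in the source experiments only as a
figure, so the ranges are configurable defaults). Per-pair dependence can
be independent, maximum entropy, or an M-family mixture; for mixtures with
unequal rates the same calibration machinery runs with per-margin rates.

## Numerical and design choices not fixed by the problem

* Log base 2 everywhere; entropies and MI in bits.
* "Random correlation strengths" in the null-comparison experiment are read
  as Uniform(0, 0.5) — within the comfortably feasible range for rate-3
  marginals; configurable.
* Per-cell seeds in experiment grids derive from the base seed by a fixed
  linear congruential step (`derive_seed()`), so cells are independent work
  units and any execution order reproduces the same numbers.
* The rejection decision uses $p < \alpha$ (strict), the conservative
  reading when $p$ lies exactly on a lattice point.
* Labels on a sample given to the entropy-difference statistic are ignored
  with a notice; unlabelled samples given to the mutual-information
  statistic are an error.

## Limitations

* Pairs only: higher-order structure visible only in triples or larger
  ensembles is invisible to the test (rejection counts can only
  underestimate).
* Poisson marginals only (the marginal interface is pluggable but no other
  family ships); strongly non-Poisson counts are flagged by the auxiliary
  GOF tests rather than absorbed by the null.
* Power depends on the injected dependence strength of the validation
  generators ($\rho_1$, inner weight), which are conventions, not measured
  quantities.
* The nuisance search is stochastic; the level guarantee never depends on
  it, but reported power at a fixed budget has simulation error of its own.
* At the very smallest sample sizes (n around 20) the confidence box for
  the nuisance parameters is wide enough that the worst-case maximization
  becomes markedly conservative: the achieved level drops far below nominal
  and power against weak higher-order structure shrinks with it. Power
  recovers quickly as n grows (calibration runs roughly triple the
  rejection rate on mixture data between n = 20 and n = 40).
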