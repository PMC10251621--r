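---
title: "Predicting and auditing multi-trait selection response with meritindex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting and auditing multi-trait selection response with meritindex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meritindex)
```

## The model and its assumptions

A breeding goal comprises $n$ traits with true breeding values
$\mathbf{u} \sim (0, \boldsymbol\Gamma)$, where
$\boldsymbol\Gamma = S K S$ is assembled from the genetic correlation
matrix $K$ and the genetic standard deviations $S = \mathrm{diag}(\sigma_g)$.
For $m \le n$ of these traits, estimated breeding values (EBVs) exist and
are treated as observable quasi-phenotypes. The package models them in two
steps: an *unscaled* EBV $\mathbf{q} = D\mathbf{u} + \mathbf{e}$ carries
the correct correlation with the true value ($D$ is the $m \times n$ 0/1
selection matrix; $\mathbf{e} \sim (0, \Sigma)$ independent of
$\mathbf{u}$), and the *scaled* EBV $\mathbf{c} = R\mathbf{q}$ with
$R = \mathrm{diag}(\rho^2_i)$ restores regression to the mean:
$\mathrm{Var}(c_i) = \rho^2_i \gamma_{ii}$, smaller than the genetic
variance. The reliability $\rho^2_i$ is the squared correlation between
true and estimated breeding value, which fixes the classical diagonal
error variance at $\varepsilon_{ii} = (1-\rho^2_i)/\rho^2_i\,\gamma_{ii}$.

Three assumptions matter in practice:

* **Selection acts only on the combined index** $I = \mathbf{b}'\mathbf{c}$.
  Real programs add other selection paths (cow selection, breeder
  preferences), which is precisely why the retrospective tools exist.
* **Errors are independent of true values** and, in the classical variant,
  mutually uncorrelated. The de-regression machinery relaxes the second
  part.
* **Parameters are known.** Correlations and reliabilities are themselves
  estimates; biased inputs bias every prediction downstream.

The optimum index weights solve the normal equations
$R(D\Gamma D' + \Sigma)R\,\mathbf{b} = RD\Gamma\,\mathbf{w}$, solved here
by factorisation (`solve()` on the assembled system), never via an
explicit inverse. Systems with condition number above $10^{12}$ are
refused, and a warning is emitted above $10^8$.

## Expected genetic and phenotypic trend

Selection with intensity $i$ on the index moves all $n$ goal traits by
$$\mathbf{d} = \frac{i}{\sigma_I}\,\Gamma D'\,(D\Gamma D' + \Sigma)^{-1}
D\Gamma\,\mathbf{w},$$
including correlated response in traits outside the index. The reliability
matrix cancels analytically from this expression; the trend solver
therefore works on $D\Gamma D' + \Sigma$ directly, which is both the
numerically stabler route and exactly the simplified form of the theory.
The total merit gain is $\Delta G = \mathbf{d}'\mathbf{w}$.

Compositions — the quantity practitioners compare — are computed on the
genetic-SD scale ($d_i/\sigma_{g,i}$) and normalised so absolute values
sum to 1, keeping signs. Absolute-value normalisation is the only
convention that stays consistent when some components are negative. For
the Holstein fixture every complex has genetic SD 12, so SD-scale and
trait-unit compositions coincide there; `trend_composition()` has a
`subset` argument because published comparisons are normalised within the
displayed trait set.

The phenotypic trend rescales by heritability,
$d_{p_i} = d_i h_i/\sqrt{\gamma_{ii}}$: a low-$h^2$ complex can take a
solid share of the genetic trend yet barely move phenotypically, which is
an argument about management expectations rather than breeding progress.

Selection intensity defaults to $i = 1$ and is exposed as a parameter;
every element of $\mathbf{d}$ and $\Delta G$ is linear in it while all
compositions are invariant, so the published compositions do not depend on
the (unknown) intensity of any particular program.

## De-regressing the EBV error covariance

The assumption of uncorrelated estimation errors is convenient but not
harmless. Given an empirical covariance $H$ of scaled EBVs from a large
unselected cohort, $E(H) = R(D\Gamma D' + \Sigma)R$, so
$$\hat\Sigma = R^{-1} H R^{-1} - D\Gamma D'$$
exposes the full error covariance. When $H$ is generated from a known
error covariance the recovery is exact (tested to $10^{-10}$ on random
instances).

Two numerical choices here:

* Published EBV tables give correlations, not covariances.
  `ebv_covariance_from_correlations()` reconstructs $H$ using the
  theory-implied variances $H_{ii} = \rho^2_i\gamma_{ii}$ by default;
  empirical variances can be supplied.
* Rounded two-decimal inputs can make $\hat\Sigma$ marginally indefinite;
  this is accepted with a warning because only $D\Gamma D' + \hat\Sigma$
  enters the downstream equations. For the same reason the sign summary in
  `residual_correlations()` treats correlations below `zero_tol = 0.005`
  in magnitude — half the resolution of a two-decimal table — as zero: a
  computed value of $-0.0006$ is not distinguishable from zero given the
  input precision. Setting `zero_tol = 0` gives the strict count.

For the old Holstein index, de-regression reveals distinctly nonzero error
correlations (0.47 between longevity and somatic cell score, 0.36 between
longevity and fertility) with 7 of 15 pairs negative — structure the
diagonal model cannot represent, and which shifts the index weights
whenever the off-diagonals are nonzero.

## Sensitivity to the economic weights

A plain derivative $\partial \mathbf{d}/\partial \mathbf{w}$ ignores that
weights sum to 1. The package instead perturbs one weight by
$\theta$ and reduces the others proportionally
($w^i_j = (1 - \theta/(1-w_i))\,w_j$), re-solves the index, and reports
the normalised trend change $(\mathbf{d}^i - \mathbf{d})$ per perturbed
trait. $\theta$ defaults to $0.001$; rows computed at $10^{-3}$ and
$10^{-4}$ differ by less than 0.01 per entry on the Holstein fixture, so
the approximation is effectively converged at the default. Rows are
normalised over the index traits (the set shown in published tables);
`raw_delta` retains all goal traits. Because the unperturbed index is
optimal, $\Delta G^i \le \Delta G$ always — a property tested, not assumed.

## Realized weights (index in retrospect)

Inverting the trend map gives the weights that *would have* produced an
observed trend composition $\boldsymbol\delta$
($\sum|\delta| = 1$, genetic-SD scale):
$\boldsymbol\beta = (\Gamma D'R)^{-1}\boldsymbol\delta$ and
$\boldsymbol\omega = (D\Gamma)^{-1}(D\Gamma D' + \hat\Sigma)
(\Gamma D')^{-1}\boldsymbol\delta$, rescaled to $\sum|\omega| = 1$. A
unique solution requires $D$ square and full rank — every goal trait must
be an index trait — and the package refuses anything else rather than
returning a pseudo-inverse answer whose meaning would be unclear. Signs
are preserved: a negative realized weight means selection pressure
effectively ran against the trait.

$\boldsymbol\delta$ is accepted on the genetic-SD scale, as trend
compositions are defined, and converted to trait units internally before
inversion. With equal genetic SDs the conversion is a no-op; with unequal
SDs it is what makes the forward-then-invert round trip recover the
generating weights exactly (tested to $10^{-8}$ on random full-rank
systems). Observed trends themselves can be fitted with
`observed_trend_from_yearly_means()`, the OLS slope of yearly mean EBVs on
birth year.

## The simulator as an independent oracle

`simulate_population()` draws i.i.d. individuals from exactly the model
above — $\mathbf{u} \sim N(0,\Gamma)$, $\mathbf{e} \sim N(0,\Sigma)$,
$\mathbf{c} = R(D\mathbf{u} + \mathbf{e})$ — and
`empirical_selection_response()` applies truncation selection on
$I = \mathbf{b}'\mathbf{c}$, returning the mean true breeding values of
the selected fraction and the realized intensity. Feeding the realized
intensity into the analytical trend makes the Monte-Carlo response and
$\mathbf{d}$ directly comparable; the test suite checks agreement within
three standard errors at $10^6$ individuals for the Holstein index and at
$3 \times 10^5$ for random scenarios, sizes at which sampling error is
small but a run still takes seconds.

What the simulator deliberately omits: pedigree structure, genomic
architecture, overlapping generations, selection on multiple paths,
natural selection. Individuals are i.i.d. draws from the stated
multivariate normal model — the same idealisation the analytical theory
makes. Passing simulation tests therefore validate the *algebra*, not the
realism of the model for any particular population; discrepancies between
predicted and observed trends in real programs (breeder behaviour, cow
selection paths, parameter estimation error) are exactly what the
retrospective tools are for.

`random_scenario()` generates valid inputs by construction: correlation
matrices as normalised Gram matrices of random factor loadings (positive
semidefinite without a generate-and-test loop, ridge $10^{-6}$ against
exact singularity), reliabilities uniform on a configurable range
(default 0.3–0.9, spanning typical genomic reliabilities), weights drawn
on the simplex. All randomness flows through one explicit seed, and the
caller's RNG state is saved and restored.

## Numerical choices and degenerate inputs

* **PSD tolerance.** $\Gamma$ is accepted when its smallest eigenvalue is
  $\ge -10^{-8}$ times the largest; rounded published correlation tables
  sit near the boundary. Below that, a hard error — with an opt-in repair
  by eigenvalue clipping (`repair = TRUE`), off by default because silent
  repair hides data problems.
* **Reliability 0 is rejected** (the error variance
  $(1-\rho^2)/\rho^2\,\gamma$ is undefined); reliability 1 is allowed and
  gives zero error.
* **Zero heritability is rejected** in the phenotypic conversion
  ($\sigma_p^2 = \gamma/h^2$ undefined).
* **Trait order is authoritative**: the `trait_names` order fixes every
  matrix; labelled inputs are checked against it and mismatches are
  errors, not silent reorderings. Symmetric CSV matrices may be given as
  an upper triangle and are mirrored on read.
* **Accuracy clipping**: $\rho_{TI}$ is clipped to 1 only against float
  fuzz ($\le 10^{-10}$); a larger excursion above 1 indicates inconsistent
  inputs and raises an error.

## Problem sizes in the shipped tests

The test suite exercises random instances of 2–8 traits (hundreds of
draws for the exact-recovery and round-trip properties), Monte-Carlo
populations of $2\times10^5$–$10^6$ individuals for the distributional
and selection-response checks, and the two packaged Holstein scenarios for
every published quantity. The complete suite runs in well under a minute
on a single core.
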