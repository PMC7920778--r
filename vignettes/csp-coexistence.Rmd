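---
title: "Reproductive interference, conspecific sperm precedence, and local coexistence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reproductive interference, conspecific sperm precedence, and local coexistence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cspdyn)
```

## The question

When two closely related species share mating signals, individuals waste
courtship, matings and sometimes gametes on heterospecifics. This
*reproductive interference* generates positive frequency dependence: the rarer
a species becomes, the more of its females' mating opportunities are consumed
by the wrong species, which pushes it rarer still. *Conspecific sperm
precedence* (CSP) — doubly mated females fertilising with conspecific sperm
regardless of mating order — looks like it should neutralise this cost: as
long as a female mates with at least one conspecific male before reproducing,
heterospecific matings do her no harm. `cspdyn` implements the modelling and
analysis machinery needed to test whether CSP actually rescues local
coexistence.

## The mating decision-making tree

A focal female meets suitors one at a time. Each suitor is conspecific with
probability equal to the focal species' (activity-weighted) frequency,
$f_X = a_X N_X / (a_X N_X + a_Y N_Y)$. A virgin female accepts a conspecific
with probability $p_{X|X}$ and a heterospecific with $p_{X|Y}$; a once-mated
female uses the corresponding $q$ probabilities. Two behavioural assumptions
shape the tree:

1. **The first mating always happens.** A virgin that rejects a suitor simply
   meets another; rejection never ends her search. The probability that her
   *first* mate is conspecific is therefore
   $A_X = f_X p_{X|X} / (f_X p_{X|X} + f_Y p_{X|Y})$.
2. **Later matings are take-it-or-leave-it.** Many females mate only a limited
   number of times, and a refusal of remating typically ends the mating phase
   for that opportunity. With at most $m$ matings, the female has $m - 1$
   further opportunities, each a single suitor accepted with the relevant $q$;
   a rejection wastes that opportunity.

Under complete CSP a female realises her full fecundity if and only if at
least one accepted mate was conspecific. For the two-shot model ($m = 2$) this
gives the closed form implemented in `conspecific_mating_probability()`:

$$P_X = \frac{\left(p_{X|X} + p_{X|Y}\, q_{X|X}\, f_Y\right) f_X}
             {f_X\, p_{X|X} + f_Y\, p_{X|Y}}.$$

Note which parameters are absent: the heterospecific remating probabilities
$q_{X|Y}, q_{Y|X}$ never enter $P$, because under complete CSP a
heterospecific remating is fecundity-neutral — it neither supplies nor
displaces conspecific sperm. They are retained in the object model because the
individual-based simulator and the multiple-mating state chain need them to
track full mating histories.

The semantics above are also the only ones consistent with both limiting
behaviours we require: they reproduce the two-shot closed form exactly at
$m = 2$, and they give $P(m) \to 1$ as $m \to \infty$ whenever the focal
frequency and the conspecific remating probability are positive (each extra
opportunity is an independent chance $f_X q_{X|X}$ of securing conspecific
sperm). Had rejections been redrawn in the remating phase too, the closed form
would involve $q_{X|Y}$; had a rejection terminated the whole mating phase,
the limit would fall short of 1. For $m > 2$ the probability is computed by
exact dynamic programming over mating-count states $(i, j)$ ($i$ conspecific,
$j$ heterospecific matings, $i + j \le m$); the geometric closed form and the
Monte-Carlo simulator (`simulate_decision_tree()`) serve as independent
cross-checks in the test suite.

```{r tree}
probs <- example_mating_probs()
conspecific_mating_probability(probs, NX = 1, NY = 1, focal = "X") # 0.4667
conspecific_mating_probability(probs, 1, 1, "X", max_matings = 50) # ~1
```

## Fecundity and community dynamics

With probability $1 - c$ a female reproduces untouched by interference (think
of $c$ as niche overlap: how often the two species are in the same place at
the same time during mating); with probability $c$ she is subject to the
decision tree. Expected per-capita fecundity is therefore
$E_X = [(1 - c) + c P_X]\, r$, bounded between $(1 - c) r$ and $r$.

Mating happens fast relative to births and deaths (quasi-stationarity), so the
community follows

$$\frac{dN_X}{dt} = \left[E_X(N_X, N_Y) - v\,(N_X + b N_Y)\right] N_X,$$

and symmetrically for $Y$: logistic resource competition (strength $v$ within,
$b v$ between species) with a frequency-dependent birth term. We place $v$
against both competition terms so that the single-species equilibrium is
$r/v$ for every $v$; at the default $v = 1$ this choice is invisible.

Defaults are $r = 25$, $v = 1$, $b = 0.3$; the worked acceptance-probability
set (`example_mating_probs()`) mirrors the asymmetry measured between two
*Harmonia* ladybirds: species Y discriminates as a virgin
($p_{Y|Y} = 0.8 > p_{Y|X} = 0.4$), species X does not
($p_{X|X} = 0.4 < p_{X|Y} = 0.8$).

Key analytical facts the package recomputes numerically:

* **Boundary equilibria** (species exclusion) sit at $(r/v, 0)$ and
  $(0, r/v)$; their Jacobian eigenvalues are $-r$ along the axis and
  $r(1 - c - b)$ transverse to it.
* **Exclusion is locally stable iff $b + c > 1$**: a rare invader meets only
  heterospecifics, so its fecundity collapses to $(1-c) r$ while it suffers
  competition $b r$. `invasion_fitness()` returns $r(1 - c - b)$;
  `exclusion_boundary()` recovers the critical overlap $c^* = 1 - b$ by
  bisection on the numerically computed transverse eigenvalue.
* **Interior equilibria have no closed form**; `find_equilibria()` locates
  them by multi-start damped Newton iteration on the per-capita growth system.

```{r dynamics}
pars <- community_params(probs, c = 0.9)
expected_fecundity(pars, 1, 1)        # (13, 20.5)
stability_report(25, 0, pars)         # eigenvalues -25, -5: stable exclusion
exclusion_boundary(pars, b = 0.3)     # 0.7
```

At low overlap (`c = 0.4`) the model has a stable interior (coexistence)
equilibrium; at high overlap (`c = 0.9`) both axis equilibria are stable and
`basins()` shows the plane partitioned by a separatrix through the interior
saddle — whichever species starts on the wrong side of it is excluded. With
*symmetric* acceptance probabilities and strong assortative mating, exclusion
and coexistence can be stable simultaneously (bistability), which the test
suite verifies for one such parameter set.

## Numerical choices

* **Integration**: `deSolve::lsodar`, relative tolerance $10^{-9}$, absolute
  $10^{-12}$, horizon 1000 time units, with a root-function early exit when
  the vector-field norm drops below $10^{-10}$.
* **Extinction floor**: stored densities below $10^{-9}$ are set to zero (via
  solver events and on output) so that numerically tiny populations cannot
  later regrow; the right-hand side itself is kept smooth for the solver.
* **Origin**: species frequency is 0/0 there; the growth rate is defined as
  $(0,0)$ by convention and the Jacobian is evaluated at an offset of
  $10^{-8}\, r/v$.
* **Jacobians**: central finite differences with steps scaled to the density
  magnitude; for a coordinate exactly at zero the product structure
  $N_k g_k(N)$ makes that row exactly $\mathrm{diag}(g_k)$, which is used
  analytically — this keeps the marginal case $b + c = 1$ (transverse
  eigenvalue exactly 0) detectable at the $10^{-8}$ classification tolerance.
* **Degenerate acceptance**: if no male is acceptable to a virgin
  ($f_X p_{X|X} + f_Y p_{X|Y} = 0$) the mating probability is 0 by
  definition; the functions warn and return 0 rather than dividing by zero.
* **Root finding**: 20 x 20 Newton starts over $[0, 2r/v]^2$, step damping by
  halving, duplicate roots merged within $10^{-4}\, r/v$, every candidate
  verified against the full system residual.
* **Basins**: each lattice point is integrated to the horizon and assigned to
  the nearest stable equilibrium within $10^{-2}\, r/v$; unassignable points
  are labelled `unresolved` and kept (on an axis in a coexistence regime, for
  instance, no stable attractor is reachable — the axes are invariant).

## Signal-detection analysis of mating trials

One-female/one-male trials score, per session, whether the male attempted to
mate and, per attempt, whether the female rejected it. Treating "conspecific
partner" as the correct signal for male attempts (and "heterospecific male"
as the correct signal for female rejection), each behaviour yields a 2x2
contingency table per species and year.

`sdt_statistics()` applies the log-linear correction — add 0.5 to each
response count and 1 to each signal total — to *every* cell, not only
degenerate ones; this is the documented behaviour of the correction and keeps
the normal quantiles finite with zero cells. Then, with $z$ the standard
normal quantile, $d' = z(H) - z(F)$, criterion $= -(z(H)+z(F))/2$, and
$\beta = \exp((z(F)^2 - z(H)^2)/2)$, so $\beta = \exp(d' \times
\mathrm{criterion})$ identically. For a binary decision the ROC has one
interior point and $\mathrm{AUC} = (1 + h - f)/2$ on the uncorrected rates.
`delong_unpaired()` compares two AUCs with the DeLong structural-component
variance, a $t$ reference and Welch–Satterthwaite degrees of freedom (the
convention of the standard ROC software, which prints fractional df); a
standard-normal reference is available behind a flag.

```{r sdt}
counts <- read_counts(response_counts_file())
sdt_table(counts)[1:4, c("species", "year", "dprime", "beta", "auc")]
```

Against the packaged trial counts the male-attempt indices of the more
discriminating species come out at $d' \approx 0.793$, $\beta \approx 1.265$
(2014) and $d' \approx 0.951$ (2015). We attach a tolerance of $\pm 0.02$ to
comparisons with the published values because the exact correction variant
behind them is not stated. Two published quantities are deliberately *not*
treated as reference values: the female-rejection indices (one year has a
zero correct-rejection cell, and no standard correction reproduces the
published numbers from the printed counts, suggesting the analysis dataset
differed from the printed table) and the published AUC/D table (the published
AUCs differ from the binary-decision closed form by ~0.01–0.02, consistent
with covariate-adjusted scores feeding that ROC).

## Synthetic data

`simulate_sessions()` generates mating-trial records with the structure of
the real experiments: per female-x-male-species cell, a session contains at
least one attempt with the cell's attempt probability (plus a Poisson excess
of further attempts, mean 1 by default), each attempt is rejected with the
cell's rejection probability, and copulation follows acceptance (probability
0.9) or, rarely, rejection (coercion, probability 0.1) — both coercive mating
and copulation failure are observed in the real trials. Defaults (200
sessions per cell in tests; attempt probabilities 0.6 conspecific / 0.3
heterospecific; rejection 0.2 / 0.6) are plausible magnitudes for these
trials and exercise every code path; they are a testing harness, not a fitted
model. The generator draws from a single seeded stream per call
(`withr::with_seed`), so records are reproducible and the global RNG state is
never touched.

What the generator does *not* emulate: within-session behavioural sequences
(attempt order, latencies), individual covariates (age, size, colour),
repeated use of the same individuals across sessions, and year-to-year
population differences. Tests passing on synthetic sessions therefore
validate the bookkeeping from records to contingency tables and the
statistical machinery downstream of them — not the behavioural realism of any
particular parameter value.

## Problem sizes used in the checks

The packaged end-to-end checks integrate single trajectories to horizon
1000, scan 50 random parameter draws for the boundary-eigenvalue closed form,
map basins on a 50 x 50 lattice over $[0, 30]^2$, cross-validate the mating
probability against $10^5$ Monte-Carlo replicates for 100 random draws, and
calibrate the DeLong test against a $10^4$-replicate stratified bootstrap on
20 scenarios plus 2000 null simulations at 100 observations per arm.

## Known limitations

* Two species, deterministic densities: no demographic stochasticity,
  spatial structure, dispersal, or more-than-pairwise communities.
* CSP is complete: one conspecific mating secures full conspecific fecundity;
  partial sperm precedence would interpolate between this model and one with
  hybrid costs.
* The mating-phase timescale is fully separated from demography; systems
  where mating and mortality interleave need a different formulation.
* The comparative table records published classifications as data; the
  package summarises but never re-classifies them, and applies no
  phylogenetic correction.
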