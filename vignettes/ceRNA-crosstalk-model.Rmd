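---
title: "Modelling system-level ceRNA crosstalk: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling system-level ceRNA crosstalk: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceRNAcross)
```

## The model and its assumptions

`ceRNAcross` implements deterministic mass-action kinetics for a bipartite
network of $N$ RNA and $M$ miRNA species. Each species is synthesized at a
constant rate ($b_i$ for RNAs, $\beta_a$ for miRNAs, molecules/h), degrades
at a shared first-order rate ($d$ and $\delta$, 1/h), and each interacting
pair $(i,a)$ forms a complex at rate $k^+_{ia} m_i \mu_a$. Complexes decay
through two channels: a *stoichiometric* one (rate $\sigma$) in which the
miRNA is destroyed with its target, and a *catalytic* one (rate $\kappa$)
that recycles the miRNA. The stoichiometricity ratio
$\lambda = \sigma/(\sigma+\kappa)$ interpolates between purely catalytic
($\lambda \to 0$) and purely stoichiometric ($\lambda = 1$) repression.

Key simplifying assumptions, all standard in this modelling tradition:

* **steady state only** — we solve the unique stable fixed point; transient
  amplification of crosstalk and stochastic (master-equation) effects are
  out of scope;
* **negligible unbinding** — $k^-_{ia} = 0$, appropriate when mature miRNAs
  are predominantly Argonaute-loaded and complex formation is effectively
  committed;
* **homogeneous global rates** — $d$, $\delta$, $\sigma$, $\kappa$ are
  species-independent; heterogeneity enters only through transcription rates
  and per-edge binding strengths;
* **quenched random transcription rates** — rather than committing to one
  unknown rate assignment, rates are i.i.d. lognormal and results are
  averaged over realizations, exposing the features that do *not* depend on
  the particular assignment.

At steady state the free levels obey the coupled titration maps

$$
[\mu_a] = \frac{\mu^*_a}{1 + \sum_i [m_i]/m^0_{ia}}, \qquad
[m_i] = \frac{m^*_i}{1 + \sum_a [\mu_a]/\mu^0_{ia}},
$$

with unrepressed references $m^*_i = b_i/d$, $\mu^*_a = \beta_a/\delta$.
The thresholds $\mu^0_{ia}$ (the free-miRNA level at which repression of $i$
by $a$ crosses over) and $m^0_{ia}$ (the RNA level at which sequestration of
$a$ by $i$ crosses over) encode all binding kinetics; with $k^- = 0$ they
satisfy $\mu^0_{ia} = d/k^+_{ia}$ and are tied pairwise by

$$
\frac{\mu^0_{ia}}{m^0_{ia}} = \frac{\lambda d}{\delta},
$$

so a single per-edge number fully parameterizes each interaction.
`derive_rate_constants()` inverts these relations exactly, and the
round-trip identity is unit-tested.

## Susceptibility: exact linear response

Crosstalk from RNA $j$ to RNA $i$ is quantified by the dimensionless
susceptibility $\chi_{ij} = d_j\, \partial [m_i]/\partial b_j \ge 0$.
Differentiating the titration maps gives the closed form implemented in
`compute_susceptibility()`:

$$
\hat\chi = (\mathbb{1} - \hat W)^{-1}\,\mathrm{diag}(m/m^*), \qquad
W_{ij} = \frac{[m_i]^2}{m^*_i} \sum_{a \in (i \cap j)}
\frac{1}{\mu^0_{ia} m^0_{ja}} \frac{[\mu_a]^2}{\mu^*_a},
$$

the sum running over miRNAs targeting both $i$ and $j$. $W$ is held sparse
(its support is exactly the co-regulation structure) and $\chi$ is obtained
by sparse LU solves, never an explicit inverse. Although $W_{ij}$ vanishes
for RNAs with no shared regulator, $(\mathbb{1}-\hat W)^{-1}$ resums all
interaction chains, so $\chi_{ij}$ can be positive for topologically distant
pairs — the `chain` motif in `make_motif()` isolates this mechanism.
Stability of the steady state requires the spectral radius of $W$ to stay
below 1; the solver refuses (rather than silently returning) when the solve
fails or produces negative entries, and `validate = TRUE` adds a
power-iteration estimate of the radius.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `d` | 0.08 | 1/h | RNA degradation rate |
| `delta` | 0.027 | 1/h | miRNA degradation rate |
| `lam` | 0.2 | — | stoichiometricity ratio $\sigma/(\sigma+\kappa)$ |
| `mu0_base` | 4 | molecules | reference repression threshold $\mu_0$ |
| `b` (mean) | 8 | molecules/h | RNA transcription rate |
| `beta` (mean) | sweep variable | molecules/h | miRNA transcription rate |
| `cv_tr` | 0.1–2 | — | CV of lognormal transcription rates |
| `complex_decay_total` | 1 | 1/h | $\sigma + \kappa$; nuisance scale |

The defaults give $\mu^0/m^0 = \lambda d/\delta \approx 0.59$ and, for the
homogeneous scenario ($\mu^0_{ia} = 2\mu_0 = 8$), an association rate
$k^+ = d/\mu^0 \approx 0.01$–$0.02$ /molecule/h. `complex_decay_total` only
sets complex abundances and ODE transients; the free-level fixed point is
provably independent of it (and tested to be).

**Binding heterogeneity (BH).** Three scenarios map the four CLASH
interaction classes to multipliers of `mu0_base`: *low* (all pairs
$2\mu_0$), *medium* (k-mer pairs $\mu_0$, the rest $2\mu_0$), *high* (a
2-fold ladder 1, 2, 4, 8 across kmer, seed-nc, noseed-9nt, noseed). Only
the 2-fold spacing and the special role of k-mer pairings are empirically
constrained; the relative order of the two no-seed classes in the high
scenario is a package choice, made configurable through
`bh_scenario(multipliers =)`. All k-mer seed lengths (6–9 nt) share one
strength. When an input file carries duplicate $(i,a)$ rows with different
modes, the strongest (lowest-multiplier) mode is kept and the collapse is
logged — a single interaction channel per pair is a model assumption, not a
parsing accident.

**Transcriptional heterogeneity (TH).** Rates are lognormal with exact
mean/CV parameterization ($s^2 = \ln(1+cv^2)$, location
$\ln(\text{mean}) - s^2/2$), the same CV applied to RNAs and miRNAs.

## The synthetic interactome generator

`generate_network()` emulates the three features of measured CLASH-style
interactomes that drive the system-level results: heavy-tailed degree
distributions on both sides (bipartite configuration-style sampling from
truncated discrete power-law propensities, default exponent 2.2), at most
one edge per pair, and the empirical binding-mode composition (default
frequencies 0.08, 0.77, 0.05, 0.10 — only the 77% non-canonical share is
empirically fixed; the remainder split is a documented choice). It does
**not** reproduce degree–degree correlations, mode–degree associations, or
any particular degree sequence of a real interactome — analyses requiring
those should load a real edge list via `load_interactome()` and use
`rewire_degree_preserving()` as the matched null. Consequently, passing
tests on synthetic networks demonstrates correctness of the machinery and
the qualitative shape of the crosstalk landscape, not quantitative agreement
with any particular measured interactome.

Nodes left with degree zero by the generator are retained (they decouple
harmlessly), whereas the file loader prunes isolated species, mirroring the
parsing convention for real interactomes. System-level analyses in the test
suite therefore prune generator output first
(`subnetwork_by_modes(net, binding_modes())`): with isolated RNAs retained,
the expression-CV curve saturates at large miRNA availability (the free
pool becomes bimodal) instead of showing the interior maximum characteristic
of fully connected interactomes.

## Numerical choices

* **Fixed-point solver**: damped alternating iteration of the two titration
  maps, damping 0.5 halved on residual oscillation (floor 1/64), initialized
  at $(m^*, \text{reduced } \mu)$. Both maps are monotone and bounded, which
  makes the iteration robust across the full repression range; default
  tolerance $10^{-12}$ (maximum relative update), with the undamped
  fixed-point residual re-verified before returning. Non-convergence is an
  error carrying the last residual.
* **ODE oracle**: `integrate_odes()` integrates the full mass-action system
  (free species *and* complexes) with `deSolve::lsoda` at
  rtol = atol = $10^{-10}$ to $t = 50/\delta$, far beyond the slowest
  relaxation time. Fixed-point and ODE solutions agree within $10^{-6}$
  relative on motifs and random networks (tested).
* **Finite-difference oracle**: central differences with relative step
  $10^{-4}$ at solver tolerance $10^{-14}$, so truncation dominates
  round-off for all resolvable entries. The scheme's absolute resolution
  limit for column $j$ is $d\,(10\,\mathrm{tol}\,\max m)/(2 b_j \epsilon)$
  (solver error propagated through the difference quotient); it is attached
  to every result as the `noise_floor` attribute, and comparisons against
  the analytic $\chi$ use the standard two-term form
  $|\chi - \chi_{FD}| \le 10^{-4}|\chi_{FD}| + \text{floor}$. Entries below
  the floor (in practice $\lesssim 10^{-6}$ of the dominant scale) are
  dominated by amplified solver round-off in the difference and cannot be
  certified in purely relative terms by any direct-perturbation scheme in
  double precision.
* **Peak locations** along $\bar\beta$ sweeps are read off a log-parabola
  through the grid argmax and its neighbours, making peak-ordering
  statements robust to the 25-point grid resolution.
* **Degenerate inputs**: selectivity rows/columns with zero off-diagonal
  sum are excluded from $S_{in}/S_{out}$ (0/0 is undefined) with exclusion
  counts reported; all-zero susceptibility, zero-variance locality
  correlation and empty asymmetry sets return `NA` with a warning rather
  than a number.

## Design choices in the metrics

* Averages over "pairs of distinct RNAs" are over **ordered** pairs — the
  susceptibility matrix is directional.
* The locality correlation $\rho$ (Pearson, over ordered distinct pairs,
  zeros included) is returned as the true coefficient in $[-1, 1]$; for this
  model it is positive in practice but not by construction.
* The asymmetry index is the mean of
  $|\chi_{ij}-\chi_{ji}|/(\chi_{ij}+\chi_{ji})$ over unordered pairs whose
  total exceeds a floor (default $10^{-8}\chi_{\max}$, excluding numerically
  zero pairs). Other definitions can be swapped in by operating on
  `coef(fit)` directly.
* Sextile persistence breaks ties by stable pair index and reports both the
  naive $1/6$ chance level and a seeded permutation baseline (default 1000
  rank shuffles).
* The susceptible region is operationalized as the $\bar\beta$ window where
  the mean susceptibility reaches at least 5% of its peak.
* In `rewire_degree_preserving()`, each rewired edge inherits the mode of
  the edge that contributed its miRNA endpoint, preserving the mode
  multiset; whether real randomization protocols shuffle modes relative to
  pairs is underdetermined, so this is a declared convention.
* β̄ sweeps default to 25 log-spaced points over $0.1$–$10^4$ molecules/h,
  spanning the unrepressed to fully repressed limits.

## Problem sizes used by the tests

The test and acceptance analyses run at desk scale, chosen so the whole
suite completes in minutes while every qualitative signature is resolved: a
CLASH-like network of 300 RNA / 60 miRNA species and 1200 edges (≈ 280 RNAs
after pruning), 25-point β̄ grids, 12 transcription-rate realizations per
condition (30 for the rank-persistence analysis), 10-network null-model
ensembles, and oracle scans over 20 randomized conditions with
$N \le 30$. Real-interactome studies (e.g. $N \approx 7000$) use the same
code paths — $W$ stays sparse and $\chi$ is obtained column-wise by linear
solves — but need correspondingly more compute.

## Known limitations

* Steady state only: no transient crosstalk amplification, no
  recycling-round-dependent miRNA decay, no stochasticity.
* Susceptibilities are linear responses to *small* perturbations of
  transcription rates; strong inductions leave the linear regime.
* Uncorrelated rate heterogeneity: correlated transcription programs would
  change the fluctuation-processing conclusions.
* Responses with respect to miRNA transcription rates
  ($\partial m/\partial\beta$) are not implemented.
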