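---
title: "Diversity-dependent island diversification: models, likelihood and model choice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity-dependent island diversification: models, likelihood and model choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(islandDD)
```

## The model

An island of age $t_0$ (in My; the present is time 0) receives colonists
from a mainland pool of $M$ species. Four per-capita rates drive the
assembly of the island community:

* colonization $\gamma_N = \gamma_0 (1 - N/K)$, per mainland species per My;
* cladogenesis $\lambda_{c,N} = \lambda_{c0} (1 - N/K)$, per island species
  per My, splitting one island species into two endemic daughters;
* anagenesis $\lambda_a$, per non-endemic island species per My, turning a
  colonist into an endemic species without changing diversity;
* extinction $\mu$, per island species per My.

Colonization and cladogenesis decline linearly with the diversity $N$ and
stop at the carrying capacity $K$ (negative values are clamped to zero, so
$K$ need not be an integer); extinction and anagenesis are
diversity-independent. The scientific question the package addresses is the
*scope* of $N$:

* **CS (clade-specific)**: $N$ counts only the species descending from the
  same mainland ancestor; every colonist clade has its own copy of $K$.
* **IW (island-wide)**: $N$ counts all island species of the focal taxon,
  so different clades suppress each other's colonization and speciation.
* **DI (diversity-independent)**: $K = \infty$; CS and IW then coincide.

The data are the colonization times (stem ages) and branching times
(reconstructed node ages) of the extant island clades, plus each clade's
endemicity status. Sampling is assumed complete: every extant island
species appears in the data. A repeat colonization by a mainland species
whose island descendant has not yet speciated or undergone anagenesis
*resets* that lineage's colonization time rather than founding a second
clade; consequently valid datasets contain no two clades sharing a mainland
ancestor.

## The likelihood

The island-wide likelihood cannot factor over clades, so it is computed by
the $Q$ approach: $Q_n(t)$ is the probability that a realization of the
process is consistent with the data up to time $t$ while carrying $n$
*hidden* species — species alive at $t$ that leave no extant sampled
descendant. Between observed events, with $k$ reconstructed lineages
present, $Q$ obeys the master equation

$$
\frac{dQ_n}{dt} =
\left[M\,\gamma_{N-1} + \lambda_{c,N-1}\,(n - 1 + 2k_g)\right] Q_{n-1}
+ \mu (n+1)\, Q_{n+1}
- \left[M\,\gamma_N + (\lambda_{c,N} + \mu) N + \lambda_a k_{ne}\right] Q_n ,
$$

with $N = n + k$. Hidden species arise from unobserved colonizations
(mainland multiplicity $M$) and from cladogenesis; the inflow counts each of
the $k_g$ "grower" lineages (observed lineages whose extant descendant is
endemic) **twice**, because either daughter of an observed split can carry
the observed line onward and the two designations are disjoint futures. The
outflow keeps the physical total event rate: observed lineages may not die
($\mu k$ is pure loss), and lineages whose extant species is non-endemic
($k_{ne}$ of them) may neither split nor undergo anagenesis. The asymmetry
between the inflow and outflow coefficients is easy to get wrong; the
package pins it two independent ways — against the closed-form probability
that a constant-rate birth–death lineage leaves exactly one extant
descendant, and against a brute-force Monte-Carlo oracle
(`loglik_oracle_mc()`) that estimates the likelihood of small datasets by
binning millions of simulator outcomes.

At an observed colonization $Q$ is multiplied by the per-mainland-species
rate $\gamma_N$ (the colonist's identity is part of the data); at an
observed branching by $\lambda_{c,N}\,k_j$, where $k_j$ is the number of
reconstructed lineages of the branching clade just before the event (the
data record which clade branched, not which lineage). Endemic singletons —
extant single-species clades that are endemic — must have acquired
anagenesis or a (later pruned) cladogenesis at some unknown time; the state
vector carries an extra index counting such still-"pending" lineages, with
transitions $\lambda_a e$ and $2\lambda_{c,N} e$ into the endemized class.
Under complete sampling no hidden species may remain at the present, so the
loglikelihood is $\log Q_{0,0}(0)$.

The CS likelihood is assembled exactly as the IW likelihood of each clade
alone with a mainland pool of one, summed over clades, plus $M - C$ copies
of the empty-island term — so the two models differ *only* in the scope of
the feedback, and their loglikelihoods are directly comparable. The DI
likelihood is the CS likelihood at $K = \infty$.

### Colonization bookkeeping

Unobserved colonizations founding hidden clades use the full mainland
multiplicity $M$ by default. This "pooled" convention absorbs the reset
rule: a repeat colonization of a still-unspeciated observed lineage would
reset its recorded colonization time (a pure loss of consistency), and the
pooled loss term $M \gamma_N$ covers founding and reset alike. It makes the
single-colonist likelihood $\gamma_0 e^{-M \gamma_0 t_0}$, independent of
the colonization age. The exact accounting of histories in which an earlier
colonization is itself reset into the observed lineage is not expressible
in the $Q$ frame; the residual error is $O(\gamma_0 t_0 / M)$ per clade,
far below the Monte-Carlo oracle's resolution at the tested scales. A
refined allocation (`colonization_multiplicity = "pool_minus_active"`),
which excludes currently reset-prone lineages from the founding
multiplicity while keeping their reset risk as a loss, is available for
sensitivity analysis.

## Numerics

Between events the master equation is linear with a Metzler (nonnegative
off-diagonal) generator, so the package propagates $Q$ by
**uniformization**: $e^{A\Delta t} = e^{-c\Delta t} e^{(A + cI)\Delta t}$
expanded as a positive series — no cancellation, with the series truncated
at relative tolerance `tol` (default $10^{-14}$) and the term budget sized
to the series norm, which exceeds the diagonal bound by up to
$\lambda_{c0} k$ because of the doubled grower inflow. The vector is
renormalized at every event and substep, accumulating a log scale factor,
so event multiplications by rates as small as $\gamma_0 \sim 10^{-4}$
cannot underflow. Because the generator couples neighbouring hidden counts
only, the support of the vector grows by at most one state per series term;
propagation is restricted to the live support, which makes the empirical
problem size (65 species, $K \approx 132$, $M = 1000$) run in about a
millisecond per likelihood evaluation.

The hidden-state truncation $n_{\max}$ is adaptive: after each interval the
top entry's share is examined and, if it exceeds `tail_tol`
($10^{-12}$), the interval is re-run with a half-again larger state space
(never beyond $\lceil K \rceil - k$, where the clamped rates make states
unreachable). For infinite $K$ the raw-mass criterion would chase
exponentially growing hidden populations that can no longer influence
$Q_0$ at the present, so by default the criterion weights the entry at
hidden count $n$ by $p_\text{ext}(t)^n$ — the probability that a hidden
lineage leaves no extant descendant in the remaining time, evaluated at the
diversity-independent upper bound $\lambda_{c0}$, which only overstates a
hidden lineage's survival. The unweighted rule is available
(`weighted_tail = FALSE`) and the two agree to $10^{-6}$ on the test
problems. A second, independent numerical route through the same generator
(`engine = "r"`, `deSolve::lsoda`) is used in the test suite to cross-check
the uniformization core.

Optimization is Nelder–Mead on transformed parameters: rates on the log
scale and $K$ as $K_\text{low} + e^\theta$, where $K_\text{low}$ is the
largest observed diversity in the parameter's scope (largest clade for CS,
total island species for IW) — below that bound the likelihood is zero.
Defaults start from moment matches (a Yule-style growth-rate estimate for
$\lambda_{c0}$, half of it for $\mu$, $C/(M t_0)$ for $\gamma_0$, twice the
observed maximum for $K$) and additional starts perturb each parameter
log-uniformly in $[0.1, 10]$. Each start has an evaluation budget (default
5000); exhausted starts keep their best value and are flagged. Ties at the
same event age are broken deterministically (colonizations before
branchings, then by clade name), so repeated evaluations are bit-identical.

## The simulator and what the synthetic data emulate

`simulate_iw()` and `simulate_cs()` are exact Gillespie simulations —
waiting times are exponential at the current total rate, which is piecewise
constant between events; no tau-leaping — and their pruned output contains
exactly what a reconstructed phylogeny of the extant species shows. The CS
simulator exploits the independence of mainland lineages: species whose
first potential colonization falls after the present are skipped, which
makes $M = 1000$ replicates cheap. The simulators can produce
recolonization doublets (a mainland species founding a second surviving
clade after its first clade speciated); the likelihood's data model
excludes these, so bootstrap replicates relabel doublets as distinct
mainland ancestors — at the fitted colonization rates this affects well
under 1% of clades.

`make_table1_fixture()` provides the package's standing example: an island
of 30 My, a mainland pool of 1000, and five endemic clades of 28, 21, 3, 5
and 8 species with colonization ages 22.09, 13.75, 11.03, 8.85 and 8.43 My.
Only this clade structure — the sizes and stem ages reported for the five
*Eleutherodactylus* frog colonizations of Hispaniola — is taken from the
literature; the within-clade branching ages are **synthesized** as uniform
order statistics below each colonization age (seeded, reproducible). Tests passing on this fixture therefore validate
the machinery — likelihood, optimization, bootstrap — not any empirical
claim about the real branching tempo, whose reconstruction lives in the
original data deposit. In particular the fixture's fitted parameters and
bootstrap thresholds need not (and do not) reproduce the published
empirical values, while scale-free quantities — misselection rates at the
published parameter values — do.

## Model choice

AIC/BIC weights are reported (`information_criteria()`; the BIC
effective-sample-size convention for island data is genuinely open, so
`n_eff` defaults to the number of observed events and is exposed), but the
primary instrument is the parametric-bootstrap likelihood-ratio test
(`bootstrap_lrt()`): simulate under each fitted model, refit both models to
every replicate starting from the empirical estimates (with the starting
$K$ raised to the replicate's observed diversity when necessary), and
locate the empirical $\Delta = LL_{CS} - LL_{IW}$ within the two simulated
$\Delta$ distributions. CS is selected when $\Delta$ exceeds the 95th
percentile of the IW-generated differences while staying inside the
CS-generated distribution; IW symmetrically via the 5th percentile of the
CS-generated differences; anything else is indecisive. Quantiles use the
inclusive linear-interpolation convention (R type 7), recorded in the
result's metadata. The rule is monotone in $\Delta$ and caps the
probability of selecting IW when CS is true at 5% by construction.

## Problem sizes used in the tests and the acceptance script

The test suite checks the analytic toy likelihoods exactly; the Monte-Carlo
oracle suite runs $10^5$ simulations per toy case; simulator laws use
$10^4$ (Poisson colonization) and 2000 (CS/IW coincidence at $K = \infty$)
replicates; parameter recovery fits 100 datasets simulated at the published
CS estimates; and the misselection rates are estimated from 100 bootstrap
replicates per generating model, against 3-standard-error binomial bands
around the published 7.7% and 19%. `scripts/acceptance.R` fits all five
variants to the fixture (three starts each), runs a 60+60-replicate
bootstrap and a 1000-simulation goodness-of-fit ensemble. These sizes are
the package's choice of a thorough-but-routine desktop run; all are
arguments, so larger studies only cost time.

## Known limitations

* Colonization-time uncertainty (maximum-age colonizations) and clades with
  unsampled species are out of scope: the likelihood assumes complete
  sampling with known event times.
* Recolonization doublets are excluded from the data model (none occur in
  the motivating empirical system; the simulators can emit them and the
  bootstrap relabels them).
* The pooled colonization convention leaves $O(\gamma_0 t_0/M)$ relative
  error per clade from reset histories (negligible for $M \gg C$, the
  regime the models are meant for).
* The likelihood is unconditioned (no conditioning on island survival or on
  at least one colonization); this matches the use of unconditioned
  simulations throughout, and a conditioning convention can be layered on
  by subtracting the empty-island term if needed.
* Per-clade distinct carrying capacities, trait- or area-dependence, and
  protracted speciation are not modelled.
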