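---
title: "Modelling seizure propagation as epidemic spreading on brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling seizure propagation as epidemic spreading on brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epispread)
```

## The model

`epispread` treats the recruitment of brain regions into a seizure as an
epidemic process on a patient-specific functional network. Each region of
interest (ROI) is a node; the coupling weight $w_{ij} \in [0,1]$ between two
ROIs acts as a local modulation of the spreading probability. The dynamics
are the discrete-time stochastic SIR (susceptible--infected--recovered)
process, where S, I and R stand for the preictal, ictal and postictal
states:

* at each step, every infected node $i$ attempts to infect each susceptible
  neighbour $j$ independently with probability $\beta\, w_{ij}$;
* every node that was infected before the step recovers with probability
  $\gamma$ (a node cannot recover in the very step it was infected).

Because all per-link attempts are independent Bernoulli trials, the
probability that a susceptible node $i$ escapes infection in one step is
$\prod_{j \in I} (1 - \beta w_{ij})$; the engine realizes exactly this
product law. Rather than iterating every step, the compiled engine draws the
*first-success* step of each link directly: the first success of a
Bernoulli($p$) sequence is Geometric($p$), so node $j$'s candidate infection
time from $i$ is $t_i + H_{ij}$ with $H_{ij} \sim \mathrm{Geom}(\beta
w_{ij})$, valid while $H_{ij} \le G_i$, where $G_i \sim \mathrm{Geom}(\gamma)$
is $i$'s infectious period. Infection times are then first-arrival times,
computed Dijkstra-style in $O(E \log n)$ per realization instead of
$O(TE)$. The two formulations are algebraically identical; the test suite
verifies the engine against an exact state-space enumeration of the per-step
process on small graphs, and against a plain step-by-step reference
simulator.

A third control parameter enters through the network itself: raw coupling
matrices are thresholded at link density $\theta$ (keeping the
$\mathrm{round}(\theta\, n(n-1)/2)$ strongest links, *unbinarized*), with
the resulting mean degree $\kappa = 2L/n$. Spreading speed is governed by
the rescaled rate $\beta\kappa$ and the spreading-to-recovery ratio
$\beta\kappa/\gamma$; fit surfaces are near-constant along this ridge, which
is the model's chief degeneracy.

## The fit statistic

A recorded seizure pattern assigns integer activation steps to the ROIs that
became active among the $N_\mathrm{SEEG}$ electrode-sampled ROIs
($\mathbb{S}$ active, $\mathbb{H}$ inactive). A simulation is summarized per
ROI by $P_{IR}(i)$, the fraction of realizations in which ROI $i$ was ever
infected, and by its mean first-infection step. The goodness of fit
combines:

* $C_w$: the weighted Pearson correlation between recorded activation steps
  and simulated mean activation times over the ROIs active in *both*
  patterns, weighted by $P_{IR}$;
* $P_\mathrm{overlap} = N_\mathrm{SEEG}^{-1}\big[\sum_{i\in\mathbb{S}}
  P_{IR}(i) + \sum_{i\in\mathbb{H}} (1 - P_{IR}(i))\big]$, the agreement of
  seizure extension;
* the total correlation $C = C_w \cdot P_\mathrm{overlap}$, which is 1 for
  exactly equal patterns and $-1$ for fully reversed activation orders with
  equal seizure areas.

Two readings of the recorded/simulated "activation order" are possible (raw
times versus ranks). We correlate the integer recorded steps (ties kept as
equal values) against the real-valued simulated mean times, with no rank
transform; this avoids arbitrary tie-breaking, and both readings order the
ROIs identically when $P_{IR}$ is close to 1. A degenerate correlation
(fewer than two jointly active ROIs, or zero variance from complete ties)
maps to $C_w = 0$ with a flag: a pattern carrying no order information
should neither reward nor punish a parameter point.

## Fitting, seed search and virtual resections

`fit_patient()` grid-searches $\beta, \gamma \in \{10^{-4}, 10^{-3},
10^{-2}, 10^{-1}\}$ and $\kappa/n \in \{0.025, 0.05, 0.10, 0.20, 0.30\}$,
with the resection area (RA) as the epidemic seed, averaging $C$ over
`n_iterations` independent evaluations (the default 10 matches the
convention for clinical-scale runs; the bundled analyses use 2 at reduced
realization counts, trading precision for runtime). `population_fit()`
averages the per-patient maps point-wise and reports the shared optimum plus
the per-patient fit at that optimum.

`seed_likelihood_map()` scores every ROI as a candidate single seed at the
patient's *frozen* best-fit parameters: refitting per seed would inflate the
degeneracy of an already ill-posed problem, so only the spreading rate is
rescaled by the out-connectivity ratio $E_\mathrm{RA}/E_R$ to keep the
initial spreading pressure comparable across seeds. ROIs without links
cannot spread and are excluded with a flag.
`recursive_seed_optimization()` grows multi-ROI seeds greedily. The
combinatorial scan uses a reduced number of realizations per candidate
(default $10^3$) and rescores the kept seed at full precision; ties are
broken by lower ROI index after rounding $C$ to 6 decimals, which makes the
selection deterministic and invariant to candidate order.

`virtual_resection_effect()` simulates the same seed on the baseline network
and on a copy with all links incident to the RA set to zero. Nodes are kept
in the graph, so metric denominators are unchanged and the seed remains
infectable as seed even if fully disconnected; the epidemic size then hits
its floor $|{\rm seed}|/n$. The effect measure is the normalized decrease
$\delta_R = (IR_0 - IR_R)/IR_0$. Covariates follow the node-set metric
conventions below; the pairwise scan correlates each covariate with
$\log \delta_R$, flooring non-positive $\delta_R$ (possible from sampling
noise at tiny effects) at one tenth of the smallest positive observed value,
with a warning. `stepwise_regression()` performs bidirectional selection on
linear terms with partial-F thresholds (enter $p < 0.05$, remove
$p > 0.10$), dropping exactly collinear columns first.

## Network metric conventions

For correlation-weight graphs no single convention is universal, so the
choices are explicit and isolated behind `node_set_metrics()`:

* path length of a link is $1/w_{ij}$; weighted shortest paths define both
  betweenness (unnormalized counts, connected pairs only) and efficiency
  (node efficiency is the mean of $1/d(i,j)$ over $j \ne i$; disconnected
  pairs contribute 0);
* clustering is the Onnela geometric-mean triangle intensity on the
  thresholded weights, which stays in $[0,1]$ and reduces to the binary
  coefficient on unit weights;
* out-connectivity $E_X$ counts links with exactly one endpoint in the node
  set $X$; for the whole network only average clustering and efficiency are
  reported.

On unit-weight graphs all path-based metrics equal their textbook
unweighted values, which the tests verify by exhaustive path enumeration.

## What the synthetic generator emulates

Clinical data of this kind (MEG coupling matrices, SEEG seizure patterns,
resection masks with surgical outcomes) cannot be shared, so the package
ships a generator whose cohorts make every stage testable against known
ground truth.

* **Networks.** ROI positions are drawn uniformly in a spherical shell
  (inner/outer radii 48/80 mm, pairwise distances spanning roughly 0--160
  mm) and coupled by an exponential distance rule, $w_{ij} =
  e^{-\alpha d_{ij} + \varepsilon}$ with $\alpha = 0.052\,\mathrm{mm}^{-1}$.
  The log-weight noise default $\sigma = 1.7$ is calibrated so that distance
  explains about half the log-weight variance, matching the reported
  agreement between functional-coupling matrices and pure EDR surrogates;
  it is what keeps thresholded graphs from collapsing into purely local
  clusters.
* **Patients.** The true seed is a spatially contiguous cluster (default 3
  ROIs). Electrode sampling covers the seed and its immediate neighbourhood
  and is biased towards the seed centroid (length scale 60 mm), reflecting
  electrode planning around the hypothesized onset zone. The SEEG-style
  pattern is the mean activation order of a small batch of model
  realizations at the true parameters, discretized to integer steps (a new
  step starts when the mean time leaves a one-step-wide bin). Configurations
  whose typical seizure activates fewer than 25% of the sampled ROIs are
  resampled: patients enter a surgery cohort only with seizures that
  demonstrably propagate.
* **Outcome groups.** SF-like patients have a resection area that contains
  the true seed (padded with its nearest neighbours, sizes 3--13); NSF-like
  patients have a resection area grown around a distant centre, disjoint
  from the seed. The default cohort shape is 11 SF + 4 NSF.

What the generator does **not** emulate: volume-conduction structure and
measurement noise of real coupling matrices, electrode geometry and
contact-to-ROI assignment, multiple seizures per patient, non-binary ictal
activity, and any anatomical atlas. Passing recovery tests therefore show
that the pipeline is *self-consistent* under its own generating model — not
that the model is adequate for clinical data.

## Generating conditions and problem sizes

The generating parameters are $\beta^* = \gamma^* = 10^{-3}$ at
$\theta^* = 0.10$ ($\kappa \approx 8$ on the 80-node test networks). This
point is grid-interior on every axis, and its spreading timescale is
comparable to the horizon $T = 1000$, so seizures are *partial*: extent
(through $P_\mathrm{overlap}$) and timing (through $C_w$) both carry
information, which is what makes the ridge degeneracy resolvable at all.
Strongly supercritical settings saturate the sampled set and leave the
ratio unidentified upward; strongly subcritical ones never leave the seed.

The bundled tests and the acceptance script run at desk scale: 80-node
networks, 30 sampled ROIs, 300--1000 realizations per evaluation and 2 fit
iterations per grid point. The clinical-scale defaults (246 ROIs, $10^4$
realizations, 10 iterations, $T = 1000$) remain the function defaults.
Recovery is asserted along the ridge: an individual fit counts as recovered
when $|\log_{10}(\widehat{\beta\kappa/\gamma}) - \log_{10}
(\beta^*\kappa^*/\gamma^*)| \le 1$, one decade being one grid step in
$\beta$ or $\gamma$; the population optimum is required to land within one
grid step of the truth on every axis.

## Numerical choices and edge cases

* Step ordering: infections use start-of-step states; recovery applies only
  to previously infected nodes. The enumeration oracle implements the same
  ordering.
* One master RNG seed drives each simulation (`set.seed` before the
  compiled engine); identical seeds give bit-identical results. Grid
  searches draw per-evaluation sub-seeds from the master stream.
* The mean activation time of a ROI is the average first-infection step
  over the realizations in which it was infected, and is missing where
  $P_{IR} = 0$. (Summing the per-step activation probabilities, an
  alternative reading, equals this quantity only under a survival-function
  interpretation; both order the ROIs identically when $P_{IR} \approx 1$.)
* Thresholding ties at the cutoff weight are broken by (weight descending,
  node-pair lexicographic), so thresholds are reproducible and nested.
* A realization is flagged truncated when the horizon $T$ ends it while an
  infectious node still had a never-infected neighbour.
* Degenerate group comparisons (zero variance) and degenerate correlations
  are flagged rather than thrown.

## Known limitations

* The parameter surface is strongly degenerate along $\beta\kappa/\gamma$;
  individual argmaxes scatter along the ridge, and only the ridge position
  itself is a stable estimand. The population average sharpens it.
* Activation *order* is the only temporal information used; the model
  cannot distinguish fast from slow spreading, and deactivation patterns
  are out of scope (they would require a real timescale and local recovery
  rates).
* Greedy seed growth is not guaranteed to find the optimal seed of a given
  size, and its fit need not be monotone in seed size; results are recorded
  as-is.
* The synthetic eligibility rule (minimum seizure extent) means the tested
  regime excludes patients whose seizures barely propagate; conclusions do
  not extend to such cases.
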