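# epispread

Individualized seizure-propagation models built from epidemic spreading on
weighted brain networks.

## The problem

In presurgical evaluation of drug-resistant epilepsy, the clinical team must
decide which brain regions to resect so that seizures stop. The available
evidence is indirect: a functional connectivity matrix over atlas regions
(ROIs), a seizure-propagation pattern recorded by depth electrodes (SEEG)
that samples only a few dozen ROIs, and — after surgery — the resected
region set and the outcome (seizure-free or not). `epispread` is for
researchers who want to model that setting quantitatively: it simulates
seizure spread as a stochastic SIR (susceptible–infected–recovered) process
on the patient's network, fits the model to the recorded pattern, generates
alternative hypotheses for the seizure onset zone, and quantifies the effect
of (virtual) resections.

## The model

Each infected ROI *i* infects a susceptible neighbour *j* in one time step
with probability *β·w<sub>ij</sub>*, where *w<sub>ij</sub>* ∈ [0, 1] is the
coupling weight, and recovers with probability *γ*. Networks are thresholded
at link density *θ* (mean degree *κ*), giving three global parameters
(*β*, *γ*, *κ*). A simulated seizure is summarized by the per-ROI infection
probability *P<sub>IR</sub>(i)* and mean activation time; agreement with the
recorded pattern is the total correlation

> *C* = *C<sub>w</sub>* · *P*<sub>overlap</sub>,

where *C<sub>w</sub>* is the *P<sub>IR</sub>*-weighted Pearson correlation of
activation orders over the jointly active ROIs and *P*<sub>overlap</sub>
measures the agreement of seizure extension over the sampled ROIs. *C* is 1
for identical patterns, −1 for reversed activation order with equal seizure
areas. Parameters are fitted by grid search with the resection area as the
epidemic seed; seed-likelihood maps, greedy multi-ROI seed optimization and
virtual resections (δ<sub>R</sub>, the normalized decrease in spreading)
build on the fitted model. Because clinical recordings of this kind are not
shareable, the package includes a synthetic-cohort generator
(exponential-distance-rule networks, known true seeds, SF/NSF-like resection
areas) so that every stage is testable against ground truth.

## Worked example

```r
library(epispread)

# a synthetic patient: EDR network, contiguous 3-ROI seed, SEEG-style
# pattern generated at beta = gamma = 1e-3, theta = 0.10
edr <- make_edr_network(n = 80, rng_seed = 101)
pat <- make_patient(edr, beta = 1e-3, gamma = 1e-3, theta = 0.10,
                    n_sampled = 30, rng_seed = 201)

# fit the model with the resection area as seed
fm <- fit_patient(pat$raw_weights, pat$ra, pat$seeg_pattern,
                  n_realizations = 1000, T = 1000, n_iterations = 2,
                  rng_seed = 301)
attr(fm, "best")
#>   kappa_frac  beta gamma kappa   C_mean         C_sd  C_w_mean P_overlap_mean
#> 8        0.1 0.001 1e-04   7.9 0.660729 0.0001085942 0.8944692      0.7386833
#>   degenerate_frac missing beta_kappa ratio
#> 8               0   FALSE     0.0079    79

# virtual resection of the RA at the best-fit parameters
b <- attr(fm, "best")
net <- threshold_network(pat$raw_weights, b$kappa_frac)
out <- virtual_resection_effect(net, pat$ra, pat$true_seed,
                                spread_params(b$beta, b$gamma, T = 1000,
                                              n_realizations = 2000,
                                              rng_seed = 11))
round(c(IR_0 = out$ir_0, IR_R = out$ir_r, delta_R = out$delta_R), 3)
#>    IR_0    IR_R delta_R
#>   0.596   0.038   0.937
```

The fit finds the correct threshold level and spreading rate (*κ* = 7.9,
*β* = 10<sup>−3</sup>) with *C* ≈ 0.66; the recovery rate sits one grid
step below the truth — the fit surface is near-degenerate along the
spreading-to-recovery ridge *βκ/γ*, which is why recovery is judged along
that ridge (true ratio 7.9, fitted 79, one decade = one grid step).
Disconnecting the resection area (which contains the true seed for this
SF-like patient) removes about 94% of the spreading.

## The analysis workflow

The `analysis/` scripts run the full study arc on a synthetic cohort of 11
seizure-free-like and 4 non-seizure-free-like patients and write tidy tables
under `results/`:

1. `01_simulate_cohort.R` — generate the cohort and ground-truth manifest.
2. `02_fit_patients.R` — per-patient fit maps, best fits, group comparison
   and ROC/AUC of the fit.
3. `03_population_model.R` — population-average fit map, shared optimum,
   per-patient fit at the optimum and its AUC.
4. `04_seed_likelihood.R` — seed-likelihood maps, best single seeds,
   RA vs non-RA contrast, random-seed baseline.
5. `05_virtual_resections.R` — optimized seeds of sizes 1–5, δ<sub>R</sub>
   per patient and size, covariate scan against log δ<sub>R</sub>, stepwise
   regression.

Run them from the repository root, e.g.
`Rscript analysis/01_simulate_cohort.R`.

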