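#' Fit the propagation model for every patient in a cohort
#'
#' Runs [fit_patient()] (resection area as seed) for each patient of a
#' synthetic cohort, on a shared grid.
#'
#' @param cohort list from [make_cohort()].
#' @param grid shared parameter grid.
#' @param n_realizations,T,n_iterations simulation settings per grid point.
#' @param rng_seed master seed; patient i uses `rng_seed + i`.
#' @return List of `fit_map` objects, one per patient.
#' @export
fit_cohort <- function(cohort, grid = default_fit_grid(),
                       n_realizations = 10000L, T = 1000L,
                       n_iterations = 10L, rng_seed = 1L) {
  lapply(seq_along(cohort$patients), function(i) {
    pat <- cohort$patients[[i]]
    fit_patient(pat$raw_weights, pat$ra, pat$seeg_pattern, grid = grid,
                n_realizations = n_realizations, T = T,
                n_iterations = n_iterations, rng_seed = rng_seed + i)
  })
}

#' Per-patient best fits of a cohort
#'
#' @param cohort list from [make_cohort()].
#' @param fitmaps list from [fit_cohort()].
#' @return data.frame: `patient`, `outcome`, `C`, `beta`, `gamma`,
#'   `kappa_frac`, `kappa`, `beta_kappa`, `ratio` (spreading-to-recovery
#'   ratio beta * kappa / gamma).
#' @export
cohort_best_fits <- function(cohort, fitmaps) {
  rows <- lapply(seq_along(fitmaps), function(i) {
    b <- attr(fitmaps[[i]], "best")
    data.frame(patient = cohort$manifest$patient[i],
               outcome = cohort$manifest$outcome[i],
               C = b$C_mean, beta = b$beta, gamma = b$gamma,
               kappa_frac = b$kappa_frac, kappa = b$kappa,
               beta_kappa = b$beta_kappa, ratio = b$ratio,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Virtual-resection outcomes across a cohort
#'
#' For each patient, at the patient's best-fit parameters: builds optimized
#' seeds of the requested sizes by greedy recursive optimization, then
#' simulates the virtual resection of the RA for each seed. Rows are pooled
#' over patients and seed sizes, matching the pooled correlation/regression
#' analysis.
#'
#' @param cohort list from [make_cohort()].
#' @param best_fits data.frame from [cohort_best_fits()].
#' @param seed_sizes seed sizes to evaluate (default 1:5).
#' @param n_realizations realizations for resection runs and seed rescoring.
#' @param scan_realizations realizations per candidate in the greedy scan.
#' @param T maximum steps.
#' @param rng_seed master seed.
#' @return data.frame: `patient`, `outcome`, `seed_size`, `seed_members`,
#'   `ir_0`, `ir_r`, `delta_R`, `ratio`, plus every covariate from
#'   [virtual_resection_effect()].
#' @export
cohort_resection_outcomes <- function(cohort, best_fits, seed_sizes = 1:5,
                                      n_realizations = 10000L,
                                      scan_realizations = 1000L,
                                      T = 1000L, rng_seed = 1L) {
  rows <- list()
  for (i in seq_along(cohort$patients)) {
    pat <- cohort$patients[[i]]
    bf <- best_fits[i, ]
    net <- threshold_network(pat$raw_weights, bf$kappa_frac)
    e_ra <- out_connectivity(net, pat$ra)
    seeds <- recursive_seed_optimization(
      net, pat$seeg_pattern, bf$beta, bf$gamma, pat$ra,
      max_size = max(seed_sizes), n_realizations = n_realizations,
      scan_realizations = scan_realizations, T = T,
      rng_seed = rng_seed + 131L * i)
    for (k in seed_sizes) {
      if (k > nrow(seeds)) next   # greedy growth stopped early
      seed <- strsplit(seeds$members[k], ",")[[1]]
      e_seed <- out_connectivity(net, seed)
      b <- suppressWarnings(rescale_beta_for_seed(bf$beta, e_ra, e_seed))
      params <- spread_params(b, bf$gamma, T = T,
                              n_realizations = n_realizations,
                              rng_seed = rng_seed + 131L * i + k)
      out <- virtual_resection_effect(net, pat$ra, seed, params)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(patient = cohort$manifest$patient[i],
                   outcome = pat$outcome, seed_size = k,
                   seed_members = seeds$members[k],
                   ir_0 = out$ir_0, ir_r = out$ir_r, delta_R = out$delta_R,
                   ratio = bf$ratio, stringsAsFactors = FALSE),
        as.data.frame(t(out$covariates)))
    }
  }
  do.call(rbind, rows)
}
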