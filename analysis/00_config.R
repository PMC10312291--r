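# Shared settings for the analysis scripts. Every script regenerates the
# cohort deterministically from these values, so the stages can be run
# independently and in any order after 01.

library(epispread)

cfg <- list(
  master_seed = 20260901L,
  n_nodes     = 80L,    # ROIs per synthetic network
  n_sf        = 11L,    # seizure-free-like patients
  n_nsf       = 4L,     # non-seizure-free-like patients
  n_sampled   = 30L,    # electrode-sampled ROIs per patient
  true_params = list(beta = 1e-3, gamma = 1e-3, theta = 0.10),
  fit_nr      = 300L,   # realizations per fit evaluation
  fit_iter    = 2L,     # fit iterations per grid point
  Tmax        = 1000L,  # maximum simulation steps
  results_dir = file.path("results")
)

dir.create(cfg$results_dir, recursive = TRUE, showWarnings = FALSE)

build_cohort <- function(cfg) {
  suppressWarnings(make_cohort(
    cfg$n_sf, cfg$n_nsf, n_nodes = cfg$n_nodes, params = cfg$true_params,
    n_sampled = cfg$n_sampled, rng_seed = cfg$master_seed))
}

write_tsv <- function(df, name) {
  path <- file.path(cfg$results_dir, name)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  message("wrote ", path)
  invisible(path)
}
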