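#!/usr/bin/env Rscript
# Stage 1: generate the synthetic patient cohort (EDR networks, ground-truth
# seeds, SEEG-style seizure patterns, resection areas) and write the
# ground-truth manifest plus per-patient input files.

source(file.path("analysis", "00_config.R"))

cohort <- build_cohort(cfg)
write_tsv(cohort$manifest, "cohort_manifest.tsv")

for (i in seq_along(cohort$patients)) {
  dir <- file.path(cfg$results_dir, "cohort", cohort$manifest$patient[i])
  write_synthetic_patient(cohort$patients[[i]], dir)
}
message(sprintf(
  "cohort: %d patients (%d SF-like, %d NSF-like), %d-node networks, %d sampled ROIs",
  nrow(cohort$manifest), cfg$n_sf, cfg$n_nsf, cfg$n_nodes, cfg$n_sampled))
message(sprintf(
  "seizure extents: %s active ROIs (of %d sampled)",
  paste(range(sapply(cohort$patients,
                     function(p) length(p$seeg_pattern$active))), collapse = "-"),
  cfg$n_sampled))
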