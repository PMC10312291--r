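test_that("EDR weights follow exp(-alpha d) exactly without noise", {
  edr <- make_edr_network(n = 20, alpha = 0.052, noise_sd = 0, rng_seed = 1)
  d <- as.matrix(dist(edr$positions))
  expected <- exp(-0.052 * d)
  diag(expected) <- 0
  expect_equal(unname(edr$weights), unname(expected), tolerance = 1e-12)
  # strictly decreasing in distance: log-weights perfectly anticorrelated
  ut <- upper.tri(d)
  expect_equal(cor(log(edr$weights[ut]), -d[ut]), 1)
  # the documented spot value: alpha = 0.052 at d = 50 mm
  expect_equal(exp(-0.052 * 50), 0.0743, tolerance = 1e-3)
})

test_that("EDR geometry and weight ranges are valid", {
  edr <- make_edr_network(n = 60, rng_seed = 2)
  w <- edr$weights
  expect_true(all(w[upper.tri(w)] > 0 & w[upper.tri(w)] <= 1))
  expect_equal(w, t(w))
  expect_true(all(diag(w) == 0))
  r <- sqrt(rowSums(edr$positions^2))
  expect_true(all(r >= 48 - 1e-9 & r <= 80 + 1e-9))
  # reproducible
  expect_identical(make_edr_network(n = 60, rng_seed = 2)$weights, w)
})

test_that("synthetic patients satisfy their ground-truth invariants", {
  edr <- make_edr_network(n = 60, rng_seed = 3)
  sf <- make_patient(edr, theta = 0.10, beta = 1e-3, gamma = 1e-3,
                     n_sampled = 25, outcome = "SF", rng_seed = 4)
  expect_true(all(sf$true_seed %in% sf$ra))            # RA contains the seed
  expect_true(all(sf$true_seed %in% sf$sampled_rois))  # seed is sampled
  expect_gte(length(sf$ra), 3)
  expect_lte(length(sf$ra), 13)
  expect_s3_class(sf$seeg_pattern, "seizure_pattern")
  expect_gte(length(sf$seeg_pattern$active), ceiling(0.25 * 25))

  nsf <- make_patient(edr, theta = 0.10, beta = 1e-3, gamma = 1e-3,
                      n_sampled = 25, outcome = "NSF", rng_seed = 5)
  expect_length(intersect(nsf$ra, nsf$true_seed), 0)   # disjoint resection

  # full sampling covers every ROI
  all_s <- make_patient(edr, theta = 0.10, beta = 1e-3, gamma = 1e-3,
                        n_sampled = 60, outcome = "SF", rng_seed = 6)
  expect_setequal(all_s$sampled_rois, rownames(edr$weights))
})

test_that("activation steps are integers starting at 0 with ties preserved", {
  steps <- epispread:::bin_activation_steps(
    c(a = 3.0, b = 3.4, c = 5.1, d = 5.15, e = 9))
  expect_equal(steps, c(a = 0L, b = 0L, c = 1L, d = 1L, e = 2L))
  # a pattern built from them starts at step 0
  edr <- make_edr_network(n = 60, rng_seed = 3)
  pat <- make_patient(edr, theta = 0.10, beta = 1e-3, gamma = 1e-3,
                      n_sampled = 25, rng_seed = 7)
  expect_equal(min(pat$seeg_pattern$steps), 0)
  expect_true(all(pat$seeg_pattern$steps == round(pat$seeg_pattern$steps)))
})

test_that("cohorts are reproducible and mirror the requested group sizes", {
  co <- make_cohort(n_sf = 3, n_nsf = 2, n_nodes = 50, n_sampled = 20,
                    params = list(beta = 1e-3, gamma = 1e-3, theta = 0.10),
                    rng_seed = 11)
  expect_equal(nrow(co$manifest), 5)
  expect_equal(sum(co$manifest$outcome == "SF"), 3)
  expect_equal(sum(co$manifest$outcome == "NSF"), 2)
  co2 <- make_cohort(n_sf = 3, n_nsf = 2, n_nodes = 50, n_sampled = 20,
                     params = list(beta = 1e-3, gamma = 1e-3, theta = 0.10),
                     rng_seed = 11)
  expect_identical(co$manifest, co2$manifest)
  # the manifest suffices to recompute labels without re-simulation
  for (i in seq_len(5)) {
    seed <- strsplit(co$manifest$true_seed[i], ",")[[1]]
    ra <- strsplit(co$manifest$ra[i], ",")[[1]]
    if (co$manifest$outcome[i] == "SF") {
      expect_true(all(seed %in% ra))
    } else {
      expect_length(intersect(seed, ra), 0)
    }
  }
})

test_that("synthetic patients round-trip through the pipeline file formats", {
  edr <- make_edr_network(n = 40, rng_seed = 12)
  pat <- make_patient(edr, theta = 0.10, beta = 1e-3, gamma = 1e-3,
                      n_sampled = 18, rng_seed = 13)
  dir <- file.path(tempdir(), "synthpat")
  write_synthetic_patient(pat, dir)
  w <- read_network_matrix(file.path(dir, "network.tsv"))
  expect_equal(w, pat$raw_weights, tolerance = 1e-12)
  sp <- read_seizure_pattern(file.path(dir, "pattern.tsv"),
                             file.path(dir, "sampled_rois.txt"))
  expect_equal(sort(names(sp$steps)), sort(names(pat$seeg_pattern$steps)))
  expect_setequal(sp$sampled_rois, pat$seeg_pattern$sampled_rois)
  expect_equal(read_node_set(file.path(dir, "resection_area.txt")), pat$ra)
  unlink(dir, recursive = TRUE)
})
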