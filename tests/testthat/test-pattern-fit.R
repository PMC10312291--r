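# handy constructor for a fake simulation result over named ROIs
fake_sim <- function(p, t) {
  structure(list(p_infected = p, mean_activation = t), class = "sir_result")
}

test_that("weighted Pearson reduces to ordinary correlation and handles weights", {
  set.seed(1)
  x <- rnorm(10); y <- rnorm(10)
  expect_equal(weighted_pearson(x, y, rep(1, 10)), cor(x, y))
  expect_equal(weighted_pearson(x, x, runif(10, 0.1, 2)), 1)
  # zero-weight points are dropped: two effective points, opposite order
  expect_equal(weighted_pearson(c(1, 2, 3), c(3, 1, 2), c(1, 1, 0)), -1)
  # degenerate cases
  expect_true(is.na(weighted_pearson(c(1, 2), c(1, 1), c(1, 1))))
  expect_true(is.na(weighted_pearson(1, 1, 1)))
  expect_error(weighted_pearson(x, y, rep(-1, 10)), "nonnegative")
})

test_that("total correlation matches the worked overlap example", {
  seeg <- seizure_pattern(c(a = 1, b = 2), c("a", "b", "c", "d"))
  sim <- fake_sim(c(a = 1, b = 0.5, c = 0.5, d = 0),
                  c(a = 0, b = 1.4, c = 2, d = NA))
  fr <- total_correlation(seeg, sim)
  expect_equal(fr$P_overlap, 0.75)
  expect_equal(fr$C_w, 1)
  expect_equal(fr$C, 0.75)
  expect_false(fr$degenerate)
})

test_that("total correlation is 1 for equal patterns and -1 for reversed order", {
  # binary P_IR exactly on the recorded active set, identical order
  seeg <- seizure_pattern(c(a = 0, b = 1, c = 2), c("a", "b", "c", "d", "e"))
  sim_eq <- fake_sim(c(a = 1, b = 1, c = 1, d = 0, e = 0),
                     c(a = 0, b = 1, c = 2, d = NA, e = NA))
  fr <- total_correlation(seeg, sim_eq)
  expect_equal(fr$P_overlap, 1)
  expect_equal(fr$C, 1)
  # same areas, exactly reversed activation order
  sim_rev <- fake_sim(c(a = 1, b = 1, c = 1, d = 0, e = 0),
                      c(a = 2, b = 1, c = 0, d = NA, e = NA))
  expect_equal(total_correlation(seeg, sim_rev)$C, -1)
})

test_that("C = C_w * P_overlap to machine precision on random patterns", {
  set.seed(42)
  for (rep in 1:25) {
    rois <- paste0("r", 1:12)
    act <- sample(rois, sample(3:8, 1))
    seeg <- seizure_pattern(setNames(sample(0:4, length(act), TRUE), act), rois)
    p <- setNames(runif(12), rois)
    p[act[1:2]] <- 1   # ensure two jointly active ROIs
    t <- setNames(rnorm(12, 5, 2), rois)
    t[p == 0] <- NA
    fr <- total_correlation(seeg, fake_sim(p, t))
    expect_identical(fr$C, fr$C_w * fr$P_overlap)
    expect_true(abs(fr$C_w) <= 1 && fr$P_overlap >= 0 && fr$P_overlap <= 1)
  }
})

test_that("P_overlap equals 1 exactly when P_IR is the indicator of the active set", {
  seeg <- seizure_pattern(c(a = 0, b = 1), c("a", "b", "c"))
  ind <- fake_sim(c(a = 1, b = 1, c = 0), c(a = 0, b = 1, c = NA))
  expect_equal(total_correlation(seeg, ind)$P_overlap, 1)
  off <- fake_sim(c(a = 1, b = 0.99, c = 0), c(a = 0, b = 1, c = NA))
  expect_lt(total_correlation(seeg, off)$P_overlap, 1)
})

test_that("degenerate correlations map to C_w = 0 with a flag", {
  # only one jointly active ROI
  seeg <- seizure_pattern(c(a = 0, b = 1), c("a", "b", "c"))
  sim <- fake_sim(c(a = 1, b = 0, c = 0), c(a = 0, b = NA, c = NA))
  fr <- total_correlation(seeg, sim)
  expect_true(fr$degenerate)
  expect_equal(fr$C_w, 0)
  expect_equal(fr$C, 0)
})

test_that("the SIR pattern restricts a simulation to the sampled ROIs", {
  net <- path3_net()
  sim <- run_sir(net, "A", spread_params(1, 0, T = 5, n_realizations = 20,
                                         rng_seed = 1))
  sp <- sir_pattern(sim, c("A", "C"))
  expect_equal(sp$sampled_rois, c("A", "C"))
  expect_equal(length(sp$p_infected), 2)
  expect_equal(sp$active, c("A", "C"))
  # wavefront ordering equals hop order on the full sample
  sp_all <- sir_pattern(sim, c("A", "B", "C"))
  expect_equal(order(sp_all$mean_activation), 1:3)
  # beta = 0: active set is the sampled part of the seed
  sim0 <- run_sir(net, "A", spread_params(0, 0.5, T = 5, n_realizations = 20,
                                          rng_seed = 2))
  expect_equal(sir_pattern(sim0, c("A", "B"))$active, "A")
  expect_error(sir_pattern(sim, c("A", "Z")), "cover")
})

test_that("a deterministic pattern fitted against itself gives C = 1", {
  net <- star5_net()
  params <- spread_params(1, 0, T = 10, n_realizations = 50, rng_seed = 5)
  sim <- run_sir(net, "L2", params)
  steps <- sim$mean_activation  # integer steps already
  seeg <- seizure_pattern(steps, net$labels)
  expect_equal(total_correlation(seeg, run_sir(net, "L2", params))$C, 1)
})

test_that("fit maps have complete grids and coherent argmax bookkeeping", {
  grid <- default_fit_grid()
  expect_equal(nrow(grid), 80)
  set.seed(2)
  n <- 16
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2)
  m <- m + t(m)
  rois <- paste0("roi_", 1:n)
  dimnames(m) <- list(rois, rois)
  seeg <- seizure_pattern(setNames(0:3, rois[1:4]), rois[1:8])
  small_grid <- default_fit_grid(beta = c(1e-2, 1e-1), gamma = c(1e-2, 1e-1),
                                 kappa_frac = c(0.1, 0.3))
  fm <- fit_patient(m, rois[1:2], seeg, grid = small_grid,
                    n_realizations = 100, T = 50, n_iterations = 3,
                    rng_seed = 3)
  expect_equal(nrow(fm), 8)
  expect_true(all(!is.na(fm$C_mean)))
  b <- attr(fm, "best")
  expect_equal(b$C_mean, max(fm$C_mean))
  expect_equal(b$ratio, b$beta * b$kappa / b$gamma)
})

test_that("population fit averages maps and checks grid compatibility", {
  # two constant maps average to a constant map
  make_const_map <- function(val) {
    g <- default_fit_grid(beta = 1e-2, gamma = c(1e-2, 1e-1),
                          kappa_frac = c(0.1, 0.2))
    g$kappa <- g$kappa_frac * 10
    g$C_mean <- val; g$C_sd <- 0; g$C_w_mean <- NA; g$P_overlap_mean <- NA
    g$degenerate_frac <- 0; g$missing <- FALSE
    class(g) <- c("fit_map", "data.frame")
    attr(g, "best") <- epispread:::fit_map_best(g)
    g
  }
  pop <- population_fit(list(make_const_map(0.2), make_const_map(0.4)))
  expect_equal(pop$C_mean, rep(0.3, nrow(pop)))
  expect_equal(attr(pop, "per_patient_C"), c(0.2, 0.4))
  # a single patient is its own population model
  one <- population_fit(list(make_const_map(0.25)))
  expect_true(all(one$C_mean == 0.25))
  bad <- make_const_map(0.1)
  bad$beta <- bad$beta * 10
  expect_error(population_fit(list(make_const_map(0.1), bad)), "grid")
})

test_that("fit iteration noise shrinks roughly as 1/sqrt(N_R)", {
  net <- cycle4_net()
  seeg <- seizure_pattern(c(n1 = 0, n2 = 1, n3 = 2), net$labels)
  sd_at <- function(nr) {
    cs <- sapply(1:40, function(i) {
      p <- spread_params(0.4, 0.4, T = 30, n_realizations = nr,
                         rng_seed = 1000 + i)
      total_correlation(seeg, run_sir(net, "n1", p))$C
    })
    sd(cs)
  }
  r <- sd_at(50) / sd_at(800)
  expect_gt(r, 2)   # expected factor 4, allow generous noise
  expect_lt(r, 9)
})
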