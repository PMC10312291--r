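test_that("exact enumeration reproduces hand-computed values on the unit path", {
  net <- path3_net()
  p <- spread_params(0.5, 1, T = 5, n_realizations = 1)
  ex <- exact_sir_enumeration(net, "A", p)
  expect_equal(unname(ex$p_infected), c(1, 0.5, 0.25))
  expect_equal(ex$ir, 7 / 12)
  expect_equal(unname(ex$mean_activation[1:2]), c(0, 1))
})

test_that("Monte-Carlo engine agrees with exact enumeration within 3 binomial SEs", {
  fixtures <- list(
    list(net = path3_net(), seed = "A", beta = 0.5, gamma = 1),
    list(net = star5_net(), seed = "L1", beta = 0.6, gamma = 0.5),
    list(net = cycle4_net(), seed = "n1", beta = 0.7, gamma = 0.3),
    list(net = path3_net(), seed = c("A", "C"), beta = 0.3, gamma = 0.4))
  nr <- 10000L
  for (f in fixtures) {
    p <- spread_params(f$beta, f$gamma, T = 5, n_realizations = nr,
                       rng_seed = 99)
    ex <- exact_sir_enumeration(f$net, f$seed, p)
    mc <- run_sir(f$net, f$seed, p)
    expect_true(all(abs(mc$p_infected - ex$p_infected) <=
                      binom_3se(ex$p_infected, nr)),
                info = paste("P_IR deviation on", f$net$n_nodes, "nodes"))
    expect_lt(abs(mc$ir - ex$ir), 3 * mc$ir_sd / sqrt(nr) + 1e-3)
  }
})

test_that("beta = 0 confines the epidemic to the seed in every realization", {
  net <- cycle4_net()
  p <- spread_params(0, 0.5, T = 10, n_realizations = 200, rng_seed = 2)
  res <- run_sir(net, c("n1", "n3"), p)
  expect_true(all(res$sizes == 2 / 4))
  expect_equal(res$ir, 0.5)
  expect_equal(unname(res$p_infected), c(1, 0, 1, 0))
})

test_that("beta = 1, gamma = 0 on unit weights gives a deterministic hop-distance wavefront", {
  star <- star5_net()
  p <- spread_params(1, 0, T = 10, n_realizations = 50, rng_seed = 3)
  res <- run_sir(star, "L1", p)
  expect_true(all(res$p_infected == 1))
  expect_equal(unname(res$mean_activation), c(1, 0, 2, 2, 2))
  expect_true(all(res$sizes == 1))
})

test_that("seed invariants hold: P_IR(seed) = 1, activation 0, IR >= |seed|/n", {
  net <- cycle4_net()
  p <- spread_params(0.2, 0.6, T = 50, n_realizations = 500, rng_seed = 4)
  res <- run_sir(net, "n2", p)
  expect_equal(unname(res$p_infected["n2"]), 1)
  expect_equal(unname(res$mean_activation["n2"]), 0)
  expect_gte(res$ir, 1 / 4)
  expect_gte(min(res$sizes), 1 / 4)
})

test_that("the step-by-step reference process conserves states and agrees with enumeration", {
  net <- path3_net()
  ref <- sync_sir_reference(net, "A", beta = 0.5, gamma = 1, T = 5,
                            n_realizations = 4000, rng_seed = 6)
  expect_true(ref$counts_ok)
  expect_true(ref$transitions_ok)
  expect_true(all(abs(ref$p_infected - c(1, 0.5, 0.25)) <=
                    binom_3se(c(1, 0.5, 0.25), 4000)))
})

test_that("P_IR is monotone non-decreasing in beta", {
  net <- cycle4_net()
  p_lo <- run_sir(net, "n1", spread_params(0.1, 0.5, T = 30,
                                           n_realizations = 4000, rng_seed = 8))
  p_hi <- run_sir(net, "n1", spread_params(0.6, 0.5, T = 30,
                                           n_realizations = 4000, rng_seed = 9))
  expect_true(all(p_hi$p_infected >= p_lo$p_infected -
                    binom_3se(p_lo$p_infected, 4000)))
})

test_that("simulations are bit-identical under a fixed seed", {
  net <- cycle4_net()
  p <- spread_params(0.3, 0.2, T = 50, n_realizations = 300, rng_seed = 123)
  a <- run_sir(net, "n1", p)
  b <- run_sir(net, "n1", p)
  expect_identical(a$p_infected, b$p_infected)
  expect_identical(a$sizes, b$sizes)
  p2 <- spread_params(0.3, 0.2, T = 50, n_realizations = 300, rng_seed = 124)
  expect_false(identical(run_sir(net, "n1", p2)$sizes, a$sizes))
})

test_that("truncation at T is flagged only when spreading could continue", {
  # gamma = 0 and tiny beta: infected nodes persist at T next to susceptibles
  net <- path3_net()
  p <- spread_params(0.05, 0, T = 2, n_realizations = 500, rng_seed = 11)
  res <- run_sir(net, "A", p)
  expect_gt(res$truncated_fraction, 0.5)
  # full saturation: nothing left to infect, no truncation
  p2 <- spread_params(1, 0, T = 5, n_realizations = 50, rng_seed = 12)
  expect_equal(run_sir(net, "A", p2)$truncated_fraction, 0)
})

test_that("beta rescaling follows the out-connectivity ratio and clips", {
  expect_equal(rescale_beta_for_seed(0.05, 30, 30), 0.05)
  expect_equal(rescale_beta_for_seed(0.01, 40, 20), 0.02)
  expect_equal(rescale_beta_for_seed(0.1, 10, 1000), 0.001)
  expect_warning(b <- rescale_beta_for_seed(0.5, 100, 10), "clipped")
  expect_equal(b, 1)
  expect_error(rescale_beta_for_seed(0.1, 10, 0), "cannot spread")
})

test_that("parameter and seed validation reject bad inputs", {
  expect_error(spread_params(1.5, 0.1), NULL)
  expect_error(run_sir(path3_net(), "Z",
                       spread_params(0.1, 0.1, n_realizations = 10)),
               "unknown ROI")
  expect_error(exact_sir_enumeration(star5_net(), "H",
                                     spread_params(0.1, 0.1, T = 50)),
               "n <= 6")
})
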