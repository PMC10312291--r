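# out-connectivity (link count to the rest of the network) of a node set
out_connectivity <- function(net, nodes) {
  idx <- match_nodes(net, nodes)
  sum(net$weights[idx, -idx, drop = FALSE] > 0)
}

# evaluate total correlation for one seed at fixed global parameters,
# rescaling beta by the out-connectivity ratio relative to the RA
evaluate_seed <- function(net, seeg, seed, beta, gamma, e_ra,
                          n_realizations, T, rng_seed) {
  e_seed <- out_connectivity(net, seed)
  if (e_seed == 0) return(NULL)
  b <- suppressWarnings(rescale_beta_for_seed(beta, e_ra, e_seed))
  p <- spread_params(b, gamma, T = T, n_realizations = n_realizations,
                     rng_seed = rng_seed)
  total_correlation(seeg, run_sir(net, seed, p))
}

#' Seed-likelihood map over single ROIs
#'
#' For every ROI R with at least one link, the total correlation `C_R`
#' between the recorded pattern and the simulation with R as the sole
#' epidemic seed, at the patient's best-fit global parameters. Parameters are
#' *not* refitted per seed; only the spreading rate is rescaled by the
#' out-connectivity ratio `E_RA / E_R` so that the initial spreading level is
#' maintained. Isolated ROIs are excluded and flagged.
#'
#' @param net `brain_network` thresholded at the best-fit link density.
#' @param seeg the recorded `seizure_pattern`.
#' @param beta,gamma best-fit global rates (beta as fitted with the RA seed).
#' @param ra resection area (reference seed for the beta rescaling).
#' @param n_realizations,T simulation settings per seed evaluation.
#' @param rng_seed master seed.
#' @return data.frame of class `seed_map`: `roi`, `C_R`, `in_ra`, `excluded`.
#' @export
seed_likelihood_map <- function(net, seeg, beta, gamma, ra,
                                n_realizations = 10000L, T = 1000L,
                                rng_seed = 1L) {
  stopifnot(inherits(net, "brain_network"))
  e_ra <- out_connectivity(net, ra)
  set.seed(rng_seed)
  seeds <- sample.int(.Machine$integer.max, net$n_nodes)
  ra_labels <- net$labels[match_nodes(net, ra)]
  out <- data.frame(roi = net$labels, C_R = NA_real_,
                    in_ra = net$labels %in% ra_labels, excluded = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(net$n_nodes)) {
    fr <- evaluate_seed(net, seeg, net$labels[i], beta, gamma, e_ra,
                        n_realizations, T, seeds[i])
    if (is.null(fr)) out$excluded[i] <- TRUE else out$C_R[i] <- fr$C
  }
  class(out) <- c("seed_map", "data.frame")
  out
}

#' Summaries of alternative seed choices
#'
#' Compares four seed definitions on the same footing: the best single ROI
#' (`best`), the full resection area as one seed (`ra`), the average over RA
#' members as single seeds (`ra_mean`), and the mean over random seeds of the
#' same size as the RA (`rnd`, default 20 draws).
#'
#' @param map a `seed_map` from [seed_likelihood_map()].
#' @inheritParams seed_likelihood_map
#' @param n_random number of random seeds.
#' @return List with `best`, `best_roi`, `ra`, `ra_mean`, `rnd`, `rnd_values`.
#' @export
seed_summaries <- function(map, net, seeg, beta, gamma, ra,
                           n_random = 20L, n_realizations = 10000L,
                           T = 1000L, rng_seed = 1L) {
  if (length(ra) == 0) stop("'ra' must not be empty")
  e_ra <- out_connectivity(net, ra)
  ok <- !map$excluded & !is.na(map$C_R)
  ibest <- which(ok)[which.max(map$C_R[ok])]

  set.seed(rng_seed)
  seeds <- sample.int(.Machine$integer.max, n_random + 1L)
  ra_fit <- evaluate_seed(net, seeg, ra, beta, gamma, e_ra,
                          n_realizations, T, seeds[1])
  set.seed(rng_seed + 1L)
  rnd_values <- vapply(seq_len(n_random), function(k) {
    cand <- sample(net$labels, length(match_nodes(net, ra)))
    fr <- evaluate_seed(net, seeg, cand, beta, gamma, e_ra,
                        n_realizations, T, seeds[k + 1])
    if (is.null(fr)) NA_real_ else fr$C
  }, numeric(1))

  in_ra <- map$roi %in% net$labels[match_nodes(net, ra)]
  list(best = map$C_R[ibest], best_roi = map$roi[ibest],
       ra = if (is.null(ra_fit)) NA_real_ else ra_fit$C,
       ra_mean = mean(map$C_R[in_ra & ok]),
       rnd = mean(rnd_values, na.rm = TRUE), rnd_values = rnd_values)
}

#' Greedy recursive seed optimization
#'
#' Starting from the best single seed, grows the seed one ROI at a time: at
#' each size k every single-node augmentation of the current seed is scored
#' by the total correlation (at a reduced number of realizations for the
#' scan), the best is kept (ties broken by lower ROI index after rounding C
#' to 6 decimals), and the kept seed is re-evaluated at the full number of
#' realizations. Global parameters stay frozen at the patient's best fit;
#' beta is rescaled by seed out-connectivity at every evaluation.
#'
#' @inheritParams seed_likelihood_map
#' @param max_size largest seed size to build (default 5).
#' @param scan_realizations realizations per candidate during the scan.
#' @param start_seed optional starting ROI; defaults to the argmax of a
#'   single-ROI scan.
#' @return data.frame with one row per size: `size`, `members`
#'   (comma-separated), `C`, `C_sd`.
#' @export
recursive_seed_optimization <- function(net, seeg, beta, gamma, ra,
                                        max_size = 5L,
                                        n_realizations = 10000L,
                                        scan_realizations = 1000L,
                                        T = 1000L, rng_seed = 1L,
                                        start_seed = NULL) {
  e_ra <- out_connectivity(net, ra)
  set.seed(rng_seed)
  seed_pool <- sample.int(.Machine$integer.max, 10000L)
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    seed_pool[seed_i]
  }
  score <- function(seed, nr) {
    fr <- evaluate_seed(net, seeg, seed, beta, gamma, e_ra, nr, T, next_seed())
    if (is.null(fr)) NA_real_ else fr$C
  }

  if (is.null(start_seed)) {
    c1 <- vapply(net$labels, function(r) score(r, scan_realizations),
                 numeric(1))
    if (all(is.na(c1))) stop("no single ROI leads to spreading")
    c1r <- round(c1, 6)
    start_seed <- net$labels[which(c1r == max(c1r, na.rm = TRUE))[1]]
  }

  current <- start_seed
  rows <- list()
  repeat {
    full <- replicate(3, score(current, n_realizations))
    rows[[length(rows) + 1L]] <- data.frame(
      size = length(current), members = paste(current, collapse = ","),
      C = mean(full), C_sd = stats::sd(full), stringsAsFactors = FALSE)
    if (length(current) >= max_size) break
    cand <- setdiff(net$labels, current)
    cs <- vapply(cand, function(r) score(c(current, r), scan_realizations),
                 numeric(1))
    if (all(is.na(cs))) break   # no augmentation spreads
    csr <- round(cs, 6)
    current <- c(current, cand[which(csr == max(csr, na.rm = TRUE))[1]])
  }
  do.call(rbind, rows)
}
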