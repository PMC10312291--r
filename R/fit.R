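#' Weighted Pearson correlation
#'
#' `sum(w (x - xw)(y - yw)) / sqrt(sum(w (x - xw)^2) sum(w (y - yw)^2))` with
#' weighted means `xw`, `yw`. With equal weights this reduces to the ordinary
#' Pearson correlation.
#'
#' @param x,y numeric vectors.
#' @param w nonnegative weights.
#' @return The correlation, or `NA` when fewer than two points carry positive
#'   weight or either weighted variance is zero (degenerate case).
#' @export
weighted_pearson <- function(x, y, w) {
  stopifnot(length(x) == length(y), length(x) == length(w))
  if (any(w < 0)) stop("weights must be nonnegative")
  keep <- w > 0 & !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]; w <- w[keep]
  if (length(x) < 2) return(NA_real_)
  xw <- sum(w * x) / sum(w)
  yw <- sum(w * y) / sum(w)
  vx <- sum(w * (x - xw)^2)
  vy <- sum(w * (y - yw)^2)
  if (vx == 0 || vy == 0) return(NA_real_)
  sum(w * (x - xw) * (y - yw)) / sqrt(vx * vy)
}

#' Total correlation between a recorded and a simulated seizure pattern
#'
#' The goodness of fit combines two factors. `C_w` is the weighted Pearson
#' correlation between the activation orders of the ROIs active in *both*
#' patterns (x = recorded activation steps, y = simulated mean activation
#' times), weighted by the fraction of realizations in which each ROI was
#' infected, `P_IR(i)`. `P_overlap` measures the agreement of seizure
#' extension over the `N_SEEG` sampled ROIs:
#' `P_overlap = (sum_{i in S} P_IR(i) + sum_{i in H} (1 - P_IR(i))) / N_SEEG`
#' with S and H the recorded active and inactive sets. The total correlation
#' is `C = C_w * P_overlap`: 1 for exactly equal patterns, 0 for null overlap
#' or correlation, -1 for fully anticorrelated activation orders with equal
#' seizure areas. A degenerate `C_w` (fewer than two jointly active ROIs, or
#' zero variance) is mapped to 0 and flagged.
#'
#' @param seeg a `seizure_pattern` (the recorded pattern).
#' @param sim a `sir_result` covering the pattern's sampled ROIs.
#' @param p_threshold threshold on `P_IR` for simulated-active membership.
#' @return A list of class `fit_result`: `C`, `C_w`, `P_overlap`, `P_act`,
#'   `P_inact`, `degenerate`.
#' @export
total_correlation <- function(seeg, sim, p_threshold = 0) {
  stopifnot(inherits(seeg, "seizure_pattern"))
  sp <- sir_pattern(sim, seeg$sampled_rois, p_threshold)
  p <- sp$p_infected

  both <- intersect(seeg$active, sp$active)
  cw <- weighted_pearson(unname(seeg$steps[both]),
                         unname(sp$mean_activation[both]),
                         unname(p[both]))
  degenerate <- is.na(cw)
  if (degenerate) cw <- 0

  p_act <- sum(p[seeg$active])
  p_inact <- sum(1 - p[seeg$inactive])
  n_seeg <- length(seeg$sampled_rois)
  p_overlap <- (p_act + p_inact) / n_seeg

  structure(list(C = cw * p_overlap, C_w = cw, P_overlap = p_overlap,
                 P_act = p_act / n_seeg, P_inact = p_inact / n_seeg,
                 degenerate = degenerate),
            class = "fit_result")
}

#' Default parameter grid for model fitting
#'
#' Spreading and recovery rates on a decade grid, link densities as fractions
#' of the node count: `beta, gamma in {1e-4, 1e-3, 1e-2, 1e-1}`,
#' `kappa/n in {0.025, 0.05, 0.10, 0.20, 0.30}` (80 points).
#'
#' @param beta,gamma,kappa_frac grid axes.
#' @return data.frame with one row per (kappa_frac, beta, gamma) point.
#' @export
default_fit_grid <- function(beta = 10^(-4:-1), gamma = 10^(-4:-1),
                             kappa_frac = c(0.025, 0.05, 0.10, 0.20, 0.30)) {
  expand.grid(kappa_frac = kappa_frac, beta = beta, gamma = gamma,
              KEEP.OUT.ATTRS = FALSE)
}

#' Fit the propagation model to a patient's seizure pattern
#'
#' Grid search over (kappa, beta, gamma): for each link density the raw
#' weight matrix is thresholded, the SIR process is run from the seed
#' (normally the resection area) and the total correlation with the recorded
#' pattern is computed. Each grid point is evaluated `n_iterations` times
#' with independent realizations; the mean and standard deviation of `C`
#' across iterations are stored.
#'
#' @param weights raw (unthresholded) weight matrix or `brain_network`.
#' @param ra seed node set used for fitting (the resection area).
#' @param seeg the recorded `seizure_pattern`.
#' @param grid data.frame from [default_fit_grid()].
#' @param n_realizations Monte-Carlo realizations per evaluation.
#' @param T maximum steps per realization.
#' @param n_iterations independent fit iterations per grid point.
#' @param rng_seed master seed for the whole grid search.
#' @return A data.frame of class `fit_map` with columns `kappa_frac`,
#'   `kappa`, `beta`, `gamma`, `C_mean`, `C_sd`, `C_w_mean`,
#'   `P_overlap_mean`, `degenerate_frac`, `missing`, plus attributes `best`
#'   (the argmax row, with rescaled rate `beta * kappa` and ratio
#'   `beta * kappa / gamma`) and `n_iterations`.
#' @export
fit_patient <- function(weights, ra, seeg, grid = default_fit_grid(),
                        n_realizations = 10000L, T = 1000L,
                        n_iterations = 10L, rng_seed = 1L) {
  stopifnot(inherits(seeg, "seizure_pattern"), nrow(grid) > 0)
  w <- if (inherits(weights, "brain_network")) weights$weights else weights
  set.seed(rng_seed)
  # one RNG stream for the whole search; per-evaluation seeds drawn from it
  eval_seeds <- sample.int(.Machine$integer.max,
                           nrow(grid) * n_iterations)

  out <- grid
  out$kappa <- NA_real_
  out$C_mean <- NA_real_; out$C_sd <- NA_real_
  out$C_w_mean <- NA_real_; out$P_overlap_mean <- NA_real_
  out$degenerate_frac <- NA_real_
  out$missing <- FALSE

  for (kf in unique(grid$kappa_frac)) {
    net_k <- threshold_network(w, kf)
    rows <- which(grid$kappa_frac == kf)
    ra_idx <- match_nodes(net_k, ra)
    disconnected <- sum(net_k$weights[ra_idx, , drop = FALSE] > 0) == 0
    for (r in rows) {
      out$kappa[r] <- net_k$mean_degree
      if (disconnected) {
        out$missing[r] <- TRUE
        next
      }
      cs <- numeric(n_iterations); cws <- numeric(n_iterations)
      pov <- numeric(n_iterations); dg <- logical(n_iterations)
      for (it in seq_len(n_iterations)) {
        p <- spread_params(grid$beta[r], grid$gamma[r], T = T,
                           n_realizations = n_realizations,
                           rng_seed = eval_seeds[(r - 1) * n_iterations + it])
        fr <- total_correlation(seeg, run_sir(net_k, ra, p))
        cs[it] <- fr$C; cws[it] <- fr$C_w
        pov[it] <- fr$P_overlap; dg[it] <- fr$degenerate
      }
      out$C_mean[r] <- mean(cs)
      out$C_sd[r] <- if (n_iterations > 1) stats::sd(cs) else NA_real_
      out$C_w_mean[r] <- mean(cws)
      out$P_overlap_mean[r] <- mean(pov)
      out$degenerate_frac[r] <- mean(dg)
    }
  }
  class(out) <- c("fit_map", "data.frame")
  attr(out, "n_iterations") <- n_iterations
  attr(out, "best") <- fit_map_best(out)
  out
}

# argmax row of a fit map, with derived rescaled rate and ratio
fit_map_best <- function(map) {
  ok <- which(!map$missing & !is.na(map$C_mean))
  if (length(ok) == 0) stop("fit map has no valid points")
  best <- ok[which.max(map$C_mean[ok])]
  row <- map[best, , drop = FALSE]
  class(row) <- "data.frame"
  row$beta_kappa <- row$beta * row$kappa
  row$ratio <- row$beta * row$kappa / row$gamma
  row
}

#' @export
print.fit_map <- function(x, ...) {
  b <- attr(x, "best")
  cat(sprintf(
    "fit_map: %d grid points; best C = %.3f at beta = %g, gamma = %g, kappa = %.1f\n",
    nrow(x), b$C_mean, b$beta, b$gamma, b$kappa))
  invisible(x)
}

#' Population model: average fit maps across patients
#'
#' Averages the per-patient total correlation at each grid point,
#' `Cbar(beta, gamma, kappa) = mean over patients of C_pat`, and locates the
#' population-optimal parameter triple. Per-patient `C` values at that point
#' are returned for group statistics.
#'
#' @param fitmaps list of `fit_map` objects sharing one grid.
#' @return A `fit_map` of the averaged values, with attributes `best` and
#'   `per_patient_C` (per-patient C at the population optimum).
#' @export
population_fit <- function(fitmaps) {
  stopifnot(length(fitmaps) >= 1)
  key <- function(m) paste(m$kappa_frac, m$beta, m$gamma, sep = "|")
  k0 <- key(fitmaps[[1]])
  for (m in fitmaps[-1])
    if (!identical(key(m), k0)) stop("fit maps do not share a common grid")

  cmat <- vapply(fitmaps, function(m) m$C_mean, numeric(nrow(fitmaps[[1]])))
  cmat <- matrix(cmat, nrow = nrow(fitmaps[[1]]))
  out <- fitmaps[[1]]
  out$C_mean <- rowMeans(cmat, na.rm = TRUE)
  out$C_sd <- apply(cmat, 1, stats::sd)
  out$C_w_mean <- NA_real_; out$P_overlap_mean <- NA_real_
  out$degenerate_frac <- NA_real_
  out$missing <- apply(vapply(fitmaps, function(m) m$missing,
                              logical(nrow(out))), 1, all)
  class(out) <- c("fit_map", "data.frame")
  best <- fit_map_best(out)
  attr(out, "best") <- best
  ibest <- which(out$kappa_frac == best$kappa_frac &
                 out$beta == best$beta & out$gamma == best$gamma)[1]
  attr(out, "per_patient_C") <- cmat[ibest, ]
  out
}
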