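#' Synthetic brain network from the exponential distance rule
#'
#' Generates ROI positions uniformly in a spherical shell (radii chosen so
#' pairwise distances span roughly 0-160 mm, the scale on which the decay
#' exponent alpha is expressed in mm^-1) and couples ROIs with weights
#' `w_ij = exp(-alpha * d_ij) * exp(e)`, `e ~ Normal(0, noise_sd^2)`, clipped
#' to (0, 1\]. At `noise_sd = 0` weights decrease strictly with distance.
#'
#' @param n number of ROIs (default 246, the Brainnetome atlas size).
#' @param alpha exponential decay exponent per mm (default 0.052).
#' @param noise_sd standard deviation of the log-weight noise; the default
#'   1.7 makes distance explain about half the log-weight variance,
#'   matching the agreement between functional-coupling and pure-EDR
#'   matrices these networks emulate.
#' @param rng_seed integer seed.
#' @param radii inner/outer shell radii in mm.
#' @return List with `weights` (symmetric matrix in (0, 1\], zero diagonal,
#'   labelled `roi_1` ...) and `positions` (n x 3 matrix, mm).
#' @export
make_edr_network <- function(n = 246L, alpha = 0.052, noise_sd = 1.7,
                             rng_seed = 1L, radii = c(48, 80)) {
  stopifnot(n >= 10, alpha > 0, noise_sd >= 0)
  set.seed(rng_seed)
  repeat {
    u <- matrix(stats::rnorm(3 * n), n, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- (stats::runif(n, radii[1]^3, radii[2]^3))^(1 / 3)
    pos <- u * r
    d <- as.matrix(stats::dist(pos))
    if (min(d[upper.tri(d)]) > 1e-6) break   # resample coincident points
  }
  logw <- -alpha * d
  if (noise_sd > 0) {
    eps <- matrix(0, n, n)
    eps[upper.tri(eps)] <- stats::rnorm(n * (n - 1) / 2, sd = noise_sd)
    eps <- eps + t(eps)
    logw <- logw + eps
  }
  w <- pmin(exp(logw), 1)
  diag(w) <- 0
  labels <- paste0("roi_", seq_len(n))
  dimnames(w) <- list(labels, labels)
  rownames(pos) <- labels
  list(weights = w, positions = pos)
}

# assign integer activation steps to sorted mean activation times:
# a new step starts when the time leaves the current one-step-wide bin
bin_activation_steps <- function(times) {
  ord <- order(times)
  t_sorted <- times[ord]
  steps <- integer(length(times))
  step <- 0L
  bin_start <- t_sorted[1]
  for (k in seq_along(t_sorted)) {
    if (t_sorted[k] - bin_start >= 1) {
      step <- step + 1L
      bin_start <- t_sorted[k]
    }
    steps[ord[k]] <- step
  }
  stats::setNames(steps, names(times))
}

#' Synthetic patient with known ground truth
#'
#' Builds one virtual patient on top of an EDR network: a spatially
#' contiguous true seed, an electrode sampling biased towards the seed's
#' neighbourhood (mirroring clinical electrode planning around the
#' hypothesized onset zone), an SEEG-style seizure pattern generated by the
#' SIR model at the true parameters (mean activation over a small batch of
#' realizations, discretized to integer steps), and a resection area that
#' either contains the true seed (seizure-free-like, `"SF"`) or is disjoint
#' from it (non-seizure-free-like, `"NSF"`).
#'
#' @param edr list from [make_edr_network()].
#' @param beta,gamma,theta true generating parameters (grid-interior by
#'   default).
#' @param true_seed_size number of contiguous seed ROIs.
#' @param n_sampled number of electrode-sampled ROIs (clinical range 30-60).
#' @param outcome `"SF"` or `"NSF"`.
#' @param ra_size resection-area size (clinical range 3-13; at least
#'   `true_seed_size` for SF patients). Default: drawn from 3-13.
#' @param pattern_realizations batch size for generating the SEEG pattern.
#' @param sampling_bias_mm length scale of the electrode-placement bias.
#' @param T maximum simulation steps.
#' @param rng_seed integer seed.
#' @return A list of class `synthetic_patient`: `network` (thresholded
#'   `brain_network`), `raw_weights`, `positions`, `true_seed`,
#'   `true_params`, `sampled_rois`, `seeg_pattern`, `ra`, `outcome`.
#' @export
make_patient <- function(edr, beta = 1e-2, gamma = 1e-2, theta = 0.10,
                         true_seed_size = 3L, n_sampled = 44L,
                         outcome = c("SF", "NSF"), ra_size = NULL,
                         pattern_realizations = 20L, sampling_bias_mm = 60,
                         T = 1000L, rng_seed = 1L) {
  outcome <- match.arg(outcome)
  set.seed(rng_seed)
  labels <- rownames(edr$weights)
  n <- length(labels)
  stopifnot(n_sampled <= n, true_seed_size >= 1)
  if (is.null(ra_size))
    ra_size <- sample(max(3L, true_seed_size):13L, 1)
  if (outcome == "SF") ra_size <- max(ra_size, true_seed_size)

  net <- threshold_network(edr$weights, theta)

  # patients in a surgery cohort have seizures that demonstrably propagate;
  # resample the configuration until the typical seizure activates a
  # minimal fraction of the sampled ROIs
  min_active <- max(true_seed_size + 2L, ceiling(0.25 * n_sampled))
  seeg <- NULL
  for (attempt in seq_len(25)) {
    # contiguous true seed: a random centre and its spatially nearest ROIs
    centre <- sample.int(n, 1)
    d_centre <- sqrt(colSums((t(edr$positions) - edr$positions[centre, ])^2))
    true_seed <- labels[order(d_centre)[seq_len(true_seed_size)]]

    # electrode sampling: the seed and its closest neighbourhood are always
    # covered; remaining electrodes are biased towards the seed centroid
    seed_centroid <- colMeans(edr$positions[true_seed, , drop = FALSE])
    d_seed <- sqrt(colSums((t(edr$positions) - seed_centroid)^2))
    forced <- labels[order(d_seed)[seq_len(min(true_seed_size + 5L, n_sampled))]]
    rest <- setdiff(labels, forced)
    prob <- exp(-d_seed[match(rest, labels)] / sampling_bias_mm)
    extra <- sample(rest, n_sampled - length(forced), prob = prob)
    sampled <- c(forced, extra)

    # SEEG-style pattern from the model at the true parameters
    p <- spread_params(beta, gamma, T = T,
                       n_realizations = pattern_realizations,
                       rng_seed = (rng_seed + 7919L * attempt) %%
                         .Machine$integer.max)
    sim <- run_sir(net, true_seed, p)
    active_sampled <- intersect(sampled,
                                names(sim$p_infected)[sim$p_infected >= 0.5])
    if (length(active_sampled) >= min_active) break
    if (attempt == 25)
      stop("seizures failed to propagate at the chosen parameters")
    warning("seizure pattern too small (", length(active_sampled),
            " active ROIs); resampling the configuration")
  }
  steps <- bin_activation_steps(sim$mean_activation[active_sampled])
  seeg <- seizure_pattern(steps, sampled)

  if (outcome == "SF") {
    # superset of the seed, padded with its nearest neighbours
    ra <- unique(c(true_seed, labels[order(d_seed)]))[seq_len(ra_size)]
  } else {
    # NSF: resection built around a distant centre, disjoint from the seed
    eligible <- which(d_seed > stats::quantile(d_seed, 0.5))
    alt <- sample(eligible, 1)
    d_alt <- sqrt(colSums((t(edr$positions) - edr$positions[alt, ])^2))
    cand <- setdiff(labels[order(d_alt)], true_seed)
    ra <- cand[seq_len(ra_size)]
  }

  structure(
    list(network = net, raw_weights = edr$weights,
         positions = edr$positions, true_seed = true_seed,
         true_params = list(beta = beta, gamma = gamma, theta = theta),
         sampled_rois = sampled, seeg_pattern = seeg, ra = ra,
         outcome = outcome),
    class = "synthetic_patient")
}

#' Synthetic patient cohort
#'
#' Generates a reproducible cohort of SF-like and NSF-like patients, each on
#' an independent EDR network, with a ground-truth manifest sufficient to
#' recompute every expected label without re-simulation. The default shape
#' (11 SF + 4 NSF) mirrors a clinical surgery cohort.
#'
#' @param n_sf,n_nsf numbers of SF-like and NSF-like patients.
#' @param n_nodes ROIs per network.
#' @param params shared true parameters: list with `beta`, `gamma`, `theta`,
#'   applied to every patient; or a list of such lists, one per patient.
#' @param rng_seed master seed; patient i uses a derived sub-seed.
#' @param alpha,noise_sd EDR generator settings (see [make_edr_network()]).
#' @param ... further arguments passed to [make_patient()]
#'   (`true_seed_size`, `n_sampled`, `pattern_realizations`, `T`, ...).
#' @return List with `patients` (list of `synthetic_patient`) and `manifest`
#'   (data.frame: patient, outcome, true parameters, seed and RA members,
#'   n_sampled).
#' @export
make_cohort <- function(n_sf = 11L, n_nsf = 4L, n_nodes = 246L,
                        params = list(beta = 1e-2, gamma = 1e-2, theta = 0.10),
                        rng_seed = 1L, alpha = 0.052, noise_sd = 1.7,
                        ...) {
  n_pat <- n_sf + n_nsf
  stopifnot(n_pat >= 2)
  shared <- !is.null(params$beta)
  outcomes <- c(rep("SF", n_sf), rep("NSF", n_nsf))
  patients <- vector("list", n_pat)
  rows <- vector("list", n_pat)
  for (i in seq_len(n_pat)) {
    pp <- if (shared) params else params[[i]]
    sub_seed <- (rng_seed + 104729L * i) %% .Machine$integer.max
    edr <- make_edr_network(n = n_nodes, alpha = alpha, noise_sd = noise_sd,
                            rng_seed = sub_seed)
    pat <- make_patient(edr, beta = pp$beta, gamma = pp$gamma,
                        theta = pp$theta, outcome = outcomes[i],
                        rng_seed = sub_seed + 1L, ...)
    patients[[i]] <- pat
    rows[[i]] <- data.frame(
      patient = paste0("P", i), outcome = outcomes[i],
      beta = pp$beta, gamma = pp$gamma, theta = pp$theta,
      true_seed = paste(pat$true_seed, collapse = ","),
      ra = paste(pat$ra, collapse = ","),
      n_sampled = length(pat$sampled_rois),
      stringsAsFactors = FALSE)
  }
  list(patients = patients, manifest = do.call(rbind, rows))
}

#' Write a synthetic patient to disk in the pipeline's file formats
#'
#' Writes the raw weight matrix, the seizure-pattern table plus sampled-ROI
#' list, the resection-area node set, and a ground-truth JSON manifest.
#'
#' @param patient a `synthetic_patient`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_synthetic_patient <- function(patient, dir) {
  stopifnot(inherits(patient, "synthetic_patient"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_network_matrix(patient$raw_weights, file.path(dir, "network.tsv"))
  write_seizure_pattern(patient$seeg_pattern,
                        file.path(dir, "pattern.tsv"),
                        file.path(dir, "sampled_rois.txt"))
  write_node_set(patient$ra, file.path(dir, "resection_area.txt"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    manifest <- list(outcome = patient$outcome,
                     true_seed = patient$true_seed,
                     true_params = patient$true_params,
                     ra = patient$ra)
    jsonlite::write_json(manifest, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(dir)
}
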