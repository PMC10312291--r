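#' Effect of a virtual resection on spreading
#'
#' Simulates the SIR process from the same seed on the baseline network and
#' on the network with every link incident to the resection area set to zero,
#' with identical parameters, and quantifies the effect as the normalized
#' decrease in spreading `delta_R = (IR_0 - IR_R) / IR_0`, where `IR` is the
#' mean fraction of nodes ever infected. All network covariates used in the
#' resection analysis are computed alongside: metrics of the RA (baseline),
#' of the seed (baseline, post-resection, and decrease `pre - post`), and of
#' the whole network (clustering and efficiency, same three scenarios).
#'
#' @param net baseline `brain_network` (thresholded at the best-fit density).
#' @param ra resection area node set.
#' @param seed epidemic seed node set (seed nodes remain infected as seed
#'   even if the resection disconnects them).
#' @param params a `spread_params` object used for both runs.
#' @return A list of class `resection_outcome`: `ir_0`, `ir_r`, `delta_R`,
#'   `floor_case` (seed fully isolated by the resection), and `covariates`
#'   (named numeric vector: `S_RA`, `E_RA`, `BC_RA`, `c_RA`, `F_RA`;
#'   `S_seed`, `E_seed`, `BC_seed`, `c_seed`, `F_seed` plus their `_post` and
#'   `d`-prefixed decreases; `c_netw`, `F_netw` likewise).
#' @export
virtual_resection_effect <- function(net, ra, seed, params) {
  stopifnot(inherits(net, "brain_network"), inherits(params, "spread_params"))
  if (length(ra) == 0) {
    res_net <- net
  } else {
    res_net <- resect(net, ra)
  }
  base <- run_sir(net, seed, params)
  post <- run_sir(res_net, seed, params)
  delta <- (base$ir - post$ir) / base$ir

  m_ra <- if (length(ra) > 0) node_set_metrics(net, ra) else
    list(S = 0, E = 0, BC = 0, c = 0, F = 0)
  m_seed0 <- node_set_metrics(net, seed)
  m_seedR <- node_set_metrics(res_net, seed)
  m_net0 <- node_set_metrics(net)
  m_netR <- node_set_metrics(res_net)

  cov <- c(
    S_RA = m_ra$S, E_RA = m_ra$E, BC_RA = m_ra$BC, c_RA = m_ra$c,
    F_RA = m_ra$F,
    S_seed = m_seed0$S, E_seed = m_seed0$E, BC_seed = m_seed0$BC,
    c_seed = m_seed0$c, F_seed = m_seed0$F,
    E_seed_post = m_seedR$E, BC_seed_post = m_seedR$BC,
    c_seed_post = m_seedR$c, F_seed_post = m_seedR$F,
    dE_seed = m_seed0$E - m_seedR$E, dBC_seed = m_seed0$BC - m_seedR$BC,
    dc_seed = m_seed0$c - m_seedR$c, dF_seed = m_seed0$F - m_seedR$F,
    c_netw = m_net0$c, F_netw = m_net0$F,
    c_netw_post = m_netR$c, F_netw_post = m_netR$F,
    dc_netw = m_net0$c - m_netR$c, dF_netw = m_net0$F - m_netR$F)

  structure(
    list(ir_0 = base$ir, ir_r = post$ir, delta_R = delta,
         floor_case = m_seedR$E == 0 && length(ra) > 0,
         covariates = cov),
    class = "resection_outcome")
}

#' Pairwise covariate correlations with the resection effect
#'
#' Pearson correlation of each covariate with `log(delta_R)` across
#' observations (patients x seed sizes pooled). Non-positive `delta_R`
#' values, possible from sampling noise at tiny effects, are floored at one
#' tenth of the smallest positive observed value and flagged. Constant
#' covariates are skipped with a note.
#'
#' @param outcomes data.frame with a `delta_R` column and one column per
#'   covariate.
#' @param covariates covariate column names (default: all except `delta_R`
#'   and id-like columns `patient`, `seed_size`).
#' @return data.frame: `covariate`, `sign`, `r2`, `p`, `skipped`.
#' @export
resection_covariate_scan <- function(outcomes, covariates = NULL) {
  if (is.null(covariates))
    covariates <- setdiff(names(outcomes),
                          c("delta_R", "log_delta_R", "patient", "seed_size"))
  y <- log_delta(outcomes$delta_R)
  out <- data.frame(covariate = covariates, sign = NA_character_,
                    r2 = NA_real_, p = NA_real_, skipped = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(covariates)) {
    x <- outcomes[[covariates[i]]]
    if (stats::var(x) == 0) {
      out$skipped[i] <- TRUE
      next
    }
    ct <- stats::cor.test(x, y)
    out$sign[i] <- ifelse(unname(ct$estimate) >= 0, "+", "-")
    out$r2[i] <- unname(ct$estimate)^2
    out$p[i] <- ct$p.value
  }
  out
}

# log delta_R with flooring of non-positive values (sampling noise)
log_delta <- function(delta) {
  pos <- delta[delta > 0]
  if (length(pos) == 0) stop("no positive resection effects to log-transform")
  floor_val <- min(pos) / 10
  n_floored <- sum(delta <= 0)
  if (n_floored > 0)
    warning(n_floored, " non-positive delta_R value(s) floored at ",
            signif(floor_val, 3))
  log(pmax(delta, floor_val))
}

#' Stepwise linear regression with partial-F entry/removal
#'
#' Bidirectional stepwise selection on linear terms only: at each round the
#' candidate with the smallest partial-F p-value enters if p < `p_enter`,
#' then terms whose partial-F p-value exceeds `p_remove` are removed (worst
#' first), until the model is stable. Collinear covariates are dropped with a
#' warning before selection. For single-degree-of-freedom terms the partial F
#' test equals the squared-t test reported by `drop1`.
#'
#' @param response numeric response (e.g. `log(delta_R)`).
#' @param covariates data.frame of candidate covariates (complete cases).
#' @param p_enter,p_remove entry and removal thresholds (0.05 / 0.10).
#' @return List with `model` (the selected `lm`), `selected`, `dropped_collinear`,
#'   `r2`, `adj_r2`, `f_statistic`, `p_value`, `n`.
#' @export
stepwise_regression <- function(response, covariates,
                                p_enter = 0.05, p_remove = 0.10) {
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(response))
  if (any(is.na(response)) || any(is.na(covariates)))
    stop("complete cases required")
  dat <- cbind(.y = response, covariates)

  # drop exactly collinear covariates up front
  mm <- stats::model.matrix(~ ., data = covariates)
  q <- qr(mm)
  dropped <- character(0)
  if (q$rank < ncol(mm)) {
    keep_cols <- colnames(mm)[q$pivot[seq_len(q$rank)]]
    dropped <- setdiff(colnames(mm), c(keep_cols, "(Intercept)"))
    warning("dropping collinear covariate(s): ", paste(dropped, collapse = ", "))
    covariates <- covariates[, setdiff(names(covariates), dropped),
                             drop = FALSE]
    dat <- cbind(.y = response, covariates)
  }
  candidates <- names(covariates)

  partial_f_p <- function(small, big) {
    a <- stats::anova(small, big)
    a[["Pr(>F)"]][2]
  }
  fit_terms <- function(terms) {
    fml <- if (length(terms) == 0) .y ~ 1
           else stats::reformulate(terms, response = ".y")
    stats::lm(fml, data = dat)
  }

  selected <- character(0)
  repeat {
    changed <- FALSE
    # forward step
    pool <- setdiff(candidates, selected)
    if (length(pool) > 0) {
      base_fit <- fit_terms(selected)
      ps <- vapply(pool, function(v)
        partial_f_p(base_fit, fit_terms(c(selected, v))), numeric(1))
      if (min(ps, na.rm = TRUE) < p_enter) {
        selected <- c(selected, pool[which.min(ps)])
        changed <- TRUE
      }
    }
    # backward step
    repeat {
      if (length(selected) == 0) break
      full_fit <- fit_terms(selected)
      ps <- vapply(selected, function(v)
        partial_f_p(fit_terms(setdiff(selected, v)), full_fit), numeric(1))
      if (max(ps, na.rm = TRUE) > p_remove) {
        selected <- setdiff(selected, selected[which.max(ps)])
        changed <- TRUE
      } else break
    }
    if (!changed) break
  }

  model <- fit_terms(selected)
  sm <- summary(model)
  fstat <- if (length(selected) > 0) unname(sm$fstatistic[1]) else NA_real_
  pval <- if (length(selected) > 0)
    stats::pf(sm$fstatistic[1], sm$fstatistic[2], sm$fstatistic[3],
              lower.tail = FALSE) else NA_real_
  list(model = model, selected = selected, dropped_collinear = dropped,
       r2 = sm$r.squared, adj_r2 = sm$adj.r.squared,
       f_statistic = fstat, p_value = unname(pval), n = length(response))
}
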