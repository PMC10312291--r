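#' Spreading-process parameters
#'
#' @param beta global spreading rate in \[0, 1\]; an infected node i infects a
#'   susceptible neighbour j in one step with probability `beta * w_ij`.
#' @param gamma global recovery rate in \[0, 1\].
#' @param T maximum number of steps per realization.
#' @param n_realizations number of Monte-Carlo realizations N_R.
#' @param rng_seed integer master seed for the simulation.
#' @return A list of class `spread_params`.
#' @export
spread_params <- function(beta, gamma, T = 1000L, n_realizations = 10000L,
                          rng_seed = 1L) {
  stopifnot(beta >= 0, beta <= 1, gamma >= 0, gamma <= 1,
            T >= 1, n_realizations >= 1)
  structure(list(beta = beta, gamma = gamma, T = as.integer(T),
                 n_realizations = as.integer(n_realizations),
                 rng_seed = as.integer(rng_seed)),
            class = "spread_params")
}

#' Simulate SIR seizure spreading on a brain network
#'
#' Runs `n_realizations` independent realizations of the discrete-time
#' stochastic SIR process from the seed set. In each step, every node that is
#' infected at the start of the step attempts to infect each susceptible
#' neighbour independently with probability `beta * w_ij`; nodes infected
#' before the step then recover with probability `gamma` (a node cannot
#' recover in the step it was infected). A realization ends when no infected
#' node remains, when spreading can no longer continue, or at step `T`.
#'
#' @param net a `brain_network`.
#' @param seed nonempty node set (labels or indices) infected at step 0.
#' @param params a `spread_params` object.
#' @return A list of class `sir_result` with per-ROI `p_infected` (fraction
#'   of realizations in which the ROI was ever infected), `mean_activation`
#'   (mean first-infection step over the realizations in which the ROI was
#'   infected; `NA` where never infected), `ir` (mean fraction of nodes ever
#'   infected), `ir_sd`, `sizes` (per-realization fractions), and
#'   `truncated_fraction` (realizations stopped at `T` while spreading was
#'   still possible).
#' @export
run_sir <- function(net, seed, params) {
  stopifnot(inherits(net, "brain_network"), inherits(params, "spread_params"))
  idx <- match_nodes(net, seed)
  if (length(idx) == 0) stop("'seed' must be a nonempty node set")
  set.seed(params$rng_seed)
  raw <- sir_engine(net$weights, idx - 1L, params$beta, params$gamma,
                    params$T, params$n_realizations)
  names(raw$p_infected) <- net$labels
  names(raw$mean_activation) <- net$labels
  structure(
    list(p_infected = raw$p_infected,
         mean_activation = raw$mean_activation,
         ir = mean(raw$sizes), ir_sd = stats::sd(raw$sizes),
         sizes = raw$sizes,
         truncated_fraction = raw$truncated_fraction,
         seed = net$labels[idx], params = params),
    class = "sir_result")
}

#' Serialize a simulation result to a tidy table
#'
#' @param x a `sir_result`.
#' @param ... unused.
#' @return data.frame with columns `roi`, `p_infected`, `mean_activation`.
#' @export
as.data.frame.sir_result <- function(x, ...) {
  data.frame(roi = names(x$p_infected),
             p_infected = unname(x$p_infected),
             mean_activation = unname(x$mean_activation),
             stringsAsFactors = FALSE)
}

#' Exact SIR outcome distribution by state-space enumeration
#'
#' Sums over every stochastic branch of the discrete-time SIR process with
#' its probability, under the same step ordering as [run_sir()]. Feasible
#' only for tiny instances; used as the independent oracle for the
#' Monte-Carlo engine.
#'
#' @inheritParams run_sir
#' @return A list of class `sir_result` with exact `p_infected`,
#'   `mean_activation` and `ir`.
#' @export
exact_sir_enumeration <- function(net, seed, params) {
  stopifnot(inherits(net, "brain_network"), inherits(params, "spread_params"))
  n <- net$n_nodes
  if (n > 6 || params$T > 6)
    stop("exact enumeration requires n <= 6 and T <= 6")
  idx <- match_nodes(net, seed)
  if (length(idx) == 0) stop("'seed' must be a nonempty node set")
  w <- net$weights
  beta <- params$beta; gamma <- params$gamma; Tmax <- params$T

  p_inf <- numeric(n)      # P(ever infected)
  t_sum <- numeric(n)      # E[first-infection step ; infected]
  ir_sum <- 0

  absorb <- function(prob, tinf) {
    inf <- tinf >= 0
    p_inf <<- p_inf + prob * inf
    t_sum <<- t_sum + prob * ifelse(inf, tinf, 0)
    ir_sum <<- ir_sum + prob * sum(inf) / n
  }

  # state: integer vector (0 S, 1 I, 2 R), tinf first-infection steps
  recurse <- function(state, tinf, t, prob) {
    inf_nodes <- which(state == 1L)
    if (length(inf_nodes) == 0 || t == Tmax) {
      absorb(prob, tinf)
      return(invisible())
    }
    sus <- which(state == 0L)
    # per-susceptible infection probability this step
    p_i <- vapply(sus, function(i)
      1 - prod(1 - beta * w[i, inf_nodes]), numeric(1))
    at_risk <- sus[p_i > 0]
    p_i <- p_i[p_i > 0]
    if (length(at_risk) == 0 && gamma == 0) {
      absorb(prob, tinf)   # nothing can ever change
      return(invisible())
    }
    # branch over infection outcomes (subsets of at-risk nodes)
    n_risk <- length(at_risk)
    for (mask in seq_len(2^n_risk) - 1L) {
      hit <- as.logical(bitwAnd(mask, 2^(seq_len(n_risk) - 1L)))
      p_infection <- prod(ifelse(hit, p_i, 1 - p_i))
      if (p_infection == 0) next
      # branch over recovery outcomes of previously infected nodes
      n_old <- length(inf_nodes)
      for (rmask in seq_len(2^n_old) - 1L) {
        rec <- as.logical(bitwAnd(rmask, 2^(seq_len(n_old) - 1L)))
        p_recovery <- prod(ifelse(rec, gamma, 1 - gamma))
        if (p_recovery == 0) next
        st2 <- state; ti2 <- tinf
        st2[at_risk[hit]] <- 1L
        ti2[at_risk[hit]] <- t + 1L
        st2[inf_nodes[rec]] <- 2L
        recurse(st2, ti2, t + 1L, prob * p_infection * p_recovery)
      }
    }
    invisible()
  }

  state <- integer(n); tinf <- rep(-1L, n)
  state[idx] <- 1L; tinf[idx] <- 0L
  recurse(state, tinf, 0L, 1)

  mean_act <- ifelse(p_inf > 0, t_sum / p_inf, NA_real_)
  names(p_inf) <- net$labels
  names(mean_act) <- net$labels
  structure(
    list(p_infected = p_inf, mean_activation = mean_act,
         ir = ir_sum, ir_sd = NA_real_, sizes = NULL,
         truncated_fraction = NA_real_,
         seed = net$labels[idx], params = params),
    class = "sir_result")
}

#' Rescale the spreading rate by seed out-connectivity
#'
#' When a seed other than the resection area is used, the spreading rate is
#' rescaled by the ratio of out-connectivities so that the initial spreading
#' level is comparable: `beta * E_ra / E_seed`, clipped to \[0, 1\].
#'
#' @param beta spreading rate fitted with the resection area as seed.
#' @param e_ra out-connectivity (link count) of the resection area.
#' @param e_seed out-connectivity of the candidate seed; must be positive.
#' @return Rescaled spreading rate.
#' @export
rescale_beta_for_seed <- function(beta, e_ra, e_seed) {
  if (e_seed <= 0) stop("seed has no outgoing links and cannot spread")
  b <- beta * e_ra / e_seed
  if (b > 1) {
    warning("rescaled beta clipped to 1")
    b <- 1
  }
  b
}
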