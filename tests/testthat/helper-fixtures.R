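# tiny graph fixtures, built in code

# path A - B - C with unit weights
path3_net <- function() {
  w <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  w["A", "B"] <- w["B", "A"] <- 1
  w["B", "C"] <- w["C", "B"] <- 1
  brain_network(w)
}

# star K_{1,4}: hub H with 4 leaves, unit weights
star5_net <- function() {
  labs <- c("H", "L1", "L2", "L3", "L4")
  w <- matrix(0, 5, 5, dimnames = list(labs, labs))
  w["H", c("L1", "L2", "L3", "L4")] <- 1
  w <- pmax(w, t(w))
  brain_network(w)
}

triangle_net <- function() {
  w <- matrix(1, 3, 3) - diag(3)
  brain_network(w, labels = c("A", "B", "C"))
}

# weighted 4-cycle with distinct weights
cycle4_net <- function() {
  labs <- paste0("n", 1:4)
  w <- matrix(0, 4, 4, dimnames = list(labs, labs))
  w["n1", "n2"] <- 0.9; w["n2", "n3"] <- 0.6
  w["n3", "n4"] <- 0.8; w["n4", "n1"] <- 0.4
  w <- pmax(w, t(w))
  brain_network(w)
}

# 4-node complete graph with 6 distinct weights
complete4_mat <- function() {
  labs <- paste0("r", 1:4)
  w <- matrix(0, 4, 4, dimnames = list(labs, labs))
  w[upper.tri(w)] <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.5)
  w + t(w)
}

# independent step-by-step reference SIR simulator; tracks per-step state
# counts so conservation and the S -> I -> R transition order can be checked
sync_sir_reference <- function(net, seed, beta, gamma, T, n_realizations,
                               rng_seed = 1) {
  set.seed(rng_seed)
  w <- net$weights
  n <- nrow(w)
  idx <- match(seed, net$labels)
  p_count <- numeric(n)
  counts_ok <- TRUE
  transitions_ok <- TRUE
  sizes <- numeric(n_realizations)
  for (r in seq_len(n_realizations)) {
    state <- rep("S", n); state[idx] <- "I"
    ever <- state == "I"
    for (t in seq_len(T)) {
      infected <- which(state == "I")
      if (length(infected) == 0) break
      prev <- state
      for (i in infected) {
        for (j in which(state == "S" & w[i, ] > 0)) {
          if (stats::runif(1) < beta * w[i, j]) { state[j] <- "I"; ever[j] <- TRUE }
        }
      }
      for (i in infected) if (stats::runif(1) < gamma) state[i] <- "R"
      counts_ok <- counts_ok &&
        sum(state %in% c("S", "I", "R")) == n
      # legal transitions only: S->S/I, I->I/R, R->R
      legal <- (prev == "S" & state %in% c("S", "I")) |
               (prev == "I" & state %in% c("I", "R")) |
               (prev == "R" & state == "R")
      transitions_ok <- transitions_ok && all(legal)
    }
    p_count <- p_count + ever
    sizes[r] <- mean(ever)
  }
  list(p_infected = stats::setNames(p_count / n_realizations, net$labels),
       ir = mean(sizes), sizes = sizes,
       counts_ok = counts_ok, transitions_ok = transitions_ok)
}

# binomial three-standard-error band for a Monte-Carlo probability estimate
binom_3se <- function(p, n) 3 * sqrt(pmax(p * (1 - p), 1e-12) / n)
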