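#' Graph metrics for a node set
#'
#' Computes the covariates used in the virtual-resection analysis for a node
#' set X: size `S` (number of nodes), out-connectivity `E` (number of links
#' with exactly one endpoint in X), and the averages over X of per-node
#' betweenness centrality `BC`, weighted clustering `c`, and efficiency `F`.
#'
#' Conventions for correlation-weight graphs: path length of a link (i, j) is
#' 1/w_ij; the efficiency of node i is the mean over j != i of 1/d(i, j) with
#' d the weighted shortest-path distance (disconnected pairs contribute 0);
#' betweenness is the unnormalized shortest-path count over connected pairs;
#' clustering is the Onnela geometric-mean triangle intensity, which is
#' bounded in \[0, 1\] and reduces to the binary clustering coefficient on
#' unit weights.
#'
#' @param net a `brain_network`.
#' @param nodes node set X (labels or indices); `NULL` selects the whole
#'   network, for which only the network averages `c` and `F` are meaningful
#'   (`E` is returned as `NA`).
#' @return A list with elements `S`, `E`, `BC`, `c`, `F`.
#' @export
node_set_metrics <- function(net, nodes = NULL) {
  stopifnot(inherits(net, "brain_network"))
  whole <- is.null(nodes)
  idx <- if (whole) seq_len(net$n_nodes) else match_nodes(net, nodes)
  if (length(idx) == 0) stop("node set must not be empty")

  w <- net$weights
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  lengths <- 1 / igraph::E(g)$weight

  bc <- igraph::betweenness(g, weights = lengths, directed = FALSE)
  d <- igraph::distances(g, weights = lengths)
  inv_d <- 1 / d
  diag(inv_d) <- NA              # exclude self-distances
  inv_d[is.infinite(d)] <- 0     # disconnected pairs contribute 0
  eff <- rowMeans(inv_d, na.rm = TRUE)
  cc <- onnela_clustering(w)

  e_out <- if (whole) NA_real_ else {
    sum(w[idx, -idx, drop = FALSE] > 0)
  }
  list(S = length(idx), E = e_out,
       BC = mean(bc[idx]), c = mean(cc[idx]), F = mean(eff[idx]))
}

# Onnela-type weighted clustering: c_i = (Wh^(1/3))^3 _ii / (k_i (k_i - 1)),
# with Wh = W / max(W) and k_i the binary degree; 0 where k_i < 2.
onnela_clustering <- function(w) {
  k <- rowSums(w > 0)
  mx <- max(w)
  if (mx == 0) return(rep(0, nrow(w)))
  wh <- (w / mx)^(1 / 3)
  tri <- diag(wh %*% wh %*% wh)
  out <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  as.numeric(out)
}
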