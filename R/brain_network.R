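#' Weighted brain network
#'
#' A `brain_network` holds a symmetric, non-negative weight matrix over ROIs
#' (region-of-interest nodes) together with its link density and mean degree.
#' Weights are functional-coupling strengths in \[0, 1\]; the diagonal is zero.
#'
#' @param weights symmetric numeric matrix, values in \[0, 1\], zero diagonal.
#' @param labels optional character vector of ROI labels; defaults to the
#'   matrix dimnames or `"roi_1"`, `"roi_2"`, ...
#' @param density link density theta recorded for this network (`NA` for an
#'   unthresholded matrix).
#'
#' @return An object of class `brain_network` with elements `weights`,
#'   `labels`, `n_nodes`, `density` (theta), and `mean_degree` (kappa =
#'   2L/n over retained links).
#' @export
brain_network <- function(weights, labels = NULL, density = NA_real_) {
  if (!is.matrix(weights) || nrow(weights) != ncol(weights))
    stop("'weights' must be a square matrix")
  if (any(is.na(weights)))
    stop("'weights' must not contain NA")
  if (any(weights < 0) || any(weights > 1))
    stop("weights must lie in [0, 1]")
  if (max(abs(weights - t(weights))) > 1e-12)
    stop("'weights' must be symmetric")
  if (any(diag(weights) != 0))
    stop("diagonal of 'weights' must be exactly zero")
  n <- nrow(weights)
  if (is.null(labels)) {
    labels <- rownames(weights)
    if (is.null(labels)) labels <- paste0("roi_", seq_len(n))
  }
  if (length(labels) != n) stop("'labels' length must match matrix dimension")
  dimnames(weights) <- list(labels, labels)
  n_links <- sum(weights[upper.tri(weights)] > 0)
  structure(
    list(weights = weights, labels = labels, n_nodes = n,
         density = density, mean_degree = 2 * n_links / n),
    class = "brain_network")
}

#' @export
print.brain_network <- function(x, ...) {
  cat(sprintf("brain_network: %d ROIs, %d links (kappa = %.2f, theta = %s)\n",
              x$n_nodes, round(x$mean_degree * x$n_nodes / 2), x$mean_degree,
              ifelse(is.na(x$density), "NA", format(x$density))))
  invisible(x)
}

#' Rescale a correlation matrix to coupling weights
#'
#' Maps correlation values r in \[-1, 1\] linearly to coupling weights
#' (r + 1)/2 in \[0, 1\], so that 0.5 means no coupling, 1 perfect
#' correlation and 0 perfect anticorrelation. The diagonal is set to zero.
#'
#' @param raw_matrix symmetric matrix of correlation values in \[-1, 1\].
#' @return Matrix of weights in \[0, 1\] with zero diagonal.
#' @export
rescale_coupling <- function(raw_matrix) {
  if (any(raw_matrix < -1 | raw_matrix > 1, na.rm = TRUE))
    stop("correlation values must lie in [-1, 1]")
  w <- (raw_matrix + 1) / 2
  diag(w) <- 0
  w
}

#' Threshold a weight matrix at a link density
#'
#' Keeps the `round(theta * n(n-1)/2)` largest-weight links and sets all
#' others to zero; retained links keep their weights (thresholded, not
#' binarized). Ties at the cutoff weight are broken deterministically by
#' (weight descending, node-pair lexicographic).
#'
#' @param x square symmetric weight matrix or a `brain_network`.
#' @param theta link density in (0, 1\]: fraction of possible links retained.
#' @return A `brain_network` with `density = theta` and the implied kappa.
#' @export
threshold_network <- function(x, theta) {
  w <- if (inherits(x, "brain_network")) x$weights else x
  labels <- if (inherits(x, "brain_network")) x$labels else rownames(w)
  if (!is.numeric(theta) || length(theta) != 1 || theta <= 0 || theta > 1)
    stop("'theta' must be a single value in (0, 1]")
  n <- nrow(w)
  n_keep <- round(theta * n * (n - 1) / 2)
  ut <- which(upper.tri(w))
  pos <- ut[w[ut] > 0]
  if (n_keep < 1 || length(pos) == 0)
    stop("thresholding at theta = ", theta, " leaves no links")
  n_keep <- min(n_keep, length(pos))
  # stable order: weight descending, then (row, col) lexicographic
  rows <- ((pos - 1) %% n) + 1
  cols <- ((pos - 1) %/% n) + 1
  ord <- order(-w[pos], rows, cols)
  keep <- pos[ord[seq_len(n_keep)]]
  out <- matrix(0, n, n)
  out[keep] <- w[keep]
  out <- out + t(out)
  dimnames(out) <- dimnames(w)
  brain_network(out, labels = labels, density = theta)
}

#' Virtually resect a node set
#'
#' Returns a copy of the network in which every link incident to the
#' resection set `ra` has weight zero. Nodes are kept in the graph, so node
#' counts and metric denominators are unchanged.
#'
#' @param net a `brain_network`.
#' @param ra character or integer vector of ROIs to disconnect (may be empty).
#' @return A `brain_network` with the same density annotation.
#' @export
resect <- function(net, ra) {
  stopifnot(inherits(net, "brain_network"))
  idx <- match_nodes(net, ra)
  if (length(idx) == net$n_nodes)
    warning("resecting all nodes: the resulting network is edgeless")
  w <- net$weights
  w[idx, ] <- 0
  w[, idx] <- 0
  brain_network(w, labels = net$labels, density = net$density)
}

# resolve node identifiers (labels or indices) to integer indices
match_nodes <- function(net, nodes) {
  if (length(nodes) == 0) return(integer(0))
  if (is.character(nodes)) {
    idx <- match(nodes, net$labels)
    if (any(is.na(idx))) stop("unknown ROI labels: ",
                              paste(nodes[is.na(idx)], collapse = ", "))
  } else {
    idx <- as.integer(nodes)
    if (any(idx < 1 | idx > net$n_nodes)) stop("node index out of range")
  }
  idx
}

#' Read / write a square weight matrix
#'
#' The on-disk format is a whitespace- or comma-delimited square matrix with
#' a header row of ROI labels. ROI labels are opaque strings.
#'
#' @param path file path.
#' @return `read_network_matrix` returns a labelled numeric matrix.
#' @export
read_network_matrix <- function(path) {
  sep <- if (grepl(",", readLines(path, n = 1L))) "," else ""
  df <- utils::read.table(path, header = TRUE, check.names = FALSE,
                          sep = sep, comment.char = "")
  m <- as.matrix(df)
  rownames(m) <- colnames(m)
  storage.mode(m) <- "double"
  m
}

#' @rdname read_network_matrix
#' @param m matrix to write.
#' @export
write_network_matrix <- function(m, path) {
  utils::write.table(as.data.frame(m), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a node-set file (one ROI label per line)
#'
#' @param path file path.
#' @return Character vector of ROI labels.
#' @export
read_node_set <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' @rdname read_node_set
#' @param nodes character vector of ROI labels.
#' @export
write_node_set <- function(nodes, path) {
  writeLines(as.character(nodes), path)
  invisible(path)
}
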