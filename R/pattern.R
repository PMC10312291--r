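#' Seizure propagation pattern over sampled ROIs
#'
#' A seizure pattern records, for the subset of ROIs sampled by SEEG
#' electrodes, which ROIs became active during a seizure and at which integer
#' activation step (ties allowed: several ROIs may share a step). Sampled
#' ROIs that never became active form the inactive set.
#'
#' @param activation_step named numeric vector (or 2-column data.frame
#'   `roi`, `activation_step`) of activation steps for the active ROIs.
#' @param sampled_rois character vector of all electrode-sampled ROIs; must
#'   contain every active ROI.
#' @return A list of class `seizure_pattern` with `sampled_rois`, `steps`
#'   (named, active set only), `active`, `inactive`.
#' @export
seizure_pattern <- function(activation_step, sampled_rois) {
  if (is.data.frame(activation_step)) {
    steps <- stats::setNames(activation_step[[2]],
                             as.character(activation_step[[1]]))
  } else {
    steps <- activation_step
  }
  if (is.null(names(steps)) || any(!nzchar(names(steps))))
    stop("activation steps must be named by ROI")
  if (length(steps) == 0) stop("a seizure pattern needs at least one active ROI")
  sampled_rois <- as.character(sampled_rois)
  if (!all(names(steps) %in% sampled_rois))
    stop("all active ROIs must be in 'sampled_rois'")
  if (anyDuplicated(names(steps))) stop("duplicated ROI in activation steps")
  structure(
    list(sampled_rois = sampled_rois,
         steps = steps,
         active = names(steps),
         inactive = setdiff(sampled_rois, names(steps))),
    class = "seizure_pattern")
}

#' @export
print.seizure_pattern <- function(x, ...) {
  cat(sprintf("seizure_pattern: %d sampled ROIs, %d active (%d steps)\n",
              length(x$sampled_rois), length(x$active),
              length(unique(x$steps))))
  invisible(x)
}

#' Restrict a simulation to the sampled ROIs (the SIR seizure pattern)
#'
#' Subsamples the per-ROI infection probabilities and mean activation times
#' of a simulation to the electrode-sampled ROIs. The active set is the
#' sampled ROIs with `p_infected > p_threshold`; the (real-valued) mean
#' activation time is the ordering variable of the pattern.
#'
#' @param sim a `sir_result` covering all sampled ROIs.
#' @param sampled_rois character vector of sampled ROIs.
#' @param p_threshold inclusion threshold on `p_infected` (default 0:
#'   any ROI ever infected counts as active).
#' @return List with `sampled_rois`, `p_infected`, `mean_activation`
#'   (both restricted), and `active`.
#' @export
sir_pattern <- function(sim, sampled_rois, p_threshold = 0) {
  stopifnot(inherits(sim, "sir_result"))
  sampled_rois <- as.character(sampled_rois)
  if (!all(sampled_rois %in% names(sim$p_infected)))
    stop("simulation does not cover all sampled ROIs")
  p <- sim$p_infected[sampled_rois]
  t <- sim$mean_activation[sampled_rois]
  list(sampled_rois = sampled_rois, p_infected = p, mean_activation = t,
       active = sampled_rois[p > p_threshold])
}

#' Read / write a seizure-pattern table
#'
#' The table is tab-separated with columns `roi` and `activation_step` for
#' the active ROIs; the full sampled-ROI list is a separate node-set file
#' (ROIs in the list but absent from the table are the inactive set).
#'
#' @param pattern_path path to the pattern table.
#' @param sampled_path path to the sampled-ROI node-set file.
#' @return A `seizure_pattern`.
#' @export
read_seizure_pattern <- function(pattern_path, sampled_path) {
  tab <- utils::read.table(pattern_path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  seizure_pattern(tab, read_node_set(sampled_path))
}

#' @rdname read_seizure_pattern
#' @param pattern a `seizure_pattern` to write.
#' @export
write_seizure_pattern <- function(pattern, pattern_path, sampled_path) {
  utils::write.table(
    data.frame(roi = names(pattern$steps),
               activation_step = unname(pattern$steps)),
    pattern_path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_node_set(pattern$sampled_rois, sampled_path)
  invisible(pattern_path)
}
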