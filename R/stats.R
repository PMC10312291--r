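#' ROC curve and AUC for surgical-outcome classification
#'
#' AUC by the rank (Mann-Whitney) formula with midranks for ties; a positive
#' is the seizure-free (good outcome) class, i.e. the AUC is the probability
#' that a randomly chosen positive scores higher than a randomly chosen
#' negative (+ half the tie probability).
#'
#' @param scores numeric classifier scores (higher = more positive-like).
#' @param labels class labels; `positive` marks the positive class.
#' @param positive value of `labels` treated as positive (default `"SF"`).
#' @return List with `auc` and `curve` (data.frame of `threshold`, `fpr`,
#'   `tpr` over all distinct score thresholds).
#' @export
roc_auc <- function(scores, labels, positive = "SF") {
  stopifnot(length(scores) == length(labels), !any(is.na(scores)))
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)   # midranks
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1)),
    tpr = vapply(thr, function(t) mean(scores[pos] >= t), numeric(1)))
  list(auc = auc, curve = curve)
}

#' Student t comparison between groups
#'
#' Two-sided Student t test, paired or unpaired (equal-variance) per flag.
#' Zero-variance input (e.g. a paired comparison with constant differences)
#' is returned as a degenerate result rather than an error.
#'
#' @param x,y numeric vectors (equal length when `paired`).
#' @param paired paired test flag.
#' @return List with `t`, `df`, `p`, `mean_diff`, `degenerate`.
#' @export
group_compare <- function(x, y, paired = FALSE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (paired && length(x) != length(y))
    stop("paired comparison requires equal lengths")
  degenerate <- if (paired) stats::var(x - y) == 0
                else stats::var(x) == 0 && stats::var(y) == 0
  if (degenerate) {
    return(list(t = NA_real_, df = NA_real_, p = NA_real_,
                mean_diff = mean(x) - mean(y), degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(x) - mean(y), degenerate = FALSE)
}
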