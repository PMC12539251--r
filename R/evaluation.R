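## Scoring predictions against known modification sites, ROC/AUC,
## region intersection, and small report utilities.

#' Match predicted sites to known sites within a shift window
#'
#' Modifications perturb the current of neighbouring bases, so a predicted
#' site is counted correct if any known site on the same contig and strand
#' lies within `window` bases, and a known site is detected if any
#' prediction lies within `window` bases. Precision is prediction-centric
#' and recall truth-centric: one truth detected by several nearby
#' predictions produces no false positives among them.
#'
#' @param pred,truth Data.frames with columns `contig`, `position`,
#'   `strand` (e.g. positive sites from [call_sites()] and a ground-truth
#'   BED read with [read_bed_sites()]).
#' @param window Maximum distance in bases; detection performance
#'   typically plateaus at 4. Default 4.
#' @param universe Optional data.frame of all tested sites (same columns);
#'   when given, true negatives are counted as universe sites not within
#'   `window` of any truth and not predicted.
#' @return List of class `nanodiff_match`: `correct_preds`, `total_preds`,
#'   `detected_truths`, `total_truths`, and `tp`, `fp`, `fn` (plus `tn`
#'   when `universe` is supplied).
#' @export
match_with_shift <- function(pred, truth, window = 4, universe = NULL) {
  if (window < 0) stop_param("window must be >= 0")
  near <- function(a, b) {
    ## for each row of a: is any row of b on same contig/strand within window?
    if (NROW(a) == 0) return(logical(0))
    if (NROW(b) == 0) return(rep(FALSE, NROW(a)))
    out <- logical(NROW(a))
    akey <- paste(a$contig, a$strand, sep = "\r")
    bkey <- paste(b$contig, b$strand, sep = "\r")
    for (g in intersect(unique(akey), unique(bkey))) {
      ai <- which(akey == g)
      bp <- sort(b$position[bkey == g])
      lo <- findInterval(a$position[ai] - window - 1L, bp)
      hi <- findInterval(a$position[ai] + window, bp)
      out[ai] <- hi > lo
    }
    out
  }
  pred_ok <- near(pred, truth)
  truth_ok <- near(truth, pred)
  res <- list(correct_preds = sum(pred_ok), total_preds = NROW(pred),
              detected_truths = sum(truth_ok), total_truths = NROW(truth),
              tp = sum(pred_ok), fp = sum(!pred_ok), fn = sum(!truth_ok),
              window = window)
  if (!is.null(universe)) {
    adjacent <- near(universe, truth)
    called <- near(universe, data.frame(contig = pred$contig,
                                        position = pred$position,
                                        strand = pred$strand))
    ## tn: tested sites that are neither truth-adjacent nor called
    res$tn <- sum(!adjacent & !called)
  }
  structure(res, class = "nanodiff_match")
}

#' @export
print.nanodiff_match <- function(x, ...) {
  s <- prf1(x)
  cat(sprintf("nanodiff match (window %d): %d/%d predictions correct, %d/%d known sites detected\n",
              x$window, x$correct_preds, x$total_preds, x$detected_truths,
              x$total_truths))
  cat(sprintf("  precision %.3f  recall %.3f  F1 %.3f\n",
              s["precision"], s["recall"], s["f1"]))
  invisible(x)
}

#' Precision, recall and F1 from a match result
#'
#' `precision = correct predictions / total predictions` (positive
#' predictive value), `recall = detected known sites / total known sites`
#' (sensitivity), `f1 = 2PR/(P+R)` (harmonic mean). Any 0/0 is defined
#' as 0.
#'
#' @param match A [match_with_shift()] result (or any list with
#'   `correct_preds`, `total_preds`, `detected_truths`, `total_truths`).
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
prf1 <- function(match) {
  div0 <- function(a, b) if (b == 0) 0 else a / b
  p <- div0(match$correct_preds, match$total_preds)
  r <- div0(match$detected_truths, match$total_truths)
  c(precision = p, recall = r, f1 = div0(2 * p * r, p + r))
}

#' ROC curve and AUC over a score threshold sweep
#'
#' Sites are predicted positive when `score >= t`; sweeping `t` over the
#' observed scores traces TPR = TP/(TP+FN) against FPR = FP/(TN+FP), and
#' the AUC is the trapezoidal area under that curve. Scores are typically
#' the per-site absolute feature differences (`|d_mean|`, `|d_dwell|`, ...)
#' and labels whether the site is adjacent to a known modification. The
#' trapezoid over tied scores counts ties as one half, so the AUC equals
#' the pairwise-concordance (rank) statistic.
#'
#' @param scores Numeric vector.
#' @param labels Logical or 0/1 vector, same length; both classes must be
#'   present.
#' @return List of class `nanodiff_roc` with `thresholds`, `tpr`, `fpr`
#'   (curve points, (0,0) to (1,1)) and `auc`.
#' @export
#' @examples
#' roc_auc(c(0.9, 0.1), c(1, 0))$auc  # 1
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels))
    stop_param("scores and labels must be matching complete vectors")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop_param("AUC undefined: both classes must be present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  thr <- unique(s)
  tp_cum <- cumsum(labels[o])
  fp_cum <- cumsum(!labels[o])
  last <- c(which(diff(s) != 0), length(s))  # end index of each tied block
  tpr <- c(0, tp_cum[last] / n_pos, 1)
  fpr <- c(0, fp_cum[last] / n_neg, 1)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(thresholds = c(Inf, thr, -Inf), tpr = unname(tpr),
                 fpr = unname(fpr), auc = auc), class = "nanodiff_roc")
}

#' @export
print.nanodiff_roc <- function(x, ...) {
  cat(sprintf("nanodiff ROC: %d threshold(s), AUC = %.4f\n",
              length(x$thresholds), x$auc))
  invisible(x)
}

#' @export
plot.nanodiff_roc <- function(x, ...) {
  plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
       xlab = "false positive rate", ylab = "true positive rate", ...)
  abline(0, 1, lty = 3, col = "grey60")
  legend("bottomright", sprintf("AUC = %.3f", x$auc), bty = "n")
  invisible(x)
}

#' Min-rule intersection count of two region sets
#'
#' The number of regions of A overlapping B generally differs from the
#' number of regions of B overlapping A, so the intersection size is
#' reported conservatively as the smaller of the two counts. Overlap means
#' a nonempty interval intersection on the same contig and strand
#' (half-open coordinates).
#'
#' @param A,B Data.frames with `contig`, `start`, `end`, `strand`
#'   (e.g. [call_regions()] output).
#' @return Integer: `min(#A overlapping B, #B overlapping A)`.
#' @export
region_intersection_count <- function(A, B) {
  overlaps_any <- function(a, b) {
    if (NROW(a) == 0 || NROW(b) == 0) return(logical(NROW(a)))
    vapply(seq_len(NROW(a)), function(i) {
      same <- b$contig == a$contig[i] & b$strand == a$strand[i]
      any(same & b$start < a$end[i] & a$start[i] < b$end)
    }, logical(1))
  }
  min(sum(overlaps_any(A, B)), sum(overlaps_any(B, A)))
}

#' Phred-scaled score from a mapping accuracy
#'
#' `-log10(1 - accuracy)`, putting per-site mapping accuracy on the same
#' scale as basecalling Q scores. A perfect accuracy of 1 is capped at 60
#' and flagged via the `capped` attribute.
#'
#' @param accuracy Numeric vector in `[0, 1]`.
#' @return Phred scores; attribute `capped` marks capped entries.
#' @export
#' @examples
#' phred_from_accuracy(0.99)  # 2
phred_from_accuracy <- function(accuracy) {
  if (anyNA(accuracy) || any(accuracy < 0 | accuracy > 1))
    stop_param("accuracy must lie in [0, 1]")
  capped <- accuracy == 1
  out <- ifelse(capped, 60, -log10(1 - accuracy))
  attr(out, "capped") <- capped
  out
}

#' Counts per million
#'
#' `cpm_i = q_i / sum_j(q_j) * 1e6` for per-gene read counts `q`; the
#' result sums to one million.
#'
#' @param counts Non-negative numeric vector with positive total.
#' @return CPM values, same length.
#' @export
#' @examples
#' cpm(c(1, 1, 2))  # 250000 250000 500000
cpm <- function(counts) {
  if (anyNA(counts) || any(counts < 0))
    stop_param("counts must be non-negative")
  total <- sum(counts)
  if (total <= 0) stop_param("total count must be positive")
  counts / total * 1e6
}
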