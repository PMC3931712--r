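# ROC curves and AUC by descending-score threshold sweep with grouped ties
# (trapezoidal integration, equivalent to half-credit for tied pairs).

#' ROC curve and AUC for a binary score ranking
#'
#' Sweeps thresholds over the distinct scores in descending order, grouping
#' ties at a single step, and integrates the curve trapezoidally. The
#' resulting AUC equals the Mann-Whitney pairwise statistic with half credit
#' for ties, and is invariant under any strictly monotone transform of the
#' scores.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary labels (0/1); both classes must be present.
#' @return Object of class `roc_result`: list with `thresholds`, `fpr`,
#'   `tpr` (each starting at the (0,0) operating point), `auc`, `n_pos`,
#'   `n_neg`.
#' @export
#' @examples
#' r <- roc_curve(c(0.9, 0.8, 0.4, 0.2), c(1, 1, 0, 0))
#' r$auc  # 1: perfect separation
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores/labels length mismatch")
  if (any(!is.finite(scores))) stop("scores must be finite")
  labels <- as.numeric(labels)
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0L || N == 0L)
    stop("both classes must be present to compute a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]
  y <- labels[o]
  n <- length(s)
  last <- c(s[-n] != s[-1L], TRUE)  # last index within each tied block
  tp <- cumsum(y)[last]
  fp <- cumsum(1 - y)[last]
  res <- list(thresholds = c(Inf, s[last]),
              fpr = c(0, fp / N), tpr = c(0, tp / P),
              auc = .trapezoid(c(0, fp / N), c(0, tp / P)),
              n_pos = P, n_neg = N)
  class(res) <- "roc_result"
  res
}

.trapezoid <- function(x, y) {
  k <- length(x)
  sum(diff(x) * (y[-1L] + y[-k]) / 2)
}

#' Area under the ROC curve
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) roc_curve(scores, labels)$auc

#' Genome-wide ROC pooled over chromosomes
#'
#' Concatenates all chromosomes' intervals into one ranking and computes the
#' pooled ROC (the primary result: a single genome-wide ranking). The
#' per-chromosome AUC mean (macro average) is reported alongside;
#' chromosomes lacking one of the two classes are skipped in the macro
#' average with a warning.
#'
#' @inheritParams roc_curve
#' @param group Chromosome (or other grouping) label per interval.
#' @return A `roc_result` with additional fields `per_group_auc` (named
#'   vector) and `macro_auc`.
#' @export
averaged_roc <- function(scores, labels, group) {
  if (length(group) != length(scores)) stop("group length mismatch")
  pooled <- roc_curve(scores, labels)
  groups <- split(seq_along(scores), group)
  per <- vapply(groups, function(ix) {
    if (length(unique(labels[ix])) < 2L) return(NA_real_)
    auc(scores[ix], labels[ix])
  }, numeric(1))
  if (anyNA(per))
    warning("group(s) with a single class skipped in the macro average: ",
            paste(names(per)[is.na(per)], collapse = ", "))
  pooled$per_group_auc <- per
  pooled$macro_auc <- mean(per, na.rm = TRUE)
  pooled
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC = %.4f (%d positives, %d negatives)\n",
              x$auc, x$n_pos, x$n_neg))
  if (!is.null(x$macro_auc))
    cat(sprintf("  per-group mean AUC = %.4f over %d group(s)\n",
                x$macro_auc, length(x$per_group_auc)))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, add = FALSE, ...) {
  if (add) {
    lines(x$fpr, x$tpr, ...)
  } else {
    plot(x$fpr, x$tpr, type = "l", xlim = c(0, 1), ylim = c(0, 1),
         xlab = "false positive rate", ylab = "true positive rate", ...)
    abline(0, 1, lty = 3, col = "grey")
  }
  invisible(x)
}

#' Write a ROC curve as TSV (fpr, tpr, threshold)
#' @param roc A `roc_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc <- function(roc, path) {
  df <- data.frame(threshold = sprintf("%.6f", roc$thresholds),
                   fpr = sprintf("%.6f", roc$fpr),
                   tpr = sprintf("%.6f", roc$tpr))
  df$threshold[1L] <- "Inf"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
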