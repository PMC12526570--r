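# Evaluation: confusion matrix, one-vs-rest metric suite (precision,
# sensitivity, specificity, F1, accuracy, as percentages) and ROC/PR
# summaries with micro-averaging.

#' Confusion matrix
#'
#' `counts[i, j]` is the number of windows with true class `i` predicted as
#' class `j` (classes in [rhythm_classes()] order).
#'
#' @param y_true,y_pred Label vectors (names, factors or 0-3 codes) of equal
#'   length.
#' @param levels Class levels (default the four rhythm classes).
#' @return Integer matrix with class dimnames.
#' @export
confusion <- function(y_true, y_pred, levels = rhythm_classes()) {
  if (length(y_true) != length(y_pred))
    abort("label vectors must have equal length", "invalid_input")
  to_name <- function(v) {
    if (is.numeric(v)) {
      if (any(!v %in% (seq_along(levels) - 1L)))
        abort("unknown integer label", "invalid_input")
      levels[v + 1L]
    } else {
      v <- as.character(v)
      if (any(!v %in% levels)) abort("unknown class label", "invalid_input")
      v
    }
  }
  tab <- table(factor(to_name(y_true), levels = levels),
               factor(to_name(y_pred), levels = levels))
  m <- matrix(as.integer(tab), nrow(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- c("true", "predicted")
  m
}

#' One-vs-rest metrics from a confusion matrix
#'
#' For each class c (one-vs-rest): precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(FP+TN)`, F1 = harmonic mean of precision
#' and sensitivity, accuracy `(TP+TN)/(TP+FN+FP+TN)` — all as percentages.
#' Zero-denominator cases yield `NA` (an explicit undefined marker).
#' The overall row reports support-weighted averages of the per-class
#' metrics and the plain multi-class accuracy.
#'
#' @param cm Confusion matrix from [confusion()].
#' @param digits Rounding (half-up) for the report; `NULL` disables.
#' @return An `eval_report`: list with `per_class` and `overall` data frames
#'   and the raw one-vs-rest counts.
#' @export
per_class_metrics <- function(cm, digits = 2) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm) || sum(cm) == 0)
    abort("confusion matrix must be square and non-empty", "invalid_input")
  k <- nrow(cm)
  total <- sum(cm)
  safe <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  pre <- safe(tp, tp + fp)
  sen <- safe(tp, tp + fn)
  spe <- safe(tn, fp + tn)
  f1 <- ifelse(!is.na(pre) & !is.na(sen) & (pre + sen) > 0,
               2 * pre * sen / (pre + sen), NA_real_)
  acc <- safe(tp + tn, tp + fn + fp + tn)
  support <- rowSums(cm)
  wavg <- function(v) {
    ok <- !is.na(v)
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * support[ok]) / sum(support[ok])
  }
  overall <- data.frame(Pre = wavg(pre), Sen = wavg(sen), Spe = wavg(spe),
                        F1 = wavg(f1), Acc = 100 * sum(tp) / total)
  per <- data.frame(class = rownames(cm) %||% paste0("class", seq_len(k) - 1),
                    TP = tp, FP = fp, TN = tn, FN = fn,
                    Pre = pre, Sen = sen, Spe = spe, F1 = f1, Acc = acc,
                    row.names = NULL)
  if (!is.null(digits)) {
    rnd <- function(v) round_half_away(v * 10^digits) / 10^digits
    per[, 6:10] <- lapply(per[, 6:10], rnd)
    overall[] <- lapply(overall, rnd)
  }
  structure(list(per_class = per, overall = overall,
                 confusion = cm),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("Per-class metrics (%):\n")
  print(x$per_class[, c("class", "Pre", "Sen", "Spe", "F1", "Acc")],
        row.names = FALSE)
  cat("\nOverall (support-weighted; Acc = multi-class accuracy):\n")
  print(x$overall, row.names = FALSE)
  if (!is.null(x$roc)) {
    cat(sprintf("\nmicro-average AUC %.3f, micro-average AP %.3f\n",
                x$roc$micro_auc, x$roc$micro_ap))
  }
  invisible(x)
}

# Trapezoidal ROC AUC from scores for binary labels (1 = positive).
roc_auc_binary <- function(labels, scores) {
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  if (npos == 0 || nneg == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  tps <- cumsum(lab == 1); fps <- cumsum(lab == 0)
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)   # threshold sweep at unique scores
  tpr <- c(0, tps[keep] / npos)
  fpr <- c(0, fps[keep] / nneg)
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

# Step-wise average precision (area under the PR curve, step interpolation).
average_precision <- function(labels, scores) {
  npos <- sum(labels == 1)
  if (npos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  tps <- cumsum(lab == 1)
  prec <- tps / seq_along(lab)
  sum(prec[lab == 1]) / npos
}

#' ROC and precision-recall summaries
#'
#' One-vs-rest ROC per class via a threshold sweep with trapezoidal AUC,
#' plus micro-averaged ROC AUC and average precision obtained by pooling all
#' (class, window) decisions.
#'
#' @param y_true Labels (names, factors or 0-3 codes).
#' @param scores Probability matrix (rows on the simplex, one column per
#'   class).
#' @param levels Class levels.
#' @return List with `per_class_auc`, `micro_auc`, `micro_ap`.
#' @export
roc_pr <- function(y_true, scores, levels = rhythm_classes()) {
  if (any(abs(rowSums(scores) - 1) > 1e-5))
    abort("score rows must lie on the probability simplex", "invalid_input")
  yt <- encode_labels(y_true)
  k <- ncol(scores)
  onehot <- one_hot(yt, k)
  per <- vapply(seq_len(k), function(j) roc_auc_binary(onehot[, j], scores[, j]), 0)
  names(per) <- levels[seq_len(k)]
  list(per_class_auc = per,
       micro_auc = roc_auc_binary(as.vector(onehot), as.vector(scores)),
       micro_ap = average_precision(as.vector(onehot), as.vector(scores)))
}

#' Evaluate a fitted model on labeled windows
#'
#' @param object A fitted [fusion_dma()] model.
#' @param x Window matrix.
#' @param y True labels.
#' @param ssm Optional precomputed self-similarity tensor.
#' @return An `eval_report` with confusion matrix, per-class and overall
#'   metrics, and ROC/PR summaries in `$roc`.
#' @export
evaluate_model <- function(object, x, y, ssm = NULL) {
  probs <- predict(object, x, ssm = ssm, type = "prob")
  pred <- max.col(probs) - 1L
  cm <- confusion(encode_labels(y), pred, levels = object$levels)
  rep <- per_class_metrics(cm)
  rep$roc <- roc_pr(y, probs, levels = object$levels)
  rep
}
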