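# Classification quality metrics: ACC, F1, BACC, MCC from confusion
# counts, with explicit flagging of zero-denominator (undefined) cases,
# plus per-class one-vs-rest MCC for the four-compartment mode.

#' Binary confusion counts
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive the label counted as positive.
#' @return a `confusion_binary`: list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(y_true, y_pred, positive) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (length(y_true) < 1) stop("empty prediction vector")
  tp <- sum(y_true == positive & y_pred == positive)
  fp <- sum(y_true != positive & y_pred == positive)
  tn <- sum(y_true != positive & y_pred != positive)
  fn <- sum(y_true == positive & y_pred != positive)
  structure(list(TP = tp, FP = fp, TN = tn, FN = fn,
                 positive = as.character(positive)),
            class = "confusion_binary")
}

#' Multiclass confusion table
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param labels declared label order for rows (truth) and columns
#'   (prediction); defaults to the sorted union.
#' @return C x C integer table, truth in rows.
#' @export
confusion_table <- function(y_true, y_pred, labels = NULL) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have equal length")
  if (is.null(labels)) labels <- sort(union(y_true, y_pred))
  outside <- setdiff(union(y_true, y_pred), labels)
  if (length(outside))
    stop("label(s) outside declared set: ", paste(outside, collapse = ", "))
  table(factor(y_true, labels), factor(y_pred, labels), dnn = NULL)
}

ratio_or_na <- function(num, den) if (den == 0) NA_real_ else num / den

#' Metrics from a binary confusion matrix
#'
#' Implements the standard confusion-matrix formulas:
#' ACC = (TP+TN)/(TP+TN+FP+FN); PPV = TP/(TP+FP); TPR = TP/(TP+FN);
#' TNR = TN/(TN+FP); F1 = 2 PPV TPR/(PPV+TPR); BACC = (TPR+TNR)/2;
#' MCC = (TP TN - FP FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A zero denominator makes the affected metric `NA` and lists it in
#' `undefined` — never a silent 0.
#'
#' @param cm a `confusion_binary` from [confusion()].
#' @return a `metric_report`: list with `ACC`, `F1`, `BACC`, `MCC`,
#'   `PPV`, `TPR`, `TNR` and character vector `undefined`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_binary"))
  tp <- cm$TP; fp <- cm$FP; tn <- cm$TN; fn <- cm$FN
  n <- tp + fp + tn + fn
  if (n < 1) stop("empty confusion matrix")
  acc <- (tp + tn) / n
  ppv <- ratio_or_na(tp, tp + fp)
  tpr <- ratio_or_na(tp, tp + fn)
  tnr <- ratio_or_na(tn, tn + fp)
  f1 <- if (is.na(ppv) || is.na(tpr) || (ppv + tpr) == 0) NA_real_
        else 2 * ppv * tpr / (ppv + tpr)
  bacc <- if (is.na(tpr) || is.na(tnr)) NA_real_ else (tpr + tnr) / 2
  den <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) NA_real_
         else (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(den)
  out <- list(ACC = acc, F1 = f1, BACC = bacc, MCC = mcc,
              PPV = ppv, TPR = tpr, TNR = tnr)
  out$undefined <- names(which(vapply(out[1:7], is.na, logical(1))))
  class(out) <- "metric_report"
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("ACC %.3f  F1 %s  BACC %s  MCC %s\n", x$ACC,
              format(x$F1, digits = 3), format(x$BACC, digits = 3),
              format(x$MCC, digits = 3)))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

binary_from_table <- function(cm, positive) {
  stopifnot(positive %in% rownames(cm))
  i <- match(positive, rownames(cm))
  structure(list(TP = as.integer(cm[i, i]),
                 FP = as.integer(sum(cm[-i, i])),
                 TN = as.integer(sum(cm[-i, -i])),
                 FN = as.integer(sum(cm[i, -i])),
                 positive = positive),
            class = "confusion_binary")
}

#' Per-class one-vs-rest Matthews correlation coefficients
#'
#' Each class is binarised one-vs-rest and the binary MCC formula applied,
#' as used for reporting four-compartment mitochondrial performance.
#'
#' @param cm C x C confusion table from [confusion_table()].
#' @return named numeric vector, one (possibly `NA`-flagged) MCC per class.
#' @export
per_class_mcc <- function(cm) {
  stopifnot(nrow(cm) >= 2, nrow(cm) == ncol(cm))
  vapply(rownames(cm), function(lab)
    compute_metrics(binary_from_table(cm, lab))$MCC, numeric(1))
}

#' Evaluate predictions with the report-table metric set
#'
#' Binary mode: F1 is the macro average of the two one-vs-rest F1 scores,
#' BACC and MCC the usual binary quantities.  Multiclass mode: ACC is the
#' overall accuracy, BACC the macro average of per-class recalls, F1 the
#' macro-averaged one-vs-rest F1 and MCC the macro average of per-class
#' one-vs-rest MCCs.  Undefined components are dropped from macro averages
#' and counted in `n_undefined`.
#'
#' Within a macro average an undefined per-class component contributes 0
#' (a class never predicted earns no credit — dropping it instead would
#' reward degenerate all-majority classifiers); the count of affected
#' classes is reported in `n_undefined`.
#'
#' @param y_true,y_pred label vectors.
#' @param labels declared label set.
#' @return named list: `ACC`, `F1`, `BACC`, `MCC`, `n_undefined`.
#' @export
evaluate_predictions <- function(y_true, y_pred, labels = NULL) {
  cm <- confusion_table(y_true, y_pred, labels)
  labs <- rownames(cm)
  reports <- lapply(labs, function(l)
    compute_metrics(binary_from_table(cm, l)))
  acc <- sum(diag(cm)) / sum(cm)
  macro <- function(field) {
    v <- vapply(reports, `[[`, numeric(1), field)
    if (all(is.na(v))) return(NA_real_)
    v[is.na(v)] <- 0
    mean(v)
  }
  f1 <- macro("F1")
  if (length(labs) == 2) {
    bacc <- reports[[1]]$BACC
    mcc <- reports[[1]]$MCC
  } else {
    bacc <- macro("TPR")
    mcc <- macro("MCC")
  }
  n_undef <- sum(vapply(reports, function(r) length(r$undefined) > 0,
                        logical(1)))
  list(ACC = acc, F1 = f1, BACC = bacc, MCC = mcc, n_undefined = n_undef)
}
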