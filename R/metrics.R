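#' One-vs-rest confusion counts per class
#'
#' For each class of the label space, counts true positives, true negatives,
#' false positives and false negatives of the one-vs-rest reduction; each
#' row sums to the number of observations.
#'
#' @param truth,pred factors over the same label space.
#' @return data.frame with columns `class`, `TP`, `TN`, `FP`, `FN`,
#'   `support`.
#' @export
confusion_counts <- function(truth, pred) {
  lv <- levels(factor(truth))
  truth <- factor(truth, levels = lv)
  pred <- factor(pred, levels = lv)
  stopifnot(length(truth) == length(pred))
  out <- lapply(lv, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- length(truth) - tp - fp - fn
    data.frame(class = cl, TP = tp, TN = tn, FP = fp, FN = fn,
               support = tp + fn)
  })
  do.call(rbind, out)
}

#' Classification metrics: accuracy, macro precision, macro recall
#'
#' Accuracy is the fraction of correctly classified observations (for the
#' two-class one-vs-rest table this equals `(TP+TN)/(TP+TN+FP+FN)`).
#' Precision (`TP/(TP+FP)`) and recall (`TP/(TP+FN)`) are macro-averaged over
#' the classes with nonzero support; a class never predicted contributes
#' precision 0.
#'
#' @param truth,pred factors over the same label space.
#' @return object of class `classification_metrics`: list with `accuracy`,
#'   `precision`, `recall` and the per-class `counts` table.
#' @export
classification_metrics <- function(truth, pred) {
  cc <- confusion_counts(truth, pred)
  obs <- cc[cc$support > 0, , drop = FALSE]
  prec <- ifelse(obs$TP + obs$FP > 0, obs$TP / (obs$TP + obs$FP), 0)
  rec <- obs$TP / (obs$TP + obs$FN)
  structure(list(accuracy = mean(as.character(truth) == as.character(pred)),
                 precision = mean(prec), recall = mean(rec), counts = cc),
            class = "classification_metrics")
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.4f | precision %.4f | recall %.4f (macro)\n",
              x$accuracy, x$precision, x$recall))
  invisible(x)
}

#' Evaluate a fitted classifier on a dataset
#'
#' @param model an [inception_time()] model.
#' @param ds a [labeled_dataset()].
#' @return a [classification_metrics()] object.
#' @export
evaluate <- function(model, ds) {
  stopifnot(length(ds) >= 1L)
  pred <- predict(model, ds)
  truth <- factor(as.character(ds$labels), levels = model$classes)
  classification_metrics(truth, factor(as.character(pred),
                                       levels = model$classes))
}
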