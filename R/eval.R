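#' Predict segment labels from a trained model
#'
#' Takes the argmax over the model's class probabilities. For the SSGAN's
#' K+1-way head, a fake-class argmax on real data (possible early in
#' training) falls back to the higher of the two real-class probabilities;
#' all ties resolve to the lowest class index.
#'
#' @param model An `ssgan_fit`, `cnn_fit`, or bare `ssgan_classifier`.
#' @param frames A `frame_set` of spectral frames or a numeric matrix.
#' @return Integer vector of predicted labels in `{0, 1}` (or `0..K-1`).
#' @export
predict_segments <- function(model, frames) {
  clf <- if (inherits(model, c("ssgan_fit", "cnn_fit"))) model$classifier
         else model
  stopifnot(inherits(clf, "ssgan_classifier"))
  if (!isTRUE(clf$trained))
    warning("classifier has not been trained; predictions are from random weights")
  probs <- forward_classifier(clf, frames)
  predict_from_probs(probs)
}

#' @rdname predict_segments
#' @param probs Probability matrix, one row per segment; with 3+ columns the
#'   last column is the generated/fake class and is excluded from the
#'   decision.
#' @export
predict_from_probs <- function(probs) {
  probs <- check_simplex(probs)
  real <- if (ncol(probs) > 2) probs[, -ncol(probs), drop = FALSE] else probs
  # which.max resolves ties to the lowest index
  apply(real, 1, which.max) - 1L
}

#' Reference six-task evaluation outcome
#'
#' The per-task confusion counts of a six-task SSGAN pre-warning evaluation
#' (each task: 200 segments, 60 tendency-positive), used in the package's
#' worked examples and arithmetic consistency checks. Feeding these rows to
#' [aggregate_tasks()] yields macro averages of 94.4% accuracy and 95.1%
#' specificity.
#'
#' @return A named list of six `confusion_counts` (tasks `A`--`F`).
#' @export
reference_task_counts <- function() {
  rows <- list(
    A = c(55, 129, 11, 5),
    B = c(56, 136, 4, 4),
    C = c(53, 134, 6, 7),
    D = c(56, 129, 11, 4),
    E = c(55, 132, 8, 5),
    F = c(59, 139, 1, 1)
  )
  lapply(rows, function(r) confusion_counts(r[1], r[2], r[3], r[4]))
}

#' Confusion counts with defecation tendency as the positive class
#'
#' @param predicted,truth Equal-length label vectors over `{0, 1}`.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN` (summing to the number of segments).
#' @export
confusion <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (!all(predicted %in% 0:1) || !all(truth %in% 0:1))
    stop("labels must be 0/1", call. = FALSE)
  confusion_counts(TP = sum(predicted == 1 & truth == 1),
                   TN = sum(predicted == 0 & truth == 0),
                   FP = sum(predicted == 1 & truth == 0),
                   FN = sum(predicted == 0 & truth == 1))
}

#' @rdname confusion
#' @param TP,TN,FP,FN Non-negative integer counts.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  structure(lapply(as.list(v), as.integer), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP=%d TN=%d FP=%d FN=%d (n=%d)\n",
              x$TP, x$TN, x$FP, x$FN, x$TP + x$TN + x$FP + x$FN))
  invisible(x)
}

rate_or_na <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined: zero denominator")
    return(NA_real_)
  }
  num / den
}

#' Classification rates from confusion counts
#'
#' `accuracy` = (TP+TN)/(TP+FP+TN+FN); `specificity` = TN/(TN+FP);
#' `sensitivity` = TP/(TP+FN), with label 1 (defecation tendency) as the
#' positive class. A zero denominator yields `NA` with a warning.
#'
#' @param counts A `confusion_counts`.
#' @return A rate in \[0, 1\], or `NA`.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rate_or_na(counts$TP + counts$TN,
             counts$TP + counts$FP + counts$TN + counts$FN, "accuracy")
}

#' @rdname accuracy
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rate_or_na(counts$TN, counts$TN + counts$FP, "specificity")
}

#' @rdname accuracy
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rate_or_na(counts$TP, counts$TP + counts$FN, "sensitivity")
}

#' Round-half-up percent formatting
#'
#' Formats a rate as a percentage with one decimal, rounding halves upward
#' (so 0.92142... prints as "92.1", 0.98333... as "98.3"). Display-only; all
#' internal arithmetic stays exact.
#'
#' @param rate Numeric rate(s) in \[0, 1\].
#' @param digits Decimal places, default 1.
#' @return Numeric percentage(s).
#' @export
percent <- function(rate, digits = 1) {
  f <- 10^digits
  floor(rate * 100 * f + 0.5) / f
}

#' Aggregate per-task confusion counts into a metrics report
#'
#' Computes accuracy, specificity and sensitivity for each task, then the
#' unweighted (macro) mean of each rate across tasks, plus the mean of the
#' raw counts. Matches the per-task-then-average arithmetic of a multi-task
#' evaluation table.
#'
#' @param counts_list List of `confusion_counts`, optionally named by task.
#' @return An object of class `metrics_report`: list with `per_task` (data
#'   frame, one row per task) and `average` (one-row data frame of macro
#'   means).
#' @export
aggregate_tasks <- function(counts_list) {
  stopifnot(is.list(counts_list), length(counts_list) >= 1)
  if (inherits(counts_list, "confusion_counts"))
    counts_list <- list(counts_list)
  tasks <- names(counts_list) %||% LETTERS[seq_along(counts_list)]
  if (is.null(names(counts_list))) names(counts_list) <- tasks
  per <- do.call(rbind, lapply(seq_along(counts_list), function(i) {
    c0 <- counts_list[[i]]
    stopifnot(inherits(c0, "confusion_counts"))
    data.frame(task = names(counts_list)[i], TP = c0$TP, TN = c0$TN,
               FP = c0$FP, FN = c0$FN,
               accuracy = accuracy(c0), specificity = specificity(c0),
               sensitivity = sensitivity(c0))
  }))
  avg <- data.frame(task = "Average",
                    TP = mean(per$TP), TN = mean(per$TN),
                    FP = mean(per$FP), FN = mean(per$FN),
                    accuracy = mean(per$accuracy),
                    specificity = mean(per$specificity),
                    sensitivity = mean(per$sensitivity))
  structure(list(per_task = per, average = avg), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  tab <- rbind(x$per_task, x$average)
  tab$accuracy <- percent(tab$accuracy)
  tab$specificity <- percent(tab$specificity)
  tab$sensitivity <- percent(tab$sensitivity)
  names(tab)[6:8] <- c("Accuracy(%)", "Spc(%)", "Sen(%)")
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Recording-level warning decision
#'
#' Raises a warning for a recording when the fraction of its segments
#' predicted as class 1 (defecation tendency) reaches `threshold_fraction`.
#' The default 0.5 requires a majority of tendency segments; a threshold of
#' `1/24` (one segment of a nominal 60-second recording) recovers
#' any-segment behavior.
#'
#' @param predictions Integer vector of 0/1 segment predictions for one
#'   recording.
#' @param threshold_fraction Fraction in (0, 1\].
#' @return `"warn"` or `"no_warn"`.
#' @export
warning_decision <- function(predictions, threshold_fraction = 0.5) {
  if (length(predictions) == 0) stop("no segment predictions", call. = FALSE)
  stopifnot(all(predictions %in% 0:1), threshold_fraction > 0,
            threshold_fraction <= 1)
  if (mean(predictions == 1) >= threshold_fraction) "warn" else "no_warn"
}
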