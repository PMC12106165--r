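#  Eye-level multi-label evaluation: per-class one-vs-rest confusion metrics
#  (ACC, sensitivity, specificity, F1), rank-statistic AUROC from per-disease
#  scores, average accuracy, and the per-eye outcome categories (correct,
#  misdetection, over-detection, under-detection).

# AUROC as the Mann-Whitney concordance of scores, ties counted 1/2.
auroc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

diag_sets <- function(x) {
  lapply(x, function(d) if (inherits(d, "eyelid_diagnosis")) d$diseases else as.character(d))
}

diag_score <- function(d, cls) {
  if (inherits(d, "eyelid_diagnosis")) {
    if (cls %in% names(d$scores)) unname(d$scores[[cls]]) else 0
  } else as.numeric(cls %in% as.character(d))
}

#' Evaluate predicted against true diagnosis sets
#'
#' Metrics are computed with the eye as the unit of measurement, one-vs-rest
#' per class: accuracy, sensitivity, specificity, F1, and AUROC from the
#' per-disease supporting scores (rank statistic).  `aacc` is the unweighted
#' mean of the per-class accuracies.  Each eye is also categorised as a
#' correct diagnosis (predicted set equals truth), over-detection (proper
#' superset), under-detection (proper subset), or misdetection (any other
#' mismatch).
#'
#' @param predictions list of `eyelid_diagnosis` objects (or plain character
#'   vectors of disease labels).
#' @param truth list of character vectors (the true label set per eye; empty
#'   = normal), aligned with `predictions`.
#' @param classes classes to score; defaults to every label present in truth
#'   or predictions.
#' @return object of class `evaluation_report`: `per_class` data.frame
#'   (`class`, `tp`, `fp`, `tn`, `fn`, `acc`, `sensitivity`, `specificity`,
#'   `f1`, `auroc`), `aacc`, `macro_f1`, `categories` (per-eye data.frame),
#'   `category_counts`, `n_eyes`.
#' @export
evaluate_diagnoses <- function(predictions, truth, classes = NULL) {
  if (length(predictions) != length(truth))
    abort("evaluate_diagnoses: predictions and truth differ in length")
  pred_sets <- diag_sets(predictions)
  truth_sets <- lapply(truth, as.character)
  if (is.null(classes))
    classes <- sort(unique(c(unlist(pred_sets), unlist(truth_sets))))
  n <- length(truth_sets)
  per <- lapply(classes, function(cls) {
    p <- vapply(pred_sets, function(s) cls %in% s, TRUE)
    t <- vapply(truth_sets, function(s) cls %in% s, TRUE)
    tp <- sum(p & t); fp <- sum(p & !t); tn <- sum(!p & !t); fn <- sum(!p & t)
    sc <- vapply(predictions, diag_score, 0, cls = cls)
    data.frame(class = cls, tp = tp, fp = fp, tn = tn, fn = fn,
               acc = (tp + tn) / n,
               sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
               f1 = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_,
               auroc = auroc_rank(sc, t))
  })
  per <- do.call(rbind, per)
  cat_of <- function(p, t) {
    if (setequal(p, t)) "correct"
    else if (all(t %in% p) && length(p) > length(t)) "over-detection"
    else if (all(p %in% t) && length(p) < length(t)) "under-detection"
    else "misdetection"
  }
  cats <- mapply(cat_of, pred_sets, truth_sets)
  categories <- data.frame(
    eye = seq_len(n),
    predicted = vapply(pred_sets, paste, "", collapse = " + "),
    truth = vapply(truth_sets, paste, "", collapse = " + "),
    category = unname(cats))
  lv <- c("correct", "misdetection", "over-detection", "under-detection")
  structure(list(per_class = per,
                 aacc = mean(per$acc),
                 macro_f1 = mean(per$f1, na.rm = TRUE),
                 categories = categories,
                 category_counts = table(factor(cats, levels = lv)),
                 n_eyes = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat(sprintf("<evaluation_report> %d eyes, %d classes; aACC %.2f%%, macro F1 %.3f\n",
              x$n_eyes, nrow(x$per_class), 100 * x$aacc, x$macro_f1))
  df <- x$per_class
  df[c("acc", "sensitivity", "specificity", "f1", "auroc")] <-
    round(df[c("acc", "sensitivity", "specificity", "f1", "auroc")], digits)
  print(df[, c("class", "acc", "sensitivity", "specificity", "f1", "auroc")],
        row.names = FALSE)
  cat("outcome categories: ",
      paste(sprintf("%s %d", names(x$category_counts), x$category_counts),
            collapse = ", "), "\n")
  invisible(x)
}
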