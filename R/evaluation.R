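## Confusion-matrix evaluation with stress as the positive class:
## per-participant accuracy, precision, recall and F1, plus an unweighted
## (macro) average row across participants.

#' Confusion matrix for binary stress predictions
#'
#' Stress (label 1) is the positive class: TP counts stress windows
#' predicted stress, TN non-stress predicted non-stress, FP (Type I error)
#' non-stress predicted stress, FN (Type II error) stress predicted
#' non-stress.
#'
#' @param truth,predicted Equal-length binary 0/1 vectors (>= 1 element).
#' @return A `confusion_matrix` list with `tp`, `fp`, `fn`, `tn` and
#'   `total`.
#' @export
confusion_matrix <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop_with("stressfl_length_mismatch",
              "truth and predicted must have equal lengths")
  }
  stopifnot(length(truth) >= 1, all(truth %in% 0:1),
            all(predicted %in% 0:1))
  tp <- sum(truth == 1 & predicted == 1)
  fp <- sum(truth == 0 & predicted == 1)
  fn <- sum(truth == 1 & predicted == 0)
  tn <- sum(truth == 0 & predicted == 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 total = length(truth)),
            class = "confusion_matrix")
}

## 0/0 cases return 0 carrying a degenerate-denominator flag, keeping
## macro averages total.
flagged_ratio <- function(num, den) {
  if (den == 0) return(structure(0, degenerate = TRUE))
  num / den
}

#' Classification metrics from a confusion matrix
#'
#' `accuracy = (TP + TN) / total`, `precision = TP / (TP + FP)`,
#' `recall = TP / (TP + FN)`, `f1 = 2 P R / (P + R)`.  A zero denominator
#' yields 0 with attribute `degenerate = TRUE` rather than an error.
#'
#' @param cm A [confusion_matrix()].
#' @return A single value in `[0, 1]`.
#' @export
accuracy <- function(cm) flagged_ratio(cm$tp + cm$tn, cm$total)

#' @rdname accuracy
#' @export
precision <- function(cm) flagged_ratio(cm$tp, cm$tp + cm$fp)

#' @rdname accuracy
#' @export
recall <- function(cm) flagged_ratio(cm$tp, cm$tp + cm$fn)

#' @rdname accuracy
#' @export
f1_score <- function(cm) {
  p <- precision(cm)
  r <- recall(cm)
  flagged_ratio(2 * as.numeric(p) * as.numeric(r),
                as.numeric(p) + as.numeric(r))
}

## Half-up rounding used for display (the tables' 4-decimal format).
round_half_up <- function(x, digits = 4) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Evaluate one strategy's predictions
#'
#' Computes a confusion matrix and the four metrics for every
#' participant, then appends an `"Average"` row holding the unweighted
#' arithmetic mean of the participant rows.  Full precision is kept in
#' the report; [report_table()] renders the 4-decimal display form.
#'
#' @param result A `strategy_result` from [run_individual()],
#'   [run_centralized()] or [run_federated()].
#' @return An `evaluation_report`: list with `strategy`, `rows` (tibble of
#'   participant metrics plus the average row) and `confusions`.
#' @export
evaluate_strategy <- function(result) {
  stopifnot(inherits(result, "strategy_result"),
            length(result$predictions) > 0)
  ids <- names(result$predictions)
  cms <- lapply(result$predictions, function(pr) {
    if (nrow(pr) == 0) {
      stop_with("stressfl_empty_predictions", "empty prediction set")
    }
    confusion_matrix(pr$truth, pr$predicted)
  })
  rows <- tibble::tibble(
    participant = ids,
    accuracy = vapply(cms, function(cm) as.numeric(accuracy(cm)), 0,
                      USE.NAMES = FALSE),
    precision = vapply(cms, function(cm) as.numeric(precision(cm)), 0,
                       USE.NAMES = FALSE),
    recall = vapply(cms, function(cm) as.numeric(recall(cm)), 0,
                    USE.NAMES = FALSE),
    f1 = vapply(cms, function(cm) as.numeric(f1_score(cm)), 0,
                USE.NAMES = FALSE)
  )
  avg <- tibble::tibble(
    participant = "Average",
    accuracy = mean(rows$accuracy),
    precision = mean(rows$precision),
    recall = mean(rows$recall),
    f1 = mean(rows$f1)
  )
  structure(list(strategy = result$strategy,
                 rows = rbind(rows, avg),
                 confusions = cms),
            class = "evaluation_report")
}

#' Display table of an evaluation report
#'
#' @param report An `evaluation_report`.
#' @param digits Decimals for half-up display rounding (default 4).
#' @return Tibble with rounded metric columns.
#' @export
report_table <- function(report, digits = 4) {
  out <- report$rows
  for (cn in c("accuracy", "precision", "recall", "f1")) {
    out[[cn]] <- round_half_up(out[[cn]], digits)
  }
  out
}

#' Side-by-side summary of several strategies
#'
#' One row per strategy carrying the macro-average metrics -- the data
#' behind a strategy-comparison chart.
#'
#' @param reports List of `evaluation_report`s.
#' @return Tibble with `strategy`, `accuracy`, `precision`, `recall`,
#'   `f1`, sorted by strategy name.
#' @export
compare_strategies <- function(reports) {
  stopifnot(length(reports) >= 1)
  rows <- lapply(reports, function(rep) {
    avg <- rep$rows[rep$rows$participant == "Average", ]
    tibble::tibble(strategy = rep$strategy,
                   accuracy = avg$accuracy, precision = avg$precision,
                   recall = avg$recall, f1 = avg$f1)
  })
  out <- do.call(rbind, rows)
  out[order(out$strategy), ]
}

#' Write an evaluation report as CSV and JSON
#'
#' The CSV mirrors the per-participant table layout (Participant, Acc, P,
#' R, F1 with a final Average row, 4-decimal display rounding); the JSON
#' twin keeps full precision.
#'
#' @param report An `evaluation_report`.
#' @param path_csv,path_json Output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_report <- function(report, path_csv = NULL, path_json = NULL) {
  if (!is.null(path_csv)) {
    disp <- report_table(report)
    names(disp) <- c("Participant", "Acc", "P", "R", "F1")
    disp[-1] <- lapply(disp[-1], function(x) sprintf("%.4f", x))
    write.csv(disp, path_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(strategy = report$strategy, rows = report$rows),
      path_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(c(path_csv, path_json))
}
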