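.eval_classes <- c("detected", "not_detected", "inconclusive", "not_tested")

#' Map an extraction status to a validation class
#'
#' The manual-review protocol scores each sampled test into one of four
#' classes. Extraction statuses map onto them as: `identified` is a detected
#' mutation; `not_detected` stays; `insufficient_dna` and `cancelled` mean
#' the test was not performed; `unparseable` results are inconclusive pending
#' review.
#'
#' @param status Character vector of extraction statuses.
#' @return Character vector over `detected`, `not_detected`, `inconclusive`,
#'   `not_tested`.
#' @export
status_to_class <- function(status) {
  out <- c(identified = "detected",
           not_detected = "not_detected",
           insufficient_dna = "not_tested",
           cancelled = "not_tested",
           unparseable = "inconclusive")[status]
  if (anyNA(out)) {
    stop("unknown status value(s): ",
         paste(unique(status[is.na(out)]), collapse = ", "), call. = FALSE)
  }
  unname(out)
}

#' Draw a simple random validation sample
#'
#' Uniform simple random sample without replacement, reproducible from the
#' seed; the sampled identifiers are returned in their original order, as a
#' chart reviewer would work through them.
#'
#' @param ids Vector of record identifiers.
#' @param n Sample size; must not exceed `length(ids)`.
#' @param seed Integer seed.
#' @return Vector of `n` sampled identifiers, in original order.
#' @examples
#' draw_sample(1:100, 10, seed = 1)
#' @export
draw_sample <- function(ids, n, seed) {
  if (n > length(ids)) {
    stop("sample size n (", n, ") exceeds number of ids (", length(ids), ")",
         call. = FALSE)
  }
  idx <- withr::with_seed(as.integer(seed),
                          sample.int(length(ids), size = n),
                          .rng_kind = "Mersenne-Twister",
                          .rng_normal_kind = "Inversion",
                          .rng_sample_kind = "Rejection")
  ids[sort(idx)]
}

#' Construct a confusion matrix from counts
#'
#' A 4x4 actual-by-predicted table over the validation classes, in the fixed
#' order detected, not_detected, inconclusive, not_tested.
#'
#' @param counts 4x4 numeric matrix of non-negative counts, rows = actual,
#'   columns = predicted, in class order.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4L, ncol(counts) == 4L, all(counts >= 0))
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(actual = .eval_classes, predicted = .eval_classes)
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' Tally an actual-vs-predicted confusion matrix
#'
#' @param labels Data frame of manual-review labels: columns `id` and
#'   `actual` (one of the four validation classes).
#' @param predictions Data frame of algorithm output: columns `id` and either
#'   `status` (an extraction status, mapped via [status_to_class()]) or
#'   `predicted` (already a validation class). Every label id must have a
#'   prediction.
#' @return A `confusion_matrix`.
#' @export
build_confusion <- function(labels, predictions) {
  stopifnot(is.data.frame(labels), all(c("id", "actual") %in% names(labels)),
            is.data.frame(predictions), "id" %in% names(predictions))
  bad <- setdiff(labels$actual, .eval_classes)
  if (length(bad)) {
    stop("unknown actual class(es): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  pred <- if ("predicted" %in% names(predictions)) {
    predictions$predicted
  } else if ("status" %in% names(predictions)) {
    status_to_class(predictions$status)
  } else {
    stop("predictions need a 'status' or 'predicted' column", call. = FALSE)
  }
  m <- match(labels$id, predictions$id)
  if (anyNA(m)) {
    stop("label id(s) without prediction: ",
         paste(labels$id[is.na(m)], collapse = ", "), call. = FALSE)
  }
  tab <- table(factor(labels$actual, levels = .eval_classes),
               factor(pred[m], levels = .eval_classes))
  confusion_matrix(unclass(tab))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> (rows = actual, cols = predicted)\n")
  print(unclass(x))
  invisible(x)
}

#' Accuracy, sensitivity and specificity of the extraction
#'
#' The correctness rule scores three cells as correct extractions: actual
#' detected predicted detected, actual not-detected predicted not-detected,
#' and actual inconclusive predicted not-detected (samples whose clinician
#' comment was not a definitive result are correctly extracted as
#' "Not Detected" — comment analysis is out of the extraction's scope).
#' Sensitivity is the detected-detected fraction of actual detected samples;
#' specificity the not-detected fraction of actual not-detected samples.
#' Metrics with a zero denominator are reported as `NA` (undefined), never 0.
#'
#' When full per-sample predictions are available, pass `correct`: a logical
#' vector scoring each sample under the stricter rule that a detected sample
#' must also have the right mutation location; accuracy then uses it instead
#' of the matrix-cell rule (the matrix alone cannot express location
#' agreement).
#'
#' @param cm A `confusion_matrix`.
#' @param correct Optional logical vector of per-sample correctness flags.
#' @return An object of class `metrics_report`: `accuracy`, `sensitivity`,
#'   `specificity` (proportions in `[0, 1]` or `NA`), `n_correct`, `n_total`.
#' @examples
#' cm <- confusion_matrix(rbind(c(35, 0, 0, 0), c(0, 308, 0, 0),
#'                              c(0, 10, 0, 0), c(0, 9, 0, 0)))
#' compute_metrics(cm)
#' @export
compute_metrics <- function(cm, correct = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n_total <- sum(cm)
  n_correct <- if (!is.null(correct)) {
    stopifnot(is.logical(correct), length(correct) == n_total)
    sum(correct)
  } else {
    cm["detected", "detected"] + cm["not_detected", "not_detected"] +
      cm["inconclusive", "not_detected"]
  }
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  structure(list(accuracy = ratio(n_correct, n_total),
                 sensitivity = ratio(cm["detected", "detected"],
                                     sum(cm["detected", ])),
                 specificity = ratio(cm["not_detected", "not_detected"],
                                     sum(cm["not_detected", ])),
                 n_correct = as.integer(n_correct),
                 n_total = as.integer(n_total),
                 rule = if (is.null(correct)) "matrix-cell" else "per-sample"),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", 100 * v)
  cat("<metrics_report>", x$n_correct, "/", x$n_total, "correct\n")
  cat("  accuracy:   ", pct(x$accuracy), "\n")
  cat("  sensitivity:", pct(x$sensitivity), "\n")
  cat("  specificity:", pct(x$specificity), "\n")
  cat("  rule:       ", x$rule, "\n")
  invisible(x)
}

#' Per-location precision and recall
#'
#' Supplementary location-level evaluation: for each assay location, the
#' fraction of predicted calls that are true (precision) and the fraction of
#' true calls that were predicted (recall), matching on (result id, location)
#' pairs among identified results. Not part of the headline accuracy.
#'
#' @param truth Long-format ground-truth records (`result_id`, `status`,
#'   `location`).
#' @param predicted Long-format extraction records of the same shape.
#' @return Tibble with `location`, `n_true`, `n_pred`, `precision`, `recall`.
#' @export
location_metrics <- function(truth, predicted) {
  key <- function(d) {
    d <- d[d$status == "identified" & !is.na(d$location), , drop = FALSE]
    paste(d$result_id, d$location, sep = "|")
  }
  tk <- key(truth)
  pk <- key(predicted)
  locs <- unname(.loc_label)
  loc_of <- function(k) sub("^.*\\|", "", k)
  tibble::tibble(
    location = locs,
    n_true = vapply(locs, function(l) sum(loc_of(tk) == l), integer(1),
                    USE.NAMES = FALSE),
    n_pred = vapply(locs, function(l) sum(loc_of(pk) == l), integer(1),
                    USE.NAMES = FALSE),
    precision = vapply(locs, function(l) {
      p <- pk[loc_of(pk) == l]
      if (length(p) == 0L) NA_real_ else mean(p %in% tk)
    }, numeric(1), USE.NAMES = FALSE),
    recall = vapply(locs, function(l) {
      t <- tk[loc_of(tk) == l]
      if (length(t) == 0L) NA_real_ else mean(t %in% pk)
    }, numeric(1), USE.NAMES = FALSE))
}
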