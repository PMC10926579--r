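table1_counts <- rbind(c(35, 0, 0, 0),
                       c(0, 308, 0, 0),
                       c(0, 10, 0, 0),
                       c(0, 9, 0, 0))

test_that("random validation samples are reproducible and well-formed", {
  ids <- sprintf("id%04d", 1:8900)
  s <- draw_sample(ids, 362, seed = 3)
  expect_length(s, 362)
  expect_identical(anyDuplicated(s), 0L)
  expect_identical(s, ids[sort(match(s, ids))])  # original order
  expect_equal(362 / 8900, 0.0407, tolerance = 0.01)
  expect_identical(draw_sample(ids, 362, seed = 3), s)
  expect_false(identical(draw_sample(ids, 362, seed = 4), s))
  expect_identical(draw_sample(ids, length(ids), seed = 1), ids)
  expect_error(draw_sample(ids, 9000, seed = 1), "exceeds")
})

test_that("the review-table confusion matrix is tallied from labels and predictions", {
  labels <- tibble::tibble(
    id = seq_len(362),
    actual = rep(c("detected", "not_detected", "inconclusive", "not_tested"),
                 c(35, 308, 10, 9)))
  predictions <- tibble::tibble(
    id = seq_len(362),
    status = rep(c("identified", "not_detected"), c(35, 327)))
  cm <- build_confusion(labels, predictions)
  expect_identical(unname(unclass(cm)), table1_counts)
})

test_that("perfect predictions give a diagonal matrix; empty labels all zeros", {
  labels <- tibble::tibble(id = 1:10,
                           actual = rep(c("detected", "not_detected"), 5))
  predictions <- tibble::tibble(id = 1:10,
                                predicted = labels$actual)
  cm <- build_confusion(labels, predictions)
  expect_identical(sum(diag(cm)), 10)
  expect_identical(sum(cm) - sum(diag(cm)), 0)

  cm0 <- build_confusion(tibble::tibble(id = integer(), actual = character()),
                         tibble::tibble(id = integer(), status = character()))
  expect_identical(sum(cm0), 0)
})

test_that("an id without a prediction is an error listing the id", {
  labels <- tibble::tibble(id = c("a", "b"), actual = c("detected", "detected"))
  predictions <- tibble::tibble(id = "a", status = "identified")
  expect_error(build_confusion(labels, predictions), "b")
})

test_that("metrics reproduce the review-table arithmetic", {
  m <- compute_metrics(confusion_matrix(table1_counts))
  expect_identical(m$n_total, 362L)
  expect_identical(m$n_correct, 353L)
  expect_equal(m$accuracy, 353 / 362)
  expect_equal(round(100 * m$accuracy, 1), 97.5)
  expect_identical(m$sensitivity, 1)
  expect_identical(m$specificity, 1)
})

test_that("degenerate matrices give trivial or undefined metrics, never zero-division", {
  all_right <- matrix(0, 4, 4); all_right[1, 1] <- 1; all_right[2, 2] <- 1
  expect_identical(compute_metrics(confusion_matrix(all_right))$accuracy, 1)

  all_missed <- matrix(0, 4, 4); all_missed[1, 2] <- 5
  m <- compute_metrics(confusion_matrix(all_missed))
  expect_identical(m$sensitivity, 0)
  expect_true(is.na(m$specificity))

  empty <- compute_metrics(confusion_matrix(matrix(0, 4, 4)))
  expect_true(is.na(empty$accuracy))
})

test_that("per-sample correctness flags override the matrix-cell rule", {
  cm <- confusion_matrix(table1_counts)
  flags <- rep(c(TRUE, FALSE), c(350, 12))
  m <- compute_metrics(cm, correct = flags)
  expect_identical(m$n_correct, 350L)
  expect_identical(m$rule, "per-sample")
})

test_that("accuracy is invariant under label row permutation", {
  labels <- tibble::tibble(
    id = 1:20,
    actual = rep(c("detected", "not_detected"), 10))
  predictions <- tibble::tibble(id = 1:20, status = rep(
    c("identified", "not_detected"), 10))
  a <- compute_metrics(build_confusion(labels, predictions))$accuracy
  perm <- withr::with_seed(9, sample(20))
  b <- compute_metrics(build_confusion(labels[perm, ], predictions))$accuracy
  expect_identical(a, b)
})

test_that("status-to-class mapping covers the taxonomy and rejects strangers", {
  expect_identical(status_to_class(c("identified", "not_detected",
                                     "insufficient_dna", "cancelled",
                                     "unparseable")),
                   c("detected", "not_detected", "not_tested", "not_tested",
                     "inconclusive"))
  expect_error(status_to_class("maybe"), "maybe")
})

test_that("location-level precision and recall score (result, location) pairs", {
  truth <- tibble::tibble(result_id = c("r1", "r1", "r2"),
                          status = "identified",
                          location = c("exon19", "T790M", "L858R"))
  pred <- tibble::tibble(result_id = c("r1", "r1", "r2"),
                         status = "identified",
                         location = c("exon19", "T790M", "exon19"))
  lm <- location_metrics(truth, pred)
  e19 <- lm[lm$location == "exon19", ]
  expect_equal(e19$precision, 0.5)  # r2/exon19 predicted but not true
  expect_equal(e19$recall, 1)
  expect_equal(lm[lm$location == "L858R", ]$recall, 0)
  expect_true(is.na(lm[lm$location == "G719X", ]$precision))
})
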