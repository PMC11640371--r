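test_that("confusion matrix counts true/predicted pairs", {
  cm <- confusion_matrix(rep("a", 10), rep("a", 10), labels = c("a", "b"))
  expect_equal(sum(diag(cm)), 10)
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  cm2 <- confusion_matrix("a", "b", labels = c("a", "b"))
  expect_equal(cm2["a", "b"], 1L, ignore_attr = TRUE)
  expect_equal(sum(cm2), 1)

  withr::with_seed(1, {
    truth <- sample(letters[1:4], 200, replace = TRUE)
    pred <- sample(letters[1:4], 200, replace = TRUE)
  })
  cm3 <- confusion_matrix(truth, pred)
  expect_equal(unname(rowSums(cm3)), unname(table(factor(truth,
                                                         rownames(cm3)))),
               ignore_attr = TRUE)
  expect_error(confusion_matrix(c("a", "z"), c("a", "a"),
                                labels = c("a", "b")), "outside")
  expect_error(confusion_matrix(c("a"), c("a", "b")), "equal length")
})

test_that("metrics match the one-vs-rest definitions on a hand-worked case", {
  # rows = true class: (8, 2) for "pos", (1, 9) for "neg"
  cm <- matrix(c(8, 2, 1, 9), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  rep <- metrics_from_cm(cm)
  expect_equal(rep$per_class$sensitivity[1], 0.8)
  expect_equal(rep$per_class$specificity[1], 0.9)
  expect_equal(rep$accuracy, 0.85)
  expect_equal(rep$per_class$recall, rep$per_class$sensitivity)

  ident <- diag(5) * 4
  rownames(ident) <- colnames(ident) <- letters[1:5]
  rep2 <- metrics_from_cm(ident)
  expect_equal(rep2$accuracy, 1)
  expect_true(all(rep2$per_class$sensitivity == 1))
  expect_true(all(rep2$per_class$specificity == 1))
  expect_equal(rep2$macro$f1, 1)
})

test_that("macro F1 is invariant under class relabeling", {
  withr::with_seed(2, {
    truth <- sample(letters[1:4], 120, replace = TRUE)
    pred <- ifelse(stats::runif(120) < 0.7, truth,
                   sample(letters[1:4], 120, replace = TRUE))
  })
  base <- metrics_from_cm(confusion_matrix(truth, pred,
                                           labels = letters[1:4]))
  perm <- c(a = "c", b = "d", c = "a", d = "b")
  rep_p <- metrics_from_cm(confusion_matrix(unname(perm[truth]),
                                            unname(perm[pred]),
                                            labels = letters[1:4]))
  expect_equal(rep_p$macro$f1, base$macro$f1, tolerance = 1e-12)
  expect_equal(rep_p$accuracy, base$accuracy, tolerance = 1e-12)
})

test_that("zero-denominator rates report 0 with an explicit flag", {
  # class "c" never occurs in truth or predictions
  cm <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"),
                         labels = c("a", "b", "c"))
  rep <- metrics_from_cm(cm)
  expect_equal(rep$per_class$sensitivity[3], 0)
  expect_true("c" %in% rep$zero_denominator)
})

test_that("reports round-trip losslessly through JSON", {
  withr::with_seed(3, {
    truth <- sample(class_labels(), 60, replace = TRUE)
    pred <- sample(class_labels(), 60, replace = TRUE)
  })
  rep <- evaluate_predictions(truth, pred)
  path <- tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- read_eval_report(path)
  expect_equal(back$accuracy, rep$accuracy, tolerance = 0)
  expect_identical(back$confusion, rep$confusion)
  expect_equal(back$per_class, rep$per_class, tolerance = 0)
})

test_that("comparison tables carry one macro-metric row per model", {
  r1 <- metrics_from_cm(diag(3) * 5 + 1)
  r2 <- metrics_from_cm(diag(3) * 5)
  tab <- comparison_table(list(fusion = r1, single = r2))
  expect_equal(nrow(tab), 2L)
  expect_equal(names(tab), c("model", "sensitivity", "specificity",
                             "accuracy", "f1"))
  expect_true(all(tab$accuracy >= 0 & tab$accuracy <= 1))
})

test_that("accuracy lies between the extreme per-class sensitivities for balanced classes", {
  withr::with_seed(4, {
    truth <- rep(letters[1:3], each = 40)
    pred <- ifelse(stats::runif(120) < 0.6, truth,
                   sample(letters[1:3], 120, replace = TRUE))
  })
  rep <- metrics_from_cm(confusion_matrix(truth, pred, labels = letters[1:3]))
  expect_gte(rep$accuracy, min(rep$per_class$sensitivity) - 1e-12)
  expect_lte(rep$accuracy, max(rep$per_class$sensitivity) + 1e-12)
})
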