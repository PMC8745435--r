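# Diagnostic performance statistics

test_that("confusion matrix counts and validates labels", {
  cm <- confusion_matrix(rep(c("A", "B"), c(6, 4)), rep(c("A", "B"), c(6, 4)),
                         classes = c("A", "B"))
  expect_equal(unname(diag(cm)), c(6L, 4L))
  expect_equal(sum(cm), 10)

  cm2 <- confusion_matrix(c("A", "A", "B"), c("A", "B", "B"), c("A", "B"))
  expect_equal(unclass(cm2), matrix(c(1L, 0L, 1L, 1L), 2, 2,
                                    dimnames = list(truth = c("A", "B"),
                                                    predicted = c("A", "B"))))
  expect_error(confusion_matrix(character(), character()), "empty")
  expect_error(confusion_matrix("A", c("A", "B")), "length mismatch")
  expect_error(confusion_matrix("A", "C", classes = c("A", "B")), "unknown label")
})

test_that("sensitivity and specificity are one-vs-rest with macro and micro", {
  cm <- confusion_matrix(rep(c("A", "B"), c(10, 10)),
                         c(rep("A", 8), rep("B", 2), rep("A", 1), rep("B", 9)),
                         classes = c("A", "B"))
  ss <- sens_spec(cm)
  expect_equal(ss$per_class$sensitivity[1], 0.8)
  expect_equal(ss$per_class$specificity[1], 0.9)
  expect_equal(ss$accuracy, 17 / 20)
  expect_equal(unname(ss$micro["sensitivity"]), ss$accuracy)

  perfect <- confusion_matrix(rep(c("A", "B", "C"), 5), rep(c("A", "B", "C"), 5))
  sp <- sens_spec(perfect)
  expect_true(all(sp$per_class$sensitivity == 1))
  expect_true(all(sp$per_class$specificity == 1))

  # class absent from truth -> undefined sensitivity, not zero
  cm3 <- confusion_matrix(c("A", "A"), c("A", "B"), classes = c("A", "B"))
  expect_true(is.na(sens_spec(cm3)$per_class$sensitivity[2]))
})

test_that("micro-averaged sensitivity equals accuracy on random matrices", {
  set.seed(47)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- 60
    truth <- sample(LETTERS[1:k], n, replace = TRUE)
    pred <- ifelse(runif(n) < 0.6, truth, sample(LETTERS[1:k], n, replace = TRUE))
    cm <- confusion_matrix(truth, pred, LETTERS[1:k])
    ss <- sens_spec(cm)
    expect_equal(unname(ss$micro["sensitivity"]), sum(diag(cm)) / n)
  }
})

test_that("Cohen's kappa matches hand computations", {
  agree <- confusion_matrix(rep(c("A", "B"), 10), rep(c("A", "B"), 10))
  expect_equal(cohens_kappa(agree)$kappa, 1)
  expect_equal(cohens_kappa(agree)$se, 0)

  chance <- structure(matrix(c(25L, 25L, 25L, 25L), 2, 2,
                             dimnames = list(truth = c("A", "B"),
                                             predicted = c("A", "B"))),
                      class = c("confusion_matrix", "matrix"))
  expect_equal(cohens_kappa(chance)$kappa, 0)

  cm <- structure(matrix(c(20L, 10L, 5L, 15L), 2, 2,
                         dimnames = list(truth = c("A", "B"),
                                         predicted = c("A", "B"))),
                  class = c("confusion_matrix", "matrix"))
  k <- cohens_kappa(cm)
  expect_equal(k$kappa, 0.4)
  expect_true(k$ci[1] <= k$kappa && k$kappa <= k$ci[2])

  degen <- structure(matrix(c(10L, 0L, 0L, 0L), 2, 2,
                            dimnames = list(truth = c("A", "B"),
                                            predicted = c("A", "B"))),
                     class = c("confusion_matrix", "matrix"))
  expect_error(cohens_kappa(degen), "degenerate")
})

test_that("kappa is invariant under simultaneous class reordering", {
  set.seed(53)
  truth <- sample(c("A", "B", "C"), 90, replace = TRUE)
  pred <- ifelse(runif(90) < 0.5, truth, sample(c("A", "B", "C"), 90, TRUE))
  k1 <- cohens_kappa(confusion_matrix(truth, pred, c("A", "B", "C")))$kappa
  k2 <- cohens_kappa(confusion_matrix(truth, pred, c("C", "A", "B")))$kappa
  expect_equal(k1, k2)
})

test_that("kappa point estimate agrees with an independent implementation", {
  skip_if_not_installed("e1071")
  set.seed(59)
  truth <- sample(c("A", "B", "C"), 120, replace = TRUE)
  pred <- ifelse(runif(120) < 0.55, truth, sample(c("A", "B", "C"), 120, TRUE))
  cm <- confusion_matrix(truth, pred, c("A", "B", "C"))
  expect_equal(cohens_kappa(cm)$kappa,
               e1071::classAgreement(unclass(cm))$kappa)
})

test_that("ROC/AUC handles separation, ties and the pair-count identity", {
  sep <- roc_auc(c(5, 6, 7, 1, 2, 3), rep(c("pos", "neg"), each = 3),
                 positive = "pos", n_boot = 0)
  expect_equal(sep$auc, 1)

  ties <- roc_auc(rep(2, 10), rep(c("pos", "neg"), 5), positive = "pos",
                  n_boot = 0)
  expect_equal(ties$auc, 0.5)

  quad <- roc_auc(c(3, 1, 2, 0), c("pos", "pos", "neg", "neg"),
                  positive = "pos", n_boot = 0)
  expect_equal(quad$auc, 0.75)

  expect_error(roc_auc(1:3, rep("pos", 3), positive = "pos"), "both classes")

  # trapezoid AUC == Mann-Whitney pair statistic, ties counted 1/2
  set.seed(61)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    labels <- sample(c("pos", "neg"), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(labels)) < 2) next
    scores <- sample(0:8, n, replace = TRUE) + ifelse(labels == "pos", 1, 0)
    r <- roc_auc(scores, labels, positive = "pos", n_boot = 0)
    xs <- scores[labels == "pos"]; ys <- scores[labels == "neg"]
    pairs <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(r$auc, mean(pairs))
    # curve starts at (0,0) and ends at (1,1)
    expect_equal(unlist(r$roc[1, c("fpr", "tpr")]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$roc[nrow(r$roc), c("fpr", "tpr")]), c(fpr = 1, tpr = 1))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(67)
  labels <- sample(c("pos", "neg"), 80, replace = TRUE)
  scores <- rnorm(80) + (labels == "pos")
  mine <- roc_auc(scores, labels, positive = "pos", n_boot = 0)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, levels = c("neg", "pos"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(mine, ref)
})

test_that("the bootstrap CI is deterministic under a fixed seed", {
  set.seed(71)
  labels <- sample(c("pos", "neg"), 60, replace = TRUE)
  scores <- rnorm(60) + 1.2 * (labels == "pos")
  r1 <- roc_auc(scores, labels, positive = "pos", n_boot = 500, seed = 9L)
  r2 <- roc_auc(scores, labels, positive = "pos", n_boot = 500, seed = 9L)
  expect_identical(r1$ci, r2$ci)
  expect_true(r1$ci[1] <= r1$auc + 1e-12 && r1$auc <= r1$ci[2] + 1e-12)
  r3 <- roc_auc(scores, labels, positive = "pos", n_boot = 500, seed = 10L)
  expect_false(identical(r1$ci, r3$ci))
})

test_that("Pearson correlation matches closed forms and flags bad input", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_correlation(x, -x)$r, -1)
  r <- pearson_correlation(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(r$r, 0.6)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "constant")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})
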