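test_that("screening metrics reproduce hand-verified confusion matrices", {
  # 314-case test set: 131/1/159/23
  m <- computeMetrics(confusionCounts(131, 1, 159, 23))
  expect_equal(m@accuracy, 92.36)
  expect_equal(m@kappa, 84.67)
  expect_equal(m@f1, 91.61)
  expect_equal(m@sensitivity, 99.24)
  expect_equal(m@specificity, 87.36)
  # perfect classifier
  p <- computeMetrics(confusionCounts(50, 0, 70, 0))
  expect_equal(c(p@sensitivity, p@specificity, p@accuracy, p@f1, p@kappa),
               c(100, 100, 100, 100, 100))
  # constant (all-malignant) prediction has zero chance-corrected agreement
  cst <- computeMetrics(confusionCounts(40, 0, 0, 60))
  expect_equal(cst@kappa, 0)
  expect_equal(cst@po, cst@pe)  # closed form: Po = Pe for constant predictors
})

test_that("undefined metrics are NA rather than zero", {
  # no malignant cases at all: sensitivity undefined
  m <- computeMetrics(confusionCounts(0, 0, 50, 10))
  expect_true(is.na(m@sensitivity))
  expect_false(is.na(m@specificity))
})

test_that("the alternative sen-spe F1 definition is exposed", {
  cm <- confusionCounts(131, 1, 159, 23)
  alt <- computeMetrics(cm, f1Definition = "sen-spe")
  # 2 * 99.24 * 87.36 / (99.24 + 87.36) = 92.92, not the tabulated 91.61
  expect_equal(alt@f1, 92.92, tolerance = 0.005)
})

test_that("kappa agrees with an independent implementation", {
  set.seed(41)
  for (i in 1:10) {
    tp <- sample(5:100, 1); fn <- sample(0:50, 1)
    tn <- sample(5:100, 1); fp <- sample(0:50, 1)
    m <- computeMetrics(confusionCounts(tp, fn, tn, fp))
    tab <- as.table(matrix(c(tn, fp, fn, tp), 2,
                           dimnames = list(pred = c("b", "m"),
                                           truth = c("b", "m"))))
    ck <- caret::confusionMatrix(tab)
    kappaRaw <- (m@po - m@pe) / (1 - m@pe)   # unrounded kappa fraction
    expect_equal(kappaRaw, unname(ck$overall["Kappa"]), tolerance = 1e-9)
    expect_equal(m@po, unname(ck$overall["Accuracy"]), tolerance = 1e-9)
  }
})

test_that("kappa never exceeds observed agreement and is 100 only when perfect", {
  set.seed(42)
  for (i in 1:50) {
    tp <- sample(0:80, 1); fn <- sample(0:80, 1)
    tn <- sample(0:80, 1); fp <- sample(0:80, 1)
    if (tp + fn + tn + fp == 0) next
    m <- computeMetrics(confusionCounts(tp, fn, tn, fp))
    if (is.na(m@kappa)) next
    expect_lte(m@kappa, m@accuracy + 1e-9)
    if (m@kappa == 100) expect_true(fn == 0 && fp == 0)
  }
})

test_that("confusion reconstruction inverts printed rates exactly", {
  cm <- reconstructConfusion(132, 182, 99.24, 87.36)
  expect_equal(c(cm@TP, cm@FN, cm@TN, cm@FP), c(131L, 1L, 159L, 23L))
  cm2 <- reconstructConfusion(132, 182, 100, 100)
  expect_equal(c(cm2@TP, cm2@FN, cm2@TN, cm2@FP), c(132L, 0L, 182L, 0L))
  cm3 <- reconstructConfusion(132, 182, 67.42, 78.02)
  expect_equal(cm3@TP, 89L)   # 0.6742 * 132 = 89.0
  expect_equal(cm3@TN, 142L)  # 0.7802 * 182 = 142.0
  # internal-consistency identity on reconstructed matrices
  set.seed(43)
  for (i in 1:25) {
    nm <- sample(20:200, 1); nb <- sample(20:200, 1)
    sen <- round(runif(1, 40, 100), 2)
    spe <- round(runif(1, 40, 100), 2)
    cm <- reconstructConfusion(nm, nb, sen, spe)
    m <- computeMetrics(cm)
    lhs <- m@sensitivity * nm + m@specificity * nb
    expect_equal(lhs, 100 * (cm@TP + cm@TN), tolerance = 0.005 * (nm + nb))
    expect_equal(cm@TP + cm@FN, nm)
    expect_equal(cm@TN + cm@FP, nb)
  }
})

test_that("rank AUC behaves at the extremes and matches pROC with ties", {
  lab <- c(rep("benign", 4), rep("malignant", 4))
  expect_equal(rocAuc(c(1:4, 5:8) / 10, lab), 1)
  expect_equal(rocAuc(c(5:8, 1:4) / 10, lab), 0)
  expect_error(rocAuc(1:4 / 10, rep("benign", 4)), "both classes")
  # null distribution: independent scores give AUC ~ 0.5
  set.seed(44)
  scores <- runif(1000)
  labels <- sample(c("benign", "malignant"), 1000, replace = TRUE)
  expect_lt(abs(rocAuc(scores, labels) - 0.5), 0.05)
  set.seed(45)
  s <- sample(seq(0, 1, 0.1), 200, replace = TRUE)  # heavy ties
  l <- ifelse(runif(200) < plogis(4 * (s - 0.5)), "malignant", "benign")
  if (length(unique(l)) == 2) {
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = factor(l, c("benign", "malignant")),
      predictor = s, quiet = TRUE, direction = "<")))
    expect_equal(rocAuc(s, l), ref, tolerance = 1e-9)
  }
})
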