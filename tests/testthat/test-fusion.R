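# Brute-force oracles written independently of the implementation.
oracleMajority <- function(labels) {
  nb <- sum(labels == "benign"); nm <- sum(labels == "malignant")
  if (nb > nm) "benign" else "malignant"
}
oracleSoft <- function(probs) {
  p1 <- sum(probs[, 1]) / nrow(probs); p2 <- sum(probs[, 2]) / nrow(probs)
  if (p1 > p2) "benign" else "malignant"
}
oracleMax <- function(probs) {
  p1 <- max(probs[, 1]); p2 <- max(probs[, 2])
  if (p1 > p2) "benign" else "malignant"
}

test_that("majority vote matches exhaustive enumeration up to n = 7", {
  expect_equal(majorityVote(c("benign", "benign", "malignant")), "benign")
  expect_equal(majorityVote(rep("malignant", 11)), "malignant")
  expect_error(majorityVote(character(0)), "no labels")
  for (n in 1:7) {
    for (code in 0:(2^n - 1)) {
      labels <- ifelse(bitwAnd(code, 2^(0:(n - 1))) > 0, "malignant", "benign")
      expect_identical(majorityVote(labels), oracleMajority(labels))
    }
  }
})

test_that("soft and max votes match arithmetic oracles on probability grids", {
  sv <- softVote(rbind(c(0.6, 0.4), c(0.2, 0.8)))
  expect_equal(unname(sv$probs), c(0.4, 0.6))
  expect_equal(sv$label, "malignant")
  mv <- maxVote(rbind(c(0.6, 0.4), c(0.2, 0.8)))
  expect_equal(unname(mv$probs), c(0.6, 0.8))
  expect_equal(mv$label, "malignant")
  # single pair reduces to its own argmax
  expect_equal(softVote(rbind(c(0.7, 0.3)))$label, "benign")
  expect_equal(maxVote(rbind(c(0.7, 0.3)))$label, "benign")
  # exact ties resolve to malignant
  expect_equal(softVote(rbind(c(0.5, 0.5), c(0.5, 0.5)))$label, "malignant")
  expect_equal(maxVote(rbind(c(0.5, 0.5)))$label, "malignant")
  # exhaustive grids with step 0.25, n <= 3
  grid <- seq(0, 1, by = 0.25)
  for (n in 1:3) {
    combos <- expand.grid(rep(list(grid), n))
    for (i in seq_len(nrow(combos))) {
      p1 <- as.numeric(combos[i, ])
      probs <- cbind(p1, 1 - p1)
      expect_identical(softVote(probs)$label, oracleSoft(probs))
      expect_identical(maxVote(probs)$label, oracleMax(probs))
    }
  }
})

test_that("voting rules are permutation invariant; averaged pair sums to one", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:11, 1)
    p1 <- runif(n)
    probs <- cbind(p1, 1 - p1)
    perm <- sample(n)
    expect_identical(softVote(probs)$label, softVote(probs[perm, ])$label)
    expect_identical(maxVote(probs)$label, maxVote(probs[perm, ])$label)
    labels <- ifelse(p1 > 0.5, "benign", "malignant")
    expect_identical(majorityVote(labels), majorityVote(labels[perm]))
    expect_equal(sum(softVote(probs)$probs), 1)
    expect_true(all(softVote(probs)$probs >= 0 & softVote(probs)$probs <= 1))
    expect_true(all(maxVote(probs)$probs >= 0 & maxVote(probs)$probs <= 1))
  }
})

test_that("stacking separates the toy set and preserves order sensitivity", {
  toy <- toyStackSet()
  st <- fitStacker(toy$X, toy$labels, "svm_rbf")
  expect_s4_class(st, "StackerModel")
  pred <- predictStacked(st, toy$X)
  expect_equal(mean(pred == toy$labels), 1)           # separable by margin
  # the all-zero vector lies on the benign side of the class-mean geometry
  expect_equal(predictStacked(st, rep(0, 11)), "benign")
  # training exemplar recovers its own class
  expect_equal(predictStacked(st, toy$X[1, ]), toy$labels[1])
  # repeated calls identical
  expect_identical(predictStacked(st, toy$X[5, ]), predictStacked(st, toy$X[5, ]))
  # length mismatch rejected
  expect_error(predictStacked(st, rep(0.5, 7)), "length")
  # random forest kind accepted
  rf <- fitStacker(toy$X, toy$labels, "random_forest")
  expect_equal(mean(predictStacked(rf, toy$X) == toy$labels), 1)
  # order sensitivity: a stacker trained on position-coded classes flips
  # when the informative coordinate is permuted away
  set.seed(33)
  n <- 60L
  X <- matrix(runif(n * 3, 0.45, 0.55), n, 3)
  X[1:30, 1] <- 0.05; X[31:60, 1] <- 0.95   # only position 1 informative
  lab <- rep(c("benign", "malignant"), each = 30)
  st2 <- fitStacker(X, lab, "svm_linear")
  v <- c(0.95, 0.5, 0.5)
  expect_equal(predictStacked(st2, v), "malignant")
  expect_equal(predictStacked(st2, v[c(2, 3, 1)]), "benign")
})

test_that("fitStacker validates its inputs", {
  toy <- toyStackSet(nPerClass = 5L, len = 4L)
  expect_error(fitStacker(toy$X, toy$labels[1:3]), "one label")
  expect_error(fitStacker(toy$X[1:5, ], rep("benign", 5)), "two samples")
})

test_that("fuseDecision dispatches every rule consistently with its primitive", {
  set.seed(34)
  p1 <- runif(11)
  probs <- cbind(p1, 1 - p1)
  expect_identical(fuseDecision(probs, "soft"), softVote(probs)$label)
  expect_identical(fuseDecision(probs, "max"), maxVote(probs)$label)
  lab <- ifelse(p1 > 1 - p1, "benign", "malignant")
  expect_identical(fuseDecision(probs, "majority"), majorityVote(lab))
  toy <- toyStackSet()
  st <- fitStacker(toy$X, toy$labels, "svm_rbf")
  stackProbs <- cbind(1 - toy$X[1, ], toy$X[1, ])
  expect_identical(fuseDecision(stackProbs, "stack-rbf", st),
                   predictStacked(st, toy$X[1, ]))
  expect_error(fuseDecision(probs, "stack-rbf"), "stacker")
})
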