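test_that("cross entropy matches its analytic values and is additive", {
  perfect <- matrix(c(1, 0, 0), 1)
  expect_equal(cross_entropy(perfect, 1L), 0)
  expect_equal(cross_entropy(matrix(0.25, 1, 4), 1L), log(4))
  P <- rbind(c(0.7, 0.3), c(0.2, 0.8))
  y <- c(1L, 2L)
  expect_equal(cross_entropy(rbind(P, P), c(y, y)), 2 * cross_entropy(P, y))
  expect_equal(cross_entropy(P, y, reduce = "mean"), cross_entropy(P, y) / 2)
  expect_warning(v <- cross_entropy(matrix(c(0, 1), 1), 1L), "floored")
  expect_true(is.finite(v))
})

test_that("weighted cross entropy reduces to the plain loss and selects the true-class weight", {
  set.seed(1)
  P <- t(apply(matrix(runif(40), 10), 1, function(r) r / sum(r)))
  y <- sample(1:4, 10, TRUE)
  expect_equal(weighted_cross_entropy(P, y, rep(1, 4)), cross_entropy(P, y))
  expect_equal(weighted_cross_entropy(P, y, rep(0, 4)), 0)
  # single sample: loss is w[c] * (-log P[c])
  p1 <- matrix(c(0.6, 0.4), 1)
  expect_equal(weighted_cross_entropy(p1, 1L, c(2.5, 1)), -2.5 * log(0.6))
  # uniform weights 1/C scale the loss by 1/C exactly
  expect_equal(weighted_cross_entropy(P, y, rep(0.25, 4)),
               cross_entropy(P, y) / 4)
  expect_error(weighted_cross_entropy(P, y, c(-1, 1, 1, 1)), "non-negative")
})

test_that("focal loss decays toward easy samples and reduces at delta = 0", {
  set.seed(2)
  P <- t(apply(matrix(runif(30), 10), 1, function(r) r / sum(r)))
  y <- sample(1:3, 10, TRUE)
  expect_equal(focal_loss(P, y, delta = 0), cross_entropy(P, y))
  expect_equal(focal_loss(matrix(c(0.5, 0.5), 1), 1L, delta = 2),
               0.25 * log(2))
  expect_equal(focal_loss(matrix(c(1, 0), 1), 1L, delta = 3), 0)
  for (d in c(0.5, 1, 2, 5)) {
    expect_lte(focal_loss(P, y, delta = d), cross_entropy(P, y))
  }
})

test_that("class error rates complement the per-class recall", {
  expect_equal(class_error_rates(diag(c(3, 4, 5))), c(0, 0, 0))
  cm <- rbind(c(3, 1), c(0, 6))
  er <- class_error_rates(cm)
  expect_equal(er, c(0.25, 0))
  tpr <- diag(cm) / rowSums(cm)
  expect_equal(er + tpr, c(1, 1))
  expect_warning(z <- class_error_rates(rbind(c(0, 0), c(1, 1))),
                 "no true samples")
  expect_equal(z[1], 0)
})

test_that("the weight scheduler normalizes transformed error rates", {
  expect_equal(update_class_weights(c(0.1, 0.3), "identity"), c(0.25, 0.75))
  expect_equal(update_class_weights(c(0, 0), "exp1"), c(0.5, 0.5))
  expect_equal(update_class_weights(c(0.2, 0.2, 0.2), "exp100"), rep(1 / 3, 3))
  expect_warning(u <- update_class_weights(c(0, 0), "cube"), "uniform")
  expect_equal(u, c(0.5, 0.5))
  # scaling error rates leaves identity-rho weights unchanged
  er <- c(0.1, 0.2, 0.4)
  expect_equal(update_class_weights(er, "identity"),
               update_class_weights(er * 2, "identity"))
  expect_equal(sum(update_class_weights(c(0.5, 0.9, 0.1), "exp10")), 1)
  # rho transforms are non-decreasing on [0, 1]
  y <- seq(0, 1, length.out = 50)
  for (kind in c("identity", "cube", "exp1", "exp10", "exp100")) {
    expect_true(all(diff(rho_transform(kind)(y)) >= 0), info = kind)
  }
})

test_that("confusion matrices count samples into the true-by-predicted layout", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), 2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2,
               dimnames = list(true = 1:2, pred = 1:2)))
  expect_equal(sum(cm), 3)
  perfect <- confusion_matrix(c(1, 2, 3), c(1, 2, 3), 3)
  expect_true(all(perfect[upper.tri(perfect) | lower.tri(perfect)] == 0))
  empty <- confusion_matrix(integer(0), integer(0), 2)
  expect_equal(sum(empty), 0)
  expect_error(confusion_matrix(c(1, 5), c(1, 1), 2), "1..n_classes")
})

test_that("binary metrics follow the formula set on a worked example", {
  # TP = 3, FP = 1, FN = 1, TN = 5 for class 1
  cm <- matrix(c(3L, 1L, 1L, 5L), 2, 2, byrow = TRUE)
  m <- classification_metrics(cm)
  expect_equal(m$precision, 0.75)
  expect_equal(m$sensitivity, 0.75)
  expect_equal(m$f1, 0.75)
  expect_equal(m$accuracy, 0.8)

  ideal <- classification_metrics(diag(c(1L, 1L)))
  expect_equal(ideal$accuracy, 1)
  expect_equal(ideal$f1, 1)
})

test_that("multiclass metrics match an independent per-formula oracle", {
  set.seed(9)
  for (i in 1:300) {
    C <- sample(2:5, 1)
    cm <- matrix(rpois(C * C, 3), C, C)
    if (sum(cm) == 0) cm[1, 1] <- 1
    m <- suppressWarnings(classification_metrics(cm))
    oracle <- t(vapply(seq_len(C), function(k) metrics_oracle_class(cm, k),
                       numeric(4)))
    expect_equal(m$per_class$precision, oracle[, "precision"])
    expect_equal(m$per_class$sensitivity, oracle[, "sensitivity"])
    expect_equal(m$per_class$f1, oracle[, "f1"])
    expect_equal(m$macro_f1, mean(oracle[, "f1"]))
    expect_equal(m$accuracy, sum(diag(cm)) / sum(cm))
    expect_true(all(unlist(m[c("accuracy", "precision", "sensitivity", "f1")]) >= 0))
    expect_true(all(unlist(m[c("accuracy", "precision", "sensitivity", "f1")]) <= 1))
  }
})

test_that("undefined precision from an empty predicted column is 0 with a warning", {
  cm <- matrix(c(0L, 0L, 2L, 3L), 2, 2)  # nothing predicted as class 1
  expect_warning(m <- classification_metrics(cm), "precision")
  expect_equal(m$per_class$precision[1], 0)
})

test_that("separable convolution costs and their ratio follow the formulas", {
  c1 <- conv_costs(1, 1, 1, 1, 1)
  expect_equal(c1$c_nor, 1)
  expect_equal(c1$c_sep, 2)
  expect_equal(c1$ratio, 0.5)
  expect_equal(conv_costs(7, 7, 32, 64, 3)$ratio, 576 / 73)
  set.seed(4)
  for (i in 1:100) {
    a <- sample(1:64, 5, TRUE)
    cc <- conv_costs(a[1], a[2], a[3], a[4], a[5])
    expect_equal(cc$ratio, cc$c_nor / cc$c_sep)
  }
  # ratio independent of spatial size and input depth
  expect_equal(conv_costs(1, 1, 1, 64, 3)$ratio, conv_costs(9, 5, 17, 64, 3)$ratio)
  expect_error(conv_costs(0, 1, 1, 1, 1), "positive integers")
})

test_that("metrics reports tidy into per-class and summary tibbles", {
  cm <- confusion_matrix(c(1, 1, 2, 3, 3), c(1, 2, 2, 3, 3), 3)
  m <- classification_metrics(cm)
  expect_equal(nrow(tidy(m)), 3L)
  gl <- glance(m)
  expect_equal(gl$accuracy, m$accuracy)
  expect_equal(gl$macro_f1, m$macro_f1)
})
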