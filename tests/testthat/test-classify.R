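test_that("two well-separated 1-D classes recover the midpoint boundary", {
  set.seed(16)
  x <- matrix(c(rnorm(50, 0), rnorm(50, 10)), ncol = 1)
  y <- rep(c("a", "b"), each = 50)
  fit <- train_lda(x, y)
  # the decision threshold is where the two scores are equal
  sc <- predict(fit, matrix(seq(0, 10, by = 0.01), ncol = 1), type = "score")
  thr <- seq(0, 10, by = 0.01)[which.min(abs(sc[, 1] - sc[, 2]))]
  expect_gt(thr, 4); expect_lt(thr, 6)
  xv <- matrix(c(rnorm(500, 0), rnorm(500, 10)), ncol = 1)
  yv <- rep(c("a", "b"), each = 500)
  expect_gt(mean(predict(fit, xv) == yv), 0.99)
  # training set on separable classes is classified perfectly
  expect_identical(as.character(predict(fit, x)), y)
})

test_that("ridge regularization covers rank-deficient features", {
  set.seed(17)
  x <- matrix(rnorm(60), 30, 2)
  x <- cbind(x, x[, 1])                  # duplicated column
  y <- rep(c("a", "b", "c"), each = 10)
  expect_silent(fit <- train_lda(x, y, lambda = 1e-6))
  expect_length(predict(fit, x), 30)
  expect_error(train_lda(x[1:3, ], y[1:3]), "classes")
  expect_error(train_lda(matrix(c(1, NA, 2, 3), 2), c("a", "b")), "finite")
})

test_that("prediction equals the brute-force discriminant argmax", {
  set.seed(18)
  x <- matrix(rnorm(200 * 4), 200)
  y <- sample(c("a", "b", "c", "d"), 200, replace = TRUE)
  fit <- train_lda(x, y)
  xnew <- matrix(rnorm(100 * 4), 100)
  pred <- predict(fit, xnew)
  # independent evaluation of g_c(x) = x' S^-1 mu_c - mu_c' S^-1 mu_c / 2
  Sinv <- solve(fit$cov)
  for (i in 1:100) {
    g <- vapply(fit$levels, function(l) {
      mu <- fit$means[l, ]
      drop(xnew[i, ] %*% Sinv %*% mu - 0.5 * mu %*% Sinv %*% mu)
    }, numeric(1))
    expect_identical(as.character(pred[i]), names(which.max(g)))
  }
  expect_error(predict(fit, xnew[, 1:3]), "features")
})

test_that("prediction agrees with an independent reference LDA", {
  skip_if_not_installed("MASS")
  set.seed(19)
  x <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 1.5), 50, 2),
             matrix(rnorm(100, 3), 50, 2))
  y <- rep(c("a", "b", "c"), each = 50)
  fit <- train_lda(x, y, lambda = 0)
  ref <- MASS::lda(x, grouping = y, prior = rep(1 / 3, 3))
  xnew <- matrix(rnorm(400), 200, 2)
  agree <- mean(as.character(predict(fit, xnew)) ==
                as.character(predict(ref, xnew)$class))
  expect_gt(agree, 0.995)
})

test_that("exact class means classify to their class; ties break by label order", {
  set.seed(20)
  x <- rbind(matrix(rnorm(40, 0, 1), 20, 2), matrix(rnorm(40, 6, 1), 20, 2))
  y <- rep(c("a", "b"), each = 20)
  fit <- train_lda(x, y)
  expect_identical(as.character(predict(fit, fit$means)), c("a", "b"))
  # symmetric construction: equidistant point scores tie, first label wins
  fit$means <- rbind(a = c(-1, 0), b = c(1, 0))
  fit$cov_inv <- diag(2)
  fit$W <- fit$cov_inv %*% t(fit$means)
  fit$b <- -0.5 * colSums(t(fit$means) * fit$W)
  expect_identical(as.character(predict(fit, matrix(c(0, 0), 1))), "a")
})

test_that("performance indices follow the one-vs-rest definitions", {
  perfect <- diag(c(5, 7, 9))
  pi <- performance_indices(perfect)
  expect_true(all(pi$Acc == 1 & pi$S == 1 & pi$P == 1 & pi$SP == 1))
  M <- matrix(c(8, 3, 2, 7), 2)   # rows = truth
  pi2 <- performance_indices(M)
  expect_equal(pi2$TP[1], 8); expect_equal(pi2$FN[1], 2)
  expect_equal(pi2$FP[1], 3); expect_equal(pi2$TN[1], 7)
  expect_equal(pi2$Acc[1], 0.75)
  expect_equal(pi2$S[1], 0.8)
  expect_equal(pi2$P[1], 8 / 11)
  expect_equal(pi2$SP[1], 0.7)
  # never-predicted class has undefined precision
  M3 <- matrix(c(5, 5, 0, 0), 2)
  expect_true(is.na(performance_indices(M3)$P[2]))
  expect_error(performance_indices(matrix(c(-1, 2, 3, 4), 2)), "negative")
})

test_that("index identities hold on random confusion matrices", {
  set.seed(21)
  for (rep_i in 1:200) {
    k <- sample(2:6, 1)
    M <- matrix(rpois(k * k, 4), k)
    pi <- performance_indices(M)
    expect_equal(pi$TP + pi$FN, rowSums(M))
    expect_equal(pi$TP + pi$FP, colSums(M))
    idx <- as.matrix(pi[, c("Acc", "S", "P", "SP")])
    expect_true(all(idx >= 0 & idx <= 1, na.rm = TRUE))
    expect_equal(as.matrix(pi[, c("Acc", "S", "P", "SP")]), oracle_indices(M),
                 ignore_attr = TRUE)
  }
})

test_that("iterated evaluation is deterministic, balanced and unbiased at chance", {
  set.seed(22)
  x <- matrix(rnorm(240 * 3), 240)
  y <- rep(c("a", "b", "c", "d"), each = 60)
  e1 <- evaluate_iterated(x, y, n_iter = 25, seed = 99)
  e2 <- evaluate_iterated(x, y, n_iter = 25, seed = 99)
  expect_identical(e1, e2)
  expect_error(evaluate_iterated(x[1:100, ], y[1:100], n_iter = 5, seed = 1),
               "unbalanced")
  # label-independent features: mean per-class sensitivity near 1/k
  e3 <- evaluate_iterated(x, y, n_iter = 200, seed = 7)
  s_iter <- apply(e3$per_iter[, , "S"], 1, mean)
  expect_lt(abs(mean(s_iter) - 0.25), 3 * stats::sd(s_iter))
})

test_that("separable classes evaluate perfectly with a small train/val gap", {
  set.seed(23)
  x <- rbind(matrix(rnorm(80, 0), 40, 2), matrix(rnorm(80, 8), 40, 2),
             matrix(rnorm(80, 16), 40, 2))
  y <- rep(c("a", "b", "c"), each = 40)
  ev <- evaluate_iterated(x, y, n_iter = 50, seed = 3)
  expect_equal(unname(ev$macro["Acc"]), 1)
  expect_equal(unname(ev$macro["S"]), 1)
  # no-overfitting audit: training and validation accuracy nearly equal
  expect_lt(abs(ev$train_accuracy - mean(ev$per_iter[, , "Acc"])), 0.02)
})
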