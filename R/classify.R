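#' Linear discriminant classifier with pooled ridge-regularized covariance
#'
#' Fits the Gaussian equal-covariance linear discriminant model: per-class
#' means, a pooled within-class covariance with an added ridge `lambda * I`
#' for rank safety, and uniform priors (the iterated evaluation always
#' presents balanced classes). Prediction takes the maximal linear
#' discriminant score; ties break deterministically in favour of the
#' earlier class label.
#'
#' @param x Observations x features numeric matrix.
#' @param y Class labels (coerced to factor; level order defines the
#'   tie-break order).
#' @param lambda Ridge added to the pooled covariance (default 1e-6).
#' @return An object of class `emg_lda` with elements `means`, `cov_inv`,
#'   `levels`, `lambda` and the linear score pieces `W` (features x classes)
#'   and `b` (class offsets).
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 4), 20))
#' fit <- train_lda(x, rep(c("a", "b"), each = 20))
#' table(predict(fit, x), rep(c("a", "b"), each = 20))
#' @export
train_lda <- function(x, y, lambda = 1e-6) {
  x <- as.matrix(x)
  if (!all(is.finite(x))) stop("train_lda: features must be finite", call. = FALSE)
  y <- factor(y)
  lev <- levels(y)
  if (length(lev) < 2L) stop("train_lda: need at least 2 classes", call. = FALSE)
  n_c <- table(y)
  if (any(n_c < 2L)) stop("train_lda: every class needs >= 2 observations",
                          call. = FALSE)
  p <- ncol(x)
  means <- matrix(NA_real_, length(lev), p, dimnames = list(lev, colnames(x)))
  for (l in lev) means[l, ] <- colMeans(x[y == l, , drop = FALSE])
  S <- matrix(0, p, p)
  for (l in lev) {
    xc <- sweep(x[y == l, , drop = FALSE], 2L, means[l, ])
    S <- S + crossprod(xc)
  }
  S <- S / (nrow(x) - length(lev)) + diag(lambda, p)
  cov_inv <- tryCatch(solve(S), error = function(e)
    stop("train_lda: singular pooled covariance; increase lambda", call. = FALSE))
  W <- cov_inv %*% t(means)                       # p x k
  b <- -0.5 * colSums(t(means) * W)               # uniform priors drop out
  structure(list(means = means, cov = S, cov_inv = cov_inv, levels = lev,
                 lambda = lambda, W = W, b = b),
            class = "emg_lda")
}

#' @export
print.emg_lda <- function(x, ...) {
  cat(sprintf("Linear discriminant model: %d classes, %d features (lambda = %g)\n",
              length(x$levels), nrow(x$W), x$lambda))
  cat("  classes:", paste(x$levels, collapse = ", "), "\n")
  invisible(x)
}

#' @param object An `emg_lda` model.
#' @param newdata Observations x features matrix.
#' @param type `"class"` (default) or `"score"` for the discriminant
#'   score matrix.
#' @param ... Unused.
#' @rdname train_lda
#' @export
predict.emg_lda <- function(object, newdata, type = c("class", "score"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != nrow(object$W))
    stop(sprintf("predict.emg_lda: %d features supplied, model expects %d",
                 ncol(newdata), nrow(object$W)), call. = FALSE)
  sc <- newdata %*% object$W + rep(object$b, each = nrow(newdata))
  colnames(sc) <- object$levels
  if (type == "score") return(sc)
  # max.col with ties.method "first" = deterministic earlier-label tie-break
  factor(object$levels[max.col(sc, ties.method = "first")],
         levels = object$levels)
}

#' One-vs-rest performance indices from a confusion matrix
#'
#' For each class `c` of a k x k confusion matrix (rows = truth, columns =
#' prediction): `TP = M[c,c]`, `FN = rowsum - TP`, `FP = colsum - TP`,
#' `TN = total - TP - FN - FP`, and the four indices
#' `Acc = (TP+TN)/(TP+FP+TN+FN)`, `S = TP/(TP+FN)`, `P = TP/(TP+FP)`,
#' `SP = TN/(TN+FP)`. Precision is `NA` when the class was never predicted
#' (`TP+FP = 0`) and such entries are excluded from averages downstream.
#'
#' @param confusion Non-negative numeric matrix, rows = true classes.
#' @return Data frame with one row per class: `TP`, `TN`, `FP`, `FN`,
#'   `Acc`, `S`, `P`, `SP`.
#' @examples
#' performance_indices(matrix(c(8, 3, 2, 7), 2))  # Acc 0.75, S 0.8, ...
#' @export
performance_indices <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (any(confusion < 0))
    stop("performance_indices: negative counts", call. = FALSE)
  k <- nrow(confusion)
  total <- sum(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- total - tp - fn - fp
  data.frame(
    class = if (!is.null(rownames(confusion))) rownames(confusion)
            else as.character(seq_len(k)),
    TP = tp, TN = tn, FP = fp, FN = fn,
    Acc = (tp + tn) / total,
    S = tp / (tp + fn),
    P = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    SP = tn / (tn + fp),
    row.names = NULL)
}

#' Iterated balanced 50/50 linear-discriminant evaluation
#'
#' The evaluation scheme used throughout: in each of `n_iter` iterations the
#' balanced observation pool is split at random into training and validation
#' halves with an equal number of observations of every class in each half,
#' an LDA is trained and the validation confusion matrix accumulated.
#' Per-class indices are computed per iteration and then averaged over
#' iterations (mean and standard deviation).
#'
#' @param x Observations x features matrix.
#' @param y Class labels; every class must have the same count.
#' @param n_iter Number of iterations (default 1000).
#' @param split Training fraction (default 0.5).
#' @param seed Integer seed; the whole run is reproducible from it.
#' @param lambda Ridge for [train_lda()].
#' @param condition Optional per-observation factor; when given, per-level
#'   confusion matrices of the validation predictions are accumulated too
#'   (used for per-effort-level reporting).
#' @return An object of class `emg_eval`: list with `levels`,
#'   `confusion` (summed over iterations), `per_iter` (iterations x classes
#'   x 4 index array), `mean`, `sd` (classes x 4), `macro` (named means over
#'   classes), `n_iter`, `seed`, and `condition` results if requested.
#' @export
evaluate_iterated <- function(x, y, n_iter = 1000, split = 0.5, seed = 1,
                              lambda = 1e-6, condition = NULL) {
  x <- as.matrix(x)
  y <- factor(y)
  lev <- levels(y)
  counts <- table(y)
  if (length(unique(as.integer(counts))) != 1L)
    stop("evaluate_iterated: classes are unbalanced; subsample first",
         call. = FALSE)
  idx_by_class <- lapply(lev, function(l) which(y == l))
  n_tr <- as.integer(round(counts[[1]] * split))
  if (n_tr < 2L || counts[[1]] - n_tr < 1L)
    stop("evaluate_iterated: too few observations per class for the split",
         call. = FALSE)
  if (!is.null(condition)) condition <- factor(condition)
  k <- length(lev)
  per_iter <- array(NA_real_, c(n_iter, k, 4),
                    dimnames = list(NULL, lev, c("Acc", "S", "P", "SP")))
  conf_total <- matrix(0, k, k, dimnames = list(lev, lev))
  cond_conf <- if (!is.null(condition))
    lapply(stats::setNames(levels(condition), levels(condition)),
           function(l) matrix(0, k, k, dimnames = list(lev, lev)))
  train_acc <- numeric(n_iter)
  set.seed(seed)
  for (it in seq_len(n_iter)) {
    tr <- unlist(lapply(idx_by_class, function(ix) sample(ix, n_tr)))
    va <- setdiff(unlist(idx_by_class), tr)
    fit <- train_lda(x[tr, , drop = FALSE], y[tr], lambda = lambda)
    pred <- predict(fit, x[va, , drop = FALSE])
    cm <- table(factor(y[va], levels = lev), pred)
    conf_total <- conf_total + cm
    pi <- performance_indices(cm)
    per_iter[it, , ] <- as.matrix(pi[, c("Acc", "S", "P", "SP")])
    train_acc[it] <- mean(predict(fit, x[tr, , drop = FALSE]) == y[tr])
    if (!is.null(condition)) {
      for (l in levels(condition)) {
        sel <- condition[va] == l
        if (any(sel))
          cond_conf[[l]] <- cond_conf[[l]] +
            table(factor(y[va][sel], levels = lev),
                  factor(pred[sel], levels = lev))
      }
    }
  }
  mean_idx <- apply(per_iter, c(2, 3), mean, na.rm = TRUE)
  sd_idx <- apply(per_iter, c(2, 3), stats::sd, na.rm = TRUE)
  out <- list(levels = lev, confusion = conf_total, per_iter = per_iter,
              mean = mean_idx, sd = sd_idx,
              macro = colMeans(mean_idx, na.rm = TRUE),
              train_accuracy = mean(train_acc),
              n_iter = n_iter, split = split, seed = seed)
  if (!is.null(condition))
    out$condition <- lapply(cond_conf, performance_indices)
  structure(out, class = "emg_eval")
}

#' @export
print.emg_eval <- function(x, ...) {
  cat(sprintf("Iterated LDA evaluation: %d classes, %d iterations (seed %d)\n",
              length(x$levels), x$n_iter, x$seed))
  cat(sprintf("  macro indices: Acc %.3f  S %.3f  P %.3f  SP %.3f\n",
              x$macro["Acc"], x$macro["S"], x$macro["P"], x$macro["SP"]))
  invisible(x)
}

#' @export
summary.emg_eval <- function(object, ...) {
  cat(sprintf("Iterated LDA evaluation (%d iterations, 50/50 balanced splits)\n",
              object$n_iter))
  tab <- cbind(mean = object$mean, sd = object$sd)
  print(round(tab, 4))
  cat(sprintf("mean training-set accuracy: %.4f\n", object$train_accuracy))
  invisible(object)
}
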