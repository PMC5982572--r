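# Classification protocol and classifiers.
#
# Protocol: 100 s of signal (50 s per group, the target group being the
# temporal concatenation of the 700 ms target epochs and the non-target
# group the concatenation of the Group-2 slices).  The first half of each
# group trains the classifier; the second half is cut into 5 s pieces and
# interleaved target-first into a 10-segment alternating test sequence.
# Accuracy is reported per feature window (130 test points at the default
# 2 s / 0.25 s windowing).
#
# LDA: two-class linear discriminant with pooled covariance (ridge-
# regularized if singular).  SVM: soft-margin C-SVC trained by a
# deterministic maximal-violating-pair SMO on the dual; kernels linear,
# quadratic (1 + x.y)^2, and RBF exp(-||x-y||^2 / (2 sigma^2)).  Features
# are z-scored with training-set statistics before fitting (the sigma = 1
# RBF scale presumes a normalized feature space); decision scores of
# exactly zero go to the non-target class.

#' Train/test split protocol
#'
#' @param total_duration total seconds used (default 100).
#' @param per_group seconds per group (default 50; must be half the total).
#' @param test_segment_length test segment length in seconds (default 5).
#' @param test_segment_count number of alternating test segments (default
#'   10; `length * count` must equal `per_group`).
#' @return A `split_protocol`.
#' @export
split_protocol <- function(total_duration = 100, per_group = 50,
                           test_segment_length = 5, test_segment_count = 10) {
  if (per_group * 2 != total_duration) {
    stopf("per_group * 2 must equal total_duration")
  }
  if (test_segment_length * test_segment_count != per_group) {
    stopf("test_segment_length * test_segment_count must equal per_group")
  }
  structure(list(total_duration = total_duration, per_group = per_group,
                 test_segment_length = test_segment_length,
                 test_segment_count = test_segment_count),
            class = "split_protocol")
}

#' Assemble the target / non-target group signals
#'
#' Concatenates the epochs of each label in acquisition order and truncates
#' to exactly `per_group` seconds.
#'
#' @param epochs an `epoch_set`.
#' @param protocol a [split_protocol()].
#' @return List with `p300`, `nonp300` (numeric vectors of
#'   `per_group * fs` samples) and `sampling_rate`.
#' @export
assemble_groups <- function(epochs, protocol = split_protocol()) {
  fs <- epochs$sampling_rate
  need <- as.integer(round(protocol$per_group * fs))
  grab <- function(lab) {
    sel <- which(epochs$label == lab)
    sel <- sel[order(epochs$onset_s[sel])]
    x <- as.vector(t(epochs$epochs[sel, , drop = FALSE]))
    if (length(x) < need) {
      stopf("group '%s' has %.2f s of epochs but the protocol needs %g s",
            lab, length(x) / fs, protocol$per_group)
    }
    x[seq_len(need)]
  }
  if (need == 0L) {
    return(list(p300 = numeric(0), nonp300 = numeric(0), sampling_rate = fs))
  }
  list(p300 = grab("target"), nonp300 = grab("nontarget"),
       sampling_rate = fs)
}

#' Split group signals into training halves and alternating test segments
#'
#' The first half of each group signal becomes training material; the second
#' half of each is cut into `test_segment_count / 2` pieces of
#' `test_segment_length` seconds and interleaved target-first into the
#' alternating test sequence.
#'
#' @param groups an [assemble_groups()] result.
#' @param protocol a [split_protocol()].
#' @return List with `train` (list `p300`, `nonp300`), `test` (list of
#'   `list(samples, label)` in sequence order), `sampling_rate`, `protocol`.
#' @export
split_train_test <- function(groups, protocol = split_protocol()) {
  fs <- groups$sampling_rate
  half <- protocol$per_group / 2 * fs
  seg <- protocol$test_segment_length * fs
  if (half != round(half) || seg != round(seg)) {
    stopf("protocol durations are not an integer number of samples at %g Hz", fs)
  }
  half <- as.integer(half); seg <- as.integer(seg)
  n_per_group <- protocol$test_segment_count %/% 2L
  if (n_per_group * seg != half) {
    stopf("test segments do not tile the testing half")
  }
  cut_segs <- function(x) {
    lapply(seq_len(n_per_group) - 1L,
           function(i) x[(half + i * seg + 1L):(half + (i + 1L) * seg)])
  }
  segs_t <- cut_segs(groups$p300)
  segs_n <- cut_segs(groups$nonp300)
  test <- vector("list", protocol$test_segment_count)
  for (i in seq_len(n_per_group)) {
    test[[2L * i - 1L]] <- list(samples = segs_t[[i]], label = "target")
    test[[2L * i]] <- list(samples = segs_n[[i]], label = "nontarget")
  }
  list(train = list(p300 = groups$p300[seq_len(half)],
                    nonp300 = groups$nonp300[seq_len(half)]),
       test = test, sampling_rate = fs, protocol = protocol)
}

#' Classifier specification
#'
#' @param algorithm `"svm"` or `"lda"`.
#' @param kernel SVM kernel: `"rbf"` (`exp(-||xi - xj||^2 / (2 sigma^2))`),
#'   `"linear"`, or `"quadratic"` (`(1 + xi.xj)^2`); ignored for LDA.
#' @param sigma RBF scale (> 0, default 1).
#' @param C soft-margin penalty (> 0, default 1).
#' @param standardize z-score features with training statistics before
#'   fitting (default TRUE).
#' @return A `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("svm", "lda"),
                            kernel = c("rbf", "linear", "quadratic"),
                            sigma = 1, C = 1, standardize = TRUE) {
  algorithm <- match.arg(algorithm)
  kernel <- match.arg(kernel)
  check_scalar(sigma, "sigma")
  check_scalar(C, "C")
  structure(list(algorithm = algorithm,
                 kernel = if (algorithm == "svm") kernel else NULL,
                 sigma = sigma, C = C, standardize = isTRUE(standardize)),
            class = "classifier_spec")
}

spec_label <- function(spec) {
  if (spec$algorithm == "lda") "lda" else paste0("svm-", spec$kernel)
}

kernel_matrix <- function(spec, X, Y = X) {
  switch(spec$kernel,
         linear = X %*% t(Y),
         quadratic = (1 + X %*% t(Y))^2,
         rbf = {
           d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
           exp(-pmax(d2, 0) / (2 * spec$sigma^2))
         })
}

#' Train a classifier on a 2-D feature set
#'
#' @param spec a [classifier_spec()].
#' @param train_set a `feature_set` containing both classes (>= 2 points
#'   each).
#' @return A `p300_model` usable with [predict()] and [evaluate()].
#' @export
train_classifier <- function(spec, train_set) {
  if (!inherits(spec, "classifier_spec")) stopf("'spec' must be a classifier_spec")
  X <- as.matrix(train_set[, c("x", "y")])
  y <- ifelse(train_set$label == "target", 1, -1)
  if (length(unique(y)) < 2) stopf("training set must contain both classes")
  if (min(table(y)) < 2) stopf("need at least 2 training points per class")

  key <- apply(X, 1, paste, collapse = "\r")
  conflicting <- intersect(key[y == 1], key[y == -1])
  if (length(conflicting)) {
    warnf("degenerate training input: %d identical feature point(s) appear in both classes",
          length(conflicting))
  }

  if (spec$standardize) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    if (any(scale_ == 0)) {
      warnf("constant feature in training set; left unscaled")
      scale_[scale_ == 0] <- 1
    }
  } else {
    center <- c(0, 0); scale_ <- c(1, 1)
  }
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")

  fit <- if (spec$algorithm == "lda") {
    lda_fit(Xs, y)
  } else {
    svm_smo_fit(Xs, y, spec)
  }
  structure(
    list(spec = spec, fit = fit, center = center, scale = scale_,
         feature_pair = attr(train_set, "feature_pair"),
         n_train = nrow(Xs)),
    class = "p300_model")
}

# two-class LDA with pooled covariance; ridge fallback for singularity
lda_fit <- function(X, y) {
  X1 <- X[y == 1, , drop = FALSE]
  X2 <- X[y == -1, , drop = FALSE]
  n1 <- nrow(X1); n2 <- nrow(X2)
  mu1 <- colMeans(X1); mu2 <- colMeans(X2)
  Sp <- ((n1 - 1) * stats::cov(X1) + (n2 - 1) * stats::cov(X2)) / (n1 + n2 - 2)
  ridge <- 0
  if (!is.finite(rcond_2x2(Sp)) || rcond_2x2(Sp) < 1e-10) {
    ridge <- 1e-6 * mean(diag(Sp)) + 1e-12
    warnf("singular pooled covariance; ridge term %g added", ridge)
    Sp <- Sp + diag(ridge, ncol(X))
  }
  w <- solve(Sp, mu1 - mu2)
  b <- -sum(w * (mu1 + mu2)) / 2 + log(n1 / n2)
  list(type = "lda", w = w, b = b, ridge = ridge)
}

rcond_2x2 <- function(S) {
  e <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(e)) == 0) return(0)
  min(abs(e)) / max(abs(e))
}

# Deterministic SMO (maximal-violating-pair working set selection) for the
# C-SVC dual.  n is small here (hundreds), so a dense kernel matrix is fine.
svm_smo_fit <- function(X, y, spec, tol = 1e-6, max_iter = 200000L) {
  n <- nrow(X)
  K <- kernel_matrix(spec, X)
  C <- spec$C
  alpha <- numeric(n)
  f0 <- numeric(n)              # sum_j alpha_j y_j K_ij (no bias)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    viol <- -(f0 - y)           # -E_i = y_i - f0_i
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == -1 & alpha < C - 1e-12) | (y == 1 & alpha > 1e-12)
    if (!any(up) || !any(lo)) break
    i <- which(up)[which.max(viol[up])]
    j <- which(lo)[which.min(viol[lo])]
    if (viol[i] - viol[j] < tol || iter > max_iter) break
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-12) eta <- 1e-12
    aj_old <- alpha[j]; ai_old <- alpha[i]
    Ei <- f0[i] - y[i]; Ej <- f0[j] - y[j]
    aj_new <- aj_old + y[j] * (Ei - Ej) / eta
    if (y[i] != y[j]) {
      L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
    } else {
      L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
    }
    aj_new <- min(max(aj_new, L), H)
    ai_new <- ai_old + y[i] * y[j] * (aj_old - aj_new)
    if (abs(aj_new - aj_old) < 1e-14) break
    alpha[i] <- ai_new; alpha[j] <- aj_new
    f0 <- f0 + (ai_new - ai_old) * y[i] * K[, i] +
      (aj_new - aj_old) * y[j] * K[, j]
  }
  free <- alpha > 1e-8 & alpha < C - 1e-8
  b <- if (any(free)) {
    mean(y[free] - f0[free])
  } else {
    viol <- -(f0 - y)
    up <- (y == 1 & alpha < C - 1e-12) | (y == -1 & alpha > 1e-12)
    lo <- (y == -1 & alpha < C - 1e-12) | (y == 1 & alpha > 1e-12)
    (max(viol[up]) + min(viol[lo])) / 2
  }
  sv <- alpha > 1e-8
  list(type = "svm", sv_x = X[sv, , drop = FALSE],
       sv_coef = (alpha * y)[sv], b = b, n_sv = sum(sv), iter = iter)
}

#' Predict labels for feature points
#'
#' Decision scores of exactly zero are assigned to the non-target class
#' (conservative detection).
#'
#' @param object a `p300_model`.
#' @param newdata a `feature_set` or two-column matrix.
#' @param ... unused.
#' @return Character vector of `"target"`/`"nontarget"`, with the numeric
#'   decision scores as attribute `"score"`.
#' @export
predict.p300_model <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else
    as.matrix(newdata[, c("x", "y")])
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  score <- if (object$fit$type == "lda") {
    as.vector(Xs %*% object$fit$w + object$fit$b)
  } else {
    as.vector(kernel_matrix(object$spec, Xs, object$fit$sv_x) %*%
                object$fit$sv_coef + object$fit$b)
  }
  labels <- ifelse(score > 0, "target", "nontarget")
  attr(labels, "score") <- score
  labels
}

#' Evaluate a trained classifier on a labeled test feature set
#'
#' @param model a [train_classifier()] model.
#' @param test_set a non-empty `feature_set` with the same feature pair as
#'   the training set.
#' @return An `eval_result`: `accuracy` (percent of windows correct),
#'   `per_class_accuracy`, `n_test_points`, `confusion` (2x2 table).
#' @export
evaluate <- function(model, test_set) {
  if (!inherits(model, "p300_model")) stopf("'model' must be a p300_model")
  if (nrow(test_set) == 0L) stopf("test set is empty")
  tp <- attr(test_set, "feature_pair")
  if (!is.null(tp) && !identical(tp, model$feature_pair)) {
    stopf("feature pair mismatch: model uses (%s), test set uses (%s)",
          paste(model$feature_pair, collapse = ", "),
          paste(tp, collapse = ", "))
  }
  pred <- predict(model, test_set)
  truth <- test_set$label
  conf <- table(factor(truth, c("target", "nontarget")),
                factor(pred, c("target", "nontarget")),
                dnn = c("truth", "predicted"))
  acc <- 100 * mean(pred == truth)
  per_class <- vapply(c("target", "nontarget"), function(l) {
    sel <- truth == l
    if (any(sel)) 100 * mean(pred[sel] == l) else NA_real_
  }, 0.0)
  structure(list(accuracy = acc, per_class_accuracy = per_class,
                 n_test_points = length(truth), confusion = conf),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("accuracy %.1f%% on %d test windows (target %.1f%%, non-target %.1f%%)\n",
              x$accuracy, x$n_test_points, x$per_class_accuracy[["target"]],
              x$per_class_accuracy[["nontarget"]]))
  invisible(x)
}

#' Save / load a trained model as a plain-text key-value file
#'
#' @param model a `p300_model`.
#' @param path file path.
#' @return `save_model`: invisibly `path`; `load_model`: a `p300_model`.
#' @export
save_model <- function(model, path) {
  obj <- list(version = 1L,
              spec = unclass(model$spec), fit = model$fit,
              center = model$center, scale = model$scale,
              feature_pair = model$feature_pair, n_train = model$n_train)
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path))
  fit <- obj$fit
  if (fit$type == "svm") {
    fit$sv_x <- matrix(unlist(fit$sv_x), ncol = 2)
  } else {
    fit$w <- as.numeric(fit$w)
  }
  structure(
    list(spec = structure(obj$spec, class = "classifier_spec"), fit = fit,
         center = as.numeric(obj$center), scale = as.numeric(obj$scale),
         feature_pair = as.character(obj$feature_pair),
         n_train = obj$n_train),
    class = "p300_model")
}
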