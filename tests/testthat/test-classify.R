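# Protocol assembly/splitting and the LDA / SVM classifiers.

test_that("protocol invariants are enforced", {
  expect_error(split_protocol(total_duration = 100, per_group = 40), "total")
  expect_error(split_protocol(test_segment_length = 6), "per_group")
  p <- split_protocol()
  expect_equal(p$per_group * 2, p$total_duration)
})

test_that("group assembly concatenates epochs and truncates to 50 s", {
  ep <- default_epochs()
  groups <- assemble_groups(ep)
  expect_length(groups$p300, 50 * 128)      # 72 x 89 = 6408 -> 6400
  expect_length(groups$nonp300, 50 * 128)
  # concatenation order and content: first epoch leads the group signal
  first_target <- ep$epochs[which(ep$label == "target")[1], ]
  expect_equal(groups$p300[1:89], first_target)
  # insufficient material is an error naming the deficit
  few <- ep
  keep <- c(which(ep$label == "target")[1:10], which(ep$label == "nontarget"))
  few$epochs <- ep$epochs[keep, ]; few$label <- ep$label[keep]
  few$onset_s <- ep$onset_s[keep]
  expect_error(assemble_groups(few), "needs 50 s")
  # zero-length protocol: empty signals
  p0 <- split_protocol(total_duration = 0, per_group = 0,
                       test_segment_length = 0, test_segment_count = 10)
  expect_length(assemble_groups(ep, p0)$p300, 0)
})

test_that("train/test split alternates 10 five-second segments target-first", {
  groups <- assemble_groups(default_epochs())
  sp <- split_train_test(groups)
  expect_length(sp$train$p300, 25 * 128)
  expect_length(sp$train$nonp300, 25 * 128)
  expect_length(sp$test, 10)
  expect_equal(vapply(sp$test, `[[`, "", "label"),
               rep(c("target", "nontarget"), 5))
  expect_true(all(lengths(lapply(sp$test, `[[`, "samples")) == 5 * 128))
  # train + test reconstruct each group signal exactly; no sample reused
  expect_equal(c(sp$train$p300,
                 unlist(lapply(sp$test[c(1, 3, 5, 7, 9)], `[[`, "samples"))),
               groups$p300)
  expect_equal(c(sp$train$nonp300,
                 unlist(lapply(sp$test[c(2, 4, 6, 8, 10)], `[[`, "samples"))),
               groups$nonp300)
  # 13 windows per 5 s segment, 130 test points in total
  feats <- lapply(sp$test, function(seg) {
    build_feature_vectors(abs(seg$samples), seg$label, c("skewness", "std"),
                          sampling_rate = 128)
  })
  expect_true(all(vapply(feats, nrow, 0L) == 13))
  expect_equal(sum(vapply(feats, nrow, 0L)), 130)
})

test_that("LDA separates separable clusters and matches MASS::lda", {
  tr <- gaussian_clusters(40, mu_t = c(3, 3), mu_n = c(-3, -3), sd = 0.5)
  model <- train_classifier(classifier_spec("lda"), tr)
  expect_equal(evaluate(model, tr)$accuracy, 100)
  # independent oracle: MASS::lda predictions on fresh data
  te <- gaussian_clusters(60, mu_t = c(3, 3), mu_n = c(-3, -3), sd = 2,
                          seed = 2)
  ours <- predict(model, te)
  mass_fit <- MASS::lda(cbind(tr$x, tr$y), grouping = tr$label)
  theirs <- as.character(predict(mass_fit, cbind(te$x, te$y))$class)
  expect_gt(mean(ours == theirs), 0.97)
})

test_that("the RBF kernel solves the XOR pattern where linear cannot", {
  set.seed(6)
  quad <- function(n, cx, cy) cbind(rnorm(n, cx, 0.3), rnorm(n, cy, 0.3))
  X <- rbind(quad(25, 2, 2), quad(25, -2, -2), quad(25, 2, -2), quad(25, -2, 2))
  tr <- data.frame(window_start_s = 1:100, label = rep(c("target", "nontarget"), each = 50),
                   x = X[, 1], y = X[, 2])
  attr(tr, "feature_pair") <- c("skewness", "std")
  class(tr) <- c("feature_set", "data.frame")
  acc <- function(kern) {
    m <- train_classifier(classifier_spec("svm", kern), tr)
    evaluate(m, tr)$accuracy
  }
  expect_gt(acc("rbf"), acc("linear"))
  expect_gte(acc("rbf"), 95)
  expect_gt(acc("quadratic"), acc("linear"))  # quadratic also fits XOR
})

test_that("LDA and linear SVM agree on well-separated Gaussian clusters", {
  tr <- gaussian_clusters(50, mu_t = c(2, 2), mu_n = c(-2, -2), seed = 3)
  te <- gaussian_clusters(100, mu_t = c(2, 2), mu_n = c(-2, -2), seed = 4)
  a_lda <- evaluate(train_classifier(classifier_spec("lda"), tr), te)$accuracy
  a_svm <- evaluate(train_classifier(classifier_spec("svm", "linear"), tr),
                    te)$accuracy
  expect_lte(abs(a_lda - a_svm), 5)
})

test_that("label-permuted test data scores at chance", {
  tr <- gaussian_clusters(50, mu_t = c(2, 2), mu_n = c(-2, -2), seed = 5)
  model <- train_classifier(classifier_spec("svm", "rbf"), tr)
  n <- 2000
  te <- gaussian_clusters(n / 2, mu_t = c(2, 2), mu_n = c(-2, -2), seed = 6)
  set.seed(7)
  te$label <- sample(te$label)
  acc <- evaluate(model, te)$accuracy
  expect_lt(abs(acc - 50), 3 * sqrt(0.25 / n) * 100)
})

test_that("training is deterministic and degenerate input is flagged", {
  tr <- gaussian_clusters(30, mu_t = c(1, 1), mu_n = c(-1, -1), seed = 8)
  m1 <- train_classifier(classifier_spec("svm", "rbf"), tr)
  m2 <- train_classifier(classifier_spec("svm", "rbf"), tr)
  expect_identical(m1$fit, m2$fit)
  # identical points in both classes: warning, accuracy cannot exceed chance
  dup <- tr
  dup$x <- rep(c(1, 2, 3), 20); dup$y <- rep(c(1, 2, 3), 20)
  expect_warning(md <- train_classifier(classifier_spec("svm", "rbf"), dup),
                 "both classes")
  expect_lte(evaluate(md, dup)$accuracy, 50)
  # single-class input is an error
  one <- tr[tr$label == "target", ]
  attr(one, "feature_pair") <- attr(tr, "feature_pair")
  class(one) <- class(tr)
  expect_error(train_classifier(classifier_spec("svm", "rbf"), one),
               "both classes")
})

test_that("evaluation reports per-window accuracy and confusion counts", {
  tr <- gaussian_clusters(40, mu_t = c(3, 3), mu_n = c(-3, -3), sd = 0.4)
  model <- train_classifier(classifier_spec("svm", "rbf"), tr)
  ev <- evaluate(model, tr)
  expect_equal(ev$accuracy, 100)
  expect_equal(ev$n_test_points, 80)
  expect_equal(sum(ev$confusion), 80)
  expect_equal(unname(ev$per_class_accuracy), c(100, 100))
  # feature-pair mismatch is an error
  other <- tr
  attr(other, "feature_pair") <- c("avg_power", "auc")
  expect_error(evaluate(model, other), "mismatch")
  expect_error(evaluate(model, tr[0, ]), "empty")
})

test_that("models survive a save/load round trip", {
  tr <- gaussian_clusters(30, mu_t = c(2, 1), mu_n = c(-1, -2), seed = 9)
  te <- gaussian_clusters(50, mu_t = c(2, 1), mu_n = c(-1, -2), seed = 10)
  for (spec in list(classifier_spec("svm", "rbf"), classifier_spec("lda"))) {
    model <- train_classifier(spec, tr)
    path <- file.path(tempdir(), "model.json")
    save_model(model, path)
    back <- load_model(path)
    expect_equal(as.vector(predict(back, te)), as.vector(predict(model, te)))
  }
})
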