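test_that("z-scoring standardizes train, handles constants and test rows", {
  x <- withr::with_seed(1, matrix(rnorm(200, 5, 3), 50, 4,
                                  dimnames = list(NULL, paste0("f", 1:4))))
  z <- zscore_fit_apply(x)
  expect_equal(unname(colMeans(z$train)), rep(0, 4), tolerance = 1e-9)
  expect_equal(unname(apply(z$train, 2, sd)), rep(1, 4), tolerance = 1e-9)

  xc <- cbind(x, const = 7)
  expect_warning(zc <- zscore_fit(xc), "constant")
  expect_true(all(zscore_apply(zc, xc)[, "const"] == 0))

  mu <- matrix(colMeans(x), 1, dimnames = list(NULL, colnames(x)))
  sc <- zscore_fit(x)
  expect_equal(unname(zscore_apply(sc, mu)[1, ]), rep(0, 4),
               tolerance = 1e-12)
  expect_error(zscore_apply(sc, x[, c(2, 1, 3, 4)]),
               class = "painbci_validation_error")
})

test_that("SVM separates well-separated clouds and stays calibrated on noise", {
  n <- 100
  x <- withr::with_seed(4, rbind(matrix(rnorm(n * 2, 0), n, 2),
                                 matrix(rnorm(n * 2, 6), n, 2)))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("P", "R"), each = n)
  m <- train_svm(x, y, svm_config(C = 1, gamma = 0.5))
  expect_gte(mean(predict(m, x) == y), 0.99)
  pr <- predict(m, x, type = "prob")
  expect_gt(mean(pr[1:n, "P"]), 0.9)

  expect_error(train_svm(x, rep("P", 2 * n)),
               class = "painbci_validation_error")

  # identical duplicated rows with conflicting labels: no crash, p near 0.5
  xd <- matrix(rep(c(1, 2), each = 20), 20, 2,
               dimnames = list(NULL, c("f1", "f2")))
  yd <- rep(c("P", "R"), 10)
  md <- train_svm(xd, yd, svm_config(gamma = 0.5))
  prd <- predict(md, xd[1, , drop = FALSE], type = "prob")
  expect_equal(unname(prd[1, "P"]), 0.5, tolerance = 0.15)
})

test_that("group-shuffled labels give chance-level grouped CV", {
  sub <- sc_subject(1)
  # window-level label shuffling destroys both the class signal and the
  # within-stimulus label coherence; grouped CV must fall to chance
  accs <- vapply(0:2, function(s) {
    ft <- sub$ft
    ft$label <- withr::with_seed(s, sample(ft$label))
    attr(ft, "feature_names") <- feature_names(sub$ft)
    cross_validate(ft, cv_plan(4, s, c("P", "R")))$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("grouped k-fold deals whole stimuli round-robin, deterministically", {
  groups <- rep(1:36, each = 36)
  folds <- grouped_kfold(groups, 4, seed = 2)
  gf <- attr(folds, "group_folds")
  expect_equal(as.integer(table(gf)), rep(9L, 4))
  # every window of one stimulus shares its fold
  expect_true(all(tapply(folds, groups, function(f) length(unique(f))) == 1))
  expect_identical(folds, grouped_kfold(groups, 4, seed = 2))
  # leave-one-stimulus-out limit case
  loo <- grouped_kfold(1:10, 10, seed = 1)
  expect_equal(sort(unique(loo)), 1:10)
  expect_error(grouped_kfold(1:3, 4), class = "painbci_validation_error")
})

test_that("classification metrics arithmetic", {
  y_true <- c(rep("P", 40), rep("R", 60))
  y_pred <- c(rep("P", 30), rep("R", 10), rep("P", 5), rep("R", 55))
  m <- classification_metrics(y_true, y_pred, c("P", "R"))
  expect_equal(m$accuracy, 0.85)
  expect_equal(unname(m$recall["P"]), 0.75)
  expect_equal(unname(m$precision["P"]), 30 / 35)
  expect_equal(matrix(m$confusion, 2), rbind(c(30, 10), c(5, 55)))

  perf <- classification_metrics(c("P", "R", "R"), c("P", "R", "R"))
  expect_equal(unname(diag(perf$row_normalized)), c(1, 1))

  allp <- classification_metrics(rep(c("P", "NP", "R"), 4),
                                 rep("P", 12), c("P", "NP", "R"))
  expect_equal(unname(allp$recall["P"]), 1)
  expect_equal(allp$accuracy, 1 / 3)
})

test_that("window-level folds leak across overlapping windows; grouped folds do not", {
  # under stimulus-level label shuffling there is no true class signal, so
  # any accuracy above chance in window-level folds is pure leakage from
  # overlapping windows of the same stimulus straddling the split
  sub <- sc_subject(31)
  evl <- unique(sub$ft[, c("event_id", "label")])
  diffs <- vapply(0:4, function(s) {
    ft <- sub$ft
    shuf <- withr::with_seed(s, sample(evl$label))
    ft$label <- shuf[match(ft$event_id, evl$event_id)]
    attr(ft, "feature_names") <- feature_names(sub$ft)
    u <- cross_validate(ft, cv_plan(4, s, c("P", "R")),
                        grouped = FALSE)$accuracy
    g <- cross_validate(ft, cv_plan(4, s, c("P", "R")),
                        grouped = TRUE)$accuracy
    u - g
  }, 0)
  expect_true(all(diffs > 0))   # inflation on every seed
})

test_that("cross-validation is deterministic and supports 3 classes", {
  sub <- sc_subject(1)
  r1 <- cross_validate(sub$ft, cv_plan(4, 3, c("P", "R")))
  r2 <- cross_validate(sub$ft, cv_plan(4, 3, c("P", "R")))
  expect_identical(r1$confusion, r2$confusion)
  r3 <- cross_validate(sub$ft, cv_plan(4, 3, c("P", "NP", "R")))
  expect_equal(sum(r3$confusion), nrow(sub$ft))
  expect_gt(r3$accuracy, 1 / 3)   # SC separates P from the rest
})
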