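# Classifiers, cross-validation protocol, method comparison, confusion
# analysis and the real-sample scoring scheme.

test_that("KNN with k = 1 reproduces its training set exactly", {
  set.seed(2)
  x <- matrix(rnorm(60 * 5), 60, 5)
  y <- factor(rep(letters[1:3], each = 20))
  clf <- train_classifier("KNN", x, y, hyper = list(k = 1))
  expect_equal(predict(clf, x)$class, y)
})

test_that("tree learners are deterministic under a fixed seed", {
  set.seed(3)
  x <- matrix(rnorm(90 * 6), 90, 6)
  y <- factor(rep(c("u", "v", "w"), each = 30))
  for (cl in c("RF", "XGB")) {
    p1 <- predict(train_classifier(cl, x, y, hyper = list(ntree = 100,
                                                          nrounds = 30),
                                   seed = 5), x)
    p2 <- predict(train_classifier(cl, x, y, hyper = list(ntree = 100,
                                                          nrounds = 30),
                                   seed = 5), x)
    expect_identical(p1$class, p2$class, label = cl)
  }
})

test_that("well-separated Gaussian blobs are classified almost perfectly", {
  set.seed(4)
  n <- 120
  x <- rbind(matrix(rnorm(n * 2, 0, 0.5), ncol = 2),
             matrix(rnorm(n * 2, 6, 0.5), ncol = 2))
  y <- factor(rep(c("lo", "hi"), each = n))
  tr <- c(seq_len(80), n + seq_len(80))
  te <- setdiff(seq_len(2 * n), tr)
  for (cl in c("KNN", "RF", "XGB")) {
    clf <- train_classifier(cl, x[tr, ], y[tr],
                            hyper = list(ntree = 100, nrounds = 30),
                            seed = 1)
    expect_gte(mean(predict(clf, x[te, ])$class == y[te]), 0.99)
  }
})

test_that("PL demands a trained CNN and non-finite latents are rejected", {
  expect_error(train_classifier("PL", matrix(0, 2, 2),
                                factor(c("a", "b"))), "softmax head")
  x <- matrix(c(1, NA, 2, 3), 2, 2)
  expect_error(train_classifier("RF", x, factor(c("a", "b"))),
               "non-finite latent")
})

test_that("cross-validation is perfect on a perfectly encoded dataset", {
  set.seed(6)
  ds <- fixture_ds_perfect(n_per_class = 15)
  ev <- cross_validate(ds, preprocess = "none",
                       representation = "identity", classifier = "KNN",
                       k = 5, repeats = 3, seed = 2)
  expect_equal(ev$accuracy, rep(1, 3))
  expect_length(ev$accuracy, 3)
  expect_equal(unname(ev$recall), rep(1, 3))
})

test_that("label-shuffled data scores at chance level", {
  set.seed(7)
  ds <- fixture_ds_perfect(n_per_class = 24, noise = 0.1)
  ds$labels <- sample(ds$labels)
  ev <- cross_validate(ds, preprocess = "none",
                       representation = "identity", classifier = "KNN",
                       k = 4, repeats = 3, seed = 9)
  # 3 classes: chance = 1/3; binomial 3-sigma band around it
  band <- 3 * sqrt(1 / 3 * 2 / 3 / nrow(ds$intensities))
  expect_lt(abs(ev$mean - 1 / 3), band + 0.08)
})

test_that("the evaluation report carries one accuracy per repeat", {
  ds <- fixture_ds_perfect(n_per_class = 10, noise = 0.3)
  ev <- cross_validate(ds, preprocess = "none",
                       representation = "identity", classifier = "KNN",
                       k = 5, repeats = 7, seed = 3)
  expect_length(ev$accuracy, 7)
  expect_true(all(ev$accuracy >= 0 & ev$accuracy <= 1))
  expect_equal(rowSums(ev$confusion), rep(1, 3), ignore_attr = TRUE)
})

test_that("classes smaller than k are rejected", {
  ds <- fixture_ds_perfect(n_per_class = 3)
  expect_error(cross_validate(ds, preprocess = "none",
                              representation = "identity",
                              classifier = "KNN", k = 5, repeats = 1),
               "< k")
})

test_that("Wilcoxon comparison separates clear gaps and ties", {
  expect_equal(as.character(compare_wilcoxon(rep(0.8, 20), rep(0.8, 20))),
               "indistinguishable")
  v <- compare_wilcoxon(rep(0.9, 20) + seq(0, 1e-3, length.out = 20),
                        rep(0.5, 20) + seq(0, 1e-3, length.out = 20))
  expect_equal(as.character(v), "better")
  expect_lt(attr(v, "p.value"), 1e-6)
  expect_equal(as.character(
    compare_wilcoxon(rep(0.5, 20),
                     rep(0.9, 20) + seq(0, 1e-3, length.out = 20))),
    "worse")
  expect_error(compare_wilcoxon(1:3 / 10, 1:4 / 10), "equal length")
})

test_that("overlapping distributions are indistinguishable at alpha = 0.01", {
  set.seed(11)
  # simulated null calibration: tiny shift far below the noise scale
  res <- replicate(40, {
    a <- rnorm(10, 0.80, 0.03)
    b <- rnorm(10, 0.801, 0.03)
    as.character(compare_wilcoxon(a, b)) == "indistinguishable"
  })
  expect_gt(mean(res), 0.9)
})

test_that("confusion report rows sum to one and diagnose perfection and chance", {
  y <- factor(rep(ff_shapes(), each = 10), levels = ff_shapes())
  cr <- confusion_report(y, y)
  expect_equal(unname(cr$confusion), diag(9), ignore_attr = TRUE)
  expect_equal(unname(cr$recall), rep(1, 9))
  set.seed(12)
  ypred <- sample(y, replace = FALSE)
  cr2 <- confusion_report(ypred, y)
  expect_equal(rowSums(cr2$confusion), rep(1, 9), ignore_attr = TRUE)
  set.seed(13)
  big <- factor(sample(ff_shapes(), 9000, TRUE), levels = ff_shapes())
  truth <- factor(rep(ff_shapes(), each = 1000), levels = ff_shapes())
  cr3 <- confusion_report(big, truth)
  expect_lt(max(abs(cr3$confusion - 1 / 9)), 0.05)
})

test_that("real-sample scores follow the informative-confusion map", {
  all_ok <- real_data_score(rep("sphere", 10), rep("sphere", 10))
  expect_equal(all_ok$total, 10)
  expect_equal(real_data_score("prolate_ellipsoid", "sphere")$total, 0)
  expect_equal(real_data_score("oblate_ellipsoid",
                               "prolate_ellipsoid")$total, 0)
  expect_equal(real_data_score("core_shell_cylinder", "sphere")$total, -1)
  expect_equal(real_data_score("hollow_sphere",
                               "core_shell_sphere")$total, 0)
  expect_equal(real_data_score(rep("cylinder", 10),
                               rep("sphere", 10))$total, -10)
  expect_error(real_data_score("pyramid", "sphere"), "unknown class")
  mixed <- real_data_score(
    c("sphere", "prolate_ellipsoid", "cylinder"),
    c("sphere", "sphere", "sphere"))
  expect_equal(mixed$contributions, c(1L, 0L, -1L))
})

test_that("session aggregation reports frequencies that sum to one", {
  pm <- rbind(c("sphere", "cylinder"), c("sphere", "sphere"),
              c("oblate_ellipsoid", "cylinder"))
  out <- score_sessions(pm, c("sphere", "cylinder"))
  expect_equal(colSums(out$frequencies), c(1, 1), ignore_attr = TRUE)
  expect_equal(out$frequencies["sphere", 1], 2 / 3, ignore_attr = TRUE)
  expect_length(out$scores, 3)
  # session 2: sphere correct (+1), cylinder predicted sphere (-1)
  expect_equal(out$scores[2], 0)
})

test_that("a label leaked only into test folds cannot raise accuracy", {
  ds <- fixture_ds_x()
  base <- cross_validate(ds, representation = "identity",
                         classifier = "RF", hyper = list(ntree = 150),
                         k = 3, repeats = 2, seed = 21)
  leak <- cross_validate(ds, representation = "identity",
                         classifier = "RF", hyper = list(ntree = 150),
                         k = 3, repeats = 2, seed = 21, canary = TRUE)
  expect_lte(leak$mean, base$mean + 0.10)
  expect_lt(leak$mean, 0.9)
})
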