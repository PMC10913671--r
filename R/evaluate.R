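# Benchmark protocols: repeated stratified cross-validation, rank-sum
# method comparison, cross-configuration transfer, confusion analysis and
# the real-sample scoring scheme.

#' Subset a dataset by curve index
#'
#' @param dataset A `saxs_dataset`.
#' @param idx Integer or logical row index.
#' @param drop_levels Drop unused label levels (default `FALSE`: class set
#'   is part of the problem definition).
#' @return The subsetted `saxs_dataset`.
#' @export
dataset_subset <- function(dataset, idx, drop_levels = FALSE) {
  out <- dataset
  out$intensities <- dataset$intensities[idx, , drop = FALSE]
  out$q <- dataset$q[idx, , drop = FALSE]
  out$labels <- if (drop_levels) droplevels(dataset$labels[idx]) else
    dataset$labels[idx]
  out$config_ids <- dataset$config_ids[idx]
  out$params <- dataset$params[idx, , drop = FALSE]
  out$models <- dataset$models[idx]
  out
}

# stratified fold ids (1..k) drawn with the current RNG
.stratified_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in levels(labels)) {
    m <- which(labels == cl)
    if (length(m) < k) {
      stop("class '", cl, "' has ", length(m), " < k = ", k, " members",
           call. = FALSE)
    }
    folds[m[sample.int(length(m))]] <- rep_len(seq_len(k), length(m))
  }
  folds
}

#' Repeated stratified k-fold cross-validation of one method
#'
#' The full protocol: in every repeat the dataset is split into k
#' stratified folds; for each fold the preprocessing statistics,
#' representation (including the CNN) and classifier are fitted on the
#' training folds only and evaluated on the held-out fold.  The repeat's
#' accuracy pools the held-out predictions of all folds.  Repeats re-draw
#' the folds and re-initialize all learners with derived seeds `seed + r`,
#' so different methods run with paired splits when given the same `seed`.
#'
#' @inheritParams ff_fit
#' @param k Number of folds (default 5).
#' @param repeats Number of train/test repetitions (default 20).
#' @param seed Base seed.
#' @param canary Diagnostic leakage check: append one extra latent feature
#'   that is random noise in training folds but equals the numeric class
#'   label in test folds.  With a leakage-free pipeline this cannot raise
#'   accuracy.
#' @return Object of class `ff_eval`: `accuracy` (one value per repeat),
#'   `mean`, `sd`, `ci3` (mean +- 3 sd), row-normalized `confusion`,
#'   per-class `recall`, `predictions` (last repeat).
#' @export
cross_validate <- function(dataset, preprocess = "best",
                           representation = "cnn", classifier = "XGB",
                           input_mode = "I", hyper = list(),
                           cnn_opts = list(), k = 5, repeats = 20,
                           seed = 1, canary = FALSE) {
  labels <- factor(dataset$labels)
  n <- length(labels)
  acc <- numeric(repeats)
  cm <- matrix(0, nlevels(labels), nlevels(labels),
               dimnames = list(levels(labels), levels(labels)))
  last_pred <- NULL
  for (r in seq_len(repeats)) {
    rs <- (seed + r) %% 2147483647L
    set.seed(rs)
    folds <- .stratified_folds(labels, k)
    pred <- factor(rep(NA_character_, n), levels = levels(labels))
    for (f in seq_len(k)) {
      te <- folds == f
      dtr <- dataset_subset(dataset, !te)
      pipeline <- pp_fit(pp_pipeline(preprocess), dtr$intensities, dtr$q)
      trtr <- pp_apply(pipeline, dtr$intensities, dtr$q)
      rep_f <- rep_fit(representation, trtr$x, q = trtr$q,
                       labels = dtr$labels, input_mode = input_mode,
                       cnn_opts = cnn_opts, seed = rs + f)
      dte <- dataset_subset(dataset, te)
      trte <- pp_apply(pipeline, dte$intensities, dte$q)
      if (classifier == "PL") {
        pr <- predict(train_classifier("PL", NULL, dtr$labels,
                                       cnn_model = rep_f$state),
                      trte$x, q = trte$q)
        pred[te] <- pr$class
      } else {
        ltr <- rep_transform(rep_f, trtr$x, trtr$q)
        lte <- rep_transform(rep_f, trte$x, trte$q)
        if (canary) {
          set.seed(rs + 1000L + f)
          ltr <- cbind(ltr, stats::runif(nrow(ltr)))
          lte <- cbind(lte, as.numeric(dte$labels))
        }
        ok_tr <- stats::complete.cases(ltr)
        ok_te <- stats::complete.cases(lte)
        clf <- train_classifier(classifier, ltr[ok_tr, , drop = FALSE],
                                dtr$labels[ok_tr], hyper = hyper,
                                seed = rs + f)
        if (any(ok_te)) {
          pred[which(te)[ok_te]] <-
            predict(clf, lte[ok_te, , drop = FALSE])$class
        }
      }
    }
    scored <- !is.na(pred)
    acc[r] <- mean(pred[scored] == labels[scored])
    cm <- cm + table(labels, pred, useNA = "no")
    last_pred <- pred
  }
  conf <- confusion_report(last_pred, labels, counts = cm)
  structure(list(accuracy = acc, mean = mean(acc), sd = stats::sd(acc),
                 ci3 = mean(acc) + c(-3, 3) * stats::sd(acc),
                 confusion = conf$confusion, recall = conf$recall,
                 predictions = last_pred, labels = labels,
                 method = list(preprocess = preprocess,
                               representation = representation,
                               classifier = classifier,
                               input_mode = input_mode),
                 k = k, repeats = repeats, seed = seed),
            class = "ff_eval")
}

#' @export
print.ff_eval <- function(x, ...) {
  cat("<ff_eval> ", x$method$representation, " ° ", x$method$classifier,
      ": accuracy ", sprintf("%.1f%%", 100 * x$mean), " +- ",
      sprintf("%.1f", 300 * x$sd), " (3 sigma, ", x$repeats,
      " repeats, ", x$k, "-fold CV)\n", sep = "")
  invisible(x)
}

#' Compare two methods' repeat accuracies with a Wilcoxon rank-sum test
#'
#' @param accuracies_a,accuracies_b Equal-length vectors of per-repeat
#'   accuracies (or `ff_eval` objects).
#' @param alpha Significance threshold (default 0.01).
#' @return `"better"`, `"worse"` or `"indistinguishable"` (for a), with
#'   the p value as attribute `p.value`.
#' @export
compare_wilcoxon <- function(accuracies_a, accuracies_b, alpha = 0.01) {
  a <- if (inherits(accuracies_a, "ff_eval")) accuracies_a$accuracy else
    accuracies_a
  b <- if (inherits(accuracies_b, "ff_eval")) accuracies_b$accuracy else
    accuracies_b
  if (length(a) != length(b)) {
    stop("repeat vectors must have equal length", call. = FALSE)
  }
  if (all(a == b)) {
    return(structure("indistinguishable", p.value = 1))
  }
  p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  verdict <- if (!is.finite(p) || p >= alpha) "indistinguishable"
    else if (mean(a) > mean(b)) "better" else "worse"
  structure(verdict, p.value = p)
}

#' Cross-configuration transfer experiment
#'
#' Trains one method on each provided training dataset and evaluates it on
#' every test dataset (typically single-configuration synthetic test sets),
#' repeating with derived seeds.  Reproduces the structure of the
#' train-configuration x test-configuration accuracy table: diagonal-high
#' for single-configuration training, restored by mixed training.
#'
#' @param train_sets Named list of training `saxs_dataset`s (e.g. DS_X,
#'   DS_N, DS_mix, DS_all).
#' @param test_sets Named list of test `saxs_dataset`s (one per
#'   configuration), grid-compatible with the training sets.
#' @inheritParams ff_fit
#' @param repeats Number of training repetitions per cell.
#' @return Object of class `ff_transfer`: `accuracy` (train x test matrix
#'   of means), `sd`, `per_repeat`.
#' @export
transfer_matrix <- function(train_sets, test_sets, preprocess = "best",
                            representation = "cnn", classifier = "XGB",
                            input_mode = "I", hyper = list(),
                            cnn_opts = list(), repeats = 5, seed = 1) {
  J <- unique(c(vapply(train_sets, function(d) ncol(d$intensities), 1L),
                vapply(test_sets, function(d) ncol(d$intensities), 1L)))
  if (length(J) != 1) {
    stop("all datasets must share the input length J; use ",
         "resample_to_grid()/truncate_low_q() consistently", call. = FALSE)
  }
  res <- array(NA_real_, c(length(train_sets), length(test_sets), repeats),
               dimnames = list(names(train_sets), names(test_sets), NULL))
  for (i in seq_along(train_sets)) {
    for (r in seq_len(repeats)) {
      fit <- ff_fit(train_sets[[i]], preprocess = preprocess,
                    representation = representation,
                    classifier = classifier, input_mode = input_mode,
                    hyper = hyper, cnn_opts = cnn_opts,
                    seed = (seed + r) %% 2147483647L)
      for (j in seq_along(test_sets)) {
        pred <- predict(fit, test_sets[[j]])
        truth <- factor(test_sets[[j]]$labels, levels = fit$classes)
        res[i, j, r] <- mean(pred == truth, na.rm = TRUE)
      }
    }
  }
  structure(list(accuracy = apply(res, 1:2, mean),
                 sd = apply(res, 1:2, stats::sd), per_repeat = res,
                 repeats = repeats),
            class = "ff_transfer")
}

#' @export
print.ff_transfer <- function(x, ...) {
  cat("<ff_transfer> mean accuracy (train rows x test columns, ",
      x$repeats, " repeats)\n", sep = "")
  print(round(100 * x$accuracy, 1))
  invisible(x)
}

#' Row-normalized confusion matrix and per-class recall
#'
#' @param predictions Factor (or character) of predicted classes.
#' @param labels True classes, same length.
#' @param counts Optional precomputed contingency table (rows = truth) to
#'   normalize instead.
#' @return List with `confusion` (rows sum to 1) and `recall` (diagonal).
#' @export
confusion_report <- function(predictions, labels, counts = NULL) {
  labels <- factor(labels)
  if (is.null(counts)) {
    predictions <- factor(predictions, levels = levels(labels))
    counts <- table(labels, predictions, useNA = "no")
  }
  counts <- unclass(as.matrix(counts))
  rs <- rowSums(counts)
  conf <- counts / ifelse(rs == 0, 1, rs)
  list(confusion = conf, recall = diag(conf))
}

# informative-confusion map: the paper's stated pairs (sphere ~ ellipsoids,
# prolate ~ oblate/sphere, core-shell sphere ~ shelled near-shapes)
# extended symmetrically by the same similarity logic — homogeneous
# near-shapes pairwise informative, shelled near-shapes pairwise
# informative; cylinders have no near-shape in the other group.
.informative_map <- list(
  sphere = c("prolate_ellipsoid", "oblate_ellipsoid"),
  prolate_ellipsoid = c("oblate_ellipsoid", "sphere"),
  oblate_ellipsoid = c("prolate_ellipsoid", "sphere"),
  cylinder = character(0),
  core_shell_cylinder = character(0),
  core_shell_sphere = c("core_shell_prolate", "core_shell_oblate",
                        "hollow_sphere"),
  core_shell_prolate = c("core_shell_oblate", "core_shell_sphere",
                         "hollow_sphere"),
  core_shell_oblate = c("core_shell_prolate", "core_shell_sphere",
                        "hollow_sphere"),
  hollow_sphere = c("core_shell_sphere", "core_shell_prolate",
                    "core_shell_oblate"))

#' Score predictions on labelled real samples
#'
#' Each sample contributes +1 for a correct prediction, 0 for an
#' informative prediction (confusion with a geometrically similar form
#' factor: sphere with an ellipsoid, prolate with an oblate or sphere,
#' core-shell sphere with another shelled near-shape, ...) and -1
#' otherwise; with 10 samples the total ranges from -10 (all misclassified)
#' to +10 (all correct).
#'
#' @param predictions Predicted classes (character/factor).
#' @param truth True classes, same length, within [ff_shapes()].
#' @return Object of class `real_score`: `contributions` in `{-1, 0, +1}`
#'   and `total`.
#' @export
real_data_score <- function(predictions, truth) {
  predictions <- as.character(predictions)
  truth <- as.character(truth)
  stopifnot(length(predictions) == length(truth))
  if (!all(c(predictions, truth) %in% ff_shapes())) {
    stop("unknown class label(s): ",
         paste(setdiff(c(predictions, truth), ff_shapes()),
               collapse = ", "), call. = FALSE)
  }
  contrib <- vapply(seq_along(truth), function(i) {
    if (predictions[i] == truth[i]) 1L
    else if (predictions[i] %in% .informative_map[[truth[i]]]) 0L
    else -1L
  }, integer(1))
  structure(list(contributions = contrib, total = sum(contrib)),
            class = "real_score")
}

#' @export
print.real_score <- function(x, ...) {
  cat("<real_score> total ", sprintf("%+d", x$total), " over ",
      length(x$contributions), " samples (",
      sum(x$contributions == 1), " correct, ",
      sum(x$contributions == 0), " informative, ",
      sum(x$contributions == -1), " wrong)\n", sep = "")
  invisible(x)
}

#' Aggregate real-sample predictions over repeated training sessions
#'
#' @param prediction_matrix Sessions x samples matrix of predicted class
#'   labels (character), e.g. one row per independently trained model.
#' @param truth True class per sample.
#' @return List with `frequencies` (classes x samples prediction
#'   frequencies over sessions, columns sum to 1), `scores` (per-session
#'   [real_data_score()] totals), `mean`, `sd`.
#' @export
score_sessions <- function(prediction_matrix, truth) {
  pm <- rbind(prediction_matrix)
  scores <- apply(pm, 1, function(p) real_data_score(p, truth)$total)
  freq <- apply(pm, 2, function(col) {
    tab <- table(factor(col, levels = ff_shapes()))
    as.numeric(tab) / length(col)
  })
  rownames(freq) <- ff_shapes()
  list(frequencies = freq, scores = scores, mean = mean(scores),
       sd = stats::sd(scores))
}
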