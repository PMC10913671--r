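# Classifiers operating on latent spaces.  KNN is implemented here with a
# deterministic smallest-class-index tie-break (reproducibility contract);
# RF and XGBoost wrap randomForest / xgboost; PL is the CNN's own softmax
# head and is only valid with the cnn representation.

.classifiers <- c("KNN", "RF", "XGB", "PL")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a classifier on a latent-space matrix
#'
#' @param classifier `"KNN"`, `"RF"`, `"XGB"` or `"PL"`.
#' @param latent Numeric latent matrix (N x d), finite.
#' @param labels Factor of length N.
#' @param hyper Named list of hyper-parameters. Defaults: KNN `k = 5`
#'   (Euclidean distance, distance-then-index tie order, smallest class
#'   index on tied votes); RF `ntree = 500`; XGB `nrounds = 500`,
#'   `max_depth = 6`, `eta = 0.1`.
#' @param seed Integer seed (tree learners).
#' @param cnn_model For `"PL"` only: the trained [cnn_build()] network
#'   whose softmax head is the classifier.
#' @return Object of class `ff_classifier`.
#' @export
train_classifier <- function(classifier, latent, labels, hyper = list(),
                             seed = 1, cnn_model = NULL) {
  classifier <- match.arg(classifier, .classifiers)
  labels <- factor(labels)
  if (classifier == "PL") {
    if (is.null(cnn_model) || !inherits(cnn_model, "cnn_model")) {
      stop("PL is the CNN's softmax head: it is only employed in ",
           "combination with the cnn representation", call. = FALSE)
    }
    return(structure(list(classifier = "PL", cnn = cnn_model,
                          classes = levels(labels)),
                     class = "ff_classifier"))
  }
  latent <- rbind(latent)
  bad <- !stats::complete.cases(latent) | !apply(is.finite(latent), 1, all)
  if (any(bad)) {
    stop("non-finite latent features for ", sum(bad),
         " curve(s); check the representation", call. = FALSE)
  }
  fit <- switch(classifier,
    KNN = list(x = latent, y = labels, k = hyper$k %||% 5L),
    RF = {
      set.seed(seed)
      randomForest::randomForest(x = latent, y = labels,
                                 ntree = hyper$ntree %||% 500L)
    },
    XGB = {
      colnames(latent) <- paste0("f", seq_len(ncol(latent)))
      xgboost::xgboost(
        x = latent, y = labels,
        objective = if (nlevels(labels) > 2) "multi:softprob" else
          "binary:logistic",
        nrounds = hyper$nrounds %||% 500L,
        max_depth = hyper$max_depth %||% 6L,
        learning_rate = hyper$eta %||% 0.1,
        nthreads = 1L, seed = seed, verbosity = 0)
    })
  structure(list(classifier = classifier, fit = fit,
                 classes = levels(labels)),
            class = "ff_classifier")
}

# Euclidean KNN with deterministic tie handling: neighbours ordered by
# (distance, training index); tied votes resolved to the smallest class
# index.
.knn_predict <- function(fit, newx) {
  tr <- fit$x; k <- min(fit$k, nrow(tr))
  d2 <- outer(rowSums(newx^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(newx)), rowSums(tr^2)) - 2 * newx %*% t(tr)
  ncl <- nlevels(fit$y)
  prob <- matrix(0, nrow(newx), ncl, dimnames = list(NULL, levels(fit$y)))
  cls <- integer(nrow(newx))
  for (i in seq_len(nrow(newx))) {
    nb <- order(d2[i, ], seq_len(nrow(tr)))[seq_len(k)]
    votes <- tabulate(as.integer(fit$y[nb]), nbins = ncl)
    prob[i, ] <- votes / k
    cls[i] <- which.max(votes)  # which.max takes the first (smallest) index
  }
  list(class = factor(levels(fit$y)[cls], levels = levels(fit$y)),
       prob = prob)
}

#' Predict with a trained latent-space classifier
#'
#' @param object An [train_classifier()] result.
#' @param latent New latent matrix (for `"PL"`, the preprocessed curves and
#'   optionally `q`, forwarded to the network).
#' @param q q grid(s), `"PL"`/`"Iq"` mode only.
#' @param ... Unused.
#' @return List with `class` (factor) and `prob` (N x n_classes matrix).
#' @export
predict.ff_classifier <- function(object, latent, q = NULL, ...) {
  latent <- rbind(latent)
  out <- switch(object$classifier,
    KNN = .knn_predict(object$fit, latent),
    RF = {
      prob <- stats::predict(object$fit, latent, type = "prob")
      list(class = factor(colnames(prob)[max.col(prob, "first")],
                          levels = object$classes),
           prob = prob)
    },
    XGB = {
      colnames(latent) <- paste0("f", seq_len(ncol(latent)))
      prob <- stats::predict(object$fit, latent)
      if (length(object$classes) == 2 && is.null(dim(prob))) {
        prob <- cbind(1 - prob, prob)  # P(second level) from the binary fit
      }
      colnames(prob) <- object$classes
      list(class = factor(object$classes[max.col(prob, "first")],
                          levels = object$classes),
           prob = prob)
    },
    PL = {
      prob <- cnn_predict_proba(object$cnn, latent, q)
      cls <- object$classes[max.col(prob[, seq_along(object$classes),
                                         drop = FALSE], "first")]
      list(class = factor(cls, levels = object$classes),
           prob = prob[, seq_along(object$classes), drop = FALSE])
    })
  out
}

#' @export
print.ff_classifier <- function(x, ...) {
  cat("<ff_classifier> ", x$classifier, " over ",
      length(x$classes), " classes\n", sep = "")
  invisible(x)
}
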