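# The central modelling interface: fit one form-factor classification
# method (preprocessing ° representation ° classifier) on a labelled
# dataset, and predict form factors for new curves.

#' Fit a form-factor classification model
#'
#' Chains the three stages of the classification method on a training
#' dataset: (i) the preprocessing pipeline ([pp_pipeline()], statistics
#' fitted here and frozen), (ii) the latent-space representation
#' ([rep_fit()]), (iii) the classifier ([train_classifier()]).  `"PL"`
#' (the softmax perceptron layer) is only valid with the `"cnn"`
#' representation, whose trained head it reuses.
#'
#' @param dataset A `saxs_dataset` from [build_dataset()] (or compatible
#'   list with `intensities`, `q`, `labels`).
#' @param preprocess Preprocessing spec for [pp_pipeline()] (default
#'   `"best"` = TH, IntN, LOG, STD, QLOG).
#' @param representation Representation kind for [rep_fit()].
#' @param classifier `"KNN"`, `"RF"`, `"XGB"` or `"PL"`.
#' @param input_mode CNN input mode: `"I"` or `"Iq"` (2-channel (I, q)).
#' @param hyper Classifier hyper-parameters, see [train_classifier()].
#' @param cnn_opts CNN training options, see [cnn_train()].
#' @param seed Integer seed controlling every stochastic element of the
#'   fit.
#' @return Object of class `ff_model` with [predict.ff_model()],
#'   [print.ff_model()] and [summary.ff_model()] methods.
#' @examples
#' \donttest{
#' cfg <- builtin_config("Xeuss1800HR")
#' ds <- build_dataset("DS_X", n_per_class = 6, seed = 7,
#'                     configs = list(cfg), shapes = c("sphere", "cylinder"))
#' fit <- ff_fit(ds, representation = "identity", classifier = "KNN")
#' predict(fit, ds)
#' }
#' @export
ff_fit <- function(dataset, preprocess = "best", representation = "cnn",
                   classifier = "XGB", input_mode = "I", hyper = list(),
                   cnn_opts = list(), seed = 1) {
  stopifnot(is.matrix(dataset$intensities))
  labels <- factor(dataset$labels)
  pipeline <- if (inherits(preprocess, "pp_pipeline")) preprocess else
    pp_pipeline(preprocess)
  pipeline <- pp_fit(pipeline, dataset$intensities, dataset$q)
  tr <- pp_apply(pipeline, dataset$intensities, dataset$q)
  rep <- rep_fit(representation, tr$x, q = tr$q, labels = labels,
                 input_mode = input_mode, cnn_opts = cnn_opts, seed = seed)
  if (classifier == "PL") {
    clf <- train_classifier("PL", NULL, labels, cnn_model = rep$state)
  } else {
    latent <- rep_transform(rep, tr$x, tr$q)
    ok <- stats::complete.cases(latent)
    if (!all(ok) && !startsWith(rep$kind, "franke")) {
      stop("non-finite latent features from representation '", rep$kind,
           "'", call. = FALSE)
    }
    clf <- train_classifier(classifier, latent[ok, , drop = FALSE],
                            labels[ok], hyper = hyper, seed = seed)
  }
  structure(list(pipeline = pipeline, rep = rep, clf = clf,
                 classes = levels(labels), input_mode = input_mode,
                 J = ncol(dataset$intensities), seed = seed,
                 n_train = nrow(dataset$intensities),
                 q_grid = dataset$q[1, ]),
            class = "ff_model")
}

# accept a saxs_dataset, a saxs_curve or a bare matrix + grid
.newdata_xq <- function(object, newdata, q = NULL) {
  if (inherits(newdata, "saxs_curve")) {
    list(x = rbind(newdata$intensity),
         q = rbind(newdata$q))
  } else if (is.list(newdata) && !is.null(newdata$intensities)) {
    list(x = newdata$intensities, q = newdata$q)
  } else {
    x <- rbind(newdata)
    if (is.null(q)) stop("matrix input requires the q grid(s)",
                         call. = FALSE)
    list(x = x, q = if (is.matrix(q)) q else
      matrix(q, nrow(x), length(q), byrow = TRUE))
  }
}

#' Predict form factors for new curves
#'
#' @param object An [ff_fit()] model.
#' @param newdata A `saxs_dataset`, a [saxs_curve()], or an intensity
#'   matrix (then supply `q`). Curves must be on the training grid length.
#' @param type `"class"` for the predicted labels (default), `"prob"` for
#'   the class-probability matrix (all-zero rows with an `NA` class for
#'   curves whose representation is undefined, e.g. no gyration radius).
#' @param q Optional q grid(s) for matrix input.
#' @param ... Unused.
#' @return Factor of predicted classes, or probability matrix.
#' @export
predict.ff_model <- function(object, newdata, type = c("class", "prob"),
                             q = NULL, ...) {
  type <- match.arg(type)
  nd <- .newdata_xq(object, newdata, q)
  if (ncol(nd$x) != object$J) {
    stop("curve length ", ncol(nd$x), " does not match the training ",
         "grid length ", object$J, "; resample first", call. = FALSE)
  }
  tr <- pp_apply(object$pipeline, nd$x, nd$q)
  if (object$clf$classifier == "PL") {
    out <- predict(object$clf, tr$x, q = tr$q)
  } else {
    latent <- rep_transform(object$rep, tr$x, tr$q)
    ok <- stats::complete.cases(latent)
    cls <- factor(rep(NA_character_, nrow(latent)),
                  levels = object$classes)
    prob <- matrix(0, nrow(latent), length(object$classes),
                   dimnames = list(NULL, object$classes))
    if (any(ok)) {
      pr <- predict(object$clf, latent[ok, , drop = FALSE])
      cls[ok] <- pr$class
      prob[ok, ] <- pr$prob
    }
    out <- list(class = cls, prob = prob)
  }
  if (type == "class") out$class else out$prob
}

#' @export
print.ff_model <- function(x, ...) {
  cat("<ff_model> ", paste(if (length(x$pipeline$spec))
    paste(x$pipeline$spec, collapse = " ° ") else "I", "°",
    x$rep$kind, "°", x$clf$classifier), "\n", sep = "")
  cat("  trained on ", x$n_train, " curves (J = ", x$J, "), ",
      length(x$classes), " classes, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ff_model <- function(object, ...) {
  cat("Form-factor classification model\n")
  cat("  preprocessing: ", if (length(object$pipeline$spec))
    paste(object$pipeline$spec, collapse = " ° ") else "(identity)", "\n",
    sep = "")
  cat("  representation: ", object$rep$kind, " (latent dim ",
      rep_dim(object$rep), ")", if (object$rep$kind == "cnn")
        paste0(", input mode ", object$input_mode), "\n", sep = "")
  cat("  classifier: ", object$clf$classifier, "\n", sep = "")
  cat("  classes: ", paste(object$classes, collapse = ", "), "\n", sep = "")
  cat("  training curves: ", object$n_train, ", grid length ", object$J,
      "\n", sep = "")
  invisible(object)
}
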