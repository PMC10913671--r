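# Latent-space representations on preprocessed curves: identity, Kratky
# invariant features (5 or 200 points), PCA at 90% kept variance, and the
# supervised CNN encoder.  All share a fit/transform interface so the
# cross-validation harness can fit them strictly inside training folds.

#' Fit a PCA representation keeping a target fraction of variance
#'
#' @param x Training matrix (curves in rows).
#' @param variance_kept Fraction of total variance to keep (default 0.90):
#'   the smallest k principal components whose cumulative explained
#'   variance reaches it are retained.
#' @return Object of class `pca_model` with `k`, `explained` (cumulative
#'   at k) and the projection.
#' @export
pca_fit <- function(x, variance_kept = 0.90) {
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  ev <- ev / sum(ev)
  k <- which(cumsum(ev) >= variance_kept - 1e-12)[1]
  if (is.na(k)) {
    k <- length(ev)
    warning("degenerate covariance: keeping all ", k, " components",
            call. = FALSE)
  }
  structure(list(center = pr$center, rotation = pr$rotation[, seq_len(k),
                                                            drop = FALSE],
                 k = k, explained = cumsum(ev)[k],
                 variance_kept = variance_kept),
            class = "pca_model")
}

#' Project curves onto a fitted PCA basis
#' @param model A [pca_fit()] result.
#' @param x Matrix (or vector) of curves on the fitting grid.
#' @return Score matrix N x k.
#' @export
pca_transform <- function(model, x) {
  stopifnot(inherits(model, "pca_model"))
  sweep(rbind(x), 2, model$center, "-") %*% model$rotation
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model> k = ", x$k, " components, ",
      round(100 * x$explained, 1), "% variance kept\n", sep = "")
  invisible(x)
}

.rep_kinds <- c("identity", "franke5", "franke200", "pca90", "cnn")

#' Fit a latent-space representation on training curves
#'
#' Dispatcher over the representation kinds compared in the benchmark:
#' \describe{
#'   \item{identity}{the preprocessed intensity space itself (dim J)}
#'   \item{franke5 / franke200}{[franke_features()] with 5 / 200 V' points
#'     (+ Rg); needs no fitting; undefined for cylinder-like shapes}
#'   \item{pca90}{[pca_fit()] at 90\% kept variance}
#'   \item{cnn}{[cnn_build()] + [cnn_train()]; the encoder output (dim 256)
#'     is the latent space and the trained softmax head doubles as the
#'     perceptron-layer classifier}
#' }
#'
#' @param kind One of `"identity"`, `"franke5"`, `"franke200"`, `"pca90"`,
#'   `"cnn"`.
#' @param x Preprocessed training matrix (N x J).
#' @param q Final q grid(s) from the preprocessing pipeline (vector or
#'   N x J matrix); used by the invariant features and the CNN's `"Iq"`
#'   mode.
#' @param labels Training labels (required for `"cnn"`).
#' @param input_mode CNN input mode, `"I"` or `"Iq"`.
#' @param cnn_opts List of [cnn_train()] options (`epochs`, `batch`, `lr`,
#'   `dropout`).
#' @param seed Integer seed (CNN initialization/training).
#' @return Object of class `ff_representation` with a fitted state; apply
#'   with [rep_transform()].
#' @export
rep_fit <- function(kind, x, q = NULL, labels = NULL, input_mode = "I",
                    cnn_opts = list(), seed = 1) {
  kind <- match.arg(kind, .rep_kinds)
  x <- rbind(x)
  state <- switch(kind,
    identity = NULL,
    franke5 = list(n_points = 5),
    franke200 = list(n_points = 200),
    pca90 = pca_fit(x),
    cnn = {
      if (is.null(labels)) stop("cnn representation requires labels",
                                call. = FALSE)
      m <- cnn_build(ncol(x), input_mode = input_mode,
                     n_classes = max(9L, nlevels(factor(labels))),
                     seed = seed)
      do.call(cnn_train, c(list(model = m, x = x, labels = labels, q = q,
                                seed = seed), cnn_opts))
    })
  structure(list(kind = kind, state = state, J = ncol(x),
                 input_mode = input_mode),
            class = "ff_representation")
}

#' Transform curves into a fitted latent space
#'
#' @param rep A fitted [rep_fit()] object.
#' @param x Preprocessed curves (vector or matrix) on the fitting grid.
#' @param q q grid(s) matching `x` (needed by `franke*` and CNN `"Iq"`).
#' @return Latent matrix; for `franke*`, rows of curves for which no
#'   gyration radius exists are `NA` (callers exclude them).
#' @export
rep_transform <- function(rep, x, q = NULL) {
  stopifnot(inherits(rep, "ff_representation"))
  x <- rbind(x)
  switch(rep$kind,
    identity = x,
    pca90 = pca_transform(rep$state, x),
    cnn = cnn_encode(rep$state, x, q),
    franke5 = , franke200 = {
      np <- rep$state$n_points
      qm <- if (is.matrix(q)) q else
        matrix(q, nrow(x), length(q), byrow = TRUE)
      out <- matrix(NA_real_, nrow(x), np + 1)
      colnames(out) <- c(paste0("V", seq_len(np)), "Rg")
      for (i in seq_len(nrow(x))) {
        fe <- tryCatch(
          franke_features(saxs_curve(qm[i, ], x[i, ]), n_points = np),
          error = function(e) NULL)
        if (!is.null(fe)) out[i, ] <- fe
      }
      out
    })
}

#' Latent dimensionality of a fitted representation
#' @param rep A [rep_fit()] object.
#' @return Integer dimension of the transformed space.
#' @export
rep_dim <- function(rep) {
  switch(rep$kind,
    identity = rep$J,
    franke5 = 6L,
    franke200 = 201L,
    pca90 = rep$state$k,
    cnn = 256L)
}
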