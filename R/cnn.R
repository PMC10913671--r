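# R interface to the compiled 1D convolutional encoder.

.cnn_min_len <- 120L  # two conv-conv-pool(6) stages need >= 120 inputs

#' Build the supervised convolutional encoder
#'
#' Constructs the (untrained) network
#' conv(64,k7,ReLU) - conv(64,k7,ReLU) - maxpool(6) - dropout(0.25) -
#' conv(64,k7,ReLU) - conv(256,k7,ReLU) - maxpool(6) - dropout(0.25) -
#' global max pool (latent dimension 256) - dense softmax head.
#' Convolutions are unpadded; in `"Iq"` input mode the network takes two
#' channels (intensity and the q grid), which lets one model serve several
#' device configurations.
#'
#' @param input_len Curve length J (>= 120).
#' @param input_mode `"I"` (intensity only) or `"Iq"` (2-channel (I, q)).
#' @param n_classes Number of output classes.
#' @param seed Integer seed for weight initialization.
#' @return Object of class `cnn_model`.
#' @export
cnn_build <- function(input_len, input_mode = c("I", "Iq"), n_classes = 9,
                      seed = 1) {
  input_mode <- match.arg(input_mode)
  input_len <- as.integer(input_len)
  if (input_len < .cnn_min_len) {
    stop("input_len must be >= ", .cnn_min_len,
         " for two pool-6 stages", call. = FALSE)
  }
  n_channels <- if (input_mode == "Iq") 2L else 1L
  structure(list(params = .cnn_init_cpp(n_channels, n_classes, seed),
                 input_len = input_len, input_mode = input_mode,
                 n_channels = n_channels, n_classes = n_classes,
                 seed = seed, trained = FALSE, q_scale = NULL,
                 classes = NULL, loss = NULL),
            class = "cnn_model")
}

#' Number of trainable parameters of a [cnn_build()] network
#' @param model A `cnn_model`.
#' @return Integer parameter count.
#' @export
cnn_param_count <- function(model) {
  sum(vapply(model$params, length, integer(1)))
}

# stack intensity (+ standardized q) channels into the N x (C*L) layout the
# compiled code expects
.cnn_input <- function(model, x, q = NULL) {
  x <- rbind(x)
  if (ncol(x) != model$input_len) {
    stop("curve length ", ncol(x), " does not match the network input ",
         "length ", model$input_len, call. = FALSE)
  }
  if (model$input_mode == "I") return(x)
  if (is.null(q)) stop("input_mode 'Iq' requires the q grid(s)",
                       call. = FALSE)
  qm <- if (is.matrix(q)) q else
    matrix(q, nrow(x), length(q), byrow = TRUE)
  if (!all(dim(qm) == dim(x))) stop("q grid dimensions mismatch",
                                    call. = FALSE)
  if (is.null(model$q_scale)) {
    stop("q channel scaling not fitted; train the model first",
         call. = FALSE)
  }
  cbind(x, (qm - model$q_scale$center) / model$q_scale$scale)
}

#' Train the convolutional encoder
#'
#' Adam on categorical cross-entropy over preprocessed curves.  A non-finite
#' loss aborts with an error.  Reproducible for fixed seed.
#'
#' @param model A `cnn_model` from [cnn_build()].
#' @param x Preprocessed intensity matrix (N x J).
#' @param labels Factor (or vector coercible to one) of length N.
#' @param q Per-curve q grids (matrix N x J or shared vector); required in
#'   `"Iq"` mode, standardized internally with statistics frozen from this
#'   training set.
#' @param epochs,batch,lr,dropout Training hyper-parameters.
#' @param seed Integer seed for shuffling and dropout.
#' @return The trained `cnn_model` (fields `loss`, `classes` filled).
#' @export
cnn_train <- function(model, x, labels, q = NULL, epochs = 50, batch = 128,
                      lr = 1e-3, dropout = 0.25, seed = 1) {
  stopifnot(inherits(model, "cnn_model"))
  labels <- factor(labels)
  if (nlevels(labels) > model$n_classes) {
    stop("more classes than network outputs", call. = FALSE)
  }
  if (model$input_mode == "Iq") {
    qm <- if (is.matrix(q)) q else
      matrix(q, nrow(rbind(x)), length(q), byrow = TRUE)
    model$q_scale <- list(center = mean(qm),
                          scale = max(stats::sd(qm), 1e-12))
  }
  X <- .cnn_input(model, x, q)
  if (any(!is.finite(X))) {
    stop("non-finite values in the CNN training input", call. = FALSE)
  }
  y <- as.integer(labels) - 1L
  res <- .cnn_train_cpp(model$params, X, y, model$n_channels,
                        as.integer(epochs), as.integer(batch), lr, dropout,
                        as.integer(seed) %% 2147483647L)
  model$params <- res$params
  model$loss <- as.numeric(res$loss)
  model$classes <- levels(labels)
  model$trained <- TRUE
  model
}

#' Encode curves into the 256-dimensional latent space
#'
#' Runs the convolutional block only (detached from the softmax head),
#' with dropout disabled: deterministic at inference.
#'
#' @inheritParams cnn_train
#' @return Latent matrix N x 256.
#' @export
cnn_encode <- function(model, x, q = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  .cnn_forward_cpp(model$params, .cnn_input(model, x, q),
                   model$n_channels, TRUE)
}

#' Class probabilities from the full network (softmax head)
#'
#' @inheritParams cnn_train
#' @return Probability matrix N x n_classes (rows sum to 1), with column
#'   names after training.
#' @export
cnn_predict_proba <- function(model, x, q = NULL) {
  stopifnot(inherits(model, "cnn_model"))
  p <- .cnn_forward_cpp(model$params, .cnn_input(model, x, q),
                        model$n_channels, FALSE)
  if (!is.null(model$classes)) {
    colnames(p) <- c(model$classes,
                     rep("", model$n_classes - length(model$classes)))
  }
  p
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> input ", x$input_len, " x ", x$n_channels,
      " channel(s) -> latent 256 -> ", x$n_classes, " classes (",
      format(cnn_param_count(x), big.mark = ","), " parameters, ",
      if (x$trained) "trained" else "untrained", ")\n", sep = "")
  invisible(x)
}
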