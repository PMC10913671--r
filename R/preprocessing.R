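# The five SAXS-specific preprocessing operators and their left-to-right
# composition: TH (threshold), LOG, STD (per-bin standardization), IntN
# (Porod-invariant normalization), QLOG (logarithmic q resampling).
#
# Operators act on an intensity matrix X (curves in rows) together with its
# q grid(s); STD carries fitted statistics so that the transform learned on
# training folds can be frozen and reused on test folds.

#' Threshold intensities from below (TH)
#'
#' Clamps every intensity to at least `threshold` (default 1e-15 cm^-1,
#' chosen to be always below the signal) so that subsequent logarithms are
#' defined even after noise has produced zero-count bins.
#'
#' @param x Numeric vector or matrix of intensities (curves in rows).
#' @param threshold Clamp value, cm^-1.
#' @return Same shape as `x`.
#' @export
pp_th <- function(x, threshold = 1e-15) {
  pmax(x, threshold)
}

#' Elementwise natural logarithm (LOG)
#'
#' @param x Positive intensities (apply [pp_th()] first).
#' @return log(x), same shape.
#' @export
pp_log <- function(x) {
  if (any(x <= 0)) {
    stop("LOG requires positive intensities; apply TH first", call. = FALSE)
  }
  log(x)
}

#' Fit per-bin standardization statistics (STD)
#'
#' @param x Matrix of curves (rows) at a fixed grid length J.
#' @return List with `mean` and `sd` vectors of length J (class `pp_std`).
#'   Bins with zero spread get `sd = NA` and are centered but not scaled by
#'   [pp_std_apply()].
#' @export
pp_std_fit <- function(x) {
  x <- rbind(x)
  m <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s == 0] <- NA_real_
  structure(list(mean = m, sd = s), class = "pp_std")
}

#' Apply frozen standardization statistics
#'
#' @param x Vector or matrix of curves on the same grid the statistics were
#'   fitted on.
#' @param stats A `pp_std` object from [pp_std_fit()].
#' @return Standardized curves, same shape as `x`.
#' @export
pp_std_apply <- function(x, stats) {
  stopifnot(inherits(stats, "pp_std"))
  vec <- is.null(dim(x))
  x <- rbind(x)
  if (ncol(x) != length(stats$mean)) {
    stop("statistics length (", length(stats$mean),
         ") does not match curve length (", ncol(x), ")", call. = FALSE)
  }
  degenerate <- is.na(stats$sd)
  if (any(degenerate)) {
    warning(sum(degenerate), " constant bin(s) centered but not scaled",
            call. = FALSE)
  }
  sd <- ifelse(degenerate, 1, stats$sd)
  out <- sweep(sweep(x, 2, stats$mean, "-"), 2, sd, "/")
  if (vec) drop(out) else out
}

#' Porod-invariant normalization (IntN)
#'
#' Divides each curve by its truncated invariant integral(I q^2 dq),
#' evaluated with the trapezoidal rule on the native grid, so that the
#' output's own invariant is exactly 1.  Removes contrast and volume
#' fraction scale from the classification problem.
#'
#' @param x Vector or matrix of linear-scale intensities.
#' @param q q grid in A^-1: a vector shared by all rows, or a matrix of
#'   per-row grids with the same dimensions as `x`.
#' @return Normalized curves, same shape as `x`.
#' @export
pp_intn <- function(x, q) {
  vec <- is.null(dim(x))
  x <- rbind(x)
  if (is.matrix(q)) {
    if (!all(dim(q) == dim(x))) stop("q grid dimensions mismatch",
                                     call. = FALSE)
    inv <- vapply(seq_len(nrow(x)), function(i) {
      sum(.trap_weights(q[i, ]) * q[i, ]^2 * x[i, ])
    }, numeric(1))
  } else {
    if (ncol(x) != length(q)) stop("q length mismatch", call. = FALSE)
    inv <- as.numeric((sweep(x, 2, q^2, "*")) %*% .trap_weights(q))
  }
  if (any(inv <= 0)) {
    stop("non-positive invariant integral; IntN needs linear-scale ",
         "positive intensities", call. = FALSE)
  }
  out <- x / inv
  if (vec) drop(out) else out
}

# trapezoid quadrature weights for an arbitrary increasing grid
.trap_weights <- function(q) {
  n <- length(q)
  w <- numeric(n)
  dq <- diff(q)
  w[1] <- dq[1] / 2
  w[n] <- dq[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (dq[-1] + dq[-(n - 1)]) / 2
  w
}

#' Logarithmic q resampling (QLOG)
#'
#' Replaces the (linearly sampled) q grid by the same number of points
#' logarithmically spaced between the original endpoints (both endpoints
#' preserved exactly) and linearly interpolates the intensities onto the
#' new grid.  Condenses the information-rich medium/high-q region.
#'
#' @param x Vector or matrix of intensities.
#' @param q Source q grid with positive first value (truncate first
#'   otherwise): a shared vector, or a matrix of per-row grids.
#' @return List with `x` (resampled intensities, same shape) and `q` (the
#'   log-spaced grid, same form as the input grid).
#' @export
pp_qlog <- function(x, q) {
  vec <- is.null(dim(x))
  x <- rbind(x)
  one <- function(row, qrow) {
    if (qrow[1] <= 0) stop("QLOG requires q[1] > 0; truncate low q first",
                           call. = FALSE)
    n <- length(qrow)
    qlog <- exp(seq(log(qrow[1]), log(qrow[n]), length.out = n))
    qlog[1] <- qrow[1]; qlog[n] <- qrow[n]
    list(x = stats::approx(qrow, row, xout = qlog)$y, q = qlog)
  }
  if (is.matrix(q)) {
    if (!all(dim(q) == dim(x))) stop("q grid dimensions mismatch",
                                     call. = FALSE)
    outx <- x; outq <- q
    for (i in seq_len(nrow(x))) {
      r <- one(x[i, ], q[i, ])
      outx[i, ] <- r$x; outq[i, ] <- r$q
    }
    list(x = if (vec) drop(outx) else outx, q = outq)
  } else {
    r1 <- one(x[1, ], q)
    outx <- x
    outx[1, ] <- r1$x
    if (nrow(x) > 1) {
      for (i in 2:nrow(x)) outx[i, ] <- one(x[i, ], q)$x
    }
    list(x = if (vec) drop(outx) else outx, q = r1$q)
  }
}

.pp_ops <- c("TH", "LOG", "STD", "IntN", "QLOG")

#' Compose preprocessing operators into a pipeline
#'
#' Builds a deterministic left-to-right pipeline from operator tags.  The
#' pipeline is fitted on a training matrix (which freezes the STD
#' statistics on whatever grid precedes STD in the chain) and can then be
#' applied to further curves.  Validation enforces that LOG is preceded by
#' TH and that IntN receives linear-scale intensities (i.e. appears before
#' LOG and STD).
#'
#' @param spec Character vector of tags from
#'   `c("TH", "LOG", "STD", "IntN", "QLOG")`, applied left to right, or the
#'   preset name `"best"` for `TH, IntN, LOG, STD, QLOG` (the combination
#'   with the highest benchmark accuracy), or `"none"` for the identity.
#' @param threshold TH clamp value.
#' @return Object of class `pp_pipeline` with `$fit(x, q)` -> fitted
#'   pipeline and `$apply(x, q)` -> `list(x, q)`; see also
#'   [pp_fit()] / [pp_apply()].
#' @export
pp_pipeline <- function(spec = "best", threshold = 1e-15) {
  if (length(spec) == 1 && spec %in% c("best", "none")) {
    spec <- switch(spec, best = c("TH", "IntN", "LOG", "STD", "QLOG"),
                   none = character(0))
  }
  if (!all(spec %in% .pp_ops)) {
    stop("unknown operator tag(s): ",
         paste(setdiff(spec, .pp_ops), collapse = ", "), call. = FALSE)
  }
  if ("LOG" %in% spec) {
    if (!("TH" %in% spec) || match("TH", spec) > match("LOG", spec)) {
      stop("LOG requires a preceding TH", call. = FALSE)
    }
  }
  if ("IntN" %in% spec) {
    after <- spec[seq_len(match("IntN", spec) - 1)]
    if (any(c("LOG", "STD") %in% after)) {
      stop("IntN must receive linear-scale intensities: place it before ",
           "LOG and STD", call. = FALSE)
    }
  }
  structure(list(spec = spec, threshold = threshold, std_stats = NULL),
            class = "pp_pipeline")
}

#' Fit a preprocessing pipeline on training curves
#'
#' Runs the chain on the training matrix and freezes the STD statistics at
#' their position in the chain (leakage-free: statistics come only from the
#' curves given here).
#'
#' @param pipeline A [pp_pipeline()].
#' @param x Training intensity matrix (curves in rows).
#' @param q Shared q grid.
#' @return Fitted `pp_pipeline`.
#' @export
pp_fit <- function(pipeline, x, q) {
  stopifnot(inherits(pipeline, "pp_pipeline"))
  cur <- rbind(x); curq <- q
  for (op in pipeline$spec) {
    if (op == "STD") {
      pipeline$std_stats <- pp_std_fit(cur)
      cur <- pp_std_apply(cur, pipeline$std_stats)
    } else {
      stepped <- .pp_step(op, cur, curq, pipeline)
      cur <- stepped$x; curq <- stepped$q
    }
  }
  pipeline$fitted <- TRUE
  pipeline
}

#' Apply a fitted preprocessing pipeline
#'
#' @param pipeline A fitted [pp_pipeline()] (see [pp_fit()]); pipelines
#'   without STD need no fitting.
#' @param x Intensity vector or matrix.
#' @param q Shared q grid.
#' @return List with transformed `x` and final `q` grid.
#' @export
pp_apply <- function(pipeline, x, q) {
  stopifnot(inherits(pipeline, "pp_pipeline"))
  vec <- is.null(dim(x))
  cur <- rbind(x); curq <- q
  for (op in pipeline$spec) {
    if (op == "STD") {
      if (is.null(pipeline$std_stats)) {
        stop("pipeline contains STD but was not fitted; call pp_fit() on ",
             "training curves first", call. = FALSE)
      }
      cur <- rbind(pp_std_apply(cur, pipeline$std_stats))
    } else {
      stepped <- .pp_step(op, cur, curq, pipeline)
      cur <- stepped$x; curq <- stepped$q
    }
  }
  list(x = if (vec) drop(cur) else cur, q = curq)
}

.pp_step <- function(op, x, q, pipeline) {
  switch(op,
    TH = list(x = pp_th(x, pipeline$threshold), q = q),
    LOG = list(x = pp_log(x), q = q),
    IntN = list(x = pp_intn(x, q), q = q),
    QLOG = {
      res <- pp_qlog(x, q)
      list(x = rbind(res$x), q = res$q)
    })
}

#' @export
print.pp_pipeline <- function(x, ...) {
  chain <- if (length(x$spec)) paste(x$spec, collapse = " ° ") else
    "(identity)"
  cat("<pp_pipeline> ", chain,
      if (!is.null(x$std_stats)) "  [STD fitted]", "\n", sep = "")
  invisible(x)
}
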