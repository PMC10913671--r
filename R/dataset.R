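# Labelled synthetic dataset construction: parameter sampling, rendering of
# noiseless model curves through one or both device configurations,
# grid harmonization (q_max capping + oversampling to a fixed input length)
# and low-q truncation, plus curve/archive I/O.

.GENERATOR_VERSION <- "1.0"

.runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

#' Draw random particle parameters for one shape class
#'
#' Samples a [particle_model()] from the documented generator ranges:
#' primary radii log-uniform in 10-1000 A (1-100 nm particles), ellipsoid
#' aspect ratios log-uniform in [1, 6] (capped so the largest dimension
#' stays within 1000 A), cylinder length 3-30x the radius (up to 10000 A,
#' i.e. extending beyond the measurable range), shell thickness uniform in
#' 10-50% of the core's primary dimension, core/shell SLDs uniform in
#' 11-35e-6 A^-2 against a water solvent (9.47), volume fraction
#' log-uniform in 1e-4..1e-2 and polydispersity uniform in [0, 0.2].
#' Uses the current R RNG stream (seed at the caller).
#'
#' @param shape One of [ff_shapes()].
#' @return A [particle_model()].
#' @export
sample_parameters <- function(shape) {
  .check_shape(shape)
  sld_solvent <- 9.47
  sld_core <- stats::runif(1, 11, 35)
  sld_shell <- NULL
  if (.is_core_shell(shape)) {
    repeat {
      sld_shell <- stats::runif(1, 11, 35)
      if (abs(sld_shell - sld_core) >= 2) break
    }
  }
  body <- .base_body(shape)
  geometry <- if (body == "sphere") {
    list(radius = .runif_log(1, 10, 1000))
  } else if (body == "cylinder") {
    r <- .runif_log(1, 10, 500)
    list(radius = r, length = min(r * .runif_log(1, 3, 30), 10000))
  } else {
    ar <- .runif_log(1, 1, 6)
    if (shape %in% c("prolate_ellipsoid", "core_shell_prolate")) {
      re <- .runif_log(1, 10, min(600, 1000 / ar))
      list(r_polar = re * ar, r_equatorial = re)
    } else {
      re <- .runif_log(1, 10, 600)
      list(r_polar = re / ar, r_equatorial = re)
    }
  }
  if (.is_core_shell(shape)) {
    prim <- geometry[[.primary_dim(shape)]]
    geometry$thickness <- stats::runif(1, 0.1, 0.5) * prim
  }
  particle_model(shape, geometry, sld_core = sld_core,
                 sld_shell = sld_shell, sld_solvent = sld_solvent,
                 volume_fraction = .runif_log(1, 1e-4, 1e-2),
                 polydispersity = stats::runif(1, 0, 0.2))
}

# aspect ratio r_equatorial / r_polar (Fig. 5 convention); NA for
# non-ellipsoids
.aspect_ratio <- function(model) {
  g <- model$geometry
  if (!is.null(g$r_polar)) g$r_equatorial / g$r_polar else NA_real_
}

#' Linear resampling of a curve onto a target grid
#'
#' @param curve A [saxs_curve()].
#' @param target_grid Strictly increasing q values contained in the source
#'   grid's span (extrapolation is an error).
#' @return A [saxs_curve()] on `target_grid`; `sigma` (if present) is
#'   interpolated too.
#' @export
resample_to_grid <- function(curve, target_grid) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (min(target_grid) < min(curve$q) || max(target_grid) > max(curve$q)) {
    stop("target grid extends beyond the source span [",
         signif(min(curve$q), 4), ", ", signif(max(curve$q), 4),
         "]; refusing to extrapolate", call. = FALSE)
  }
  int <- stats::approx(curve$q, curve$intensity, xout = target_grid)$y
  sig <- if (!is.null(curve$sigma)) {
    stats::approx(curve$q, curve$sigma, xout = target_grid)$y
  }
  saxs_curve(target_grid, int, sigma = sig, config_id = curve$config_id)
}

#' Build a labelled synthetic dataset
#'
#' Samples `n_per_class` particle populations per shape class (balanced
#' labels) and renders each through one or both instrument configurations:
#' \describe{
#'   \item{DS_X}{every model measured on the first configuration only}
#'   \item{DS_N}{every model measured on the second configuration only}
#'   \item{DS_mix}{each model assigned one configuration, exactly half/half
#'     (deterministic alternation after a seeded shuffle)}
#'   \item{DS_all}{each model measured in both configurations (twice the
#'     curves from the same noiseless pool)}
#' }
#' All curves are harmonized to a common input length: every grid is capped
#' at the smallest configuration q_max, and shorter grids are oversampled
#' by linear interpolation to the longest capped grid length.
#'
#' @param build One of `"DS_X"`, `"DS_N"`, `"DS_mix"`, `"DS_all"`.
#' @param n_per_class Number of particle populations per shape class.
#' @param seed Integer seed; fully determines parameters and noise.
#' @param configs List of two [instrument_config()]s (first = "X", second
#'   = "N"); defaults to the built-in Xeuss1800HR / NanoInXiderHR pair.
#' @param noiseless If `TRUE`, skip counting noise (smeared curves only).
#' @param shapes Shape classes to include (default all nine).
#' @param n_quad,n_pd Quadrature orders for the intensity computation.
#' @return Object of class `saxs_dataset`: list with `intensities` (N x J),
#'   `q` (N x J per-curve grids), `labels` (factor), `config_ids`,
#'   `params` (data frame incl. aspect ratios), `models`, `provenance`.
#' @export
build_dataset <- function(build = c("DS_X", "DS_N", "DS_mix", "DS_all"),
                          n_per_class, seed = 1,
                          configs = list(builtin_config("Xeuss1800HR"),
                                         builtin_config("NanoInXiderHR")),
                          noiseless = FALSE, shapes = ff_shapes(),
                          n_quad = 76, n_pd = 15) {
  build <- match.arg(build)
  if (length(configs) < 1) stop("empty config list", call. = FALSE)
  if (build != "DS_X" && length(configs) < 2) {
    stop(build, " requires two configurations", call. = FALSE)
  }
  if (n_per_class < 1) stop("n_per_class must be >= 1", call. = FALSE)
  set.seed(seed)
  models <- list()
  labels <- character(0)
  for (sh in shapes) {
    for (i in seq_len(n_per_class)) {
      models[[length(models) + 1L]] <- sample_parameters(sh)
      labels <- c(labels, sh)
    }
  }
  n_models <- length(models)
  # which config(s) measure each model
  cfg_idx <- switch(build,
    DS_X = rep(1L, n_models),
    DS_N = rep(2L, n_models),
    DS_mix = {
      ord <- sample.int(n_models)           # seeded shuffle ...
      assign <- integer(n_models)
      assign[ord] <- rep_len(c(1L, 2L), n_models)  # ... then alternation
      assign
    },
    DS_all = NULL)
  grids <- .harmonized_grids(configs)
  render <- function(mi, ci) {
    cfg <- configs[[ci]]
    cv <- simulate_measurement(models[[mi]], cfg,
                               seed = (seed + 131L * mi + ci) %% 2147483629L,
                               noiseless = noiseless,
                               n_quad = n_quad, n_pd = n_pd)
    cv <- .cap_curve(cv, grids$q_cap)
    resample_to_grid(cv, grids$target[[ci]])
  }
  pairs <- if (build == "DS_all") {
    cbind(rep(seq_len(n_models), times = 2),
          rep(seq_along(configs[1:2]), each = n_models))
  } else {
    cbind(seq_len(n_models), cfg_idx)
  }
  J <- grids$J
  intens <- matrix(NA_real_, nrow(pairs), J)
  qmat <- matrix(NA_real_, nrow(pairs), J)
  config_ids <- character(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    cv <- render(pairs[r, 1], pairs[r, 2])
    intens[r, ] <- cv$intensity
    qmat[r, ] <- cv$q
    config_ids[r] <- cv$config_id
  }
  midx <- pairs[, 1]
  params <- data.frame(
    shape = labels[midx],
    aspect_ratio = vapply(models[midx], .aspect_ratio, numeric(1)),
    polydispersity = vapply(models[midx], function(m) m$polydispersity,
                            numeric(1)),
    volume_fraction = vapply(models[midx], function(m) m$volume_fraction,
                             numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(
    intensities = intens, q = qmat,
    labels = factor(labels[midx], levels = shapes),
    config_ids = config_ids, params = params, models = models[midx],
    provenance = list(seed = seed, build = build,
                      n_per_class = n_per_class, noiseless = noiseless,
                      configs = vapply(configs, function(c) c$name, ""),
                      generator_version = .GENERATOR_VERSION)),
    class = "saxs_dataset")
}

# common capped q_max and per-config target grids of equal length J
.harmonized_grids <- function(configs) {
  q_cap <- min(vapply(configs, function(c) c$q_max, numeric(1)))
  capped <- lapply(configs, function(c) {
    g <- config_q_grid(c)
    g[g <= q_cap + 1e-12]
  })
  J <- max(vapply(capped, length, integer(1)))
  target <- lapply(capped, function(g) {
    if (length(g) == J) g else seq(g[1], g[length(g)], length.out = J)
  })
  list(q_cap = q_cap, J = J, target = target)
}

.cap_curve <- function(curve, q_cap) {
  keep <- curve$q <= q_cap + 1e-12
  saxs_curve(curve$q[keep], curve$intensity[keep],
             sigma = if (!is.null(curve$sigma)) curve$sigma[keep],
             config_id = curve$config_id)
}

#' @export
print.saxs_dataset <- function(x, ...) {
  cat("<saxs_dataset> ", nrow(x$intensities), " curves x ",
      ncol(x$intensities), " q points (", x$provenance$build,
      ", seed ", x$provenance$seed, ")\n", sep = "")
  print(table(labels = x$labels, config = x$config_ids))
  invisible(x)
}

#' Drop the low-q region of every curve in a dataset
#'
#' Strictly removes bins with q <= `q_cut` (the low-q region of real
#' measurements often carries aggregation/air-bubble artifacts).  If the
#' per-configuration grids end up with different lengths, all curves are
#' conformed to the shortest truncated length by linear resampling over
#' their own span.
#'
#' @param dataset A `saxs_dataset`.
#' @param q_cut Cut value in A^-1 (default 0.005; 0 is the identity).
#' @return The truncated `saxs_dataset`.
#' @export
truncate_low_q <- function(dataset, q_cut = 0.005) {
  stopifnot(inherits(dataset, "saxs_dataset"))
  if (q_cut <= 0) return(dataset)
  if (q_cut >= max(dataset$q)) {
    stop("q_cut = ", q_cut, " is at or above the maximum grid value",
         call. = FALSE)
  }
  n <- nrow(dataset$intensities)
  kept <- lapply(seq_len(n), function(i) which(dataset$q[i, ] > q_cut))
  lens <- lengths(kept)
  if (any(lens < 2)) stop("q_cut leaves fewer than 2 points", call. = FALSE)
  J2 <- min(lens)
  intens <- matrix(NA_real_, n, J2)
  qmat <- matrix(NA_real_, n, J2)
  for (i in seq_len(n)) {
    qi <- dataset$q[i, kept[[i]]]
    xi <- dataset$intensities[i, kept[[i]]]
    if (length(qi) > J2) {
      tg <- seq(qi[1], qi[length(qi)], length.out = J2)
      xi <- stats::approx(qi, xi, xout = tg)$y
      qi <- tg
    }
    intens[i, ] <- xi
    qmat[i, ] <- qi
  }
  dataset$intensities <- intens
  dataset$q <- qmat
  dataset$provenance$q_cut <- q_cut
  dataset
}

#' Write / read a curve as 3-column ASCII
#'
#' Plain-text `.dat` format: `#`-prefixed header lines, then columns
#' q (A^-1), I (cm^-1) and, when available, sigma (cm^-1).
#'
#' @param curve A [saxs_curve()].
#' @param path File path.
#' @return `write_curve` returns `path` invisibly; `read_curve` returns a
#'   [saxs_curve()].
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  hdr <- c("# saxsshape 1D curve",
           if (!is.null(curve$config_id)) paste0("# config: ",
                                                 curve$config_id),
           paste0("# columns: q[1/A] I[1/cm]",
                  if (!is.null(curve$sigma)) " sigma[1/cm]"))
  m <- cbind(curve$q, curve$intensity, curve$sigma)
  body <- apply(m, 1, function(r) paste(sprintf("%.8e", r), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_curve
#' @param config_id Optional tag attached to the curve on reading (the
#'   `# config:` header is used when present).
#' @export
read_curve <- function(path, config_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  cfg <- config_id
  hdr <- grep("^# *config:", lines, value = TRUE)
  if (is.null(cfg) && length(hdr)) {
    cfg <- trimws(sub("^# *config:", "", hdr[1]))
  }
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(keep)) stop("no data rows in ", path, call. = FALSE)
  rows <- lapply(keep, function(i) {
    vals <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                 "\\s+|,")[[1]]))
    if (length(vals) < 2 || anyNA(vals)) {
      stop("malformed data at ", path, " line ", i, call. = FALSE)
    }
    vals[1:3][seq_len(min(3, length(vals)))]
  })
  ncols <- min(lengths(rows))
  m <- do.call(rbind, lapply(rows, `[`, seq_len(ncols)))
  saxs_curve(m[, 1], m[, 2], sigma = if (ncols >= 3) m[, 3],
             config_id = cfg)
}

#' Write / read a dataset archive
#'
#' Serializes the full `saxs_dataset` (intensities, grids, labels,
#' configuration ids, parameters and provenance) to a single-file archive
#' that round-trips bit-exactly.
#'
#' @param dataset A `saxs_dataset`.
#' @param path Archive file path (conventionally `.rds`).
#' @return `write_dataset` returns `path` invisibly; `read_dataset` the
#'   `saxs_dataset`.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "saxs_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  ds <- readRDS(path)
  if (!inherits(ds, "saxs_dataset")) {
    stop(path, " does not contain a saxs_dataset archive", call. = FALSE)
  }
  ds
}
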