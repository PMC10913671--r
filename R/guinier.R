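# Automated Guinier analysis and the Kratky-integral ("normalized apparent
# volume") feature space derived from it.

#' Automated Guinier fit for the radius of gyration
#'
#' Fits ln I = ln I(0) - q^2 Rg^2 / 3 on a low-q window chosen
#' automatically: starting from the first `min_points` points, the window
#' is iteratively re-set to all q with q*Rg <= `qrg_max` until the estimate
#' stabilizes.  Fails (error) when no window of at least `min_points`
#' points with a negative slope and acceptable linearity exists — e.g. for
#' very long cylinders, whose gyration radius exceeds the measurable range
#' and for which the notion loses its meaning.
#'
#' @param curve A [saxs_curve()] (or list with `q` and `intensity`).
#' @param qrg_max Upper bound of q*Rg for the fitted window (1.3 is the
#'   usual spherical-particle limit).
#' @param min_points Minimum number of points in the Guinier window.
#' @param r2_min Minimum R^2 of the linear fit for acceptance.
#' @return List of class `guinier_fit` with `rg` (Angstrom), `i0`
#'   (extrapolated I(0), cm^-1), `window` (indices used), `r2`.
#' @export
estimate_rg <- function(curve, qrg_max = 1.3, min_points = 5,
                        r2_min = 0.98) {
  q <- curve$q; I <- curve$intensity
  pos <- I > 0
  if (sum(pos[seq_len(min(20, length(q)))]) < min_points) {
    stop("no usable low-q intensities for a Guinier fit", call. = FALSE)
  }
  fit_win <- function(idx) {
    x <- q[idx]^2; y <- log(I[idx])
    f <- stats::lm.fit(cbind(1, x), y)
    slope <- f$coefficients[2]
    r2 <- 1 - sum(f$residuals^2) /
      max(sum((y - mean(y))^2), .Machine$double.eps)
    list(slope = slope, icpt = f$coefficients[1], r2 = r2)
  }
  idx <- which(pos)[seq_len(min_points)]
  rg <- NA_real_
  for (iter in 1:25) {
    f <- fit_win(idx)
    if (!is.finite(f$slope) || f$slope >= 0) {
      stop("no Guinier regime found (non-negative low-q slope)",
           call. = FALSE)
    }
    rg_new <- sqrt(-3 * f$slope)
    new_idx <- which(pos & q * rg_new <= qrg_max)
    if (length(new_idx) < min_points) {
      stop("Guinier window smaller than ", min_points, " points (q_min*Rg",
           " = ", signif(q[1] * rg_new, 3), "); gyration radius outside ",
           "the measurable range", call. = FALSE)
    }
    if (is.finite(rg) && abs(rg_new - rg) < 1e-4 * rg) {
      idx <- new_idx; rg <- rg_new; break
    }
    rg <- rg_new; idx <- new_idx
  }
  f <- fit_win(idx)
  rg <- sqrt(-3 * f$slope)
  if (f$r2 < r2_min) {
    stop("Guinier fit rejected: R^2 = ", signif(f$r2, 3), " < ", r2_min,
         call. = FALSE)
  }
  structure(list(rg = as.numeric(rg), i0 = as.numeric(exp(f$icpt)),
                 window = idx, r2 = as.numeric(f$r2)),
            class = "guinier_fit")
}

#' @export
print.guinier_fit <- function(x, ...) {
  cat("<guinier_fit> Rg = ", signif(x$rg, 5), " A, I(0) = ",
      signif(x$i0, 4), " cm^-1, ", length(x$window),
      "-point window, R^2 = ", signif(x$r2, 4), "\n", sep = "")
  invisible(x)
}

# truncated Porod invariant integral_0^qmax q^2 I(q) dq: Guinier model below
# the first grid point, trapezoid on the data above it
.invariant_to <- function(q, I, gf, q_upper) {
  qg <- seq(0, q[1], length.out = 64)
  inv <- sum(.trap_weights(qg) * qg^2 * gf$i0 * exp(-qg^2 * gf$rg^2 / 3))
  keep <- q <= q_upper
  qq <- c(q[keep], q_upper)
  II <- c(I[keep], stats::approx(q, I, xout = q_upper)$y)
  inv + sum(.trap_weights(qq) * qq^2 * II)
}

#' Kratky-integral feature space (normalized apparent volume)
#'
#' Computes the dimensionless apparent-volume profile
#' V'(x) = 2 pi^2 I(0) / (Rg^3 * integral_0^(x/Rg) q^2 I(q) dq)
#' at `n_points` values of x = q*Rg linearly spaced in `[3, 7]` (the upper
#' bound extended to 7 to retain intraparticle-contrast information of
#' shelled particles), concatenated with Rg as the last feature.  I(0) and
#' Rg come from the automated Guinier fit; intensity scale cancels, so the
#' features are invariant to contrast and volume fraction.  Not meaningful
#' for cylinder-like shapes (no gyration radius within range): the Guinier
#' error propagates.
#'
#' @param curve A [saxs_curve()].
#' @param n_points Number of V' evaluation points: 5 (6 features) or 200
#'   (201 features).
#' @param qrg_range Range of q*Rg over which V' is evaluated.
#' @param rg_fit Optional precomputed [estimate_rg()] result.
#' @return Numeric vector of length `n_points + 1` (`V1..Vn`, `Rg`).
#' @export
franke_features <- function(curve, n_points = 5, qrg_range = c(3, 7),
                            rg_fit = NULL) {
  gf <- if (is.null(rg_fit)) estimate_rg(curve) else rg_fit
  xs <- seq(qrg_range[1], qrg_range[2], length.out = n_points)
  q_needed <- max(xs) / gf$rg
  if (q_needed > max(curve$q) * 1.0001) {
    stop("q range does not reach qRg = ", max(xs), " (needs q up to ",
         signif(q_needed, 3), "); curve excluded from the invariant",
         " feature space", call. = FALSE)
  }
  I <- pmax(curve$intensity, 1e-15)
  v <- vapply(xs, function(x) {
    2 * pi^2 * gf$i0 /
      (gf$rg^3 * .invariant_to(curve$q, I, gf, x / gf$rg))
  }, numeric(1))
  out <- c(v, gf$rg)
  names(out) <- c(paste0("V", seq_len(n_points)), "Rg")
  out
}
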