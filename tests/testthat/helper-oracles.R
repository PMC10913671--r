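# Independent physics oracles used to validate the analytic kernels.

# van der Corput radical-inverse sequence (quasi-Monte-Carlo sampling)
vdc_seq <- function(n, base) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- i; f <- 1 / base; r <- 0
    while (x > 0) {
      r <- r + f * (x %% base)
      x <- x %/% base
      f <- f / base
    }
    out[i] <- r
  }
  out
}

# low-discrepancy points uniform in a body, with a seeded random shift
oracle_sample_body <- function(body, g, n, seed) {
  set.seed(seed)
  u <- cbind(vdc_seq(n, 2), vdc_seq(n, 3), vdc_seq(n, 5))
  u <- (u + matrix(stats::runif(3), n, 3, byrow = TRUE)) %% 1
  if (body == "sphere") {
    z <- 2 * u[, 1] - 1
    phi <- 2 * pi * u[, 2]
    r <- g$radius * u[, 3]^(1 / 3)
    s <- sqrt(1 - z^2)
    cbind(r * s * cos(phi), r * s * sin(phi), r * z)
  } else if (body == "cylinder") {
    th <- 2 * pi * u[, 1]
    rr <- g$radius * sqrt(u[, 2])
    cbind(rr * cos(th), rr * sin(th), g$length * (u[, 3] - 0.5))
  } else {
    z <- 2 * u[, 1] - 1
    phi <- 2 * pi * u[, 2]
    r <- u[, 3]^(1 / 3)
    s <- sqrt(1 - z^2)
    cbind(g$r_equatorial * r * s * cos(phi),
          g$r_equatorial * r * s * sin(phi),
          g$r_polar * r * z)
  }
}

# Debye-formula Monte-Carlo oracle for the orientation-averaged form factor
# P(q) = (V/n)^2 sum_ij w_i w_j sinc(q r_ij), with contrast weights w at
# points sampled in the particle envelope; completely independent of the
# quadrature-based analytic path it cross-checks.
debye_mc_oracle <- function(shape, g, slds, q, n = 6000, seed = 42,
                            nbins = 8192) {
  body <- switch(shape,
    sphere = , core_shell_sphere = , hollow_sphere = "sphere",
    cylinder = , core_shell_cylinder = "cylinder",
    "ellipsoid")
  core_shell <- shape %in% c("core_shell_sphere", "hollow_sphere",
                             "core_shell_cylinder", "core_shell_prolate",
                             "core_shell_oblate")
  if (!core_shell) {
    pts <- oracle_sample_body(body, g, n, seed)
    w <- rep(slds$core - slds$solvent, n)
  } else {
    t <- g$thickness
    go <- if (body == "sphere") list(radius = g$radius + t)
      else if (body == "cylinder") list(radius = g$radius + t,
                                        length = g$length + 2 * t)
      else list(r_polar = g$r_polar + t, r_equatorial = g$r_equatorial + t)
    pts <- oracle_sample_body(body, go, n, seed)
    in_core <- if (body == "sphere") rowSums(pts^2) <= g$radius^2
      else if (body == "cylinder") {
        (pts[, 1]^2 + pts[, 2]^2 <= g$radius^2) &
          (abs(pts[, 3]) <= g$length / 2)
      } else {
        (pts[, 1]^2 + pts[, 2]^2) / g$r_equatorial^2 +
          pts[, 3]^2 / g$r_polar^2 <= 1
      }
    sld_core <- if (shape == "hollow_sphere") slds$solvent else slds$core
    w <- ifelse(in_core, sld_core - slds$solvent,
                slds$shell - slds$solvent)
  }
  vol <- saxsshape:::.particle_volume(shape, g)
  d <- as.vector(dist(pts))
  wmat <- tcrossprod(w)
  wprod <- wmat[lower.tri(wmat)]
  dmax <- max(d) * (1 + 1e-12)
  bin <- .bincode(d, seq(0, dmax, length.out = nbins + 1))
  wb <- tapply(wprod, bin, sum)
  db <- (as.numeric(names(wb)) - 0.5) * dmax / nbins
  vapply(q, function(qq) {
    x <- qq * db
    s <- ifelse(x < 1e-8, 1, sin(x) / x)
    (vol / n)^2 * (sum(w^2) + 2 * sum(wb * s))
  }, numeric(1))
}
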