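#' Nine supported nanoparticle form-factor classes
#'
#' Class labels for the shapes the simulator and classifiers know about:
#' homogeneous spheres, cylinders, prolate and oblate ellipsoids of
#' revolution, and their shelled counterparts (a hollow sphere being a
#' core-shell sphere whose core is solvent-matched).
#'
#' @return Character vector of the nine shape labels, in canonical order.
#' @export
ff_shapes <- function() {
  c("sphere", "cylinder", "prolate_ellipsoid", "oblate_ellipsoid",
    "core_shell_sphere", "hollow_sphere", "core_shell_cylinder",
    "core_shell_prolate", "core_shell_oblate")
}

.is_core_shell <- function(shape) {
  shape %in% c("core_shell_sphere", "hollow_sphere", "core_shell_cylinder",
               "core_shell_prolate", "core_shell_oblate")
}

.check_shape <- function(shape) {
  if (!is.character(shape) || length(shape) != 1L || !(shape %in% ff_shapes())) {
    stop("unsupported shape '", paste(shape, collapse = ","),
         "'; supported shapes: ", paste(ff_shapes(), collapse = ", "),
         call. = FALSE)
  }
  shape
}

#' Describe one simulated nanoparticle population
#'
#' Bundles the shape label, geometry, scattering length densities (SLD),
#' volume fraction and polydispersity of a dilute particle population.
#' Lengths are in Angstrom, SLDs in 1e-6 A^-2 (so water is ~9.47), the
#' volume fraction is dimensionless and polydispersity is the relative
#' width sigma_r/r of a Gaussian distribution on the shape's primary
#' dimension.
#'
#' Geometry fields by shape:
#' \itemize{
#'   \item sphere: \code{radius}
#'   \item cylinder: \code{radius}, \code{length}
#'   \item prolate/oblate ellipsoid: \code{r_polar}, \code{r_equatorial}
#'     (prolate has polar >= equatorial, oblate the reverse)
#'   \item core-shell variants: core geometry as above plus a uniform shell
#'     \code{thickness} (cylinders are shelled on ends as well as sides)
#' }
#'
#' @param shape One of [ff_shapes()].
#' @param geometry Named list of lengths in Angstrom (see Details).
#' @param sld_core,sld_shell,sld_solvent Scattering length densities in
#'   1e-6 A^-2. `sld_shell` is required for core-shell shapes and ignored
#'   otherwise. For `hollow_sphere` the core SLD is forced to the solvent
#'   SLD.
#' @param volume_fraction Particle volume fraction in (0, 1); must be small
#'   enough that the interparticle structure factor is ~1 (dilute limit).
#' @param polydispersity Relative width of the size distribution on the
#'   primary dimension, >= 0.
#' @return An object of class `particle_model`.
#' @examples
#' particle_model("sphere", list(radius = 100),
#'                sld_core = 18.9, sld_solvent = 9.47)
#' @export
particle_model <- function(shape, geometry, sld_core, sld_shell = NULL,
                           sld_solvent = 9.47, volume_fraction = 1e-3,
                           polydispersity = 0) {
  .check_shape(shape)
  geometry <- as.list(geometry)
  req <- switch(shape,
    sphere = "radius",
    cylinder = c("radius", "length"),
    prolate_ellipsoid = c("r_polar", "r_equatorial"),
    oblate_ellipsoid = c("r_polar", "r_equatorial"),
    core_shell_sphere = c("radius", "thickness"),
    hollow_sphere = c("radius", "thickness"),
    core_shell_cylinder = c("radius", "length", "thickness"),
    core_shell_prolate = c("r_polar", "r_equatorial", "thickness"),
    core_shell_oblate = c("r_polar", "r_equatorial", "thickness"))
  missing_f <- setdiff(req, names(geometry))
  if (length(missing_f)) {
    stop("geometry for shape '", shape, "' is missing field(s): ",
         paste(missing_f, collapse = ", "), call. = FALSE)
  }
  lens <- unlist(geometry[req])
  if (any(!is.finite(lens)) || any(lens <= 0)) {
    stop("all geometric lengths must be finite and > 0", call. = FALSE)
  }
  if (shape %in% c("prolate_ellipsoid", "core_shell_prolate") &&
      geometry$r_polar < geometry$r_equatorial) {
    stop("prolate ellipsoid requires r_polar >= r_equatorial", call. = FALSE)
  }
  if (shape %in% c("oblate_ellipsoid", "core_shell_oblate") &&
      geometry$r_polar > geometry$r_equatorial) {
    stop("oblate ellipsoid requires r_polar <= r_equatorial", call. = FALSE)
  }
  if (shape == "hollow_sphere") sld_core <- sld_solvent
  if (.is_core_shell(shape) && is.null(sld_shell)) {
    stop("core-shell shape '", shape, "' requires sld_shell", call. = FALSE)
  }
  if (!is.numeric(volume_fraction) || volume_fraction <= 0 ||
      volume_fraction >= 1) {
    stop("volume_fraction must lie in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(polydispersity) || polydispersity < 0) {
    stop("polydispersity must be >= 0", call. = FALSE)
  }
  structure(list(shape = shape, geometry = geometry[req],
                 sld_core = sld_core, sld_shell = sld_shell,
                 sld_solvent = sld_solvent,
                 volume_fraction = volume_fraction,
                 polydispersity = polydispersity),
            class = "particle_model")
}

#' @export
print.particle_model <- function(x, ...) {
  cat("<particle_model> ", x$shape, "\n", sep = "")
  cat("  geometry [A]: ",
      paste(names(x$geometry), signif(unlist(x$geometry), 4),
            sep = " = ", collapse = ", "), "\n", sep = "")
  slds <- c(core = x$sld_core, shell = x$sld_shell, solvent = x$sld_solvent)
  cat("  SLD [1e-6 A^-2]: ",
      paste(names(slds), signif(slds, 4), sep = " = ", collapse = ", "),
      "\n", sep = "")
  cat("  volume fraction: ", signif(x$volume_fraction, 3),
      ", polydispersity: ", signif(x$polydispersity, 3), "\n", sep = "")
  invisible(x)
}

# primary dimension carrying the polydispersity, per shape
.primary_dim <- function(shape) {
  switch(shape,
    sphere = , core_shell_sphere = , hollow_sphere = "radius",
    cylinder = , core_shell_cylinder = "radius",
    prolate_ellipsoid = , oblate_ellipsoid = ,
    core_shell_prolate = , core_shell_oblate = "r_equatorial")
}
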