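# Shared fixtures: scaled-down instrument configurations (same physics,
# ~1/6 of the q points of the full benchtop grids) and lazily built,
# cached synthetic datasets so that several test files can reuse them.

coarse_xeuss <- function() {
  instrument_config("XeussCoarse", sample_detector_distance = 1800,
                    wavelength = 1.54, q_min = 0.85e-4, q_max = 0.1511,
                    delta_q = (0.1511 - 0.85e-4) / 149, beam_fwhm = 0.0016,
                    transmitted_flux = 3.43e6, counting_time = 1200,
                    n_points = 150)
}

coarse_nano <- function() {
  instrument_config("NanoCoarse", sample_detector_distance = 938,
                    wavelength = 1.54, q_min = 3.74e-4, q_max = 0.4527,
                    delta_q = (0.4527 - 3.74e-4) / 101, beam_fwhm = 0.0024,
                    transmitted_flux = 7.22e6, counting_time = 1200,
                    n_points = 102)
}

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# 9-class mixed-configuration dataset on the coarse grids
fixture_ds_mix <- function() {
  fixture("ds_mix", function() {
    build_dataset("DS_mix", n_per_class = 10, seed = 3,
                  configs = list(coarse_xeuss(), coarse_nano()))
  })
}

# 9-class single-configuration dataset, the workhorse of classifier tests
fixture_ds_x <- function() {
  fixture("ds_x", function() {
    build_dataset("DS_X", n_per_class = 12, seed = 5,
                  configs = list(coarse_xeuss()))
  })
}

# hand-made dataset whose single informative bin encodes the label exactly
fixture_ds_perfect <- function(n_per_class = 10, noise = 0) {
  J <- 24
  classes <- c("sphere", "cylinder", "oblate_ellipsoid")
  labels <- rep(classes, each = n_per_class)
  x <- matrix(1, length(labels), J)
  x[, 3] <- as.integer(factor(labels, levels = classes)) +
    stats::rnorm(length(labels), 0, noise)
  q <- matrix(rep(seq(1e-3, 0.1, length.out = J), length(labels)),
              length(labels), J, byrow = TRUE)
  structure(list(intensities = x, q = q,
                 labels = factor(labels, levels = classes),
                 config_ids = rep("toy", length(labels)),
                 params = data.frame(shape = labels),
                 models = vector("list", length(labels)),
                 provenance = list(seed = 0, build = "toy")),
            class = "saxs_dataset")
}
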