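# Guinier analysis, invariant features, PCA and the CNN encoder.

test_that("Guinier fit recovers the sphere gyration radius within 2%", {
  cfg <- builtin_config("Xeuss1800HR")
  q <- config_q_grid(cfg)
  m <- particle_model("sphere", list(radius = 100), sld_core = 14,
                      sld_solvent = 9.47, volume_fraction = 1e-3)
  cv <- simulate_measurement(m, cfg, noiseless = TRUE)
  gf <- estimate_rg(cv)
  expect_lt(abs(gf$rg / (sqrt(3 / 5) * 100) - 1), 0.02)
  expect_gt(gf$r2, 0.99)
})

test_that("a pure Guinier curve is recovered essentially exactly", {
  q <- seq(5e-4, 0.05, length.out = 300)
  rg <- 50
  cv <- saxs_curve(q, 3.2 * exp(-q^2 * rg^2 / 3))
  gf <- estimate_rg(cv)
  expect_equal(gf$rg, rg, tolerance = 1e-6)
  expect_equal(gf$i0, 3.2, tolerance = 1e-6)
})

test_that("cylinders longer than the measurable range have no gyration radius", {
  cfg <- coarse_xeuss()
  m <- particle_model("cylinder", list(radius = 30, length = 10000),
                      sld_core = 14, sld_solvent = 9.47,
                      volume_fraction = 1e-3)
  cv <- simulate_measurement(m, cfg, noiseless = TRUE)
  expect_error(estimate_rg(cv), "measurable range|Guinier")
})

test_that("invariant features have length n+1 and are monotone in qRg", {
  cfg <- coarse_xeuss()
  m <- particle_model("sphere", list(radius = 150), sld_core = 14,
                      sld_solvent = 9.47, volume_fraction = 1e-3)
  cv <- simulate_measurement(m, cfg, noiseless = TRUE)
  fe <- franke_features(cv, n_points = 5)
  expect_length(fe, 6)
  expect_named(fe, c("V1", "V2", "V3", "V4", "V5", "Rg"))
  # the denominator invariant grows with x, so V' cannot increase
  expect_true(all(diff(fe[1:5]) <= 1e-12))
  fe200 <- franke_features(cv, n_points = 200)
  expect_length(fe200, 201)
})

test_that("invariant features are scale invariant and size-collapsed", {
  cfg <- coarse_xeuss()
  mk <- function(r, phi) {
    m <- particle_model("sphere", list(radius = r), sld_core = 14,
                        sld_solvent = 9.47, volume_fraction = phi)
    simulate_measurement(m, cfg, noiseless = TRUE)
  }
  c1 <- mk(150, 1e-3)
  c2 <- saxs_curve(c1$q, 10 * c1$intensity)
  f1 <- franke_features(c1); f2 <- franke_features(c2)
  expect_equal(f1, f2, tolerance = 1e-6)   # intensity scale cancels
  # different radius: V' profile identical in qRg, Rg feature differs
  c3 <- mk(220, 1e-3)
  f3 <- franke_features(c3)
  expect_lt(max(abs(f3[1:5] / f1[1:5] - 1)), 0.01)
  expect_gt(abs(f3["Rg"] - f1["Rg"]), 10)
})

test_that("PCA keeps at least the requested variance and finds exact subspaces", {
  set.seed(20)
  basis <- matrix(rnorm(3 * 40), 3, 40)
  scores <- matrix(rnorm(60 * 3), 60, 3) %*% basis  # exact rank 3
  p <- pca_fit(scores, 0.90)
  expect_equal(p$k, 3)
  x <- matrix(rnorm(80 * 30), 80, 30)
  p2 <- pca_fit(x, 0.90)
  expect_gte(p2$explained, 0.90)
  z <- pca_transform(p2, x)
  expect_equal(ncol(z), p2$k)
})

test_that("the CNN encoder has latent dimension 256 and the pinned parameter count", {
  m <- cnn_build(150, input_mode = "I", n_classes = 9, seed = 1)
  # conv(1->64,k7)+conv(64->64,k7)+conv(64->64,k7)+conv(64->256,k7)+dense
  pinned <- (1 * 7 + 1) * 64 + (64 * 7 + 1) * 64 + (64 * 7 + 1) * 64 +
    (64 * 7 + 1) * 256 + (256 + 1) * 9
  expect_equal(cnn_param_count(m), pinned)
  expect_equal(pinned, 175241)
  m2 <- cnn_build(150, input_mode = "Iq", n_classes = 9, seed = 1)
  expect_equal(cnn_param_count(m2), pinned + 7 * 64)  # second input channel
  set.seed(2)
  x <- matrix(rnorm(4 * 150), 4, 150)
  enc <- cnn_encode(m, x)
  expect_equal(dim(enc), c(4, 256))
  p <- cnn_predict_proba(m, x)
  expect_equal(dim(p), c(4, 9))
  expect_equal(rowSums(p), rep(1, 4), tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_error(cnn_build(80), ">= 120")
})

test_that("the CNN separates a trivially separable two-class problem", {
  cfg <- coarse_xeuss()
  q <- config_q_grid(cfg)
  set.seed(33)
  curves <- lapply(seq_len(200), function(i) {
    if (i <= 100) {
      m <- particle_model("sphere", list(radius = runif(1, 80, 300)),
                         sld_core = 14, sld_solvent = 9.47,
                         volume_fraction = 10^runif(1, -4, -2))
    } else {
      m <- particle_model("cylinder",
                          list(radius = runif(1, 15, 40),
                               length = runif(1, 2000, 8000)),
                          sld_core = 14, sld_solvent = 9.47,
                          volume_fraction = 10^runif(1, -4, -2))
    }
    simulate_measurement(m, cfg, seed = 500 + i)$intensity
  })
  x <- do.call(rbind, curves)
  labels <- factor(rep(c("sphere", "cylinder"), each = 100))
  pp <- pp_fit(pp_pipeline("best"), x, q)
  tx <- pp_apply(pp, x, q)
  m <- cnn_build(ncol(tx$x), n_classes = 2, seed = 7)
  m <- cnn_train(m, tx$x, labels, epochs = 20, batch = 32, seed = 7)
  expect_true(all(diff(stats::filter(m$loss, rep(1 / 3, 3))[2:18]) < 0.5))
  p <- cnn_predict_proba(m, tx$x)
  acc <- mean(colnames(p)[max.col(p)] == labels)
  expect_gte(acc, 0.95)
})

test_that("CNN training is seed-reproducible and the encoder matches the head", {
  set.seed(5)
  x <- matrix(rnorm(60 * 150), 60, 150)
  y <- factor(rep(c("a", "b", "c"), each = 20))
  t1 <- cnn_train(cnn_build(150, n_classes = 3, seed = 9), x, y,
                  epochs = 4, batch = 16, seed = 2)
  t2 <- cnn_train(cnn_build(150, n_classes = 3, seed = 9), x, y,
                  epochs = 4, batch = 16, seed = 2)
  expect_identical(t1$loss, t2$loss)
  expect_identical(t1$params, t2$params)
  # detached encoder + softmax head reproduce the full network output
  enc <- cnn_encode(t1, x)
  logits <- enc %*% t(t1$params$W5) +
    matrix(t1$params$b5, nrow(enc), 3, byrow = TRUE)
  probs <- exp(logits - apply(logits, 1, max))
  probs <- probs / rowSums(probs)
  expect_equal(unname(cnn_predict_proba(t1, x)), probs, tolerance = 1e-10)
})

test_that("representation dispatcher fits and transforms all kinds", {
  ds <- fixture_ds_x()
  pp <- pp_fit(pp_pipeline("best"), ds$intensities, ds$q)
  tx <- pp_apply(pp, ds$intensities, ds$q)
  rid <- rep_fit("identity", tx$x)
  expect_identical(rep_transform(rid, tx$x), tx$x)
  expect_equal(rep_dim(rid), ncol(tx$x))
  rp <- rep_fit("pca90", tx$x)
  expect_equal(ncol(rep_transform(rp, tx$x)), rep_dim(rp))
  expect_error(rep_fit("cnn", tx$x), "requires labels")
})
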